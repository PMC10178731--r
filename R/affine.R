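# 2D homogeneous affine transforms between section frames.
#
# Convention (used everywhere in the package): a transform is the FORWARD map
# from the moving image's frame into the fixed image's frame. It acts on
# homogeneous (col, row, 1) coordinates, 0-based, about the image centre.
# Resampling uses the inverse (pull) map, so warp_affine(moving, T) renders
# the moving image in the fixed frame.

#' Create a 2D affine transform
#'
#' @param matrix 3x3 homogeneous matrix acting on (col, row, 1) about the
#'   image centre; bottom row must be (0, 0, 1) and the matrix invertible.
#' @param moving,fixed optional slice indices recording which pair the
#'   transform registers (provenance).
#' @return an object of class `affine2d`.
#' @export
affine_transform <- function(matrix = diag(3), moving = NA_integer_,
                             fixed = NA_integer_) {
  matrix <- unname(as.matrix(matrix))
  stopifnot(all(dim(matrix) == c(3, 3)))
  if (max(abs(matrix[3, ] - c(0, 0, 1))) > 1e-12)
    stop("affine matrix bottom row must be (0, 0, 1)")
  if (abs(det(matrix)) < 1e-12) stop("affine matrix is singular")
  structure(list(matrix = matrix, moving = as.integer(moving),
                 fixed = as.integer(fixed)),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d> moving %s -> fixed %s\n",
              ifelse(is.na(x$moving), "?", x$moving),
              ifelse(is.na(x$fixed), "?", x$fixed)))
  print(round(x$matrix, 6))
  invisible(x)
}

# Build the forward matrix from pose parameters, about centre (cx, cy) in
# (col, row) coordinates: rotate theta (radians, counter-clockwise in the
# col/row plane), shear, anisotropic scale, then translate by (tx, ty) px.
affine_from_params <- function(tx = 0, ty = 0, theta = 0, log_sx = 0,
                               log_sy = 0, shear = 0, center = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Sh <- matrix(c(1, 0, shear, 1), 2, 2)
  Sc <- diag(c(exp(log_sx), exp(log_sy)))
  A <- R %*% Sh %*% Sc
  M <- diag(3)
  M[1:2, 1:2] <- A
  M[1:2, 3] <- c(tx, ty) + center - A %*% center
  M
}

transform_center <- function(shape) c((shape[2] - 1) / 2, (shape[1] - 1) / 2)

# Apply a 3x3 forward matrix to n x 2 (col, row) points.
apply_affine_points <- function(M, pts) {
  p <- cbind(pts, 1) %*% t(M)
  p[, 1:2, drop = FALSE]
}

# Mean displacement of the image corners under T1 relative to T2 (px);
# the registration-accuracy measure used throughout the tests.
corner_error <- function(T1, T2, shape) {
  corners <- rbind(c(0, 0), c(shape[2] - 1, 0), c(0, shape[1] - 1),
                   c(shape[2] - 1, shape[1] - 1))
  m1 <- if (inherits(T1, "affine2d")) T1$matrix else T1
  m2 <- if (inherits(T2, "affine2d")) T2$matrix else T2
  d <- apply_affine_points(m1, corners) - apply_affine_points(m2, corners)
  mean(sqrt(rowSums(d^2)))
}

#' Warp an image or mask by an affine transform
#'
#' Renders the moving input in the fixed frame defined by the forward
#' transform, using bilinear resampling of the inverse map. Out-of-bounds
#' samples are filled with 0. In `"mask"` mode the bilinear result is
#' thresholded at 0.5 so the output stays binary.
#'
#' @param img 2D matrix (image or binary mask).
#' @param transform `affine2d` object or bare 3x3 matrix (forward map).
#' @param mode `"image"` (bilinear) or `"mask"` (bilinear then threshold).
#' @return warped matrix of the same shape.
#' @export
warp_affine <- function(img, transform, mode = c("image", "mask")) {
  mode <- match.arg(mode)
  M <- if (inherits(transform, "affine2d")) transform$matrix else transform
  if (abs(det(M)) < 1e-12) stop("affine matrix is singular")
  maps <- affine_pull_maps(M, dim(img))
  out <- cpp_sample_bilinear(img, maps$mapr, maps$mapc)
  if (mode == "mask") out <- matrix(as.numeric(out >= 0.5), nrow(img), ncol(img))
  out
}

# Pull maps (source row/col per output pixel) for a forward matrix.
affine_pull_maps <- function(M, shape) {
  Mi <- solve(M)
  H <- shape[1]; W <- shape[2]
  cols <- matrix(rep(0:(W - 1), each = H), H, W)
  rows <- matrix(rep(0:(H - 1), times = W), H, W)
  sc <- Mi[1, 1] * cols + Mi[1, 2] * rows + Mi[1, 3]
  sr <- Mi[2, 1] * cols + Mi[2, 2] * rows + Mi[2, 3]
  list(mapr = sr, mapc = sc)
}

# Validity mask of a warp: TRUE where the pull sample lies inside the source.
affine_valid_mask <- function(M, shape) {
  maps <- affine_pull_maps(M, shape)
  maps$mapr >= 0 & maps$mapr <= shape[1] - 1 &
    maps$mapc >= 0 & maps$mapc <= shape[2] - 1
}

#' Compose pairwise transforms into a single reference frame
#'
#' Pairwise transforms must register each slice to its predecessor
#' (provenance `(moving = i, fixed = i - 1)` for `i = 1..n-1`). The absolute
#' transform of slice `i` maps its coordinates into the reference slice's
#' frame by chaining pairwise maps; the reference slice gets the identity.
#'
#' @param pairwise list of `affine2d`, ordered by moving index.
#' @param reference_index 0-based index of the anchor slice (default 0).
#' @return list of `affine2d`, one absolute transform per slice.
#' @export
compose_to_reference <- function(pairwise, reference_index = 0) {
  n <- length(pairwise) + 1
  mov <- vapply(pairwise, function(t) t$moving, integer(1))
  fix <- vapply(pairwise, function(t) t$fixed, integer(1))
  if (any(is.na(mov)) || any(is.na(fix)) ||
      !all(mov == seq_len(n - 1)) || !all(fix == seq_len(n - 1) - 1L))
    stop("pairwise transform chain is broken: provenance must be (i, i-1) for i = 1..n-1")
  if (reference_index < 0 || reference_index >= n)
    stop("reference_index out of range")
  abs_t <- vector("list", n)
  r <- reference_index + 1L  # 1-based
  abs_t[[r]] <- diag(3)
  if (r < n) for (i in (r + 1L):n)
    abs_t[[i]] <- abs_t[[i - 1L]] %*% pairwise[[i - 1L]]$matrix
  if (r > 1) for (i in (r - 1L):1L)
    abs_t[[i]] <- abs_t[[i + 1L]] %*% solve(pairwise[[i]]$matrix)
  lapply(seq_len(n), function(i)
    affine_transform(abs_t[[i]], moving = i - 1L, fixed = reference_index))
}
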