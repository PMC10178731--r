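# Deformable registration primitives: per-pixel flow fields, local NCC loss,
# flow smoothness loss, and the backward-sampling warp.
#
# Warp convention (used for every flow in the package): backward sampling —
# the output pixel at (i, j) pulls from the input at
# (i + d_row(i, j), j + d_col(i, j)). Flows therefore live in the frame of
# the image they produce.

#' Create a flow field
#'
#' @param displacement (H, W, 2) array; channel 1 is d_row, channel 2 d_col,
#'   in pixels. Values must be finite.
#' @param moving,fixed optional provenance indices.
#' @param direction `"forward"` (moving -> fixed) or `"backward"`.
#' @return a `flow_field` object.
#' @export
flow_field <- function(displacement, moving = NA_integer_,
                       fixed = NA_integer_,
                       direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(length(dim(displacement)) == 3, dim(displacement)[3] == 2)
  if (!all(is.finite(displacement))) stop("flow displacements must be finite")
  structure(list(displacement = displacement, moving = as.integer(moving),
                 fixed = as.integer(fixed), direction = direction),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  d <- dim(x$displacement)
  mag <- sqrt(x$displacement[, , 1]^2 + x$displacement[, , 2]^2)
  cat(sprintf("<flow_field> %dx%d px, %s, mean |u| = %.3f px\n",
              d[1], d[2], x$direction, mean(mag)))
  invisible(x)
}

zero_flow <- function(H, W) flow_field(array(0, c(H, W, 2)))

flow_array <- function(flow) {
  if (inherits(flow, "flow_field")) flow$displacement else flow
}

#' Warp an image or mask by a flow field
#'
#' Backward-sampling warp with bilinear interpolation; out-of-bounds samples
#' fill with 0. Masks are thresholded at 0.5 after interpolation.
#'
#' @param img (H, W) matrix.
#' @param flow `flow_field` or (H, W, 2) array matching the image shape.
#' @param mode `"image"` or `"mask"`.
#' @return warped matrix, same shape.
#' @export
apply_flow <- function(img, flow, mode = c("image", "mask")) {
  mode <- match.arg(mode)
  u <- flow_array(flow)
  if (!all(dim(u)[1:2] == dim(img)))
    stop("flow shape does not match the image")
  H <- nrow(img); W <- ncol(img)
  rows <- matrix(rep(0:(H - 1), times = W), H, W)
  cols <- matrix(rep(0:(W - 1), each = H), H, W)
  out <- cpp_sample_bilinear(img, rows + u[, , 1], cols + u[, , 2])
  if (mode == "mask") out <- matrix(as.numeric(out >= 0.5), H, W)
  out
}

# Approximate inverse warp: find v with u(x + v(x)) ~ -v(x) by fixed-point
# iteration, then warp by v. Used to undo recorded elastic perturbations.
invert_flow <- function(flow, n_iter = 8) {
  u <- flow_array(flow)
  v <- -u
  for (it in seq_len(n_iter)) {
    ur <- apply_flow(u[, , 1], flow_field(v))
    uc <- apply_flow(u[, , 2], flow_field(v))
    v[, , 1] <- -ur
    v[, , 2] <- -uc
  }
  flow_field(v)
}

#' Local normalized cross-correlation loss
#'
#' `1 - mean(NCC_w)` over square windows of side `window` centred at every
#' pixel (windows truncated at the borders), so 0 is a perfect match and the
#' value is bounded in \[0, 2\]. Window variances are epsilon-regularised, so
#' constant windows contribute a correlation of 0.
#'
#' @param warped,fixed equal-shaped matrices.
#' @param window odd window side >= 3.
#' @return scalar loss.
#' @export
ncc_loss <- function(warped, fixed, window = 9) {
  1 - mean(local_ncc(warped, fixed, window))
}

ncc_eps <- 1e-10

# Per-pixel local NCC map (truncated windows at the borders).
local_ncc <- function(a, b, window = 9) {
  stopifnot(all(dim(a) == dim(b)), window >= 3, window %% 2 == 1)
  n <- box_count(nrow(a), ncol(a), window)
  sa <- box_sum(a, window); sb <- box_sum(b, window)
  saa <- box_sum(a * a, window); sbb <- box_sum(b * b, window)
  sab <- box_sum(a * b, window)
  cov <- sab - sa * sb / n
  va <- saa - sa^2 / n
  vb <- sbb - sb^2 / n
  cov / sqrt(pmax(va * vb, 0) + ncc_eps)
}

# Gradient of ncc_loss with respect to `a` (the warped image), derived from
# the windowed-sum formulation; all terms reduce to box filters.
local_ncc_grad <- function(a, b, window = 9) {
  n <- box_count(nrow(a), ncol(a), window)
  sa <- box_sum(a, window); sb <- box_sum(b, window)
  saa <- box_sum(a * a, window); sbb <- box_sum(b * b, window)
  sab <- box_sum(a * b, window)
  abar <- sa / n; bbar <- sb / n
  cov <- sab - sa * sb / n
  va <- saa - sa^2 / n
  vb <- sbb - sb^2 / n
  D <- sqrt(pmax(va * vb, 0) + ncc_eps)
  alpha <- 1 / D
  beta <- cov * vb / D^3
  # d loss/d a_q = -(1/N) sum_{p: q in W_p} [ alpha_p (b_q - bbar_p)
  #                                           - beta_p (a_q - abar_p) ]
  N <- length(a)
  g <- b * box_sum(alpha, window) - box_sum(alpha * bbar, window) -
    (a * box_sum(beta, window) - box_sum(beta * abar, window))
  -g / N
}

#' Flow smoothness loss
#'
#' Mean squared forward difference of the displacement field: the squared
#' row- and column-differences of both components, each averaged over the
#' interior differences and summed. A constant flow scores 0; a unit ramp
#' (`d_col = col`) scores exactly 1.
#'
#' @param flow `flow_field` or (H, W, 2) array.
#' @return non-negative scalar.
#' @export
gradient_loss <- function(flow) {
  u <- flow_array(flow)
  dr1 <- u[-1, , 1] - u[-nrow(u), , 1]
  dc1 <- u[, -1, 1] - u[, -ncol(u), 1]
  dr2 <- u[-1, , 2] - u[-nrow(u), , 2]
  dc2 <- u[, -1, 2] - u[, -ncol(u), 2]
  mean(dr1^2) + mean(dc1^2) + mean(dr2^2) + mean(dc2^2)
}

# Gradient of gradient_loss with respect to the flow array.
gradient_loss_grad <- function(u) {
  g <- array(0, dim(u))
  H <- dim(u)[1]; W <- dim(u)[2]
  for (ch in 1:2) {
    dr <- u[-1, , ch] - u[-H, , ch]
    dc <- u[, -1, ch] - u[, -W, ch]
    gr <- matrix(0, H, W); gc <- matrix(0, H, W)
    gr[-1, ] <- gr[-1, ] + 2 * dr / length(dr)
    gr[-H, ] <- gr[-H, ] - 2 * dr / length(dr)
    gc[, -1] <- gc[, -1] + 2 * dc / length(dc)
    gc[, -W] <- gc[, -W] - 2 * dc / length(dc)
    g[, , ch] <- gr + gc
  }
  g
}
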