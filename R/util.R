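# Shared internal helpers: image conversions, local sums, seeds.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Convert an RGB array to luminance
#'
#' Standard Rec. 601 luminance weights (0.299, 0.587, 0.114).
#'
#' @param img numeric array of shape (H, W, 3) with values in \[0, 1\], or an
#'   (H, W) matrix which is returned unchanged.
#' @return an (H, W) matrix of grayscale intensities.
#' @export
luminance <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Local (truncated) box sums over a w x w window, same-size output.
# Windows are clipped at the borders; pair with box_count() for means.
box_sum <- function(m, w) {
  h <- w %/% 2
  H <- nrow(m); W <- ncol(m)
  cs <- matrix(0, H + 1, W + 1)
  cs[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(0, seq_len(H) - h - 1); r2 <- pmin(H, seq_len(H) + h)
  c1 <- pmax(0, seq_len(W) - h - 1); c2 <- pmin(W, seq_len(W) + h)
  cs[r2 + 1, c2 + 1, drop = FALSE] - cs[r1 + 1, c2 + 1, drop = FALSE] -
    cs[r2 + 1, c1 + 1, drop = FALSE] + cs[r1 + 1, c1 + 1, drop = FALSE]
}

box_count <- function(H, W, w) {
  box_sum(matrix(1, H, W), w)
}

# Separable gaussian smoothing with replicated borders (kernel renormalised
# at the edges), used for pyramid antialiasing and elastic field generation.
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  conv1 <- function(x) {
    n <- length(k)
    num <- stats::filter(c(rep(0, r), x, rep(0, r)), k, sides = 2)
    den <- stats::filter(c(rep(0, r), rep(1, length(x)), rep(0, r)), k, sides = 2)
    (num / den)[(r + 1):(r + length(x))]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

# Bilinear resize of a matrix to target (rows, cols).
resize_matrix <- function(m, H2, W2) {
  EBImage::resize(m, w = H2, h = W2)
}

downsample2 <- function(m) {
  resize_matrix(smooth_gaussian(m, 0.8), max(1L, nrow(m) %/% 2L),
                max(1L, ncol(m) %/% 2L))
}

# Deterministic per-stage seed derivation from one pipeline seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483629L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

is_binary <- function(x) all(x %in% c(0, 1))

as_binary_array <- function(x) {
  y <- array(as.integer(x != 0), dim = dim(x) %||% length(x))
  y
}
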