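# Coarse registration: mutual information of intensity histograms, maximised
# over an image pyramid.

#' Mutual information of two images (bits)
#'
#' MI of the joint intensity histogram: `H(A) + H(B) - H(A,B)` with marginal
#' and joint entropies in bits. Each image is binned over its own intensity
#' range; a constant image carries no information and returns 0 (with a
#' message).
#'
#' @param a,b equal-shaped numeric matrices.
#' @param bins number of histogram bins per image (>= 2).
#' @return non-negative scalar, bits.
#' @export
mutual_information <- function(a, b, bins = 64) {
  stopifnot(all(dim(a) == dim(b)), bins >= 2)
  ia <- bin_index(a, bins)
  ib <- bin_index(b, bins)
  if (is.null(ia) || is.null(ib)) {
    message("mutual_information: constant image, MI = 0")
    return(0)
  }
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins) / length(ia)
  pa <- tabulate(ia, nbins = bins) / length(ia)
  pb <- tabulate(ib, nbins = bins) / length(ib)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  max(0, ent(pa) + ent(pb) - ent(joint))
}

bin_index <- function(x, bins) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(NULL)
  pmin(bins, 1L + as.integer(floor((x - rng[1]) / (rng[2] - rng[1]) * bins)))
}

#' Pyramid configuration for coarse affine registration
#'
#' @param n_levels number of pyramid levels (capped so that the coarsest
#'   level keeps a short side of at least 32 px).
#' @param bins histogram bins for the MI objective.
#' @param max_iter optimiser iteration budget per pyramid level.
#' @param tol relative convergence tolerance of the simplex refinement.
#' @param model `"affine"` (6 dof) or `"rigid"` (rotation + translation).
#' @param init_search_frac half-width of the integer translation grid search
#'   at the coarsest level, as a fraction of image width.
#' @param roi optional pre-registration crop, `c(row0, row1, col0, col1)`
#'   (0-based, inclusive); default uses the full frame.
#' @return a `pyramid_config` list.
#' @export
pyramid_config <- function(n_levels = 4, bins = 32, max_iter = 300,
                           tol = 1e-9, model = c("affine", "rigid"),
                           init_search_frac = 0.12, roi = NULL) {
  model <- match.arg(model)
  stopifnot(n_levels >= 1, bins >= 2, max_iter >= 1)
  structure(list(n_levels = as.integer(n_levels), bins = as.integer(bins),
                 max_iter = as.integer(max_iter), tol = tol, model = model,
                 init_search_frac = init_search_frac, roi = roi),
            class = "pyramid_config")
}

# Negative MI of fixed vs affine-warped moving, restricted to the pixels
# whose pull sample lies inside the moving image (avoids rewarding the
# zero-filled border).
neg_mi_objective <- function(par, fixed, moving, center, bins, model) {
  M <- params_to_matrix(par, center, model)
  if (abs(det(M)) < 1e-9) return(1e6)
  w <- warp_affine(moving, M, mode = "image")
  v <- affine_valid_mask(M, dim(fixed))
  # an alignment explaining less than half the frame is not acceptable:
  # shrinking the overlap region can spuriously inflate MI
  if (sum(v) < 0.5 * length(v)) return(1e6)
  -mutual_information(matrix(fixed[v]), matrix(w[v]), bins = bins)
}

params_to_matrix <- function(par, center, model) {
  if (model == "rigid")
    affine_from_params(par[1], par[2], par[3], center = center)
  else
    affine_from_params(par[1], par[2], par[3], par[4], par[5], par[6],
                       center = center)
}

matrix_to_params <- function(M, center, model) {
  # Decompose forward matrix about centre into pose parameters.
  A <- M[1:2, 1:2]
  t <- M[1:2, 3] - center + A %*% center
  theta <- atan2(A[2, 1], A[1, 1])
  if (model == "rigid") return(c(t[1], t[2], theta))
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  ShSc <- solve(R, A)  # shear %*% scale
  sx <- ShSc[1, 1] - ShSc[1, 2] * ShSc[2, 1] / ShSc[2, 2]
  sy <- ShSc[2, 2]
  shear <- ShSc[1, 2] / ShSc[2, 2]
  c(t[1], t[2], theta, log(max(sx, 1e-6)), log(max(sy, 1e-6)), shear)
}

#' Register a pair of sections with an affine transform by maximising MI
#'
#' Coarse-to-fine search over a gaussian image pyramid. The coarsest level is
#' seeded by an exhaustive integer-translation scan, then refined by
#' Nelder-Mead simplex minimisation of negative MI (rigid first, then the
#' full model), warm-starting each finer level from the level above.
#'
#' @param fixed,moving equal-shaped grayscale matrices.
#' @param config `pyramid_config()`.
#' @return `affine2d` forward map (moving -> fixed frame) with attributes
#'   `mi` (MI at the optimum), `mi_identity` (MI at the identity) and
#'   `converged` (FALSE if the search failed to beat the identity, in which
#'   case the identity is returned with a warning).
#' @export
register_pair_affine <- function(fixed, moving, config = pyramid_config()) {
  stopifnot(all(dim(fixed) == dim(moving)))
  if (!is.null(config$roi)) {
    r <- config$roi
    fixed <- fixed[(r[1] + 1):(r[2] + 1), (r[3] + 1):(r[4] + 1)]
    moving <- moving[(r[1] + 1):(r[2] + 1), (r[3] + 1):(r[4] + 1)]
  }
  n_levels <- config$n_levels
  while (n_levels > 1 && min(dim(fixed)) / 2^(n_levels - 1) < 32)
    n_levels <- n_levels - 1L
  pyr_f <- list(fixed)
  pyr_m <- list(moving)
  if (n_levels > 1) for (l in 2:n_levels) {
    pyr_f[[l]] <- downsample2(pyr_f[[l - 1]])
    pyr_m[[l]] <- downsample2(pyr_m[[l - 1]])
  }
  npar <- if (config$model == "rigid") 3L else 6L
  par <- rep(0, npar)

  for (l in n_levels:1) {
    f <- pyr_f[[l]]; m <- pyr_m[[l]]
    center <- transform_center(dim(f))
    obj <- function(p) neg_mi_objective(p, f, m, center, config$bins, config$model)
    if (l == n_levels) {
      # joint rotation + translation scan to escape the capture range of the
      # simplex (MI on weakly structured images has local maxima under
      # rotations of a few degrees)
      rad <- max(2L, as.integer(round(config$init_search_frac * ncol(f))))
      grid <- expand.grid(tx = seq(-rad, rad, by = 2), ty = seq(-rad, rad, by = 2),
                          th = seq(-12, 12, by = 3) * pi / 180)
      vals <- vapply(seq_len(nrow(grid)), function(i) {
        p <- par; p[1] <- grid$tx[i]; p[2] <- grid$ty[i]; p[3] <- grid$th[i]
        obj(p)
      }, numeric(1))
      best <- which.min(vals)
      par[1] <- grid$tx[best]; par[2] <- grid$ty[best]; par[3] <- grid$th[best]
    } else {
      par[1] <- par[1] * 2; par[2] <- par[2] * 2
    }
    scales <- c(1, 1, 0.01, rep(0.01, npar - 3))[seq_len(npar)]
    # rigid stage stabilises rotation before the full model is released
    if (config$model == "affine") {
      r3 <- stats::optim(par[1:3], function(p) obj(c(p, par[4:6])),
                         method = "Nelder-Mead",
                         control = list(maxit = config$max_iter,
                                        reltol = config$tol,
                                        parscale = scales[1:3]))
      par[1:3] <- r3$par
    }
    res <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = config$max_iter,
                                       reltol = config$tol,
                                       parscale = scales))
    par <- res$par
    if (l == 1) {
      # restart the simplex once at the finest level: Nelder-Mead can stall
      # on MI plateaus and a fresh simplex around the optimum recovers
      res2 <- stats::optim(par, obj, method = "Nelder-Mead",
                           control = list(maxit = config$max_iter,
                                          reltol = config$tol,
                                          parscale = scales / 10))
      if (res2$value < res$value) par <- res2$par
    }
  }

  center <- transform_center(dim(fixed))
  M <- params_to_matrix(par, center, config$model)
  mi_opt <- -neg_mi_objective(par, fixed, moving, center, config$bins, config$model)
  mi_id <- mutual_information(fixed, moving, bins = config$bins)
  converged <- mi_opt >= mi_id - 1e-9
  if (!converged) {
    warning("register_pair_affine: optimum did not beat the identity; returning identity")
    M <- diag(3)
    mi_opt <- mi_id
  }
  out <- affine_transform(M)
  attr(out, "mi") <- mi_opt
  attr(out, "mi_identity") <- mi_id
  attr(out, "converged") <- converged
  out
}
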