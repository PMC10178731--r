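# Unsupervised deformable finetuning: a convolutional encoder-decoder
# predicts a per-pixel flow for each consecutive (coarsely registered) pair,
# trained through the bilinear warp with a bidirectional local-NCC loss and
# a flow-gradient smoothness penalty. One shared network is trained on all
# pairs of a stack.

#' Fine-registration configuration
#'
#' @param window local NCC window side (odd, >= 3).
#' @param lambda weight of the flow smoothness (gradient) loss, >= 0.
#' @param epochs passes over the consecutive pairs.
#' @param max_lr one-cycle peak learning rate.
#' @param base_channels encoder width.
#' @param weight_decay AdamW weight decay.
#' @param seed RNG seed.
#' @return a `fine_config` list.
#' @export
fine_config <- function(window = 9, lambda = 1, epochs = 30, max_lr = 1e-2,
                        base_channels = 8, weight_decay = 1e-5, seed = 1) {
  stopifnot(window >= 3, window %% 2 == 1, lambda >= 0, epochs >= 1)
  structure(list(window = window, lambda = lambda, epochs = epochs,
                 max_lr = max_lr, base_channels = base_channels,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "fine_config")
}

# grayscale slice list from whatever the caller holds
as_gray_list <- function(stack) {
  if (inherits(stack, "section_stack")) return(lapply(stack$images, luminance))
  if (is.list(stack)) return(lapply(stack, luminance))
  stop("expected a section_stack or list of images")
}

# loss + flow gradient for one direction of one pair
flow_loss_and_grad <- function(u, moving, fixed, window, lambda) {
  H <- nrow(moving); W <- ncol(moving)
  rows <- matrix(rep(0:(H - 1), times = W), H, W)
  cols <- matrix(rep(0:(W - 1), each = H), H, W)
  mapr <- rows + u[, , 1]; mapc <- cols + u[, , 2]
  warped <- cpp_sample_bilinear(moving, mapr, mapc)
  l_ncc <- ncc_loss(warped, fixed, window)
  gw <- local_ncc_grad(warped, fixed, window)
  gmap <- cpp_sample_bilinear_grad(moving, mapr, mapc, gw)
  gu <- array(0, dim(u))
  gu[, , 1] <- gmap$gr
  gu[, , 2] <- gmap$gc
  l_smooth <- gradient_loss(u)
  gu <- gu + lambda * gradient_loss_grad(u)
  list(loss = l_ncc + lambda * l_smooth, ncc = l_ncc, smooth = l_smooth,
       gu = gu)
}

add_grads <- function(a, b) {
  for (ly in names(a)) for (pn in names(a[[ly]]))
    a[[ly]][[pn]] <- a[[ly]][[pn]] + b[[ly]][[pn]]
  a
}

#' Train the deformable registration network on a stack
#'
#' For every consecutive pair (fixed = slice i, moving = slice i+1) the
#' network maps the channel-stacked pair to a forward flow; swapping the
#' inputs yields the backward flow. The training loss is
#' `ncc(warp(moving, f_fwd), fixed) + ncc(warp(fixed, f_bwd), moving)
#'  + lambda * (grad(f_fwd) + grad(f_bwd))`.
#' The flow head is initialised near zero, so training starts from the
#' identity deformation.
#'
#' @param coarse_stack [section_stack()] or list of grayscale matrices
#'   (>= 2 slices, already coarsely aligned); height and width must be
#'   divisible by 4.
#' @param config a [fine_config()].
#' @return a `flownet_model`: list with `params`, `config`, `history`
#'   (per-epoch mean loss).
#' @export
train_fine_registration <- function(coarse_stack, config = fine_config()) {
  imgs <- as_gray_list(coarse_stack)
  n <- length(imgs)
  stopifnot(n >= 2)
  d <- dim(imgs[[1]])
  if (any(d %% 4 != 0)) stop("slice height/width must be divisible by 4")
  with_seed(config$seed, {
    params <- unet_init(2, 2, base = config$base_channels, head_sd = 1e-4)
    opt <- adamw_init(params)
    total_steps <- config$epochs * (n - 1)
    step <- 0
    history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      for (i in sample.int(n - 1)) {
        step <- step + 1
        fixed <- imgs[[i]]; moving <- imgs[[i + 1]]
        # forward direction
        fwd <- unet_forward(params, concat_ch(array(moving, c(d, 1)),
                                              array(fixed, c(d, 1))))
        lf <- flow_loss_and_grad(fwd$out, moving, fixed, config$window,
                                 config$lambda)
        gf <- unet_backward(params, fwd$cache, lf$gu)
        # backward direction (swapped inputs, shared weights)
        bwd <- unet_forward(params, concat_ch(array(fixed, c(d, 1)),
                                              array(moving, c(d, 1))))
        lb <- flow_loss_and_grad(bwd$out, fixed, moving, config$window,
                                 config$lambda)
        gb <- unet_backward(params, bwd$cache, lb$gu)
        loss <- lf$loss + lb$loss
        if (!is.finite(loss))
          stop(sprintf("fine registration diverged at epoch %d (non-finite loss)", ep))
        ep_loss <- ep_loss + loss
        lr <- onecycle_lr(step, total_steps, config$max_lr)
        upd <- adamw_step(params, add_grads(gf, gb), opt, lr,
                          weight_decay = config$weight_decay)
        params <- upd$params
        opt <- upd$opt
      }
      history[ep] <- ep_loss / (n - 1)
    }
    structure(list(params = params, config = config, history = history,
                   shape = d), class = "flownet_model")
  })
}

#' @export
print.flownet_model <- function(x, ...) {
  cat(sprintf("<flownet_model> base %d, %d epochs, final loss %.4f\n",
              x$config$base_channels, length(x$history),
              x$history[length(x$history)]))
  invisible(x)
}

#' Predict the flow aligning a moving slice to a fixed slice
#'
#' @param model a `flownet_model`.
#' @param fixed,moving grayscale matrices of the training shape.
#' @return a [flow_field()] (forward flow; warp the moving slice with it).
#' @export
predict_flow <- function(model, fixed, moving) {
  d <- dim(fixed)
  fwd <- unet_forward(model$params, concat_ch(array(moving, c(d, 1)),
                                              array(fixed, c(d, 1))))
  flow_field(fwd$out, direction = "forward")
}

#' Deformably refine a coarsely registered stack
#'
#' Trains the flow network on the stack (or reuses a supplied model) and
#' applies, for every slice i >= 1, the forward flow predicted against its
#' coarsely aligned predecessor. Slice 0 (the reference) is unchanged.
#'
#' @param coarse_stack [section_stack()] or list of grayscale matrices.
#' @param coarse_masks optional [mask_stack()] aligned 1:1.
#' @param config a [fine_config()].
#' @param model optional pre-trained `flownet_model`.
#' @return list with `images` (refined grayscale list), `masks` (refined
#'   [mask_stack()] or NULL), `flows` (list; NULL for slice 0) and `model`.
#' @export
register_fine_stack <- function(coarse_stack, coarse_masks = NULL,
                                config = fine_config(), model = NULL) {
  imgs <- as_gray_list(coarse_stack)
  n <- length(imgs)
  if (is.null(model)) model <- train_fine_registration(coarse_stack, config)
  flows <- vector("list", n)
  out_imgs <- imgs
  out_masks <- NULL
  for (i in 2:n) {
    # chain order toward the reference: the fixed target is the already
    # refined predecessor, so residual drift does not re-accumulate
    fl <- predict_flow(model, out_imgs[[i - 1]], imgs[[i]])
    fl$moving <- i - 1L
    fl$fixed <- i - 2L
    flows[[i]] <- fl
    out_imgs[[i]] <- apply_flow(imgs[[i]], fl, mode = "image")
  }
  if (!is.null(coarse_masks)) {
    m <- coarse_masks$masks
    for (i in 2:n) m[[i]] <- apply_flow(m[[i]] + 0, flows[[i]], mode = "mask")
    out_masks <- mask_stack(m, coarse_masks$pixel_um,
                            coarse_masks$thickness_um)
  }
  list(images = out_imgs, masks = out_masks, flows = flows, model = model)
}
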