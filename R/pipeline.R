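# End-to-end orchestration: one validated config drives
# segment -> coarse -> fine -> reconstruct -> skeletonize -> evaluate,
# with deterministic per-stage seeds fanned out from one global seed and a
# manifest describing every artifact.

pipeline_defaults <- function() {
  list(
    input = list(dir = NULL,
                 synthetic = list(grid_shape = c(32, 96, 96), n_tubes = 3,
                                  n_bifurcations = 2,
                                  radius_range_um = c(4, 7))),
    stain = "he",
    pixel_um = NULL,
    thickness_um = NULL,
    perturb = list(max_rotation_deg = 8, max_translation_frac = 0.06,
                   max_shear = 0.03, max_scale_dev = 0.03,
                   elastic_amplitude_px = 2, elastic_smoothness_px = 8),
    segmentation = list(patch_size = 32, train_frac = 0.7, max_epochs = 30,
                        base_channels = 8, max_lr = 3e-3, dice_target = 90),
    coarse = list(n_levels = 4, bins = 32),
    fine = list(window = 9, lambda = 1, epochs = 20, max_lr = 1e-2,
                base_channels = 8),
    volume = list(min_voxels = 64),
    out_dir = "vasc3d_out",
    seed = 1
  )
}

#' Build and validate a pipeline configuration
#'
#' Unknown keys raise an error listing them; absent optional fields take
#' documented defaults; `pixel_um` and `thickness_um` are required.
#'
#' @param config named list of overrides over the defaults (possibly
#'   nested).
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  defs <- pipeline_defaults()
  check_keys <- function(given, known, where) {
    unknown <- setdiff(names(given), known)
    if (length(unknown))
      stop(sprintf("unknown config key(s) %s in %s",
                   paste(sprintf("'%s'", unknown), collapse = ", "), where))
  }
  check_keys(config, names(defs), "pipeline config")
  for (sect in c("input", "perturb", "segmentation", "coarse", "fine",
                 "volume"))
    if (!is.null(config[[sect]]))
      check_keys(config[[sect]], names(defs[[sect]]), sect)
  cfg <- modifyList(defs, config)
  # modifyList drops NULL-valued entries; keep the optional input$dir slot
  # so configs round-trip losslessly
  if (!"dir" %in% names(cfg$input)) cfg$input["dir"] <- list(NULL)
  cfg$input <- cfg$input[c("dir", "synthetic")]
  if (is.null(cfg$pixel_um) || !is.numeric(cfg$pixel_um) || cfg$pixel_um <= 0)
    stop("config field 'pixel_um' is required and must be > 0")
  if (is.null(cfg$thickness_um) || cfg$thickness_um <= 0)
    stop("config field 'thickness_um' is required and must be > 0")
  if (!cfg$stain %in% c("he", "dab"))
    stop("config field 'stain' must be 'he' or 'dab'")
  tf <- cfg$segmentation$train_frac
  if (tf <= 0 || tf >= 1)
    stop("config field 'segmentation.train_frac' must lie in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file.
#' @return validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  pipeline_config(yaml::read_yaml(path))
}

#' Write a pipeline configuration to YAML
#'
#' @param config `pipeline_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full reconstruction pipeline
#'
#' Stages, in order: synthetic input generation (or reading a stack from
#' disk), vessel segmentation (U-net trained on the ground-truth masks, plus
#' the block-Otsu baseline), coarse MI-affine registration, deformable
#' refinement, mask alignment + inter-slice interpolation + small-object
#' filtering, skeletonization + branch statistics, and the evaluation
#' report. Every artifact is written under `config$out_dir` together with a
#' `manifest.json` (inputs, config hash, seed, stage outputs).
#'
#' @param config a `pipeline_config` (or bare list of overrides).
#' @param quiet suppress progress messages.
#' @return list with the in-memory artifacts: `stack`, `gt_masks`,
#'   `pred_masks`, `coarse`, `fine`, `volume`, `skeleton`, `branch_stats`,
#'   `report`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  outputs <- list()

  # ---- input ------------------------------------------------------------
  if (!is.null(config$input$dir)) {
    say("reading stack from %s", config$input$dir)
    inp <- read_section_stack(config$input$dir)
    stack <- inp$stack
    gt_masks <- inp$masks
    truth <- NULL
  } else {
    say("generating synthetic stack")
    syn <- config$input$synthetic
    phantom <- generate_phantom(grid_shape = unlist(syn$grid_shape),
                                n_tubes = syn$n_tubes,
                                n_bifurcations = syn$n_bifurcations,
                                radius_range_um = unlist(syn$radius_range_um),
                                spacing_um = rep(config$pixel_um, 3),
                                seed = derive_seed(seed, 1))
    gt_masks <- slice_phantom(phantom, config$thickness_um, config$pixel_um)
    stack <- render_stack(gt_masks, config$stain,
                          seed = derive_seed(seed, 100))
    pspec <- do.call(perturbation_spec,
                     c(config$perturb, list(seed = derive_seed(seed, 2))))
    pert <- perturb_stack(stack, gt_masks, pspec)
    stack <- pert$stack
    gt_masks <- pert$masks
    truth <- pert$truth
    write_section_stack(stack, file.path(out_dir, "input"), gt_masks, truth)
    outputs$input <- "input/"
  }
  if (is.null(gt_masks))
    stop("pipeline requires ground-truth masks (for training and evaluation)")

  # ---- segment ----------------------------------------------------------
  say("stage segment: training U-net + block-Otsu baseline")
  sc <- config$segmentation
  ds <- patches_from_stack(stack, gt_masks, sc$patch_size)
  sp <- split_dataset(ds, sc$train_frac, seed = derive_seed(seed, 3))
  model <- train_unet(sp$train, sp$validation,
                      seg_config(patch_size = sc$patch_size,
                                 train_frac = sc$train_frac,
                                 max_epochs = sc$max_epochs,
                                 base_channels = sc$base_channels,
                                 max_lr = sc$max_lr,
                                 dice_target = sc$dice_target,
                                 seed = derive_seed(seed, 4)))
  pred_masks <- mask_stack(lapply(stack$images, function(im)
    predict_mask(model, im)), stack$pixel_um, stack$thickness_um)
  utils::write.csv(as.data.frame(model$report),
                   file.path(out_dir, "train_report.csv"), row.names = FALSE)
  for (i in seq_along(pred_masks$masks))
    png::writePNG(pred_masks$masks[[i]] + 0,
                  file.path(out_dir, sprintf("pred_mask_%03d.png", i - 1)))
  outputs$segment <- "pred_mask_*.png, train_report.csv"

  # ---- coarse registration ----------------------------------------------
  say("stage coarse: MI-affine registration")
  coarse <- register_stack_coarse(stack, gt_masks,
                                  pyramid_config(n_levels = config$coarse$n_levels,
                                                 bins = config$coarse$bins))
  coarse_pred <- align_masks(pred_masks, coarse$absolute)
  write_transforms_json(coarse$absolute,
                        file.path(out_dir, "transforms.json"))
  outputs$coarse <- "transforms.json"

  # ---- fine registration ------------------------------------------------
  say("stage fine: deformable refinement")
  fc <- config$fine
  fine <- register_fine_stack(coarse$images, coarse$masks,
                              fine_config(window = fc$window,
                                          lambda = fc$lambda,
                                          epochs = fc$epochs,
                                          max_lr = fc$max_lr,
                                          base_channels = fc$base_channels,
                                          seed = derive_seed(seed, 5)))
  fine_pred <- coarse_pred
  for (i in 2:length(fine_pred$masks))
    fine_pred$masks[[i]] <- apply_flow(fine_pred$masks[[i]] + 0,
                                       fine$flows[[i]], mode = "mask")
  write_flows(fine$flows, file.path(out_dir, "flow"))
  outputs$fine <- "flow_*.tif, flow.json"

  # ---- reconstruct -------------------------------------------------------
  say("stage reconstruct: interpolation + filtering")
  vol <- interpolate_stack(fine$masks)
  vol <- filter_small_objects(vol, config$volume$min_voxels)
  export_volume(vol, file.path(out_dir, "volume.nii.gz"), "nifti")
  outputs$reconstruct <- "volume.nii.gz"

  # ---- skeletonize -------------------------------------------------------
  say("stage skeletonize: thinning + branch statistics")
  skel <- skeletonize_3d(vol)
  graph <- build_branch_graph(skel)
  stats <- branch_statistics(graph)
  export_volume(vessel_volume(skel$voxels, skel$spacing_um),
                file.path(out_dir, "skeleton.nii.gz"), "nifti")
  write_branch_csv(graph, file.path(out_dir, "branches.csv"), stats)
  outputs$skeletonize <- "skeleton.nii.gz, branches.csv"

  # ---- evaluate ----------------------------------------------------------
  say("stage evaluate: registration report")
  orig_gray <- lapply(stack$images, luminance)
  report <- registration_report(
    stacks_by_stage = list(original = orig_gray, coarse = coarse$images,
                           fine = fine$images),
    gt_masks = list(original = gt_masks, coarse = coarse$masks,
                    fine = fine$masks),
    pred_masks = list(original = pred_masks, coarse = coarse_pred,
                      fine = fine_pred))
  write_report_csv(report, file.path(out_dir, "report.csv"))
  outputs$evaluate <- "report.csv"

  manifest <- list(
    package = "vasc3d",
    seed = seed,
    config_hash = config_hash(config),
    input = if (!is.null(config$input$dir)) config$input$dir else "synthetic",
    stages = names(outputs),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(stack = stack, gt_masks = gt_masks, pred_masks = pred_masks,
                 model = model, coarse = coarse, fine = fine, volume = vol,
                 skeleton = skel, branch_graph = graph,
                 branch_stats = stats, report = report, manifest = manifest))
}

config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
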