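# End-to-end orchestration: simulate -> indices -> select scale -> segment ->
# classify -> evaluate -> map to cloud -> FVC.

#' Pipeline configuration
#'
#' A single master seed drives every stochastic stage through fixed derived
#' streams: the scene uses `seed`, the forest `seed + 1000`, the train/test
#' split `seed + 2000`.
#'
#' @param scene A [scene_config()] (its own seed is overridden by `seed`).
#' @param weights A [seg_weights()].
#' @param scale `"auto"` (LV-ROC selection over `scales`) or a fixed positive
#'   scale.
#' @param scales Candidate scale grid for `"auto"` (default 10..100 step 10).
#' @param use_terrain Append elevation and slope as extra criterion layers
#'   during scale selection and segmentation (default TRUE).
#' @param index `"auto"` (run [select_index()] on the scene diagnostics) or a
#'   fixed index name; default `"VDVI"`.
#' @param forest A [forest_config()] (its seed is overridden).
#' @param train_fraction Fraction of labeled segments used for training,
#'   stratified by class (default 0.6; the rest is the held-out evaluation
#'   set).
#' @param purge `"auto"` (guarded Otsu VDVI purge), `"none"`, or a numeric
#'   VDVI threshold.
#' @param out_dir Optional directory; when set, every stage artifact is
#'   written there (TIFF rasters with JSON sidecars, CSV tables and cloud,
#'   JSON report).
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(), weights = seg_weights(),
                            scale = "auto", scales = seq(10, 100, by = 10),
                            use_terrain = TRUE, index = "VDVI",
                            forest = forest_config(), train_fraction = 0.6,
                            purge = "auto", out_dir = NULL, seed = 7L) {
  stopifnot(inherits(scene, "scene_config"), inherits(weights, "seg_weights"),
            inherits(forest, "forest_config"))
  if (!identical(scale, "auto") && (!is.numeric(scale) || scale <= 0)) {
    stop("scale must be \"auto\" or a positive number")
  }
  if (!identical(index, "auto")) match_vi(index)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  structure(list(scene = scene, weights = weights, scale = scale,
                 scales = scales, use_terrain = isTRUE(use_terrain),
                 index = index, forest = forest,
                 train_fraction = train_fraction, purge = purge,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# stratified train/test split over labeled segments; deterministic given seed
stratified_split <- function(labels, fraction, seed) {
  set.seed(seed)
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    k <- max(1L, floor(fraction * length(idx)))
    if (k >= length(idx)) k <- length(idx) - 1L  # keep a held-out unit
    if (k < 1L) k <- 1L
    train[sample(idx, k)] <- TRUE
  }
  train
}

#' Run the full FVC pipeline on a synthetic scene
#'
#' Executes, in order: scene simulation, the nine vegetation indices with
#' selection diagnostics, LV-ROC scale selection, multi-resolution
#' segmentation, per-object feature extraction, random-forest training on a
#' stratified subset of truth-labeled segments, whole-scene prediction,
#' held-out accuracy evaluation, transfer of vegetation objects onto the point
#' cloud, the guarded VDVI purge, and the FVC computation. Identical
#' configuration and seed give identical reports.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `fvc_run`: a list with the scene, segmentation,
#'   model, mapping and a `report` list (chosen index, optimal scale, segment
#'   count, accuracy metrics, M, N, Q, point counts, FVC, truth FVC, resolved
#'   parameters).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  scfg <- config$scene
  scfg$seed <- config$seed
  scene <- stage("simulate", generate_scene(scfg))
  truth <- truth_classes(scene)

  vis <- stage("indices", {
    v <- lapply(vi_names(), function(nm) compute_index(scene$rgb, nm))
    names(v) <- vi_names()
    v
  })

  selection <- tryCatch(
    select_index(lapply(vis, class_error_stats, labels = truth),
                 lapply(vis, vi_histogram),
                 observed_ranges = lapply(vis, function(v) {
                   range(v$values, na.rm = TRUE)
                 })),
    error = function(e) structure(list(chosen = NA_character_,
                                       error = conditionMessage(e)),
                                  class = "index_selection"))
  chosen_index <- if (identical(config$index, "auto")) {
    if (is.na(selection$chosen)) {
      stop("pipeline stage 'select-index' failed: ", selection$error,
           call. = FALSE)
    }
    selection$chosen
  } else config$index

  terrain <- if (config$use_terrain) {
    list(elevation = scene$elevation, slope = scene$slope)
  } else NULL

  profile <- NULL
  scale <- config$scale
  if (identical(scale, "auto")) {
    profile <- stage("select-scale",
                     lv_roc(scene$rgb, config$weights, config$scales,
                            terrain_layers = terrain))
    scale <- profile$optimal_scale
  }

  seg <- stage("segment",
               segment(c(as_layer_list(scene$rgb), terrain), config$weights,
                       scale))

  feats <- stage("features",
                 segment_features(seg, scene$rgb, vis[[chosen_index]],
                                  scene$elevation, scene$slope))
  labels <- stage("samples", segment_majority_labels(seg, truth))

  train <- stratified_split(labels, config$train_fraction,
                            config$seed + 2000L)
  fcfg <- config$forest
  fcfg$seed <- config$seed + 1000L
  fx <- feats[, setdiff(names(feats), "id")]
  model <- stage("classify", train_forest(fx[train, ], labels[train], fcfg))
  pred <- stage("classify", predict(model, fx))
  evalres <- stage("evaluate",
                   evaluate_classification(pred[!train], labels[!train],
                                           classes = model$classes))

  polys <- segment_polygons(seg, pred, scene$rgb$transform)
  mapping <- stage("map3d", map_polygons(polys, scene$cloud))
  purged <- stage("map3d", {
    if (identical(config$purge, "none")) mapping
    else purge_bare_points(mapping, threshold = config$purge)
  })
  fvc_pct <- stage("fvc", fvc(purged$vegetation_point_count,
                              purged$total_count))

  report <- list(
    seed = config$seed,
    chosen_index = chosen_index,
    index_ranking = if (!is.null(selection$ranking)) {
      selection$ranking$index
    } else NA_character_,
    scale = scale,
    scale_profile = if (!is.null(profile)) profile$profile else NULL,
    n_segments = nrow(seg$segments),
    overall_accuracy = evalres$accuracy$OA,
    kappa = evalres$accuracy$kappa,
    producer_accuracy = as.list(evalres$accuracy$PA),
    user_accuracy = as.list(evalres$accuracy$UA),
    n_train = sum(train), n_test = sum(!train),
    M = purged$M, N = purged$N, Q = purged$Q,
    purge = purged$purge,
    vegetation_points = purged$vegetation_point_count,
    total_points = purged$total_count,
    fvc_percent = fvc_pct,
    truth_fvc_percent = scene$truth_fvc,
    parameters = list(
      w_color = config$weights$w_color, w_shape = config$weights$w_shape,
      w_smoothness = config$weights$w_smoothness,
      w_compactness = config$weights$w_compactness,
      use_terrain = config$use_terrain,
      train_fraction = config$train_fraction,
      n_estimators = fcfg$n_estimators, max_depth = fcfg$max_depth,
      max_features = fcfg$max_features,
      min_samples_split = fcfg$min_samples_split,
      pixel_size = scfg$pixel_size, rows = scfg$rows, cols = scfg$cols,
      point_density = scfg$point_density)
  )

  run <- structure(list(report = report, scene = scene, indices = vis,
                        selection = selection, segmentation = seg,
                        features = feats, labels = labels, train = train,
                        model = model, predicted = pred,
                        evaluation = evalres, mapping = purged),
                   class = "fvc_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.fvc_run <- function(x, ...) {
  r <- x$report
  cat("<fvc_run>\n")
  cat(sprintf("  index %s | scale %g | %d segments\n",
              r$chosen_index, r$scale, r$n_segments))
  cat(sprintf("  held-out OA %.4f, kappa %.4f (train %d / test %d)\n",
              r$overall_accuracy, r$kappa, r$n_train, r$n_test))
  cat(sprintf("  M %d, N %d, Q %.2f%%\n", r$M, r$N, r$Q))
  cat(sprintf("  FVC %.2f%% (truth %.2f%%), %d / %d points\n",
              r$fvc_percent, r$truth_fvc_percent, r$vegetation_points,
              r$total_points))
  invisible(x)
}
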