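#' Pipeline configuration
#'
#' All tunable parameters of the segmentation flow, with the study defaults:
#' liver display window W150/L80, 11-px feature window and seed patch, 5
#' relaxation iterations, graph-cut balance 0.5, bottleneck threshold 0.60
#' with a 150-degree exterior-angle gate, and 2-px polygonal approximation
#' tolerance.
#'
#' @param window,level display window width / level in HU.
#' @param patch seed patch and feature-window side (odd, px).
#' @param rl_iters relaxation-labeling iterations.
#' @param alpha graph-cut region/boundary balance in `[0, 1]`.
#' @param tb,angle_max,approx_tol post-processing parameters, see
#'   [postprocess_config()].
#' @param mode `"liver"` (full flow) or `"vessel"` (probability + relaxation
#'   + Otsu only).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window = 150, level = 80, patch = 11L,
                            rl_iters = 5L, alpha = 0.5, tb = 0.60,
                            angle_max = 150, approx_tol = 2.0,
                            mode = c("liver", "vessel")) {
  mode <- match.arg(mode)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  structure(list(window = window, level = level, patch = as.integer(patch),
                 rl_iters = as.integer(rl_iters), alpha = alpha, tb = tb,
                 angle_max = angle_max, approx_tol = approx_tol, mode = mode),
            class = "pipeline_config")
}

resolve_volume <- function(vol) {
  if (inherits(vol, "ct_volume")) vol
  else if (is.character(vol)) read_volume(vol)
  else stop("vol must be a ct_volume or a file path")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Segment a liver from a CT volume
#'
#' The full semi-automatic flow from a single seed: display windowing, seed
#' patch statistics and bivariate normal tissue model, whole-volume
#' probability map, relaxation-labeling refinement, then per slice in
#' parallel an exact graph-cut minimisation and an Otsu binarization of the
#' refined map, and finally the anatomical polish (bottleneck removal +
#' adjacent-contour constraint) fusing the two routes. Deterministic: the
#' output is a pure function of (volume, seed, config).
#'
#' @param vol a [ct_volume] or a path readable by [read_volume()].
#' @param seed a [seed_point] (or length-3 vector `x, y, z`, 0-based).
#' @param cfg a [pipeline_config()].
#' @return List with `mask` ([binary_mask]), `prob` (the refined
#'   `probability_map`), and `record` (a run record: config, input digest,
#'   per-stage timings).
#' @export
segment_liver <- function(vol, seed, cfg = pipeline_config()) {
  vol <- resolve_volume(vol)
  if (!inherits(seed, "seed_point")) seed <- seed_point(seed[1], seed[2], seed[3])
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  seed <- pipeline_stage("validate_seed",
                         validate_seed(seed, vol, margin = (cfg$patch - 1L) %/% 2L))
  wv <- pipeline_stage("window", apply_window(vol, cfg$window, cfg$level))
  ff <- pipeline_stage("local_stats",
                       local_stats(wv$intensities[seed$z + 1L, , ], cfg$patch))
  model <- pipeline_stage("fit_mnd", fit_mnd(ff, seed, patch = cfg$patch))
  pm <- pipeline_stage("probability_map",
                       probability_map(wv, model, window = cfg$patch))
  timings["model"] <- tic() - t0; t0 <- tic()
  pm <- pipeline_stage("rl_refine", rl_refine(pm, cfg$rl_iters))
  timings["relaxation"] <- tic() - t0; t0 <- tic()
  if (cfg$mode == "vessel") {
    d <- dim(pm$values)
    lab <- array(0L, d)
    for (z in seq_len(d[1]))
      lab[z, , ] <- binarize_otsu_quiet(pm$values[z, , ])
    timings["otsu"] <- tic() - t0
    mask <- binary_mask(lab, vol$spacing)
    return(list(mask = mask, prob = pm,
                record = run_record(vol, seed, cfg, timings)))
  }
  d <- dim(pm$values)
  lab <- array(0L, d)
  for (z in seq_len(d[1])) {
    lab[z, , ] <- pipeline_stage("graph_cut",
      min_cut_segment(wv$intensities[z, , ], pm$values[z, , ],
                      alpha = cfg$alpha))
  }
  timings["graph_cut"] <- tic() - t0; t0 <- tic()
  pcfg <- postprocess_config(tb = cfg$tb, angle_max = cfg$angle_max,
                             approx_tol = cfg$approx_tol)
  mask <- pipeline_stage("polish", polish_volume(pm, lab, vol, pcfg))
  timings["polish"] <- tic() - t0
  list(mask = mask, prob = pm, record = run_record(vol, seed, cfg, timings))
}

#' Vessel-extraction mode
#'
#' The reduced flow used to pull bright interior vasculature out of the
#' liver: tissue model and probability map seeded on a vessel, relaxation
#' refinement, then Otsu binarization only -- no graph cut and no anatomical
#' constraints (they are shaped for the liver outline, not tubes).
#'
#' @inheritParams segment_liver
#' @param seed_on_vessel a [seed_point] placed on the vessel.
#' @return As [segment_liver()].
#' @export
segment_vessel_mode <- function(vol, seed_on_vessel, cfg = pipeline_config()) {
  cfg$mode <- "vessel"
  segment_liver(vol, seed_on_vessel, cfg)
}

run_record <- function(vol, seed, cfg, timings) {
  list(
    config = unclass(cfg),
    seed = unclass(seed),
    input = list(dim = dim(vol$voxels), spacing = vol$spacing,
                 checksum = volume_checksum(vol)),
    timings_sec = as.list(round(timings, 3)),
    versions = list(liverseg = as.character(utils::packageVersion("liverseg")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )
}

# rolling digest over a coarse but order-sensitive numeric summary of voxels
volume_checksum <- function(vol) {
  v <- vol$voxels
  s <- c(dim(v), sum(v), sum(v * seq_along(v) %% 97), range(v))
  h <- 0
  for (b in utf8ToInt(paste(format(s, digits = 12), collapse = ",")))
    h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Parameter sweep over graph-cut weight and bottleneck angle
#'
#' Re-runs the full pipeline over a grid of `(alpha, angle_max)` values and
#' scores each result against a reference mask, for exploring the two
#' empirical parameters of the method.
#'
#' @inheritParams segment_liver
#' @param reference a [binary_mask] ground truth.
#' @param refs a [reference_errors()] for scoring.
#' @param alphas,angles numeric vectors of values to sweep.
#' @return A data frame with columns `alpha`, `angle`, the five metrics and
#'   `overall` score, one row per grid point.
#' @export
sweep_parameters <- function(vol, seed, reference, refs,
                             alphas = c(0.1, 0.5, 0.9),
                             angles = 150, cfg = pipeline_config()) {
  vol <- resolve_volume(vol)
  grid <- expand.grid(alpha = alphas, angle = angles)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ci <- cfg
    ci$alpha <- grid$alpha[i]
    ci$angle_max <- grid$angle[i]
    res <- segment_liver(vol, seed, ci)
    rep <- evaluate_masks(res$mask, reference, refs)
    data.frame(alpha = grid$alpha[i], angle = grid$angle[i],
               voe_pct = rep$voe_pct, rvd_pct = rep$rvd_pct,
               asd_mm = rep$asd_mm, rmsd_mm = rep$rmsd_mm,
               msd_mm = rep$msd_mm, overall = rep$overall)
  })
  do.call(rbind, rows)
}

#' Write a run record (and optionally a metric report) as JSON
#'
#' @param record a run record from [segment_liver()].
#' @param path output JSON path.
#' @param report optional `metric_report` to embed.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(record, path, report = NULL) {
  out <- record
  if (!is.null(report)) out$metrics <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
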