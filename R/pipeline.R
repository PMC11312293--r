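#' Compare texture methods across imaging modalities
#'
#' For each requested texture method, extracts features from the
#' multispectral and the RGB renditions of a dataset and runs the repeated
#' holdout evaluation on both, producing a method x modality accuracy
#' table.  Both inputs must cover the same class names.
#'
#' @param cubes_ms,cubes_rgb lists of [spectral_cube()]s (e.g. from
#'   [load_manifest_cubes()]), or manifest CSV paths.
#' @param methods texture methods to compare (subset of `lbp`, `riu2_lbp`,
#'   `lpq`, `rlpq`).
#' @param window LPQ window size.
#' @param classifier_config a [classifier_config()].
#' @return data.frame with columns `method`, `multispectral`, `rgb`
#'   (mean accuracies in percent); attribute `reports` holds the full
#'   `evaluation_report`s.
#' @export
run_compare <- function(cubes_ms, cubes_rgb,
                        methods = c("lbp", "riu2_lbp", "lpq", "rlpq"),
                        window = 9L,
                        classifier_config = msiband::classifier_config()) {
  cubes_ms <- as_cube_list(cubes_ms)
  cubes_rgb <- as_cube_list(cubes_rgb)
  cls_ms <- sort(unique(vapply(cubes_ms, `[[`, "", "label")))
  cls_rgb <- sort(unique(vapply(cubes_rgb, `[[`, "", "label")))
  if (!identical(cls_ms, cls_rgb))
    stop("multispectral and RGB datasets must share class names")
  reports <- list()
  rows <- lapply(methods, function(m) {
    cfg <- texture_config(m, window = window)
    rep_ms <- holdout_evaluate(feature_matrix(cubes_ms, cfg),
                               config = classifier_config)
    rep_rgb <- holdout_evaluate(feature_matrix(cubes_rgb, cfg),
                                config = classifier_config)
    reports[[m]] <<- list(multispectral = rep_ms, rgb = rep_rgb)
    data.frame(method = m, multispectral = rep_ms$mean_accuracy,
               rgb = rep_rgb$mean_accuracy)
  })
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}

#' Band-selection threshold x window accuracy sweep
#'
#' The full band-selection experiment: one consensus band selection per MI
#' threshold, then texture features per LPQ window on the retained bands
#' and a repeated holdout evaluation per cell.  The first column
#' (`all_bands`) is the no-selection baseline.  With concatenation fusion
#' the full-band features are computed once per window and column-sliced
#' per selection, so the sweep costs one feature pass per window.
#'
#' @param cubes list of [spectral_cube()]s or a manifest CSV path.
#' @param thresholds MI thresholds in bits, swept high to low.
#' @param windows LPQ window sizes (e.g. `c(3, 5, 7, 9)`).
#' @param method texture method (default `rlpq`, the strongest descriptor
#'   in this family).
#' @param selection_config a [selection_config()]; its `mi_threshold` is
#'   overridden by each swept value.
#' @param hist_config a [histogram_config()].
#' @param classifier_config a [classifier_config()].
#' @return list of class `sweep_result`: `accuracy` (windows x
#'   (1 + thresholds) matrix, percent), `n_retained` (per threshold),
#'   `selections` (list of `band_selection`), `thresholds`, `windows`.
#' @export
run_sweep <- function(cubes, thresholds, windows = c(3L, 5L, 7L, 9L),
                      method = "rlpq",
                      selection_config = msiband::selection_config(),
                      hist_config = histogram_config(),
                      classifier_config = msiband::classifier_config()) {
  cubes <- as_cube_list(cubes)
  if (length(thresholds) == 0L || length(windows) == 0L)
    stop("'thresholds' and 'windows' must be non-empty")
  sweep_tab <- threshold_sweep(cubes, thresholds, selection_config, hist_config)
  selections <- attr(sweep_tab, "selections")
  nb <- n_bands(cubes[[1]])
  acc <- matrix(NA_real_, length(windows), length(thresholds) + 1L,
                dimnames = list(paste0("window_", windows),
                                c("all_bands", paste0("mi_", thresholds))))
  for (wi in seq_along(windows)) {
    cfg <- texture_config(method, window = windows[wi])
    full <- feature_matrix(cubes, cfg)
    acc[wi, 1] <- holdout_evaluate(full, config = classifier_config)$mean_accuracy
    for (ti in seq_along(thresholds)) {
      ret <- selections[[ti]]$retained
      feats <- if (identical(sort(ret), seq_len(nb) - 1L)) full
               else slice_feature_bands(full, ret, nb)
      acc[wi, ti + 1L] <-
        holdout_evaluate(feats, config = classifier_config)$mean_accuracy
    }
  }
  structure(list(accuracy = acc,
                 n_retained = sweep_tab$n_retained,
                 selections = selections,
                 thresholds = thresholds, windows = windows,
                 config_hash = config_hash(list(selection_config, hist_config,
                                                classifier_config, method))),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("band-selection sweep: mean holdout accuracy (%)\n")
  hdr <- c("all", paste0("t=", x$thresholds, " (", x$n_retained, "b)"))
  tab <- round(x$accuracy, 2)
  colnames(tab) <- hdr
  print(tab)
  invisible(x)
}

as_cube_list <- function(x) {
  if (is.character(x) && length(x) == 1L)
    return(load_manifest_cubes(read_manifest(x)))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "spectral_cube"))) return(x)
  stop("expected a manifest path or a list of spectral_cube objects")
}

# ---- run configuration ------------------------------------------------------

#' Read or write a run configuration
#'
#' A run configuration bundles every sub-configuration of a pipeline run
#' in one YAML file (flat keys per section), so an experiment is fully
#' reproducible from its config plus a seed.  Round-trips losslessly:
#' `read_run_config(write_run_config(cfg, f))` rebuilds identical
#' configuration objects.
#'
#' @param path YAML file path.
#' @return a list with elements `hist` ([histogram_config()]), `selection`
#'   ([selection_config()]), `texture` ([texture_config()]), `classifier`
#'   ([classifier_config()]), `synth` ([synth_config()] or NULL), and
#'   scalar `manifest`, `out_dir`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- list(
    manifest = y$manifest,
    out_dir = y$out_dir %||% ".",
    hist = histogram_config(y$hist$n_bins %||% 256L),
    selection = do.call(selection_config, y$selection %||% list()),
    texture = do.call(texture_config, y$texture %||% list()),
    classifier = do.call(classifier_config, y$classifier %||% list()),
    synth = if (!is.null(y$synth)) {
      if (!is.null(y$synth$classes))
        y$synth$classes <- lapply(y$synth$classes, as.list)
      do.call(synth_config, y$synth)
    })
  cfg
}

#' @rdname read_run_config
#' @param config list as returned by `read_run_config`.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  y <- list(manifest = config$manifest, out_dir = config$out_dir,
            hist = strip(config$hist), selection = strip(config$selection),
            texture = strip(config$texture),
            classifier = strip(config$classifier),
            synth = if (!is.null(config$synth)) strip(config$synth))
  yaml::write_yaml(y, path)
  invisible(path)
}
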