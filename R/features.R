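#' Texture descriptor settings
#'
#' @param method one of `"lbp"` (256 bins), `"riu2_lbp"` (10 bins),
#'   `"lpq"` (256), `"rlpq"` (256).  LBP variants use the fixed 8-neighbour
#'   ring (P = 8, R = 1) and ignore `window`.
#' @param window odd LPQ window size (3, 5, 7 or 9; default 9).
#' @param fusion how per-band histograms combine into one cube descriptor:
#'   `"concatenate"` (default; keeps band-specific information, so band
#'   selection shrinks the feature vector proportionally) or `"mean"`.
#' @param decorrelate,rho,n_orientations passed to the LPQ family.
#' @return an object of class `texture_config`.
#' @export
texture_config <- function(method = c("rlpq", "lpq", "lbp", "riu2_lbp"),
                           window = 9L,
                           fusion = c("concatenate", "mean"),
                           decorrelate = TRUE, rho = 0.9,
                           n_orientations = 36L) {
  method <- match.arg(method)
  fusion <- match.arg(fusion)
  if (method %in% c("lpq", "rlpq")) window <- check_window(window)
  structure(list(method = method, window = as.integer(window),
                 fusion = fusion, decorrelate = decorrelate, rho = rho,
                 n_orientations = as.integer(n_orientations)),
            class = "texture_config")
}

histogram_length <- function(config) {
  switch(config$method, lbp = 256L, riu2_lbp = 10L, lpq = 256L, rlpq = 256L)
}

plane_histogram <- function(plane, config) {
  switch(config$method,
    lbp = lbp_histogram(plane, "basic"),
    riu2_lbp = lbp_histogram(plane, "riu2"),
    lpq = lpq_histogram(plane, config$window, config$decorrelate, config$rho),
    rlpq = rlpq_histogram(plane, config$window, config$decorrelate,
                          config$rho, config$n_orientations))
}

#' Texture descriptor of a cube
#'
#' Computes the configured texture histogram on each retained band and
#' fuses them: concatenation in band order (descriptor length =
#' per-band histogram length x number of bands) or the band-wise mean.
#' Each per-band histogram sums to 1 before fusion, so with concatenation
#' the descriptor of a band subset is exactly the corresponding slice of
#' the full descriptor.
#'
#' @param cube a [spectral_cube()].
#' @param config a [texture_config()].
#' @param retained 0-based band indices to use (default: all bands).
#' @return an object of class `texture_descriptor`: list with `values`,
#'   `method`, `window`, `fusion`, `band_ids`, `source_id`.
#' @export
#' @examples
#' cube <- spectral_cube(array(runif(24 * 24 * 3), c(24, 24, 3)))
#' length(cube_features(cube, texture_config("rlpq", 5))$values)  # 3 x 256
cube_features <- function(cube, config = texture_config(), retained = NULL) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(config, "texture_config"))
  if (is.null(retained)) retained <- seq_len(n_bands(cube)) - 1L
  if (length(retained) == 0L) stop("'retained' must name at least one band")
  idx <- as.integer(retained) + 1L
  if (any(idx < 1L | idx > n_bands(cube)))
    stop("retained band indices out of range")
  hists <- lapply(idx, function(i) plane_histogram(cube_band(cube, i), config))
  values <- if (config$fusion == "concatenate") unlist(hists)
            else Reduce(`+`, hists) / length(hists)
  structure(list(values = as.numeric(values), method = config$method,
                 window = config$window, fusion = config$fusion,
                 band_ids = cube$band_ids[idx], source_id = cube$source_id),
            class = "texture_descriptor")
}

#' @export
print.texture_descriptor <- function(x, ...) {
  cat(sprintf("texture_descriptor: %s (window %d), %d values over %d band(s), fusion %s\n",
              x$method, x$window, length(x$values), length(x$band_ids),
              x$fusion))
  invisible(x)
}

#' Feature matrix of a dataset
#'
#' Applies [cube_features()] to every cube and stacks the descriptors into
#' a samples x features matrix, carrying labels and the patch-group keys
#' used for leakage-free splitting.
#'
#' @param cubes list of [spectral_cube()]s.
#' @inheritParams cube_features
#' @return list of class `feature_set`: `x` (matrix), `labels` (character),
#'   `groups` (character, from [patch_group()]), `method`, `window`,
#'   `retained`.
#' @export
feature_matrix <- function(cubes, config = texture_config(), retained = NULL) {
  stopifnot(length(cubes) >= 1L)
  descs <- lapply(cubes, cube_features, config = config, retained = retained)
  x <- do.call(rbind, lapply(descs, `[[`, "values"))
  structure(list(x = x,
                 labels = vapply(cubes, `[[`, "", "label"),
                 groups = patch_group(vapply(cubes, `[[`, "", "source_id")),
                 method = config$method, window = config$window,
                 retained = retained),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d samples x %d features (%s, window %d)\n",
              nrow(x$x), ncol(x$x), x$method, x$window))
  cat("  classes:", paste(unique(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Slice a concatenated feature set down to a band subset
#'
#' For concatenation fusion the per-band histograms occupy contiguous
#' column blocks, so restricting to the retained bands is a column slice —
#' no recomputation needed.
#'
#' @param features a `feature_set` built with concatenation over
#'   `n_bands_total` bands.
#' @param retained 0-based band indices to keep.
#' @param n_bands_total number of bands the features were computed over.
#' @return a new `feature_set`.
#' @export
slice_feature_bands <- function(features, retained, n_bands_total) {
  L <- ncol(features$x) / n_bands_total
  if (L != round(L))
    stop("feature width is not a multiple of the band count")
  cols <- as.vector(vapply(as.integer(retained),
                           function(b) b * L + seq_len(L), numeric(L)))
  out <- features
  out$x <- features$x[, cols, drop = FALSE]
  out$retained <- as.integer(retained)
  out
}

#' Write a feature set to CSV
#'
#' One row per sample: descriptor columns `f1..fP`, then `label` and
#' `group` provenance columns; the header is preceded by comment lines
#' recording method, window and config hash.
#'
#' @param features a `feature_set`.
#' @param path output CSV path.
#' @export
write_features_csv <- function(features, path) {
  df <- as.data.frame(features$x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$label <- features$labels
  df$group <- features$groups
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# method=", features$method, " window=", features$window),
    paste0("# config_hash=", config_hash(features[c("method", "window", "retained")]))),
    con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df))
  structure(list(x = as.matrix(df[, fcols, drop = FALSE]),
                 labels = df$label, groups = df$group,
                 method = NA_character_, window = NA_integer_,
                 retained = NULL),
            class = "feature_set")
}
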