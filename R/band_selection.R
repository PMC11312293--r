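#' Settings for consensus band selection
#'
#' @param mi_threshold redundancy threshold in bits: an adjacent pair with
#'   MI at or above it is considered redundant.  Typical values for 8-bit
#'   quantization lie between 2.5 and 3.25 bits.
#' @param n_sample_images number of images drawn (stratified by class) to
#'   vote on the selection; about 25 suffices when the MI profiles of a
#'   dataset share their shape.
#' @param majority_fraction a band is retained if it is selected in strictly
#'   more than this fraction of the sample images (default 0.5: strict
#'   majority).
#' @param seed integer seed for the stratified draw of sample images.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(mi_threshold = 3, n_sample_images = 25L,
                             majority_fraction = 0.5, seed = 1L) {
  if (mi_threshold <= 0) stop("'mi_threshold' must be positive")
  if (majority_fraction <= 0 || majority_fraction > 1)
    stop("'majority_fraction' must be in (0, 1]")
  structure(list(mi_threshold = mi_threshold,
                 n_sample_images = as.integer(n_sample_images),
                 majority_fraction = majority_fraction,
                 seed = as.integer(seed)),
            class = "selection_config")
}

# Decompose the adjacent-pair MI sequence into maximal redundancy runs.
# Pair (i, i+1) with MI >= threshold joins band i+1 to the run containing
# band i (opening a run at i if none is active); MI < threshold closes the
# run.  Returns a list of integer vectors of 0-based band indices; bands in
# no run are singletons handled by the caller.
redundancy_runs <- function(mi_values, threshold) {
  runs <- list()
  current <- integer(0)
  for (i in seq_along(mi_values)) {
    if (mi_values[i] >= threshold) {
      if (length(current) == 0L) current <- i - 1L       # open at band i-1 (0-based)
      current <- c(current, i)                           # band i joins (0-based i)
    } else if (length(current) > 0L) {
      runs[[length(runs) + 1L]] <- current
      current <- integer(0)
    }
  }
  if (length(current) > 0L) runs[[length(runs) + 1L]] <- current
  runs
}

#' Select informative bands of a single cube
#'
#' The adjacent-band MI profile is scanned left to right.  Pairs with MI at
#' or above the threshold accrete into maximal *redundancy runs* of
#' consecutive bands; from each run exactly one band survives — the one
#' with the highest entropy (ties broken toward the lower band index).
#' Bands flanked only by low-MI pairs belong to no run and are retained
#' unconditionally, so every band is either retained or dropped as the
#' non-maximal member of exactly one run.
#'
#' @param cube a [spectral_cube()] with at least 2 bands.
#' @param mi_threshold redundancy threshold in bits.
#' @param config a [histogram_config()]; the same quantization is used for
#'   the MI values and the tie-breaking entropies.
#' @param profile optionally, a precomputed [adjacent_mi_profile()] of the
#'   cube (must carry entropies), to avoid recomputation.
#' @return integer vector of retained 0-based band indices, strictly
#'   increasing.
#' @export
#' @examples
#' px <- array(runif(32 * 32 * 4), c(32, 32, 4))
#' px[, , 3] <- px[, , 2]  # band 2 duplicated as band 3
#' select_bands_single(spectral_cube(px), mi_threshold = 2)
select_bands_single <- function(cube, mi_threshold,
                                config = histogram_config(),
                                profile = NULL) {
  if (is.null(profile)) {
    stopifnot(inherits(cube, "spectral_cube"))
    if (n_bands(cube) < 2L) stop("band selection needs at least 2 bands")
    profile <- adjacent_mi_profile(cube, config)
  }
  nb <- length(profile$entropies)
  runs <- redundancy_runs(profile$values, mi_threshold)
  dropped <- logical(nb)
  for (run in runs) {
    ent <- profile$entropies[run + 1L]
    keep <- run[which.max(ent)]        # which.max ties -> first = lowest index
    dropped[setdiff(run, keep) + 1L] <- TRUE
  }
  which(!dropped) - 1L
}

#' Consensus band selection over a sample of images
#'
#' Runs [select_bands_single()] on a seeded, class-stratified sample of
#' cubes and retains the bands selected in strictly more than
#' `majority_fraction` of them.  Selection is meant as an offline,
#' once-per-acquisition-setup procedure: the retained index list is then
#' reused for every new image from the same setup.
#'
#' @param cubes list of [spectral_cube()]s (all with the same band count).
#' @param config a [selection_config()].
#' @param hist_config a [histogram_config()].
#' @return an object of class `band_selection`: list with `retained`
#'   (sorted 0-based indices), `votes` (sample-image x band logical
#'   matrix), `threshold`, `per_image_entropy` (sample-image x band),
#'   `sample_ids`, `config` and `hist_config`.
#' @export
select_bands_consensus <- function(cubes, config = selection_config(),
                                   hist_config = histogram_config()) {
  if (length(cubes) == 0L) stop("empty cube list")
  nb <- n_bands(cubes[[1]])
  if (any(vapply(cubes, n_bands, integer(1)) != nb))
    stop("all cubes must share the same band count")
  idx <- stratified_sample(vapply(cubes, `[[`, "", "label"),
                           min(config$n_sample_images, length(cubes)),
                           config$seed)
  votes <- matrix(FALSE, length(idx), nb)
  ents <- matrix(NA_real_, length(idx), nb)
  for (k in seq_along(idx)) {
    prof <- adjacent_mi_profile(cubes[[idx[k]]], hist_config)
    sel <- select_bands_single(mi_threshold = config$mi_threshold,
                               profile = prof)
    votes[k, sel + 1L] <- TRUE
    ents[k, ] <- prof$entropies
  }
  share <- colMeans(votes)
  retained <- which(share > config$majority_fraction) - 1L
  if (length(retained) == 0L)   # degenerate: fall back to most-voted band
    retained <- which.max(share) - 1L
  structure(list(retained = as.integer(retained), votes = votes,
                 threshold = config$mi_threshold,
                 per_image_entropy = ents,
                 sample_ids = vapply(cubes[idx], `[[`, "", "source_id"),
                 config = config, hist_config = hist_config),
            class = "band_selection")
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("band_selection: %d of %d bands retained (MI threshold %.3g bits)\n",
              length(x$retained), ncol(x$votes), x$threshold))
  cat("  retained:", paste(x$retained, collapse = " "), "\n")
  cat(sprintf("  consensus over %d sample image(s), majority fraction %.2f\n",
              nrow(x$votes), x$config$majority_fraction))
  invisible(x)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Seeded class-stratified sample of n indices, spreading the draw as evenly
# as possible over classes (unlabeled data counts as one class).
stratified_sample <- function(labels, n, seed) {
  labels[!nzchar(labels)] <- "<unlabeled>"
  classes <- unique(labels)
  by_class <- split(seq_along(labels), factor(labels, levels = classes))
  pools <- with_seed(seed,
    lapply(by_class, function(ix) ix[sample.int(length(ix))]))
  take <- integer(0)
  round_i <- 1L
  while (length(take) < n && round_i <= max(lengths(pools))) {
    for (p in seq_along(pools)) {
      if (length(take) >= n) break
      if (round_i <= length(pools[[p]])) take <- c(take, pools[[p]][round_i])
    }
    round_i <- round_i + 1L
  }
  sort(take[seq_len(min(n, length(take)))])
}

#' Sweep the consensus selection over several MI thresholds
#'
#' One consensus selection per threshold.  Because lowering the threshold
#' can only grow redundancy runs, the number of retained bands is
#' non-increasing as the threshold decreases.
#'
#' @inheritParams select_bands_consensus
#' @param thresholds numeric vector of MI thresholds in bits.
#' @return data.frame with one row per threshold: `threshold`,
#'   `n_retained`, and `retained` (space-separated 0-based indices);
#'   attribute `selections` holds the full `band_selection` objects.
#' @export
threshold_sweep <- function(cubes, thresholds, config = selection_config(),
                            hist_config = histogram_config()) {
  if (length(thresholds) == 0L) stop("'thresholds' must be non-empty")
  sels <- lapply(thresholds, function(t) {
    cfg <- config
    cfg$mi_threshold <- t
    select_bands_consensus(cubes, cfg, hist_config)
  })
  out <- data.frame(
    threshold = thresholds,
    n_retained = vapply(sels, function(s) length(s$retained), integer(1)),
    retained = vapply(sels, function(s) paste(s$retained, collapse = " "), ""))
  attr(out, "selections") <- sels
  out
}

#' Persist or reload a band selection as JSON
#'
#' The JSON records the retained indices, threshold, vote matrix, seed and
#' a hash of the configuration, so an offline selection can be audited and
#' reused for all later images from the same acquisition setup.
#'
#' @param selection a `band_selection`.
#' @param path JSON file path.
#' @export
write_band_selection <- function(selection, path) {
  obj <- list(retained = selection$retained,
              threshold = selection$threshold,
              majority_fraction = selection$config$majority_fraction,
              seed = selection$config$seed,
              n_bins = selection$hist_config$n_bins,
              sample_ids = selection$sample_ids,
              votes = selection$votes,
              config_hash = config_hash(selection$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_band_selection
#' @return `read_band_selection`: list with at least `retained` and
#'   `threshold`.
#' @export
read_band_selection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$retained <- as.integer(obj$retained)
  obj
}

#' Hash a configuration object
#'
#' MD5 of the canonical serialized form; embedded in every output artifact
#' so that results can be traced to the exact configuration that produced
#' them.
#'
#' @param x any R object.
#' @return 32-character hex string.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
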