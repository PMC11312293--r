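#' Histogram quantization settings for entropy and mutual information
#'
#' All entropies and mutual informations in the package are estimated from
#' discrete histograms of quantized intensities.  Each band is independently
#' min-max rescaled to `0 .. n_bins - 1` and floored to integer bins, and
#' logarithms are base 2, so every quantity is in bits and bounded by
#' `log2(n_bins)` (8 bits at the 256-bin default, which is the dominant
#' convention in MI-based image registration and makes thresholds in the
#' 2.5-3.25 bit range meaningful).  A constant band occupies a single bin
#' and has zero entropy.
#'
#' @param n_bins number of histogram bins per band (>= 2), default 256.
#' @return an object of class `histogram_config`.
#' @export
histogram_config <- function(n_bins = 256L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("'n_bins' must be an integer >= 2")
  structure(list(n_bins = n_bins, log_base = 2), class = "histogram_config")
}

#' Quantize an intensity plane to integer histogram bins
#'
#' Min-max rescales the plane to `[0, n_bins - 1]` and floors; the maximum
#' value maps to the top bin and a constant plane maps entirely to bin 0.
#'
#' @param band numeric matrix (or vector) of finite intensities.
#' @param config a [histogram_config()].
#' @return integer vector of bin indices in `0 .. n_bins - 1`.
#' @export
quantize_band <- function(band, config = histogram_config()) {
  v <- as.numeric(band)
  if (length(v) == 0L) stop("band is empty")
  if (!all(is.finite(v))) stop("band contains non-finite intensities")
  rng <- range(v)
  if (rng[1] == rng[2]) return(integer(length(v)))   # constant: single bin
  q <- floor((v - rng[1]) / (rng[2] - rng[1]) * config$n_bins)
  as.integer(pmin(q, config$n_bins - 1L))
}

#' Shannon entropy of a quantized intensity plane
#'
#' `H = -sum(p * log2(p))` over occupied bins of the quantized histogram
#' (empty bins contribute nothing).  Bounded by `0 <= H <= log2(n_bins)`.
#'
#' @inheritParams quantize_band
#' @return entropy in bits.
#' @export
#' @examples
#' band_entropy(matrix(0:255, 16, 16))  # all 256 levels once: 8 bits
band_entropy <- function(band, config = histogram_config()) {
  q <- quantize_band(band, config)
  p <- tabulate(q + 1L, nbins = config$n_bins)
  p <- p[p > 0] / length(q)
  -sum(p * log2(p))
}

#' Joint entropy of two co-registered planes
#'
#' Entropy of the 2-D joint histogram (`n_bins` x `n_bins`) of the two
#' quantized planes.  Satisfies
#' `max(H(A), H(B)) <= H(A,B) <= H(A) + H(B)`.
#'
#' @param a,b numeric matrices of identical shape.
#' @inheritParams quantize_band
#' @return joint entropy in bits.
#' @export
joint_entropy <- function(a, b, config = histogram_config()) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("joint entropy requires planes of identical shape")
  qa <- quantize_band(a, config)
  qb <- quantize_band(b, config)
  joint <- qa * config$n_bins + qb
  p <- tabulate(joint + 1L, nbins = config$n_bins^2)
  p <- p[p > 0] / length(qa)
  -sum(p * log2(p))
}

#' Mutual information between two image bands
#'
#' `MI(A,B) = H(A) + H(B) - H(A,B)` on the shared quantization of
#' [histogram_config()].  Symmetric, non-negative (floating residue below 0
#' is clipped), and bounded by `min(H(A), H(B))`.  High MI between adjacent
#' spectral bands flags redundancy; see [select_bands_single()].
#'
#' @inheritParams joint_entropy
#' @return mutual information in bits.
#' @export
mutual_information <- function(a, b, config = histogram_config()) {
  mi <- band_entropy(a, config) + band_entropy(b, config) -
    joint_entropy(a, b, config)
  max(mi, 0)
}

#' Adjacent-band mutual information profile of a cube
#'
#' Computes `MI(band i, band i+1)` for every adjacent pair in spectral
#' order, the curve whose plateaus reveal runs of mutually redundant bands.
#'
#' @param cube a [spectral_cube()] with at least 2 bands.
#' @inheritParams quantize_band
#' @return an object of class `mi_profile`: list with `values` (length
#'   `B - 1`, bits), `entropies` (length `B`, per-band bits), `band_ids`,
#'   and `config`.
#' @export
adjacent_mi_profile <- function(cube, config = histogram_config()) {
  stopifnot(inherits(cube, "spectral_cube"))
  nb <- n_bands(cube)
  if (nb < 2L) stop("MI profile needs a cube with at least 2 bands")
  ent <- vapply(seq_len(nb), function(i) band_entropy(cube_band(cube, i), config),
                numeric(1))
  vals <- vapply(seq_len(nb - 1L), function(i) {
    mutual_information(cube_band(cube, i), cube_band(cube, i + 1L), config)
  }, numeric(1))
  structure(list(values = vals, entropies = ent,
                 band_ids = cube$band_ids, config = config,
                 source_id = cube$source_id),
            class = "mi_profile")
}

#' @export
print.mi_profile <- function(x, ...) {
  cat(sprintf("mi_profile: %d adjacent-band pairs (%d bins, bits)\n",
              length(x$values), x$config$n_bins))
  cat(sprintf("  MI range [%.3f, %.3f], mean %.3f\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.mi_profile <- function(x, ...) {
  data.frame(band_index = seq_along(x$values) - 1L,
             mi_bits = x$values)
}

#' Write an MI profile to CSV
#'
#' Columns `band_index` (0-based, pair i relates band i to band i+1) and
#' `mi_bits`.
#'
#' @param profile an [adjacent_mi_profile()] result.
#' @param path output CSV path.
#' @export
write_mi_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Plot adjacent-band MI profiles
#'
#' Draws the MI-vs-band curve for one or several cubes on a common axis;
#' overlaying several samples shows whether the redundancy structure is
#' stable across the dataset (the basis for selecting bands offline once).
#'
#' @param x an `mi_profile` or list of them.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mi_profile <- function(x, ...) {
  profiles <- if (inherits(x, "mi_profile")) list(x) else x
  vals <- sapply(profiles, `[[`, "values")
  graphics::matplot(seq_len(nrow(as.matrix(vals))), as.matrix(vals),
                    type = "l", lty = 1,
                    xlab = "adjacent band pair (i, i+1)",
                    ylab = "mutual information (bits)", ...)
  invisible(x)
}
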