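#' Construct a spectral cube
#'
#' A `spectral_cube` is the package's central container: a height x width x
#' bands numeric array of intensities together with ordered band identifiers,
#' an optional class label and a provenance string.  Band order is the
#' acquisition's spectral order; mutual information is only meaningful
#' between bands that are adjacent in this order.
#'
#' @param pixels numeric array with dimensions height x width x bands, all
#'   values finite.  A matrix is promoted to a single-band cube.
#' @param band_ids character or numeric identifiers, one per band
#'   (wavelength in nm where known, else a 0-based index).  Defaults to
#'   `0:(B-1)`.
#' @param label class label of the sample, or `""` when unknown.
#' @param source_id provenance string (file of origin, plus a `#p<i>` suffix
#'   after patch splitting).
#' @return an object of class `spectral_cube`.
#' @seealso [split_patches()], [load_cube()], [adjacent_mi_profile()]
#' @export
#' @examples
#' cube <- spectral_cube(array(runif(16 * 16 * 4), c(16, 16, 4)))
#' dim(cube$pixels)
spectral_cube <- function(pixels, band_ids = NULL, label = "",
                          source_id = "<memory>") {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("'pixels' must be a height x width x bands array")
  if (!is.numeric(pixels) || !all(is.finite(pixels)))
    stop("cube intensities must be finite numeric values")
  nb <- dim(pixels)[3L]
  if (nb < 1L) stop("cube must contain at least one band")
  if (is.null(band_ids)) band_ids <- seq_len(nb) - 1L
  if (length(band_ids) != nb)
    stop("'band_ids' must have one entry per band (", nb, ")")
  structure(
    list(pixels = pixels, band_ids = band_ids,
         label = as.character(label), source_id = as.character(source_id)),
    class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("spectral_cube: %d x %d pixels, %d band(s)\n", d[1], d[2], d[3]))
  if (nzchar(x$label)) cat("  label:    ", x$label, "\n")
  cat("  source:   ", x$source_id, "\n")
  cat("  bands:    ", paste(utils::head(x$band_ids, 8), collapse = ", "),
      if (d[3] > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$pixels)

n_bands <- function(cube) dim(cube$pixels)[3L]

#' Extract one band of a cube as a matrix
#'
#' @param cube a [spectral_cube()].
#' @param i 1-based band position.
#' @return the band's height x width intensity matrix.
#' @export
cube_band <- function(cube, i) {
  stopifnot(inherits(cube, "spectral_cube"),
            i >= 1L, i <= n_bands(cube))
  cube$pixels[, , i, drop = TRUE]
}

#' Restrict a cube to a subset of its bands
#'
#' @param cube a [spectral_cube()].
#' @param retained 0-based band indices to keep, in increasing order (the
#'   indexing used by [select_bands_single()] and friends).
#' @return a new `spectral_cube` containing only the retained bands.
#' @export
subset_bands <- function(cube, retained) {
  stopifnot(inherits(cube, "spectral_cube"), length(retained) >= 1L)
  idx <- as.integer(retained) + 1L
  if (any(idx < 1L) || any(idx > n_bands(cube)))
    stop("retained band indices out of range")
  spectral_cube(cube$pixels[, , idx, drop = FALSE],
                band_ids = cube$band_ids[idx],
                label = cube$label, source_id = cube$source_id)
}

#' Split a cube into its four quadrant patches
#'
#' Dataset enlargement: each acquired image is divided into 4 non-overlapping
#' quadrant patches, so a manifest of N images yields 4N samples.  Quadrants
#' are the 2 x 2 tiling of the even-cropped image: an odd trailing row or
#' column is dropped so that patches stay disjoint.
#'
#' @param cube a [spectral_cube()] with height and width at least 2.
#' @return list of 4 `spectral_cube`s (top-left, top-right, bottom-left,
#'   bottom-right), labels inherited and `source_id` suffixed `#p0`..`#p3`.
#' @export
#' @examples
#' cube <- spectral_cube(array(runif(20 * 16 * 3), c(20, 16, 3)))
#' patches <- split_patches(cube)
#' dim(patches[[1]]$pixels)  # 10 x 8 x 3
split_patches <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$pixels)
  if (d[1] < 2L || d[2] < 2L)
    stop("cube must be at least 2 x 2 to split into quadrants")
  h <- d[1] %/% 2L
  w <- d[2] %/% 2L
  rows <- list(1:h, 1:h, h + 1:h, h + 1:h)
  cols <- list(1:w, w + 1:w, 1:w, w + 1:w)
  lapply(0:3, function(k) {
    spectral_cube(cube$pixels[rows[[k + 1L]], cols[[k + 1L]], , drop = FALSE],
                  band_ids = cube$band_ids, label = cube$label,
                  source_id = paste0(cube$source_id, "#p", k))
  })
}

#' Group key of a patch: its originating slide
#'
#' Patches cut from the same acquired image share micro-texture; keeping them
#' in the same train/test fold avoids leakage.  The group key strips the
#' `#p<i>` patch suffix from `source_id`.
#'
#' @param source_ids character vector of cube `source_id`s.
#' @return character vector of group keys.
#' @export
patch_group <- function(source_ids) sub("#p[0-9]+$", "", source_ids)
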