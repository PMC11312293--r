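#' Configuration of the synthetic multispectral dataset generator
#'
#' The generator emulates the statistical structure the band-selection
#' method assumes, without any real acquisition: class-specific
#' micro-texture (an oriented sinusoid plus pixel noise per band),
#' adjacent-band correlation (the per-band noise fields follow an AR(1)
#' chain with coefficient `band_corr`, so neighbouring bands share
#' information and the adjacent-MI profile rises with `band_corr`), and
#' known redundancy (duplicate bands: a source band plus small Gaussian
#' perturbation, inserted immediately after their source in spectral
#' order).  The returned ground-truth map makes recovery checks possible:
#' at an MI threshold between the duplicate-pair MI and the base-pair MI,
#' selection should drop exactly the non-representative duplicates.
#'
#' @param n_images_per_class cubes generated per class.
#' @param classes named list of texture recipes, each a list with
#'   `orientation` (degrees), `frequency` (cycles/pixel) and `noise_sd`
#'   (intensity units; intensities are unit-less floats of order 1,
#'   quantization is deferred to [histogram_config()]).  Default: 4 tissue
#'   grades with distinct orientations and frequencies.
#' @param height,width cube dimensions in pixels.
#' @param n_base_bands number of non-duplicate bands.
#' @param duplicate_groups list of `list(source = <0-based base-band
#'   index>, n_copies = <k>, sd = <perturbation sd>)`.
#' @param band_corr AR(1) correlation `rho` in `[0, 1)` linking the noise
#'   fields of adjacent base bands.
#' @param amplitude sinusoid amplitude shared by all classes.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_images_per_class = 10L,
                         classes = default_class_recipes(),
                         height = 64L, width = 64L,
                         n_base_bands = 9L,
                         duplicate_groups = list(),
                         band_corr = 0.9,
                         amplitude = 0.2,
                         seed = 1L) {
  if (length(classes) == 0L) stop("at least one class recipe is required")
  if (band_corr < 0 || band_corr >= 1) stop("'band_corr' must be in [0, 1)")
  if (n_images_per_class < 1L) stop("'n_images_per_class' must be >= 1")
  for (g in duplicate_groups) {
    if (g$source < 0 || g$source >= n_base_bands)
      stop("duplicate group source out of base-band range")
    if (g$sd < 0) stop("perturbation sd must be >= 0")
  }
  structure(list(n_images_per_class = as.integer(n_images_per_class),
                 classes = classes, height = as.integer(height),
                 width = as.integer(width),
                 n_base_bands = as.integer(n_base_bands),
                 duplicate_groups = duplicate_groups,
                 band_corr = band_corr, amplitude = amplitude,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_class_recipes <- function() {
  list(normal      = list(orientation = 0,   frequency = 0.08, noise_sd = 0.20),
       hyperplastic = list(orientation = 45, frequency = 0.15, noise_sd = 0.20),
       adenoma     = list(orientation = 90,  frequency = 0.25, noise_sd = 0.20),
       carcinoma   = list(orientation = 135, frequency = 0.35, noise_sd = 0.20))
}

#' Generate a labeled synthetic multispectral dataset
#'
#' Every cube is built band by band: base band k carries the class sinusoid
#' (random phase per band per image, so bands share texture statistics but
#' not pixel values) plus its AR(1)-correlated noise field; duplicate bands
#' are their source band plus independent Gaussian perturbation and sit
#' immediately after the source in band order.
#'
#' @param config a [synth_config()].
#' @return list with `cubes` (list of [spectral_cube()]s, labels set) and
#'   `redundancy_map`: list with `groups` (one integer vector of final
#'   0-based band indices per duplicate group, source first),
#'   `duplicate_of` (per final band: 0-based final index of its source, or
#'   `NA` for base bands) and `n_bands`.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(n_images_per_class = 2,
#'   n_base_bands = 4, duplicate_groups = list(list(source = 1, n_copies = 1, sd = 0.01))))
#' length(ds$cubes)      # 8 cubes
#' ds$redundancy_map$groups
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  map <- redundancy_layout(config)
  cubes <- with_seed(config$seed, {
    out <- list()
    for (cl in names(config$classes)) {
      recipe <- config$classes[[cl]]
      for (img in seq_len(config$n_images_per_class)) {
        out[[length(out) + 1L]] <- synth_cube(config, recipe, map, cl,
          sprintf("synthetic://%s/%03d", cl, img))
      }
    }
    out
  })
  list(cubes = cubes, redundancy_map = map)
}

# Final band layout: base bands in order with each duplicate group's copies
# spliced in right after their source band.
redundancy_layout <- function(config) {
  copies_after <- integer(config$n_base_bands)        # copies per base band
  sd_of <- rep(NA_real_, config$n_base_bands)
  for (g in config$duplicate_groups) {
    copies_after[g$source + 1L] <- copies_after[g$source + 1L] +
      as.integer(g$n_copies)
    sd_of[g$source + 1L] <- g$sd
  }
  total <- config$n_base_bands + sum(copies_after)
  base_pos <- integer(config$n_base_bands)            # final index of base k
  duplicate_of <- rep(NA_integer_, total)
  pos <- 0L
  groups <- list()
  for (k in seq_len(config$n_base_bands)) {
    base_pos[k] <- pos
    if (copies_after[k] > 0L) {
      members <- pos + 0:copies_after[k]
      duplicate_of[pos + 1L + seq_len(copies_after[k])] <- pos
      groups[[length(groups) + 1L]] <- members
      pos <- pos + copies_after[k]
    }
    pos <- pos + 1L
  }
  list(groups = groups, duplicate_of = duplicate_of, n_bands = total,
       base_positions = base_pos,
       copies_after = copies_after, copy_sd = sd_of)
}

# One synthetic cube.  Consumes the active RNG stream.
synth_cube <- function(config, recipe, map, label, source_id) {
  h <- config$height; w <- config$width
  theta <- recipe$orientation * pi / 180
  u <- outer(seq_len(h), rep(1, w)) * sin(theta) +
       outer(rep(1, h), seq_len(w)) * cos(theta)
  px <- array(0, c(h, w, map$n_bands))
  noise <- NULL
  rho <- config$band_corr
  for (k in seq_len(config$n_base_bands)) {
    eps <- matrix(stats::rnorm(h * w), h, w)
    noise <- if (is.null(noise)) eps else rho * noise + sqrt(1 - rho^2) * eps
    phase <- stats::runif(1, 0, 2 * pi)
    band <- config$amplitude * sin(2 * pi * recipe$frequency * u + phase) +
      recipe$noise_sd * noise
    pos <- map$base_positions[k]
    px[, , pos + 1L] <- band
    if (map$copies_after[k] > 0L) {
      for (c_i in seq_len(map$copies_after[k])) {
        px[, , pos + 1L + c_i] <- band +
          map$copy_sd[k] * matrix(stats::rnorm(h * w), h, w)
      }
    }
  }
  spectral_cube(px, label = label, source_id = source_id)
}

#' Write a synthetic dataset to disk
#'
#' Cubes go to 16-bit multi-page TIFFs (min-max rescaled per cube), plus a
#' manifest CSV and a ground-truth redundancy JSON, mirroring what the
#' other pipeline stages consume.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- data.frame(path = character(0), label = character(0),
                        modality = character(0))
  for (i in seq_along(dataset$cubes)) {
    cube <- dataset$cubes[[i]]
    f <- file.path(dir, sprintf("cube_%04d.tif", i))
    rng <- range(cube$pixels)
    q <- cube
    q$pixels <- round((cube$pixels - rng[1]) /
                        max(rng[2] - rng[1], .Machine$double.eps) * 65535)
    save_cube(q, f, format = "tiff")
    entries[i, ] <- c(basename(f), cube$label, "multispectral")
  }
  jsonlite::write_json(dataset$redundancy_map[c("groups", "duplicate_of", "n_bands")],
                       file.path(dir, "redundancy_map.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- file.path(dir, "manifest.csv")
  write_manifest(entries, manifest)
  invisible(manifest)
}
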