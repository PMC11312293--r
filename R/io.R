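#' Read an image cube from disk
#'
#' Supported containers: multi-page TIFF (one page per band), ENVI
#' `.hdr`/raw pairs (BSQ/BIL/BIP interleaves are normalized to band-last on
#' load), and PNG/JPEG/TIFF RGB images read as 3-band cubes with band ids
#' `R,G,B`.  Intensities are kept at the file's native integer bit depth
#' where the format exposes it (TIFF, ENVI); PNG/JPEG decoders return
#' normalized values which are rescaled to 0..255.  Quantization for entropy
#' estimation happens later, in [histogram_config()], never at load time.
#'
#' @param path file to read.  For ENVI, either the `.hdr` or the raw file.
#' @param modality `"multispectral"` (TIFF or ENVI cube) or `"rgb"`.
#' @param label optional class label to attach.
#' @return a [spectral_cube()] with bands as the last axis.
#' @export
load_cube <- function(path, modality = c("multispectral", "rgb"), label = "") {
  modality <- match.arg(modality)
  if (!file.exists(path) && !file.exists(envi_header_path(path)))
    stop("cannot read cube: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pixels <-
    if (modality == "rgb") read_rgb_pixels(path, ext)
    else if (ext %in% c("tif", "tiff")) read_tiff_cube(path)
    else read_envi_cube(path)
  band_ids <- if (modality == "rgb") c("R", "G", "B")[seq_len(dim(pixels)[3L])]
              else attr(pixels, "band_ids") %||% (seq_len(dim(pixels)[3L]) - 1L)
  attr(pixels, "band_ids") <- NULL
  spectral_cube(pixels, band_ids = band_ids, label = label, source_id = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_tiff_cube <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("cannot read TIFF ", path, ": ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L, drop = TRUE] else p  # greyscale pages
  })
  sizes <- vapply(pages, function(p) dim(p), integer(2))
  if (any(sizes[1, ] != sizes[1, 1]) || any(sizes[2, ] != sizes[2, 1]))
    stop("format error: TIFF pages of ", path, " differ in size")
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

read_rgb_pixels <- function(path, ext) {
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported RGB format: .", ext))
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

# ---- ENVI hdr + raw ---------------------------------------------------------

envi_header_path <- function(path) {
  if (tolower(tools::file_ext(path)) == "hdr") path else paste0(path, ".hdr")
}

envi_raw_path <- function(path) {
  if (tolower(tools::file_ext(path)) == "hdr")
    sub("\\.hdr$", "", path, ignore.case = TRUE)
  else path
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get <- function(key, required = TRUE) {
    m <- regmatches(txt, regexec(
      paste0("(?im)^\\s*", key, "\\s*=\\s*([^\\n{]+)"), txt, perl = TRUE))[[1]]
    if (length(m) < 2) {
      if (required) stop("ENVI header ", hdr_path, " lacks field '", key, "'")
      return(NULL)
    }
    trimws(m[2])
  }
  list(samples = as.integer(get("samples")),
       lines = as.integer(get("lines")),
       bands = as.integer(get("bands")),
       data_type = as.integer(get("data type")),
       interleave = tolower(get("interleave", required = FALSE) %||% "bsq"),
       byte_order = as.integer(get("byte order", required = FALSE) %||% "0"))
}

envi_type_info <- function(code) {
  # ENVI data type codes -> readBin arguments
  switch(as.character(code),
    "1" = list(what = "integer", size = 1, signed = FALSE),
    "2" = list(what = "integer", size = 2, signed = TRUE),
    "4" = list(what = "double", size = 4, signed = TRUE),
    "5" = list(what = "double", size = 8, signed = TRUE),
    "12" = list(what = "integer", size = 2, signed = FALSE),
    stop("unsupported ENVI data type code: ", code))
}

read_envi_cube <- function(path) {
  hdr <- envi_header_path(path)
  raw <- envi_raw_path(path)
  if (!file.exists(hdr)) stop("cannot read ENVI cube: missing header ", hdr)
  if (!file.exists(raw)) stop("cannot read ENVI cube: missing raw file ", raw)
  h <- parse_envi_header(hdr)
  ti <- envi_type_info(h$data_type)
  n <- h$samples * h$lines * h$bands
  con <- file(raw, "rb"); on.exit(close(con))
  v <- readBin(con, ti$what, n = n, size = ti$size, signed = ti$signed,
               endian = if (h$byte_order == 1) "big" else "little")
  if (length(v) != n)
    stop("format error: ENVI raw file ", raw, " holds ", length(v),
         " values, expected ", n)
  # normalize interleave to (row, col, band)
  arr <- switch(h$interleave,
    bsq = aperm(array(v, c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bil = aperm(array(v, c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bip = aperm(array(v, c(h$bands, h$samples, h$lines)), c(3, 2, 1)),
    stop("unsupported ENVI interleave: ", h$interleave))
  arr
}

write_envi_cube <- function(cube, path) {
  raw <- envi_raw_path(path)
  hdr <- envi_header_path(path)
  d <- dim(cube$pixels)
  writeLines(c(
    "ENVI",
    "description = { msiband spectral cube }",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0"), hdr)
  con <- file(raw, "wb"); on.exit(close(con))
  # BSQ, sample-fastest: transpose each band to row-major
  writeBin(as.numeric(aperm(cube$pixels, c(2, 1, 3))), con, size = 8,
           endian = "little")
  invisible(path)
}

#' Write an image cube to disk
#'
#' TIFF output is one page per band.  The TIFF container here is integer
#' only: integer-valued cubes in 0..255 are written at 8 bits, 0..65535 at
#' 16 bits, both bit-exact on reload; cubes with fractional values are
#' written to ENVI (`data type 5`, float64, BSQ), which round-trips doubles
#' bit-exactly.  Passing `format = "tiff"` for a fractional cube rescales
#' min-max to 16-bit with a warning.
#'
#' @param cube a [spectral_cube()].
#' @param path output path (`.tif` or ENVI raw path; `.hdr` is added).
#' @param format `"tiff"` or `"envi"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
save_cube <- function(cube, path, format = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff" else "envi"
  }
  if (format == "envi") return(invisible(write_envi_cube(cube, path)))
  px <- cube$pixels
  if (any(px != round(px)) || min(px) < 0 || max(px) > 65535) {
    warning("fractional or out-of-range intensities rescaled to 16-bit for TIFF")
    rng <- range(px)
    px <- round((px - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps) * 65535)
  }
  bits <- if (max(px) <= 255) 8L else 16L
  denom <- 2^bits - 1
  pages <- lapply(seq_len(dim(px)[3L]), function(i) px[, , i] / denom)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

# ---- manifests --------------------------------------------------------------

#' Read or write a dataset manifest
#'
#' A manifest is a CSV with columns `path,label,modality` listing every
#' sample image of a dataset.  `read_manifest` validates the modality column
#' and (optionally) that every path exists; `load_manifest_cubes` loads all
#' entries, optionally applying the 4-patch dataset enlargement.
#'
#' @param path manifest CSV path.
#' @param check_paths verify that every listed file exists.
#' @return `read_manifest`: a data.frame with columns `path`, `label`,
#'   `modality` and attribute `class_names` (ordered unique labels).
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "modality")
  if (!all(need %in% names(m)))
    stop("manifest must have columns path,label,modality")
  bad <- !m$modality %in% c("multispectral", "rgb")
  if (any(bad)) stop("unknown modality in manifest: ",
                     paste(unique(m$modality[bad]), collapse = ", "))
  if (check_paths) {
    rel <- file.path(dirname(path), m$path)
    m$path <- ifelse(file.exists(m$path), m$path, rel)
    missing <- !file.exists(m$path)
    if (any(missing)) stop("manifest entries not found: ",
                           paste(utils::head(m$path[missing], 3), collapse = ", "))
  }
  attr(m, "class_names") <- unique(m$label)
  m
}

#' @rdname read_manifest
#' @param manifest data.frame as returned by `read_manifest`.
#' @param split apply [split_patches()] to every loaded cube, quadrupling the
#'   number of samples.
#' @return `load_manifest_cubes`: a list of [spectral_cube()]s.
#' @export
load_manifest_cubes <- function(manifest, split = FALSE) {
  cubes <- mapply(function(p, l, mod) load_cube(p, mod, label = l),
                  manifest$path, manifest$label, manifest$modality,
                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  if (split) cubes <- unlist(lapply(cubes, split_patches), recursive = FALSE)
  cubes
}

#' @rdname read_manifest
#' @param entries data.frame with columns `path`, `label`, `modality`.
#' @export
write_manifest <- function(entries, path) {
  utils::write.csv(entries[, c("path", "label", "modality")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
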