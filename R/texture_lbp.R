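#' Local binary pattern codes and histograms
#'
#' Classic 8-neighbour LBP (P = 8, R = 1): each interior pixel is encoded by
#' thresholding its 8 neighbours against the centre (neighbour >= centre
#' maps to 1, so ties count as 1) and reading the ring as an 8-bit code.
#' The ring is ordered clockwise from the top-left neighbour, with bit k
#' weighted `2^k`:
#'
#' ```
#'   bit 0  bit 1  bit 2
#'   bit 7  centre bit 3
#'   bit 6  bit 5  bit 4
#' ```
#'
#' The `riu2` variant pools codes into 10 rotation-invariant bins: a code
#' whose circular bit string has at most 2 transitions ("uniform") maps to
#' its number of set bits (bins 0..8); all non-uniform codes share bin 9.
#'
#' @param plane numeric matrix, at least 3 x 3.
#' @param variant `"basic"` (256 bins) or `"riu2"` (10 bins).
#' @return `lbp_histogram`: numeric histogram vector summing to 1.
#'   `lbp_codes`: integer matrix of raw codes (0..255) for the interior
#'   pixels.
#' @export
#' @examples
#' h <- lbp_histogram(matrix(runif(64), 8, 8), "riu2")
#' sum(h)  # 1
lbp_histogram <- function(plane, variant = c("basic", "riu2")) {
  variant <- match.arg(variant)
  codes <- lbp_codes(plane)
  if (variant == "basic") {
    h <- tabulate(codes + 1L, nbins = 256L)
  } else {
    h <- tabulate(lbp_riu2_table()[codes + 1L] + 1L, nbins = 10L)
  }
  h / length(codes)
}

#' @rdname lbp_histogram
#' @export
lbp_codes <- function(plane) {
  plane <- as.matrix(plane)
  d <- dim(plane)
  if (d[1] < 3L || d[2] < 3L) stop("LBP needs a plane of at least 3 x 3")
  rows <- 2:(d[1] - 1L)
  cols <- 2:(d[2] - 1L)
  ctr <- plane[rows, cols, drop = FALSE]
  # clockwise from top-left: (dr, dc)
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
               c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  codes <- matrix(0L, length(rows), length(cols))
  for (k in seq_along(offs)) {
    nb <- plane[rows + offs[[k]][1], cols + offs[[k]][2], drop = FALSE]
    codes <- codes + bitwShiftL(1L, k - 1L) * (nb >= ctr)
  }
  codes
}

# riu2 lookup: code -> bin.  Uniform (<= 2 circular 0/1 transitions) codes
# map to their popcount 0..8; the rest to bin 9.  Cached after first use.
lbp_riu2_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t0 <- integer(256)
    for (code in 0:255) {
      bits <- bitwAnd(bitwShiftR(code, 0:7), 1L)
      transitions <- sum(bits != bits[c(2:8, 1)])
      t0[code + 1L] <- if (transitions <= 2L) sum(bits) else 9L
    }
    tab <<- t0
    tab
  }
})
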