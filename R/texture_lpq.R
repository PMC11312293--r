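#' Local phase quantization descriptors
#'
#' LPQ encodes each pixel by the phase of a short-term Fourier transform
#' (STFT) computed with a uniform window x window neighbourhood at the four
#' low, non-zero frequencies `u1 = (a, 0)`, `u2 = (0, a)`, `u3 = (a, a)`,
#' `u4 = (a, -a)` with `a = 1/window`.  The real and imaginary parts of the
#' four coefficients form an 8-vector whose signs (>= 0 maps to 1, bit j
#' weighted `2^(j-1)`, real parts first) give a 0..255 code; the descriptor
#' is the normalized 256-bin code histogram.  Because the DC frequency is
#' excluded and only signs are kept, the descriptor is exactly invariant to
#' affine intensity changes `a * I + b` with `a > 0`, and the phase codes
#' are robust to centrally symmetric blur.
#'
#' With `decorrelate = TRUE` (default) the 8 coefficients are first
#' whitened with the transform derived from an isotropic exponential
#' image-correlation model (coefficient `rho`), which spreads the code
#' distribution over the histogram.
#'
#' The rotation-invariant variant (`rlpq_histogram`) first estimates a
#' characteristic orientation at every pixel from the sign of the imaginary
#' part of STFT coefficients placed on a circle of `n_orientations`
#' frequencies, then extracts the same 8-bit phase code in the rotated
#' frame (window resampled by bilinear interpolation).  Rotating the image
#' rotates the characteristic orientation with it, so the histogram is
#' approximately rotation invariant.
#'
#' Pixels whose (possibly rotated) window does not fit inside the plane are
#' excluded, so histograms are computed over interior pixels only.
#'
#' @param plane numeric matrix, at least `window` in both dimensions
#'   (slightly more for `rlpq`, whose rotated window needs a wider margin).
#' @param window odd window size >= 3 (3, 5, 7 or 9 in typical use;
#'   default 9).
#' @param decorrelate whiten the coefficients before sign quantization.
#' @param rho correlation coefficient of the whitening model.
#' @return normalized 256-bin histogram (`*_histogram`), or the integer
#'   code matrix over valid pixels (`*_codes`).
#' @export
#' @examples
#' p <- matrix(runif(400), 20, 20)
#' h <- lpq_histogram(p, window = 5)
#' all.equal(h, lpq_histogram(2 * p + 3, window = 5))  # gain/offset invariant
lpq_histogram <- function(plane, window = 9L, decorrelate = TRUE, rho = 0.9) {
  codes <- lpq_codes(plane, window, decorrelate, rho)
  tabulate(codes + 1L, nbins = 256L) / length(codes)
}

#' @rdname lpq_histogram
#' @export
lpq_codes <- function(plane, window = 9L, decorrelate = TRUE, rho = 0.9) {
  G <- lpq_coefficients(plane, window)
  quantize_lpq(G, window, decorrelate, rho)
}

#' @rdname lpq_histogram
#' @param n_orientations number of circle frequencies used for the
#'   characteristic-orientation estimate.
#' @param orientation override for the per-pixel orientation: `NULL`
#'   (estimate it), a scalar angle in radians (0 reduces rlpq to plain
#'   LPQ), or a matrix matching the valid region.
#' @export
rlpq_histogram <- function(plane, window = 9L, decorrelate = TRUE, rho = 0.9,
                           n_orientations = 36L, orientation = NULL) {
  codes <- rlpq_codes(plane, window, decorrelate, rho, n_orientations,
                      orientation)
  tabulate(codes + 1L, nbins = 256L) / length(codes)
}

#' @rdname lpq_histogram
#' @export
rlpq_codes <- function(plane, window = 9L, decorrelate = TRUE, rho = 0.9,
                       n_orientations = 36L, orientation = NULL) {
  if (is.null(orientation))
    orientation <- rlpq_orientation(plane, window, n_orientations)
  G <- lpq_coefficients(plane, window, xi = orientation)
  quantize_lpq(G, window, decorrelate, rho)
}

# ---- internals --------------------------------------------------------------

lpq_frequencies <- function(a) {
  list(c(a, 0), c(0, a), c(a, a), c(a, -a))   # (ux, uy); x = columns, y = rows
}

check_window <- function(window) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  window
}

# STFT coefficients at the 4 LPQ frequencies over the valid interior region.
# Returns an 8 x n real matrix (Re F1..F4 then Im F1..F4), columns in
# column-major order of the valid region, with attributes vdim/margin.
#
# xi = 0 (or NULL): axis-aligned window, margin (window-1)/2, integer
# sampling.  Otherwise xi gives per-pixel frame rotations; the window is
# resampled by bilinear interpolation and the margin widens to fit the
# rotated corners.  Both branches share one offset loop so that a forced
# zero orientation reproduces the axis-aligned coefficients exactly.
lpq_coefficients <- function(plane, window, xi = NULL) {
  plane <- as.matrix(plane)
  window <- check_window(window)
  r <- (window - 1L) %/% 2L
  a <- 1 / window
  d <- dim(plane)
  rotated <- !(is.null(xi) || (length(xi) == 1L && xi == 0))
  margin <- if (rotated) as.integer(ceiling(r * sqrt(2) - 1e-9)) + 1L else r
  if (d[1] < 2L * margin + 1L || d[2] < 2L * margin + 1L)
    stop("plane too small for window ", window,
         if (rotated) " (rotated frame)" else "")
  rows <- (margin + 1L):(d[1] - margin)
  cols <- (margin + 1L):(d[2] - margin)
  nv <- length(rows) * length(cols)
  if (rotated) {
    if (length(xi) == 1L) xi <- rep(xi, nv)
    if (length(xi) != nv)
      stop("'orientation' must be scalar or match the valid region (",
           length(rows), " x ", length(cols), ")")
    cosx <- cos(as.vector(xi)); sinx <- sin(as.vector(xi))
    R0 <- rep(rows, times = length(cols))
    C0 <- rep(cols, each = length(rows))
  }
  freqs <- lpq_frequencies(a)
  Fre <- matrix(0, 4L, nv)
  Fim <- matrix(0, 4L, nv)
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (rotated) {
        rr <- R0 + (sinx * dx + cosx * dy)
        cc <- C0 + (cosx * dx - sinx * dy)
        r0 <- floor(rr); c0 <- floor(cc)
        fr <- rr - r0; fc <- cc - c0
        s <- (1 - fr) * (1 - fc) * plane[cbind(r0, c0)] +
             (1 - fr) * fc       * plane[cbind(r0, c0 + 1)] +
             fr       * (1 - fc) * plane[cbind(r0 + 1, c0)] +
             fr       * fc       * plane[cbind(r0 + 1, c0 + 1)]
      } else {
        s <- as.vector(plane[rows + dy, cols + dx, drop = FALSE])
      }
      for (j in 1:4) {
        ph <- -2 * pi * (freqs[[j]][1] * dx + freqs[[j]][2] * dy)
        Fre[j, ] <- Fre[j, ] + cos(ph) * s
        Fim[j, ] <- Fim[j, ] + sin(ph) * s
      }
    }
  }
  structure(rbind(Fre, Fim), vdim = c(length(rows), length(cols)),
            margin = margin,
            scale = mean(abs(plane)) * window^2 + .Machine$double.xmin)
}

# Sign-quantize (optionally whitened) coefficient columns into 8-bit codes.
# Coefficients below a tolerance relative to the window's intensity mass are
# exact zeros up to floating residue (e.g. every coefficient of a constant
# plane) and are snapped to 0 so their sign bit is deterministic.
quantize_lpq <- function(G, window, decorrelate, rho) {
  vdim <- attr(G, "vdim")
  tol <- 1e-9 * attr(G, "scale")
  if (decorrelate) G <- lpq_whitening(window, rho) %*% G
  G[abs(G) < tol] <- 0
  codes <- integer(ncol(G))
  for (j in 1:8) codes <- codes + bitwShiftL(1L, j - 1L) * (G[j, ] >= 0)
  matrix(as.integer(codes), vdim[1], vdim[2])
}

# Whitening transform for the 8 coefficient components under an isotropic
# exponential correlation model: C_ij = rho^dist(y_i, y_j) over window
# points, D = M C M^T with M the real/imaginary STFT basis rows, and the
# transform is the transposed eigenbasis of D.  Cached per (window, rho).
lpq_whitening <- local({
  cache <- list()
  function(window, rho) {
    key <- paste(window, rho)
    if (!is.null(cache[[key]])) return(cache[[key]])
    window <- check_window(window)
    r <- (window - 1L) %/% 2L
    a <- 1 / window
    pts <- expand.grid(dy = -r:r, dx = -r:r)   # column-major like the loop
    C <- rho^as.matrix(stats::dist(pts[, c("dx", "dy")]))
    W <- t(vapply(lpq_frequencies(a), function(u)
      exp(-2i * pi * (u[1] * pts$dx + u[2] * pts$dy)), complex(nrow(pts))))
    M <- rbind(Re(W), Im(W))
    D <- M %*% C %*% t(M)
    V <- t(eigen(D, symmetric = TRUE)$vectors)
    cache[[key]] <<- V
    V
  }
})

#' Characteristic orientation map for rotation-invariant LPQ
#'
#' At every valid pixel the STFT is evaluated at `n_orientations`
#' frequencies of modulus `1/window` spaced uniformly on the circle; the
#' complex sum `b = sum_i sgn(Im F(v_i)) exp(i theta_i)` points along the
#' dominant local orientation and `Arg(b)` is returned.  A constant
#' neighbourhood (all coefficients zero) yields orientation 0.
#'
#' @inheritParams lpq_histogram
#' @inheritParams rlpq_histogram
#' @return matrix of angles (radians) over the rotated-frame valid region.
#' @export
rlpq_orientation <- function(plane, window = 9L, n_orientations = 36L) {
  plane <- as.matrix(plane)
  window <- check_window(window)
  r <- (window - 1L) %/% 2L
  a <- 1 / window
  margin <- as.integer(ceiling(r * sqrt(2) - 1e-9)) + 1L
  d <- dim(plane)
  if (d[1] < 2L * margin + 1L || d[2] < 2L * margin + 1L)
    stop("plane too small for window ", window, " (rotated frame)")
  rows <- (margin + 1L):(d[1] - margin)
  cols <- (margin + 1L):(d[2] - margin)
  thetas <- 2 * pi * (seq_len(n_orientations) - 1L) / n_orientations
  b <- matrix(0 + 0i, length(rows), length(cols))
  for (t in seq_along(thetas)) {
    u <- a * c(cos(thetas[t]), sin(thetas[t]))   # (ux, uy)
    Im_f <- matrix(0, length(rows), length(cols))
    for (dy in -r:r) {
      ky <- sin(-2 * pi * u[2] * dy); kyc <- cos(-2 * pi * u[2] * dy)
      for (dx in -r:r) {
        ph_im <- kyc * sin(-2 * pi * u[1] * dx) + ky * cos(-2 * pi * u[1] * dx)
        Im_f <- Im_f + ph_im * plane[rows + dy, cols + dx, drop = FALSE]
      }
    }
    b <- b + sign(Im_f) * exp(1i * thetas[t])
  }
  matrix(Arg(b), length(rows), length(cols))
}
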