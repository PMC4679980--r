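#' Design the temporal band-pass filter
#'
#' 4th-order Butterworth band-pass in the digital domain, intended for
#' zero-phase (forward-backward) application. The default pass-band of
#' 0.01-0.2 Hz isolates low-frequency BOLD fluctuations while excluding
#' respiratory and cardiac bands.
#'
#' @param tr Repetition time in seconds.
#' @param low_hz,high_hz Pass-band edges in Hz; requires
#'   0 <= low_hz < high_hz < Nyquist = 1/(2 tr).
#' @param order Butterworth prototype order (default 4).
#' @return A list with numerator/denominator coefficients \code{b}, \code{a}.
#' @export
design_bandpass <- function(tr, low_hz = 0.01, high_hz = 0.2, order = 4L) {
  nyq <- 1 / (2 * tr)
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop("need 0 <= low_hz < high_hz", call. = FALSE)
  if (high_hz >= nyq)
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g Hz)",
                 high_hz, nyq), call. = FALSE)
  if (low_hz > 0) {
    flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  } else {
    flt <- signal::butter(order, high_hz / nyq, type = "low")
  }
  list(b = as.numeric(flt$b), a = as.numeric(flt$a))
}

# Steady-state initial conditions for the direct-form-II-transposed filter
# (Gustafsson-style start), so a constant input produces a constant output
# from the first sample. Solves (I - A') zi = B for the companion form.
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L] / a[1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(comp), B)
}

# One IIR pass over the rows (time) of a T x N matrix, vectorized across
# columns; direct form II transposed. zi_scale gives per-column state
# initialization as outer(zi, zi_scale).
iir_filter_matrix <- function(b, a, x, zi = NULL, zi_scale = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1L]
  a <- c(a, rep(0, n - length(a))) / a[1L]
  nt <- nrow(x); nc <- ncol(x)
  y <- matrix(0, nt, nc)
  z <- if (is.null(zi)) matrix(0, n - 1L, nc) else zi %o% zi_scale
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b[1L] * xt + z[1L, ]
    if (n > 2L) {
      for (k in 1:(n - 2L))
        z[k, ] <- b[k + 1L] * xt + z[k + 1L, ] - a[k + 1L] * yt
    }
    z[n - 1L, ] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  y
}

# One forward-backward sweep with odd-reflection end padding and
# steady-state initial conditions.
filtfilt_once <- function(b, a, x, pad, zi) {
  nt <- nrow(x)
  top <- 2 * matrix(x[1L, ], pad, ncol(x), byrow = TRUE) -
    x[(pad + 1L):2L, , drop = FALSE]
  bot <- 2 * matrix(x[nt, ], pad, ncol(x), byrow = TRUE) -
    x[(nt - 1L):(nt - pad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- iir_filter_matrix(b, a, xp, zi = zi, zi_scale = xp[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- iir_filter_matrix(b, a, y, zi = zi, zi_scale = y[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(pad + 1L):(pad + nt), , drop = FALSE]
}

# Zero-phase filtering of each column of a T x N matrix. The residual edge
# transient of a single forward-backward sweep is direction-dependent, so
# the sweep is run in both time orders and averaged: the antisymmetric part
# of the transient cancels and a symmetric input yields an exactly
# symmetric output, while the steady-state response (|H|^2) is unchanged.
filtfilt_matrix <- function(b, a, x) {
  n <- max(length(a), length(b))
  pad <- 3L * (n - 1L)
  nt <- nrow(x)
  if (nt <= pad + 1L)
    stop("time series too short (", nt, " points) for the filter order",
         call. = FALSE)
  zi <- filter_zi(b, a)
  y1 <- filtfilt_once(b, a, x, pad, zi)
  xr <- x[nt:1L, , drop = FALSE]
  y2 <- filtfilt_once(b, a, xr, pad, zi)
  (y1 + y2[nt:1L, , drop = FALSE]) / 2
}

#' Band-pass filter a 4D time series
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' to every voxel time course. With \code{low_hz > 0} the DC component is
#' removed; the output has the same shape, grid and TR as the input.
#'
#' @param img A \code{\link{ts_image}}.
#' @param low_hz,high_hz Pass-band edges in Hz (defaults 0.01 and 0.2).
#' @param order Butterworth prototype order.
#' @return A filtered \code{\link{ts_image}}.
#' @export
bandpass <- function(img, low_hz = 0.01, high_hz = 0.2, order = 4L) {
  stopifnot(inherits(img, "ts_image"))
  flt <- design_bandpass(img$tr, low_hz, high_hz, order)
  d <- dim(img$data)
  x <- matrix(img$data, nrow = prod(d[1:3]), ncol = d[4])
  y <- t(filtfilt_matrix(flt$b, flt$a, t(x)))
  out <- img
  out$data <- array(y, dim = d)
  out
}

#' Extract the in-mask voxel-by-time matrix
#'
#' @param img A \code{\link{ts_image}}.
#' @param mask A \code{\link{mask3d}} on the same grid.
#' @return An object of class \code{vox_matrix}: a list with \code{values}
#'   (T x N matrix, column j the time course of the j-th mapped voxel),
#'   \code{tr} and \code{index_map}.
#' @export
extract_matrix <- function(img, mask) {
  stopifnot(inherits(img, "ts_image"), inherits(mask, "mask3d"))
  check_same_grid(spatial_dim(img), img$affine, spatial_dim(mask),
                  mask$affine, what = "series and mask")
  map <- voxel_index_map(mask)
  d <- dim(img$data)
  flat <- matrix(img$data, nrow = prod(d[1:3]), ncol = d[4])
  values <- t(flat[map$linear, , drop = FALSE])
  structure(list(values = values, tr = img$tr, index_map = map),
            class = "vox_matrix")
}

#' @export
print.vox_matrix <- function(x, ...) {
  cat(sprintf("<vox_matrix> %d time points x %d voxels, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' Per-voxel temporal standard deviation map
#'
#' Sample standard deviation (denominator T - 1) of each in-mask voxel's
#' time course; zero outside the mask.
#'
#' @param img A \code{\link{ts_image}} with at least two volumes.
#' @param mask A \code{\link{mask3d}} on the same grid.
#' @return An object of class \code{sd_map}: list with \code{values}
#'   (3D array) and \code{mask}.
#' @export
temporal_sd_map <- function(img, mask) {
  stopifnot(inherits(img, "ts_image"), inherits(mask, "mask3d"))
  check_same_grid(spatial_dim(img), img$affine, spatial_dim(mask),
                  mask$affine, what = "series and mask")
  d <- dim(img$data)
  if (d[4] < 2L) stop("need at least 2 volumes", call. = FALSE)
  map <- voxel_index_map(mask)
  flat <- matrix(img$data, nrow = prod(d[1:3]), ncol = d[4])
  xs <- flat[map$linear, , drop = FALSE]
  mu <- rowMeans(xs)
  sds <- sqrt(rowSums((xs - mu)^2) / (d[4] - 1))
  vol <- array(0, dim = d[1:3])
  vol[map$linear] <- sds
  structure(list(values = vol, mask = mask), class = "sd_map")
}
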