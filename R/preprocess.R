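#' Canonical double-gamma hemodynamic response function
#'
#' Double-gamma HRF sampled on the TR grid, peak-normalized to 1. The
#' positive lobe peaks at `peak` seconds and the undershoot at `undershoot`
#' seconds with relative amplitude `ratio`. The kernel is zero at t = 0.
#'
#' @param tr sampling interval in seconds.
#' @param duration kernel support in seconds (default 30).
#' @param peak time-to-peak of the positive lobe in seconds (default 6).
#' @param undershoot time-to-trough of the undershoot in seconds (default 16).
#' @param ratio undershoot amplitude relative to the peak (default 1/6).
#' @return numeric vector of length `ceiling(duration / tr)` with maximum 1.
#' @examples
#' h <- hrf_kernel(1.5)
#' length(h)            # 20 samples over 30 s
#' which.max(h)         # peak near 6 s
#' @export
hrf_kernel <- function(tr, duration = 30, peak = 6, undershoot = 16,
                       ratio = 1 / 6) {
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  n <- ceiling(duration / tr)
  t <- (seq_len(n) - 1) * tr
  # gamma densities with rate 1 have mode shape - 1, so shape = time + 1
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, rate = 1)
  h / max(h)
}

#' Build an HRF-convolved event design matrix
#'
#' One boxcar regressor per schematic event over its half-open interval
#' `[t_k, t_{k+1})`, plus a nuisance regressor for the initial countdown.
#' Boxcars are sampled at TR onsets (0-based grid), convolved with the HRF
#' at TR resolution, truncated to the run length, and z-scored column-wise.
#'
#' @param event_bounds `n_events + 1` strictly increasing timestamps in
#'   seconds; the first bound marks the end of the countdown.
#' @param countdown countdown duration in seconds (0 for none).
#' @param n_trs number of volumes in the run.
#' @param tr repetition time in seconds.
#' @param hrf convolution kernel; defaults to `hrf_kernel(tr)`.
#' @return a `n_trs` x `(n_events + 1)` matrix with columns
#'   `event_1 ... event_K, countdown` and attribute `nuisance` naming the
#'   countdown column. Columns have mean 0 and unit sample sd.
#' @export
build_design_matrix <- function(event_bounds, countdown, n_trs, tr,
                                hrf = hrf_kernel(tr)) {
  if (any(diff(event_bounds) <= 0))
    stop("event_bounds must be strictly increasing (no overlapping or ",
         "empty events)", call. = FALSE)
  if (min(event_bounds) < 0 || max(event_bounds) > n_trs * tr)
    stop("event_bounds must lie within [0, n_trs * tr]", call. = FALSE)
  k <- length(event_bounds) - 1
  times <- (seq_len(n_trs) - 1) * tr
  box <- matrix(0, n_trs, k + 1)
  for (j in seq_len(k)) {
    box[, j] <- as.numeric(times >= event_bounds[j] & times < event_bounds[j + 1])
    if (!any(box[, j] > 0))
      stop(sprintf("event %d covers no TR (shorter than one TR?)", j),
           call. = FALSE)
    if (all(box[, j] > 0))
      stop(sprintf("event %d spans the whole run: constant boxcar cannot be z-scored",
                   j), call. = FALSE)
  }
  box[, k + 1] <- as.numeric(times >= 0 & times < countdown)
  conv <- apply(box, 2, function(x) {
    y <- stats::convolve(x, rev(hrf), type = "open")
    y[seq_len(n_trs)]
  })
  sdv <- apply(conv, 2, stats::sd)
  if (any(sdv[seq_len(k)] < .Machine$double.eps^0.5)) {
    stop("event regressor is constant after convolution (an event spanning ",
         "the whole run cannot be z-scored)", call. = FALSE)
  }
  # a zero-duration countdown yields an all-zero nuisance column; keep it
  # centered but unscaled so the design stays full rank only when it varies
  out <- conv
  for (j in seq_len(k + 1)) {
    if (sdv[j] >= .Machine$double.eps^0.5) {
      out[, j] <- (conv[, j] - mean(conv[, j])) / sdv[j]
    }
  }
  if (countdown <= 0) out <- out[, seq_len(k), drop = FALSE]
  colnames(out) <- c(sprintf("event_%d", seq_len(k)),
                     if (countdown > 0) "countdown")
  attr(out, "nuisance") <- if (countdown > 0) "countdown" else character(0)
  attr(out, "tr") <- tr
  out
}

#' Remove slow drift and z-score a timeseries
#'
#' Projects out Legendre drift polynomials of order 0 through
#' `1 + floor(run_duration / 150)` and z-scores each vertex. Vertices that
#' are constant after detrending (zero variance) are flagged invalid and set
#' to zero rather than raising an error.
#'
#' @param timeseries T x V matrix (time by vertices).
#' @param run_duration run length in seconds (sets the polynomial order).
#' @param tr repetition time in seconds (unused beyond documentation of the
#'   grid; the polynomial basis is evaluated on the T acquired volumes).
#' @return list with `data` (detrended, z-scored T x V matrix), `valid`
#'   (logical V), and `order` (maximum polynomial order removed).
#' @export
detrend_zscore <- function(timeseries, run_duration, tr = NULL) {
  n <- nrow(timeseries)
  ord <- 1 + floor(run_duration / 150)
  basis <- legendre_basis(n, ord)
  beta <- solve(crossprod(basis), crossprod(basis, timeseries))
  resid <- timeseries - basis %*% beta
  sdv <- apply(resid, 2, stats::sd)
  valid <- sdv >= .Machine$double.eps^0.5
  out <- resid
  out[, valid] <- scale(resid[, valid, drop = FALSE])
  out[, !valid] <- 0
  list(data = out, valid = valid, order = ord)
}

# Legendre polynomials P_0..P_ord evaluated on n points spanning [-1, 1]
legendre_basis <- function(n, ord) {
  x <- seq(-1, 1, length.out = n)
  p <- matrix(0, n, ord + 1)
  p[, 1] <- 1
  if (ord >= 1) p[, 2] <- x
  if (ord >= 2) {
    for (m in 2:ord) {
      p[, m + 1] <- ((2 * m - 1) * x * p[, m] - (m - 1) * p[, m - 1]) / m
    }
  }
  p
}
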