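#' Subtract a background spectrum
#'
#' Removes a measured background (e.g. quartz substrate or culture medium)
#' from a sample spectrum: `intensity - scale * background`.
#'
#' @param s a [spectrum()] or [spectrum_set()].
#' @param bg background [spectrum()] on the same grid.
#' @param scale scalar multiplier for the background (default 1).
#' @return object of the same class as `s`.
#' @export
subtract_background <- function(s, bg, scale = 1) UseMethod("subtract_background")

#' @keywords internal
check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a, b, tolerance = 0)))
    stop("grids do not match", call. = FALSE)
}

#' @export
subtract_background.spectrum <- function(s, bg, scale = 1) {
  check_same_grid(s$wavenumber, bg$wavenumber)
  spectrum(s$wavenumber, s$intensity - scale * bg$intensity, s$id)
}

#' @export
subtract_background.spectrum_set <- function(s, bg, scale = 1) {
  check_same_grid(s$wavenumber, bg$wavenumber)
  spectrum_set(s$wavenumber, s$intensity - scale * bg$intensity, s$meta)
}

# polynomial design matrix on a conditioning-friendly scaled axis
poly_basis <- function(wavenumber, order) {
  x <- 2 * (wavenumber - min(wavenumber)) / diff(range(wavenumber)) - 1
  outer(x, 0:order, `^`)
}

baseline_one <- function(B, y, n_iter) {
  fit <- drop(B %*% qr.coef(qr(B), y))
  tol <- 1e-9 * max(diff(range(y)), 1e-300)
  # points above fit + (noise sd estimated from negative residuals) are
  # treated as peak and dropped from the next fit; the kept-fraction floor
  # keeps the polynomial anchored over the whole axis
  min_keep <- min(length(y), max(10L * ncol(B), ceiling(0.2 * length(y))))
  for (k in seq_len(n_iter)) {
    r <- y - fit
    sigma <- if (any(r < 0)) sqrt(mean(r[r < 0]^2)) else 0
    keep <- r <= sigma + tol
    if (sum(keep) < min_keep) break
    fit_new <- drop(B %*% qr.coef(qr(B[keep, , drop = FALSE]), y[keep]))
    if (max(abs(fit_new - fit)) <= tol) { fit <- fit_new; break }
    fit <- fit_new
  }
  fit
}

#' Iterative polynomial baseline correction
#'
#' Fits a polynomial of degree `order` to the spectrum, iteratively excluding
#' points lying above the current fit so that peaks do not attract the
#' baseline; the converged fit estimates the slowly varying fluorescence /
#' stray-light background. Peak-free regions anchor the fit exactly, so a
#' spectrum that is already baseline-free is left (numerically) unchanged.
#'
#' @param s a [spectrum()] or [spectrum_set()].
#' @param order polynomial degree (>= 0); default 3.
#' @param n_iter maximum reweighting iterations (>= 1); default 20.
#' @return for a spectrum, a list with `corrected` and `baseline` spectra;
#'   for a set, a list with `corrected` and `baseline` spectrum sets.
#' @export
correct_baseline <- function(s, order = 3, n_iter = 20) UseMethod("correct_baseline")

check_baseline_args <- function(n, order, n_iter) {
  if (order < 0 || n_iter < 1) stop("order must be >= 0 and n_iter >= 1", call. = FALSE)
  if (order >= n) stop("polynomial order must be below the number of grid points", call. = FALSE)
}

#' @export
correct_baseline.spectrum <- function(s, order = 3, n_iter = 20) {
  check_baseline_args(length(s$wavenumber), order, n_iter)
  B <- poly_basis(s$wavenumber, order)
  bl <- baseline_one(B, s$intensity, n_iter)
  list(corrected = spectrum(s$wavenumber, s$intensity - bl, s$id),
       baseline = spectrum(s$wavenumber, bl, paste0(s$id, "_baseline")))
}

#' @export
correct_baseline.spectrum_set <- function(s, order = 3, n_iter = 20) {
  check_baseline_args(length(s$wavenumber), order, n_iter)
  B <- poly_basis(s$wavenumber, order)
  bl <- apply(s$intensity, 2L, function(y) baseline_one(B, y, n_iter))
  colnames(bl) <- colnames(s$intensity)
  list(corrected = spectrum_set(s$wavenumber, s$intensity - bl, s$meta),
       baseline = spectrum_set(s$wavenumber, bl))
}

#' Trapezoidal band area
#'
#' Integrates intensity over the grid points falling in the closed interval
#' `[window[1], window[2]]` by the trapezoid rule.
#'
#' @param s a [spectrum()].
#' @param window numeric length-2, `c(lo, hi)` in cm\eqn{^{-1}}.
#' @return scalar area.
#' @export
band_area <- function(s, window) {
  stopifnot(inherits(s, "spectrum"), length(window) == 2L)
  lo <- min(window); hi <- max(window)
  idx <- which(s$wavenumber >= lo & s$wavenumber <= hi)
  if (length(idx) < 2L)
    stop("window must contain at least 2 grid points", call. = FALSE)
  x <- s$wavenumber[idx]; y <- s$intensity[idx]
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Ester-band (internal standard) normalization
#'
#' Divides a spectrum by the area of the ester C=O stretching band
#' (1720-1770 cm\eqn{^{-1}} by default). Every ester contributes one C=O
#' group, so this area serves as a per-mole internal intensity standard; the
#' normalized spectrum has unit band area.
#'
#' @param s a [spectrum()] or [spectrum_set()].
#' @param window integration window, default `c(1720, 1770)`.
#' @return object of the same class, unit ester-band area.
#' @export
normalize_ester_band <- function(s, window = c(1720, 1770)) UseMethod("normalize_ester_band")

#' @export
normalize_ester_band.spectrum <- function(s, window = c(1720, 1770)) {
  a <- band_area(s, window)
  if (!is.finite(a) || a <= 0)
    stop("nonpositive ester-band area; cannot normalize", call. = FALSE)
  spectrum(s$wavenumber, s$intensity / a, s$id)
}

#' @export
normalize_ester_band.spectrum_set <- function(s, window = c(1720, 1770)) {
  m <- s$intensity
  for (j in seq_len(ncol(m))) {
    a <- band_area(get_spectrum(s, j), window)
    if (!is.finite(a) || a <= 0)
      stop(sprintf("nonpositive ester-band area in spectrum '%s'",
                   colnames(m)[j]), call. = FALSE)
    m[, j] <- m[, j] / a
  }
  spectrum_set(s$wavenumber, m, s$meta)
}

#' Standard preprocessing chain
#'
#' Applies, in order: background subtraction (optional), iterative polynomial
#' baseline correction, and ester-band normalization. This fixed order is the
#' one the analytical pipeline assumes everywhere.
#'
#' @param set a [spectrum_set()].
#' @param background optional background [spectrum()].
#' @param bg_scale background scale factor (default 1).
#' @param baseline_order polynomial degree for the baseline (default 3).
#' @param n_iter baseline iterations (default 20).
#' @param norm_window ester-band window (default `c(1720, 1770)`).
#' @return preprocessed [spectrum_set()].
#' @export
preprocess_spectra <- function(set, background = NULL, bg_scale = 1,
                               baseline_order = 3, n_iter = 20,
                               norm_window = c(1720, 1770)) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!is.null(background)) set <- subtract_background(set, background, bg_scale)
  set <- correct_baseline(set, order = baseline_order, n_iter = n_iter)$corrected
  normalize_ester_band(set, norm_window)
}
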