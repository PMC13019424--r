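#' @keywords internal
assert_grid <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("wavenumber grid must be numeric with at least 2 points", call. = FALSE)
  if (any(!is.finite(values)))
    stop("wavenumber grid must be finite", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("wavenumber grid must be strictly increasing", call. = FALSE)
  invisible(values)
}

#' Default wavenumber grid
#'
#' The working Raman-shift axis used throughout the package:
#' 650 to 1800 cm\eqn{^{-1}} at 1 cm\eqn{^{-1}} spacing (1151 points), covering
#' the fingerprint region in which all analytical models are built.
#'
#' @param from,to,by grid limits and spacing in cm\eqn{^{-1}}.
#' @return numeric vector of wavenumbers, strictly increasing.
#' @export
default_grid <- function(from = 650, to = 1800, by = 1) {
  assert_grid(seq(from, to, by = by))
}

#' Single Raman spectrum
#'
#' A spectrum is an intensity vector on a strictly increasing wavenumber grid
#' (cm\eqn{^{-1}}), with an identifier. Wavenumbers are stored ascending;
#' report functions render them descending, following spectroscopic convention.
#'
#' @param wavenumber numeric vector, strictly increasing, cm\eqn{^{-1}}.
#' @param intensity numeric vector, same length as `wavenumber`, all finite.
#' @param id character scalar identifier.
#' @return an object of class `"spectrum"`.
#' @export
spectrum <- function(wavenumber, intensity, id = "spectrum") {
  assert_grid(wavenumber)
  if (length(intensity) != length(wavenumber))
    stop("intensity and wavenumber lengths differ", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensity must be finite", call. = FALSE)
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity),
                 id = as.character(id)[1L]),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s': %d points, %g-%g cm-1>\n",
              x$id, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Collection of spectra on a shared grid
#'
#' @param wavenumber shared grid (strictly increasing, cm\eqn{^{-1}}).
#' @param intensity numeric matrix, `length(wavenumber)` rows, one column per
#'   spectrum; column names are the spectrum ids (must be unique).
#' @param meta optional data frame of per-spectrum metadata with an `id`
#'   column matching the intensity column names (composition, role, ...).
#' @return an object of class `"spectrum_set"`.
#' @export
spectrum_set <- function(wavenumber, intensity, meta = NULL) {
  assert_grid(wavenumber)
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(wavenumber))
    stop("intensity rows must match grid length", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  ids <- colnames(intensity)
  if (is.null(ids)) {
    ids <- sprintf("s%03d", seq_len(ncol(intensity)))
    colnames(intensity) <- ids
  }
  if (anyDuplicated(ids))
    stop("spectrum ids must be unique", call. = FALSE)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!("id" %in% names(meta)) || !identical(as.character(meta$id), ids))
      stop("meta must carry an 'id' column matching the spectra", call. = FALSE)
  }
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = intensity, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set: %d spectra, %d points, %g-%g cm-1>\n",
              ncol(x$intensity), length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) ncol(x$intensity)

#' Extract one spectrum from a set
#'
#' @param set a [spectrum_set()].
#' @param id column id or index.
#' @return a [spectrum()].
#' @export
get_spectrum <- function(set, id) {
  stopifnot(inherits(set, "spectrum_set"))
  spectrum(set$wavenumber, set$intensity[, id],
           if (is.character(id)) id else colnames(set$intensity)[id])
}

#' Assemble spectra into a set
#'
#' @param spectra list of [spectrum()] objects on one identical grid.
#' @param meta optional metadata data frame (see [spectrum_set()]).
#' @return a [spectrum_set()].
#' @export
bind_spectra <- function(spectra, meta = NULL) {
  stopifnot(length(spectra) >= 1L)
  g <- spectra[[1L]]$wavenumber
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavenumber, g, tolerance = 0)))
      stop("all spectra must share one grid", call. = FALSE)
  m <- vapply(spectra, `[[`, numeric(length(g)), "intensity")
  colnames(m) <- vapply(spectra, `[[`, character(1L), "id")
  spectrum_set(g, m, meta)
}

#' Linear resampling onto a new grid
#'
#' Interpolates intensities linearly onto a target grid that must lie within
#' the closed span of the source grid. A target identical to the source grid
#' returns the input unchanged.
#'
#' @param s a [spectrum()] or [spectrum_set()].
#' @param grid target wavenumber grid.
#' @return object of the same class on the new grid.
#' @export
resample <- function(s, grid) UseMethod("resample")

#' @export
resample.spectrum <- function(s, grid) {
  if (identical(grid, s$wavenumber)) return(s)
  if (min(grid) < min(s$wavenumber) || max(grid) > max(s$wavenumber))
    stop("target grid outside the span of the source grid", call. = FALSE)
  spectrum(grid, stats::approx(s$wavenumber, s$intensity, xout = grid)$y, s$id)
}

#' @export
resample.spectrum_set <- function(s, grid) {
  if (identical(grid, s$wavenumber)) return(s)
  if (min(grid) < min(s$wavenumber) || max(grid) > max(s$wavenumber))
    stop("target grid outside the span of the source grid", call. = FALSE)
  m <- apply(s$intensity, 2L, function(y)
    stats::approx(s$wavenumber, y, xout = grid)$y)
  colnames(m) <- colnames(s$intensity)
  spectrum_set(grid, m, s$meta)
}

# scramble (base, k) into a well-separated 31-bit seed so that nearby base
# seeds do not share per-sample RNG streams
mix_seed <- function(base, k) {
  m <- 2147483647
  s <- (as.numeric(base) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + as.numeric(k) * 9973) %% m
  as.integer((s * 16807) %% m)
}

# evaluate RNG-dependent code under a local, restored seed
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  saved <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", saved, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}
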