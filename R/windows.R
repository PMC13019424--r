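#' Spectral window set
#'
#' A set of closed wavenumber intervals `[lo, hi]` restricting a model to
#' informative regions. Stored and displayed sorted descending by upper edge
#' (the convention spectra are plotted in); intervals must not overlap with
#' positive measure, though adjacent intervals may share an endpoint.
#'
#' @param x either a character string in the `"1800-1700,1500-1380,..."`
#'   dialect, or a 2-column matrix / list of `c(lo, hi)` pairs.
#' @return an object of class `"window_set"`: list with `intervals`
#'   (matrix with columns `lo`, `hi`).
#' @export
window_set <- function(x) {
  if (inherits(x, "window_set")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    parts <- strsplit(trimws(strsplit(x, ",")[[1L]]), "-")
    iv <- t(vapply(parts, function(p) {
      if (length(p) != 2L) stop("bad window token; expected 'hi-lo'", call. = FALSE)
      v <- suppressWarnings(as.numeric(p))
      if (any(is.na(v))) stop("non-numeric window bound", call. = FALSE)
      sort(v)
    }, numeric(2L)))
  } else if (is.matrix(x)) {
    iv <- t(apply(x, 1L, sort))
  } else if (is.list(x)) {
    iv <- t(vapply(x, function(p) sort(as.numeric(p)), numeric(2L)))
  } else stop("cannot interpret windows", call. = FALSE)
  colnames(iv) <- c("lo", "hi")
  if (any(iv[, "lo"] >= iv[, "hi"]))
    stop("each window needs lo < hi", call. = FALSE)
  iv <- iv[order(iv[, "hi"], decreasing = TRUE), , drop = FALSE]
  if (nrow(iv) > 1L)
    for (k in 2:nrow(iv))
      if (iv[k, "hi"] > iv[k - 1L, "lo"])
        stop("windows overlap", call. = FALSE)
  structure(list(intervals = iv), class = "window_set")
}

#' @export
format.window_set <- function(x, ...) {
  paste(sprintf("%g-%g", x$intervals[, "hi"], x$intervals[, "lo"]),
        collapse = ",")
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set:", format(x), ">\n")
  invisible(x)
}

#' Extract windowed channels from a spectrum set
#'
#' Builds the regression data matrix: channels are the grid points falling in
#' each closed interval, concatenated in window order (descending upper edge).
#'
#' @param set a [spectrum_set()].
#' @param windows a [window_set()] (or anything [window_set()] accepts).
#' @return list with `x` (samples x channels matrix, rows named by spectrum
#'   id) and `channel_map` (wavenumber of each channel, cm\eqn{^{-1}}).
#' @export
extract_windows <- function(set, windows) {
  stopifnot(inherits(set, "spectrum_set"))
  w <- window_set(windows)
  idx <- integer(0)
  for (k in seq_len(nrow(w$intervals))) {
    lo <- w$intervals[k, "lo"]; hi <- w$intervals[k, "hi"]
    j <- which(set$wavenumber >= lo & set$wavenumber <= hi)
    if (length(j) == 0L)
      stop(sprintf("window %g-%g contains no grid points", hi, lo), call. = FALSE)
    idx <- c(idx, j)
  }
  list(x = t(set$intensity[idx, , drop = FALSE]),
       channel_map = set$wavenumber[idx])
}
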