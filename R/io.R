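#' Read spectra from wide CSV
#'
#' Expected layout: header `wavenumber_cm1,<id1>,<id2>,...`; one row per grid
#' point, wavenumbers strictly increasing, '.' decimal separator.
#'
#' @param path file path.
#' @return a [spectrum_set()].
#' @export
load_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("spectra CSV needs a wavenumber column and at least one spectrum", call. = FALSE)
  if (names(df)[1L] != "wavenumber_cm1")
    stop("first column must be 'wavenumber_cm1'", call. = FALSE)
  wn <- as.numeric(df[[1L]])
  if (any(is.na(wn)) || any(vapply(df[-1L], function(v) any(is.na(v)), logical(1L))))
    stop("malformed spectra CSV: missing or non-numeric values", call. = FALSE)
  if (any(diff(wn) <= 0))
    stop("wavenumber column must be strictly increasing (no duplicate rows)", call. = FALSE)
  m <- as.matrix(df[-1L])
  spectrum_set(wn, m)
}

#' Write spectra to wide CSV
#'
#' Inverse of [load_spectra()]; values written with 15 significant digits so
#' a save/load roundtrip reproduces the set to near machine precision.
#'
#' @param set a [spectrum_set()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  df <- data.frame(wavenumber_cm1 = format(set$wavenumber, digits = 15, trim = TRUE),
                   check.names = FALSE)
  for (j in seq_len(ncol(set$intensity)))
    df[[colnames(set$intensity)[j]]] <-
      format(set$intensity[, j], digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write composition tables
#'
#' Compositions are mole percentages of the five fatty acyl groups, CSV
#' layout `sample_id,MA,PA,SA,OA,LA`.
#'
#' @param path file path.
#' @return data frame with `sample_id` and the five acyl columns.
#' @export
load_compositions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample_id", acyl_species())
  if (!all(need %in% names(df)))
    stop("composition CSV must have columns sample_id,MA,PA,SA,OA,LA", call. = FALSE)
  df[, need]
}

#' @rdname load_compositions
#' @param comps composition data frame.
#' @export
save_compositions <- function(comps, path) {
  df <- comps[, c("sample_id", acyl_species())]
  for (sp in acyl_species()) df[[sp]] <- format(df[[sp]], digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The five fatty acyl groups
#'
#' Myristate (MA, 14:0), palmitate (PA, 16:0), stearate (SA, 18:0), oleate
#' (OA, 18:1) and linoleate (LA, 18:2) -- the dominant acyl groups of
#' triacylglycerols in mammalian cells, and the components every model in
#' this package quantifies.
#'
#' @return character vector of the five species codes, in canonical order.
#' @export
acyl_species <- function() c("MA", "PA", "SA", "OA", "LA")
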