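#' Per-acyl FAME-to-TAG spectral variance via two-class PCA
#'
#' The core of the calibration-transfer method. Replicate spectra of a pure
#' FAME and of the TAG bearing the same acyl group are pooled and decomposed
#' by PCA (channels mean-centered over the pooled set). The first principal
#' component captures the systematic FAME/TAG contrast while measurement
#' noise falls into the later components, so the spectral variance is
#'
#' \deqn{\Delta S_D = (Sc_{TAG} - Sc_{FAME}) \cdot L_{PC1}}
#'
#' with `Sc` the class-mean PC1 scores and `L_PC1` the unit PC1 loading.
#' With exactly one spectrum per class this reduces to the plain difference
#' spectrum; with noisy replicates it is a noise-filtered estimate of it.
#' The loading sign is arbitrary and provably cancels in the product.
#'
#' @param fame_reps [spectrum_set()] of preprocessed pure-FAME replicates.
#' @param tag_reps [spectrum_set()] of preprocessed pure-TAG replicates,
#'   same grid.
#' @param species optional species code stored on the result.
#' @return an object of class `"delta_spectrum"`: list with `species`,
#'   `wavenumber`, `delta`, `pc1_loading` (unit norm), `score_fame`,
#'   `score_tag` (class-mean scores), `pc1_explained` (variance fraction).
#' @export
compute_delta <- function(fame_reps, tag_reps, species = NULL) {
  stopifnot(inherits(fame_reps, "spectrum_set"), inherits(tag_reps, "spectrum_set"))
  check_same_grid(fame_reps$wavenumber, tag_reps$wavenumber)
  X <- rbind(t(fame_reps$intensity), t(tag_reps$intensity))
  n_f <- ncol(fame_reps$intensity)
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = 0L)
  tot <- sum(sv$d^2)
  if (tot <= 1e-20 * max(1, sum(X^2)))
    stop("degenerate variance: all pooled spectra are identical", call. = FALSE)
  loading <- sv$v[, 1L]
  scores <- drop(Xc %*% loading)
  structure(list(
    species = species,
    wavenumber = fame_reps$wavenumber,
    pc1_loading = loading,
    score_fame = mean(scores[seq_len(n_f)]),
    score_tag = mean(scores[-seq_len(n_f)]),
    delta = (mean(scores[-seq_len(n_f)]) - mean(scores[seq_len(n_f)])) * loading,
    pc1_explained = sv$d[1L]^2 / tot), class = "delta_spectrum")
}

#' @export
print.delta_spectrum <- function(x, ...) {
  cat(sprintf("<delta_spectrum %s: PC1 explains %.1f%%, |delta| = %.3g>\n",
              if (is.null(x$species)) "" else x$species,
              100 * x$pc1_explained, sqrt(sum(x$delta^2))))
  invisible(x)
}

#' Build the transfer set for all five acyl groups
#'
#' Runs [compute_delta()] per species on matched pure FAME / TAG replicate
#' sets.
#'
#' @param fame_pures,tag_pures named lists (by species) of [spectrum_set()]
#'   replicate sets, or of single [spectrum()] objects.
#' @return an object of class `"transfer_set"`: list with `deltas` (named
#'   list of [compute_delta()] results) and the shared `wavenumber` grid.
#' @export
compute_transfer_set <- function(fame_pures, tag_pures) {
  as_set <- function(x) if (inherits(x, "spectrum")) bind_spectra(list(x)) else x
  deltas <- stats::setNames(lapply(acyl_species(), function(sp) {
    if (is.null(fame_pures[[sp]]) || is.null(tag_pures[[sp]]))
      stop(sprintf("missing pure spectra for species %s", sp), call. = FALSE)
    compute_delta(as_set(fame_pures[[sp]]), as_set(tag_pures[[sp]]), sp)
  }), acyl_species())
  g <- deltas[[1L]]$wavenumber
  for (d in deltas) check_same_grid(g, d$wavenumber)
  structure(list(deltas = deltas, wavenumber = g), class = "transfer_set")
}

#' Simulate a TAG mixture spectrum from a FAME mixture spectrum
#'
#' Applies the concentration-weighted spectral variances:
#' \deqn{S_{TAG} = S_{FAME} + \sum_i \Delta S_{D i} \, c_i}
#' where \eqn{c_i} is the mole fraction of acyl group \eqn{i} (mole %
#' divided by 100, so a pure component receives its full delta).
#'
#' @param s_fame preprocessed FAME mixture [spectrum()] on the transfer grid.
#' @param composition named mole-% vector (names in `acyl_species()`).
#' @param transfer a `"transfer_set"` from [compute_transfer_set()].
#' @return simulated TAG [spectrum()].
#' @export
simulate_tag <- function(s_fame, composition, transfer) {
  stopifnot(inherits(transfer, "transfer_set"))
  check_same_grid(s_fame$wavenumber, transfer$wavenumber)
  y <- s_fame$intensity
  for (sp in acyl_species()) {
    f <- composition[[sp]]
    if (!is.null(f) && !is.na(f) && f != 0)
      y <- y + (f / 100) * transfer$deltas[[sp]]$delta
  }
  spectrum(s_fame$wavenumber, y, s_fame$id)
}

#' Simulate TAG spectra for a whole calibration set
#'
#' Applies [simulate_tag()] to every spectrum of a set, taking each sample's
#' composition from the set metadata.
#'
#' @param fame_set preprocessed [spectrum_set()] whose `meta` carries the
#'   `MA`..`LA` mole-% columns.
#' @param transfer a `"transfer_set"`.
#' @return a [spectrum_set()] of simulated TAG spectra, metadata preserved.
#' @export
simulate_tag_dataset <- function(fame_set, transfer) {
  stopifnot(inherits(fame_set, "spectrum_set"))
  if (length(fame_set) == 0L) return(fame_set)
  if (is.null(fame_set$meta) || !all(acyl_species() %in% names(fame_set$meta)))
    stop("spectrum set lacks composition metadata", call. = FALSE)
  check_same_grid(fame_set$wavenumber, transfer$wavenumber)
  m <- fame_set$intensity
  for (j in seq_len(ncol(m))) {
    comp <- unlist(fame_set$meta[j, acyl_species()])
    for (sp in acyl_species())
      if (comp[[sp]] != 0)
        m[, j] <- m[, j] + (comp[[sp]] / 100) * transfer$deltas[[sp]]$delta
  }
  spectrum_set(fame_set$wavenumber, m, fame_set$meta)
}

#' Serialize / restore a transfer set as JSON
#'
#' @param transfer a `"transfer_set"`.
#' @param path file path.
#' @return `path` (save) or a `"transfer_set"` (load).
#' @export
save_transfer_set <- function(transfer, path) {
  stopifnot(inherits(transfer, "transfer_set"))
  obj <- list(grid = transfer$wavenumber,
              deltas = lapply(transfer$deltas, function(d)
                d[c("species", "delta", "pc1_loading",
                    "score_fame", "score_tag", "pc1_explained")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_transfer_set
#' @export
load_transfer_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- as.numeric(obj$grid)
  deltas <- stats::setNames(lapply(acyl_species(), function(sp) {
    d <- obj$deltas[[sp]]
    structure(list(species = d$species, wavenumber = g,
                   pc1_loading = as.numeric(d$pc1_loading),
                   score_fame = d$score_fame, score_tag = d$score_tag,
                   delta = as.numeric(d$delta),
                   pc1_explained = d$pc1_explained),
              class = "delta_spectrum")
  }), acyl_species())
  structure(list(deltas = deltas, wavenumber = g), class = "transfer_set")
}
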