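#' Noise model parameters for synthetic mixtures
#'
#' Gaussian channel noise plus a slow polynomial baseline drift, emulating
#' shot noise and the fluorescence / stray-light undulation of measured
#' spectra. `sigma_rel` and `drift_amp_rel` are expressed relative to the
#' maximum pure-component intensity so they read as fractions of full scale.
#'
#' @param sigma_rel Gaussian noise sd as a fraction of the maximum
#'   pure-component intensity (default 0.01).
#' @param drift_order polynomial degree of the baseline drift (default 2).
#' @param drift_amp_rel peak drift amplitude as a fraction of the maximum
#'   pure-component intensity (default 0.02).
#' @param seed integer seed making every generated spectrum reproducible.
#' @return an object of class `"noise_params"`.
#' @export
noise_params <- function(sigma_rel = 0.01, drift_order = 2,
                         drift_amp_rel = 0.02, seed = 1L) {
  stopifnot(sigma_rel >= 0, drift_amp_rel >= 0, drift_order >= 0)
  structure(list(sigma_rel = sigma_rel, drift_order = as.integer(drift_order),
                 drift_amp_rel = drift_amp_rel, seed = as.integer(seed)),
            class = "noise_params")
}

simplex_sample <- function(n) {
  # flat Dirichlet over the 5-simplex, in mole %
  g <- matrix(stats::rgamma(n * 5L, shape = 1), nrow = n)
  100 * g / rowSums(g)
}

#' Mixture design for calibration and test sets
#'
#' Generates the training/test composition design: the training set always
#' contains the five pure vertices (100% of each species), the ten 50/50
#' binary midpoints and the centroid, topped up with draws from a flat
#' Dirichlet over the 5-simplex; the test set is drawn independently from the
#' same Dirichlet. Defaults follow the 165-training / 20-test layout used to
#' build and evaluate the analytical models. All compositions sum to 100.
#'
#' @param n_train number of training compositions (>= 5; default 165).
#' @param n_test number of test compositions (default 20).
#' @param seed integer seed.
#' @return list of class `"mixture_design"` with data frames `train` and
#'   `test` (`sample_id`, `MA`..`LA`) and the `seed`.
#' @export
generate_design <- function(n_train = 165, n_test = 20, seed = 1L) {
  stopifnot(n_train >= 5)
  sp <- acyl_species()
  fixed <- diag(5) * 100
  mids <- t(utils::combn(5L, 2L, function(ij) {
    v <- numeric(5L); v[ij] <- 50; v
  }))
  fixed <- rbind(fixed, mids, rep(20, 5L))
  fixed <- fixed[seq_len(min(nrow(fixed), n_train)), , drop = FALSE]
  with_seed(seed, {
    extra <- n_train - nrow(fixed)
    train <- rbind(fixed, if (extra > 0) simplex_sample(extra))
    test <- simplex_sample(n_test)
    colnames(train) <- colnames(test) <- sp
    structure(list(
      train = data.frame(sample_id = sprintf("train_%03d", seq_len(n_train)),
                         train, check.names = FALSE),
      test = data.frame(sample_id = sprintf("test_%03d", seq_len(n_test)),
                        test, check.names = FALSE),
      seed = as.integer(seed)), class = "mixture_design")
  })
}

#' Synthesize one mixture spectrum
#'
#' Mixes pure-component spectra linearly in mole fraction and adds the noise
#' model: a random polynomial drift plus i.i.d. Gaussian channel noise, both
#' drawn reproducibly from `noise$seed`.
#'
#' @param composition named numeric vector of mole % (names in
#'   `acyl_species()`); entries for species absent from `components` must be 0.
#' @param components named list of pure-component [spectrum()] objects on a
#'   shared grid.
#' @param noise a [noise_params()] or `NULL` for a noise-free mixture.
#' @param id spectrum id.
#' @return a [spectrum()].
#' @export
mix_spectrum <- function(composition, components, noise = NULL, id = "mixture") {
  used <- names(composition)[composition != 0]
  missing <- setdiff(used, names(components))
  if (length(missing))
    stop(sprintf("no component spectrum for species: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  g <- components[[1L]]$wavenumber
  for (s in components) check_same_grid(g, s$wavenumber)
  y <- numeric(length(g))
  for (sp in names(components)) {
    f <- composition[[sp]]
    if (!is.null(f) && !is.na(f) && f != 0)
      y <- y + (f / 100) * components[[sp]]$intensity
  }
  if (!is.null(noise) && (noise$sigma_rel > 0 || noise$drift_amp_rel > 0)) {
    ref <- max(vapply(components, function(s) max(s$intensity), numeric(1L)))
    y <- y + with_seed(noise$seed, {
      drift <- numeric(length(g))
      if (noise$drift_amp_rel > 0) {
        x <- 2 * (g - min(g)) / diff(range(g)) - 1
        coefs <- stats::runif(noise$drift_order + 1L, -1, 1)
        drift <- drop(outer(x, 0:noise$drift_order, `^`) %*% coefs)
        m <- max(abs(drift))
        if (m > 0) drift <- drift * (noise$drift_amp_rel * ref / m)
      }
      drift + if (noise$sigma_rel > 0)
        stats::rnorm(length(g), sd = noise$sigma_rel * ref) else 0
    })
  }
  spectrum(g, y, id)
}

#' Generate a full synthetic data set
#'
#' Renders the pure components of the requested ester form and synthesizes
#' one raw (un-preprocessed) mixture spectrum per composition, with
#' per-sample seeds fanned out deterministically from `noise$seed`.
#'
#' @param compositions data frame with `sample_id` and `MA`..`LA` columns
#'   (one block of a [generate_design()]).
#' @param ester_form `"FAME"` or `"TAG"`.
#' @param noise a [noise_params()] or `NULL`.
#' @param grid wavenumber grid.
#' @param seed_offset added to `noise$seed` before the per-sample fan-out, so
#'   train/test blocks generated from one base seed stay independent.
#' @return a [spectrum_set()] whose `meta` carries the compositions.
#' @export
generate_dataset <- function(compositions, ester_form, noise = noise_params(),
                             grid = default_grid(), seed_offset = 0L) {
  comps <- render_pure_components(ester_form, grid)
  spectra <- vector("list", nrow(compositions))
  for (k in seq_len(nrow(compositions))) {
    nk <- if (is.null(noise)) NULL else
      noise_params(noise$sigma_rel, noise$drift_order, noise$drift_amp_rel,
                   seed = mix_seed(noise$seed + seed_offset, k))
    spectra[[k]] <- mix_spectrum(
      unlist(compositions[k, acyl_species()]), comps, nk,
      id = compositions$sample_id[k])
  }
  meta <- data.frame(id = compositions$sample_id,
                     compositions[, acyl_species()],
                     check.names = FALSE, row.names = NULL)
  bind_spectra(spectra, meta)
}
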