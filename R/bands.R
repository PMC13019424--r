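# cache for the parsed band-model table
.band_env <- new.env(parent = emptyenv())

#' Pseudo-Voigt line profile
#'
#' Unit-peak-height profile: `eta` Lorentzian plus `1 - eta` Gaussian, both
#' with full width at half maximum `fwhm`.
#'
#' @param x wavenumbers at which to evaluate.
#' @param center band center, cm\eqn{^{-1}}.
#' @param fwhm full width at half maximum, cm\eqn{^{-1}} (> 0).
#' @param eta Lorentzian fraction in `[0, 1]`.
#' @return numeric vector, 1 at `x == center`.
#' @export
pseudo_voigt <- function(x, center, fwhm, eta) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  u <- (x - center) / (fwhm / 2)
  eta / (1 + u^2) + (1 - eta) * exp(-log(2) * u^2)
}

load_band_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "band_models.json", package = "acylquant",
                        mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

band_models <- function() {
  if (is.null(.band_env$models)) .band_env$models <- load_band_models()
  .band_env$models
}

validate_band_model <- function(m) {
  centers <- vapply(m$bands, `[[`, numeric(1L), "center")
  co <- centers >= 1720 & centers <= 1770
  if (sum(co) != 1L)
    stop("band model must contain exactly one C=O band in [1720, 1770]", call. = FALSE)
  unsat <- any(centers >= 1600 & centers <= 1700)
  if (unsat != (m$species %in% c("OA", "LA")))
    stop("bands in [1600, 1700] must appear iff the species is unsaturated", call. = FALSE)
  for (b in m$bands)
    if (b$fwhm <= 0 || b$amplitude < 0)
      stop("bands need fwhm > 0 and amplitude >= 0", call. = FALSE)
  m
}

#' Built-in pure-component band model
#'
#' Returns the pseudo-Voigt band table for one pure fatty ester: a fatty acid
#' methyl ester (FAME) or the triacylglycerol (TAG) bearing the same acyl
#' group. The tables encode the qualitative FAME/TAG contrasts seen in
#' lipid Raman spectra: the TAG ester C=O stretch is blue-shifted by
#' 4 cm\eqn{^{-1}} and 1.3x broader; the CH2/CH3 bending region (1500-1400)
#' carries a different amplitude ratio; the methyl-ester C-O-CH3 bands near
#' 862 cm\eqn{^{-1}} are replaced by glycerol-ester C-O-C bands; and for the
#' unsaturated species the C=C bands in 1700-1600 shift slightly. The
#' CH2/CH3 bend at 1439 is ordered SA > PA > MA among saturated species, and
#' unsaturation bands near 1650 / 1260 cm\eqn{^{-1}} scale with the number
#' of double bonds (LA > OA, absent for saturated species).
#'
#' @param species one of `"MA"`, `"PA"`, `"SA"`, `"OA"`, `"LA"`.
#' @param ester_form `"FAME"` or `"TAG"`.
#' @return a band model: list with `species`, `ester_form`, `bands` (each
#'   band has `center`, `fwhm`, `amplitude`, `shape`).
#' @export
component_model <- function(species, ester_form) {
  if (!species %in% acyl_species())
    stop(sprintf("unknown species '%s'", species), call. = FALSE)
  if (!ester_form %in% c("FAME", "TAG"))
    stop(sprintf("unknown ester form '%s'", ester_form), call. = FALSE)
  validate_band_model(band_models()[[species]][[ester_form]])
}

#' Render a band model to a spectrum
#'
#' Sums the model's pseudo-Voigt profiles (unit peak height scaled by each
#' band's amplitude) on a wavenumber grid. Noise-free.
#'
#' @param model a band model, e.g. from [component_model()].
#' @param grid wavenumber grid (default [default_grid()]).
#' @param id spectrum id (default derived from the model).
#' @return a [spectrum()].
#' @export
render_bands <- function(model, grid = default_grid(), id = NULL) {
  assert_grid(grid)
  y <- numeric(length(grid))
  for (b in model$bands)
    y <- y + b$amplitude * pseudo_voigt(grid, b$center, b$fwhm, b$shape)
  if (is.null(id))
    id <- if (!is.null(model$species)) paste0(model$species, "_", model$ester_form)
          else "render"
  spectrum(grid, y, id)
}

#' Render all five pure components of one ester form
#'
#' @param ester_form `"FAME"` or `"TAG"`.
#' @param grid wavenumber grid.
#' @return named list of [spectrum()], one per species.
#' @export
render_pure_components <- function(ester_form, grid = default_grid()) {
  stats::setNames(
    lapply(acyl_species(), function(sp)
      render_bands(component_model(sp, ester_form), grid)),
    acyl_species())
}
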