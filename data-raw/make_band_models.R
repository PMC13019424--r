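# Builds inst/extdata/band_models.json: pseudo-Voigt band tables for the five
# FAME / TAG pure components on 650-1800 cm^-1. Amplitudes/widths are package
# design values (positions follow standard lipid Raman assignments); the C=O
# amplitude of each model is calibrated so that every pure spectrum within a
# class has the same ester-band area over 1720-1770 cm^-1 (one ester per mole).

pv <- function(x, center, fwhm, eta) {
  u <- (x - center) / (fwhm / 2)
  eta / (1 + u^2) + (1 - eta) * exp(-log(2) * u^2)
}

band <- function(center, fwhm, amplitude, shape) {
  list(center = center, fwhm = fwhm, amplitude = amplitude, shape = shape)
}

species <- c("MA", "PA", "SA", "OA", "LA")

amp1439 <- c(MA = 0.78, PA = 0.88, SA = 1.00, OA = 0.82, LA = 0.75)
amp1302 <- c(MA = 0.55, PA = 0.55, SA = 0.55, OA = 0.50, LA = 0.45)
amp1063 <- c(MA = 0.30, PA = 0.34, SA = 0.38, OA = 0.25, LA = 0.20)
amp1100 <- c(MA = 0.28, PA = 0.31, SA = 0.34, OA = 0.22, LA = 0.18)
amp1129 <- c(MA = 0.25, PA = 0.28, SA = 0.31, OA = 0.20, LA = 0.16)

skeletal <- list(
  MA = list(band(845, 14, 0.22, 0.2), band(891, 12, 0.18, 0.2), band(980, 14, 0.12, 0.2)),
  PA = list(band(850, 14, 0.20, 0.2), band(888, 12, 0.20, 0.2), band(1008, 14, 0.14, 0.2)),
  SA = list(band(855, 14, 0.18, 0.2), band(885, 12, 0.22, 0.2), band(1025, 14, 0.12, 0.2)),
  OA = list(band(856, 14, 0.14, 0.2), band(970, 16, 0.10, 0.2)),
  LA = list(band(858, 14, 0.12, 0.2), band(914, 16, 0.12, 0.2))
)

# C=C stretch (1600-1700) and =C-H bend (~1265): unsaturated species only,
# linoleate (two double bonds) stronger than oleate (one).
unsat <- list(
  OA = list(cc = band(1655, 12, 0.45, 0.15), ch = band(1265, 14, 0.35, 0.2)),
  LA = list(cc = band(1656, 12, 0.85, 0.15), ch = band(1266, 14, 0.68, 0.2))
)

make_model <- function(sp, form) {
  co_center <- if (form == "FAME") 1740 else 1744
  co_fwhm <- if (form == "FAME") 20 else 26           # TAG C=O blue-shifted +4, broader x1.3
  ch_scale <- if (form == "FAME") 1 else 1.12         # CH2/CH3-to-ester ratio shift
  bands <- list(
    band(co_center, co_fwhm, 0.60, 0.25),             # ester C=O stretch (calibrated below)
    band(1439, 20, amp1439[[sp]] * ch_scale, 0.3),    # CH2/CH3 bend
    band(1455, 14, 0.30 * ch_scale, 0.3),             # CH3 shoulder
    band(1302, 16, amp1302[[sp]], 0.2),               # CH2 twist
    band(1129, 12, amp1129[[sp]], 0.2),
    band(1100, 12, amp1100[[sp]], 0.2),
    band(1063, 12, amp1063[[sp]], 0.2)
  )
  bands <- c(bands, skeletal[[sp]])
  if (sp %in% c("OA", "LA")) {
    cc <- unsat[[sp]]$cc
    if (form == "TAG") {                              # acyl interactions around C=C
      cc$center <- cc$center + 2
      cc$amplitude <- cc$amplitude * 0.95
    }
    bands <- c(bands, list(cc, unsat[[sp]]$ch))
  }
  if (form == "FAME") {
    bands <- c(bands, list(band(862, 16, 0.28, 0.2)))                      # C-O-CH3 ester
  } else {
    bands <- c(bands, list(band(820, 16, 0.16, 0.2), band(875, 16, 0.20, 0.2)))  # glycerol C-O-C
  }
  bands
}

grid <- seq(650, 1800, by = 1)
win <- grid >= 1720 & grid <= 1770
trapz <- function(y) sum(diff(grid[win]) * (y[win][-1] + y[win][-sum(win)]) / 2)

render <- function(bands) {
  y <- numeric(length(grid))
  for (b in bands) y <- y + b$amplitude * pv(grid, b$center, b$fwhm, b$shape)
  y
}

target <- c(FAME = 13.0, TAG = 16.5)  # ester-band area per class

models <- list()
for (sp in species) {
  models[[sp]] <- list()
  for (form in c("FAME", "TAG")) {
    bands <- make_model(sp, form)
    co <- 1L  # C=O is first
    rest <- bands[-co]
    tail_area <- trapz(render(rest))
    unit <- trapz(render(list(modifyList(bands[[co]], list(amplitude = 1)))))
    bands[[co]]$amplitude <- (target[[form]] - tail_area) / unit
    stopifnot(abs(trapz(render(bands)) - target[[form]]) < 1e-9)
    models[[sp]][[form]] <- list(species = sp, ester_form = form, bands = bands)
  }
}

jsonlite::write_json(models, "inst/extdata/band_models.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", length(species) * 2, "models\n")
for (sp in species)
  cat(sp, "FAME C=O amp", models[[sp]]$FAME$bands[[1]]$amplitude,
      " TAG C=O amp", models[[sp]]$TAG$bands[[1]]$amplitude, "\n")
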