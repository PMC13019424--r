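co_band <- function(m) {
  for (b in m$bands) if (b$center >= 1720 && b$center <= 1770) return(b)
  NULL
}

amp_at <- function(m, center, tol = 3) {
  a <- 0
  for (b in m$bands) if (abs(b$center - center) <= tol) a <- a + b$amplitude
  a
}

test_that("component models encode the FAME/TAG spectral contrasts", {
  # saturated FAMEs carry no C=C band in 1600-1700
  for (sp in c("MA", "PA", "SA")) {
    centers <- vapply(component_model(sp, "FAME")$bands, `[[`, numeric(1), "center")
    expect_false(any(centers >= 1600 & centers <= 1700))
  }
  for (sp in c("OA", "LA")) {
    centers <- vapply(component_model(sp, "FAME")$bands, `[[`, numeric(1), "center")
    expect_true(any(centers >= 1600 & centers <= 1700))
  }
  # TAG ester C=O blue-shifted and broader than the FAME counterpart
  for (sp in acyl_species()) {
    f <- co_band(component_model(sp, "FAME"))
    t <- co_band(component_model(sp, "TAG"))
    expect_gt(t$center, f$center)
    expect_equal(t$fwhm / f$fwhm, 1.3, tolerance = 1e-9)
  }
  # two double bonds beat one at the C=C stretch
  expect_gt(amp_at(component_model("LA", "FAME"), 1650, tol = 8),
            amp_at(component_model("OA", "FAME"), 1650, tol = 8))
  # CH2/CH3 bend ordering among the saturated species
  a1439 <- vapply(c("MA", "PA", "SA"), function(sp)
    amp_at(component_model(sp, "FAME"), 1439, tol = 1), numeric(1))
  expect_true(a1439[["SA"]] > a1439[["PA"]] && a1439[["PA"]] > a1439[["MA"]])
  expect_error(component_model("XX", "FAME"), "unknown species")
  expect_error(component_model("MA", "OIL"), "unknown ester form")
})

test_that("rendering sums unit-height pseudo-Voigt profiles", {
  g <- default_grid()
  empty <- render_bands(list(species = NULL, bands = list()), g)
  expect_equal(empty$intensity, numeric(1151))
  one <- render_bands(list(bands = list(list(center = 1000, fwhm = 10,
                                             amplitude = 2.5, shape = 0.5))), g)
  expect_equal(one$intensity[g == 1000], 2.5)
  m1 <- component_model("MA", "FAME"); m2 <- component_model("OA", "TAG")
  both <- list(bands = c(m1$bands, m2$bands))
  expect_equal(render_bands(both, g)$intensity,
               render_bands(m1, g)$intensity + render_bands(m2, g)$intensity)
})

test_that("mixing is linear in mole fraction and reproducible from seeds", {
  comps <- render_pure_components("FAME")
  pure <- mix_spectrum(c(MA = 100, PA = 0, SA = 0, OA = 0, LA = 0), comps, NULL)
  expect_equal(pure$intensity, comps$MA$intensity)
  half <- mix_spectrum(c(MA = 50, PA = 50, SA = 0, OA = 0, LA = 0), comps, NULL)
  expect_equal(half$intensity, (comps$MA$intensity + comps$PA$intensity) / 2)
  np <- noise_params(seed = 77)
  a <- mix_spectrum(c(MA = 30, PA = 70, SA = 0, OA = 0, LA = 0), comps, np)
  b <- mix_spectrum(c(MA = 30, PA = 70, SA = 0, OA = 0, LA = 0), comps, np)
  expect_identical(a$intensity, b$intensity)
  expect_error(mix_spectrum(c(MA = 50, PA = 50), comps["MA"], NULL), "no component")
  # noiseless mixing is exactly linear in mole fraction
  fr <- with_test_seed(5, { v <- rgamma(5, 1); 100 * v / sum(v) })
  names(fr) <- acyl_species()
  mixed <- mix_spectrum(fr, comps, NULL)
  by_hand <- Reduce(`+`, lapply(acyl_species(), function(sp)
    (fr[[sp]] / 100) * comps[[sp]]$intensity))
  expect_equal(mixed$intensity, by_hand, tolerance = 1e-12)
})

test_that("mixture designs cover the simplex and are seed-deterministic", {
  d <- generate_design(seed = 3)
  expect_equal(nrow(d$train), 165L)
  expect_equal(nrow(d$test), 20L)
  tr <- as.matrix(d$train[, acyl_species()])
  expect_true(all(abs(rowSums(tr) - 100) < 1e-9))
  expect_true(all(abs(rowSums(as.matrix(d$test[, acyl_species()])) - 100) < 1e-9))
  # pure vertices, binary midpoints and the centroid are present
  expect_equal(tr[1:5, ], diag(5) * 100, ignore_attr = TRUE)
  expect_equal(sort(unique(tr[6, ])), c(0, 50))
  expect_equal(tr[16, ], rep(20, 5), ignore_attr = TRUE)
  expect_identical(generate_design(seed = 3), d)
  d2 <- generate_design(seed = 4)
  expect_false(isTRUE(all.equal(d2$train, d$train)))
  expect_error(generate_design(n_train = 3), "n_train")
})

test_that("datasets render one raw spectrum per composition, reproducibly", {
  d <- generate_design(seed = 9)
  np <- noise_params(seed = 9)
  train <- generate_dataset(d$train, "FAME", np)
  test <- generate_dataset(d$test, "TAG", np, seed_offset = 500000L)
  expect_equal(length(train) + length(test), 185L)
  expect_identical(train$meta$id, d$train$sample_id)
  # zero-noise vertices equal the component renders
  pure <- generate_dataset(d$train[1:5, ], "FAME", NULL)
  comps <- render_pure_components("FAME")
  for (j in 1:5)
    expect_equal(pure$intensity[, j], comps[[j]]$intensity, ignore_attr = TRUE)
  # regenerated output is byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  save_spectra(generate_dataset(d$test[1:4, ], "TAG", np), f1)
  save_spectra(generate_dataset(d$test[1:4, ], "TAG", np), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("FAME-to-TAG differences concentrate in the reported regions", {
  g <- default_grid()
  in_regions <- (g >= 1700 & g <= 1800) | (g >= 1400 & g <= 1500) |
    (g >= 800 & g <= 900)
  for (sp in acyl_species()) {
    f <- render_bands(component_model(sp, "FAME"), g)
    t <- render_bands(component_model(sp, "TAG"), g)
    d <- t$intensity - f$intensity
    expect_gt(sum(d[in_regions]^2) / sum(d^2), 0.6)
    # unsaturation markers near 1650 and 1260
    rel1650 <- f$intensity[g == 1650] / max(f$intensity)
    rel1260 <- f$intensity[g == 1260] / max(f$intensity)
    if (sp %in% c("OA", "LA")) {
      expect_gt(rel1650, 0.05); expect_gt(rel1260, 0.05)
    } else {
      expect_lt(rel1650, 0.02); expect_lt(rel1260, 0.02)
    }
  }
})
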