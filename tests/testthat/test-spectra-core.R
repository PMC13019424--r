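test_that("spectrum and grid validation enforce the data-model invariants", {
  expect_error(spectrum(c(650, 650, 651), c(1, 2, 3)), "strictly increasing")
  expect_error(spectrum(c(651, 650), c(1, 2)), "strictly increasing")
  expect_error(spectrum(c(650, 700), c(1, 2, 3)), "lengths differ")
  expect_error(spectrum(c(650, 700), c(1, NA)), "finite")
  expect_error(spectrum_set(c(650, 700), cbind(a = c(1, 2), a = c(3, 4))), "unique")
  expect_length(default_grid(), 1151L)
})

test_that("resampling interpolates linearly within the source span", {
  g <- default_grid()
  s <- spectrum(g, 2 * g, "lin")
  expect_identical(resample(s, g), s)
  r <- resample(s, c(700.5, 701.5))
  expect_equal(r$intensity, c(1401, 1403))
  expect_identical(r$id, "lin")
  expect_error(resample(s, c(1700, 1850)), "outside")
})

test_that("background subtraction is elementwise with a scale factor", {
  g <- c(650, 651)
  s <- spectrum(g, c(3, 3)); bg <- spectrum(g, c(1, 2))
  expect_equal(subtract_background(s, bg, 2)$intensity, c(1, -1))
  expect_equal(subtract_background(s, s, 1)$intensity, c(0, 0))
  expect_equal(subtract_background(s, bg, 0)$intensity, s$intensity)
  s3 <- spectrum(c(650, 652), c(3, 3))
  expect_error(subtract_background(s3, bg), "grids")
})

test_that("baseline correction recovers injected polynomial baselines", {
  g <- default_grid()
  x <- 2 * (g - min(g)) / diff(range(g)) - 1
  # a polynomial is its own baseline
  quad <- 1 + 2 * x + 3 * x^2
  cb <- correct_baseline(spectrum(g, quad), order = 2)
  expect_lt(max(abs(cb$corrected$intensity)), 1e-6 * max(abs(quad)))
  # constant spectrum
  cb2 <- correct_baseline(spectrum(g, rep(7, length(g))), order = 3)
  expect_equal(cb2$baseline$intensity, rep(7, length(g)), tolerance = 1e-9)
  # inject-and-recover: known peaks on a known cubic
  cubic <- 5 + 3 * x - 2 * x^2 + 1.5 * x^3
  peaks <- 2 * exp(-log(2) * ((g - 900) / 15)^2) +
    1.5 * exp(-log(2) * ((g - 1450) / 20)^2) +
    exp(-log(2) * ((g - 1740) / 12)^2)
  cb3 <- correct_baseline(spectrum(g, cubic + peaks), order = 3)
  rel_rms <- sqrt(mean((cb3$baseline$intensity - cubic)^2)) / sqrt(mean(cubic^2))
  expect_lt(rel_rms, 0.01)
  expect_error(correct_baseline(spectrum(c(650, 651), 1:2), order = 2), "order")
})

test_that("band area integrates by the trapezoid rule on closed intervals", {
  g <- default_grid()
  expect_equal(band_area(spectrum(g, rep(2, length(g))), c(1720, 1770)), 100)
  expect_equal(band_area(spectrum(g, rep(0, length(g))), c(1720, 1770)), 0)
  tri <- pmax(0, 1 - abs(g - 1000) / 5)   # base 10 cm-1, apex 1
  expect_equal(band_area(spectrum(g, tri), c(990, 1010)), 5)
  expect_error(band_area(spectrum(g, g), c(1000.2, 1000.8)), "2 grid points")
})

test_that("ester-band normalization yields unit area and is scale-invariant", {
  g <- default_grid()
  s <- render_bands(component_model("PA", "FAME"), g)
  n1 <- normalize_ester_band(s)
  expect_equal(band_area(n1, c(1720, 1770)), 1, tolerance = 1e-12)
  n2 <- normalize_ester_band(spectrum(g, 17.3 * s$intensity, s$id))
  expect_equal(n2$intensity, n1$intensity, tolerance = 1e-12)
  expect_equal(normalize_ester_band(n1)$intensity, n1$intensity, tolerance = 1e-12)
  expect_error(normalize_ester_band(spectrum(g, rep(0, length(g)) - 1)),
               "nonpositive")
})

test_that("window extraction concatenates closed intervals in order", {
  g <- default_grid()
  set <- bind_spectra(list(spectrum(g, g, "a"), spectrum(g, 2 * g, "b")))
  full <- extract_windows(set, "1800-650")
  expect_equal(dim(full$x), c(2L, 1151L))
  expect_equal(full$x[1, ], g, ignore_attr = TRUE)
  ma <- extract_windows(set, table1_windows()[["MA"]])
  expect_equal(ncol(ma$x), 101L + 121L + 91L + 281L)  # 594 channels
  expect_equal(ma$channel_map[1:101], seq(1700, 1800))
  # property: channel count equals the analytic count of grid points
  for (rep in 1:20) {
    iv <- with_test_seed(rep, {
      edges <- sort(sample(seq(650, 1800), 6))
      list(c(edges[1], edges[2] - 1), c(edges[3], edges[4] - 1),
           c(edges[5], edges[6]))
    })
    n_expect <- sum(vapply(iv, function(w)
      sum(g >= w[1] & g <= w[2]), numeric(1)))
    expect_equal(ncol(extract_windows(set, iv)$x), n_expect)
  }
  expect_error(window_set("1800-1700,1750-1600"), "overlap")
  expect_error(extract_windows(set, list(c(1810, 1900))), "no grid points")
})

test_that("spectra CSV roundtrips and rejects malformed files", {
  g <- default_grid()
  set <- bind_spectra(list(spectrum(g, sin(g / 50) + 2, "s1"),
                           spectrum(g, cos(g / 70) + 2, "s2"),
                           spectrum(g, sqrt(g), "s3")))
  f <- tempfile(fileext = ".csv")
  save_spectra(set, f)
  back <- load_spectra(f)
  expect_equal(back$wavenumber, set$wavenumber, tolerance = 1e-12)
  expect_equal(back$intensity, set$intensity, tolerance = 1e-12)
  # duplicate wavenumber rows
  bad <- read.csv(f, check.names = FALSE)
  bad[2, 1] <- bad[1, 1]
  f2 <- tempfile(fileext = ".csv")
  write.csv(bad, f2, row.names = FALSE)
  expect_error(load_spectra(f2), "strictly increasing")
  # shape bookkeeping: 1151 rows x 6 columns -> 5 spectra on 1151 points
  wide <- data.frame(wavenumber_cm1 = g, a = g, b = g, c = g, d = g, e = g)
  f3 <- tempfile(fileext = ".csv")
  write.csv(wide, f3, row.names = FALSE)
  got <- load_spectra(f3)
  expect_equal(length(got), 5L)
  expect_equal(length(got$wavenumber), 1151L)
})

test_that("the preprocessing chain is idempotent after the first normalization", {
  comps <- render_pure_components("FAME")
  noise <- noise_params(sigma_rel = 0, drift_order = 2, drift_amp_rel = 0.05,
                        seed = 11)
  s <- mix_spectrum(c(MA = 20, PA = 20, SA = 20, OA = 20, LA = 20), comps,
                    noise, "drifted")
  set <- bind_spectra(list(s))
  once <- preprocess_spectra(set, baseline_order = 3)
  twice <- preprocess_spectra(once, baseline_order = 3)
  expect_lt(max(abs(twice$intensity - once$intensity)), 1e-9)
})
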