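orthonormal_pures <- function(p = 40, seed = 8) {
  q <- with_test_seed(seed, qr.Q(qr(matrix(rnorm(p * 5), p))))
  colnames(q) <- acyl_species()
  structure(list(k = q, species = acyl_species(), channel_map = seq_len(p)),
            class = "pure_matrix")
}

test_that("classical least squares solves the unmixing exactly", {
  pures <- orthonormal_pures()
  s <- 0.3 * pures$k[, 1] + 0.7 * pures$k[, 2]
  expect_equal(drop(clsr_predict(pures, rbind(s), as_percent = FALSE)),
               c(MA = 0.3, PA = 0.7, SA = 0, OA = 0, LA = 0), tolerance = 1e-10)
  # negative coefficients are allowed
  s2 <- pures$k[, 1] - 0.2 * pures$k[, 2]
  expect_equal(drop(clsr_predict(pures, rbind(s2), as_percent = FALSE))[["PA"]],
               -0.2, tolerance = 1e-10)
  # noiseless synthetic mixtures: recovery vs an independent normal-equations oracle
  fx <- make_raw_mixtures(n = 8, seed = 21)
  pm <- pure_matrix(fx$components)
  got <- clsr_predict(pm, fx$set)
  oracle <- t(solve(crossprod(pm$k), crossprod(pm$k, fx$set$intensity))) * 100
  expect_equal(got, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(got, fx$fractions, tolerance = 1e-8, ignore_attr = TRUE)
  # rank deficiency is an error
  bad <- pm; bad$k[, 2] <- bad$k[, 1]
  expect_error(clsr_predict(bad, fx$set), "rank deficient")
})

test_that("nonnegative least squares satisfies KKT and matches oracles", {
  pures <- orthonormal_pures()
  # inactive constraints reproduce CLSR
  s <- 0.3 * pures$k[, 1] + 0.7 * pures$k[, 2]
  expect_equal(nnlsr_predict(pures, rbind(s)), clsr_predict(pures, rbind(s)),
               tolerance = 1e-8)
  # active constraint: orthonormal pures, s = 2 p1 - p2
  s2 <- 2 * pures$k[, 1] - pures$k[, 2]
  got <- drop(nnlsr_predict(pures, rbind(s2), as_percent = FALSE))
  expect_equal(got, c(MA = 2, PA = 0, SA = 0, OA = 0, LA = 0), tolerance = 1e-8)
  # dense grid-search oracle on the two-component subproblem
  K2 <- pures$k[, 1:2]
  expect_equal(unname(got[1:2]), nnls_grid_oracle(K2, s2), tolerance = 2e-3)
  # zero spectrum
  expect_equal(drop(nnlsr_predict(pures, rbind(rep(0, 40)))), rep(0, 5),
               ignore_attr = TRUE)
  # KKT on random instances + objective comparison against CLSR
  for (rep_ in 1:10) {
    inst <- with_test_seed(rep_, {
      K <- matrix(rnorm(30 * 5), 30)
      list(K = K, s = rnorm(30))
    })
    c_nn <- drop(pracma::lsqnonneg(inst$K, inst$s)$x)
    grad <- drop(crossprod(inst$K, inst$K %*% c_nn - inst$s))
    expect_true(all(abs(grad[c_nn > 1e-10]) < 1e-8))
    expect_true(all(grad[c_nn <= 1e-10] >= -1e-8))
    c_ls <- drop(qr.coef(qr(inst$K), inst$s))
    obj <- function(cc) sum((inst$K %*% cc - inst$s)^2)
    if (all(c_ls >= 0)) expect_equal(obj(c_nn), obj(c_ls), tolerance = 1e-8)
    else expect_gte(obj(c_nn), obj(c_ls) - 1e-10)
  }
})

test_that("NIPALS PLS1 matches its algebraic identities", {
  # rank-1 predictors with y proportional to the score: one LV is exact
  r1 <- with_test_seed(4, {
    t <- rnorm(25); p <- rnorm(12)
    list(X = tcrossprod(t, p), y = 3 * t + 1)
  })
  f1 <- plsr_fit(r1$X, r1$y, 1)
  expect_equal(plsr_predict(f1, r1$X), r1$y, tolerance = 1e-10,
               ignore_attr = TRUE)
  # full-rank PLS equals ordinary least squares on the training data
  fr <- with_test_seed(5, list(X = matrix(rnorm(20 * 8), 20), y = rnorm(20)))
  ff <- plsr_fit(fr$X, fr$y, 8)
  Xc <- cbind(1, fr$X)
  ols <- drop(Xc %*% qr.coef(qr(Xc), fr$y))
  expect_equal(plsr_predict(ff, fr$X), ols, tolerance = 1e-8, ignore_attr = TRUE)
  # the training-mean spectrum predicts the training-mean response
  expect_equal(drop(plsr_predict(ff, rbind(colMeans(fr$X)))), mean(fr$y),
               ignore_attr = TRUE)
  expect_error(plsr_fit(fr$X, rep(1, 20), 2), "zero variance")
  expect_error(plsr_fit(fr$X, fr$y, 25), "n_lv")
  # training RMSEC is non-increasing in the number of latent variables
  path <- acylquant:::plsr_coef_path(ff)
  rmsec <- vapply(seq_len(ff$n_lv), function(a) {
    yh <- drop(sweep(fr$X, 2, ff$x_mean) %*% path[, a]) + ff$y_mean
    rmse(yh, fr$y)
  }, numeric(1))
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("cross-validation picks the known number of latent factors", {
  hits <- 0L
  for (s_ in 1:100) {
    inst <- with_test_seed(s_, {
      t <- rnorm(50); p <- rnorm(10)
      list(X = tcrossprod(t, p), y = 2 * t + rnorm(50, sd = 0.3))
    })
    cv <- select_n_lv(inst$X, inst$y, max_lv = 3, k_folds = 10, seed = s_)
    if (cv$n_lv == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
  # determinism and the single-candidate case
  inst <- with_test_seed(7, list(X = matrix(rnorm(40 * 6), 40), y = rnorm(40)))
  a <- select_n_lv(inst$X, inst$y, max_lv = 4, seed = 3)
  b <- select_n_lv(inst$X, inst$y, max_lv = 4, seed = 3)
  expect_identical(a, b)
  expect_equal(select_n_lv(inst$X, inst$y, max_lv = 1, seed = 3)$n_lv, 1L,
               ignore_attr = TRUE)
})

test_that("greedy window search finds signal regions and breaks ties upward", {
  g <- seq(650, 1800, by = 10)
  n <- 40
  made <- with_test_seed(10, {
    y <- runif(n, 0, 100)
    m <- matrix(rnorm(length(g) * n, sd = 0.05), length(g))
    sig <- g >= 1500 & g <= 1700     # all predictive signal in one region
    for (j in seq_len(n)) m[sig, j] <- m[sig, j] + y[j] / 100
    list(set = spectrum_set(g, m + 2), y = y)  # offset keeps intensities "real"
  })
  res <- optimize_windows(made$set, made$y, k_folds = 5, seed = 2, max_lv = 3)
  # the signal region wins the first greedy round and stays selected
  singles <- res$trace[!grepl(",", res$trace$windows), ]
  expect_equal(singles$windows[which.min(singles$rmsecv)], "1700-1500")
  expect_true(any(res$selected$intervals[, "lo"] == 1500 &
                    res$selected$intervals[, "hi"] == 1700))
  expect_equal(res$cv_score, min(res$trace$rmsecv))
  # identical copies of the signal in every region: one region suffices and
  # the tie goes to the highest-wavenumber one
  made2 <- with_test_seed(11, {
    y <- runif(n, 0, 100)
    m <- matrix(rep(y / 100, each = length(g)), length(g)) + 2
    list(set = spectrum_set(g, m), y = y)
  })
  res2 <- optimize_windows(made2$set, made2$y, k_folds = 5, seed = 2, max_lv = 2)
  expect_equal(nrow(res2$selected$intervals), 1L)
  expect_equal(unname(res2$selected$intervals[1, ]), c(1700, 1800))
  # the selected set is at least as good as the best single region evaluated
  expect_lte(res$cv_score, min(singles$rmsecv) + 1e-12)
})

test_that("the three backends agree on noiseless synthetic mixtures", {
  fx <- make_raw_mixtures(n = 30, seed = 33)
  pm <- pure_matrix(fx$components)
  truth <- fx$fractions
  cls <- clsr_predict(pm, fx$set)
  nnl <- nnlsr_predict(pm, fx$set)
  expect_equal(cls, truth, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(nnl, truth, tolerance = 1e-6, ignore_attr = TRUE)
  X <- t(fx$set$intensity)
  for (sp in acyl_species()) {
    fit <- plsr_fit(X, truth[, sp], 4)   # centered 5-component mixtures: rank 4
    expect_equal(plsr_predict(fit, X), truth[, sp], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("trained models roundtrip through JSON and predict identically", {
  fx <- make_raw_mixtures(n = 25, seed = 12)
  set <- preprocess_spectra(fx$set)
  m <- train_species_model(set, fx$fractions[, "OA"], table1_windows()[["OA"]],
                           species = "OA", n_lv = 4)
  f <- tempfile(fileext = ".json")
  save_plsr_model(m, f)
  back <- load_plsr_model(f)
  expect_equal(predict(back, set), predict(m, set), tolerance = 1e-12)
  expect_identical(format(back$windows), format(m$windows))
})
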