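#' Pure-component spectra matrix
#'
#' Stacks preprocessed pure-component spectra as columns, in canonical
#' species order, for classical / nonnegative least-squares unmixing.
#'
#' @param components named list of pure [spectrum()] objects on one grid.
#' @param windows optional [window_set()] restricting the channels.
#' @return list of class `"pure_matrix"`: `k` (channels x components),
#'   `species`, `channel_map`.
#' @export
pure_matrix <- function(components, windows = NULL) {
  set <- bind_spectra(components[acyl_species()])
  if (!is.null(windows)) {
    ew <- extract_windows(set, windows)
    k <- t(ew$x); map <- ew$channel_map
  } else {
    k <- set$intensity; map <- set$wavenumber
  }
  colnames(k) <- acyl_species()
  structure(list(k = k, species = acyl_species(), channel_map = map),
            class = "pure_matrix")
}

as_sample_matrix <- function(x, windows = NULL) {
  if (inherits(x, "spectrum")) x <- bind_spectra(list(x))
  if (inherits(x, "spectrum_set")) {
    if (!is.null(windows)) extract_windows(x, windows)$x else t(x$intensity)
  } else as.matrix(x)
}

#' Classical least-squares unmixing (CLSR)
#'
#' Fits each spectrum as an unconstrained linear combination of the pure
#' component spectra by ordinary least squares; coefficients are mole
#' fractions, reported as mole % (can be negative or exceed 100 -- CLSR
#' imposes no constraint).
#'
#' @param pures a [pure_matrix()].
#' @param x a [spectrum()], [spectrum_set()], or samples x channels matrix
#'   on the same channels as `pures`.
#' @param as_percent multiply mole-fraction coefficients by 100 (default).
#' @return samples x 5 matrix of coefficients.
#' @export
clsr_predict <- function(pures, x, as_percent = TRUE) {
  stopifnot(inherits(pures, "pure_matrix"))
  X <- as_sample_matrix(x)
  if (ncol(X) != nrow(pures$k)) stop("channel count mismatch", call. = FALSE)
  qk <- qr(pures$k)
  if (qk$rank < ncol(pures$k))
    stop("pure spectra matrix is rank deficient", call. = FALSE)
  co <- t(qr.coef(qk, t(X)))
  colnames(co) <- pures$species
  rownames(co) <- rownames(X)
  if (as_percent) co * 100 else co
}

#' Nonnegative least-squares unmixing (NNLSR)
#'
#' As [clsr_predict()] but with coefficients constrained nonnegative,
#' solved by the Lawson-Hanson active-set method. At the solution the
#' Karush-Kuhn-Tucker conditions hold: the gradient vanishes on active
#' components and is nonnegative on clamped ones.
#'
#' @inheritParams clsr_predict
#' @return samples x 5 matrix of nonnegative coefficients.
#' @export
nnlsr_predict <- function(pures, x, as_percent = TRUE) {
  stopifnot(inherits(pures, "pure_matrix"))
  X <- as_sample_matrix(x)
  if (ncol(X) != nrow(pures$k)) stop("channel count mismatch", call. = FALSE)
  co <- t(apply(X, 1L, function(s) pracma::lsqnonneg(pures$k, s)$x))
  colnames(co) <- pures$species
  rownames(co) <- rownames(X)
  if (as_percent) co * 100 else co
}

#' NIPALS PLS1 fit
#'
#' Partial least-squares regression with a single response, by the NIPALS
#' algorithm: predictors and response are mean-centered; for each latent
#' variable the weight vector is the (normalized) covariance `X'y`, scores
#' `t = Xw`, x-loading `p = X't/(t't)`, y-loading `q = y't/(t't)`, and `X`,
#' `y` are deflated. The regression vector is `b = W (P'W)^{-1} q`, giving
#' the affine prediction `yhat = (x - x_mean) b + y_mean`.
#'
#' Component extraction stops early at the effective rank of the problem:
#' a component whose score standard deviation falls below `rank_tol` of the
#' first component's is treated as numerically rank-null and not extracted
#' (the returned `n_lv` records the count actually fitted). Spectral data
#' never support predictive structure four orders of magnitude below the
#' leading variance, and regressing on such directions produces explosive
#' coefficients.
#'
#' @param X samples x channels matrix.
#' @param y numeric response (mole %).
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n-1, p)`.
#' @param rank_tol relative score-sd floor for component extraction
#'   (default 1e-4).
#' @return object of class `"plsr_fit"` with `x_mean`, `y_mean`, `W`, `P`,
#'   `q`, `coef`, `n_lv`.
#' @export
plsr_fit <- function(X, y, n_lv, rank_tol = 1e-4) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n_lv < 1L || n_lv > min(n - 1L, p))
    stop("n_lv must be in [1, min(samples - 1, channels)]", call. = FALSE)
  if (stats::var(y) == 0)
    stop("degenerate target: response has zero variance", call. = FALSE)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xd <- sweep(X, 2L, x_mean); yd <- y - y_mean
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); q <- numeric(n_lv)
  x_scale <- sum(sweep(X, 2L, x_mean)^2)
  t2_first <- NA_real_
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * sqrt(x_scale * sum((y - y_mean)^2)) ||
        sum(Xd^2) < 1e-24 * x_scale) { n_lv <- a - 1L; break }
    w <- w / nw
    tt <- drop(Xd %*% w)
    t2 <- sum(tt^2)
    if (is.na(t2_first)) t2_first <- t2
    # effective-rank stop: score spread negligible vs the first component
    if (t2 < rank_tol^2 * t2_first) { n_lv <- a - 1L; break }
    P[, a] <- drop(crossprod(Xd, tt)) / t2
    q[a] <- sum(yd * tt) / t2
    W[, a] <- w
    Xd <- Xd - tcrossprod(tt, P[, a])
    yd <- yd - q[a] * tt
  }
  if (n_lv < 1L) stop("no usable latent variable (X'y vanished)", call. = FALSE)
  W <- W[, seq_len(n_lv), drop = FALSE]
  P <- P[, seq_len(n_lv), drop = FALSE]
  q <- q[seq_len(n_lv)]
  b <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, q = q,
                 coef = b, n_lv = n_lv), class = "plsr_fit")
}

# regression vectors for every truncation 1..n_lv of one fit (for CV paths)
plsr_coef_path <- function(fit) {
  vapply(seq_len(fit$n_lv), function(a) {
    W <- fit$W[, seq_len(a), drop = FALSE]
    P <- fit$P[, seq_len(a), drop = FALSE]
    drop(W %*% solve(crossprod(P, W), fit$q[seq_len(a)]))
  }, numeric(length(fit$x_mean)))
}

#' Predict from a PLS1 fit
#'
#' @param fit a `"plsr_fit"`.
#' @param X samples x channels matrix on the training channels.
#' @return numeric vector of predictions (mole %), not clipped to
#'   `[0, 100]`; an attribute `out_of_range` flags values outside it.
#' @export
plsr_predict <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(fit$x_mean))
    stop("channel count mismatch with the fitted model", call. = FALSE)
  yhat <- drop(sweep(X, 2L, fit$x_mean) %*% fit$coef) + fit$y_mean
  attr(yhat, "out_of_range") <- yhat < 0 | yhat > 100
  yhat
}

cv_folds <- function(n, k_folds, seed) {
  if (k_folds < 2L || k_folds > n)
    stop("k_folds must be in [2, n]", call. = FALSE)
  with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
}

#' Cross-validated choice of the number of latent variables
#'
#' k-fold cross-validation of [plsr_fit()] over `1..max_lv` latent
#' variables; the chosen count attains the global minimum RMSECV, taking the
#' smallest count on ties.
#'
#' @param X samples x channels matrix.
#' @param y response vector.
#' @param max_lv largest candidate count (>= 1; silently capped by the fold
#'   training sizes).
#' @param k_folds number of folds (default 10).
#' @param seed seed for the fold shuffle.
#' @return list of class `"cv_report"`: `rmsecv` (named by LV count),
#'   `n_lv` (chosen), `folds`.
#' @export
select_n_lv <- function(X, y, max_lv, k_folds = 10, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(max_lv >= 1)
  n <- nrow(X)
  folds <- cv_folds(n, k_folds, seed)
  # cap by the smallest fold-training size so every fold can fit `cap` LVs
  cap <- max(1L, min(max_lv, n - max(tabulate(folds)) - 1L, ncol(X)))
  sse <- numeric(cap); cnt <- 0L
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    fit <- plsr_fit(X[tr, , drop = FALSE], y[tr],
                    min(cap, sum(tr) - 1L, ncol(X)))
    path <- plsr_coef_path(fit)
    Xte <- sweep(X[!tr, , drop = FALSE], 2L, fit$x_mean)
    for (a in seq_len(cap)) {
      b <- path[, min(a, fit$n_lv)]
      sse[a] <- sse[a] + sum((drop(Xte %*% b) + fit$y_mean - y[!tr])^2)
    }
    cnt <- cnt + sum(!tr)
  }
  rmsecv <- sqrt(sse / cnt)
  names(rmsecv) <- seq_len(cap)
  structure(list(rmsecv = rmsecv, n_lv = which.min(rmsecv), folds = folds),
            class = "cv_report")
}

#' Greedy forward selection of spectral windows
#'
#' Starting from an empty window set, repeatedly adds the candidate region
#' that most lowers the cross-validated RMSECV of a PLS1 model, stopping
#' when no addition improves it by more than `tol`. Ties are broken in
#' favor of the higher-wavenumber region. The same fold split is reused for
#' every candidate so scores are comparable.
#'
#' @param set preprocessed [spectrum_set()].
#' @param y response vector (mole %).
#' @param region_pool list/matrix of candidate `c(lo, hi)` intervals, or a
#'   window-dialect string; default [default_region_pool()].
#' @param k_folds,seed cross-validation controls.
#' @param max_lv largest latent-variable count tried per candidate model.
#' @param tol minimum RMSECV improvement to accept a region (default 1e-6).
#' @return list of class `"window_search"`: `selected` ([window_set()]),
#'   `cv_score`, `trace` (data frame of candidate set / score pairs).
#' @export
optimize_windows <- function(set, y, region_pool = default_region_pool(),
                             k_folds = 10, seed = 1L, max_lv = 10, tol = 1e-6) {
  pool <- window_set(region_pool)$intervals   # descending by hi
  if (nrow(pool) == 0L) stop("empty region pool", call. = FALSE)
  score_of <- function(iv) {
    ew <- extract_windows(set, window_set(iv))
    cv <- select_n_lv(ew$x, y, max_lv = max_lv, k_folds = k_folds, seed = seed)
    min(cv$rmsecv)
  }
  chosen <- matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("lo", "hi")))
  remaining <- seq_len(nrow(pool))
  best <- Inf
  trace <- list()
  repeat {
    step_best <- Inf; step_idx <- NA_integer_
    for (r in remaining) {             # pool order = descending hi = tie order
      cand <- rbind(chosen, pool[r, , drop = FALSE])
      sc <- score_of(cand)
      trace[[length(trace) + 1L]] <-
        data.frame(windows = format(window_set(cand)), rmsecv = sc)
      # numerically tied candidates go to the first (highest-wavenumber) one
      if (!is.finite(step_best) ||
          sc < step_best - max(1e-12, 1e-9 * abs(step_best))) {
        step_best <- sc; step_idx <- r
      }
    }
    if (!is.finite(step_best) || step_best >= best - tol) break
    best <- step_best
    chosen <- rbind(chosen, pool[step_idx, , drop = FALSE])
    remaining <- setdiff(remaining, step_idx)
    if (length(remaining) == 0L) break
  }
  if (nrow(chosen) == 0L) {            # first region always enters
    first <- do.call(rbind, trace)
    k <- which.min(first$rmsecv)
    chosen <- window_set(first$windows[k])$intervals
    best <- first$rmsecv[k]
  }
  structure(list(selected = window_set(chosen), cv_score = best,
                 trace = do.call(rbind, trace)), class = "window_search")
}

#' Table-style breakpoint region pool
#'
#' The candidate regions for window selection: the partition of the working
#' range induced by the breakpoints 650, 800, 930, 1110, 1200, 1280, 1380,
#' 1500, 1700, 1800 cm\eqn{^{-1}}, the boundaries the published window sets
#' are built from.
#'
#' @return list of `c(lo, hi)` intervals.
#' @export
default_region_pool <- function() {
  bp <- c(650, 800, 930, 1110, 1200, 1280, 1380, 1500, 1700, 1800)
  lapply(seq_len(length(bp) - 1L), function(i) c(bp[i], bp[i + 1L]))
}

#' Train one per-species PLS1 model on a windowed spectrum set
#'
#' Extracts the model's spectral windows, optionally chooses the number of
#' latent variables by cross-validation, and fits the final PLS1 model on
#' all samples.
#'
#' @param set preprocessed training [spectrum_set()].
#' @param y response (mole % of the target species).
#' @param windows a [window_set()] or window string.
#' @param species species code stored on the model.
#' @param n_lv `"auto"` (cross-validated, default) or an integer.
#' @param max_lv,k_folds,seed cross-validation controls.
#' @return object of class `"plsr_model"`: the `"plsr_fit"` plus `windows`,
#'   `channel_map`, `species`, `cv` (a `"cv_report"` or `NULL`).
#' @export
train_species_model <- function(set, y, windows, species = NULL,
                                n_lv = "auto", max_lv = 12, k_folds = 10,
                                seed = 1L) {
  w <- window_set(windows)
  ew <- extract_windows(set, w)
  cv <- NULL
  if (identical(n_lv, "auto")) {
    cv <- select_n_lv(ew$x, y, max_lv = max_lv, k_folds = k_folds, seed = seed)
    n_lv <- cv$n_lv
  }
  fit <- plsr_fit(ew$x, y, n_lv)
  structure(c(fit, list(windows = w, channel_map = ew$channel_map,
                        species = species, cv = cv)),
            class = c("plsr_model", "plsr_fit"))
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model %s: %d LV, windows %s>\n",
              if (is.null(x$species)) "" else x$species,
              x$n_lv, format(x$windows)))
  invisible(x)
}

#' Predict mole % from a trained per-species model
#'
#' @param object a `"plsr_model"`.
#' @param set preprocessed [spectrum_set()] on the training grid.
#' @param ... unused.
#' @return numeric predictions with an `out_of_range` attribute.
#' @export
predict.plsr_model <- function(object, set, ...) {
  ew <- extract_windows(set, object$windows)
  if (!isTRUE(all.equal(ew$channel_map, object$channel_map, tolerance = 0)))
    stop("channel map mismatch: grid differs from the training grid", call. = FALSE)
  p <- plsr_predict(object, ew$x)
  names(p) <- rownames(ew$x)
  p
}

#' Serialize / restore a per-species PLS model as JSON
#'
#' @param model a `"plsr_model"`.
#' @param path file path.
#' @return `path` (save) or a `"plsr_model"` (load).
#' @export
save_plsr_model <- function(model, path) {
  obj <- list(species = model$species, windows = format(model$windows),
              n_lv = model$n_lv, x_mean = model$x_mean, y_mean = model$y_mean,
              coef = model$coef, channel_map = model$channel_map)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_plsr_model
#' @export
load_plsr_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(x_mean = as.numeric(o$x_mean), y_mean = o$y_mean,
                 W = NULL, P = NULL, q = NULL, coef = as.numeric(o$coef),
                 n_lv = o$n_lv, windows = window_set(o$windows),
                 channel_map = as.numeric(o$channel_map),
                 species = o$species, cv = NULL),
            class = c("plsr_model", "plsr_fit"))
}
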