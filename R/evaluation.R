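#' Root-mean-square error
#'
#' \eqn{\sqrt{\sum_i (\hat y_i - y_i)^2 / n}} -- the calibration error
#' (RMSEC) when computed on training samples and the prediction error
#' (RMSEP) when computed on independent test samples. Note the `n`
#' denominator, unlike the `n - 1` of [sample_sd()]: RMSE measures accuracy
#' against known values, the SD measures precision around the mean.
#'
#' @param y_hat predicted values (mole %).
#' @param y reference values, same length.
#' @return scalar RMSE.
#' @export
rmse <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((y_hat - y)^2))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (\hat y_i - y_i)^2 / \sum (y_i - \bar y)^2}.
#'
#' @inheritParams rmse
#' @return scalar, at most 1 (negative when worse than the mean).
#' @export
r_squared <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop("length mismatch", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero-variance reference values", call. = FALSE)
  1 - sum((y_hat - y)^2) / ss_tot
}

#' Sample standard deviation (n - 1 denominator)
#'
#' Dispersion of replicate analyses around their mean:
#' \eqn{\mu = \sqrt{\sum_i (\hat y_i - \bar y)^2 / (n - 1)}}.
#'
#' @param values numeric vector, length >= 2.
#' @return scalar SD.
#' @export
sample_sd <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  sqrt(sum((values - mean(values))^2) / (length(values) - 1L))
}

#' Standard error of a mean
#'
#' \eqn{\mu_a = \mu / \sqrt{n}}: the dispersion expected for the mean of `n`
#' independent measurements with per-measurement SD `sd`.
#'
#' @param sd standard deviation (>= 0).
#' @param n number of measurements (>= 1).
#' @return scalar standard error.
#' @export
standard_error <- function(sd, n) {
  if (sd < 0) stop("sd must be nonnegative", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  sd / sqrt(n)
}

#' Summarize predicted compositions
#'
#' Per-species mean, SD and standard error over a table of predicted
#' compositions, plus the "unknown" remainder: the five modeled acyl groups
#' need not exhaust a real fat, so `unknown = 100 - sum(means)`. The
#' remainder may be negative when predictions over-sum; it is reported as-is
#' with a flag.
#'
#' @param predictions samples x 5 matrix or data frame of mole %, columns
#'   named by species (`MA`..`LA`).
#' @return object of class `"composition_summary"`: data frame `table`
#'   (species, mean, sd, se), `total_known`, `unknown`, `n`, and logical
#'   `oversum` flag.
#' @export
composition_summary <- function(predictions) {
  p <- as.matrix(as.data.frame(predictions)[, acyl_species()])
  if (nrow(p) < 2L) stop("need at least 2 samples", call. = FALSE)
  n <- nrow(p)
  mean_ <- colMeans(p)
  sd_ <- apply(p, 2L, sample_sd)
  tab <- data.frame(species = acyl_species(), mean = unname(mean_),
                    sd = unname(sd_), se = unname(sd_ / sqrt(n)))
  total <- sum(mean_)
  structure(list(table = tab, total_known = total, unknown = 100 - total,
                 n = n, oversum = total > 100), class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  tab <- x$table
  # report in the table convention: 2 decimals, species then remainder
  cat("composition (mole %), n =", x$n, "\n")
  for (k in seq_len(nrow(tab)))
    cat(sprintf("  %-3s %6.2f +/- %.2f (se %.2f)\n",
                tab$species[k], tab$mean[k], tab$sd[k], tab$se[k]))
  cat(sprintf("  unknown %6.2f\n  total known %6.2f%s\n",
              x$unknown, x$total_known,
              if (x$oversum) "  [predictions over-sum]" else ""))
  invisible(x)
}

#' Write a composition summary as CSV
#'
#' Rows are the five acyl groups plus `unknown` and `total_known`; values
#' rounded to 2 decimals, matching the reporting convention.
#'
#' @param x a `"composition_summary"`.
#' @param path file path.
#' @export
save_composition_summary <- function(x, path) {
  df <- rbind(
    data.frame(row = x$table$species, mean = round(x$table$mean, 2),
               sd = round(x$table$sd, 2), se = round(x$table$se, 2)),
    data.frame(row = c("unknown", "total_known"),
               mean = round(c(x$unknown, x$total_known), 2),
               sd = NA_real_, se = NA_real_))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-species evaluation report
#'
#' RMSEC / RMSEP and calibration / prediction R-squared for one model.
#'
#' @param y_cal_hat,y_cal training predictions and references.
#' @param y_pred_hat,y_pred test predictions and references.
#' @param species species code.
#' @return one-row data frame with `species`, `rmsec`, `rmsep`, `r2_cal`,
#'   `r2_pred`, `n_train`, `n_test`.
#' @export
evaluation_report <- function(y_cal_hat, y_cal, y_pred_hat, y_pred,
                              species = NA_character_) {
  data.frame(species = species,
             rmsec = rmse(y_cal_hat, y_cal),
             rmsep = rmse(y_pred_hat, y_pred),
             r2_cal = r_squared(y_cal_hat, y_cal),
             r2_pred = r_squared(y_pred_hat, y_pred),
             n_train = length(y_cal), n_test = length(y_pred))
}
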