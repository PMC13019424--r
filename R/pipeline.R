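#' Published spectral window sets per acyl model
#'
#' The optimized spectral window regions of the five TAG analytical models,
#' in the `"hi-lo,..."` dialect.
#'
#' @return named character vector (one window string per species).
#' @export
table1_windows <- function() {
  c(MA = "1800-1700,1500-1380,1200-1110,930-650",
    PA = "1800-1700,1380-1280,1110-800",
    SA = "1800-1700,1500-1280,1200-650",
    OA = "1800-1380,1280-930,800-650",
    LA = "1800-1500,1380-1280,1200-930,800-650")
}

#' Default pipeline configuration
#'
#' All tunable parameters of an end-to-end run, overridable via a YAML file
#' ([load_config()]) or argument. The single global `seed` fans out to
#' per-stage seeds by fixed offsets, so one integer pins every random draw.
#'
#' @param ... name/value overrides of the defaults.
#' @return named list of class `"run_config"`.
#' @export
default_config <- function(...) {
  cfg <- list(
    grid_from = 650, grid_to = 1800, grid_by = 1,
    n_train = 165, n_test = 20,
    sigma_rel = 0.01, drift_order = 2, drift_amp_rel = 0.02,
    baseline_order = 3, baseline_iter = 20,
    norm_window = c(1720, 1770),
    windows = "table1",            # "table1", "auto", or named list of strings
    max_lv = 12, k_folds = 10,
    seed = 1L,
    out_dir = "acylquant_run")
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [default_config()].
#' @param ... further overrides applied after the file.
#' @return a `"run_config"`.
#' @export
load_config <- function(path, ...) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  do.call(default_config, c(vals, list(...)))
}

cfg_grid <- function(cfg) default_grid(cfg$grid_from, cfg$grid_to, cfg$grid_by)
cfg_noise <- function(cfg, offset = 0L)
  noise_params(cfg$sigma_rel, cfg$drift_order, cfg$drift_amp_rel,
               seed = cfg$seed + offset)
cfg_preprocess <- function(cfg, set)
  preprocess_spectra(set, baseline_order = cfg$baseline_order,
                     n_iter = cfg$baseline_iter, norm_window = cfg$norm_window)

cfg_windows <- function(cfg) {
  if (identical(cfg$windows, "table1") || identical(cfg$windows, "auto"))
    return(table1_windows())
  unlist(cfg$windows)[acyl_species()]
}

artifact <- function(cfg, name) file.path(cfg$out_dir, name)

#' Pipeline stage: simulate
#'
#' Generates the mixture design and raw synthetic FAME training / TAG test
#' spectra, and writes them (plus composition tables) to the output
#' directory.
#'
#' @param cfg a `"run_config"`.
#' @return invisibly, the list of written file paths.
#' @export
stage_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- cfg_grid(cfg)
  design <- generate_design(cfg$n_train, cfg$n_test, seed = cfg$seed)
  train <- generate_dataset(design$train, "FAME", cfg_noise(cfg), g,
                            seed_offset = 0L)
  test <- generate_dataset(design$test, "TAG", cfg_noise(cfg), g,
                           seed_offset = 500000L)
  paths <- c(train_spectra = artifact(cfg, "train_fame_spectra.csv"),
             train_comps = artifact(cfg, "train_compositions.csv"),
             test_spectra = artifact(cfg, "test_tag_spectra.csv"),
             test_comps = artifact(cfg, "test_compositions.csv"))
  save_spectra(train, paths[["train_spectra"]])
  save_compositions(design$train, paths[["train_comps"]])
  save_spectra(test, paths[["test_spectra"]])
  save_compositions(design$test, paths[["test_comps"]])
  message(sprintf("[simulate] %d train FAME + %d test TAG spectra -> %s",
                  cfg$n_train, cfg$n_test, cfg$out_dir))
  invisible(paths)
}

#' Pipeline stage: transfer
#'
#' Renders noise-free pure FAME/TAG pairs, preprocesses them, computes the
#' per-acyl spectral variances and writes the transfer set JSON.
#'
#' @param cfg a `"run_config"`.
#' @return invisibly, the transfer JSON path.
#' @export
stage_transfer <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- cfg_grid(cfg)
  prep_pures <- function(form) {
    set <- bind_spectra(unname(render_pure_components(form, g)))
    set <- cfg_preprocess(cfg, set)
    stats::setNames(lapply(seq_len(5L), function(j) get_spectrum(set, j)),
                    acyl_species())
  }
  transfer <- compute_transfer_set(prep_pures("FAME"), prep_pures("TAG"))
  path <- artifact(cfg, "transfer_set.json")
  save_transfer_set(transfer, path)
  ev <- vapply(transfer$deltas, `[[`, numeric(1L), "pc1_explained")
  message(sprintf("[transfer] PC1 explained: %s",
                  paste(sprintf("%s %.0f%%", names(ev), 100 * ev), collapse = ", ")))
  invisible(path)
}

#' Pipeline stage: train
#'
#' Loads the FAME training spectra and transfer set, preprocesses, converts
#' to simulated TAG spectra, and fits one windowed PLS1 model per acyl
#' group (latent variables chosen by cross-validation).
#'
#' @param cfg a `"run_config"`.
#' @return invisibly, the named list of model JSON paths.
#' @export
stage_train <- function(cfg) {
  spath <- artifact(cfg, "train_fame_spectra.csv")
  cpath <- artifact(cfg, "train_compositions.csv")
  tpath <- artifact(cfg, "transfer_set.json")
  for (p in c(spath, cpath, tpath))
    if (!file.exists(p)) stop(sprintf("missing input: %s", p), call. = FALSE)
  set <- load_spectra(spath)
  comps <- load_compositions(cpath)
  set$meta <- data.frame(id = comps$sample_id, comps[, acyl_species()],
                         check.names = FALSE)
  transfer <- load_transfer_set(tpath)
  sim <- simulate_tag_dataset(cfg_preprocess(cfg, set), transfer)
  wins <- cfg_windows(cfg)
  paths <- character(0)
  for (sp in acyl_species()) {
    m <- train_species_model(sim, sim$meta[[sp]], wins[[sp]], species = sp,
                             max_lv = cfg$max_lv, k_folds = cfg$k_folds,
                             seed = cfg$seed + 900L)
    p <- artifact(cfg, sprintf("model_%s.json", sp))
    save_plsr_model(m, p)
    paths[sp] <- p
    message(sprintf("[train] %s: %d LV on windows %s", sp, m$n_lv, format(m$windows)))
  }
  invisible(paths)
}

#' Pipeline stage: predict
#'
#' Applies the five trained models to a spectra CSV and writes per-sample
#' predicted compositions.
#'
#' @param cfg a `"run_config"`.
#' @param spectra_path spectra CSV (default: the simulated test set).
#' @return invisibly, the predictions CSV path.
#' @export
stage_predict <- function(cfg, spectra_path = artifact(cfg, "test_tag_spectra.csv")) {
  if (!file.exists(spectra_path))
    stop(sprintf("missing input: %s", spectra_path), call. = FALSE)
  set <- cfg_preprocess(cfg, load_spectra(spectra_path))
  pred <- data.frame(sample_id = colnames(set$intensity))
  for (sp in acyl_species()) {
    mp <- artifact(cfg, sprintf("model_%s.json", sp))
    if (!file.exists(mp)) stop(sprintf("missing model: %s", mp), call. = FALSE)
    pred[[sp]] <- as.numeric(predict(load_plsr_model(mp), set))
  }
  path <- artifact(cfg, "predictions.csv")
  save_compositions(pred, path)
  message(sprintf("[predict] %d samples -> %s", nrow(pred), path))
  invisible(path)
}

#' Pipeline stage: evaluate
#'
#' Joins predictions with reference compositions and writes a per-species
#' report (RMSEP, R-squared) plus a composition summary.
#'
#' @param cfg a `"run_config"`.
#' @return invisibly, the per-species report data frame.
#' @export
stage_evaluate <- function(cfg) {
  pred <- load_compositions(artifact(cfg, "predictions.csv"))
  truth <- load_compositions(artifact(cfg, "test_compositions.csv"))
  stopifnot(identical(pred$sample_id, truth$sample_id))
  rep_ <- do.call(rbind, lapply(acyl_species(), function(sp)
    data.frame(species = sp,
               rmsep = rmse(pred[[sp]], truth[[sp]]),
               r2_pred = r_squared(pred[[sp]], truth[[sp]]),
               n_test = nrow(pred))))
  utils::write.csv(rep_, artifact(cfg, "evaluation.csv"), row.names = FALSE)
  save_composition_summary(composition_summary(pred),
                           artifact(cfg, "composition_summary.csv"))
  message(paste(sprintf("[evaluate] %s RMSEP %.2f", rep_$species, rep_$rmsep),
                collapse = "  "))
  invisible(rep_)
}

#' Pipeline stage: cluster
#'
#' Median-linkage clustering of the predicted compositions; writes the
#' merge matrix CSV.
#'
#' @param cfg a `"run_config"`.
#' @return invisibly, the `"linkage_tree"`.
#' @export
stage_cluster <- function(cfg) {
  pred <- load_compositions(artifact(cfg, "predictions.csv"))
  tree <- hca_median(as.matrix(pred[, acyl_species()]), labels = pred$sample_id)
  save_linkage(tree, artifact(cfg, "linkage.csv"))
  message(sprintf("[cluster] %d leaves -> %s", tree$n, artifact(cfg, "linkage.csv")))
  invisible(tree)
}

#' Run the composed pipeline
#'
#' simulate -> transfer -> train -> predict -> evaluate -> cluster, all from
#' one configuration; identical configurations (including seed) reproduce
#' byte-identical numeric artifacts.
#'
#' @param cfg a `"run_config"`.
#' @return invisibly, the evaluation report data frame.
#' @export
run_pipeline <- function(cfg = default_config()) {
  stage_simulate(cfg)
  stage_transfer(cfg)
  stage_train(cfg)
  stage_predict(cfg)
  rep_ <- stage_evaluate(cfg)
  stage_cluster(cfg)
  invisible(rep_)
}

#' Closed-loop transfer benchmark
#'
#' The package's end-to-end accuracy readout, entirely in memory: generate
#' the mixture design; synthesize noisy FAME training mixtures; compute
#' transfer deltas from noise-free preprocessed pure FAME/TAG pairs; build
#' simulated TAG training spectra; fit the five windowed PLS1 models
#' (cross-validated latent variables); and evaluate them on directly
#' rendered synthetic TAG test mixtures whose true compositions are known
#' by construction. With `use_transfer = FALSE` the models are instead
#' trained on the FAME spectra unchanged, quantifying the cost of ignoring
#' the FAME/TAG spectral difference.
#'
#' @param seed global seed (fans out to design / noise / CV seeds).
#' @param n_train,n_test design sizes (defaults 165 / 20).
#' @param sigma_rel,drift_order,drift_amp_rel noise model (see
#'   [noise_params()]).
#' @param windows named window strings per species (default
#'   [table1_windows()]).
#' @param max_lv,k_folds cross-validation controls; `n_lv` may be an
#'   integer to skip cross-validation.
#' @param n_lv `"auto"` or fixed integer latent-variable count.
#' @param baseline_order baseline polynomial degree.
#' @param use_transfer train on simulated TAG spectra (default) or raw
#'   FAME spectra.
#' @return list: `rmsep` (named per-species), `rmsec`, `n_lv` (per
#'   species), `predictions` (test samples x species), `truth`.
#' @export
transfer_benchmark <- function(seed = 1L, n_train = 165, n_test = 20,
                               sigma_rel = 0.01, drift_order = 2,
                               drift_amp_rel = 0.02,
                               windows = table1_windows(),
                               max_lv = 12, k_folds = 10, n_lv = "auto",
                               baseline_order = 3, use_transfer = TRUE) {
  g <- default_grid()
  noise <- noise_params(sigma_rel, drift_order, drift_amp_rel, seed = seed)
  design <- generate_design(n_train, n_test, seed = seed)
  fame_train <- generate_dataset(design$train, "FAME", noise, g, seed_offset = 0L)
  tag_test <- generate_dataset(design$test, "TAG", noise, g, seed_offset = 500000L)
  prep <- function(set) preprocess_spectra(set, baseline_order = baseline_order)
  fame_train <- prep(fame_train)
  tag_test <- prep(tag_test)
  train_set <- if (use_transfer) {
    prep_pures <- function(form) {
      set <- prep(bind_spectra(unname(render_pure_components(form, g))))
      stats::setNames(lapply(seq_len(5L), function(j) get_spectrum(set, j)),
                      acyl_species())
    }
    simulate_tag_dataset(fame_train,
                         compute_transfer_set(prep_pures("FAME"), prep_pures("TAG")))
  } else fame_train
  rmsep <- rmsec <- nlv <- stats::setNames(numeric(5L), acyl_species())
  pred <- matrix(NA_real_, n_test, 5L, dimnames = list(NULL, acyl_species()))
  for (sp in acyl_species()) {
    m <- train_species_model(train_set, train_set$meta[[sp]], windows[[sp]],
                             species = sp, n_lv = n_lv, max_lv = max_lv,
                             k_folds = k_folds, seed = seed + 900L)
    rmsec[sp] <- rmse(predict(m, train_set), train_set$meta[[sp]])
    pred[, sp] <- predict(m, tag_test)
    rmsep[sp] <- rmse(pred[, sp], design$test[[sp]])
    nlv[sp] <- m$n_lv
  }
  list(rmsep = rmsep, rmsec = rmsec, n_lv = nlv, predictions = pred,
       truth = design$test)
}
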