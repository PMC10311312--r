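#' Run the window-length / horizon scenario grid
#'
#' For every combination of window length `t` and horizon `n`, splits the
#' cohort once (patient-level, stratified by converter status), normalises
#' with training statistics, builds first-window sequences, and trains
#' `repeats` models with distinct derived seeds: the direct architecture when
#' `n = 1`, the sequence-to-sequence architecture when `n >= 2`.  Each repeat
#' re-randomises initialisation, batching and dropout but reuses the fixed
#' train/test split.  Scenarios with no eligible samples, a single class in
#' training, or an empty/degenerate test set are skipped with a log entry.
#'
#' @param cohort An imputed `mci_cohort` (run [filter_missingness()] and
#'   [impute_knn()] first, or see [preprocess_cohort()]).
#' @param t_list Window lengths (default `c(2, 3, 5, 6)`).
#' @param n_list Horizons (default `1:4`).
#' @param repeats Models per scenario (default 15).
#' @param config Base [model_config()]; its seed is ignored in favour of
#'   seeds derived from `seed`.
#' @param test_fraction Held-out patient fraction (default 0.30).
#' @param use_demographics Feed the encoded demographic vector to the head.
#' @param include_age Append per-visit age to the longitudinal features.
#' @param include_cn Allow CN visits inside input windows.
#' @param seed Master seed; the full result table is reproducible given it.
#' @return A tidy data.frame with one row per (t, n, repeat): scenario
#'   metadata, sample counts, confusion counts, precision, sensitivity, F2.
#'   Skipped scenarios are recorded in attribute `"skipped"`.
#' @export
run_scenarios <- function(cohort, t_list = c(2L, 3L, 5L, 6L), n_list = 1:4,
                          repeats = 15L, config = model_config(),
                          test_fraction = 0.30, use_demographics = TRUE,
                          include_age = TRUE, include_cn = FALSE, seed = 1L) {
  parts <- split_stratified(cohort, test_fraction = test_fraction,
                            seed = derive_seed(seed, 1L))
  state <- fit_minmax(parts$train)
  train_c <- apply_minmax(parts$train, state)
  test_c <- apply_minmax(parts$test, state)
  enc <- if (use_demographics) fit_demographic_encoder(parts$train)
  rows <- list()
  skipped <- list()
  for (t in t_list) for (n in n_list) {
    tr <- build_sequences(train_c, t, n, demo_encoder = enc,
                          include_cn = include_cn, include_age = include_age)
    te <- build_sequences(test_c, t, n, demo_encoder = enc,
                          include_cn = include_cn, include_age = include_age)
    if (!length(tr$y) || !length(te$y) || length(unique(tr$y)) < 2) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        t = t, n = n,
        reason = if (!length(tr$y)) "no eligible training samples"
                 else if (!length(te$y)) "no eligible test samples"
                 else "single training class")
      next
    }
    for (r in seq_len(repeats)) {
      cfg <- config
      cfg$seed <- derive_seed(seed, t, n, r)
      fit <- train_model(tr, cfg)
      ev <- evaluate_model(fit, te)
      ev$architecture <- fit$architecture
      ev$repeat_index <- r
      ev$seed <- cfg$seed
      ev$n_train <- length(tr$y)
      ev$train_converters <- sum(tr$y == 1)
      ev$test_converters <- sum(te$y == 1)
      rows[[length(rows) + 1L]] <- ev
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
  out
}

#' Summarise a scenario table
#'
#' Per-scenario mean and standard deviation of F2 and sensitivity over
#' repeats.
#'
#' @param results A [run_scenarios()] table.
#' @return A data.frame with one row per (t, n).
#' @export
summarize_scenarios <- function(results) {
  agg <- function(fml, fun, nm) {
    a <- stats::aggregate(fml, data = results, FUN = fun)
    names(a)[3] <- nm
    a
  }
  out <- Reduce(function(a, b) merge(a, b, by = c("t", "n")), list(
    agg(f2 ~ t + n, mean, "mean_f2"),
    agg(f2 ~ t + n, stats::sd, "sd_f2"),
    agg(sensitivity ~ t + n, mean, "mean_sensitivity"),
    agg(sensitivity ~ t + n, stats::sd, "sd_sensitivity")))
  out[order(out$t, out$n), ]
}

#' Mean-aggregate the input window of each sample
#'
#' Collapses each sample's `t x F` window to the per-feature mean, the flat
#' representation used by the non-recurrent baselines (demographics are
#' deliberately excluded).
#'
#' @param samples A `sequence_set`.
#' @return A data.frame, one row per sample, `F` feature columns.
#' @export
baseline_mean_aggregate <- function(samples) {
  M <- apply(samples$X, c(1, 3), mean)
  M <- matrix(M, nrow = dim(samples$X)[1],
              dimnames = list(NULL, samples$feature_names))
  as.data.frame(M)
}

#' Train and evaluate the mean-aggregation baselines
#'
#' Random forest and radial-kernel support vector machine classifiers fitted
#' on the per-feature window means, with class weights proportional to the
#' same positive-class weight `alpha` used by the recurrent loss, evaluated
#' with the same confusion-count metrics as [evaluate_model()].
#'
#' @param train_samples,test_samples `sequence_set`s.
#' @param alpha Positive-class weight (default 0.7).
#' @param threshold Probability threshold (default 0.5).
#' @param seed Seed for the random forest.
#' @return A data.frame with one row per baseline (`method` column).
#' @export
run_baselines <- function(train_samples, test_samples, alpha = 0.7,
                          threshold = 0.5, seed = 1L) {
  Xtr <- baseline_mean_aggregate(train_samples)
  Xte <- baseline_mean_aggregate(test_samples)
  ytr <- factor(train_samples$y, levels = c(0, 1))
  wts <- c("0" = 1 - alpha, "1" = alpha)
  rows <- list()
  with_seed(derive_seed(seed, 101L), {
    rf <- randomForest::randomForest(Xtr, ytr, classwt = wts)
    p_rf <- stats::predict(rf, Xte, type = "prob")[, "1"]
    rows$rf <- confusion_metrics(test_samples$y, as.integer(p_rf >= threshold),
                                 t = test_samples$t, n = test_samples$n,
                                 threshold = threshold)
    rows$rf$method <- "random_forest"
    sv <- e1071::svm(Xtr, ytr, kernel = "radial", probability = TRUE,
                     class.weights = wts)
    p_sv <- attr(stats::predict(sv, Xte, probability = TRUE),
                 "probabilities")[, "1"]
    rows$svm <- confusion_metrics(test_samples$y, as.integer(p_sv >= threshold),
                                  t = test_samples$t, n = test_samples$n,
                                  threshold = threshold)
    rows$svm$method <- "svm"
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Shared engine for the paired ablation harnesses: runs the scenario grid
# twice with one switch toggled and identical derived seeds, so the two arms
# differ only in the ablated component.
paired_ablation <- function(cohort, arm_labels, toggles, t_list, n_list,
                            repeats, config, seed, ...) {
  arms <- vector("list", 2)
  for (i in 1:2) {
    res <- do.call(run_scenarios,
                   c(list(cohort = cohort, t_list = t_list, n_list = n_list,
                          repeats = repeats, config = config, seed = seed),
                     toggles[[i]], list(...)))
    res$arm <- arm_labels[i]
    arms[[i]] <- res
  }
  out <- do.call(rbind, arms)
  rownames(out) <- NULL
  out
}

#' Demographic-integration ablation
#'
#' Runs each scenario twice — with the encoded demographic vector fed to the
#' classification head, and with a zero-width demographic vector — paired by
#' seed so that both arms share identical longitudinal inputs, splits,
#' initial encoder weights and batch orders.
#'
#' @inheritParams run_scenarios
#' @return A tidy data.frame with an `arm` column
#'   (`"with_demographics"` / `"without_demographics"`), two rows per
#'   (scenario, repeat).
#' @export
ablation_demographics <- function(cohort, t_list = c(2L, 3L, 5L, 6L),
                                  n_list = 1:4, repeats = 15L,
                                  config = model_config(), seed = 1L, ...) {
  paired_ablation(cohort,
                  c("with_demographics", "without_demographics"),
                  list(list(use_demographics = TRUE),
                       list(use_demographics = FALSE)),
                  t_list, n_list, repeats, config, seed, ...)
}

#' Age-as-time ablation
#'
#' Runs each scenario twice — with and without the per-visit age column in
#' the input windows — paired by seed.  On cohorts with irregular inter-visit
#' gaps where progression accrues per elapsed month, the age column is the
#' only carrier of elapsed time, so the with-age arm is expected to do at
#' least as well; on constant-interval cohorts with per-visit drift it
#' carries no extra information.
#'
#' @inheritParams run_scenarios
#' @return A tidy data.frame with an `arm` column (`"with_age"` /
#'   `"without_age"`), two rows per (scenario, repeat).
#' @export
age_ablation <- function(cohort, t_list = 3L, n_list = 1L, repeats = 15L,
                         config = model_config(), seed = 1L, ...) {
  paired_ablation(cohort, c("with_age", "without_age"),
                  list(list(include_age = TRUE), list(include_age = FALSE)),
                  t_list, n_list, repeats, config, seed, ...)
}
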