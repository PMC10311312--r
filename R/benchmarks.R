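# Reproducible benchmark experiments on synthetic cohorts.  These are the
# package's standard evaluation studies: each one simulates a preset cohort,
# runs the pipeline and models under fixed study conditions, and returns the
# summary quantities.  All randomness derives from the single `seed`.

#' Learnability benchmark on the strong-signal cohort
#'
#' Trains the next-visit classifier at (t = 3, n = 1) and the
#' sequence-to-sequence model at (t = 3, n = 2) on the `strong_signal` preset
#' (1000 patients, low noise) and reports test F2 averaged over several
#' training seeds.
#'
#' @param seed Master seed.
#' @param n_patients Cohort size.
#' @param n_seeds Training repetitions averaged.
#' @param epochs Training epochs per fit.
#' @return List with `f2_direct`, `f2_seq2seq` (means) and the per-seed
#'   vectors.
#' @export
benchmark_learnability <- function(seed = 1L, n_patients = 1000L,
                                   n_seeds = 5L, epochs = 60L) {
  co <- simulate_cohort(simulation_presets("strong_signal",
                                           n_patients = n_patients,
                                           seed = derive_seed(seed, 31L)))
  pp <- preprocess_cohort(co, seed = derive_seed(seed, 32L))
  run <- function(t, n) {
    tr <- build_sequences(pp$train, t, n, demo_encoder = pp$demo_encoder)
    te <- build_sequences(pp$test, t, n, demo_encoder = pp$demo_encoder)
    vapply(seq_len(n_seeds), function(k) {
      cfg <- model_config(epochs = epochs, seed = derive_seed(seed, 33L, t, n, k))
      evaluate_model(train_model(tr, cfg), te)$f2
    }, numeric(1))
  }
  direct <- run(3L, 1L)
  seq2seq <- run(3L, 2L)
  list(f2_direct = mean(direct), f2_seq2seq = mean(seq2seq),
       per_seed_direct = direct, per_seed_seq2seq = seq2seq)
}

#' Window-length and horizon trend benchmark
#'
#' Runs the full scenario grid (t in 2,3,5,6; n in 1..4) on the default
#' synthetic cohort and summarises how mean test F2 moves with the number of
#' input visits and with the prediction horizon (Spearman correlations of the
#' aggregated scenario means).
#'
#' @param seed Master seed.
#' @param n_patients Cohort size (default 1200).
#' @param repeats Model repetitions per scenario (default 15).
#' @param epochs Training epochs per fit.
#' @return List with the per-scenario `summary` table, `spearman_t`
#'   (aggregate mean F2 vs t), `spearman_n` (aggregate mean F2 vs n),
#'   `spearman_t_next_visit` (F2 vs t at n = 1) and the per-window-length
#'   horizon correlations `panel_spearman_n`.
#' @export
benchmark_trends <- function(seed = 1L, n_patients = 1200L, repeats = 15L,
                             epochs = 250L) {
  co <- simulate_cohort(simulation_presets("default", n_patients = n_patients,
                                           seed = derive_seed(seed, 41L)))
  imputed <- impute_knn(filter_missingness(co))
  res <- run_scenarios(imputed, repeats = repeats,
                       config = model_config(epochs = epochs),
                       seed = derive_seed(seed, 42L))
  sm <- summarize_scenarios(res)
  tm <- stats::aggregate(mean_f2 ~ t, sm, mean)
  nm <- stats::aggregate(mean_f2 ~ n, sm, mean)
  n1 <- sm[sm$n == 1, ]
  panels <- vapply(unique(sm$t), function(tt) {
    pr <- sm[sm$t == tt, ]
    stats::cor(pr$n, pr$mean_f2, method = "spearman")
  }, numeric(1))
  names(panels) <- paste0("t", unique(sm$t))
  list(summary = sm, results = res,
       spearman_t = stats::cor(tm$t, tm$mean_f2, method = "spearman"),
       spearman_n = stats::cor(nm$n, nm$mean_f2, method = "spearman"),
       spearman_t_next_visit = stats::cor(n1$t, n1$mean_f2,
                                          method = "spearman"),
       panel_spearman_n = panels)
}

#' Loss-weighting benchmark on the imbalanced cohort
#'
#' Trains the next-visit classifier on the `imbalanced` preset (about one
#' converter per four nonconverters) at two positive-class weights, paired by
#' training seed, and reports mean test sensitivity per weight.
#'
#' @param seed Master seed.
#' @param repeats Training repetitions per weight.
#' @param epochs Training epochs per fit.
#' @param alphas The two positive-class weights compared.
#' @return List with `sensitivity` (named by alpha) and `delta`
#'   (high-alpha minus low-alpha mean sensitivity).
#' @export
benchmark_alpha <- function(seed = 1L, repeats = 15L, epochs = 150L,
                            alphas = c(0.5, 0.9)) {
  co <- simulate_cohort(simulation_presets("imbalanced",
                                           seed = derive_seed(seed, 51L)))
  imputed <- impute_knn(filter_missingness(co))
  parts <- split_stratified(imputed, seed = derive_seed(seed, 52L))
  st <- fit_minmax(parts$train)
  enc <- fit_demographic_encoder(parts$train)
  tr <- build_sequences(apply_minmax(parts$train, st), 3L, 1L,
                        demo_encoder = enc)
  te <- build_sequences(apply_minmax(parts$test, st), 3L, 1L,
                        demo_encoder = enc)
  sens <- vapply(alphas, function(a) {
    mean(vapply(seq_len(repeats), function(k) {
      cfg <- model_config(alpha = a, epochs = epochs,
                          seed = derive_seed(seed, 53L, k))
      evaluate_model(train_model(tr, cfg), te)$sensitivity
    }, numeric(1)))
  }, numeric(1))
  names(sens) <- paste0("alpha_", alphas)
  list(sensitivity = sens, delta = unname(sens[2] - sens[1]),
       train_positive_fraction = mean(tr$y))
}

#' Age-as-time benchmark
#'
#' Runs the paired age ablation at (t = 2, n = 1) on two cohorts: the
#' `irregular_time` preset, where progression accrues per elapsed month over
#' widely varying gaps so per-visit age carries real information, and the
#' `regular_time` negative control, where gaps are constant and progression
#' is per-visit so age is uninformative.  A two-visit window is used because
#' it contains a single inter-visit gap: the per-month progression rate is
#' then unidentifiable without the age column, which is where elapsed time
#' matters most.
#'
#' @param seed Master seed.
#' @param repeats Paired repetitions per arm.
#' @param epochs Training epochs per fit.
#' @return List with `delta_irregular`, `delta_control` (with-age minus
#'   without-age mean F2) and the two full ablation tables.
#' @export
benchmark_age <- function(seed = 1L, repeats = 15L, epochs = 250L) {
  run <- function(preset, k) {
    co <- simulate_cohort(simulation_presets(preset,
                                             seed = derive_seed(seed, 61L, k)))
    imputed <- impute_knn(filter_missingness(co))
    age_ablation(imputed, t_list = 2L, n_list = 1L, repeats = repeats,
                 config = model_config(epochs = epochs),
                 seed = derive_seed(seed, 62L, k))
  }
  irr <- run("irregular_time", 1L)
  ctl <- run("regular_time", 2L)
  d <- function(tab) {
    m <- tapply(tab$f2, tab$arm, mean)
    unname(m["with_age"] - m["without_age"])
  }
  list(delta_irregular = d(irr), delta_control = d(ctl),
       irregular = irr, control = ctl)
}

#' Feature-importance benchmark on the planted-signal cohort
#'
#' Trains the next-visit classifier on the `planted_feature` preset (one
#' feature carries the whole severity loading, the rest are noise) and checks
#' how often that feature ranks first in the importance report across
#' estimation seeds.  Also reports the worst-case violation of Shapley
#' efficiency (per-sample attributions summing to the prediction gap) for an
#' exhaustively enumerated small model.
#'
#' @param seed Master seed.
#' @param n_seeds Importance estimation repetitions.
#' @param epochs Training epochs for the planted-signal model.
#' @return List with `top1_rate`, `efficiency_gap`, and the last report.
#' @export
benchmark_importance <- function(seed = 1L, n_seeds = 15L, epochs = 150L) {
  co <- simulate_cohort(simulation_presets("planted_feature",
                                           n_patients = 500,
                                           seed = derive_seed(seed, 71L)))
  imputed <- impute_knn(filter_missingness(co))
  parts <- split_stratified(imputed, seed = derive_seed(seed, 72L))
  st <- fit_minmax(parts$train)
  tr <- build_sequences(apply_minmax(parts$train, st), 3L, 1L,
                        include_age = FALSE)
  te <- build_sequences(apply_minmax(parts$test, st), 3L, 1L,
                        include_age = FALSE)
  fit <- train_model(tr, model_config(epochs = epochs,
                                      seed = derive_seed(seed, 73L)))
  firsts <- vapply(seq_len(n_seeds), function(k) {
    rep <- feature_importance(fit, te, method = "permutation", nsim = 8,
                              seed = derive_seed(seed, 74L, k))
    importance_plot_data(rep)$feature[1]
  }, character(1))

  # Shapley efficiency on a small exhaustively-enumerated model
  sm <- subset_samples(te, seq_len(min(12L, length(te$y))))
  small <- tr
  small$X <- tr$X[, , 1:3, drop = FALSE]
  small$feature_names <- tr$feature_names[1:3]
  fit3 <- suppressWarnings(
    train_model(small, model_config(hidden_dim = 4, epochs = 10,
                                    seed = derive_seed(seed, 75L))))
  sm3 <- subset_samples(small, seq_len(min(12L, length(small$y))))
  rep3 <- feature_importance(fit3, sm3, method = "shapley", exact = TRUE,
                             seed = derive_seed(seed, 76L))
  phi <- attr(rep3, "phi")
  bg <- apply(sm3$X, c(2, 3), mean)
  v_full <- model_forward(fit3, sm3$X, sm3$D)
  Xbg <- sm3$X
  for (f in 1:3) {
    Xbg[, , f] <- matrix(bg[, f], dim(Xbg)[1], dim(Xbg)[2], byrow = TRUE)
  }
  v_empty <- model_forward(fit3, Xbg, sm3$D)
  list(top1_rate = mean(firsts == tr$feature_names[1]),
       efficiency_gap = max(abs(rowSums(phi) - (v_full - v_empty))),
       firsts = firsts)
}
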