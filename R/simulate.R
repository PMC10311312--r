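#' Configuration for the synthetic longitudinal cohort simulator
#'
#' The simulator emulates the structure of real MCI/AD observational cohorts:
#' each patient contributes an irregular number of visits (default 1-21) at
#' irregular intervals (default 3-60 months), carries cross-sectional
#' demographics, and progresses along a latent severity process.  Severity
#' starts at a Gaussian baseline and follows a change-point trajectory:
#' stable patients drift slowly (`pre_onset_drift`) until a latent decline
#' onset (present at entry with probability `onset_baseline_prob`, otherwise
#' arriving with monthly hazard `onset_hazard_month`), after which severity
#' rises at a per-patient lognormal rate around `drift_rate` per month
#' (APOE-e4 carriers faster), always plus a Gaussian innovation; a patient
#' is diagnosed AD from the first visit at which severity reaches
#' `conversion_threshold`, and the AD state is absorbing.  Observed longitudinal features are noisy linear read-outs of
#' severity (`feature_loadings[f] * severity + N(0, noise_sd)`), each cell
#' independently masked missing with probability `missing_rate` (missing
#' completely at random).  Age accumulates the sampled inter-visit gaps, so
#' the per-visit age column carries the irregular time axis.
#'
#' @param n_patients Number of patients.
#' @param n_features Number of longitudinal features (age excluded).
#' @param visits_per_patient Integer range `c(min, max)` of per-patient visit
#'   counts.
#' @param visits_dist `"uniform"` (default) draws visit counts uniformly
#'   over the range; `"skewed"` draws them from a truncated negative-binomial
#'   (mean about 6.5 visits, long thin tail), the shape seen in cohorts where
#'   few patients stay a decade.
#' @param interval_months Integer range `c(min, max)` of inter-visit gaps.
#' @param interval_dist `"protocol"` (default) draws gaps from the visit
#'   spacings typical of scheduled AD cohort protocols — mostly 6 or 12
#'   months, with occasional longer gaps from missed visits — restricted to
#'   `interval_months`; `"loguniform"` draws them uniformly on the log scale;
#'   `"uniform"` draws them uniformly over the range.
#' @param baseline_age_mean,baseline_age_sd Baseline age distribution (years).
#' @param baseline_severity_mean,baseline_severity_sd Latent severity at the
#'   first visit.
#' @param drift_rate Post-onset decline rate: severity per month for a
#'   patient whose decline has started (per-patient lognormal spread via
#'   `slope_heterogeneity_sd`).
#' @param drift_per `"month"` accrues progression with elapsed time (the
#'   realistic setting); `"visit"` treats every gap as 12 months so
#'   progression is tied to visit count regardless of real gap length (the
#'   negative control for age-as-time tests).
#' @param pre_onset_drift Severity drift per month before decline onset
#'   (stable MCI; near zero).
#' @param onset_hazard_month Monthly hazard that a stable patient's decline
#'   begins (APOE-e4 carriers scaled by `apoe4_drift_multiplier`).  Decline
#'   onset is the change point that makes far-horizon prediction genuinely
#'   harder than next-visit prediction: it cannot be read from a window
#'   recorded before it happens.
#' @param onset_baseline_prob Probability that decline is already under way
#'   at study entry (enriched late-MCI recruitment).
#' @param apoe4_drift_multiplier Drift multiplier (>= 1) for APOE-e4 carriers
#'   (one or two alleles).
#' @param slope_heterogeneity_sd Progression rates differ between patients
#'   (fast progressors versus stable MCI): each patient's drift is scaled by a
#'   mean-one lognormal random slope with this log-scale standard deviation.
#'   0 gives homogeneous progression.
#' @param conversion_threshold Severity at which the diagnosis switches to AD.
#' @param innovation_sd Standard deviation of the Gaussian severity innovation
#'   (per sqrt-year in month mode, per visit-step in visit mode).
#' @param feature_loadings Length-`n_features` loadings of each feature on
#'   severity; default decays linearly from 1 to 0.3.
#' @param noise_sd Observation noise of the features (> 0).
#' @param missing_rate MCAR probability that a feature cell is masked.
#' @param apoe4_probs Probabilities of 0, 1, 2 e4 alleles.
#' @param seed Integer seed; the whole cohort is reproducible given it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_patients = 400,
                              n_features = 8,
                              visits_per_patient = c(1L, 21L),
                              visits_dist = c("uniform", "skewed"),
                              interval_months = c(3L, 60L),
                              interval_dist = c("protocol", "loguniform",
                                                "uniform"),
                              baseline_age_mean = 73,
                              baseline_age_sd = 6,
                              baseline_severity_mean = -0.9,
                              baseline_severity_sd = 0.6,
                              drift_rate = 0.08,
                              drift_per = c("month", "visit"),
                              pre_onset_drift = 0.002,
                              onset_hazard_month = 0.008,
                              onset_baseline_prob = 0.3,
                              apoe4_drift_multiplier = 1.5,
                              slope_heterogeneity_sd = 0.35,
                              conversion_threshold = 1.2,
                              innovation_sd = 0.06,
                              feature_loadings = NULL,
                              noise_sd = 0.15,
                              missing_rate = 0.10,
                              apoe4_probs = c(0.6, 0.3, 0.1),
                              seed = 1L) {
  drift_per <- match.arg(drift_per)
  visits_dist <- match.arg(visits_dist)
  interval_dist <- match.arg(interval_dist)
  stopifnot_scalar_number(n_patients, "n_patients", lower = 1)
  stopifnot_scalar_number(n_features, "n_features", lower = 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 1e-12)
  stopifnot_scalar_number(missing_rate, "missing_rate", 0, 1)
  stopifnot_scalar_number(apoe4_drift_multiplier, "apoe4_drift_multiplier",
                          lower = 1)
  stopifnot_scalar_number(slope_heterogeneity_sd, "slope_heterogeneity_sd",
                          lower = 0)
  stopifnot_scalar_number(onset_hazard_month, "onset_hazard_month", 0, 1)
  stopifnot_scalar_number(onset_baseline_prob, "onset_baseline_prob", 0, 1)
  for (rng in list(visits_per_patient = visits_per_patient,
                   interval_months = interval_months)) {
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 1) {
      stop("config error: range must be c(min, max) with 1 <= min <= max",
           call. = FALSE)
    }
  }
  if (is.null(feature_loadings)) {
    feature_loadings <- seq(1, 0.3, length.out = n_features)
  }
  if (length(feature_loadings) != n_features) {
    stop("config error: feature_loadings must have length n_features",
         call. = FALSE)
  }
  if (length(apoe4_probs) != 3L || any(apoe4_probs < 0)) {
    stop("config error: apoe4_probs must be 3 non-negative probabilities",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_features = as.integer(n_features),
                 visits_per_patient = as.integer(visits_per_patient),
                 visits_dist = visits_dist,
                 interval_months = as.integer(interval_months),
                 interval_dist = interval_dist,
                 baseline_age_mean = baseline_age_mean,
                 baseline_age_sd = baseline_age_sd,
                 baseline_severity_mean = baseline_severity_mean,
                 baseline_severity_sd = baseline_severity_sd,
                 drift_rate = drift_rate, drift_per = drift_per,
                 pre_onset_drift = pre_onset_drift,
                 onset_hazard_month = onset_hazard_month,
                 onset_baseline_prob = onset_baseline_prob,
                 apoe4_drift_multiplier = apoe4_drift_multiplier,
                 slope_heterogeneity_sd = slope_heterogeneity_sd,
                 conversion_threshold = conversion_threshold,
                 innovation_sd = innovation_sd,
                 feature_loadings = feature_loadings,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 apoe4_probs = apoe4_probs / sum(apoe4_probs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Latent severity path for one patient: a change-point process.  The patient
# is either stable (drift pre_onset_drift per month) or declining (drift
# drift_rate * rate_mult per month, APOE-e4 carriers faster); decline starts
# at study entry with probability onset_baseline_prob, otherwise begins later
# with monthly hazard onset_hazard_month (carriers scaled).  An onset inside
# an inter-visit gap contributes the declining rate for half that gap.  In
# drift_per = "visit" mode every gap is treated as 12 months, so progression
# is tied to visit count, not elapsed time (the negative control for
# age-as-time experiments).
severity_path <- function(config, n_visits, gaps, carrier, rate_mult = 1) {
  mult <- if (carrier) config$apoe4_drift_multiplier else 1
  rate <- config$drift_rate * rate_mult * mult
  hazard <- min(config$onset_hazard_month * mult, 1)
  s <- numeric(n_visits)
  s[1] <- stats::rnorm(1, config$baseline_severity_mean,
                       config$baseline_severity_sd)
  onset <- stats::runif(1) < config$onset_baseline_prob
  onset_visit <- if (onset) 1L else NA_integer_
  if (n_visits > 1) {
    for (j in 2:n_visits) {
      g <- if (config$drift_per == "month") gaps[j - 1] else 12
      frac <- 1 # fraction of the gap spent declining
      if (!onset) {
        if (stats::runif(1) < 1 - (1 - hazard)^g) {
          onset <- TRUE
          onset_visit <- j
          frac <- 0.5
        } else {
          frac <- 0
        }
      }
      drift <- (config$pre_onset_drift * (1 - frac) + rate * frac) * g
      innov <- stats::rnorm(1, 0, config$innovation_sd * sqrt(g / 12))
      s[j] <- s[j - 1] + drift + innov
    }
  }
  list(s = s, onset_visit = onset_visit)
}

#' Simulate a synthetic longitudinal MCI/AD cohort
#'
#' Draws a cohort from the latent-severity progression process described in
#' [simulation_config()].  The returned object has the same structure as a
#' cohort loaded from disk, so every downstream stage (filtering, imputation,
#' splitting, sequence construction, model training) can be exercised without
#' access-restricted clinical data.
#'
#' @param config A [simulation_config()].
#' @return An `mci_cohort` with attribute `"truth"`: a data.frame of the
#'   per-patient latent quantities (baseline severity, carrier status,
#'   conversion visit or NA).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    P <- config$n_patients
    Fn <- config$n_features
    feat_names <- sprintf("feat%02d", seq_len(Fn))

    gender <- sample(c("F", "M"), P, replace = TRUE)
    race <- sample(c("White", "Black", "Asian", "Other"), P, replace = TRUE,
                   prob = c(0.7, 0.15, 0.1, 0.05))
    ethnicity <- sample(c("NotHispanic", "Hispanic"), P, replace = TRUE,
                        prob = c(0.9, 0.1))
    education <- pmin(pmax(round(stats::rnorm(P, 16, 2.5)), 6), 20)
    apoe4 <- sample(0:2, P, replace = TRUE, prob = config$apoe4_probs)

    visits_list <- vector("list", P)
    shet <- config$slope_heterogeneity_sd
    rate_mult <- if (shet > 0) {
      stats::rlnorm(P, meanlog = -shet^2 / 2, sdlog = shet) # mean one
    } else rep(1, P)
    truth <- data.frame(patient_id = sprintf("P%04d", seq_len(P)),
                        baseline_severity = NA_real_,
                        apoe4_carrier = apoe4 >= 1,
                        rate_mult = rate_mult,
                        onset_visit = NA_integer_,
                        conversion_visit = NA_integer_,
                        stringsAsFactors = FALSE)
    # sample() treats a length-1 vector as 1:x, so guard degenerate ranges
    draw_range <- function(rng, n) {
      vals <- seq(rng[1], rng[2])
      if (length(vals) == 1) rep(vals, n) else sample(vals, n, replace = TRUE)
    }
    draw_gaps <- function(n) {
      if (n < 1) return(integer(0))
      rng <- config$interval_months
      if (config$interval_dist == "protocol" && rng[1] < rng[2]) {
        grid <- c(3, 6, 12, 18, 24, 36, 48, 60)
        wts <- c(0.05, 0.45, 0.30, 0.10, 0.05, 0.03, 0.01, 0.01)
        keep <- grid >= rng[1] & grid <= rng[2]
        sample(grid[keep], n, replace = TRUE, prob = wts[keep])
      } else if (config$interval_dist == "loguniform" && rng[1] < rng[2]) {
        pmin(pmax(round(exp(stats::runif(n, log(rng[1]), log(rng[2])))),
                  rng[1]), rng[2])
      } else {
        draw_range(rng, n)
      }
    }
    draw_visits <- function() {
      rng <- config$visits_per_patient
      if (config$visits_dist == "skewed" && rng[1] < rng[2]) {
        min(max(1L + stats::rnbinom(1, size = 3, mu = 5.5), rng[1]), rng[2])
      } else {
        draw_range(rng, 1)
      }
    }
    for (p in seq_len(P)) {
      nv <- draw_visits()
      gaps <- draw_gaps(nv - 1)
      months <- c(0, cumsum(gaps))[seq_len(nv)]
      sp <- severity_path(config, nv, gaps, apoe4[p] >= 1, rate_mult[p])
      s <- sp$s
      truth$onset_visit[p] <- sp$onset_visit
      crossed <- s >= config$conversion_threshold
      conv <- if (any(crossed)) which(crossed)[1] else NA_integer_
      dx <- rep("MCI", nv)
      if (!is.na(conv)) dx[conv:nv] <- "AD" # absorbing
      truth$baseline_severity[p] <- s[1]
      truth$conversion_visit[p] <- conv

      X <- outer(s, config$feature_loadings) +
        matrix(stats::rnorm(nv * Fn, 0, config$noise_sd), nv, Fn)
      if (config$missing_rate > 0) {
        X[matrix(stats::runif(nv * Fn) < config$missing_rate, nv, Fn)] <- NA
      }
      age0 <- stats::rnorm(1, config$baseline_age_mean, config$baseline_age_sd)
      vdf <- data.frame(patient_id = truth$patient_id[p],
                        visit_index = seq_len(nv),
                        visit_month = months,
                        age = age0 + months / 12,
                        diagnosis = dx,
                        stringsAsFactors = FALSE)
      vdf[feat_names] <- as.data.frame(X)
      visits_list[[p]] <- vdf
    }
    visits <- do.call(rbind, visits_list)
    rownames(visits) <- NULL
    demographics <- data.frame(patient_id = truth$patient_id,
                               gender = gender, race = race,
                               ethnicity = ethnicity, education = education,
                               apoe4 = apoe4, stringsAsFactors = FALSE)
    cohort <- new_cohort(visits, demographics, feat_names)
    attr(cohort, "truth") <- truth
    validate_cohort(cohort)
    cohort
  })
}

#' Named preset simulation configurations
#'
#' Fixed study conditions used throughout the package's experiments and tests:
#' \describe{
#'   \item{default}{Realistic moderate-noise cohort with the full 1-21 visit
#'     and 3-60 month irregularity ranges.}
#'   \item{strong_signal}{Large low-noise cohort with mildly irregular,
#'     shorter gaps; conversion is close to deterministic given the observed
#'     window, so recurrent models should reach high F2 (learnability
#'     benchmark).}
#'   \item{imbalanced}{Slower drift so positive (converting) windows are the
#'     clear minority; used for loss-weighting experiments.}
#'   \item{irregular_time}{Wide 3-60 month gaps with per-month drift, so the
#'     per-visit age column carries real signal about elapsed time.}
#'   \item{regular_time}{Constant 12-month gaps with per-visit drift: the
#'     negative control in which age carries no extra information.}
#'   \item{planted_feature}{One feature carries all of the severity loading;
#'     the remaining features are pure noise (feature-importance benchmark).}
#' }
#'
#' @param name Preset name.
#' @param n_patients,seed Overrides applied to the preset.
#' @return A [simulation_config()].
#' @export
simulation_presets <- function(name = c("default", "strong_signal",
                                        "imbalanced", "irregular_time",
                                        "regular_time", "planted_feature"),
                               n_patients = NULL, seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    default = simulation_config(seed = seed),
    strong_signal = simulation_config(
      n_patients = 1000, visits_per_patient = c(5L, 12L),
      visits_dist = "uniform", interval_months = c(11L, 13L),
      interval_dist = "uniform", noise_sd = 0.05, innovation_sd = 0.05,
      missing_rate = 0.05, drift_rate = 0.06, onset_baseline_prob = 1,
      slope_heterogeneity_sd = 0.4, apoe4_drift_multiplier = 1.5,
      conversion_threshold = 1.2, baseline_severity_mean = -1.2,
      baseline_severity_sd = 0.9, seed = seed),
    imbalanced = simulation_config(
      n_patients = 600, visits_per_patient = c(4L, 16L),
      visits_dist = "uniform", interval_months = c(6L, 24L),
      interval_dist = "uniform", drift_rate = 0.06,
      onset_baseline_prob = 0.45, onset_hazard_month = 0.008,
      baseline_severity_mean = -1.1, baseline_severity_sd = 0.6,
      noise_sd = 0.3, innovation_sd = 0.12, seed = seed),
    irregular_time = simulation_config(
      n_patients = 600, visits_per_patient = c(7L, 14L),
      visits_dist = "uniform", baseline_age_sd = 2, interval_months = c(3L, 60L),
      interval_dist = "uniform", drift_rate = 0.03, drift_per = "month",
      onset_baseline_prob = 1, slope_heterogeneity_sd = 0.8,
      noise_sd = 0.3, innovation_sd = 0.08, missing_rate = 0.05,
      seed = seed),
    regular_time = simulation_config(
      n_patients = 600, visits_per_patient = c(7L, 14L),
      visits_dist = "uniform", baseline_age_sd = 2, interval_months = c(12L, 12L),
      interval_dist = "uniform", drift_rate = 0.03, drift_per = "visit",
      onset_baseline_prob = 1, slope_heterogeneity_sd = 0.8,
      noise_sd = 0.3, innovation_sd = 0.08, missing_rate = 0.05,
      seed = seed),
    planted_feature = simulation_config(
      n_patients = 500, n_features = 6,
      feature_loadings = c(1, 0, 0, 0, 0, 0),
      visits_per_patient = c(4L, 14L), visits_dist = "uniform",
      interval_months = c(6L, 18L), interval_dist = "uniform",
      onset_baseline_prob = 1, slope_heterogeneity_sd = 0.4,
      noise_sd = 0.3, innovation_sd = 0.1, missing_rate = 0.05,
      drift_rate = 0.04, seed = seed)
  )
  if (!is.null(n_patients)) cfg$n_patients <- as.integer(n_patients)
  cfg
}

#' Summarise a cohort
#'
#' Reports the patient count, visit-count distribution, converter counts,
#' per-feature missing rates, and (optionally) eligible-sample counts per
#' window/horizon scenario.
#'
#' @param cohort An `mci_cohort`.
#' @param t_list,n_list Optional window lengths and horizons for which
#'   per-scenario eligible converter/nonconverter counts are tabulated.
#' @param include_cn Passed to the window-eligibility rule (see
#'   [build_sequences()]).
#' @return A list with elements `n_patients`, `n_visits`,
#'   `visit_count_table`, `n_converters`, `n_nonconverters`,
#'   `feature_missing_rates`, and `scenario_counts` (a data.frame, or `NULL`).
#' @export
cohort_summary <- function(cohort, t_list = NULL, n_list = NULL,
                           include_cn = FALSE) {
  v <- cohort$visits
  if (!nrow(v)) stop("empty-input error: cohort has no visits", call. = FALSE)
  per_patient <- split(v$diagnosis, v$patient_id)
  converters <- vapply(per_patient, function(d) any(d == "AD"), logical(1))
  out <- list(
    n_patients = n_patients(cohort),
    n_visits = nrow(v),
    visit_count_table = table(lengths(per_patient)),
    n_converters = sum(converters),
    n_nonconverters = sum(!converters),
    feature_missing_rates = vapply(cohort$feature_names,
                                   function(f) mean(is.na(v[[f]])), numeric(1)),
    scenario_counts = NULL
  )
  if (!is.null(t_list) && !is.null(n_list)) {
    rows <- list()
    for (t in t_list) for (n in n_list) {
      w <- eligible_windows(cohort, t, n, include_cn = include_cn)
      rows[[length(rows) + 1L]] <- data.frame(
        t = t, n = n, n_samples = length(w$y),
        converters = sum(w$y == 1), nonconverters = sum(w$y == 0))
    }
    out$scenario_counts <- do.call(rbind, rows)
  }
  out
}
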