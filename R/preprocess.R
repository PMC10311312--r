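#' Drop high-missingness visits, then high-missingness features
#'
#' First removes visits whose fraction of missing feature values exceeds
#' `visit_missing_max`, then removes features whose missing fraction across
#' the remaining visits exceeds `feature_missing_max`; patients left with no
#' visits are dropped.  The visit-level fraction is computed over the
#' longitudinal feature columns (age and diagnosis are bookkeeping columns,
#' not part of the missingness budget).
#'
#' @param cohort An `mci_cohort` with missing values flagged as `NA`.
#' @param visit_missing_max,feature_missing_max Fractions in (0, 1]; defaults
#'   0.40 and 0.60.
#' @return The filtered cohort, with attribute `"filter_log"` recording counts
#'   dropped at each stage.
#' @export
filter_missingness <- function(cohort, visit_missing_max = 0.40,
                               feature_missing_max = 0.60) {
  stopifnot_scalar_number(visit_missing_max, "visit_missing_max", 1e-12, 1)
  stopifnot_scalar_number(feature_missing_max, "feature_missing_max", 1e-12, 1)
  v <- cohort$visits
  fn <- cohort$feature_names
  na_mat <- is.na(as.matrix(v[fn]))
  visit_frac <- rowMeans(na_mat)
  keep_visit <- visit_frac <= visit_missing_max
  v2 <- v[keep_visit, , drop = FALSE]

  feat_frac <- colMeans(is.na(as.matrix(v2[fn])))
  keep_feat <- fn[feat_frac <= feature_missing_max]
  if (!length(keep_feat)) {
    stop("degenerate-output error: all features exceed the missingness threshold",
         call. = FALSE)
  }
  v2 <- v2[c("patient_id", "visit_index", "visit_month", "age", "diagnosis",
             keep_feat)]
  # re-number visit_index within patient after visit drops
  v2$visit_index <- stats::ave(seq_len(nrow(v2)), v2$patient_id, FUN = seq_along)
  keep_pid <- unique(v2$patient_id)
  demo <- cohort$demographics[cohort$demographics$patient_id %in% keep_pid, ,
                              drop = FALSE]
  rownames(v2) <- rownames(demo) <- NULL
  out <- new_cohort(v2, demo, keep_feat)
  attr(out, "filter_log") <- list(
    visits_dropped = sum(!keep_visit),
    features_dropped = setdiff(fn, keep_feat),
    patients_dropped = n_patients(cohort) - length(keep_pid))
  validate_cohort(out)
  out
}

#' Diagnosis-constrained k-nearest-neighbour imputation
#'
#' Each missing feature value is replaced by the mean of that feature over the
#' k nearest visit records, where candidate neighbours are restricted to visit
#' records with the same diagnosis that observe the feature.  Distance is
#' Euclidean over the features observed in both records, rescaled by
#' `sqrt(F / n_shared)` to stay comparable across missingness patterns; ties
#' are broken by record order.  When no same-diagnosis record observes the
#' feature, the same-diagnosis feature mean is used (and counted in the log);
#' as a last resort the overall feature mean is used.  Observed values are
#' never changed, so the operation is idempotent.
#'
#' @param cohort An `mci_cohort` (typically after [filter_missingness()]).
#' @param k Number of neighbours (default 5).
#' @return The imputed cohort (no missing feature values remain), with
#'   attribute `"impute_log"` counting imputed cells and mean-fallbacks.
#' @export
impute_knn <- function(cohort, k = 5L) {
  stopifnot_scalar_number(k, "k", lower = 1)
  v <- cohort$visits
  fn <- cohort$feature_names
  M <- as.matrix(v[fn])
  Fn <- length(fn)
  obs <- !is.na(M)
  Mz <- M
  Mz[!obs] <- 0
  dx <- v$diagnosis
  need <- which(rowSums(!obs) > 0)
  n_fallback <- 0L
  for (i in need) {
    cand_all <- which(dx == dx[i])
    cand_all <- cand_all[cand_all != i]
    if (length(cand_all)) {
      # squared distance over mutually observed features, vectorised:
      # sum over shared features of (x_c - x_i)^2
      oi <- obs[i, ]
      Xc <- Mz[cand_all, , drop = FALSE]
      Oc <- obs[cand_all, , drop = FALSE]
      sh <- Oc & rep(oi, each = length(cand_all))
      d2 <- rowSums(((Xc - rep(Mz[i, ], each = length(cand_all)))^2) * sh)
      n_sh <- rowSums(sh)
      dist <- ifelse(n_sh > 0, sqrt(d2 * Fn / n_sh), Inf)
    }
    for (f in which(!obs[i, ])) {
      val <- NA_real_
      if (length(cand_all)) {
        has_f <- obs[cand_all, f]
        if (any(has_f)) {
          cc <- cand_all[has_f]
          dd <- dist[has_f]
          ord <- order(dd, cc) # ties broken by record order
          val <- mean(M[cc[ord[seq_len(min(k, length(cc)))]], f])
        }
      }
      if (is.na(val)) {
        n_fallback <- n_fallback + 1L
        same <- M[dx == dx[i], f]
        val <- mean(same, na.rm = TRUE)
        if (is.nan(val)) val <- mean(M[, f], na.rm = TRUE)
      }
      v[[fn[f]]][i] <- val
    }
  }
  out <- new_cohort(v, cohort$demographics, fn)
  attr(out, "impute_log") <- list(cells_imputed = sum(!obs),
                                  mean_fallbacks = n_fallback)
  if (n_fallback > 0) {
    message(sprintf("impute_knn: %d cell(s) fell back to the diagnosis-class mean",
                    n_fallback))
  }
  attr(out, "truth") <- attr(cohort, "truth")
  out
}

#' Patient-level stratified train/test split
#'
#' Patients are stratified by converter status (whether the record ever
#' reaches an AD diagnosis) and split so that each stratum contributes
#' `test_fraction` of its patients (rounded) to the test partition.  No
#' patient appears in both partitions.  A stratum with fewer than 2 patients
#' is assigned to the training partition with a warning.
#'
#' @param cohort An `mci_cohort`.
#' @param test_fraction Fraction of patients held out (default 0.30).
#' @param seed Integer seed; the split is reproducible given it.
#' @return `list(train = , test = )` of `mci_cohort`s.
#' @export
split_stratified <- function(cohort, test_fraction = 0.30, seed = 1L) {
  stopifnot_scalar_number(test_fraction, "test_fraction", 0, 1)
  v <- cohort$visits
  per_patient <- split(v$diagnosis, v$patient_id)
  pids <- names(per_patient)
  converter <- vapply(per_patient, function(d) any(d == "AD"), logical(1))
  test_ids <- character(0)
  with_seed(seed, {
    for (stratum in unique(converter)) {
      ids <- pids[converter == stratum]
      if (length(ids) < 2) {
        warning("stratification warning: stratum with < 2 patients assigned to train")
        next
      }
      n_test <- round(length(ids) * test_fraction)
      test_ids <- c(test_ids, sample(ids, n_test))
    }
  })
  subset_cohort <- function(keep) {
    vv <- v[v$patient_id %in% keep, , drop = FALSE]
    dd <- cohort$demographics[cohort$demographics$patient_id %in% keep, ,
                              drop = FALSE]
    rownames(vv) <- rownames(dd) <- NULL
    new_cohort(vv, dd, cohort$feature_names)
  }
  list(train = subset_cohort(setdiff(pids, test_ids)),
       test = subset_cohort(test_ids))
}

#' Fit per-feature min-max normalisation state on a training cohort
#'
#' @param train The training `mci_cohort` (after imputation).
#' @param include_age Whether the per-visit age column is normalised too
#'   (it enters the model as a longitudinal feature, so the default is TRUE).
#' @return A `minmax_state` data.frame with columns `feature`, `min`, `max`.
#' @export
fit_minmax <- function(train, include_age = TRUE) {
  v <- train$visits
  cols <- c(train$feature_names, if (include_age) "age")
  state <- data.frame(feature = cols,
                      min = vapply(cols, function(f) min(v[[f]], na.rm = TRUE),
                                   numeric(1)),
                      max = vapply(cols, function(f) max(v[[f]], na.rm = TRUE),
                                   numeric(1)),
                      stringsAsFactors = FALSE)
  rownames(state) <- NULL
  class(state) <- c("minmax_state", "data.frame")
  state
}

#' Apply a fitted min-max normalisation state
#'
#' Maps each feature through `(x - min) / (max - min)` with the training
#' minima/maxima.  Values outside the training range map outside `[0, 1]` and
#' are deliberately not clipped; a feature constant in training maps to 0.
#'
#' @param cohort An `mci_cohort`.
#' @param state A [fit_minmax()] state; it must cover every cohort feature.
#' @return The normalised cohort.
#' @export
apply_minmax <- function(cohort, state) {
  v <- cohort$visits
  cols <- c(cohort$feature_names, if ("age" %in% state$feature) "age")
  miss <- setdiff(cols, state$feature)
  if (length(miss)) {
    stop("schema error: normalisation state lacks feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (f in cols) {
    i <- match(f, state$feature)
    rng <- state$max[i] - state$min[i]
    v[[f]] <- if (rng > 0) (v[[f]] - state$min[i]) / rng else rep(0, nrow(v))
  }
  out <- new_cohort(v, cohort$demographics, cohort$feature_names)
  attr(out, "truth") <- attr(cohort, "truth")
  out
}

#' Fit the demographic encoder on a training cohort
#'
#' Captures the category order of `gender`, `race` and `ethnicity`, and the
#' training range of `education`, so that test-time encoding is fixed by the
#' training partition.
#'
#' @param train The training `mci_cohort`.
#' @return A `demographic_encoder`.
#' @export
fit_demographic_encoder <- function(train) {
  d <- train$demographics
  enc <- list(levels = list(), education_range = NULL)
  for (field in c("gender", "race", "ethnicity")) {
    if (field %in% names(d)) {
      enc$levels[[field]] <- sort(unique(as.character(d[[field]])))
    }
  }
  if ("education" %in% names(d)) {
    enc$education_range <- range(as.numeric(d$education), na.rm = TRUE)
  }
  enc$has_apoe4 <- "apoe4" %in% names(d)
  enc$dim <- sum(lengths(enc$levels)) +
    (!is.null(enc$education_range)) + enc$has_apoe4
  class(enc) <- "demographic_encoder"
  enc
}

#' Encode per-patient demographics as a numeric vector
#'
#' Categorical fields are one-hot encoded in the category order captured at
#' training time (a test-time category unseen in training encodes as all
#' zeros, with a message); education is min-max scaled by the training range;
#' the APOE-e4 allele count enters as a numeric 0/1/2.
#'
#' @param demographics A demographics data.frame (one row per patient, as in
#'   `cohort$demographics`).
#' @param encoder A [fit_demographic_encoder()] object.
#' @return A numeric matrix, one row per patient, `encoder$dim` columns.
#' @export
encode_demographics <- function(demographics, encoder) {
  stopifnot(inherits(encoder, "demographic_encoder"))
  n <- nrow(demographics)
  blocks <- list()
  unseen <- 0L
  for (field in names(encoder$levels)) {
    lev <- encoder$levels[[field]]
    x <- as.character(demographics[[field]])
    B <- matrix(0, n, length(lev),
                dimnames = list(NULL, paste(field, lev, sep = "_")))
    hit <- match(x, lev)
    unseen <- unseen + sum(is.na(hit))
    ok <- which(!is.na(hit))
    B[cbind(ok, hit[ok])] <- 1
    blocks[[field]] <- B
  }
  if (!is.null(encoder$education_range)) {
    rng <- diff(encoder$education_range)
    edu <- as.numeric(demographics$education)
    blocks$education <- matrix(
      if (rng > 0) (edu - encoder$education_range[1]) / rng else 0,
      ncol = 1, dimnames = list(NULL, "education"))
  }
  if (encoder$has_apoe4) {
    blocks$apoe4 <- matrix(as.numeric(demographics$apoe4), ncol = 1,
                           dimnames = list(NULL, "apoe4"))
  }
  if (unseen > 0) {
    message(sprintf("encode_demographics: %d unseen categor%s encoded as zeros",
                    unseen, if (unseen == 1) "y" else "ies"))
  }
  do.call(cbind, blocks)
}

# Enumerate eligible (window, target) pairs under the first-window policy:
# a patient is eligible iff it has >= t + n visits, no input-window visit is
# AD (nor CN unless include_cn), and the target visit's diagnosis is MCI or
# AD.  Returns patient ids, window row indices and binary labels.
eligible_windows <- function(cohort, t, n, include_cn = FALSE,
                             sliding = FALSE) {
  if (t < 1 || n < 1) stop("parameter error: t and n must be >= 1", call. = FALSE)
  v <- cohort$visits
  idx_by_pid <- split(seq_len(nrow(v)), v$patient_id)
  pid_out <- character(0); rows_out <- list(); y_out <- integer(0)
  for (pid in names(idx_by_pid)) {
    rows <- idx_by_pid[[pid]]
    Tn <- length(rows)
    starts <- if (sliding) seq_len(max(Tn - t - n + 1, 0)) else
      if (Tn >= t + n) 1L else integer(0)
    for (s in starts) {
      win <- rows[s:(s + t - 1)]
      tgt <- rows[s + t + n - 1]
      dwin <- v$diagnosis[win]
      dtgt <- v$diagnosis[tgt]
      if (any(dwin == "AD")) next
      if (!include_cn && any(dwin == "CN")) next
      if (!dtgt %in% c("MCI", "AD")) next
      pid_out <- c(pid_out, pid)
      rows_out[[length(rows_out) + 1L]] <- win
      y_out <- c(y_out, as.integer(dtgt == "AD"))
      if (!sliding) break
    }
  }
  list(patient_id = pid_out, window_rows = rows_out, y = y_out)
}

#' Build fixed-length model input sequences from a preprocessed cohort
#'
#' For each eligible patient, takes the first `t` visits as the input window
#' and the diagnosis at visit `t + n` as the binary target (`0` = MCI, `1` =
#' AD).  A patient is eligible iff it has at least `t + n` visits, no
#' input-window visit is already AD, no window visit is CN unless
#' `include_cn`, and the target visit's diagnosis is MCI or AD.  Per-visit age
#' is appended as the last feature column when `include_age` is set, carrying
#' the irregular elapsed-time information.  The cohort must already be imputed
#' (and normally normalised): missing values in the window are an error.
#'
#' @param cohort A preprocessed `mci_cohort`.
#' @param t Window length (visits), >= 1.
#' @param n Horizon (visits ahead of the window), >= 1.
#' @param demo_encoder Optional [fit_demographic_encoder()]; when supplied the
#'   samples carry an encoded demographic matrix `D`, otherwise `D` has zero
#'   columns.
#' @param include_cn Allow CN diagnoses inside the input window.
#' @param include_age Append age as a longitudinal feature column.
#' @param sliding Use every eligible window start (default: first window only,
#'   one sample per patient).
#' @return A `sequence_set`: list with `X` (array `n_samples x t x F`), `D`
#'   (matrix), `y` (integer 0/1), `patient_id`, `t`, `n`, `feature_names`.
#' @export
build_sequences <- function(cohort, t, n, demo_encoder = NULL,
                            include_cn = FALSE, include_age = TRUE,
                            sliding = FALSE) {
  w <- eligible_windows(cohort, t, n, include_cn = include_cn,
                        sliding = sliding)
  v <- cohort$visits
  cols <- c(cohort$feature_names, if (include_age) "age")
  ns <- length(w$y)
  X <- array(NA_real_, dim = c(ns, t, length(cols)),
             dimnames = list(NULL, NULL, cols))
  for (i in seq_len(ns)) {
    X[i, , ] <- as.matrix(v[w$window_rows[[i]], cols, drop = FALSE])
  }
  if (ns > 0 && anyNA(X)) {
    stop("build_sequences: input windows contain missing values; impute first",
         call. = FALSE)
  }
  D <- if (!is.null(demo_encoder)) {
    demo <- cohort$demographics[match(w$patient_id,
                                      cohort$demographics$patient_id), ,
                                drop = FALSE]
    encode_demographics(demo, demo_encoder)
  } else {
    matrix(0, ns, 0)
  }
  structure(list(X = X, D = D, y = w$y, patient_id = w$patient_id,
                 t = t, n = n, feature_names = cols),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf(
    "<sequence_set> %d samples (window t=%d, horizon n=%d), %d features, %d demographic columns\n  positives (AD at target): %d (%.1f%%)\n",
    length(x$y), x$t, x$n, length(x$feature_names), ncol(x$D),
    sum(x$y == 1), if (length(x$y)) 100 * mean(x$y == 1) else 0))
  invisible(x)
}

# Subset a sequence_set by sample index (used by CV folding and baselines).
subset_samples <- function(samples, idx) {
  structure(list(X = samples$X[idx, , , drop = FALSE],
                 D = samples$D[idx, , drop = FALSE],
                 y = samples$y[idx],
                 patient_id = samples$patient_id[idx],
                 t = samples$t, n = samples$n,
                 feature_names = samples$feature_names),
            class = "sequence_set")
}

#' Run the full preprocessing pipeline on a cohort
#'
#' Convenience wrapper applying the canonical stage order: missingness
#' filtering, diagnosis-constrained KNN imputation, patient-level stratified
#' split, then min-max normalisation fitted on the training partition only
#' and applied to both partitions (no test leakage).
#'
#' @param cohort A raw `mci_cohort`.
#' @param visit_missing_max,feature_missing_max See [filter_missingness()].
#' @param k See [impute_knn()].
#' @param test_fraction,seed See [split_stratified()].
#' @return `list(train, test, normalization, demo_encoder, filter_log)`.
#' @export
preprocess_cohort <- function(cohort, visit_missing_max = 0.40,
                              feature_missing_max = 0.60, k = 5L,
                              test_fraction = 0.30, seed = 1L) {
  filtered <- filter_missingness(cohort, visit_missing_max, feature_missing_max)
  imputed <- impute_knn(filtered, k = k)
  parts <- split_stratified(imputed, test_fraction = test_fraction, seed = seed)
  state <- fit_minmax(parts$train)
  list(train = apply_minmax(parts$train, state),
       test = apply_minmax(parts$test, state),
       normalization = state,
       demo_encoder = fit_demographic_encoder(parts$train),
       filter_log = attr(filtered, "filter_log"))
}
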