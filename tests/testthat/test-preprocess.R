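toy_missingness_cohort <- function() {
  # 2 patients, 8 visits, 20 features, scripted missingness
  set.seed(31)
  spec <- list()
  for (p in 1:2) {
    Feat <- matrix(rnorm(4 * 20), 4, 20)
    spec[[p]] <- list(diagnosis = c("MCI", "MCI", "MCI", "AD"),
                      features = Feat)
  }
  co <- make_toy_cohort(spec, feature_names = sprintf("g%02d", 1:20))
  co
}

test_that("visit and feature missingness filters follow the 40%/60% rule", {
  co <- toy_missingness_cohort()
  # visit 1 of patient 1: 9 of 20 features missing (45% > 40%) -> dropped
  co$visits[1, co$feature_names[1:9]] <- NA
  filtered <- filter_missingness(co)
  expect_equal(nrow(filtered$visits), 7L)
  expect_false(any(filtered$visits$patient_id == "T01" &
                     filtered$visits$visit_month == 0))

  # feature missing in 65% of remaining visits -> dropped
  co2 <- toy_missingness_cohort()
  miss_rows <- 1:5 # 5 of 8 visits = 62.5% > 60%
  co2$visits[miss_rows, "g03"] <- NA
  filtered2 <- filter_missingness(co2)
  expect_false("g03" %in% filtered2$feature_names)
  expect_false("g03" %in% names(filtered2$visits))
})

test_that("filtering counts match a brute-force recount on scripted missingness", {
  set.seed(77)
  spec <- lapply(1:5, function(p) {
    nv <- sample(2:6, 1)
    Feat <- matrix(rnorm(nv * 10), nv, 10)
    Feat[runif(length(Feat)) < 0.3] <- NA
    list(diagnosis = sample(c("MCI", "AD"), nv, replace = TRUE),
         features = Feat)
  })
  co <- make_toy_cohort(spec, feature_names = sprintf("m%02d", 1:10))
  filtered <- filter_missingness(co, 0.4, 0.6)

  M <- as.matrix(co$visits[co$feature_names])
  keep_v <- rowMeans(is.na(M)) <= 0.4
  keep_f <- colMeans(is.na(M[keep_v, , drop = FALSE])) <= 0.6
  expect_equal(nrow(filtered$visits), sum(keep_v))
  expect_equal(filtered$feature_names, co$feature_names[keep_f])
})

test_that("tied-distance neighbours average to the class mean (k = 5)", {
  # six MCI records identical except f1 = 1..5 and missing
  Feat <- cbind(c(1, 2, 3, 4, 5, NA), rep(2, 6), rep(7, 6))
  co <- make_toy_cohort(list(list(diagnosis = rep("MCI", 6), features = Feat)),
                        feature_names = c("f1", "f2", "f3"))
  imp <- impute_knn(co, k = 5)
  expect_equal(imp$visits$f1[6], 3.0)
})

test_that("records without missing values pass through imputation unchanged", {
  co <- simulate_cohort(simulation_config(n_patients = 25, seed = 9))
  complete_rows <- stats::complete.cases(co$visits[co$feature_names])
  imp <- impute_knn(co)
  for (f in co$feature_names) {
    expect_equal(imp$visits[[f]][complete_rows], co$visits[[f]][complete_rows])
  }
  expect_false(anyNA(imp$visits[co$feature_names]))
})

test_that("imputation only borrows from records with the same diagnosis", {
  # the nearest record overall is MCI, but the target is AD
  Feat <- rbind(c(NA, 10),   # AD target
                c(1, 10.1),  # MCI, nearest by f2
                c(9, 10.2),  # MCI
                c(5, 30))    # AD, far in f2 but the only legal donor
  co <- make_toy_cohort(list(list(diagnosis = c("AD", "MCI", "MCI", "AD"),
                                  features = Feat)),
                        feature_names = c("f1", "f2"))
  imp <- impute_knn(co, k = 1)
  expect_equal(imp$visits$f1[1], 5)

  # unrestricted oracle would have picked the MCI record instead
  expect_false(isTRUE(all.equal(imp$visits$f1[1], 1)))
})

test_that("imputation agrees with the brute-force oracle and is idempotent", {
  co <- simulate_cohort(simulation_config(n_patients = 20, seed = 13,
                                          missing_rate = 0.2))
  imp <- impute_knn(co, k = 5)
  orc <- oracle_knn_impute(co$visits, co$feature_names, k = 5)
  expect_equal(as.matrix(imp$visits[co$feature_names]), orc,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(impute_knn(imp, k = 5)$visits, imp$visits)
})

test_that("the class-mean fallback fills features no same-diagnosis donor observes", {
  Feat <- rbind(c(NA, 1), c(NA, 2), c(3, 4))
  co <- make_toy_cohort(list(list(diagnosis = c("AD", "AD", "MCI"),
                                  features = Feat)),
                        feature_names = c("f1", "f2"))
  expect_message(imp <- impute_knn(co, k = 2), "fell back")
  expect_equal(imp$visits$f1[1:2], c(3, 3)) # global mean rescue
})

test_that("stratified splitting is patient-level, exact and reproducible", {
  # 10 converters and 10 nonconverters -> test takes 3 of each at 30%
  spec <- c(
    lapply(1:10, function(i) list(diagnosis = c("MCI", "MCI", "AD"),
                                  features = matrix(rnorm(6), 3, 2))),
    lapply(1:10, function(i) list(diagnosis = c("MCI", "MCI", "MCI"),
                                  features = matrix(rnorm(6), 3, 2)))
  )
  co <- make_toy_cohort(spec)
  parts <- split_stratified(co, 0.3, seed = 21)
  conv <- function(c) {
    per <- split(c$visits$diagnosis, c$visits$patient_id)
    sum(vapply(per, function(d) any(d == "AD"), logical(1)))
  }
  expect_equal(n_patients(parts$test), 6L)
  expect_equal(conv(parts$test), 3L)
  expect_length(intersect(unique(parts$train$visits$patient_id),
                          unique(parts$test$visits$patient_id)), 0L)
  parts2 <- split_stratified(co, 0.3, seed = 21)
  expect_identical(parts, parts2)

  # larger cohort: both partitions near the cohort converter fraction
  big <- simulate_cohort(simulation_config(n_patients = 100, seed = 17))
  ps <- split_stratified(big, 0.3, seed = 3)
  frac <- function(c) conv(c) / n_patients(c)
  whole <- frac(big)
  expect_lt(abs(frac(ps$train) - whole), 0.05)
  expect_lt(abs(frac(ps$test) - whole), 0.05)
})

test_that("a singleton stratum goes to training with a warning", {
  spec <- c(
    list(list(diagnosis = c("MCI", "AD"), features = matrix(rnorm(4), 2, 2))),
    lapply(1:6, function(i) list(diagnosis = c("MCI", "MCI"),
                                 features = matrix(rnorm(4), 2, 2)))
  )
  co <- make_toy_cohort(spec)
  expect_warning(parts <- split_stratified(co, 0.3, seed = 1),
                 "stratification")
  expect_true(all(parts$test$visits$diagnosis == "MCI"))
})

test_that("min-max normalisation maps train to [0,1] and extrapolates on test", {
  co <- make_toy_cohort(list(list(diagnosis = rep("MCI", 3),
                                  features = matrix(c(2, 4, 6), 3, 1))),
                        feature_names = "f1")
  st <- fit_minmax(co, include_age = FALSE)
  scaled <- apply_minmax(co, st)
  expect_equal(scaled$visits$f1, c(0, 0.5, 1))

  te <- make_toy_cohort(list(list(diagnosis = rep("MCI", 1),
                                  features = matrix(8, 1, 1))),
                        feature_names = "f1")
  expect_equal(apply_minmax(te, st)$visits$f1, 1.5) # unclipped

  const <- make_toy_cohort(list(list(diagnosis = rep("MCI", 3),
                                     features = matrix(7, 3, 1))),
                           feature_names = "f1")
  stc <- fit_minmax(const, include_age = FALSE)
  expect_equal(apply_minmax(const, stc)$visits$f1, c(0, 0, 0))

  bad <- make_toy_cohort(list(list(diagnosis = rep("MCI", 2),
                                   features = matrix(1:4, 2, 2))),
                         feature_names = c("f1", "zz"))
  expect_error(apply_minmax(bad, st), "schema error")
})

test_that("test-set normalisation uses training statistics only", {
  co <- simulate_cohort(simulation_config(n_patients = 60, seed = 19))
  imp <- impute_knn(filter_missingness(co))
  parts <- split_stratified(imp, 0.3, seed = 2)
  st_train <- fit_minmax(parts$train)
  st_test <- fit_minmax(parts$test)
  a <- apply_minmax(parts$test, st_train)
  b <- apply_minmax(parts$test, st_test)
  f <- parts$test$feature_names[1]
  expect_false(isTRUE(all.equal(a$visits[[f]], b$visits[[f]])))
})

test_that("window construction follows the eligibility rules", {
  spec <- list(
    ok = list(diagnosis = c("MCI", "MCI", "MCI", "AD"),
              features = matrix(rnorm(8), 4, 2)),
    short = list(diagnosis = c("MCI", "MCI", "MCI"),
                 features = matrix(rnorm(6), 3, 2))
  )
  co <- make_toy_cohort(spec)
  s <- build_sequences(co, t = 2, n = 2)
  expect_equal(length(s$y), 1L)
  expect_equal(s$patient_id, "ok")
  expect_equal(s$y, 1L)
  expect_equal(dim(s$X), c(1, 2, 3)) # 2 features + age

  expect_equal(length(build_sequences(co, t = 3, n = 1)$y), 1L) # short excluded
  expect_error(build_sequences(co, t = 0, n = 1), "parameter error")
  expect_error(build_sequences(co, t = 2, n = 0), "parameter error")
})

test_that("AD-in-window and CN handling match the documented policy", {
  spec <- list(
    adwin = list(diagnosis = c("MCI", "AD", "AD", "AD"),
                 features = matrix(rnorm(8), 4, 2)),
    cnwin = list(diagnosis = c("CN", "MCI", "MCI", "MCI"),
                 features = matrix(rnorm(8), 4, 2))
  )
  co <- make_toy_cohort(spec)
  expect_equal(length(build_sequences(co, 2, 2)$y), 0L)
  expect_equal(build_sequences(co, 2, 2, include_cn = TRUE)$patient_id, "cnwin")
})

test_that("sample and label counts equal the exhaustive scan on a scripted cohort", {
  set.seed(55)
  spec <- lapply(1:12, function(i) {
    nv <- sample(2:8, 1)
    conv <- sample(c(TRUE, FALSE), 1)
    d <- rep("MCI", nv)
    if (conv && nv >= 3) d[sample(2:nv, 1):nv] <- "AD"
    list(diagnosis = d, features = matrix(rnorm(nv * 2), nv, 2))
  })
  co <- make_toy_cohort(spec)
  for (t in 1:3) for (n in 1:2) {
    s <- build_sequences(co, t, n)
    orc <- oracle_window_scan(co, t, n)
    expect_equal(length(s$y), nrow(orc))
    expect_equal(sort(s$patient_id), sort(orc$patient_id))
    expect_equal(sum(s$y), sum(orc$y))
    expect_lte(length(s$y), n_patients(co)) # first-window policy
  }
})

test_that("missing values in input windows are an error", {
  Feat <- matrix(c(1, NA, 2, 3, 4, 5), 3, 2)
  co <- make_toy_cohort(list(list(diagnosis = rep("MCI", 3),
                                  features = Feat)))
  expect_error(build_sequences(co, 2, 1), "impute")
})

test_that("demographic encoding is one-hot with train-fixed categories", {
  co <- simulate_cohort(simulation_config(n_patients = 40, seed = 23))
  enc <- fit_demographic_encoder(co)
  D <- encode_demographics(co$demographics, enc)
  card <- sum(lengths(enc$levels))
  expect_equal(ncol(D), card + 2) # + education + apoe4
  expect_equal(nrow(D), n_patients(co))
  # gender block is a one-hot prefix in sorted category order
  g <- D[, paste0("gender_", enc$levels$gender), drop = FALSE]
  expect_true(all(rowSums(g) == 1))
  i <- which(co$demographics$gender == "F")[1]
  expect_equal(unname(g[i, ]), c(1, 0))
  # apoe4 enters as the raw allele count
  expect_equal(unname(D[, "apoe4"]), as.numeric(co$demographics$apoe4))

  unseen <- co$demographics[1, ]
  unseen$race <- "Martian"
  expect_message(Du <- encode_demographics(unseen, enc), "unseen")
  expect_true(all(Du[1, paste0("race_", enc$levels$race)] == 0))
})

test_that("the pipeline wrapper applies filter, impute, split, normalise in order", {
  co <- simulate_cohort(simulation_config(n_patients = 60, seed = 29))
  pp <- preprocess_cohort(co, seed = 5)
  expect_false(anyNA(pp$train$visits[pp$train$feature_names]))
  expect_false(anyNA(pp$test$visits[pp$test$feature_names]))
  for (f in pp$train$feature_names) {
    expect_gte(min(pp$train$visits[[f]]), 0)
    expect_lte(max(pp$train$visits[[f]]), 1)
  }
  expect_length(intersect(unique(pp$train$visits$patient_id),
                          unique(pp$test$visits$patient_id)), 0L)
})

test_that("sliding windows yield every eligible start, first-window one per patient", {
  spec <- list(long = list(diagnosis = c("MCI", "MCI", "MCI", "MCI", "AD"),
                           features = matrix(rnorm(10), 5, 2)))
  co <- make_toy_cohort(spec)
  first <- build_sequences(co, t = 2, n = 1)
  slid <- build_sequences(co, t = 2, n = 1, sliding = TRUE)
  expect_equal(length(first$y), 1L)
  # starts 1..3 are eligible (window AD-free), targets visits 3, 4, 5
  expect_equal(length(slid$y), 3L)
  expect_equal(slid$y, c(0L, 0L, 1L))
})
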