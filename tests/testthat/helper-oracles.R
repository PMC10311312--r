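# Independent brute-force oracles used to pin down the vectorised
# implementations.  These are deliberately written as plain scalar loops from
# the defining equations, not by calling package internals.

# GRU update computed element by element.
scalar_gru_step <- function(p, x, h) {
  H <- length(h)
  r <- z <- hc <- hn <- numeric(H)
  lincomb <- function(W, U, b, i, rh = h) {
    acc <- b[i]
    for (j in seq_along(x)) acc <- acc + W[i, j] * x[j]
    for (j in seq_len(H)) acc <- acc + U[i, j] * rh[j]
    acc
  }
  for (i in seq_len(H)) r[i] <- 1 / (1 + exp(-lincomb(p$Wr, p$Ur, p$br, i)))
  for (i in seq_len(H)) z[i] <- 1 / (1 + exp(-lincomb(p$Wz, p$Uz, p$bz, i)))
  for (i in seq_len(H)) {
    hc[i] <- tanh(lincomb(p$Wh, p$Uh, p$bh, i, rh = r * h))
  }
  for (i in seq_len(H)) hn[i] <- (1 - z[i]) * h[i] + z[i] * hc[i]
  hn
}

# Unidirectional GRU pass over the rows of X from a zero state.
scalar_gru_sequence <- function(p, X) {
  h <- numeric(nrow(p$Ur))
  states <- matrix(0, nrow(X), length(h))
  for (t in seq_len(nrow(X))) {
    h <- scalar_gru_step(p, X[t, ], h)
    states[t, ] <- h
  }
  states
}

# Classification head computed with explicit loops.
scalar_head <- function(head, latent, d) {
  inp <- c(latent, d)
  Hm <- nrow(head$W2)
  z2 <- numeric(Hm)
  for (i in seq_len(Hm)) {
    z2[i] <- head$b2[i] + sum(head$W2[i, ] * inp)
  }
  r2 <- pmax(z2, 0)
  logit <- head$b1 + sum(head$W1[1, ] * r2)
  1 / (1 + exp(-logit))
}

# Diagnosis-constrained KNN imputation following the documented rule, one
# missing cell at a time, with no shared code with impute_knn().
oracle_knn_impute <- function(visits, feature_names, k = 5) {
  M <- as.matrix(visits[feature_names])
  Fn <- length(feature_names)
  out <- M
  for (i in seq_len(nrow(M))) {
    for (f in seq_len(Fn)) {
      if (!is.na(M[i, f])) next
      cand <- setdiff(which(visits$diagnosis == visits$diagnosis[i] &
                              !is.na(M[, f])), i)
      if (!length(cand)) {
        same <- M[visits$diagnosis == visits$diagnosis[i], f]
        out[i, f] <- mean(same, na.rm = TRUE)
        next
      }
      d <- numeric(length(cand))
      for (ci in seq_along(cand)) {
        c <- cand[ci]
        shared <- which(!is.na(M[i, ]) & !is.na(M[c, ]))
        d[ci] <- if (length(shared)) {
          sqrt(sum((M[i, shared] - M[c, shared])^2) * Fn / length(shared))
        } else Inf
      }
      ord <- order(d, cand)
      out[i, f] <- mean(M[cand[ord[seq_len(min(k, length(cand)))]], f])
    }
  }
  out
}

# Exhaustive-scan window eligibility (first-window policy).
oracle_window_scan <- function(cohort, t, n, include_cn = FALSE) {
  v <- cohort$visits
  out <- data.frame(patient_id = character(0), y = integer(0))
  for (pid in unique(v$patient_id)) {
    rows <- v[v$patient_id == pid, ]
    rows <- rows[order(rows$visit_index), ]
    if (nrow(rows) < t + n) next
    dwin <- rows$diagnosis[1:t]
    dtgt <- rows$diagnosis[t + n]
    if (any(dwin == "AD")) next
    if (!include_cn && any(dwin == "CN")) next
    if (!dtgt %in% c("MCI", "AD")) next
    out <- rbind(out, data.frame(patient_id = pid,
                                 y = as.integer(dtgt == "AD")))
  }
  out
}

# Exact Shapley values by direct subset enumeration (weights |S|!(F-|S|-1)!/F!)
# for a value function v(members) -> numeric vector over samples.
oracle_shapley_exact <- function(value_fn, Fn) {
  subsets <- lapply(0:(2^Fn - 1), function(m) which(bitwAnd(m, 2^(0:(Fn - 1))) > 0))
  vals <- lapply(subsets, value_fn)
  key <- vapply(subsets, function(s) paste(s, collapse = ","), character(1))
  phi <- NULL
  for (j in seq_len(Fn)) {
    contrib <- 0
    for (si in seq_along(subsets)) {
      S <- subsets[[si]]
      if (j %in% S) next
      w <- factorial(length(S)) * factorial(Fn - length(S) - 1) / factorial(Fn)
      Sj <- sort(c(S, j))
      vj <- vals[[match(paste(Sj, collapse = ","), key)]]
      contrib <- contrib + w * (vj - vals[[si]])
    }
    phi <- cbind(phi, contrib)
  }
  colnames(phi) <- NULL
  phi
}

# Build a small cohort directly from a per-patient spec list:
# list(list(diagnosis = c(...), features = matrix, age = c(...)), ...)
make_toy_cohort <- function(spec, feature_names = NULL) {
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(ncol(spec[[1]]$features)))
  }
  rows <- list()
  demo <- list()
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    pid <- names(spec)[i] %||% sprintf("T%02d", i)
    nv <- length(s$diagnosis)
    df <- data.frame(patient_id = pid, visit_index = seq_len(nv),
                     visit_month = (seq_len(nv) - 1) * 6,
                     age = s$age %||% (70 + (seq_len(nv) - 1) * 0.5),
                     diagnosis = s$diagnosis, stringsAsFactors = FALSE)
    df[feature_names] <- as.data.frame(s$features)
    rows[[i]] <- df
    demo[[i]] <- data.frame(patient_id = pid,
                            gender = s$gender %||% "F",
                            race = s$race %||% "White",
                            ethnicity = s$ethnicity %||% "NotHispanic",
                            education = s$education %||% 16,
                            apoe4 = s$apoe4 %||% 0,
                            stringsAsFactors = FALSE)
  }
  cohort <- structure(list(visits = do.call(rbind, rows),
                           demographics = do.call(rbind, demo),
                           feature_names = feature_names),
                      class = "mci_cohort")
  rownames(cohort$visits) <- rownames(cohort$demographics) <- NULL
  validate_cohort(cohort)
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
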