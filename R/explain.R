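# Per-feature attribution for trained conversion models.

# Model output for masked inputs: coalition members keep their actual values
# (all time steps of the feature), everything else is replaced by the
# background window.  X is N x T x F, background is T x F.
coalition_value <- function(model, X, D, background, members) {
  Xm <- X
  Fn <- dim(X)[3]
  out_feats <- setdiff(seq_len(Fn), members)
  for (f in out_feats) {
    Xm[, , f] <- matrix(background[, f], nrow = dim(X)[1], ncol = dim(X)[2],
                        byrow = TRUE)
  }
  model_forward(model, Xm, D)
}

#' Per-feature importance for a trained conversion model
#'
#' Two estimators are provided.  `"shapley"` computes Monte-Carlo Shapley
#' values: a feature's contribution is its average marginal effect on the
#' predicted probability when added to a random coalition of the other
#' features, where a feature outside the coalition has all of its time steps
#' replaced by the background window (training-set feature means).  With
#' `exact = TRUE` all `F!` orderings are enumerated, which is feasible for
#' small toy models and satisfies the Shapley axioms to numerical precision.
#' The report aggregates absolute per-sample attributions, matching the usual
#' mean-|SHAP| presentation.  `"permutation"` permutes one feature column
#' across samples (all time steps jointly) and reports the mean resulting F2
#' drop, floored at zero.
#'
#' @param model A trained `conversion_model`.
#' @param samples A `sequence_set` of evaluation samples (>= 20 recommended).
#' @param method `"shapley"` or `"permutation"`.
#' @param background `T x F` background window; defaults to the per-time-step
#'   feature means of `samples` (pass the training-set means for a fixed
#'   reference).
#' @param nsim Monte-Carlo permutations for `"shapley"` (ignored when
#'   `exact`), repetitions for `"permutation"`.
#' @param exact Enumerate all feature orderings (requires few features).
#' @param threshold Probability threshold used by the permutation method.
#' @param seed Seed; estimates are deterministic given it.
#' @return An `importance_report` data.frame with columns `feature`,
#'   `importance`, `method`; for `"shapley"` the signed per-sample attribution
#'   matrix is kept in attribute `"phi"` (samples x features).
#' @export
feature_importance <- function(model, samples,
                               method = c("shapley", "permutation"),
                               background = NULL, nsim = 30L, exact = FALSE,
                               threshold = 0.5, seed = 1L) {
  method <- match.arg(method)
  X <- samples$X
  Fn <- dim(X)[3]
  feats <- samples$feature_names
  if (is.null(background)) {
    background <- apply(X, c(2, 3), mean)
  }
  if (method == "shapley") {
    perms <- if (exact) {
      if (Fn > 8) stop("config error: exact enumeration needs <= 8 features",
                       call. = FALSE)
      all_permutations(Fn)
    } else {
      with_seed(derive_seed(seed, 13L),
                lapply(seq_len(nsim), function(i) sample(Fn)))
    }
    phi <- matrix(0, dim(X)[1], Fn, dimnames = list(NULL, feats))
    for (perm in perms) {
      v_prev <- coalition_value(model, X, samples$D, background, integer(0))
      members <- integer(0)
      for (f in perm) {
        members <- c(members, f)
        v_new <- coalition_value(model, X, samples$D, background, members)
        phi[, f] <- phi[, f] + (v_new - v_prev)
        v_prev <- v_new
      }
    }
    phi <- phi / length(perms)
    report <- data.frame(feature = feats, importance = colMeans(abs(phi)),
                         method = if (exact) "shapley-exact" else
                           "shapley-sampling",
                         stringsAsFactors = FALSE)
    attr(report, "phi") <- phi
  } else {
    base <- evaluate_model(model, samples, threshold = threshold)$f2
    drops <- matrix(0, nsim, Fn)
    with_seed(derive_seed(seed, 17L), {
      for (r in seq_len(nsim)) {
        for (f in seq_len(Fn)) {
          Xp <- X
          Xp[, , f] <- X[sample(dim(X)[1]), , f]
          sp <- samples
          sp$X <- Xp
          drops[r, f] <- base - evaluate_model(model, sp,
                                               threshold = threshold)$f2
        }
      }
    })
    report <- data.frame(feature = feats,
                         importance = pmax(colMeans(drops), 0),
                         method = "permutation", stringsAsFactors = FALSE)
  }
  rownames(report) <- NULL
  class(report) <- c("importance_report", "data.frame")
  report
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

#' Rank an importance report for plotting
#'
#' Sorts features by descending importance with stable ties (input order
#' preserved among equal values) and optionally keeps the top k.
#'
#' @param report An [feature_importance()] report.
#' @param k Keep at most this many features (default all).
#' @return The ranked data.frame with a `rank` column.
#' @export
importance_plot_data <- function(report, k = Inf) {
  ord <- order(-report$importance) # order() is a stable sort
  out <- report[ord, , drop = FALSE]
  out <- utils::head(out, min(k, nrow(out)))
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
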