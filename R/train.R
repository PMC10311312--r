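# Training loop: full-model backpropagation (head -> decoder -> encoder,
# through time) and Adam.

# Recursive helpers over nested parameter trees (lists of matrices/vectors).
tree_zeros <- function(p) {
  if (is.list(p)) {
    z <- lapply(p, tree_zeros)
    attributes(z) <- attributes(p)
    z
  } else if (is.matrix(p)) 0 * p else numeric(length(p))
}

tree_add <- function(a, b) {
  if (is.list(a)) {
    out <- mapply(tree_add, a, b, SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else a + b
}

# Weight-decay gradient: 2 * l2 * W on matrix leaves (biases untouched).
tree_l2_grad <- function(p, l2) {
  if (is.list(p)) {
    out <- lapply(p, tree_l2_grad, l2 = l2)
    attributes(out) <- attributes(p)
    out
  } else if (is.matrix(p)) 2 * l2 * p else numeric(length(p))
}

tree_l2_penalty <- function(p, l2) {
  if (is.list(p)) sum(vapply(p, tree_l2_penalty, numeric(1), l2 = l2))
  else if (is.matrix(p)) l2 * sum(p^2) else 0
}

adam_step <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    for (nm in names(p)) {
      res <- adam_step(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

# Trainable parameter tree of a model (decoder omitted when absent).
model_params <- function(model) {
  tr <- list(encoder = model$encoder, head = model$head)
  if (!is.null(model$decoder)) tr$decoder <- model$decoder
  tr
}

set_model_params <- function(model, tr) {
  model$encoder <- tr$encoder
  model$head <- tr$head
  if (!is.null(model$decoder)) model$decoder <- tr$decoder
  model
}

# One forward+backward pass over a batch.  `dropout_mask` (N x latent_dim or
# NULL) is drawn by the caller so the RNG stream stays in one place.
training_step <- function(model, X_steps, D, y, dropout_mask = NULL) {
  cfg <- model$config
  N <- nrow(X_steps[[1]])
  enc <- encode_batch(model, X_steps)
  latent <- enc$latent
  dec <- NULL
  if (model$architecture == "seq2seq") {
    dec <- decode_batch(model, latent, cfg$horizon)
    latent <- dec$latents[[length(dec$latents)]]
  }
  if (!is.null(dropout_mask)) latent <- latent * dropout_mask
  hf <- head_forward(model$head, latent, D)
  p <- pmin(pmax(hf$prob, 1e-7), 1 - 1e-7)
  data_loss <- -mean(cfg$alpha * y * log(p) + (1 - cfg$alpha) * (1 - y) * log(1 - p))
  loss <- data_loss + tree_l2_penalty(model_params(model), cfg$l2)

  # d loss / d logit of the weighted cross-entropy, batch-mean reduction
  dlogit <- matrix((-cfg$alpha * y * (1 - p) + (1 - cfg$alpha) * (1 - y) * p) / N,
                   ncol = 1)
  g_head <- list(W2 = NULL, b2 = NULL, W1 = NULL, b1 = NULL)
  g_head$W1 <- crossprod(dlogit, hf$r2)
  g_head$b1 <- sum(dlogit)
  dr2 <- dlogit %*% model$head$W1
  dz2 <- dr2 * (hf$z2 > 0)
  g_head$W2 <- crossprod(dz2, hf$inp)
  g_head$b2 <- colSums(dz2)
  dinp <- dz2 %*% model$head$W2
  dlatent <- dinp[, seq_len(model$latent_dim), drop = FALSE]
  if (!is.null(dropout_mask)) dlatent <- dlatent * dropout_mask

  grads <- list(encoder = NULL, head = g_head)
  if (model$architecture == "seq2seq") {
    bk <- cell_backward(model$decoder, dec$out$cache, dlatent)
    grads$decoder <- bk$grads
    dlatent <- bk$dh0
  }
  if (!is.null(model$encoder$bwd)) {
    H <- cfg$hidden_dim
    bf <- cell_backward(model$encoder$fwd, enc$fwd$cache,
                        dlatent[, seq_len(H), drop = FALSE])
    bb <- cell_backward(model$encoder$bwd, enc$bwd$cache,
                        dlatent[, H + seq_len(H), drop = FALSE])
    grads$encoder <- list(fwd = bf$grads, bwd = bb$grads)
  } else {
    bf <- cell_backward(model$encoder$fwd, enc$fwd$cache, dlatent)
    grads$encoder <- list(fwd = bf$grads)
  }
  if (cfg$l2 > 0) {
    grads <- tree_add(grads[names(model_params(model))],
                      tree_l2_grad(model_params(model), cfg$l2))
  } else {
    grads <- grads[names(model_params(model))]
  }
  list(loss = loss, data_loss = data_loss, grads = grads)
}

#' Train a conversion model
#'
#' Optimises all encoder, decoder and head parameters jointly against the
#' sensitivity-weighted binary cross-entropy ([weighted_bce()]) with Adam at
#' `config$learning_rate`, for `config$epochs` epochs of shuffled minibatches
#' of `config$batch_size`.  Dropout is applied to the latent entering the
#' classification head; the L2 penalty applies to all weight matrices.  The
#' whole run (initialisation, shuffling, dropout) is reproducible given
#' `config$seed`.
#'
#' @param samples A [build_sequences()] `sequence_set`.
#' @param config A [model_config()].
#' @param architecture `"auto"` (default) selects `"direct"` when the sample
#'   horizon is 1 and `"seq2seq"` otherwise.
#' @param verbose Print the per-epoch loss.
#' @param use_cpp Run the epoch loop through the compiled path (default).
#'   The pure-R path computes the identical updates (it is the reference the
#'   compiled path is tested against) at interpreter speed.
#' @return A trained `conversion_model` with a per-epoch `loss_trace`.
#' @export
train_model <- function(samples, config = model_config(),
                        architecture = c("auto", "direct", "seq2seq"),
                        verbose = FALSE, use_cpp = TRUE) {
  architecture <- match.arg(architecture)
  ns <- length(samples$y)
  if (ns == 0) stop("input error: no training samples", call. = FALSE)
  if (length(unique(samples$y)) < 2) {
    warning("training samples contain a single class; the classifier cannot discriminate")
  }
  if (architecture == "auto") {
    architecture <- if (samples$n == 1) "direct" else "seq2seq"
  }
  if (architecture == "seq2seq") config$horizon <- as.integer(samples$n)
  model <- init_model(config, input_dim = dim(samples$X)[3],
                      demo_dim = ncol(samples$D), architecture = architecture)
  if (config$epochs == 0) return(model)

  y_full <- samples$y
  # Draw order is fixed so the compiled and reference paths see the same RNG
  # stream: all epoch permutations first, then per-batch dropout masks in
  # training order (column-major within a batch).
  model <- with_seed(derive_seed(config$seed, 7919L), {
    perms <- vapply(seq_len(config$epochs), function(e) sample(ns),
                    integer(ns))
    if (use_cpp) {
      res <- fit_loop_cpp(model$encoder$fwd, model$encoder$bwd,
                          model$decoder, model$head,
                          samples$X, samples$D, as.numeric(y_full),
                          perms, config$batch_size, config$dropout,
                          cell_base(config$cell) == "GRU",
                          model$architecture == "seq2seq",
                          config$horizon, config$learning_rate,
                          config$alpha, config$l2)
      for (nm in names(model$encoder$fwd)) {
        model$encoder$fwd[[nm]] <- res$enc_fwd[[nm]]
      }
      if (!is.null(model$encoder$bwd)) {
        for (nm in names(model$encoder$bwd)) {
          model$encoder$bwd[[nm]] <- res$enc_bwd[[nm]]
        }
      }
      if (!is.null(model$decoder)) {
        for (nm in names(model$decoder)) {
          model$decoder[[nm]] <- res$decoder[[nm]]
        }
      }
      model$head$W2 <- res$head$W2; model$head$b2 <- as.vector(res$head$b2)
      model$head$W1 <- res$head$W1; model$head$b1 <- as.vector(res$head$b1)
      model$loss_trace <- as.vector(res$trace) / ns
      if (verbose) {
        message(sprintf("final loss %.5f after %d epochs",
                        model$loss_trace[config$epochs], config$epochs))
      }
      model
    } else {
      X_full <- as_step_list(samples$X)
      D_full <- samples$D
      params <- model_params(model)
      m <- tree_zeros(params)
      v <- tree_zeros(params)
      step_t <- 0L
      trace <- numeric(config$epochs)
      for (epoch in seq_len(config$epochs)) {
        splits <- split(perms[, epoch],
                        ceiling(seq_len(ns) / config$batch_size))
        ep_loss <- 0
        for (idx in splits) {
          Xb <- lapply(X_full, function(Xt) Xt[idx, , drop = FALSE])
          mask <- NULL
          if (config$dropout > 0) {
            mask <- matrix(
              (stats::runif(length(idx) * model$latent_dim) >=
                 config$dropout) / (1 - config$dropout),
              length(idx), model$latent_dim)
          }
          st <- training_step(model, Xb, D_full[idx, , drop = FALSE],
                              y_full[idx], dropout_mask = mask)
          step_t <- step_t + 1L
          upd <- adam_step(model_params(model), st$grads, m, v,
                           lr = config$learning_rate, t = step_t)
          m <- upd$m; v <- upd$v
          model <- set_model_params(model, upd$p)
          ep_loss <- ep_loss + st$data_loss * length(idx)
        }
        trace[epoch] <- ep_loss / ns
        if (verbose) {
          message(sprintf("epoch %d/%d  loss %.5f", epoch, config$epochs,
                          trace[epoch]))
        }
      }
      model$loss_trace <- trace
      model
    }
  })
  model
}

#' F-beta score from precision and recall
#'
#' `(1 + beta^2) * precision * recall / (beta^2 * precision + recall)`,
#' returning 0 when the denominator is 0.  With `beta = 2` (the default),
#' recall is weighted four-fold relative to precision in the denominator,
#' reflecting that a missed converter is costlier than a false alarm.
#'
#' @param precision,recall Fractions in `[0, 1]` (vectorised).
#' @param beta Recall weight (default 2).
#' @return F-beta score(s) in `[0, 1]`.
#' @export
f_beta <- function(precision, recall, beta = 2) {
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  ifelse(den > 0, num / den, 0)
}

#' Evaluate a trained model on a sample set
#'
#' Thresholds the predicted probabilities, accumulates the confusion counts,
#' and derives precision, recall (sensitivity) and the F2 score.
#'
#' @param model A trained `conversion_model`.
#' @param samples A `sequence_set`.
#' @param threshold Classification threshold on the predicted probability
#'   (default 0.5).
#' @return One-row data.frame: `t`, `n`, `tp`, `fp`, `tn`, `fn`, `precision`,
#'   `recall`, `sensitivity`, `f2`, `threshold`, `n_samples`.
#' @export
evaluate_model <- function(model, samples, threshold = 0.5) {
  if (length(samples$y) == 0) stop("input error: empty test set", call. = FALSE)
  prob <- model_forward(model, samples$X, samples$D)
  confusion_metrics(samples$y, as.integer(prob >= threshold),
                    t = samples$t, n = samples$n, threshold = threshold)
}

confusion_metrics <- function(y, pred, t = NA, n = NA, threshold = 0.5) {
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  data.frame(t = t, n = n, tp = tp, fp = fp, tn = tn, fn = fn,
             precision = precision, recall = recall, sensitivity = recall,
             f2 = f_beta(precision, recall, beta = 2),
             threshold = threshold, n_samples = length(y))
}

#' Grid search with patient-level stratified k-fold cross-validation
#'
#' Evaluates every point of the hyperparameter grid by stratified
#' cross-validation (folds assigned per patient, stratified by target label,
#' so no patient appears in two folds) and selects the configuration with the
#' highest mean F2.  Ties are broken toward the smaller model: fewer epochs,
#' then smaller hidden width, then grid order.
#'
#' @param grid Named list of candidate values for [model_config()] fields
#'   (e.g. `list(cell = c("GRU", "BiGRU"), epochs = c(10, 30))`).  Every axis
#'   must be non-empty.
#' @param samples A `sequence_set`.
#' @param folds Number of CV folds (default 5).
#' @param config_base Defaults for fields not in the grid.
#' @param seed Master seed for fold assignment and per-fit seeds.
#' @return `list(best_config, cv_table)`; `cv_table` has one row per grid
#'   point and fold.
#' @export
grid_search_cv <- function(grid, samples, folds = 5L,
                           config_base = model_config(), seed = 1L) {
  if (!length(grid) || any(!lengths(grid))) {
    stop("config error: every grid axis must be non-empty", call. = FALSE)
  }
  bad <- setdiff(names(grid), setdiff(names(config_base), "seed"))
  if (length(bad)) {
    stop("config error: unknown grid field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  gtab <- expand.grid(grid, stringsAsFactors = FALSE)

  # patient-level stratified folds
  pid <- samples$patient_id
  upid <- unique(pid)
  ylab <- vapply(upid, function(p) max(samples$y[pid == p]), numeric(1))
  fold_of <- integer(length(upid))
  names(fold_of) <- upid
  with_seed(derive_seed(seed, 11L), {
    for (cls in unique(ylab)) {
      ids <- sample(upid[ylab == cls])
      fold_of[ids] <- rep_len(seq_len(folds), length(ids))
    }
  })
  sample_fold <- fold_of[pid]

  rows <- vector("list", nrow(gtab) * folds)
  r <- 0L
  for (i in seq_len(nrow(gtab))) {
    args <- as.list(config_base)[setdiff(names(config_base), NULL)]
    for (nm in names(gtab)) args[[nm]] <- gtab[[nm]][i]
    for (j in seq_len(folds)) {
      args$seed <- derive_seed(seed, i, j)
      cfg <- do.call(model_config, args[names(args) %in% names(formals(model_config))])
      fit <- train_model(subset_samples(samples, which(sample_fold != j)), cfg)
      ev <- evaluate_model(fit, subset_samples(samples, which(sample_fold == j)))
      r <- r + 1L
      rows[[r]] <- cbind(gtab[i, , drop = FALSE], config = i, fold = j,
                         f2 = ev$f2, sensitivity = ev$sensitivity,
                         n_val = ev$n_samples, row.names = NULL)
    }
  }
  cv_table <- do.call(rbind, rows)
  mean_f2 <- tapply(cv_table$f2, cv_table$config, mean)
  epochs_val <- if ("epochs" %in% names(gtab)) gtab$epochs else
    rep(config_base$epochs, nrow(gtab))
  hidden_val <- if ("hidden_dim" %in% names(gtab)) gtab$hidden_dim else
    rep(config_base$hidden_dim, nrow(gtab))
  best_i <- order(-mean_f2[as.character(seq_len(nrow(gtab)))], epochs_val,
                  hidden_val, seq_len(nrow(gtab)))[1]
  args <- as.list(config_base)
  for (nm in names(gtab)) args[[nm]] <- gtab[[nm]][best_i]
  args$seed <- config_base$seed
  best <- do.call(model_config, args[names(args) %in% names(formals(model_config))])
  list(best_config = best, cv_table = cv_table, mean_f2 = mean_f2)
}
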