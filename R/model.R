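#' Architecture and training hyperparameters
#'
#' @param cell Recurrent cell type: `"GRU"`, `"LSTM"`, `"BiGRU"` or
#'   `"BiLSTM"`.  Bidirectional variants feed a `2 * hidden_dim`-wide latent
#'   to the classification head.
#' @param hidden_dim Hidden state width H (default 32).
#' @param mlp_hidden Width of the classification head's hidden layer;
#'   defaults to `hidden_dim`.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param dropout Dropout rate applied to the encoder/decoder latent before
#'   the head, in `[0, 1)`.
#' @param l2 L2 penalty on all weight matrices (biases excluded).
#' @param alpha Positive-class weight of the sensitivity-weighted binary
#'   cross-entropy, in (0, 1); default 0.7.
#' @param learning_rate Adam learning rate; default 0.001.
#' @param horizon Decoder roll-out length n (sequence-to-sequence
#'   architecture only).
#' @param seed Integer seed controlling initialisation, batching and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(cell = c("GRU", "LSTM", "BiGRU", "BiLSTM"),
                         hidden_dim = 32L, mlp_hidden = NULL,
                         epochs = 30L, batch_size = 32L, dropout = 0.1,
                         l2 = 1e-4, alpha = 0.7, learning_rate = 0.001,
                         horizon = 1L, seed = 1L) {
  cell <- match.arg(cell)
  stopifnot_scalar_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  stopifnot_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  stopifnot_scalar_number(dropout, "dropout", 0, 1 - 1e-12)
  stopifnot_scalar_number(l2, "l2", lower = 0)
  structure(list(cell = cell, hidden_dim = as.integer(hidden_dim),
                 mlp_hidden = as.integer(mlp_hidden %||% hidden_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 dropout = dropout, l2 = l2, alpha = alpha,
                 learning_rate = learning_rate,
                 horizon = as.integer(horizon), seed = as.integer(seed)),
            class = "model_config")
}

is_bidirectional <- function(cell) cell %in% c("BiGRU", "BiLSTM")
cell_base <- function(cell) if (cell %in% c("GRU", "BiGRU")) "GRU" else "LSTM"

#' Initialise a conversion model
#'
#' Builds the recurrent encoder (one cell, or two for bidirectional
#' variants), the optional sequence-to-sequence decoder, and the two-layer
#' classification head `y' = sigmoid(W1 ReLU(W2 (latent (+) D) + b2) + b1)`.
#' All parameters are drawn reproducibly from `config$seed`.
#'
#' @param config A [model_config()].
#' @param input_dim Number of longitudinal input features F (age included if
#'   used).
#' @param demo_dim Width of the encoded demographic vector (0 disables the
#'   demographic pathway).
#' @param architecture `"direct"` classifies from the encoder's final hidden
#'   state (next-visit prediction); `"seq2seq"` first rolls a decoder cell
#'   `config$horizon` steps forward from that state and classifies from the
#'   last decoder latent (multi-visit-ahead prediction).
#' @return A `conversion_model`.
#' @export
init_model <- function(config, input_dim, demo_dim = 0L,
                       architecture = c("direct", "seq2seq")) {
  architecture <- match.arg(architecture)
  if (architecture == "seq2seq" && config$horizon < 1) {
    stop("parameter error: horizon must be >= 1", call. = FALSE)
  }
  H <- config$hidden_dim
  latent_dim <- if (is_bidirectional(config$cell)) 2L * H else H
  with_seed(config$seed, {
    encoder <- list(fwd = cell_params(cell_base(config$cell), input_dim, H))
    if (is_bidirectional(config$cell)) {
      encoder$bwd <- cell_params(cell_base(config$cell), input_dim, H)
    }
    decoder <- if (architecture == "seq2seq") {
      cell_params(cell_base(config$cell), 1L, latent_dim)
    }
    Hm <- config$mlp_hidden
    head <- list(W2 = glorot(Hm, latent_dim + demo_dim), b2 = numeric(Hm),
                 W1 = glorot(1L, Hm), b1 = numeric(1))
    structure(list(config = config, architecture = architecture,
                   input_dim = as.integer(input_dim),
                   demo_dim = as.integer(demo_dim),
                   latent_dim = latent_dim,
                   encoder = encoder, decoder = decoder, head = head,
                   loss_trace = numeric(0)),
              class = "conversion_model")
  })
}

#' @export
print.conversion_model <- function(x, ...) {
  cat(sprintf(
    "<conversion_model> %s %s (H=%d, latent=%d, demographics=%d%s)\n",
    x$architecture, x$config$cell, x$config$hidden_dim, x$latent_dim,
    x$demo_dim,
    if (x$architecture == "seq2seq") sprintf(", horizon=%d", x$config$horizon)
    else ""))
  if (length(x$loss_trace)) {
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                length(x$loss_trace), x$loss_trace[length(x$loss_trace)]))
  }
  invisible(x)
}

# Split an N x T x F array into a list of T matrices (N x F); accepts a
# single T x F matrix as a one-sample batch.
as_step_list <- function(X) {
  if (is.matrix(X)) X <- array(X, dim = c(1, nrow(X), ncol(X)))
  stopifnot(length(dim(X)) == 3)
  N <- dim(X)[1]
  lapply(seq_len(dim(X)[2]), function(t) matrix(X[, t, ], nrow = N))
}

# Encoder over a batch: returns latent (N x latent_dim) and caches.
encode_batch <- function(model, X_steps) {
  fwd <- cell_forward(model$encoder$fwd, X_steps)
  if (!is.null(model$encoder$bwd)) {
    bwd <- cell_forward(model$encoder$bwd, rev(X_steps))
    list(latent = cbind(fwd$h, bwd$h), fwd = fwd, bwd = bwd)
  } else {
    list(latent = fwd$h, fwd = fwd)
  }
}

# Decoder roll-out: same cell type, zero input at every step, hidden state
# initialised with the encoder latent.  Returns all n latents.
decode_batch <- function(model, latent, n) {
  N <- nrow(latent)
  zero_steps <- lapply(seq_len(n), function(i) matrix(0, N, 1))
  out <- cell_forward(model$decoder, zero_steps, h0 = latent)
  latents <- lapply(seq_len(n), function(t) {
    cc <- out$cache[[t]]
    if (inherits(model$decoder, "gru_params")) {
      (1 - cc$z) * cc$h_prev + cc$z * cc$hc
    } else {
      cc$o * cc$tc
    }
  })
  list(latents = latents, out = out)
}

head_forward <- function(head, latent, D) {
  inp <- cbind(latent, D)
  z2 <- inp %*% t(head$W2) + rep(head$b2, each = nrow(inp))
  r2 <- pmax(z2, 0)
  logits <- r2 %*% t(head$W1) + rep(head$b1, each = nrow(inp))
  list(prob = as.vector(sigmoid(logits)), inp = inp, z2 = z2, r2 = r2)
}

#' Forward pass of a conversion model
#'
#' Computes the predicted probability of an AD diagnosis at the target visit
#' for one window (`T x F` matrix) or a batch (`N x T x F` array).  For the
#' sequence-to-sequence architecture the decoder is rolled `horizon` steps
#' and, with `return_latents = TRUE`, the per-step decoder latents are
#' returned for inspection.
#'
#' @param model A `conversion_model`.
#' @param X Input window(s): `T x F` matrix or `N x T x F` array.
#' @param D Encoded demographic vector/matrix, or `NULL` when the model was
#'   built with `demo_dim = 0`.
#' @param return_latents Also return decoder latents (seq2seq only).
#' @return Numeric vector of probabilities in (0, 1); or, with latents, a
#'   list `(prob, latents)` where `latents` is a list of `horizon` matrices.
#' @export
model_forward <- function(model, X, D = NULL, return_latents = FALSE) {
  X_steps <- as_step_list(X)
  N <- nrow(X_steps[[1]])
  if (ncol(X_steps[[1]]) != model$input_dim) {
    stop("dimension error: X has ", ncol(X_steps[[1]]), " features, model expects ",
         model$input_dim, call. = FALSE)
  }
  if (is.null(D)) D <- matrix(0, N, 0)
  if (!is.matrix(D)) D <- matrix(D, nrow = N, byrow = TRUE)
  if (ncol(D) != model$demo_dim) {
    stop("dimension error: D has ", ncol(D), " columns, model expects ",
         model$demo_dim, call. = FALSE)
  }
  enc <- encode_batch(model, X_steps)
  latent <- enc$latent
  latents <- NULL
  if (model$architecture == "seq2seq") {
    dec <- decode_batch(model, latent, model$config$horizon)
    latents <- dec$latents
    latent <- latents[[length(latents)]]
  }
  hf <- head_forward(model$head, latent, D)
  if (return_latents) list(prob = hf$prob, latents = latents) else hf$prob
}

#' Sensitivity-weighted binary cross-entropy
#'
#' `-(1/N) * sum(alpha * y * log(p) + (1 - alpha) * (1 - y) * log(1 - p))`
#' with natural logarithms and batch-mean reduction.  `alpha > 0.5` penalises
#' false negatives (missed converters) more than false positives, pushing the
#' trained classifier toward higher sensitivity.  Predictions are clipped to
#' `[eps, 1 - eps]` before the logarithm.
#'
#' @param y Binary labels (0/1).
#' @param y_pred Predicted probabilities.
#' @param alpha Positive-class weight in (0, 1); default 0.7.
#' @param eps Clipping constant (default 1e-7).
#' @return Scalar loss (>= 0).
#' @export
weighted_bce <- function(y, y_pred, alpha = 0.7, eps = 1e-7) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("parameter error: alpha must be in (0, 1)", call. = FALSE)
  }
  stopifnot(length(y) == length(y_pred))
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -mean(alpha * y * log(p) + (1 - alpha) * (1 - y) * log(1 - p))
}
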