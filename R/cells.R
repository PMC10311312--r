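# Recurrent cells: parameter containers, single-step reference operations,
# and batched forward/backward passes used by the training loop.
#
# Conventions: input-to-hidden matrices W* are H x F, hidden-to-hidden
# matrices U* are H x H, biases are length H.  Batched activations are
# N x H matrices, so a pre-activation is X %*% t(W) + H_prev %*% t(U) + b.

glorot <- function(nrow, ncol) {
  limit <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
}

#' Trainable parameters of a GRU cell
#'
#' The cell computes a reset gate `r = sigmoid(Wr x + Ur h + br)`, an update
#' gate `z = sigmoid(Wz x + Uz h + bz)`, a candidate state
#' `hc = tanh(Wh x + Uh (r * h) + bh)`, and the new hidden state
#' `h' = (1 - z) * h + z * hc` (elementwise products).
#'
#' Matrices are initialised Glorot-uniform from the current RNG state; biases
#' start at zero.
#'
#' @param input_dim Input width F.
#' @param hidden_dim Hidden width H.
#' @return A `gru_params` list with `Wr, Ur, Wz, Uz, Wh, Uh` (H x F / H x H)
#'   and `br, bz, bh` (length H).
#' @export
gru_params <- function(input_dim, hidden_dim) {
  H <- hidden_dim; Fn <- input_dim
  p <- list(Wr = glorot(H, Fn), Ur = glorot(H, H), br = numeric(H),
            Wz = glorot(H, Fn), Uz = glorot(H, H), bz = numeric(H),
            Wh = glorot(H, Fn), Uh = glorot(H, H), bh = numeric(H))
  structure(p, class = "gru_params", input_dim = Fn, hidden_dim = H)
}

#' Trainable parameters of an LSTM cell
#'
#' Standard LSTM with input, forget and output gates and a tanh cell
#' candidate; the forget-gate bias is initialised to 1 (common practice to
#' ease gradient flow early in training), all other biases to zero.
#'
#' @inheritParams gru_params
#' @return An `lstm_params` list with `Wi, Ui, Wf, Uf, Wo, Uo, Wg, Ug` and
#'   biases `bi, bf, bo, bg`.
#' @export
lstm_params <- function(input_dim, hidden_dim) {
  H <- hidden_dim; Fn <- input_dim
  p <- list(Wi = glorot(H, Fn), Ui = glorot(H, H), bi = numeric(H),
            Wf = glorot(H, Fn), Uf = glorot(H, H), bf = rep(1, H),
            Wo = glorot(H, Fn), Uo = glorot(H, H), bo = numeric(H),
            Wg = glorot(H, Fn), Ug = glorot(H, H), bg = numeric(H))
  structure(p, class = "lstm_params", input_dim = Fn, hidden_dim = H)
}

#' One GRU step on a single input vector
#'
#' Reference (non-batched) implementation of the gated recurrent unit update;
#' the batched training path is tested against this and against scalar-loop
#' oracles.
#'
#' @param params A [gru_params()].
#' @param x Input vector (length `input_dim`).
#' @param h_prev Previous hidden state (length `hidden_dim`).
#' @return New hidden state (length `hidden_dim`).
#' @export
gru_step <- function(params, x, h_prev) {
  H <- attr(params, "hidden_dim")
  if (length(x) != attr(params, "input_dim") || length(h_prev) != H) {
    stop("dimension error: x or h_prev length does not match the cell",
         call. = FALSE)
  }
  r <- sigmoid(as.vector(params$Wr %*% x + params$Ur %*% h_prev) + params$br)
  z <- sigmoid(as.vector(params$Wz %*% x + params$Uz %*% h_prev) + params$bz)
  hc <- tanh(as.vector(params$Wh %*% x + params$Uh %*% (r * h_prev)) + params$bh)
  (1 - z) * h_prev + z * hc
}

#' One LSTM step on a single input vector
#'
#' @param params An [lstm_params()].
#' @param x Input vector.
#' @param h_prev,c_prev Previous hidden and cell states.
#' @return `list(h = , c = )`.
#' @export
lstm_step <- function(params, x, h_prev, c_prev) {
  H <- attr(params, "hidden_dim")
  if (length(x) != attr(params, "input_dim") || length(h_prev) != H ||
      length(c_prev) != H) {
    stop("dimension error: x, h_prev or c_prev length does not match the cell",
         call. = FALSE)
  }
  i <- sigmoid(as.vector(params$Wi %*% x + params$Ui %*% h_prev) + params$bi)
  f <- sigmoid(as.vector(params$Wf %*% x + params$Uf %*% h_prev) + params$bf)
  o <- sigmoid(as.vector(params$Wo %*% x + params$Uo %*% h_prev) + params$bo)
  g <- tanh(as.vector(params$Wg %*% x + params$Ug %*% h_prev) + params$bg)
  cc <- f * c_prev + i * g
  list(h = o * tanh(cc), c = cc)
}

#' Bidirectional GRU encoding of a sequence
#'
#' Runs a forward GRU left-to-right and a backward GRU right-to-left over the
#' rows of `X` and concatenates the two hidden states at each time point, so
#' row `t` of the result is `h_fwd(t) (+) h_bwd(t)` where `h_bwd(t)` has
#' consumed inputs `T, T-1, ..., t`.
#'
#' @param forward,backward [gru_params()] for the two directions (equal
#'   `hidden_dim`).
#' @param X A `T x F` input matrix.
#' @return A `T x 2H` matrix.
#' @export
bigru_encode <- function(forward, backward, X) {
  X <- as.matrix(X)
  Tn <- nrow(X)
  if (Tn < 1) stop("dimension error: X must have at least one row", call. = FALSE)
  H <- attr(forward, "hidden_dim")
  if (attr(backward, "hidden_dim") != H) {
    stop("dimension error: forward and backward hidden sizes differ",
         call. = FALSE)
  }
  hf <- matrix(0, Tn, H)
  h <- numeric(H)
  for (t in seq_len(Tn)) {
    h <- gru_step(forward, X[t, ], h)
    hf[t, ] <- h
  }
  hb <- matrix(0, Tn, H)
  h <- numeric(H)
  for (t in rev(seq_len(Tn))) {
    h <- gru_step(backward, X[t, ], h)
    hb[t, ] <- h
  }
  cbind(hf, hb)
}

zeros_like <- function(params) {
  g <- lapply(params, function(p) if (is.matrix(p)) 0 * p else numeric(length(p)))
  attributes(g) <- attributes(params)
  g
}

# --- batched passes -------------------------------------------------------
# X_steps: list of T matrices (N x F).  Return final state(s) plus per-step
# caches for backpropagation through time.

gru_forward_batch <- function(params, X_steps, h0 = NULL) {
  N <- nrow(X_steps[[1]])
  H <- attr(params, "hidden_dim")
  h <- if (is.null(h0)) matrix(0, N, H) else h0
  tWr <- t(params$Wr); tUr <- t(params$Ur)
  tWz <- t(params$Wz); tUz <- t(params$Uz)
  tWh <- t(params$Wh); tUh <- t(params$Uh)
  cache <- vector("list", length(X_steps))
  for (t in seq_along(X_steps)) {
    Xt <- X_steps[[t]]
    r <- sigmoid(Xt %*% tWr + h %*% tUr + rep(params$br, each = N))
    z <- sigmoid(Xt %*% tWz + h %*% tUz + rep(params$bz, each = N))
    rh <- r * h
    hc <- tanh(Xt %*% tWh + rh %*% tUh + rep(params$bh, each = N))
    h_new <- (1 - z) * h + z * hc
    cache[[t]] <- list(x = Xt, h_prev = h, r = r, z = z, hc = hc, rh = rh)
    h <- h_new
  }
  list(h = h, cache = cache)
}

# dh_last: gradient wrt the final hidden state only (classification uses the
# final state).  Returns parameter gradients and the gradient wrt h0.
gru_backward_batch <- function(params, cache, dh_last) {
  g <- zeros_like(params)
  dh <- dh_last
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]
    dz <- dh * (cc$hc - cc$h_prev)
    dhc <- dh * cc$z
    dh_prev <- dh * (1 - cc$z)
    da_h <- dhc * (1 - cc$hc^2)
    g$Wh <- g$Wh + crossprod(da_h, cc$x)
    g$Uh <- g$Uh + crossprod(da_h, cc$rh)
    g$bh <- g$bh + colSums(da_h)
    drh <- da_h %*% params$Uh
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r
    da_r <- dr * cc$r * (1 - cc$r)
    g$Wr <- g$Wr + crossprod(da_r, cc$x)
    g$Ur <- g$Ur + crossprod(da_r, cc$h_prev)
    g$br <- g$br + colSums(da_r)
    dh_prev <- dh_prev + da_r %*% params$Ur
    da_z <- dz * cc$z * (1 - cc$z)
    g$Wz <- g$Wz + crossprod(da_z, cc$x)
    g$Uz <- g$Uz + crossprod(da_z, cc$h_prev)
    g$bz <- g$bz + colSums(da_z)
    dh_prev <- dh_prev + da_z %*% params$Uz
    dh <- dh_prev
  }
  list(grads = g, dh0 = dh)
}

lstm_forward_batch <- function(params, X_steps, h0 = NULL, c0 = NULL) {
  N <- nrow(X_steps[[1]])
  H <- attr(params, "hidden_dim")
  h <- if (is.null(h0)) matrix(0, N, H) else h0
  cs <- if (is.null(c0)) matrix(0, N, H) else c0
  tWi <- t(params$Wi); tUi <- t(params$Ui)
  tWf <- t(params$Wf); tUf <- t(params$Uf)
  tWo <- t(params$Wo); tUo <- t(params$Uo)
  tWg <- t(params$Wg); tUg <- t(params$Ug)
  cache <- vector("list", length(X_steps))
  for (t in seq_along(X_steps)) {
    Xt <- X_steps[[t]]
    i <- sigmoid(Xt %*% tWi + h %*% tUi + rep(params$bi, each = N))
    f <- sigmoid(Xt %*% tWf + h %*% tUf + rep(params$bf, each = N))
    o <- sigmoid(Xt %*% tWo + h %*% tUo + rep(params$bo, each = N))
    gg <- tanh(Xt %*% tWg + h %*% tUg + rep(params$bg, each = N))
    c_new <- f * cs + i * gg
    tc <- tanh(c_new)
    cache[[t]] <- list(x = Xt, h_prev = h, c_prev = cs, i = i, f = f, o = o,
                       g = gg, tc = tc)
    cs <- c_new
    h <- o * tc
  }
  list(h = h, c = cs, cache = cache)
}

lstm_backward_batch <- function(params, cache, dh_last, dc_last = NULL) {
  g <- zeros_like(params)
  dh <- dh_last
  dc <- if (is.null(dc_last)) 0 * dh_last else dc_last
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]
    do <- dh * cc$tc
    dct <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dct * cc$g
    df <- dct * cc$c_prev
    dg <- dct * cc$i
    dc <- dct * cc$f
    da_i <- di * cc$i * (1 - cc$i)
    da_f <- df * cc$f * (1 - cc$f)
    da_o <- do * cc$o * (1 - cc$o)
    da_g <- dg * (1 - cc$g^2)
    g$Wi <- g$Wi + crossprod(da_i, cc$x); g$Ui <- g$Ui + crossprod(da_i, cc$h_prev)
    g$bi <- g$bi + colSums(da_i)
    g$Wf <- g$Wf + crossprod(da_f, cc$x); g$Uf <- g$Uf + crossprod(da_f, cc$h_prev)
    g$bf <- g$bf + colSums(da_f)
    g$Wo <- g$Wo + crossprod(da_o, cc$x); g$Uo <- g$Uo + crossprod(da_o, cc$h_prev)
    g$bo <- g$bo + colSums(da_o)
    g$Wg <- g$Wg + crossprod(da_g, cc$x); g$Ug <- g$Ug + crossprod(da_g, cc$h_prev)
    g$bg <- g$bg + colSums(da_g)
    dh <- da_i %*% params$Ui + da_f %*% params$Uf + da_o %*% params$Uo +
      da_g %*% params$Ug
  }
  list(grads = g, dh0 = dh, dc0 = dc)
}

# Generic dispatch helpers so the model code is cell-agnostic.
cell_params <- function(cell_base, input_dim, hidden_dim) {
  switch(cell_base,
         GRU = gru_params(input_dim, hidden_dim),
         LSTM = lstm_params(input_dim, hidden_dim),
         stop("config error: unknown cell ", cell_base, call. = FALSE))
}

cell_forward <- function(params, X_steps, h0 = NULL) {
  if (inherits(params, "gru_params")) {
    gru_forward_batch(params, X_steps, h0)
  } else {
    lstm_forward_batch(params, X_steps, h0)
  }
}

cell_backward <- function(params, cache, dh_last) {
  if (inherits(params, "gru_params")) {
    gru_backward_batch(params, cache, dh_last)
  } else {
    lstm_backward_batch(params, cache, dh_last)
  }
}
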