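random_gru <- function(Fn, H) {
  p <- gru_params(Fn, H)
  for (nm in names(p)) p[[nm]] <- p[[nm]] + 0 # params already random via RNG
  p
}

test_that("a zero-parameter GRU step halves the previous hidden state", {
  p <- gru_params(2, 3)
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  h <- c(0.4, -1, 2)
  expect_equal(gru_step(p, c(1, 1), h), 0.5 * h)
  expect_equal(gru_step(p, c(5, -3), numeric(3)), numeric(3))
  expect_error(gru_step(p, c(1, 2, 3), h), "dimension error")
})

test_that("gru_step matches the scalar-loop evaluation on random instances", {
  set.seed(101)
  for (i in 1:100) {
    H <- sample(1:4, 1); Fn <- sample(1:3, 1)
    p <- gru_params(Fn, H)
    x <- rnorm(Fn); h <- rnorm(H)
    expect_equal(gru_step(p, x, h), scalar_gru_step(p, x, h),
                 tolerance = 1e-10)
  }
})

test_that("lstm_step matches a scalar-loop evaluation of the standard cell", {
  set.seed(102)
  for (i in 1:20) {
    H <- sample(1:4, 1); Fn <- sample(1:3, 1)
    p <- lstm_params(Fn, H)
    x <- rnorm(Fn); h <- rnorm(H); cc <- rnorm(H)
    ii <- ff <- oo <- gg <- numeric(H)
    for (k in seq_len(H)) {
      ii[k] <- 1 / (1 + exp(-(sum(p$Wi[k, ] * x) + sum(p$Ui[k, ] * h) + p$bi[k])))
      ff[k] <- 1 / (1 + exp(-(sum(p$Wf[k, ] * x) + sum(p$Uf[k, ] * h) + p$bf[k])))
      oo[k] <- 1 / (1 + exp(-(sum(p$Wo[k, ] * x) + sum(p$Uo[k, ] * h) + p$bo[k])))
      gg[k] <- tanh(sum(p$Wg[k, ] * x) + sum(p$Ug[k, ] * h) + p$bg[k])
    }
    cn <- ff * cc + ii * gg
    out <- lstm_step(p, x, h, cc)
    expect_equal(out$c, cn, tolerance = 1e-10)
    expect_equal(out$h, oo * tanh(cn), tolerance = 1e-10)
  }
})

test_that("bidirectional GRU encoding concatenates forward and reverse passes", {
  set.seed(103)
  fwd <- gru_params(2, 3); bwd <- gru_params(2, 3)

  # single step: both halves equal one gru_step from the zero state
  x1 <- matrix(rnorm(2), 1, 2)
  enc1 <- bigru_encode(fwd, bwd, x1)
  expect_equal(enc1[1, 1:3], gru_step(fwd, x1[1, ], numeric(3)))
  expect_equal(enc1[1, 4:6], gru_step(bwd, x1[1, ], numeric(3)))

  # identical parameters on a palindromic sequence: mirrored halves
  X <- rbind(c(1, -1), c(0.5, 2), c(1, -1))
  encp <- bigru_encode(fwd, fwd, X)
  Tn <- nrow(X)
  for (t in seq_len(Tn)) {
    expect_equal(encp[t, 4:6], encp[Tn + 1 - t, 1:3], tolerance = 1e-12)
  }

  # random input: backward half equals reverse-run-reverse oracle
  X <- matrix(rnorm(8), 4, 2)
  enc <- bigru_encode(fwd, bwd, X)
  expect_equal(enc[, 1:3], scalar_gru_sequence(fwd, X), tolerance = 1e-10)
  rev_states <- scalar_gru_sequence(bwd, X[4:1, , drop = FALSE])
  expect_equal(enc[, 4:6], rev_states[4:1, , drop = FALSE], tolerance = 1e-10)
})

test_that("the classification head composes with the encoder as documented", {
  cfg <- model_config(cell = "GRU", hidden_dim = 3, mlp_hidden = 4,
                      dropout = 0, seed = 7)
  model <- init_model(cfg, input_dim = 2, demo_dim = 2)

  # zero head weights: probability 0.5 for any input
  m0 <- model
  m0$head$W1 <- m0$head$W1 * 0; m0$head$W2 <- m0$head$W2 * 0
  m0$head$b1 <- 0 * m0$head$b1; m0$head$b2 <- 0 * m0$head$b2
  X <- matrix(rnorm(6), 3, 2)
  expect_equal(model_forward(m0, X, c(1, 0)), 0.5)

  # composed oracle: scalar GRU chain + scalar head
  D <- c(0.3, -1)
  states <- scalar_gru_sequence(model$encoder$fwd, X)
  expect_equal(model_forward(model, X, D),
               scalar_head(model$head, states[3, ], D), tolerance = 1e-8)

  # demographic-free model reduces to the head on the latent alone
  m_nd <- init_model(cfg, input_dim = 2, demo_dim = 0)
  expect_equal(model_forward(m_nd, X),
               scalar_head(m_nd$head, scalar_gru_sequence(m_nd$encoder$fwd, X)[3, ],
                           numeric(0)),
               tolerance = 1e-8)
  expect_error(model_forward(model, X, c(1, 0, 0)), "dimension error")
})

test_that("the decoder rolls the latent forward the documented number of steps", {
  cfg <- model_config(cell = "GRU", hidden_dim = 3, horizon = 3, dropout = 0,
                      seed = 8)
  model <- init_model(cfg, input_dim = 2, demo_dim = 0,
                      architecture = "seq2seq")
  X <- matrix(rnorm(4), 2, 2)
  out <- model_forward(model, X, return_latents = TRUE)
  expect_length(out$latents, 3L)

  # latents match chained single-step evaluations with zero inputs
  enc_final <- scalar_gru_sequence(model$encoder$fwd, X)[2, ]
  h <- enc_final
  for (s in 1:3) {
    h <- scalar_gru_step(model$decoder, 0, h)
    expect_equal(as.vector(out$latents[[s]]), h, tolerance = 1e-8)
  }

  # zero decoder parameters: one step halves the encoder state
  m0 <- model
  m0$config$horizon <- 1L
  for (nm in names(m0$decoder)) m0$decoder[[nm]] <- m0$decoder[[nm]] * 0
  out0 <- model_forward(m0, X, return_latents = TRUE)
  expect_equal(as.vector(out0$latents[[1]]), 0.5 * enc_final, tolerance = 1e-10)

  # zero head: probability 0.5 regardless of horizon
  mh <- model
  mh$head$W1 <- mh$head$W1 * 0; mh$head$W2 <- mh$head$W2 * 0
  mh$head$b1 <- 0 * mh$head$b1; mh$head$b2 <- 0 * mh$head$b2
  expect_equal(model_forward(mh, X), 0.5)
  expect_error(init_model(model_config(horizon = 0), 2, 0, "seq2seq"),
               "parameter error")
})

test_that("the weighted cross-entropy obeys its defining identities", {
  expect_lt(weighted_bce(1, 1 - 1e-9, alpha = 0.7), 1e-6)
  set.seed(104)
  y <- rbinom(40, 1, 0.4)
  p <- runif(40, 0.05, 0.95)
  plain <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(weighted_bce(y, p, alpha = 0.5), 0.5 * plain, tolerance = 1e-12)
  expect_equal(weighted_bce(1, 0.5, alpha = 0.7), 0.7 * log(2),
               tolerance = 1e-10)
  expect_error(weighted_bce(1, 0.5, alpha = 1.2), "parameter error")
  expect_error(weighted_bce(1, 0.5, alpha = 0), "parameter error")

  # monotone in alpha: increasing for positives, decreasing for negatives
  alphas <- seq(0.1, 0.9, by = 0.1)
  pos <- vapply(alphas, function(a) weighted_bce(1, 0.7, a), numeric(1))
  neg <- vapply(alphas, function(a) weighted_bce(0, 0.7, a), numeric(1))
  expect_true(all(diff(pos) > 0))
  expect_true(all(diff(neg) < 0))
})

test_that("initialisation is reproducible and has the documented shapes", {
  cfg <- model_config(cell = "GRU", hidden_dim = 32, seed = 99)
  a <- init_model(cfg, input_dim = 20, demo_dim = 0)
  b <- init_model(cfg, input_dim = 20, demo_dim = 0)
  expect_identical(a, b)

  # recurrent parameter count: 3 (F H + H^2 + H) = 5088 for F=20, H=32
  count <- sum(vapply(a$encoder$fwd, length, numeric(1)))
  expect_equal(count, 3 * (20 * 32 + 32^2 + 32))
  expect_equal(count, 5088)

  bi <- init_model(model_config(cell = "BiGRU", hidden_dim = 8, seed = 1),
                   input_dim = 5, demo_dim = 4)
  expect_equal(ncol(bi$head$W2), 2 * 8 + 4)

  ls <- init_model(model_config(cell = "LSTM", hidden_dim = 8, seed = 1),
                   input_dim = 5, demo_dim = 0)
  expect_equal(sum(vapply(ls$encoder$fwd, length, numeric(1))),
               4 * (5 * 8 + 8^2 + 8))

  # probabilities strictly inside (0, 1) for finite parameters
  X <- matrix(rnorm(10 * 3 * 5), 10 * 3 * 5)
  dim(X) <- c(10, 3, 5)
  p <- model_forward(ls, X)
  expect_true(all(p > 0 & p < 1))
})

test_that("analytic gradients match central differences for every architecture", {
  ts <- mciconvert:::training_step
  mp <- mciconvert:::model_params
  smp <- mciconvert:::set_model_params
  asl <- mciconvert:::as_step_list
  set.seed(105)
  N <- 4; T <- 3; Fn <- 2; dD <- 2
  X <- array(rnorm(N * T * Fn), c(N, T, Fn))
  D <- matrix(rnorm(N * dD), N, dD)
  y <- c(1, 0, 1, 0)
  eps <- 1e-6
  for (cell in c("GRU", "LSTM", "BiGRU", "BiLSTM")) {
    for (arch in c("direct", "seq2seq")) {
      cfg <- model_config(cell = cell, hidden_dim = 3, mlp_hidden = 3,
                          dropout = 0, l2 = 0.01, horizon = 2, seed = 6)
      model <- init_model(cfg, Fn, dD, architecture = arch)
      st <- ts(model, asl(X), D, y)
      tree <- mp(model)
      worst <- 0
      for (comp in names(tree)) {
        leaves <- if (comp == "encoder") names(tree[[comp]]) else NA
        check_leaf <- function(path) {
          obj <- tree[[path]]
          idx <- seq_along(obj)
          if (length(idx) > 6) idx <- sample(idx, 6) # spot-check large leaves
          for (i in idx) {
            t2 <- tree
            ref <- t2[[path]]; ref[i] <- ref[i] + eps; t2[[path]] <- ref
            lp <- ts(smp(model, t2), asl(X), D, y)$loss
            ref[i] <- ref[i] - 2 * eps; t2[[path]] <- ref
            lm <- ts(smp(model, t2), asl(X), D, y)$loss
            num <- (lp - lm) / (2 * eps)
            worst <<- max(worst, abs(num - st$grads[[path]][i]))
          }
        }
        if (comp == "encoder") {
          for (dir in names(tree$encoder)) {
            for (nm in names(tree$encoder[[dir]])) check_leaf(c(comp, dir, nm))
          }
        } else {
          for (nm in names(tree[[comp]])) check_leaf(c(comp, nm))
        }
      }
      expect_lt(worst, 1e-6)
    }
  }
})

test_that("the compiled training loop reproduces the reference path exactly", {
  co <- simulate_cohort(simulation_config(n_patients = 40, missing_rate = 0,
                                          seed = 44))
  s <- build_sequences(co, 3, 1, demo_encoder = fit_demographic_encoder(co))
  s2 <- s; s2$n <- 2L
  for (cell in c("GRU", "LSTM", "BiGRU", "BiLSTM")) {
    for (samples in list(s, s2)) {
      cfg <- model_config(cell = cell, hidden_dim = 5, epochs = 3,
                          batch_size = 8, dropout = 0.2, seed = 12)
      a <- suppressWarnings(train_model(samples, cfg, use_cpp = TRUE))
      b <- suppressWarnings(train_model(samples, cfg, use_cpp = FALSE))
      pa <- unlist(mciconvert:::model_params(a))
      pb <- unlist(mciconvert:::model_params(b))
      expect_lt(max(abs(pa - pb)), 1e-12)
      expect_equal(a$loss_trace, b$loss_trace, tolerance = 1e-12)
    }
  }
})

test_that("one optimisation step moves encoder, decoder and head parameters", {
  co <- simulate_cohort(simulation_config(n_patients = 30, missing_rate = 0,
                                          seed = 46))
  s <- build_sequences(co, 2, 2)
  cfg <- model_config(cell = "GRU", hidden_dim = 4, epochs = 1,
                      batch_size = 64, dropout = 0, seed = 3)
  init <- init_model(cfg, dim(s$X)[3], 0, architecture = "seq2seq")
  fit <- train_model(s, cfg, architecture = "seq2seq")
  moved <- function(a, b) max(abs(unlist(a) - unlist(b))) > 0
  expect_true(moved(fit$encoder$fwd, init$encoder$fwd))
  expect_true(moved(fit$decoder, init$decoder))
  expect_true(moved(fit$head, init$head))
})
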