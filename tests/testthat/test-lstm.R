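test_that("activations match their closed forms", {
  expect_equal(activation("sigmoid", 0), 0.5)
  expect_equal(activation("tanh", 0), 0)
  expect_equal(activation("softsign", 0), 0)
  expect_equal(activation("softsign", 1), 0.5)
  expect_equal(activation("softsign", -1), -0.5)
  x <- seq(-5, 5, by = 0.25)
  expect_equal(activation("softsign", -x), -activation("softsign", x))
  expect_true(all(abs(activation("softsign", x)) < 1))
  expect_true(all(activation("sigmoid", x) > 0 &
                    activation("sigmoid", x) < 1))
  expect_error(activation("relu", 1), "unknown")
})

test_that("cell_forward reproduces the hand-evaluated zero-weight case", {
  for (v in c("standard", "softsign")) {
    p <- lstm_params(1, 1, variant = v, seed = 1)
    for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
    st <- cell_forward(p, x_t = 0, h_prev = 0, c_prev = 2)
    expect_equal(drop(st$cache$f), 0.5)
    expect_equal(drop(st$cache$i), 0.5)
    expect_equal(drop(st$cache$o), 0.5)
    expect_equal(drop(st$cache$g), 0)
    expect_equal(drop(st$c), 1)
    expect_equal(drop(st$h), 0.5 * tanh(1))
    # zero cell state stays at zero output
    st0 <- cell_forward(p, 0, 0, 0)
    expect_equal(drop(st0$h), 0)
  }
})

test_that("gates and candidate stay inside their ranges", {
  set.seed(55)
  for (v in c("standard", "softsign")) {
    p <- lstm_params(2, 4, variant = v, seed = 71)
    x <- matrix(rnorm(10, sd = 3), 2, 5)
    st <- cell_forward(p, x, matrix(rnorm(20), 4, 5),
                       matrix(rnorm(20), 4, 5))
    for (gate in c("f", "i", "o")) {
      expect_true(all(st$cache[[gate]] > 0 & st$cache[[gate]] < 1))
    }
    expect_true(all(abs(st$cache$g) < 1))
  }
})

test_that("forward unroll matches an independent transcription", {
  for (v in c("standard", "softsign")) {
    p <- lstm_params(1, 3, variant = v, seed = 17)
    set.seed(17)
    x <- matrix(rnorm(6), ncol = 1)
    out <- lstm_forward(p, x)
    expect_equal(out$prob, oracle_lstm_prob(p, x), tolerance = 1e-12)
    expect_gt(out$prob, 0)
    expect_lt(out$prob, 1)
    expect_true(all(abs(out$h_final) < 1))
  }
  # zero parameters produce an uninformative 0.5
  p0 <- lstm_params(1, 3, seed = 1)
  for (nm in names(p0)) p0[[nm]] <- p0[[nm]] * 0
  expect_equal(lstm_forward(p0, matrix(c(1, -2), ncol = 1))$prob, 0.5)
  expect_error(lstm_forward(p0, matrix(numeric(0), ncol = 1)), "empty")
})

test_that("a one-step sequence equals cell_forward plus the head", {
  p <- lstm_params(2, 3, seed = 23)
  x1 <- c(0.4, -1.1)
  st <- cell_forward(p, x1, rep(0, 3), rep(0, 3))
  manual <- 1 / (1 + exp(-(sum(p$why * st$h) + p$bhy)))
  expect_equal(lstm_forward(p, matrix(x1, nrow = 1))$prob, manual,
               tolerance = 1e-12)
})

test_that("the two variants coincide at zero candidate pre-activation", {
  p_std <- lstm_params(1, 3, variant = "standard", seed = 5)
  p_std$Wc <- p_std$Wc * 0
  p_std$bc <- p_std$bc * 0
  p_soft <- p_std
  attr(p_soft, "variant") <- "softsign"
  x <- matrix(c(0.3, -0.8, 1.2), ncol = 1)
  expect_identical(lstm_forward(p_std, x)$prob,
                   lstm_forward(p_soft, x)$prob)
})

test_that("binary cross-entropy behaves at its anchor points", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.5, 0), log(2))
  expect_equal(bce_loss(0.9, 1), -log(0.9))  # 0.10536
  expect_lt(bce_loss(1 - 1e-9, 1), 1e-6)
  expect_error(bce_loss(0.5, 2), "binary")
  # extreme probabilities are clipped, not infinite
  expect_true(is.finite(bce_loss(0, 1)))
})

test_that("BPTT gradients match central finite differences", {
  for (v in c("standard", "softsign")) {
    for (s in 1:3) {
      p <- lstm_params(1, 3, variant = v, seed = 100 + s)
      set.seed(200 + s)
      x <- matrix(rnorm(4), ncol = 1)
      res <- gradient_check(p, x, y = s %% 2)
      expect_lt(max(res$rel_error), 1e-5)
    }
  }
})

test_that("batched gradients match finite differences too", {
  p <- lstm_params(2, 3, variant = "softsign", seed = 7)
  set.seed(7)
  xs <- lapply(1:4, function(t) matrix(rnorm(10), 2, 5))
  res <- gradient_check(p, xs, y = c(1, 0, 1, 1, 0))
  expect_lt(max(res$rel_error), 1e-5)
})

test_that("a balanced +/- pair at zero parameters is a head stationary point", {
  p <- lstm_params(1, 3, seed = 1)
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  x <- matrix(c(0.5, -0.5), ncol = 1)
  xs <- list(matrix(c(x[1], x[1]), 1), matrix(c(x[2], x[2]), 1))
  fwd <- cardiopredict:::.lstm_forward_batch(p, xs)
  g <- lstm_backward(p, fwd, y = c(1, 0))
  expect_equal(g$bhy, 0)
  expect_equal(g$why, rep(0, 3))
})

test_that("gradients are linear in the loss scale", {
  # doubling every record (two copies of the same example) leaves the
  # mean-loss gradient unchanged; a single copy with batch size 1 equals
  # the two-copy batch gradient
  p <- lstm_params(1, 2, seed = 9)
  x1 <- list(matrix(0.7, 1, 1), matrix(-0.2, 1, 1))
  x2 <- lapply(x1, function(m) cbind(m, m))
  g1 <- lstm_backward(p, cardiopredict:::.lstm_forward_batch(p, x1), 1)
  g2 <- lstm_backward(p, cardiopredict:::.lstm_forward_batch(p, x2),
                      c(1, 1))
  for (nm in names(g1)) expect_equal(g2[[nm]], g1[[nm]], tolerance = 1e-12)
})

test_that("record encoding is a bijection in both modes", {
  rec <- tibble::tibble(MAP = 93.3, age = 0.4, BMI = 24.2, PP = 40)
  feats <- c("MAP", "BMI", "PP")
  seq1 <- encode_record(rec, feats)
  expect_equal(dim(seq1), c(3, 1))
  expect_equal(drop(seq1), c(93.3, 24.2, 40))
  seq2 <- encode_record(rec, feats, mode = "single_step")
  expect_equal(dim(seq2), c(1, 3))
  expect_equal(drop(seq2), drop(seq1))
  expect_error(encode_record(rec, c("MAP", "missing")), "missing")
})

test_that("model checkpoints round-trip predictions exactly", {
  set.seed(3)
  x <- matrix(runif(60), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(20, 1, 0.5)
  m <- train_lstm(x, y, hidden_dim = 4, epochs = 2, batch_size = 10,
                  seed = 12, optimizer = "adam")
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  nd <- as.data.frame(x)
  expect_identical(predict(m, nd), predict(m2, nd))
  expect_equal(m2$features, m$features)
  expect_equal(m2$variant, m$variant)
})

test_that("training trajectories are seed-deterministic", {
  set.seed(3)
  x <- matrix(runif(90), 30, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(30, 1, 0.5)
  m1 <- train_lstm(x, y, hidden_dim = 3, epochs = 3, batch_size = 8,
                   seed = 21)
  m2 <- train_lstm(x, y, hidden_dim = 3, epochs = 3, batch_size = 8,
                   seed = 21)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})
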