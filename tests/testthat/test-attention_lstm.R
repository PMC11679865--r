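test_that("the LSTM step with all-zero parameters reduces to its closed form", {
  H <- 3
  z <- matrix(0, H, 2); zh <- matrix(0, H, H)
  cell <- lstm_cell_params(z, z, z, z, zh, zh, zh, zh,
                           rep(0, H), rep(0, H), rep(0, H), rep(0, H))
  v <- c(-1.5, 0.2, 4)
  st <- lstm_step(cell, c(1, -1), rep(0, H), v)
  expect_equal(st$f, rep(0.5, H), tolerance = 1e-12)
  expect_equal(st$i, rep(0.5, H), tolerance = 1e-12)
  expect_equal(st$o, rep(0.5, H), tolerance = 1e-12)
  expect_equal(st$candidate, rep(0, H), tolerance = 1e-12)
  expect_equal(st$c, 0.5 * v, tolerance = 1e-12)
  expect_equal(st$h, 0.5 * tanh(0.5 * v), tolerance = 1e-12)
})

test_that("a scalar LSTM step matches the direct gate-by-gate evaluation", {
  # independent oracle: plain arithmetic transcription of the cell update
  sg <- function(x) 1 / (1 + exp(-x))
  x <- 0.8; h0 <- -0.4; c0 <- 0.3
  f <- sg(0.5 * x + 0.1 * h0 + 0.05)
  i <- sg(-0.3 * x + 0.4 * h0 - 0.1)
  o <- sg(0.2 * x - 0.6 * h0 + 0.15)
  cand <- tanh(0.7 * x + 0.25 * h0 + 0.0)
  c1 <- f * c0 + i * cand
  h1 <- o * tanh(c1)

  cell <- lstm_cell_params(W_if = 0.5, W_ii = -0.3, W_io = 0.2, W_ic = 0.7,
                           W_hf = 0.1, W_hi = 0.4, W_ho = -0.6, W_hc = 0.25,
                           b_f = 0.05, b_i = -0.1, b_o = 0.15, b_c = 0)
  st <- lstm_step(cell, x, h0, c0)
  expect_equal(st$h, h1, tolerance = 1e-10)
  expect_equal(st$c, c1, tolerance = 1e-10)
})

test_that("gates stay in (0,1) and the cell state grows by at most 1 per step", {
  set.seed(5)
  for (rep in 1:10) {
    rc <- random_cell(3, 4)
    x <- rnorm(3); h <- rnorm(4); cp <- rnorm(4, sd = 3)
    st <- lstm_step(rc$cell, x, h, cp)
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(abs(st$c) <= abs(cp) + 1))
  }
})

test_that("the compiled LSTM layer reproduces the single-step reference cell", {
  set.seed(8)
  for (rep in 1:5) {
    rc <- random_cell(input = 2, hidden = 3)
    Tn <- 6; B <- 4
    X <- array(rnorm(B * 2 * Tn), c(B, 2, Tn))  # B x input x T cube layout
    Hcube <- psolstm:::cpp_lstm_sequence(rc$W, rc$U, rc$b, X)
    for (b in seq_len(B)) {
      Xb <- t(X[b, , ])  # timesteps x input
      Href <- r_lstm_sequence(rc$cell, Xb)
      expect_equal(Hcube[b, , ], t(Href), tolerance = 1e-10)
    }
  }
})

test_that("attention scores follow the concatenation score exactly", {
  # W_a = 0 -> all scores 0
  H <- matrix(rnorm(10), 5, 2)
  expect_equal(attention_scores(H, matrix(0, 3, 4), rnorm(3)), rep(0, 5))

  # scores are bounded by the L1 norm of v_a
  set.seed(14)
  W_a <- matrix(rnorm(12), 3, 4); v_a <- rnorm(3)
  expect_true(all(abs(attention_scores(H, W_a, v_a)) <= sum(abs(v_a))))

  # 2-step, 1-unit toy against direct substitution
  H2 <- matrix(c(0.3, -0.7), 2, 1)
  W2 <- matrix(c(0.5, -0.2), 1, 2)
  v2 <- 0.9
  hn <- -0.7
  expected <- c(0.9 * tanh(0.5 * 0.3 - 0.2 * hn),
                0.9 * tanh(0.5 * -0.7 - 0.2 * hn))
  expect_equal(attention_scores(H2, W2, v2), expected, tolerance = 1e-10)
})

test_that("attention weights are a softmax over time", {
  expect_equal(attention_weights(rep(2.2, 7)), rep(1 / 7, 7), tolerance = 1e-12)
  w <- attention_weights(c(0, 50))
  expect_lt(w[1], 1e-12)
  expect_gt(w[2], 1 - 1e-12)
  set.seed(2)
  for (rep in 1:10) {
    s <- rnorm(11, sd = 5)
    w <- attention_weights(s)
    expect_true(all(w > 0))
    expect_lt(abs(sum(w) - 1), 1e-12)
    # permutation equivariance
    p <- sample(11)
    expect_equal(attention_weights(s[p]), w[p], tolerance = 1e-12)
  }
})

test_that("the context vector is the weighted time-sum of hidden states", {
  set.seed(4)
  H <- matrix(rnorm(12), 4, 3)
  onehot <- c(0, 0, 1, 0)
  expect_equal(context_vector(H, onehot), H[3, ])
  expect_equal(context_vector(H, rep(0.25, 4)), colMeans(H))
  # brute-force loop oracle
  a <- attention_weights(rnorm(4))
  ref <- numeric(3)
  for (t in 1:4) ref <- ref + a[t] * H[t, ]
  expect_equal(context_vector(H, a), ref, tolerance = 1e-12)
})

test_that("the classifier emits probability rows and is deterministic in eval mode", {
  set.seed(31)
  spec <- model_spec(6, 5, 4, 0.3, num_classes = 4, timesteps = 12,
                     channels = 3)
  m <- build_model(spec)
  x <- array(rnorm(7 * 12 * 3), c(7, 12, 3))
  p1 <- predict_proba(m, x)
  expect_identical(dim(p1), c(7L, 4L))
  expect_true(all(abs(rowSums(p1) - 1) < 1e-6))
  expect_true(all(p1 > 0))
  expect_identical(p1, predict_proba(m, x))  # frozen statistics, no dropout
})

test_that("softmax probabilities are invariant to a constant logit shift", {
  set.seed(6)
  z <- rnorm(5)
  expect_equal(softmax(z), softmax(z + 123.4), tolerance = 1e-12)
  zm <- matrix(rnorm(12), 3, 4)
  expect_equal(softmax(zm), softmax(zm + 7), tolerance = 1e-12)
})

test_that("the fixed baseline spec and the attention-off ablation both build", {
  hp <- fixed_baseline_hyperparams()
  expect_identical(hp$units1, 128L)
  spec <- model_spec(hp$units1, hp$units2, hp$dense_units, hp$dropout,
                     num_classes = 4, timesteps = 8, channels = 2)
  set.seed(40)
  m <- build_model(spec)
  expect_identical(dim(m$params$W1), c(2L, 4L * 128L))
  expect_identical(dim(m$params$Wa), c(64L, 128L))  # attn_dim = units2

  off <- model_spec(4, 3, 2, 0.2, 3, 8, 2, attention = FALSE)
  moff <- build_model(off)
  expect_null(moff$params$Wa)
  p <- predict_proba(moff, array(rnorm(5 * 8 * 2), c(5, 8, 2)))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
})

test_that("analytic gradients of the full network match finite differences", {
  set.seed(77)
  for (attn in c(TRUE, FALSE)) {
    spec <- model_spec(3, 4, 5, 0.2, num_classes = 3, timesteps = 7,
                       channels = 2, attention = attn)
    m <- build_model(spec)
    X <- array(rnorm(6 * 2 * 7), c(6, 2, 7))
    y <- sample(0:2, 6, TRUE)
    lg <- psolstm:::cpp_loss_grads(m$params, X, y, attn, TRUE, TRUE)
    nms <- c("W1", "U1", "b1", "g1", "be1", "W2", "U2", "b2", "g2", "be2",
             if (attn) c("Wa", "va"), "Wd", "bd", "Wo", "bo")
    for (nm in nms) {
      p <- m$params
      for (k in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
        eps <- 1e-6
        p2 <- p
        p2[[nm]][k] <- p2[[nm]][k] + eps
        up <- psolstm:::cpp_loss_grads(p2, X, y, attn, TRUE, FALSE)$loss
        p2[[nm]][k] <- p2[[nm]][k] - 2 * eps
        dn <- psolstm:::cpp_loss_grads(p2, X, y, attn, TRUE, FALSE)$loss
        expect_lt(abs(lg$grads[[nm]][k] - (up - dn) / (2 * eps)), 1e-6)
      }
    }
  }
})

test_that("model specs outside the search bounds are rejected", {
  expect_error(model_spec(0, 5, 5, 0.2, 4, 10, 2))
  expect_error(model_spec(5, 201, 5, 0.2, 4, 10, 2))
  expect_error(model_spec(5, 5, 5, 0.05, 4, 10, 2))
  expect_error(predict_proba(build_model(model_spec(2, 2, 2, 0.2, 4, 10, 2)),
                             array(0, c(1, 9, 2))), "expected shape")
})
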