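test_that("minimal RNN step has its closed forms at parameter extremes", {
  d <- 4
  layer <- list(Wu = matrix(0, d, 25), bu = rep(0, d),
                Uh = matrix(0, d, d), Uu = matrix(0, d, d), bf = rep(0, d))
  h <- c(1, -2, 0.5, 3)
  x <- rnorm(25)
  # all-zero parameters: u = 0, f = 1/2, h_new = h/2
  expect_equal(minimal_rnn_step(h, x, layer), 0.5 * h)

  # saturated gate bias: perfect memory
  layer$bf <- rep(50, d)
  expect_equal(minimal_rnn_step(h, x, layer), h, tolerance = 1e-10)

  expect_error(minimal_rnn_step(h, x[1:10], layer), "shape")
})

test_that("minimal RNN step matches a scalar-by-scalar oracle", {
  set.seed(42)
  d <- 2
  layer <- list(Wu = matrix(rnorm(d * 3), d, 3), bu = rnorm(d),
                Uh = matrix(rnorm(d * d), d, d),
                Uu = matrix(rnorm(d * d), d, d), bf = rnorm(d))
  h <- rnorm(d)
  x <- rnorm(3)
  # independent elementwise evaluation
  u <- numeric(d); f <- numeric(d); hn <- numeric(d)
  for (i in 1:d) {
    acc <- layer$bu[i]
    for (j in 1:3) acc <- acc + layer$Wu[i, j] * x[j]
    u[i] <- tanh(acc)
  }
  for (i in 1:d) {
    acc <- layer$bf[i]
    for (j in 1:d) acc <- acc + layer$Uh[i, j] * h[j] + layer$Uu[i, j] * u[j]
    f[i] <- 1 / (1 + exp(-acc))
  }
  for (i in 1:d) hn[i] <- f[i] * h[i] + (1 - f[i]) * u[i]
  expect_equal(minimal_rnn_step(h, x, layer), hn, tolerance = 1e-12)
})

test_that("gate keeps the state a coordinatewise convex combination", {
  set.seed(1)
  for (trial in 1:20) {
    d <- sample(2:6, 1)
    layer <- list(Wu = matrix(rnorm(d * 25), d, 25), bu = rnorm(d),
                  Uh = matrix(rnorm(d * d), d, d),
                  Uu = matrix(rnorm(d * d), d, d), bf = rnorm(d))
    h <- rnorm(d, sd = 0.5)
    for (t in 1:10) h <- minimal_rnn_step(h, rnorm(25), layer)
    expect_lte(max(abs(h)), 1 + 1e-12)   # tanh bounds u; gate is convex
  }
})

test_that("linear state-space step is exactly linear", {
  d <- 3
  x <- rnorm(25)
  h <- c(1, 2, 3)
  id <- list(A = diag(d), B = matrix(0, d, 25), b = rep(0, d))
  expect_equal(lss_step(h, x, id), h)

  memoryless <- list(A = matrix(0, d, d),
                     B = matrix(rnorm(d * 25), d, 25), b = rnorm(d))
  expect_equal(lss_step(h, x, memoryless),
               lss_step(rnorm(d), x, memoryless))

  # stable dynamics decay to zero at the closed-form rate
  set.seed(2)
  A <- matrix(rnorm(9, sd = 0.2), 3, 3)
  A <- A / max(Mod(eigen(A)$values)) * 0.7
  layer <- list(A = A, B = matrix(0, 3, 25), b = rep(0, 3))
  h <- c(1, -1, 2)
  hk <- h
  for (k in 1:30) hk <- lss_step(hk, rep(0, 25), layer)
  closed <- h
  for (k in 1:30) closed <- drop(A %*% closed)
  expect_equal(hk, closed, tolerance = 1e-10)
  expect_lt(sqrt(sum(hk^2)), 0.7^30 * 10)
})

test_that("a gate-frozen linearized cell is a linear state-space map", {
  # freeze the gate (no state/input dependence) and shrink inputs so tanh
  # is in its linear regime: the gated cell must match h = A h + B x + b
  set.seed(21)
  d <- 4
  for (trial in 1:5) {
    b0 <- rnorm(1)
    cc <- plogis(b0)
    Wu <- matrix(rnorm(d * 25), d, 25) * 1e-5
    bu <- rnorm(d) * 1e-5
    rnn <- list(Wu = Wu, bu = bu, Uh = matrix(0, d, d),
                Uu = matrix(0, d, d), bf = rep(b0, d))
    lss <- list(A = diag(cc, d), B = (1 - cc) * Wu, b = (1 - cc) * bu)
    h1 <- h2 <- rnorm(d) * 1e-5
    for (t in 1:6) {
      x <- rnorm(25)
      h1 <- minimal_rnn_step(h1, x, rnn)
      h2 <- lss_step(h2, x, lss)
    }
    # agreement up to the cubic tanh remainder, far below the state scale
    expect_equal(h1, h2, tolerance = 1e-6)
  }
})

test_that("output heads give a valid simplex and affine continuous map", {
  p <- init_model("minimalrnn", hidden = 5, seed = 3)
  p$heads$Ws[] <- 0
  p$heads$Wg[] <- 0
  p$heads$bg <- rnorm(22)
  out <- predict_next(rnorm(5), p)
  expect_equal(out$probs, rep(1 / 3, 3))
  expect_equal(out$cont, p$heads$bg)

  set.seed(4)
  for (trial in 1:50) {
    p2 <- init_model("minimalrnn", hidden = 4, seed = trial)
    out2 <- predict_next(rnorm(4, sd = 5), p2)
    expect_equal(sum(out2$probs), 1, tolerance = 1e-12)
    expect_true(all(out2$probs > 0))
  }

  # hand-computed toy head
  p$heads$Ws <- matrix(0, 3, 5)
  p$heads$Ws[1, 1] <- 1
  p$heads$Ws[2, 2] <- -1
  h <- c(2, 1, 0, 0, 0)
  z <- c(2, -1, 0)
  expect_equal(predict_next(h, p)$probs, exp(z) / sum(exp(z)),
               tolerance = 1e-12)
})

test_that("masked sequence loss has its closed forms", {
  # perfect prediction: zero loss
  target <- matrix(0, 2, 25)
  target[, 1] <- 1                        # NC at both timepoints
  target[, 4:25] <- rnorm(44)
  pred <- target
  observed <- matrix(TRUE, 2, 23)
  expect_equal(sequence_loss(pred, target, observed), 0)

  # uniform diagnosis prediction at one observed timepoint: ln 3
  tgt <- matrix(0, 1, 25)
  tgt[1, 2] <- 1
  prd <- matrix(0, 1, 25)
  prd[1, 1:3] <- 1 / 3
  obs <- matrix(FALSE, 1, 23)
  obs[1, 1] <- TRUE
  expect_equal(sequence_loss(prd, tgt, obs), log(3), tolerance = 1e-12)

  expect_error(sequence_loss(prd, tgt, matrix(FALSE, 1, 23)), "observed")
})

test_that("the loss is local to observed entries", {
  set.seed(5)
  target <- matrix(rnorm(4 * 25), 4, 25)
  for (t in 1:4) { target[t, 1:3] <- 0; target[t, sample(1:3, 1)] <- 1 }
  pred <- matrix(abs(rnorm(4 * 25)), 4, 25)
  pred[, 1:3] <- pred[, 1:3] / rowSums(pred[, 1:3])
  observed <- matrix(runif(4 * 23) < 0.5, 4, 23)
  observed[1, 1] <- TRUE
  base <- sequence_loss(pred, target, observed)

  # perturbing any masked target never changes the loss
  for (trial in 1:200) {
    t <- sample(1:4, 1); j <- sample(1:23, 1)
    if (observed[t, j]) next
    target2 <- target
    if (j == 1) { target2[t, 1:3] <- 0; target2[t, sample(1:3, 1)] <- 1 }
    else target2[t, 3 + (j - 1)] <- rnorm(1, sd = 10)
    expect_identical(sequence_loss(pred, target2, observed), base)
  }

  # equals the loss on the dense observed subsequence, recomputed by hand
  manual <- 0
  for (t in 1:4) {
    if (observed[t, 1])
      manual <- manual - sum(target[t, 1:3] * log(pred[t, 1:3]))
    for (j in 2:23) if (observed[t, j])
      manual <- manual + abs(pred[t, 3 + (j - 1)] -
                               target[t, 3 + (j - 1)]) / 22
  }
  expect_equal(base, manual, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  grad_check <- function(type, strategy, L, seed) {
    set.seed(seed)
    d <- 3; n <- 2; tmax <- 4
    params <- init_model(type, hidden = d, n_layers = L, seed = seed)
    X <- array(rnorm(25 * n * tmax), c(25, n, tmax))
    OBS <- array(rbinom(25 * n * tmax, 1, 0.6), c(25, n, tmax))
    for (t in 1:tmax) for (i in 1:n) {
      OBS[1:3, i, t] <- OBS[1, i, t]
      if (OBS[1, i, t] == 1) { X[1:3, i, t] <- 0
        X[sample(1:3, 1), i, t] <- 1 }
    }
    FILL <- array(0, c(25, n, tmax))
    if (strategy == "model")
      for (t in 2:tmax) FILL[, , t] <- 1 - OBS[, , t]
    data <- list(X = X, OBS = OBS, FILL = FILL,
                 ALIVE = matrix(1, n, tmax), n = n, tmax = tmax)
    r <- adprogress:::.fb(params, data, strategy)
    eps <- 1e-6
    worst <- 0
    for (li in seq_len(L)) for (nm in names(params$layers[[li]])) {
      w <- params$layers[[li]][[nm]]
      for (ii in sample(length(w), min(3, length(w)))) {
        pp <- params; pm <- params
        pp$layers[[li]][[nm]][ii] <- w[ii] + eps
        pm$layers[[li]][[nm]][ii] <- w[ii] - eps
        num <- (adprogress:::.fb(pp, data, strategy,
                                 want_grads = FALSE)$loss -
                  adprogress:::.fb(pm, data, strategy,
                                   want_grads = FALSE)$loss) / (2 * eps)
        ana <- r$grads$layers[[li]][[nm]][ii]
        worst <- max(worst, abs(num - ana) /
                       max(1e-6, abs(num) + abs(ana)))
      }
    }
    worst
  }
  expect_lt(grad_check("minimalrnn", "forward", 1, 7), 1e-4)
  expect_lt(grad_check("minimalrnn", "model", 2, 8), 1e-4)
  expect_lt(grad_check("lss", "model", 1, 9), 1e-4)
})
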