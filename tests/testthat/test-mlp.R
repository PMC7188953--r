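test_that("initialization is seed-deterministic with the right parameter count", {
  a <- init_network(7)
  b <- init_network(7)
  expect_identical(coef(a), coef(b))
  expect_false(identical(coef(a), coef(init_network(8))))
  # 20*10+10 + 10*7+7 + 7*5+5 + 5*2+2
  expect_length(coef(a), 339)
  expect_true(all(abs(coef(a)) <= 0.5))
})

test_that("forward evaluation respects the tanh bounds and composition", {
  net <- init_network(1, c(3, 4, 2))
  net$W <- lapply(net$W, function(w) { w[] <- 0; w })
  net$b <- lapply(net$b, function(b) { b[] <- 0; b })
  expect_equal(forward(net, c(1, 2, 3)), c(0, 0))
  set.seed(61)
  big <- init_network(2)
  for (r in 1:5) {
    out <- forward(big, rnorm(20, 0, 1e6))
    expect_true(all(out > -1 & out < 1))
  }
  # single-path 1-1-1-1-1 chain reduces to nested tanh
  chain <- init_network(3, c(1, 1, 1, 1, 1))
  chain$W <- lapply(chain$W, function(w) { w[] <- 1; w })
  chain$b <- lapply(chain$b, function(b) { b[] <- 0; b })
  x <- 0.7
  expect_equal(forward(chain, x), tanh(tanh(tanh(tanh(x)))))
  expect_error(forward(big, rnorm(19)), "expected 20 inputs")
})

test_that("the analytic Jacobian matches central finite differences", {
  set.seed(62)
  net <- init_network(5, c(3, 4, 3, 2))
  X <- matrix(rnorm(12), 4, 3)
  jac <- radiotexnet:::mlp_jacobian(net, X)
  th <- coef(net)
  h <- 1e-6
  num <- matrix(0, nrow(jac$J), ncol(jac$J))
  for (p in seq_along(th)) {
    tp <- th; tp[p] <- tp[p] + h
    tm <- th; tm[p] <- tm[p] - h
    yp <- forward(radiotexnet:::vector_to_params(net, tp), X)
    ym <- forward(radiotexnet:::vector_to_params(net, tm), X)
    num[, p] <- as.numeric(t((yp - ym) / (2 * h)))
  }
  expect_lt(max(abs(num - jac$J)), 1e-6)
})

test_that("LM training solves XOR for most seeds within the epoch budget", {
  xorx <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), 4)
  xory <- c(0, 1, 1, 0)
  ok <- 0
  for (s in 1:10) {
    net <- train_mlp(xorx, xory, seed = s)
    mse <- utils::tail(net$record$mse_trace, 1)
    if (length(mse) && mse < 1e-3) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("accepted LM steps strictly decrease training MSE", {
  set.seed(63)
  X <- matrix(rnorm(40), 10, 4)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  net <- train_mlp(X, y, hidden = c(5, 3), seed = 2, max_epochs = 50,
                   goal = 1e-9)
  expect_gt(length(net$record$mse_trace), 3)
  expect_true(all(diff(net$record$mse_trace) < 0))
})

test_that("an immediately satisfied goal stops before any epoch", {
  set.seed(64)
  X <- matrix(rnorm(8), 2, 4)
  net <- train_mlp(X, c(0, 1), hidden = c(3), seed = 1, goal = 10)
  expect_equal(net$record$epochs_run, 0L)
  expect_equal(net$record$stop_reason, "goal_reached")
})

test_that("training is bit-reproducible for fixed seed and data", {
  set.seed(65)
  X <- matrix(rnorm(60), 15, 4)
  y <- as.integer(X[, 1] > 0)
  a <- train_mlp(X, y, hidden = c(5, 3), seed = 9, max_epochs = 30)
  b <- train_mlp(X, y, hidden = c(5, 3), seed = 9, max_epochs = 30)
  expect_identical(coef(a), coef(b))
  expect_identical(a$record$mse_trace, b$record$mse_trace)
})

test_that("linearly separable classes embedded in 20-D are fit perfectly", {
  ok <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    n <- 20
    y <- rep(c(0L, 1L), n / 2)
    X <- matrix(rnorm(n * 20, 0, 0.3), n)
    X[, 1] <- X[, 1] + ifelse(y == 1, 1.5, -1.5)
    X[, 2] <- X[, 2] + ifelse(y == 1, 1, -1)
    net <- train_mlp(X, y, seed = s, max_epochs = 200)
    acc <- mean(predict(net, X, type = "class") == y)
    if (acc == 1) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("scores, decisions and the tie convention follow f = pos - neg", {
  # identity-ish 2-2 net: outputs tanh(x)
  net <- init_network(1, c(2, 2))
  net$W[[1]] <- diag(2)
  net$b[[1]] <- c(0, 0)
  sc <- score_and_classify(net, c(atanh(0.9), atanh(-0.8)))
  expect_equal(sc$score, 1.7)
  expect_equal(sc$label, 1L)
  sc2 <- score_and_classify(net, c(atanh(-0.2), atanh(0.4)))
  expect_equal(sc2$score, -0.6)
  expect_equal(sc2$label, 0L)
  sc3 <- score_and_classify(net, c(0.3, 0.3))   # f exactly 0
  expect_equal(sc3$score, 0)
  expect_equal(sc3$label, 0L)
})

test_that("validation early stopping reports val_fail and keeps the best net", {
  set.seed(66)
  n <- 16
  X <- matrix(rnorm(n * 4), n)
  y <- sample(c(0L, 1L), n, TRUE)       # pure noise -> validation degrades
  Xv <- matrix(rnorm(8 * 4), 8)
  yv <- sample(c(0L, 1L), 8, TRUE)
  net <- train_mlp(X, y, validation = list(x = Xv, y = yv), seed = 4,
                   hidden = c(6), max_epochs = 400, goal = 1e-12,
                   max_val_fail = 6)
  expect_true(net$record$stop_reason %in% c("val_fail", "mu_overflow",
                                            "max_epochs"))
  if (net$record$stop_reason == "val_fail") {
    best <- min(net$record$val_trace)
    Tv <- radiotexnet:::targets_pm1(yv, 8)
    got <- mean((Tv - forward(net, Xv))^2)
    expect_equal(got, best, tolerance = 1e-10)
  }
})

test_that("networks round-trip through JSON serialization", {
  xorx <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), 4)
  net <- train_mlp(xorx, c(0, 1, 1, 0), hidden = c(4), seed = 3,
                   max_epochs = 50)
  p <- tempfile(fileext = ".json")
  write_mlp(net, p)
  back <- read_mlp(p)
  expect_equal(coef(back), coef(net))
  expect_equal(predict(back, xorx), predict(net, xorx))
  expect_equal(back$layer_sizes, net$layer_sizes)
})
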