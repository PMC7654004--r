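test_that("forward pass matches hand arithmetic", {
  # 2-input, one hidden layer with 2 ReLU units, linear output
  w <- list(list(W = matrix(c(1, -1,
                              2, 0.5), 2, 2, byrow = TRUE), b = c(0.5, -0.25)),
            list(W = matrix(c(2, -3), 2, 1), b = 1))
  x <- c(1, 2)
  h <- pmax(c(1 * 1 + 2 * 2 + 0.5, -1 * 1 + 0.5 * 2 - 0.25), 0)  # (5.5, 0)
  expect_equal(mlp_forward(w, x), 2 * 5.5 - 3 * 0 + 1)
  # all-zero weights give zero output
  w0 <- list(list(W = matrix(0, 2, 2), b = c(0, 0)),
             list(W = matrix(0, 2, 1), b = 0))
  expect_equal(mlp_forward(w0, x), 0)
  # a unit with negative pre-activation contributes nothing
  wneg <- list(list(W = matrix(c(-1, -1), 2, 1), b = 0),
               list(W = matrix(5, 1, 1), b = 0.75))
  expect_equal(mlp_forward(wneg, c(1, 1)), 0.75)
  expect_error(mlp_forward(w, c(1, 2, 3)), "dimension")
})

test_that("penalized loss sums squared error plus the weight ridge", {
  w <- list(list(W = matrix(2, 1, 1), b = 5))  # bias excluded from penalty
  expect_equal(penalized_loss(c(1, 2), c(0, 0), w, 0.5),
               1 + 4 + 0.5 * 4)
  expect_equal(penalized_loss(c(1, -1), c(0, 0), w, 0), 2)
  expect_equal(penalized_loss(c(3, 3), c(3, 3), list(list(W = matrix(0, 1, 1),
                                                          b = 0)), 7), 0)
})

test_that("inverted dropout keeps the expected fraction and scale", {
  a <- matrix(1, 1, 10000)
  expect_identical(apply_dropout(a, 1), a)
  set.seed(10)
  masked <- apply_dropout(a, 0.5)
  expect_lt(abs(mean(masked > 0) - 0.5), 0.02)
  # expectation preservation over repeated draws
  set.seed(11)
  mm <- replicate(1000, mean(apply_dropout(matrix(rnorm(100), 1), 0.7)))
  base <- mean(matrix(rnorm(100), 1))  # scale reference only
  expect_lt(abs(mean(mm)), 0.05)
  expect_error(apply_dropout(a, 0), "keep_rate")
})

test_that("analytic gradients match central finite differences", {
  set.seed(1)
  arch <- architecture(2, c(4, 3), l2_lambda = 0.03)
  w <- init_mlp(arch, 5, 0.5)
  x <- matrix(rnorm(30), 6, 5); y <- rnorm(6)
  g <- mlp_gradient(w, x, y, arch$l2_lambda)
  h <- 1e-5
  worst <- 0
  for (l in seq_along(w)) for (nm in c("W", "b")) {
    for (i in seq_along(w[[l]][[nm]])) {
      wp <- w; wp[[l]][[nm]][i] <- wp[[l]][[nm]][i] + h
      wm <- w; wm[[l]][[nm]][i] <- wm[[l]][[nm]][i] - h
      fd <- (penalized_loss(y, mlp_forward(wp, x), wp, arch$l2_lambda) -
             penalized_loss(y, mlp_forward(wm, x), wm, arch$l2_lambda)) /
        (2 * h)
      worst <- max(worst, abs(g[[l]][[nm]][i] - fd) / max(abs(fd), 1e-6))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("the early-stopping rule stops after the patience window", {
  # best 4 at evaluation 2, then five consecutive non-improvements
  tr <- early_stop_trace(c(5, 4, 4.1, 4.2, 4.3, 4.4, 4.5), patience = 5)
  expect_equal(tr$stop_index, 7)
  expect_equal(tr$best_index, 2)
  # an improvement inside the window resets the counter
  tr2 <- early_stop_trace(c(5, 4, 4.1, 3.9, 4, 4, 4, 4, 3.85), patience = 5)
  expect_true(is.na(tr2$stop_index))
  expect_equal(tr2$best_index, 9)
  # equality is not an improvement
  tr3 <- early_stop_trace(c(2, 2, 2, 2, 2, 2), patience = 5)
  expect_equal(tr3$stop_index, 6)
})

test_that("a width-1 linear-regime net recovers least squares", {
  set.seed(3)
  n <- 300; p <- 4
  Z <- matrix(rnorm(n * p), n, p)
  beta <- c(1.5, -2, 0.5, 1)
  y <- drop(Z %*% beta)  # noiseless
  arch <- architecture(1, 1, l2_lambda = 0, dropout_keep = 1)
  fit <- train_mlp(arch, Z[1:250, ], y[1:250], Z[251:300, ], y[251:300],
                   train_config(learning_rate = 1e-2, max_epochs = 1000,
                                seed = 2))
  pred <- mlp_forward(fit$weights, Z[1:250, ])
  mse0 <- mean((y[1:250] - mean(y[1:250]))^2)
  expect_lt(mean((y[1:250] - pred)^2), 0.01 * mse0)
  # effective input->output coefficients align with the OLS solution
  eff <- fit$weights[[1]]$W[, 1] * fit$weights[[2]]$W[1, 1]
  cosine <- sum(eff * beta) / sqrt(sum(eff^2) * sum(beta^2))
  expect_gt(cosine, 0.99)
})

test_that("early stopping returns the best-evaluation snapshot", {
  set.seed(6)
  n <- 200; p <- 6
  Z <- matrix(rnorm(n * p), n, p)
  y <- drop(Z %*% rnorm(p)) + rnorm(n, sd = 2)
  arch <- architecture(1, 8, l2_lambda = 0, dropout_keep = 1)
  fit <- train_mlp(arch, Z[1:150, ], y[1:150], Z[151:200, ], y[151:200],
                   train_config(learning_rate = 5e-3, max_epochs = 200,
                                seed = 4))
  pred <- mlp_forward(fit$weights, Z[151:200, ])
  expect_equal(mean((y[151:200] - pred)^2), min(fit$history),
               tolerance = 1e-10)
  expect_lte(fit$stopped_epoch, 200)
  expect_error(train_mlp(arch, Z, y, Z[0, ], numeric(0)), "tuning")
})

test_that("stronger ridge never inflates the weight norm", {
  set.seed(9)
  n <- 150; p <- 5
  Z <- matrix(rnorm(n * p), n, p)
  y <- drop(Z %*% rnorm(p)) + rnorm(n)
  wnorm <- function(fit) sum(vapply(fit$weights,
                                    function(l) sum(l$W^2), numeric(1)))
  for (s in 1:3) {
    f1 <- train_mlp(architecture(1, 4, l2_lambda = 0.01), Z[1:120, ],
                    y[1:120], Z[121:150, ], y[121:150],
                    train_config(learning_rate = 5e-3, max_epochs = 100,
                                 seed = s))
    f2 <- train_mlp(architecture(1, 4, l2_lambda = 0.1), Z[1:120, ],
                    y[1:120], Z[121:150, ], y[121:150],
                    train_config(learning_rate = 5e-3, max_epochs = 100,
                                 seed = s))
    expect_lte(wnorm(f2), wnorm(f1) + 1e-8)
  }
})

test_that("predict-mode forward ignores the RNG state", {
  set.seed(2)
  arch <- architecture(2, c(3, 3), dropout_keep = 0.6)
  w <- init_mlp(arch, 4, 0.3)
  x <- matrix(rnorm(20), 5, 4)
  set.seed(100); p1 <- mlp_forward(w, x)
  set.seed(200); p2 <- mlp_forward(w, x)
  expect_identical(p1, p2)
  # train mode with dropout is stochastic
  set.seed(1); t1 <- mlp_forward(w, x, mode = "train", keep_rate = 0.6)
  set.seed(2); t2 <- mlp_forward(w, x, mode = "train", keep_rate = 0.6)
  expect_false(identical(t1, t2))
})

test_that("random search is reproducible and picks the best candidate", {
  set.seed(12)
  n <- 120; p <- 5
  Z <- matrix(rnorm(n * p), n, p)
  y <- drop(Z %*% c(2, -1, 1, 0, 0.5))
  grids <- list(units = c(2, 4), layers = 1:2, dropout = c(0.8, 1),
                l2 = c(0, 0.01))
  cfg <- train_config(learning_rate = 5e-3, max_epochs = 40, seed = 3)
  s1 <- random_search(Z[1:90, ], y[1:90], Z[91:120, ], y[91:120], cfg,
                      n_candidates = 4, grids = grids, seed = 7)
  s2 <- random_search(Z[1:90, ], y[1:90], Z[91:120, ], y[91:120], cfg,
                      n_candidates = 4, grids = grids, seed = 7)
  expect_identical(s1$leaderboard, s2$leaderboard)
  expect_equal(s1$best_index,
               order(-s1$leaderboard$tune_cor,
                     s1$leaderboard$tune_mse)[1])
  # n_candidates = 1: that candidate wins by construction
  s3 <- random_search(Z[1:90, ], y[1:90], Z[91:120, ], y[91:120], cfg,
                      n_candidates = 1, grids = grids, seed = 7)
  expect_equal(s3$best_index, 1)
  # every candidate respects the grids
  expect_true(all(s1$leaderboard$l2 %in% grids$l2))
  expect_true(all(s1$leaderboard$dropout_keep %in% grids$dropout))
  expect_true(all(s1$leaderboard$layers %in% grids$layers))
})
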