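test_that("chronological split respects generation ordering", {
  set.seed(1)
  rec <- data.frame(id = sprintf("A%04d", 1:1800),
                    generation = rep(1:18, each = 100))
  plan <- chronological_split(rec)
  expect_setequal(plan$test_generations, c(17, 18))
  expect_equal(plan$tune_generations, 16)
  expect_setequal(plan$train_generations, 1:15)
  gm <- plan$generation_map
  expect_lt(max(gm[plan$train_ids]), min(gm[plan$tune_ids]))
  expect_lt(max(gm[plan$tune_ids]), min(gm[plan$test_ids]))
  expect_length(intersect(plan$train_ids, plan$test_ids), 0)
  expect_length(intersect(plan$train_ids, plan$tune_ids), 0)
  # 3 generations cannot give test(2) + tune(1) + train(>=1)
  rec3 <- data.frame(id = letters[1:6], generation = rep(1:3, 2))
  expect_error(chronological_split(rec3), "training generation")
})

test_that("nested subsamples are sized and strictly nested", {
  ids <- sprintf("B%04d", 1:1000)
  lad <- nested_subsamples(ids, fractions = c(1, 3), seed = 4)
  expect_equal(lengths(lad$subsets), c(10, 30))
  expect_true(all(lad$subsets[[1]] %in% lad$subsets[[2]]))
  full <- nested_subsamples(ids, fractions = 100, seed = 1)
  expect_setequal(full$subsets[[1]], ids)
  lad15 <- nested_subsamples(ids, seed = 9)
  for (i in seq_along(lad15$subsets)[-1])
    expect_true(all(lad15$subsets[[i - 1]] %in% lad15$subsets[[i]]))
  expect_equal(lengths(lad15$subsets),
               floor(c(1, 3, 5, 7, 10, 15, 20, 30, 40, 50, 60, 70, 80, 90,
                       100) * 10 + 0.5))
  expect_error(nested_subsamples(ids[1:10], fractions = c(1, 50)), "empty")
  expect_error(nested_subsamples(ids, fractions = c(5, 3)), "ascending")
})

test_that("metrics match their textbook formulas on small cases", {
  y <- c(2, 4, 6, 7, 10)
  expect_equal(prediction_correlation(y, y), 1)
  expect_equal(prediction_correlation(y, -y), -1)
  yh <- c(1, 5, 5, 8, 9)
  r_hand <- sum((y - mean(y)) * (yh - mean(yh))) /
    sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
  expect_equal(prediction_correlation(y, yh), r_hand)
  expect_true(is.na(prediction_correlation(y, rep(1, 5))))

  expect_equal(msep(c(1, 2), c(1, 2)), 0)
  expect_equal(msep(c(0, 0), c(1, 3)), 5)
  expect_equal(msep(y, y + 2), 4)

  expect_equal(relative_gain(1, 1), 0)
  expect_equal(relative_gain(1.1, 1.0), 10, tolerance = 1e-10)
  expect_equal(relative_gain(0.9, 1.0), -10, tolerance = 1e-10)
  expect_error(relative_gain(1, 0), "zero")
})

test_that("relative gain signs follow the criterion direction", {
  # better method correlation -> positive RG; better (lower) MSEP -> negative
  expect_gt(relative_gain(0.32, 0.30), 0)
  expect_lt(relative_gain(26264.8, 28000), 0)
})

test_that("predictive bias is the OLS slope of observed on predicted", {
  y <- c(1, 2, 3, 4)
  expect_equal(predictive_bias(y, y), 1)
  expect_equal(predictive_bias(y, y / 2), 2)  # deflated predictions
  yh <- c(1.2, 1.9, 3.3, 3.8)
  expect_equal(predictive_bias(y, yh), unname(coef(lm(y ~ yh))[2]))
  expect_equal(predictive_bias(y, yh, reverse = TRUE),
               unname(coef(lm(yh ~ y))[2]))
  expect_true(is.na(predictive_bias(y, rep(2, 4))))
})

test_that("spearman uses mid-ranks and matches the built-in oracle", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_between(a, a^3), 1)
  expect_equal(spearman_between(a, rev(a)), -1)
  set.seed(2)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)  # ties present
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  expect_equal(spearman_between(x, y),
               suppressWarnings(cor(x, y, method = "spearman")))
})

test_that("top-k agreement counts overlap with stable tie-breaks", {
  a <- setNames(10:1, letters[1:10])
  expect_equal(topk_agreement(a, a, k = 5), 100)
  b <- setNames(1:10, letters[1:10])
  expect_equal(topk_agreement(a, b, k = 5), 0)
  # constructed case: 3 of the top 5 shared
  x <- setNames(c(10, 9, 8, 7, 6, 1, 2, 3, 4, 5), letters[1:10])
  y <- setNames(c(10, 9, 8, 1, 2, 7, 6, 3, 4, 5), letters[1:10])
  expect_equal(topk_agreement(x, y, k = 5), 60)
  # symmetry
  set.seed(3)
  u <- rnorm(40); v <- rnorm(40)
  expect_equal(topk_agreement(u, v, k_fraction = 0.25),
               topk_agreement(v, u, k_fraction = 0.25))
  # ties broken by stable id order
  t1 <- setNames(c(1, 1, 1, 0), letters[1:4])
  expect_equal(topk_agreement(t1, t1, k = 2), 100)
  expect_error(topk_agreement(a, b, k = 11), "exceeds")
})

test_that("metrics are invariant to record order", {
  set.seed(8)
  y <- rnorm(50); yh <- y + rnorm(50)
  perm <- sample(50)
  expect_equal(prediction_correlation(y, yh),
               prediction_correlation(y[perm], yh[perm]))
  expect_equal(msep(y, yh), msep(y[perm], yh[perm]))
  expect_equal(predictive_bias(y, yh), predictive_bias(y[perm], yh[perm]))
  expect_equal(spearman_between(y, yh), spearman_between(y[perm], yh[perm]))
})

test_that("run_comparison assembles metrics on a single fraction", {
  pop <- small_population(n = 700, m = 120, seed = 23)
  G <- pop$genotypes
  ph <- pop$phenotypes
  y_star <- setNames(ph$weight - ave(ph$weight, ph$contemporary_group),
                     ph$id)
  split <- chronological_split(ph, 1, 1)
  lad <- nested_subsamples(split$train_ids, fractions = 100, seed = 2)
  rep1 <- run_comparison(y_star, G, split, lad, methods = "BRR",
                         mcmc = mcmc_config(800, 300, 2), seed = 5)
  m <- rep1$metrics
  expect_setequal(m$metric, c("prediction_correlation", "msep",
                              "bias_slope"))
  expect_equal(unique(m$fraction), 100)
  expect_true(all(is.finite(m$value)))
  expect_true(m$value[m$metric == "msep"] >= 0)
})

test_that("WT variants train on strictly more data and share the test set", {
  pop <- small_population(n = 700, m = 120, seed = 23)
  ph <- pop$phenotypes
  y_star <- setNames(ph$weight - mean(ph$weight), ph$id)
  split <- chronological_split(ph, 1, 1)
  lad <- nested_subsamples(split$train_ids, fractions = c(20, 60), seed = 3)
  # the WT set is subset + tuning for every fraction, by construction
  for (f in seq_along(lad$fractions)) {
    wt <- union(lad$subsets[[f]], split$tune_ids)
    expect_gt(length(wt), length(lad$subsets[[f]]))
    expect_length(intersect(wt, split$test_ids), 0)
  }
  rep2 <- run_comparison(y_star, pop$genotypes, split, lad,
                         methods = c("BRR", "BRR-WT"),
                         mcmc = mcmc_config(600, 200, 2), seed = 6)
  expect_equal(rep2$test_checksum,
               sum(as.numeric(utf8ToInt(paste(split$test_ids,
                                              collapse = "")))))
  expect_setequal(unique(rep2$metrics$method), c("BRR", "BRR-WT"))
  expect_false(is.null(rep2$pairwise))
  expect_true(all(rep2$pairwise$topk_agreement >= 0 &
                  rep2$pairwise$topk_agreement <= 100))
})
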