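make_marker_trait <- function(n, m, h2 = 0.5, n_qtl = m, sd_b = 1,
                              seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.5)[rep(1:m, each = n)]),
              n, m)
  # guard against monomorphic columns in tiny draws
  X[1, ] <- 0; X[2, ] <- 1
  tr <- standardize_markers(X)
  b <- numeric(m)
  b[sample(m, n_qtl)] <- rnorm(n_qtl, sd = sd_b)
  g <- drop(tr$Z %*% b)
  e <- rnorm(n, sd = sqrt(var(g) * (1 - h2) / max(h2, 1e-6)))
  list(X = X, tr = tr, b = b, y = g + e, g = g)
}

test_that("standardization centers, scales and round-trips", {
  col <- matrix(c(0, 1, 2), 3, 1)
  s <- standardize_markers(col)
  expect_equal(drop(s$Z), c(-1, 0, 1))  # sample-SD convention (n - 1)
  expect_equal(s$means, 1)
  expect_equal(s$sds, 1)
  X <- toy_dosages(100, 10, seed = 3)
  s <- standardize_markers(X)
  expect_equal(unname(colMeans(s$Z)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(s$Z, 2, sd)), rep(1, 10), tolerance = 1e-12)
  # idempotence of an already-standardized column
  s2 <- scale(s$Z[, 1])
  expect_equal(drop(s2), s$Z[, 1], tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize_markers(matrix(2, 5, 1)), "zero-variance")
  expect_error(standardize_markers(matrix(c(0, NA, 1, 2), 2, 2)), "impute")
})

test_that("the default marker-variance scale follows the printed rule", {
  pr <- prior_spec(v_a = 4.2, sigma_s2_tilde = 1)
  # single marker at p = 0.5: sigma_a2 = 1 / 0.25 = 4, S2a = 4 * 2.2 / 4.2
  expect_equal(default_marker_scale(pr, pi = 0, allele_freqs = 0.5),
               4 * 2.2 / 4.2, tolerance = 1e-12)
  # doubling the markers halves the scale
  expect_equal(default_marker_scale(pr, 0, c(0.5, 0.5)),
               default_marker_scale(pr, 0, 0.5) / 2)
  # v_a -> Inf limit: S2a -> sigma_a_tilde^2
  pr_inf <- prior_spec(v_a = 1e9, sigma_s2_tilde = 1)
  expect_equal(default_marker_scale(pr_inf, 0, 0.5), 4, tolerance = 1e-6)
  # nonzero pi enlarges the per-marker variance
  expect_equal(default_marker_scale(pr, 0.9, 0.5),
               10 * default_marker_scale(pr, 0, 0.5))
  # the factor-2 heterozygosity variant
  pr2 <- prior_spec(v_a = 4.2, sigma_s2_tilde = 1, het_factor2 = TRUE)
  expect_equal(default_marker_scale(pr2, 0, 0.5),
               default_marker_scale(pr, 0, 0.5) / 2)
  expect_error(default_marker_scale(pr, 1, 0.5), "pi")
})

test_that("BRR with fixed variances matches the closed-form ridge solution", {
  for (s in 1:2) {
    d <- make_marker_trait(100, 20, seed = s)
    va <- 0.25; ve <- 1.5
    post <- fit_brr(d$y, d$tr$Z, mcmc_config(12000, 2000, 2, seed = s),
                    fix_var_a = va, fix_var_e = ve)
    yc <- d$y - mean(d$y)
    ridge <- drop(solve(crossprod(d$tr$Z) + diag(ve / va, 20),
                        crossprod(d$tr$Z, yc)))
    # 3 Monte-Carlo SEs, conservatively inflating for autocorrelation
    mcse <- post$effect_sds / sqrt(post$retained_draw_count / 10)
    expect_true(all(abs(post$effect_means - ridge) < 3 * mcse))
    expect_equal(post$mu_mean, mean(d$y), tolerance = 0.2)
  }
})

test_that("a null response gives null effect estimates", {
  d <- make_marker_trait(80, 10, seed = 5)
  post <- fit_brr(rep(0, 80), d$tr$Z, mcmc_config(4000, 1000, 2, seed = 2),
                  fix_var_a = 0.1, fix_var_e = 1)
  expect_true(all(abs(post$effect_means) < 0.05))
})

test_that("BRR recovers signal on a dense-effect trait", {
  d <- make_marker_trait(1000, 200, h2 = 0.6, seed = 8)
  post <- fit_brr(d$y, d$tr$Z, mcmc_config(3000, 1000, 2, seed = 1))
  gebv <- drop(d$tr$Z %*% post$effect_means)
  r_fit <- cor(d$g, gebv)
  expect_gt(r_fit, 0.5)
  # a permutation null destroys the signal
  set.seed(99)
  post0 <- fit_brr(sample(d$y), d$tr$Z, mcmc_config(3000, 1000, 2, seed = 1))
  r_null <- cor(d$g, drop(d$tr$Z %*% post0$effect_means))
  expect_gt(r_fit, r_null + 0.2)
})

test_that("Bayes C-pi with pi = 0 reduces to BRR", {
  d <- make_marker_trait(120, 25, seed = 13)
  mc <- mcmc_config(12000, 4000, 2, seed = 77)
  brr <- fit_brr(d$y, d$tr$Z, mc)
  cpi <- fit_bayes_cpi(d$y, d$tr$Z, mc, prior_spec(pi_prior = 0))
  expect_true(all(cpi$inclusion_probs == 1))
  # agreement within Monte-Carlo error
  mcse <- sqrt(brr$effect_sds^2 + 1e-12) / sqrt(brr$retained_draw_count / 10)
  expect_true(all(abs(brr$effect_means - cpi$effect_means) < 4 * mcse))
})

test_that("Bayes C-pi concentrates pi high and flags true QTL", {
  d <- make_marker_trait(800, 250, h2 = 0.5, n_qtl = 8, seed = 4)
  post <- fit_bayes_cpi(d$y, d$tr$Z, mcmc_config(3000, 1200, 3, seed = 2))
  qtl <- which(d$b != 0)
  expect_gte(mean(post$pi_samples), 0.9)
  expect_gt(mean(post$inclusion_probs[qtl]),
            mean(post$inclusion_probs[-qtl]))
  expect_true(all(post$inclusion_probs >= 0 & post$inclusion_probs <= 1))
  expect_equal(post$retained_draw_count, (3000 - 1200) / 3)
})

test_that("pure-noise response drives pi up and GEBV variance down", {
  set.seed(31)
  d <- make_marker_trait(600, 150, seed = 31)
  y <- rnorm(600, sd = 10)
  post <- fit_bayes_cpi(y, d$tr$Z, mcmc_config(3000, 1000, 2, seed = 9))
  expect_gt(mean(post$pi_samples), 0.7)
  gebv <- drop(d$tr$Z %*% post$effect_means)
  expect_lt(var(gebv), 0.2 * var(y))
})

test_that("seeded chains are bit-reproducible", {
  d <- make_marker_trait(60, 12, seed = 3)
  mc <- mcmc_config(1000, 200, 2, seed = 1234)
  p1 <- fit_brr(d$y, d$tr$Z, mc)
  p2 <- fit_brr(d$y, d$tr$Z, mc)
  expect_identical(p1$effect_means, p2$effect_means)
  expect_identical(p1$variance_samples, p2$variance_samples)
  c1 <- fit_bayes_cpi(d$y, d$tr$Z, mc)
  c2 <- fit_bayes_cpi(d$y, d$tr$Z, mc)
  expect_identical(c1$pi_samples, c2$pi_samples)
})

test_that("the marker-variance update leaves the prior invariant", {
  # Gibbs-on-the-joint check: alternately draw data given the current
  # parameters and parameters given the data (a full chain per cycle);
  # the stationary marginal of sigma_a^2 must be its scaled-inv-chi2 prior
  n <- 20; m <- 5
  set.seed(55)
  Z <- standardize_markers(toy_dosages(n, m, p = 0.4, seed = 8))$Z
  va <- 4.2; S2a <- 1; ve <- 6; S2e <- 1
  pr <- prior_spec(v_a = va, S2_a = S2a, v_e = ve, S2_e = S2e)
  draws <- numeric(150)
  var_a <- 1; var_e <- 1
  for (k in seq_len(150)) {
    a <- rnorm(m, sd = sqrt(var_a))
    e <- rnorm(n, sd = sqrt(var_e))
    y <- drop(Z %*% a) + e          # mu = 0 in the generative step
    post <- fit_brr(y, Z, mcmc_config(220, 120, 1, seed = 1e6 + k), pr)
    var_a <- tail(post$variance_samples$var_a, 1)
    var_e <- tail(post$variance_samples$var_e, 1)
    draws[k] <- var_a
  }
  # prior: sigma_a^2 = va * S2a / chisq_va; compare at the prior quartiles
  qs <- va * S2a / qchisq(c(0.75, 0.5, 0.25), df = va)
  frac <- vapply(qs, function(q) mean(draws <= q), numeric(1))
  # binomial bands at 150 correlated draws, generously widened
  expect_true(all(abs(frac - c(0.25, 0.5, 0.75)) < 0.2))
})

test_that("GEBV prediction applies the training transform", {
  # hand-built 2-marker case
  Xtr <- matrix(c(0, 2, 1,
                  2, 0, 1), 3, 2)
  tr <- standardize_markers(Xtr)
  post <- structure(list(mu_mean = 10, effect_means = c(2, -1)),
                    class = "posterior_summary")
  Xnew <- matrix(c(2, 0), 1, 2)
  zn <- (c(2, 0) - tr$means) / tr$sds
  expect_equal(predict_gebv(Xnew, tr, post),
               10 + zn[1] * 2 + zn[2] * (-1))
  # zero effects give the constant mu
  post0 <- structure(list(mu_mean = 5, effect_means = c(0, 0)),
                     class = "posterior_summary")
  expect_equal(unname(predict_gebv(Xtr, tr, post0)), rep(5, 3))
  # a training row reproduces its fitted value
  expect_equal(predict_gebv(Xtr[1, , drop = FALSE], tr, post),
               10 + drop(tr$Z[1, ] %*% c(2, -1)))
  expect_error(predict_gebv(matrix(1, 1, 3), tr, post), "marker count")
})
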