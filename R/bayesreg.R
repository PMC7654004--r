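## Step two, Bayesian half: standardization, hyperprior scale rules, and R
## wrappers around the compiled Gibbs cores for Bayesian Ridge Regression
## and Bayes C-pi, plus GEBV prediction for new individuals.

#' MCMC chain settings
#'
#' Defaults follow the study protocol: 30,000 iterations, 20,000 discarded
#' as warm-up, every 5th retained.
#'
#' @param n_iter Chain length.
#' @param burn_in Discarded initial cycles; must be < n_iter.
#' @param thin Keep every `thin`-th post-warm-up draw.
#' @param seed Integer seed for the chain.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 30000L, burn_in = 20000L, thin = 5L,
                        seed = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter)
    stop("mcmc_config: burn_in must be < n_iter", call. = FALSE)
  if (thin < 1L) stop("mcmc_config: thin must be >= 1", call. = FALSE)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed)), class = "mcmc_config")
}

#' Prior specification for the whole-genome regressions
#'
#' The marker-variance hyperprior is scaled inverse chi-square with
#' `v_a = 4.2` and scale from the default rule `S2_a = sigma_a_tilde^2 *
#' (v_a - 2) / v_a`, where `sigma_a_tilde^2 = sigma_s_tilde^2 / ((1 - pi) *
#' sum_j p_j (1 - p_j))` and `sigma_s_tilde^2` is the variance attributed to
#' all markers jointly. The residual hyperprior (v_e, S2_e), unspecified by
#' the protocol, defaults to v_e = 4.2 with S2_e set at fit time so the
#' prior mode equals half the sample variance of the response (weakly
#' informative). `sigma_s_tilde^2` defaults at fit time to half the sample
#' variance of the response.
#'
#' @param v_a Marker-variance degrees of freedom (> 2 for the default scale
#'   rule).
#' @param S2_a Marker-variance scale; NA = derive by the default rule.
#' @param v_e Residual degrees of freedom.
#' @param S2_e Residual scale; NA = derive at fit time.
#' @param pi_prior "uniform" to sample pi with a Uniform(0,1) prior, or a
#'   fixed numeric value in \[0, 1).
#' @param sigma_s2_tilde Variance explained by all markers; NA = derive at
#'   fit time.
#' @param het_factor2 Use the factor-2 heterozygosity denominator
#'   `2 * sum p(1-p)` instead of the plain `sum p(1-p)` (default FALSE).
#' @return List of class `prior_spec`.
#' @export
prior_spec <- function(v_a = 4.2, S2_a = NA_real_, v_e = 4.2,
                       S2_e = NA_real_, pi_prior = "uniform",
                       sigma_s2_tilde = NA_real_, het_factor2 = FALSE) {
  if (is.na(S2_a) && v_a <= 2)
    stop("prior_spec: v_a must be > 2 for the default scale rule",
         call. = FALSE)
  if (!identical(pi_prior, "uniform")) {
    pi_prior <- as.numeric(pi_prior)
    if (is.na(pi_prior) || pi_prior < 0 || pi_prior >= 1)
      stop("prior_spec: fixed pi must be in [0, 1)", call. = FALSE)
  }
  structure(list(v_a = v_a, S2_a = S2_a, v_e = v_e, S2_e = S2_e,
                 pi_prior = pi_prior, sigma_s2_tilde = sigma_s2_tilde,
                 het_factor2 = het_factor2), class = "prior_spec")
}

#' Standardize marker dosages
#'
#' Centers each column and scales by its sample standard deviation (n - 1
#' denominator), returning the transform so new individuals can be put on
#' the training scale.
#'
#' @param G A [genotype_matrix()] or plain dosage matrix without missing
#'   entries.
#' @return List with `Z` (standardized matrix), `means`, `sds`.
#' @export
standardize_markers <- function(G) {
  X <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  if (anyNA(X))
    stop("standardize_markers: impute missing genotypes first", call. = FALSE)
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (any(s == 0))
    stop("standardize_markers: zero-variance column; run marker QC first",
         call. = FALSE)
  Z <- sweep(sweep(X, 2, mu, "-"), 2, s, "/")
  list(Z = Z, means = mu, sds = s)
}

#' Default marker-variance scale
#'
#' Implements the printed rule verbatim: `sigma_a_tilde^2 = sigma_s_tilde^2
#' / ((1 - pi) * sum_j p_j (1 - p_j))` and `S2_a = sigma_a_tilde^2 *
#' (v_a - 2) / v_a`. The common factor-2 heterozygosity denominator is
#' available behind `het_factor2` in the prior.
#'
#' @param prior A [prior_spec()] supplying v_a, sigma_s2_tilde and the
#'   denominator convention.
#' @param pi Prior exclusion probability (use 0 for BRR).
#' @param allele_freqs Counted-allele frequencies p_j.
#' @return The scale S2_a.
#' @export
default_marker_scale <- function(prior, pi, allele_freqs) {
  if (pi >= 1) stop("default_marker_scale: pi must be < 1", call. = FALSE)
  het <- sum(allele_freqs * (1 - allele_freqs))
  if (prior$het_factor2) het <- 2 * het
  if (het <= 0)
    stop("default_marker_scale: sum p(1-p) must be > 0", call. = FALSE)
  if (prior$v_a <= 2)
    stop("default_marker_scale: v_a must be > 2", call. = FALSE)
  sigma_a2 <- prior$sigma_s2_tilde / ((1 - pi) * het)
  sigma_a2 * (prior$v_a - 2) / prior$v_a
}

## fill the fit-time prior defaults from the response and allele frequencies
resolve_prior <- function(prior, y, allele_freqs, pi_for_scale) {
  vy <- stats::var(y)
  if (is.na(prior$sigma_s2_tilde)) prior$sigma_s2_tilde <- 0.5 * vy
  if (is.na(prior$S2_a))
    prior$S2_a <- default_marker_scale(prior, pi_for_scale, allele_freqs)
  if (is.na(prior$S2_e))  # mode v S2 / (v + 2) = vy / 2
    prior$S2_e <- 0.5 * vy * (prior$v_e + 2) / prior$v_e
  prior
}

new_posterior_summary <- function(fit, mcmc, model) {
  out <- list(model = model,
              mu_mean = fit$mu_mean,
              effect_means = as.numeric(fit$effect_means),
              effect_sds = if (!is.null(fit$effect_sds))
                as.numeric(fit$effect_sds),
              inclusion_probs = if (!is.null(fit$inclusion_probs))
                as.numeric(fit$inclusion_probs),
              pi_samples = if (!is.null(fit$pi_draws))
                as.numeric(fit$pi_draws),
              variance_samples = list(var_a = as.numeric(fit$var_a_draws),
                                      var_e = as.numeric(fit$var_e_draws)),
              retained_draw_count = fit$retained,
              mcmc = mcmc)
  class(out) <- "posterior_summary"
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("%s posterior: %d markers, %d retained draws\n", x$model,
              length(x$effect_means), x$retained_draw_count))
  if (!is.null(x$pi_samples))
    cat(sprintf("  posterior mean pi = %.3f\n", mean(x$pi_samples)))
  invisible(x)
}

#' Fit Bayesian Ridge Regression by Gibbs sampling
#'
#' One shared Gaussian prior N(0, sigma_a^2) on every standardized-marker
#' effect; flat prior on the intercept; scaled inverse chi-square
#' hyperpriors on sigma_a^2 (df v_a + m at the update) and sigma_e^2 (df
#' v_e + n). Effects updated singly with running-residual bookkeeping.
#'
#' @param y_star Pre-adjusted phenotypes.
#' @param Zstd Standardized marker matrix (rows = records).
#' @param mcmc A [mcmc_config()].
#' @param prior A [prior_spec()]; NA scale entries are resolved at fit time.
#' @param allele_freqs Frequencies for the default scale rule; defaults to
#'   frequencies implied by de-standardizing is unavailable here, so pass
#'   them when using the default rule (otherwise 0.5 is assumed per marker).
#' @param fix_var_a,fix_var_e Optional fixed values disabling the variance
#'   updates (used by the conjugate closed-form cross-checks).
#' @return A `posterior_summary`.
#' @export
fit_brr <- function(y_star, Zstd, mcmc = mcmc_config(),
                    prior = prior_spec(), allele_freqs = NULL,
                    fix_var_a = NULL, fix_var_e = NULL) {
  y <- as.numeric(y_star)
  Zstd <- as.matrix(Zstd)
  stopifnot(nrow(Zstd) == length(y))
  if (is.null(allele_freqs)) allele_freqs <- rep(0.5, ncol(Zstd))
  prior <- resolve_prior(prior, y, allele_freqs, pi_for_scale = 0)
  vy <- stats::var(y)
  set.seed(mcmc$seed)
  fit <- brr_gibbs_cpp(y, Zstd, mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                       prior$v_a, prior$S2_a, prior$v_e, prior$S2_e,
                       var_a0 = if (is.null(fix_var_a)) 0.5 * vy / ncol(Zstd)
                                else fix_var_a,
                       var_e0 = if (is.null(fix_var_e)) 0.5 * vy
                                else fix_var_e,
                       sample_var_a = is.null(fix_var_a),
                       sample_var_e = is.null(fix_var_e))
  new_posterior_summary(fit, mcmc, "BRR")
}

#' Fit Bayes C-pi by Gibbs sampling
#'
#' Adds to the BRR cycle a per-marker inclusion indicator delta_j sampled
#' from its full conditional (marginal-likelihood ratio of inclusion vs
#' exclusion), effect draws only for included markers, pi | delta ~
#' Beta(#excluded + 1, #included + 1) under the Uniform(0,1) prior, and a
#' sigma_a^2 update whose degrees of freedom use the included-marker count.
#'
#' @inheritParams fit_brr
#' @return A `posterior_summary` with `inclusion_probs` and `pi_samples`.
#' @export
fit_bayes_cpi <- function(y_star, Zstd, mcmc = mcmc_config(),
                          prior = prior_spec(), allele_freqs = NULL,
                          fix_var_a = NULL, fix_var_e = NULL) {
  y <- as.numeric(y_star)
  Zstd <- as.matrix(Zstd)
  stopifnot(nrow(Zstd) == length(y))
  if (is.null(allele_freqs)) allele_freqs <- rep(0.5, ncol(Zstd))
  sample_pi <- identical(prior$pi_prior, "uniform")
  pi0 <- if (sample_pi) 0.5 else prior$pi_prior
  prior <- resolve_prior(prior, y, allele_freqs, pi_for_scale = pi0)
  vy <- stats::var(y)
  set.seed(mcmc$seed)
  fit <- cpi_gibbs_cpp(y, Zstd, mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                       prior$v_a, prior$S2_a, prior$v_e, prior$S2_e,
                       var_a0 = if (is.null(fix_var_a)) 0.5 * vy / ncol(Zstd)
                                else fix_var_a,
                       var_e0 = if (is.null(fix_var_e)) 0.5 * vy
                                else fix_var_e,
                       sample_var_a = is.null(fix_var_a),
                       sample_var_e = is.null(fix_var_e),
                       pi0 = pi0, sample_pi = sample_pi)
  if (fit$empty_model_iters > 0.5 * mcmc$n_iter)
    warning("fit_bayes_cpi: all markers excluded for > 50% of the chain; ",
            "check the prior scale", call. = FALSE)
  new_posterior_summary(fit, mcmc, "BayesCpi")
}

#' Predict genomic breeding values for new individuals
#'
#' `y_hat = mu_mean + Zstd_new %*% effect_means`, with the new dosages
#' standardized by the TRAINING means and SDs.
#'
#' @param Gnew A [genotype_matrix()] or dosage matrix (no missing entries),
#'   markers in the training order.
#' @param transform List with `means` and `sds` from
#'   [standardize_markers()] on the training set.
#' @param posterior A `posterior_summary`.
#' @return Named numeric vector of predictions.
#' @export
predict_gebv <- function(Gnew, transform, posterior) {
  X <- if (inherits(Gnew, "genotype_matrix")) Gnew$dosages else as.matrix(Gnew)
  if (anyNA(X))
    stop("predict_gebv: impute missing genotypes first", call. = FALSE)
  if (ncol(X) != length(posterior$effect_means))
    stop("predict_gebv: marker count mismatch with the training fit",
         call. = FALSE)
  Zn <- sweep(sweep(X, 2, transform$means, "-"), 2, transform$sds, "/")
  drop(posterior$mu_mean + Zn %*% posterior$effect_means)
}
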