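## Experimental design and comparison metrics: forward-in-time
## (chronological) split, tuning partition, nested training sub-samples,
## and the metric suite (prediction correlation, MSEP, relative gain,
## predictive bias, Spearman rank correlation, top-ranked agreement).

#' Chronological train / tune / test split
#'
#' The newest `n_test_generations` generations form the testing set, the
#' next-newest `tune_generations` the tuning set, and everything older the
#' training set — mirroring forward prediction of young selection candidates
#' from an older reference population.
#'
#' @param records Data frame with columns `id` and `generation`.
#' @param n_test_generations Generations held out for testing (default 2).
#' @param tune_generations Generations forming the tuning set (default 1).
#' @return List of class `split_plan`: `train_ids`, `tune_ids`, `test_ids`,
#'   `generation_map`.
#' @export
chronological_split <- function(records, n_test_generations = 2L,
                                tune_generations = 1L) {
  gens <- sort(unique(records$generation))
  if (length(gens) < n_test_generations + tune_generations + 1L)
    stop("chronological_split: need at least one training generation ",
         "after removing test and tuning generations", call. = FALSE)
  test_g <- utils::tail(gens, n_test_generations)
  tune_g <- utils::tail(setdiff(gens, test_g), tune_generations)
  train_g <- setdiff(gens, c(test_g, tune_g))
  ids <- as.character(records$id)
  plan <- list(train_ids = ids[records$generation %in% train_g],
               tune_ids = ids[records$generation %in% tune_g],
               test_ids = ids[records$generation %in% test_g],
               generation_map = stats::setNames(records$generation, ids),
               train_generations = train_g, tune_generations = tune_g,
               test_generations = test_g)
  class(plan) <- "split_plan"
  plan
}

#' Nested training sub-samples
#'
#' One random permutation of the training ids; the subset at fraction f is
#' its first round(f * n / 100) elements (round half away from zero), so
#' nesting of the subsets is automatic.
#'
#' @param train_ids Character vector of training ids.
#' @param fractions Ascending percentages in (0, 100]; default the
#'   15-step ladder 1, 3, 5, 7, 10, 15, 20, 30, 40, 50, 60, 70, 80, 90, 100.
#' @param seed Integer seed for the permutation.
#' @return List of class `subsample_ladder`: `fractions`, `subsets` (list of
#'   id vectors), `permutation`.
#' @export
nested_subsamples <- function(train_ids,
                              fractions = c(1, 3, 5, 7, 10, 15, 20, 30, 40,
                                            50, 60, 70, 80, 90, 100),
                              seed = 1L) {
  if (any(diff(fractions) <= 0) || any(fractions <= 0) ||
      any(fractions > 100))
    stop("nested_subsamples: fractions must be ascending in (0, 100]",
         call. = FALSE)
  n <- length(train_ids)
  sizes <- floor(fractions * n / 100 + 0.5)  # round half away from zero
  if (any(sizes < 1))
    stop("nested_subsamples: a fraction yields an empty subset",
         call. = FALSE)
  set.seed(as.integer(seed))
  perm <- sample(as.character(train_ids))
  subsets <- lapply(sizes, function(k) perm[seq_len(k)])
  structure(list(fractions = fractions, subsets = subsets,
                 permutation = perm),
            class = "subsample_ladder")
}

#' Prediction correlation
#'
#' Pearson correlation between pre-adjusted and predicted values; undefined
#' (NA) when either vector is constant.
#'
#' @param y_star_test Pre-adjusted phenotypes of the testing set.
#' @param y_hat_test Predicted values.
#' @return Correlation, or NA if undefined.
#' @export
prediction_correlation <- function(y_star_test, y_hat_test) {
  stopifnot(length(y_star_test) == length(y_hat_test))
  if (length(y_star_test) < 3L) stop("prediction_correlation: need n >= 3",
                                     call. = FALSE)
  if (stats::sd(y_star_test) == 0 || stats::sd(y_hat_test) == 0)
    return(NA_real_)
  stats::cor(y_star_test, y_hat_test)
}

#' Mean square error of prediction
#'
#' `MSEP = sum (y*_i - y_hat_i)^2 / n_test`.
#'
#' @inheritParams prediction_correlation
#' @return Non-negative scalar.
#' @export
msep <- function(y_star_test, y_hat_test) {
  stopifnot(length(y_star_test) == length(y_hat_test),
            length(y_star_test) >= 1L)
  mean((y_star_test - y_hat_test)^2)
}

#' Relative gain
#'
#' `RG = (r1 - r2) / r2 * 100`, the percentage change of a predictive
#' criterion of one method (r1) relative to a baseline (r2).
#'
#' @param r1 Criterion of the method of interest.
#' @param r2 Criterion of the baseline; must be non-zero.
#' @return Percent gain.
#' @export
relative_gain <- function(r1, r2) {
  if (r2 == 0) stop("relative_gain: baseline criterion is zero",
                    call. = FALSE)
  (r1 - r2) / r2 * 100
}

#' Predictive bias (regression slope)
#'
#' Ordinary least-squares slope of the pre-adjusted phenotype regressed on
#' the prediction (y* as response); 1 = unbiased, > 1 = deflated
#' predictions. Set `reverse = TRUE` for the converse regression.
#'
#' @inheritParams prediction_correlation
#' @param reverse Regress y_hat on y_star instead.
#' @return Slope, or NA when the regressor is constant.
#' @export
predictive_bias <- function(y_star_test, y_hat_test, reverse = FALSE) {
  x <- if (reverse) y_star_test else y_hat_test
  y <- if (reverse) y_hat_test else y_star_test
  if (stats::var(x) == 0) return(NA_real_)
  stats::cov(y, x) / stats::var(x)
}

#' Spearman rank correlation between two prediction vectors
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param y_hat_A,y_hat_B Predictions from two methods.
#' @return rho, or NA for constant input.
#' @export
spearman_between <- function(y_hat_A, y_hat_B) {
  stopifnot(length(y_hat_A) == length(y_hat_B))
  if (length(y_hat_A) < 3L) stop("spearman_between: need n >= 3",
                                 call. = FALSE)
  ra <- rank(y_hat_A, ties.method = "average")
  rb <- rank(y_hat_B, ties.method = "average")
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) return(NA_real_)
  stats::cor(ra, rb)
}

#' Agreement on the top-ranked individuals
#'
#' Selects the top k individuals by each prediction (descending value, ties
#' broken by stable id order) and reports 100 * |intersection| / k. `k` may
#' be given directly or as a fraction of n via `k_fraction` (default 10%).
#'
#' @param y_hat_A,y_hat_B Named or unnamed prediction vectors of equal
#'   length (unnamed vectors use positional ids).
#' @param k_fraction Fraction of n selected (ignored when `k` given).
#' @param k Literal selection size.
#' @return Percent overlap in \[0, 100\].
#' @export
topk_agreement <- function(y_hat_A, y_hat_B, k_fraction = 0.10, k = NULL) {
  stopifnot(length(y_hat_A) == length(y_hat_B))
  n <- length(y_hat_A)
  if (is.null(k)) k <- max(1L, floor(k_fraction * n + 0.5))
  if (k > n) stop("topk_agreement: k exceeds the number of individuals",
                  call. = FALSE)
  ids <- names(y_hat_A)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  top <- function(v) ids[order(-v, seq_len(n))][seq_len(k)]
  100 * length(intersect(top(y_hat_A), top(y_hat_B))) / k
}

#' Compare prediction methods along the sub-sampling ladder
#'
#' For each ladder fraction: the Bayesian models train on the subset alone,
#' their WT variants on subset plus tuning set, and the MLP trains on the
#' subset with early stopping monitored on the tuning set. All methods are
#' evaluated on the one fixed testing set. Model fits never see test-set
#' phenotypes. A failing method is recorded per cell and the run continues.
#'
#' @param y_star Named vector of pre-adjusted phenotypes covering train,
#'   tune and test ids.
#' @param geno A complete (imputed) [genotype_matrix()] covering the same
#'   ids.
#' @param split A [chronological_split()] plan.
#' @param ladder A [nested_subsamples()] ladder over `split$train_ids`.
#' @param methods Subset of `c("BRR", "BayesCpi", "BRR-WT", "BayesCpi-WT",
#'   "DNN")`.
#' @param mcmc A [mcmc_config()] for the Bayesian fits.
#' @param prior A [prior_spec()].
#' @param dnn_arch An [architecture()] for the MLP (fixed across fractions),
#'   or NULL with `dnn_search` settings to search per fraction.
#' @param dnn_config A [train_config()].
#' @param dnn_search NULL, or a list(n_candidates, grids) enabling random
#'   architecture search per fraction.
#' @param k_fraction Top-ranked agreement selection fraction.
#' @param seed Base seed; per-fraction and per-method seeds derive from it.
#' @return List of class `evaluation_report`: `metrics` (tidy data frame:
#'   method, fraction, metric, value), `pairwise` (method pair rank
#'   agreement), `predictions` (per fraction, named matrix of test
#'   predictions), `test_checksum`.
#' @export
run_comparison <- function(y_star, geno, split, ladder,
                           methods = c("BRR", "BayesCpi", "DNN"),
                           mcmc = mcmc_config(), prior = prior_spec(),
                           dnn_arch = NULL, dnn_config = train_config(),
                           dnn_search = NULL, k_fraction = 0.10,
                           seed = 1L) {
  methods <- match.arg(methods, c("BRR", "BayesCpi", "BRR-WT",
                                  "BayesCpi-WT", "DNN"),
                       several.ok = TRUE)
  X <- geno$dosages
  stopifnot(!anyNA(X))
  ids_all <- rownames(X)
  need <- c(split$train_ids, split$tune_ids, split$test_ids)
  if (!all(need %in% ids_all) || !all(need %in% names(y_star)))
    stop("run_comparison: genotypes/y_star must cover all split ids",
         call. = FALSE)
  test_ids <- split$test_ids
  y_test <- y_star[test_ids]
  test_checksum <- sum(as.numeric(utf8ToInt(paste(test_ids, collapse = ""))))

  ## markers are standardized once on the full genotyped panel: allele
  ## frequencies are population quantities known for all candidates, and a
  ## shared transform keeps small sub-samples (where individual markers can
  ## be monomorphic) on the same scale as the test set
  tr <- standardize_markers(X)
  p_all <- geno$allele_freqs
  Z_test <- tr$Z[test_ids, , drop = FALSE]

  rows <- list()
  pair_rows <- list()
  preds_by_fraction <- list()

  fit_bayes_on <- function(ids, model, chain_seed) {
    mc <- mcmc; mc$seed <- chain_seed
    post <- if (model == "BRR")
      fit_brr(y_star[ids], tr$Z[ids, , drop = FALSE], mc, prior,
              allele_freqs = p_all)
    else
      fit_bayes_cpi(y_star[ids], tr$Z[ids, , drop = FALSE], mc, prior,
                    allele_freqs = p_all)
    drop(post$mu_mean + Z_test %*% post$effect_means)
  }

  for (f in seq_along(ladder$fractions)) {
    frac <- ladder$fractions[f]
    sub_ids <- ladder$subsets[[f]]
    wt_ids <- union(sub_ids, split$tune_ids)
    stopifnot(length(wt_ids) > length(sub_ids) || !length(split$tune_ids))
    preds <- list()
    for (meth in methods) {
      chain_seed <- derive_seed(seed, paste0(meth, "_f", frac))
      res <- tryCatch({
        switch(meth,
          "BRR" = fit_bayes_on(sub_ids, "BRR", chain_seed),
          "BayesCpi" = fit_bayes_on(sub_ids, "BayesCpi", chain_seed),
          "BRR-WT" = fit_bayes_on(wt_ids, "BRR", chain_seed),
          "BayesCpi-WT" = fit_bayes_on(wt_ids, "BayesCpi", chain_seed),
          "DNN" = {
            Zsub <- tr$Z[sub_ids, , drop = FALSE]
            Ztune <- tr$Z[split$tune_ids, , drop = FALSE]
            cfg <- dnn_config; cfg$seed <- chain_seed
            fit <- if (is.null(dnn_search)) {
              train_mlp(dnn_arch, Zsub, y_star[sub_ids], Ztune,
                        y_star[split$tune_ids], cfg)
            } else {
              random_search(Zsub, y_star[sub_ids], Ztune,
                            y_star[split$tune_ids], cfg,
                            n_candidates = dnn_search$n_candidates,
                            grids = dnn_search$grids,
                            seed = chain_seed)$best
            }
            mlp_forward(fit$weights, Z_test)
          })
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = meth, fraction = frac, metric = "error",
          value = NA_real_, note = conditionMessage(res),
          stringsAsFactors = FALSE)
        next
      }
      preds[[meth]] <- stats::setNames(res, test_ids)
      vals <- c(prediction_correlation = prediction_correlation(y_test, res),
                msep = msep(y_test, res),
                bias_slope = predictive_bias(y_test, res))
      rows[[length(rows) + 1L]] <- data.frame(
        method = meth, fraction = frac, metric = names(vals),
        value = as.numeric(vals), note = "", stringsAsFactors = FALSE)
    }
    if (length(preds) >= 2L) {
      nm <- names(preds)
      for (i in seq_along(nm)[-length(nm)]) for (j in (i + 1):length(nm)) {
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          method_A = nm[i], method_B = nm[j], fraction = frac,
          spearman = spearman_between(preds[[i]], preds[[j]]),
          topk_agreement = topk_agreement(preds[[i]], preds[[j]],
                                          k_fraction = k_fraction),
          stringsAsFactors = FALSE)
      }
    }
    preds_by_fraction[[as.character(frac)]] <- preds
  }
  structure(list(metrics = do.call(rbind, rows),
                 pairwise = if (length(pair_rows)) do.call(rbind, pair_rows),
                 predictions = preds_by_fraction,
                 test_ids = test_ids, test_checksum = test_checksum),
            class = "evaluation_report")
}

#' Write an evaluation report as tidy CSV
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(report$pairwise))
    utils::write.csv(report$pairwise, file.path(dir, "pairwise.csv"),
                     row.names = FALSE)
  invisible(dir)
}
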