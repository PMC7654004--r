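#!/usr/bin/env Rscript
## Stage 4: step two, Bayesian half. Fits Bayesian Ridge Regression and
## Bayes C-pi to the pre-adjusted trait on the standardized markers of the
## chronological training set, then predicts GEBV for the testing
## generations. Chains here are desk-scale (6,000 cycles, 2,000 warm-up,
## thin 5); the protocol-scale settings (30,000 / 20,000 / 5) are the
## package defaults.

library(gpcurve)

outdir <- "results/step2_bayes"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

G <- readRDS("results/qc/genotypes_clean.rds")
phen <- read.csv("results/qc/phenotypes_clean.csv", stringsAsFactors = FALSE)
pre <- read.csv("results/step1/preadjusted.csv", stringsAsFactors = FALSE)
y_star <- setNames(pre$y_star, pre$id)

split <- chronological_split(phen, n_test_generations = 1,
                             tune_generations = 1)
tr <- standardize_markers(G)
train <- split$train_ids
mc <- mcmc_config(6000, 2000, 5, seed = 11)

brr <- fit_brr(y_star[train], tr$Z[train, ], mc,
               allele_freqs = G$allele_freqs)
cpi <- fit_bayes_cpi(y_star[train], tr$Z[train, ], mc,
                     allele_freqs = G$allele_freqs)

write.csv(data.frame(marker = colnames(G$dosages),
                     brr_effect = brr$effect_means,
                     cpi_effect = cpi$effect_means,
                     cpi_inclusion = cpi$inclusion_probs),
          file.path(outdir, "marker_effects.csv"), row.names = FALSE)
write.csv(data.frame(draw = seq_along(cpi$pi_samples),
                     pi = cpi$pi_samples,
                     var_a = cpi$variance_samples$var_a,
                     var_e = cpi$variance_samples$var_e),
          file.path(outdir, "cpi_chain.csv"), row.names = FALSE)

test <- split$test_ids
gebv <- data.frame(
  id = test,
  brr = drop(brr$mu_mean + tr$Z[test, ] %*% brr$effect_means),
  cpi = drop(cpi$mu_mean + tr$Z[test, ] %*% cpi$effect_means))
write.csv(gebv, file.path(outdir, "gebv_test.csv"), row.names = FALSE)

cat(sprintf("trained on %d records, predicted %d test animals\n",
            length(train), length(test)))
cat(sprintf("BRR:      r(y*, GEBV) = %.3f\n",
            prediction_correlation(y_star[test], gebv$brr)))
cat(sprintf("Bayes Cpi: r(y*, GEBV) = %.3f, posterior mean pi = %.3f\n",
            prediction_correlation(y_star[test], gebv$cpi),
            mean(cpi$pi_samples)))
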