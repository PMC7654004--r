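#!/usr/bin/env Rscript
## Stage 6: the sub-sampling comparison. Nested training subsets (each
## larger subset containing every smaller one), BRR and Bayes C-pi fit with
## and without the tuning set (WT variants), the MLP early-stopped on the
## tuning set, all scored on the fixed testing generations by prediction
## correlation, MSEP, bias slope, rank correlation and top-ranked
## agreement. A reduced ladder keeps the desk-scale run in minutes; the
## full 15-step ladder is the package default.

library(gpcurve)

outdir <- "results/evaluation"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

G <- readRDS("results/qc/genotypes_clean.rds")
phen <- read.csv("results/qc/phenotypes_clean.csv", stringsAsFactors = FALSE)
pre <- read.csv("results/step1/preadjusted.csv", stringsAsFactors = FALSE)
y_star <- setNames(pre$y_star, pre$id)

split <- chronological_split(phen, n_test_generations = 1,
                             tune_generations = 1)
ladder <- nested_subsamples(split$train_ids,
                            fractions = c(5, 10, 20, 40, 70, 100),
                            seed = 3)

report <- run_comparison(
  y_star, G, split, ladder,
  methods = c("BRR", "BayesCpi", "BRR-WT", "BayesCpi-WT", "DNN"),
  mcmc = mcmc_config(4000, 1500, 5, seed = 5),
  dnn_arch = architecture(1, 16, l2_lambda = 0.01, dropout_keep = 0.9),
  dnn_config = train_config(max_epochs = 150, seed = 5),
  seed = 9)
write_evaluation_report(report, outdir)

m <- report$metrics
rc <- m[m$metric == "prediction_correlation", ]
wide <- reshape(rc[, c("method", "fraction", "value")],
                idvar = "fraction", timevar = "method", direction = "wide")
names(wide) <- sub("value\\.", "", names(wide))
cat("prediction correlation by training-set fraction:\n")
print(wide, row.names = FALSE, digits = 3)

gain <- function(meth, base, metric_) {
  vapply(unique(m$fraction), function(f) {
    v1 <- m$value[m$method == meth & m$fraction == f & m$metric == metric_]
    v2 <- m$value[m$method == base & m$fraction == f & m$metric == metric_]
    relative_gain(v1, v2)
  }, numeric(1))
}
cat("\nrelative gain of DNN vs BRR (correlation, %):\n")
print(round(gain("DNN", "BRR", "prediction_correlation"), 1))
cat("relative gain of DNN vs BRR (MSEP, %; negative = DNN better):\n")
print(round(gain("DNN", "BRR", "msep"), 1))
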