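#!/usr/bin/env Rscript
## Stage 5: step two, neural half. Random architecture search for the
## multilayer perceptron on the training set, early-stopped on the tuning
## generation. Desk-scale search: 12 candidates over reduced grids (the
## protocol grids and 200 candidates are available via table_grids()).

library(gpcurve)

outdir <- "results/step2_dnn"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

G <- readRDS("results/qc/genotypes_clean.rds")
phen <- read.csv("results/qc/phenotypes_clean.csv", stringsAsFactors = FALSE)
pre <- read.csv("results/step1/preadjusted.csv", stringsAsFactors = FALSE)
y_star <- setNames(pre$y_star, pre$id)

split <- chronological_split(phen, n_test_generations = 1,
                             tune_generations = 1)
tr <- standardize_markers(G)
train <- split$train_ids; tune <- split$tune_ids; test <- split$test_ids

grids <- list(units = c(4, 8, 16, 32), layers = 1:3,
              dropout = c(0.7, 0.9, 1), l2 = c(0, 0.01, 0.05))
cfg <- train_config(max_epochs = 200, seed = 7)
search <- random_search(tr$Z[train, ], y_star[train],
                        tr$Z[tune, ], y_star[tune],
                        cfg, n_candidates = 12, grids = grids, seed = 7)

write.csv(search$leaderboard, file.path(outdir, "leaderboard.csv"),
          row.names = FALSE)
pred <- mlp_forward(search$best$weights, tr$Z[test, ])
write.csv(data.frame(id = test, dnn = pred),
          file.path(outdir, "dnn_test.csv"), row.names = FALSE)

best <- search$leaderboard[search$best_index, ]
cat(sprintf("best of %d architectures: %d layer(s) [%s units], L2 = %.3f, keep = %.1f\n",
            nrow(search$leaderboard), best$layers, best$units, best$l2,
            best$dropout_keep))
cat(sprintf("tuning r = %.3f, tuning MSEP = %.1f, stopped at epoch %d (%s)\n",
            best$tune_cor, best$tune_mse, search$best$stopped_epoch,
            search$best$stop_reason))
cat(sprintf("test r(y*, prediction) = %.3f\n",
            prediction_correlation(y_star[test], pred)))
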