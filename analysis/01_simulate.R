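#!/usr/bin/env Rscript
## Stage 1: generate the synthetic broiler-like population that stands in
## for the proprietary data — a 5-generation pedigree, gene-dropped SNP
## genotypes with 1% missing calls, and a body-weight-like trait with
## h2 = 0.23, a 0.05 maternal permanent-environment fraction, sex and
## hatch-batch fixed effects. Writes the raw inputs consumed by stage 2.

library(gpcurve)

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_individuals = 1500, n_markers = 400,
                  n_generations = 5, missing_rate = 0.01, seed = 20260901)
pop <- simulate_population(cfg)

write_raw(pop$genotypes, file.path(outdir, "genotypes.raw"), pop$pedigree)
write.csv(pop$pedigree, file.path(outdir, "pedigree.csv"), row.names = FALSE)
write.csv(pop$phenotypes, file.path(outdir, "phenotypes.csv"),
          row.names = FALSE)
saveRDS(pop$truth, file.path(outdir, "truth.rds"))  # scratch ground truth

cat(sprintf("simulated %d animals (%d phenotyped), %d markers\n",
            nrow(pop$pedigree), nrow(pop$phenotypes),
            ncol(pop$genotypes$dosages)))
cat(sprintf("trait: mean %.1f g, SD %.1f g, %.2f%% missing genotype calls\n",
            mean(pop$phenotypes$weight), sd(pop$phenotypes$weight),
            100 * mean(is.na(pop$genotypes$dosages))))
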