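#!/usr/bin/env Rscript
## Stage 2: marker and phenotype quality control. Markers failing
## MAF >= 0.01, call rate >= 95% or Hardy-Weinberg P >= 1e-10 are removed,
## the survivors mean-imputed; trait records beyond +/- 3.5 SD of their
## contemporary-group mean are dropped.

library(gpcurve)

datadir <- "results/data"
outdir <- "results/qc"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

G <- read_genotypes(file.path(datadir, "genotypes.raw"))
phen <- read.csv(file.path(datadir, "phenotypes.csv"),
                 stringsAsFactors = FALSE)

thr <- qc_thresholds()  # the study's filter values
fm <- filter_markers(G, thr)
write_qc_report(fm$report, file.path(outdir, "marker_qc.csv"))
Gc <- impute_missing(fm$genotypes)
saveRDS(Gc, file.path(outdir, "genotypes_clean.rds"))  # scratch hand-off

keep <- remove_outliers(phen$weight, phen$contemporary_group,
                        z = thr$outlier_z)
removed <- nrow(phen) - length(keep)
phen_kept <- phen[keep, ]
write.csv(phen_kept, file.path(outdir, "phenotypes_clean.csv"),
          row.names = FALSE)

tab <- table(fm$report$reason[!fm$report$kept])
cat(sprintf("markers: %d in, %d kept (%s removed)\n", nrow(fm$report),
            sum(fm$report$kept),
            paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
cat(sprintf("phenotypes: %d in, %d kept, %d contemporary-group outliers\n",
            nrow(phen), length(keep), removed))
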