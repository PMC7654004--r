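## Marker and phenotype quality control: MAF, call rate, Hardy-Weinberg
## goodness-of-fit, mean imputation and contemporary-group outlier removal.

#' QC thresholds
#'
#' Default values are the filters used for the broiler panel this package
#' emulates: MAF < 0.01, call rate < 95%, Hardy-Weinberg P < 1e-10, and trait
#' records beyond +/- 3.5 SD of their contemporary-group mean.
#'
#' @param maf_min Minimum minor allele frequency.
#' @param call_rate_min Minimum fraction of non-missing calls.
#' @param hwe_p_min Minimum Hardy-Weinberg goodness-of-fit P value.
#' @param outlier_z Contemporary-group outlier threshold in SD units.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, call_rate_min = 0.95,
                          hwe_p_min = 1e-10, outlier_z = 3.5) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            call_rate_min >= 0, call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1, outlier_z > 0)
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min, outlier_z = outlier_z),
            class = "qc_thresholds")
}

#' Per-marker QC statistics
#'
#' Computes minor allele frequency, call rate, and a 1-df chi-square
#' goodness-of-fit P value of the observed genotype counts against
#' Hardy-Weinberg expectations, all over the non-missing entries of one
#' dosage column. For a monomorphic or all-missing column the HWE test is
#' undefined and P = 1 is returned (no departure is testable); an all-missing
#' column additionally reports maf = NA and call_rate = 0 so it fails the
#' call-rate filter downstream.
#'
#' @param column Numeric vector of dosages in \{0, 1, 2, NA\}.
#' @return List with `maf`, `call_rate`, `hwe_p`.
#' @export
marker_stats <- function(column) {
  obs <- column[!is.na(column)]
  if (!all(obs %in% c(0, 1, 2)))
    stop("marker_stats: dosages must be 0, 1, 2 or NA", call. = FALSE)
  call_rate <- length(obs) / length(column)
  if (!length(obs))
    return(list(maf = NA_real_, call_rate = 0, hwe_p = 1))
  p <- mean(obs) / 2
  maf <- min(p, 1 - p)
  n <- length(obs)
  counts <- c(sum(obs == 2), sum(obs == 1), sum(obs == 0))
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(expected == 0)) {
    ## p = 0 or 1: every expected-nonzero class matches observed exactly
    hwe_p <- 1
  } else {
    x2 <- sum((counts - expected)^2 / expected)
    hwe_p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }
  list(maf = maf, call_rate = call_rate, hwe_p = hwe_p)
}

#' Filter markers on MAF, call rate and Hardy-Weinberg equilibrium
#'
#' A marker is kept iff maf >= maf_min, call_rate >= call_rate_min and
#' hwe_p >= hwe_p_min. Removals are attributed to the first violated
#' criterion in the order MAF, call rate, HWE (an all-missing marker has
#' undefined MAF and is attributed to call rate). The kept set itself is
#' order-invariant. Markers named in `exclude` (e.g. a pre-supplied
#' non-autosome / unmapped list) are removed first.
#'
#' @param G A [genotype_matrix()].
#' @param thr A [qc_thresholds()].
#' @param exclude Optional character vector of marker names to drop a priori.
#' @return List with `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (data frame: marker, maf, call_rate, hwe_p, kept, reason).
#' @export
filter_markers <- function(G, thr = qc_thresholds(), exclude = NULL) {
  stats_list <- apply(G$dosages, 2, marker_stats)
  maf <- vapply(stats_list, `[[`, numeric(1), "maf")
  cr <- vapply(stats_list, `[[`, numeric(1), "call_rate")
  hwe <- vapply(stats_list, `[[`, numeric(1), "hwe_p")
  marker <- colnames(G$dosages)

  reason <- rep(NA_character_, length(marker))
  if (!is.null(exclude)) reason[marker %in% exclude] <- "excluded_list"
  fail_maf <- !is.na(maf) & maf < thr$maf_min
  fail_cr <- cr < thr$call_rate_min
  fail_hwe <- !is.na(hwe) & hwe < thr$hwe_p_min
  reason[is.na(reason) & fail_maf] <- "maf"
  reason[is.na(reason) & fail_cr] <- "call_rate"
  reason[is.na(reason) & fail_hwe] <- "hwe"
  kept <- is.na(reason)

  report <- data.frame(marker = marker, maf = maf, call_rate = cr,
                       hwe_p = hwe, kept = kept,
                       reason = ifelse(kept, "", reason),
                       stringsAsFactors = FALSE)
  if (!any(kept))
    stop("filter_markers: no markers survive QC (empty panel)", call. = FALSE)
  Gf <- genotype_matrix(G$dosages[, kept, drop = FALSE])
  list(genotypes = Gf, report = report)
}

#' Mean-impute missing genotype calls
#'
#' Each missing entry is replaced by its marker's observed mean dosage
#' (real-valued), which preserves every column mean exactly.
#'
#' @param G A [genotype_matrix()].
#' @return A complete [genotype_matrix()]-like object (dosages may be
#'   non-integer after imputation, so the result is a plain list with the
#'   same fields).
#' @export
impute_missing <- function(G) {
  X <- G$dosages
  if (!anyNA(X)) return(G)
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(mu))
    stop("impute_missing: all-missing marker present; run filter_markers first",
         call. = FALSE)
  nas <- which(is.na(X), arr.ind = TRUE)
  X[nas] <- mu[nas[, 2]]
  out <- list(ids = G$ids, dosages = X, allele_freqs = colMeans(X) / 2)
  class(out) <- "genotype_matrix"
  out
}

#' Remove contemporary-group outliers
#'
#' A record is kept iff its absolute deviation from its contemporary-group
#' mean is at most `z` group standard deviations, with the mean and sample SD
#' (n - 1 denominator) computed including the record itself. Records in
#' singleton groups are kept with a warning (their SD is undefined); a group
#' with zero SD keeps all its records (deviation 0).
#'
#' @param y Numeric trait values.
#' @param groups Contemporary-group labels, same length as `y`.
#' @param z Threshold in SD units (default 3.5).
#' @return Integer indices of the kept records.
#' @export
remove_outliers <- function(y, groups, z = 3.5) {
  stopifnot(length(y) == length(groups))
  groups <- as.character(groups)
  keep <- logical(length(y))
  singletons <- FALSE
  for (g in unique(groups)) {
    i <- which(groups == g)
    if (length(i) < 2L) {
      keep[i] <- TRUE
      singletons <- TRUE
      next
    }
    mu <- mean(y[i]); s <- stats::sd(y[i])
    dev <- abs(y[i] - mu)
    keep[i] <- if (s == 0) TRUE else dev <= z * s
  }
  if (singletons)
    warning("remove_outliers: singleton contemporary group(s) kept unchecked",
            call. = FALSE)
  which(keep)
}

#' Write a marker QC report as CSV
#'
#' @param report Report data frame from [filter_markers()].
#' @param path Output file.
#' @export
write_qc_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
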