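## Synthetic population generator: pedigree, SNP genotypes and a
## body-weight-like trait with additive, maternal permanent-environment and
## residual components. Stands in for the proprietary broiler data so every
## downstream stage is testable without a download.

#' Simulation configuration
#'
#' Collects the parameters of the synthetic population in one validated
#' object. Defaults emulate a moderate-heritability growth trait recorded on
#' a closed purebred line: h2 = 0.23 of the (random-part) phenotypic
#' variance from additive gene action, 0.05 from a maternal
#' permanent-environment effect shared by full/maternal sibs, a sex
#' dimorphism of about 300 g at weighing age and hatch-batch contemporary
#' groups.
#'
#' @param n_individuals Total animals across all generations.
#' @param n_markers Number of biallelic SNP markers.
#' @param n_generations Number of discrete, non-overlapping generations
#'   (generation 1 founders; phenotypes are recorded on generations >= 2).
#' @param maf_range Length-2 numeric in (0, 0.5]; marker allele frequencies
#'   are drawn uniformly from this interval.
#' @param prop_qtl Fraction of markers with non-zero effect (1 - pi_true).
#' @param h2_target Narrow-sense heritability of the random part of the
#'   trait.
#' @param c2_target Maternal permanent-environment fraction of the random
#'   part.
#' @param n_dams Breeding dams used per generation (maternal sibships arise
#'   from their reuse).
#' @param n_sires Breeding sires per generation; default about one per
#'   three dams, keeping within-generation relatedness modest.
#' @param n_contemporary_groups Total contemporary (hatch-batch) groups
#'   across the phenotyped generations.
#' @param sex_effect Fixed male-minus-female difference, trait units.
#' @param trait_mean Overall trait mean, trait units.
#' @param phen_var Variance of the random part (u + c + e), trait units^2.
#' @param cg_sd Standard deviation of the fixed contemporary-group effects.
#' @param missing_rate Fraction of genotype calls set missing.
#' @param seed Integer seed; every generator call is reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1500L,
                       n_markers = 500L,
                       n_generations = 5L,
                       maf_range = c(0.05, 0.5),
                       prop_qtl = 0.10,
                       h2_target = 0.23,
                       c2_target = 0.05,
                       n_dams = 75L,
                       n_sires = max(2L, round(n_dams / 3)),
                       n_contemporary_groups = 20L,
                       sex_effect = 300,
                       trait_mean = 2141.8,
                       phen_var = 18939.6,
                       cg_sd = 150,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_markers = as.integer(n_markers),
    n_generations = as.integer(n_generations),
    maf_range = as.numeric(maf_range),
    prop_qtl = prop_qtl,
    h2_target = h2_target,
    c2_target = c2_target,
    n_dams = as.integer(n_dams),
    n_sires = as.integer(n_sires),
    n_contemporary_groups = as.integer(n_contemporary_groups),
    sex_effect = sex_effect,
    trait_mean = trait_mean,
    phen_var = phen_var,
    cg_sd = cg_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(c(n_individuals, n_markers, n_generations, n_dams, n_sires,
              n_contemporary_groups) < 1L))
      stop("sim_config: all counts must be positive", call. = FALSE)
    if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
        maf_range[1] <= 0 || maf_range[2] > 0.5)
      stop("sim_config: maf_range must lie within (0, 0.5]", call. = FALSE)
    if (prop_qtl <= 0 || prop_qtl > 1)
      stop("sim_config: prop_qtl must be in (0, 1]", call. = FALSE)
    if (h2_target < 0 || c2_target < 0 || h2_target + c2_target >= 1)
      stop("sim_config: h2_target + c2_target must be < 1", call. = FALSE)
    if (missing_rate < 0 || missing_rate >= 1)
      stop("sim_config: missing_rate must be in [0, 1)", call. = FALSE)
  })
  invisible(cfg)
}

#' Construct a genotype matrix object
#'
#' @param dosages n x m numeric matrix of 0/1/2 allele dosages (NA = missing);
#'   rownames are individual ids.
#' @param allele_freqs Optional per-marker counted-allele frequency; computed
#'   from the non-missing dosages when omitted.
#' @return An object of class `genotype_matrix` with fields `ids`, `dosages`,
#'   `allele_freqs`.
#' @export
genotype_matrix <- function(dosages, allele_freqs = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("A%05d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("snp%04d", seq_len(ncol(dosages)))
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok))
    stop("genotype_matrix: dosages must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(allele_freqs))
    allele_freqs <- colMeans(dosages, na.rm = TRUE) / 2
  allele_freqs[is.nan(allele_freqs)] <- NA_real_
  if (length(allele_freqs) != ncol(dosages))
    stop("genotype_matrix: allele_freqs length must equal marker count",
         call. = FALSE)
  structure(list(ids = rownames(dosages), dosages = dosages,
                 allele_freqs = as.numeric(allele_freqs)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Simulate SNP genotypes
#'
#' Marker allele frequencies p_j are drawn Uniform(maf_range). Without a
#' pedigree every dosage is an independent Binomial(2, p_j) draw (markers in
#' Hardy-Weinberg proportions, no LD, no family structure). With a pedigree,
#' founders are drawn Binomial(2, p_j) and each descendant receives one
#' allele from each parent by Mendelian transmission (gene dropping), so
#' relatives' genotypes are correlated according to the pedigree while
#' markers remain mutually independent.
#'
#' @param n Individuals (ignored when `pedigree` is supplied).
#' @param m Markers.
#' @param maf_range Length-2 frequency interval in (0, 0.5].
#' @param missing_rate Fraction of calls masked to NA.
#' @param seed Integer seed.
#' @param pedigree Optional data frame with columns id, sire, dam in
#'   parent-before-offspring order (as from [simulate_pedigree()]).
#' @return A [genotype_matrix()]; attribute `p_sim` stores the generating
#'   frequencies.
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = 1L,
                               pedigree = NULL) {
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("simulate_genotypes: maf_range must lie within (0, 0.5]",
         call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("simulate_genotypes: missing_rate must be in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  if (!is.null(pedigree)) n <- nrow(pedigree)
  if (n < 1 || m < 1)
    stop("simulate_genotypes: n and m must be >= 1", call. = FALSE)
  p <- runif(m, maf_range[1], maf_range[2])

  if (is.null(pedigree)) {
    X <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
    ids <- sprintf("A%05d", seq_len(n))
  } else {
    ids <- as.character(pedigree$id)
    idx <- stats::setNames(seq_len(n), ids)
    sire_i <- ifelse(is.na(pedigree$sire), 0L, idx[as.character(pedigree$sire)])
    dam_i <- ifelse(is.na(pedigree$dam), 0L, idx[as.character(pedigree$dam)])
    if (any(sire_i >= seq_len(n) & sire_i > 0) ||
        any(dam_i >= seq_len(n) & dam_i > 0))
      stop("simulate_genotypes: pedigree must list parents before offspring",
           call. = FALSE)
    X <- matrix(0L, nrow = n, ncol = m)
    for (i in seq_len(n)) {
      from_sire <- if (sire_i[i] > 0) rbinom(m, 1L, X[sire_i[i], ] / 2)
                   else rbinom(m, 1L, p)
      from_dam <- if (dam_i[i] > 0) rbinom(m, 1L, X[dam_i[i], ] / 2)
                  else rbinom(m, 1L, p)
      X[i, ] <- from_sire + from_dam
    }
  }
  rownames(X) <- ids
  colnames(X) <- sprintf("snp%04d", seq_len(m))
  if (missing_rate > 0) {
    mask <- runif(length(X)) < missing_rate
    X[mask] <- NA
  }
  G <- genotype_matrix(X)
  attr(G, "p_sim") <- p
  G
}

#' Simulate a discrete-generation pedigree
#'
#' Generation 1 holds unrelated founders; every later generation's offspring
#' draw a sire and a dam from the breeding animals of the immediately
#' preceding generation, so parents always belong to an earlier generation
#' and maternal sibships arise from dam reuse. Each phenotyped generation is
#' split into hatch-batch contemporary groups.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns id, sire, dam, generation,
#'   contemporary_group, sex, in parent-before-offspring order.
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "pedigree"))
  G <- config$n_generations
  n <- config$n_individuals
  if (config$n_dams < 1L) stop("simulate_pedigree: n_dams must be >= 1",
                               call. = FALSE)
  n_founders <- if (G == 1L) n else max(config$n_dams + config$n_sires,
                                        round(n / G))
  n_founders <- min(n_founders, n)
  per_gen <- if (G == 1L) integer(0) else {
    rest <- n - n_founders
    sizes <- rep(rest %/% (G - 1L), G - 1L)
    if (rest %% (G - 1L) > 0)
      sizes[seq_len(rest %% (G - 1L))] <- sizes[seq_len(rest %% (G - 1L))] + 1L
    sizes
  }
  counts <- c(n_founders, per_gen)
  total <- sum(counts)
  id <- sprintf("A%05d", seq_len(total))
  generation <- rep(seq_len(G), counts)
  ## alternate sexes within generation so both sexes always exist, then the
  ## draw of breeders below randomizes which animals are used
  sex <- unlist(lapply(counts, function(k) {
    s <- rep(c("M", "F"), length.out = k)
    sample(s)
  }), use.names = FALSE)
  sire <- rep(NA_character_, total)
  dam <- rep(NA_character_, total)
  for (g in seq_len(G)[-1]) {
    prev <- which(generation == g - 1L)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop("simulate_pedigree: a generation lacks one sex entirely",
           call. = FALSE)
    sires_g <- sample(males, min(config$n_sires, length(males)))
    dams_g <- sample(females, min(config$n_dams, length(females)))
    off <- which(generation == g)
    sire[off] <- id[sample(sires_g, length(off), replace = TRUE)]
    dam[off] <- id[sample(dams_g, length(off), replace = TRUE)]
  }
  ## contemporary groups only for phenotyped generations (>= 2)
  cg <- rep(NA_character_, total)
  if (G > 1L) {
    per_gen_cg <- max(1L, round(config$n_contemporary_groups / (G - 1L)))
    for (g in seq_len(G)[-1]) {
      off <- which(generation == g)
      batch <- sample(rep(seq_len(per_gen_cg), length.out = length(off)))
      cg[off] <- sprintf("g%02d_b%02d", g, batch)
    }
  } else {
    cg[] <- "g01_b01"
  }
  data.frame(id = id, sire = sire, dam = dam, generation = generation,
             contemporary_group = cg, sex = sex, stringsAsFactors = FALSE)
}

#' Simulate phenotypes on a genotyped, pedigreed population
#'
#' Builds the trait as intercept + sex + contemporary group + u + c + e:
#' breeding values u = Z a from a sparse set of QTL effects (fraction
#' `prop_qtl` of markers, Gaussian), a maternal permanent-environment effect
#' c shared by a dam's offspring, and an i.i.d. Gaussian residual. Each
#' random component is rescaled empirically (divide by its realized SD) so
#' the model-scale variance components hit `h2_target * phen_var` and
#' `c2_target * phen_var` exactly per replicate; for the additive component
#' the realized-SD target carries a relatedness correction (see the
#' source) so that among relatives the implied sigma2_u, the quantity REML
#' estimates, is on target. Only non-founder generations receive
#' phenotypes.
#'
#' @param G A [genotype_matrix()] covering the pedigree ids.
#' @param pedigree Output of [simulate_pedigree()].
#' @param config The [sim_config()] used to generate both.
#' @return List with `phenotypes` (data frame: id, sire, dam, generation,
#'   contemporary_group, sex, dam_id, weight) and `truth` (marker_effects,
#'   breeding_values, maternal_effects, fixed_effects, residuals, true_vc).
#' @export
simulate_phenotypes <- function(G, pedigree, config) {
  validate_sim_config(config)
  if (config$h2_target + config$c2_target >= 1)
    stop("simulate_phenotypes: h2_target + c2_target must be < 1",
         call. = FALSE)
  if (!all(pedigree$id %in% G$ids))
    stop("simulate_phenotypes: genotypes and pedigree must share ids",
         call. = FALSE)
  set.seed(derive_seed(config$seed, "phenotypes"))

  rec <- if (config$n_generations == 1L) pedigree
         else pedigree[pedigree$generation >= 2L, , drop = FALSE]
  n <- nrow(rec)
  m <- config$n_markers
  vp <- config$phen_var

  Z <- G$dosages[match(rec$id, G$ids), , drop = FALSE]
  if (anyNA(Z)) {  # small missing fractions: mean-impute for the truth only
    mu_col <- colMeans(Z, na.rm = TRUE)
    nas <- which(is.na(Z), arr.ind = TRUE)
    Z[nas] <- mu_col[nas[, 2]]
  }
  Zc <- sweep(Z, 2, colMeans(Z), "-")

  n_qtl <- max(1L, round(config$prop_qtl * m))
  qtl <- sample.int(m, n_qtl)
  a <- numeric(m)
  a[qtl] <- rnorm(n_qtl)
  u <- drop(Zc %*% a)
  ## Rescale so the *model-scale* additive variance hits the target: among
  ## relatives the sample variance of u underestimates sigma2_u by the
  ## factor kappa = (tr(A) - 1'A1/n) / (n - 1), so the realized SD is set
  ## to sqrt(h2 * vp * kappa). In an unrelated population kappa = 1 and
  ## this is the plain divide-by-realized-SD rescale.
  kappa <- 1
  if (any(!is.na(rec$sire) | !is.na(rec$dam))) {
    Arec <- build_relationship_matrix(pedigree)[rec$id, rec$id]
    kappa <- (sum(diag(Arec)) - sum(Arec) / n) / (n - 1)
  }
  sd_u_target <- sqrt(config$h2_target * vp * kappa)
  if (config$h2_target > 0 && stats::sd(u) > 0) {
    scl <- sd_u_target / stats::sd(u)
    a <- a * scl
    u <- u * scl
  } else {
    a[] <- 0
    u[] <- 0
  }

  dam_id <- rec$dam
  dams <- unique(dam_id[!is.na(dam_id)])
  c_dam <- stats::setNames(rnorm(length(dams)), dams)
  c_ind <- ifelse(is.na(dam_id), 0, c_dam[dam_id])
  if (config$c2_target > 0 && stats::sd(c_ind) > 0) {
    scl <- sqrt(config$c2_target * vp) / stats::sd(c_ind)
    c_dam <- c_dam * scl
    c_ind <- c_ind * scl
  } else {
    c_dam[] <- 0
    c_ind[] <- 0
  }

  e <- rnorm(n)
  e2_target <- (1 - config$h2_target - config$c2_target) * vp
  e <- e / stats::sd(e) * sqrt(e2_target)

  sex_fx <- ifelse(rec$sex == "M", config$sex_effect / 2,
                   -config$sex_effect / 2)
  cgs <- sort(unique(rec$contemporary_group))
  cg_fx <- stats::setNames(rnorm(length(cgs), sd = config$cg_sd), cgs)
  fixed <- sex_fx + cg_fx[rec$contemporary_group]

  y <- config$trait_mean + fixed + u + c_ind + e

  truth <- list(
    marker_effects = a,
    breeding_values = stats::setNames(u, rec$id),
    maternal_effects = c_dam,
    fixed_effects = list(sex = c(M = config$sex_effect / 2,
                                 F = -config$sex_effect / 2),
                         contemporary_group = cg_fx,
                         intercept = config$trait_mean),
    residuals = stats::setNames(e, rec$id),
    qtl_index = qtl,
    true_vc = variance_components(config$h2_target * vp,
                                  config$c2_target * vp,
                                  e2_target)
  )
  phen <- data.frame(rec[, c("id", "sire", "dam", "generation",
                             "contemporary_group", "sex")],
                     dam_id = dam_id, weight = as.numeric(y),
                     stringsAsFactors = FALSE)
  list(phenotypes = phen, truth = truth)
}

#' Simulate a full population in one call
#'
#' Convenience wrapper: pedigree, gene-dropped genotypes and phenotypes from
#' one [sim_config()].
#'
#' @param config A [sim_config()].
#' @param gene_drop Transmit founder alleles through the pedigree (default
#'   TRUE) so relatives' genotypes, and hence breeding values, are correlated
#'   according to the pedigree.
#' @return List with `pedigree`, `genotypes`, `phenotypes`, `truth`.
#' @export
simulate_population <- function(config, gene_drop = TRUE) {
  ped <- simulate_pedigree(config)
  G <- simulate_genotypes(
    n = config$n_individuals, m = config$n_markers,
    maf_range = config$maf_range, missing_rate = config$missing_rate,
    seed = derive_seed(config$seed, "genotypes"),
    pedigree = if (gene_drop) ped else NULL
  )
  sim <- simulate_phenotypes(G, ped, config)
  list(pedigree = ped, genotypes = G, phenotypes = sim$phenotypes,
       truth = sim$truth)
}

#' Write genotypes in PLINK .raw-style text
#'
#' Header `FID IID PAT MAT SEX PHENOTYPE` followed by one dosage column per
#' SNP; missing dosages written as NA.
#'
#' @param G A [genotype_matrix()].
#' @param path Output file.
#' @param pedigree Optional pedigree supplying PAT/MAT/SEX columns.
#' @export
write_raw <- function(G, path, pedigree = NULL) {
  n <- nrow(G$dosages)
  pat <- mat <- rep(0, n); sex <- rep(0, n)
  if (!is.null(pedigree)) {
    i <- match(G$ids, pedigree$id)
    pat <- ifelse(is.na(pedigree$sire[i]), 0, pedigree$sire[i])
    mat <- ifelse(is.na(pedigree$dam[i]), 0, pedigree$dam[i])
    sex <- ifelse(pedigree$sex[i] == "M", 1, 2)
  }
  df <- data.frame(FID = G$ids, IID = G$ids, PAT = pat, MAT = mat,
                   SEX = sex, PHENOTYPE = -9, G$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' Read PLINK .raw-style or plain delimited genotype text
#'
#' Auto-detects the dialect from the header: a leading `FID IID PAT MAT SEX
#' PHENOTYPE` block marks .raw, otherwise the file is read as a plain
#' delimited dosage matrix with a header of marker names and row names in the
#' first column.
#'
#' @param path Input file.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "[ \t,]+")[[1]]
  if (length(header) >= 6 &&
      all(header[1:6] == c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))) {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    X <- as.matrix(df[, -(1:6), drop = FALSE])
    rownames(X) <- df$IID
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE, row.names = 1L)
    X <- as.matrix(df)
  }
  genotype_matrix(X)
}
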