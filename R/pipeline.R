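## Configuration and orchestration: one validated YAML config drives
## simulate -> QC -> pre-adjustment -> whole-genome fits -> evaluation,
## with a provenance manifest sufficient to relaunch the identical run.

default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "gpcurve_run",
    simulate = TRUE,
    paths = list(genotypes = NULL, phenotypes = NULL, pedigree = NULL),
    sim = list(n_individuals = 1500L, n_markers = 500L, n_generations = 5L,
               maf_range = c(0.05, 0.5), prop_qtl = 0.10, h2_target = 0.23,
               c2_target = 0.05, n_dams = 75L, n_sires = 25L,
               n_contemporary_groups = 20L, sex_effect = 300,
               missing_rate = 0.01),
    qc = list(maf_min = 0.01, call_rate_min = 0.95, hwe_p_min = 1e-10,
              outlier_z = 3.5),
    mcmc = list(n_iter = 30000L, burn_in = 20000L, thin = 5L),
    prior = list(v_a = 4.2, v_e = 4.2, pi_prior = "uniform",
                 het_factor2 = FALSE),
    dnn = list(learning_rate = 1e-4, batch_size = 256L, max_epochs = 1000L,
               eval_every = 5L, patience = 5L, init_sd = 1e-2,
               n_candidates = 200L, search = FALSE,
               units = c(8L, 8L), l2 = 0.01, dropout_keep = 0.8),
    evaluation = list(fractions = c(1, 3, 5, 7, 10, 15, 20, 30, 40, 50, 60,
                                    70, 80, 90, 100),
                      methods = c("BRR", "BayesCpi", "DNN"),
                      n_test_generations = 2L, tune_generations = 1L,
                      k_fraction = 0.10)
  )
}

## overlay user values onto defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("load_config: unknown key '%s'", full), call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]],
                                      as.list(user[[key]]), full)
    } else {
      defaults[key] <- list(user[[key]])  # NULL-safe assignment
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  if (cfg$mcmc$burn_in >= cfg$mcmc$n_iter)
    stop("load_config: mcmc.burn_in must be < mcmc.n_iter", call. = FALSE)
  if (cfg$mcmc$thin < 1) stop("load_config: mcmc.thin must be >= 1",
                              call. = FALSE)
  if (any(diff(cfg$evaluation$fractions) <= 0))
    stop("load_config: evaluation.fractions must be ascending",
         call. = FALSE)
  bad <- setdiff(cfg$evaluation$methods,
                 c("BRR", "BayesCpi", "BRR-WT", "BayesCpi-WT", "DNN"))
  if (length(bad))
    stop(sprintf("load_config: unknown method '%s'", bad[1]), call. = FALSE)
  qc <- cfg$qc
  qc_thresholds(qc$maf_min, qc$call_rate_min, qc$hwe_p_min, qc$outlier_z)
  if (!cfg$simulate &&
      (is.null(cfg$paths$genotypes) || is.null(cfg$paths$phenotypes) ||
       is.null(cfg$paths$pedigree)))
    stop("load_config: paths.* required when simulate is false",
         call. = FALSE)
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on the documented defaults (protocol
#' values: chain 30,000/20,000/5, learning rate 1e-4, batch 256, outlier z
#' 3.5, MAF 0.01, call rate 0.95, HWE 1e-10), rejects unknown keys by name,
#' and validates cross-field constraints. An empty file yields all
#' defaults.
#'
#' @param path YAML file path.
#' @return Validated config list of class `run_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_run_config(), user)
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration as YAML
#'
#' Round-trips with [load_config()]: `load_config(save_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg A `run_config`.
#' @param path Output file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Execute the full pipeline
#'
#' Simulate (or load) -> marker and phenotype QC -> imputation -> animal
#' model REML and pre-adjustment -> chronological split and nested ladder
#' -> whole-genome fits -> evaluation report. Deterministic given the
#' global seed, which fans out to stage-specific seeds so adding or
#' removing a method never perturbs the data. Writes tables, the report
#' and a provenance manifest under `cfg$outdir`.
#'
#' @param cfg A `run_config` from [load_config()] or built in code.
#' @return The `evaluation_report`, invisibly; side-effect files under
#'   `cfg$outdir`.
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   r_version = as.character(getRversion()),
                   package_version = as.character(
                     utils::packageVersion("gpcurve")),
                   stages = list())

  ## data
  if (isTRUE(cfg$simulate)) {
    scfg <- do.call(sim_config, c(cfg$sim, list(seed = derive_seed(
      cfg$seed, "simulate"))))
    pop <- simulate_population(scfg)
  } else {
    G <- read_genotypes(cfg$paths$genotypes)
    phen <- utils::read.csv(cfg$paths$phenotypes, stringsAsFactors = FALSE)
    ped <- utils::read.csv(cfg$paths$pedigree, stringsAsFactors = FALSE)
    pop <- list(genotypes = G, phenotypes = phen, pedigree = ped)
  }
  manifest$stages$data <- list(n_individuals = length(pop$genotypes$ids),
                               n_markers = ncol(pop$genotypes$dosages),
                               n_records = nrow(pop$phenotypes))

  ## marker QC + imputation
  thr <- do.call(qc_thresholds, cfg$qc[c("maf_min", "call_rate_min",
                                         "hwe_p_min", "outlier_z")])
  fm <- filter_markers(pop$genotypes, thr)
  write_qc_report(fm$report, file.path(outdir, "marker_qc.csv"))
  G <- impute_missing(fm$genotypes)
  manifest$stages$marker_qc <- list(
    n_in = nrow(fm$report), n_kept = sum(fm$report$kept),
    removed_by = as.list(table(fm$report$reason[!fm$report$kept])))

  ## phenotype QC
  phen <- pop$phenotypes
  keep <- remove_outliers(phen$weight, phen$contemporary_group,
                          z = thr$outlier_z)
  manifest$stages$phenotype_qc <- list(
    n_in = nrow(phen), n_kept = length(keep),
    n_outliers = nrow(phen) - length(keep),
    conserved = nrow(phen) == length(keep) + (nrow(phen) - length(keep)))
  phen <- phen[keep, , drop = FALSE]

  ## step one: animal model + pre-adjustment
  fit1 <- fit_animal_model(phen, pop$pedigree)
  utils::write.csv(
    data.frame(component = c("sigma2_u", "sigma2_c", "sigma2_e",
                             "phenotypic", "h2", "c2"),
               value = c(fit1$vc$sigma2_u, fit1$vc$sigma2_c,
                         fit1$vc$sigma2_e, fit1$ratios$phenotypic,
                         fit1$ratios$h2, fit1$ratios$c2)),
    file.path(outdir, "variance_components.csv"), row.names = FALSE)
  manifest$stages$mixed_model <- list(
    reml_iterations = attr(fit1$vc, "iterations"),
    h2 = fit1$ratios$h2, c2 = fit1$ratios$c2)

  ## split, ladder, comparison
  split <- chronological_split(phen, cfg$evaluation$n_test_generations,
                               cfg$evaluation$tune_generations)
  ladder <- nested_subsamples(split$train_ids, cfg$evaluation$fractions,
                              seed = derive_seed(cfg$seed, "ladder"))
  mc <- mcmc_config(cfg$mcmc$n_iter, cfg$mcmc$burn_in, cfg$mcmc$thin,
                    seed = derive_seed(cfg$seed, "mcmc"))
  pr <- prior_spec(v_a = cfg$prior$v_a, v_e = cfg$prior$v_e,
                   pi_prior = cfg$prior$pi_prior,
                   het_factor2 = isTRUE(cfg$prior$het_factor2))
  dnn_cfg <- train_config(cfg$dnn$learning_rate, cfg$dnn$batch_size,
                          cfg$dnn$max_epochs, cfg$dnn$eval_every,
                          cfg$dnn$patience, cfg$dnn$init_sd,
                          seed = derive_seed(cfg$seed, "dnn"))
  arch <- architecture(length(cfg$dnn$units), cfg$dnn$units,
                       cfg$dnn$l2, cfg$dnn$dropout_keep)
  Gk <- list(ids = G$ids, dosages = G$dosages,
             allele_freqs = G$allele_freqs)
  class(Gk) <- "genotype_matrix"
  report <- run_comparison(
    fit1$y_star, Gk, split, ladder,
    methods = cfg$evaluation$methods, mcmc = mc, prior = pr,
    dnn_arch = arch, dnn_config = dnn_cfg,
    dnn_search = if (isTRUE(cfg$dnn$search))
      list(n_candidates = cfg$dnn$n_candidates, grids = table_grids()),
    k_fraction = cfg$evaluation$k_fraction,
    seed = derive_seed(cfg$seed, "comparison"))
  write_evaluation_report(report, outdir)
  manifest$stages$evaluation <- list(
    n_train = length(split$train_ids), n_tune = length(split$tune_ids),
    n_test = length(split$test_ids), test_checksum = report$test_checksum)

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
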