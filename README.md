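# gpcurve

Genome-enabled prediction of a body-weight-like trait in a closed poultry
line, implemented as a tested, desk-scale R package: the classical two-step
analysis (pedigree REML pre-adjustment, then whole-genome regression on SNP
dosages) with three predictive machines — Bayesian Ridge Regression (BRR),
Bayes Cπ, and a multilayer perceptron — compared across nested training-set
sizes. It is aimed at quantitative-genetics researchers who want a fully
inspectable reference implementation of this pipeline, including the
experimental design for learning-curve comparisons, without access to any
proprietary data: a synthetic-population generator reproduces the variance
structure the analysis assumes.

## The model

Step one fits the animal model

    y = Xθ + Zu + Wc + e,   u ~ N(0, A σ²_u),  c ~ N(0, I σ²_c),  e ~ N(0, I σ²_e)

with sex and contemporary group fixed, **A** the pedigree relationship
matrix, and **c** a maternal permanent-environment effect. Variance
components come from EM-REML with average-information acceleration; BLUP
solutions from Henderson's mixed-model equations. The trait is then
pre-adjusted, y\* = y − Xθ̂ − Wĉ, retaining the additive signal.

Step two regresses y\* on standardized marker dosages:

* **BRR** — one shared Gaussian prior N(0, σ²_a) on every SNP effect,
  scaled-inverse-chi-square hyperpriors, Gibbs sampling (compiled core).
* **Bayes Cπ** — each effect is 0 with probability π or N(0, σ²_a)
  otherwise; π gets a Uniform(0,1) prior and per-marker inclusion
  indicators are sampled from their full conditionals.
* **MLP** — ReLU hidden layers, linear output, L2-penalized squared-error
  loss, Adam (lr 1e-4, batches of 256), inverted dropout, early stopping on
  a tuning generation, and random architecture search over the
  hyperparameter grids.

Evaluation follows forward prediction: the newest generations are the test
set, the next-newest the tuning set; nested sub-samples of the training set
(1 % ⊂ 3 % ⊂ … ⊂ 100 %) trace how prediction correlation, MSEP, relative
gain (RG = (r₁ − r₂)/r₂ × 100), predictive bias (slope of y\* on ŷ),
Spearman rank correlation and top-ranked agreement change with data volume.

## Worked example

The numbered drivers under `analysis/` run the whole study on a synthetic
population (1,500 animals over 5 generations, 400 SNPs):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc.R
Rscript analysis/03_preadjust.R
Rscript analysis/04_bayes.R
Rscript analysis/05_dnn.R
Rscript analysis/06_evaluate.R
```

Stage 3 prints the step-one fit on this replicate:

```
REML converged in 14 iterations
variance components: u 4501.6, c 490.3, e 13557.6 (g^2)
phenotypic 18549.5 g^2, h2 = 0.243, c2 = 0.026
```

i.e. estimated heritability 0.243 and maternal fraction 0.026 against
generating values 0.23 and 0.05 — single-replicate REML noise; across 50
replicates the means land within ±0.03 of the targets (that average is one
of the quantities the acceptance script recomputes). Stage 6 prints the
learning curves, e.g. prediction correlations by training fraction:

```
 fraction   BRR BayesCpi BRR-WT BayesCpi-WT   DNN
        5 0.245    0.247  0.311       0.306 0.197
       10 0.265    0.284  0.321       0.322 0.290
       20 0.304    0.375  0.347       0.334 0.329
       40 0.297    0.386  0.371       0.389 0.264
       70 0.321    0.440  0.356       0.411 0.275
      100 0.328    0.458  0.349       0.438 0.305
```

Accuracy rises with training size for every method; the WT variants
(Bayesian models refit with the tuning set added) dominate at small
fractions, where their extra records matter most. On this no-LD synthetic
trait Bayes Cπ profits from the sparse genetic architecture.

Equivalent single-call orchestration, from a YAML config with the protocol
defaults (30,000-cycle chains, 20,000 warm-up, thin 5; MAF ≥ 0.01, call
rate ≥ 95 %, HWE P ≥ 1e-10, ±3.5 SD outlier rule):

```r
library(gpcurve)
cfg <- load_config("my_run.yaml")
report <- run_pipeline(cfg)
```

## Layout

```
R/                 package code: synthetic data, QC, mixed model, Bayesian
                   samplers (src/samplers.cpp cores), MLP, evaluation, pipeline
analysis/          numbered narrative drivers writing tables under results/
tests/testthat/    unit, property and end-to-end acceptance tests
scripts/           acceptance.R
vignettes/         methods vignette (models, priors, design choices)
```
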