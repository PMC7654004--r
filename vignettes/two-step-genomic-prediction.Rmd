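---
title: "Two-step genome-enabled prediction: model, samplers, network and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step genome-enabled prediction: model, samplers, network and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

`gpcurve` implements a complete two-step genome-enabled prediction analysis
of a body-weight-like trait in a closed poultry breeding line, together with
the experimental design needed to ask how training-set size changes the
relative merit of linear Bayesian whole-genome regressions and a multilayer
perceptron. The real data motivating this design are proprietary, so the
package ships a synthetic-population generator that reproduces the variance
structure the analysis assumes; every statistical claim the package makes is
therefore checkable end to end on data whose truth is known.

# Step one: the animal model and pre-adjustment

Body weight is modelled as

$$
\mathbf{y} = \mathbf{X}\boldsymbol\theta + \mathbf{Z u} + \mathbf{W c} + \mathbf{e},
\qquad
\mathbf{u} \sim N(0, \mathbf{A}\sigma^2_u),\;
\mathbf{c} \sim N(0, \mathbf{I}\sigma^2_c),\;
\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e),
$$

with sex and contemporary group as fixed effects, $\mathbf{A}$ the pedigree
numerator relationship matrix (tabular method,
`build_relationship_matrix()`), and $\mathbf{c}$ a maternal
permanent-environment effect indexed by dams with phenotyped offspring.
Variance components are estimated by REML (`reml_variance_components()`).
The baseline update is the exact EM step
$\sigma_i^{2\,(t+1)} = \sigma_i^{2\,(t)} + \sigma_i^{4\,(t)}/t_i\,
(\mathbf{y}'\mathbf{P}\mathbf{V}_i\mathbf{P}\mathbf{y} -
\mathrm{tr}(\mathbf{P}\mathbf{V}_i))$, which is monotone in the restricted
likelihood; after three warm-up EM steps the default accelerates with
average-information (quasi-Newton) updates under step-halving, falling back
to EM whenever an AI step would leave the parameter space or reduce the
likelihood. Components whose gradient points below a small positive floor
($10^{-8}$ of the trait variance) are pinned there and dropped from the AI
system (an active-set treatment); convergence is declared when every
component's relative change falls below `tol` (default `1e-8`, at most 500
iterations, non-convergence is an error carrying the trajectory).

Why V-side algebra rather than Henderson-system traces: at desk scale
(pedigrees of a few thousand) dense Cholesky factorizations of the $n \times
n$ phenotypic covariance are fast and the EM/AI updates only need
$\mathbf{P}\mathbf{y}$, quadratic forms, and traces available from one
inverse per iteration. The fixed point is identical to the mixed-model
equation formulation; BLUP solutions themselves come from Henderson's
equations (`blup_solve()`), whose residual is checked directly in the tests.

The phenotype handed to step two is the pre-adjusted record
$\mathbf{y}^* = \mathbf{y} - \mathbf{X}\hat{\boldsymbol\theta} -
\mathbf{W}\hat{\mathbf{c}}$: fixed and maternal effects are removed while the
additive signal is retained, so the whole-genome machines compete on the
genetic part alone.

# Step two, Bayesian half

Both samplers (compiled cores in `src/samplers.cpp`) operate on markers
standardized to mean 0, variance 1 (sample SD, $n-1$), with a flat prior on
the intercept and scaled inverse chi-square hyperpriors on both variances.

* **Bayesian Ridge Regression** (`fit_brr()`): one shared
  $N(0, \sigma^2_a)$ prior on every effect; $\sigma^2_a$ updated with
  $v_a + m$ degrees of freedom, $\sigma^2_e$ with $v_e + n$.
* **Bayes C$\pi$** (`fit_bayes_cpi()`): each effect is zero with
  probability $\pi$ or $N(0, \sigma^2_a)$ otherwise. The indicator
  $\delta_j$ is drawn from its full conditional via the marginal-likelihood
  ratio of inclusion versus exclusion; effects are drawn only when
  included; $\pi \mid \delta \sim \mathrm{Beta}(\#\text{excluded}+1,
  \#\text{included}+1)$ under its Uniform(0,1) prior; the $\sigma^2_a$
  update uses the included-marker count in its degrees of freedom.

Hyperprior defaults: $v_a = 4.2$ and the scale rule
$S^2_a = \tilde\sigma^2_a (v_a - 2)/v_a$ with
$\tilde\sigma^2_a = \tilde\sigma^2_s / \big((1-\pi)\sum_j p_j(1-p_j)\big)$.
The denominator is implemented exactly as written here — without the
factor 2 of the usual heterozygosity sum; `prior_spec(het_factor2 = TRUE)`
switches to the factor-2 convention, since the two differ only by a
constant the data largely overwhelm. Unstated quantities are given weakly
informative defaults declared in `prior_spec()`: $\tilde\sigma^2_s$ is half
the sample variance of $\mathbf{y}^*$, and $(v_e, S^2_e)$ are set so the
prior mode of $\sigma^2_e$ equals half that variance. Chains default to
30,000 cycles, 20,000 warm-up, thinning 5; effects are updated singly in
fixed index order with running-residual bookkeeping, and seeded chains are
bit-reproducible because the cores draw from R's own RNG.

Correctness is established three ways in the test suite: a closed-form
conjugate (ridge) oracle with variances held fixed; the reduction
Bayes C$\pi$ $\to$ BRR at $\pi = 0$; and a prior-invariance run in which
data and parameters are alternately redrawn so the stationary marginal of
$\sigma^2_a$ must reproduce its scaled-inverse-chi-square prior.

# Step two, neural half

`train_mlp()` trains a fully connected multilayer perceptron on the
standardized dosages: ReLU hidden layers, a linear output unit, and the
penalized loss $L = (\mathbf{y}-\hat{\mathbf{o}})'(\mathbf{y}-\hat{\mathbf{o}})
+ \lambda\, \mathbf{w}'\mathbf{w}$ with biases excluded from the penalty
(biases are initialized at zero; weights at $N(0, 10^{-4})$). Optimization
is mini-batch Adam (learning rate $10^{-4}$, batches of 256 by default); the
tuning-set MSE is evaluated every 5 epochs and training stops after 5
consecutive evaluations without strict improvement, returning the weights of
the best evaluation (snapshot, not last epoch — the standard early-stopping
contract; "no improvement" means not strictly lower, with no tolerance
band). Dropout follows the keep-probability convention: the searched rates
include 1 (no dropout), masks are applied to the input and every hidden
layer but never the output, and inverted scaling ($1/\text{keep}$) makes
predict mode deterministic with no rescaling. `random_search()` draws each
candidate architecture by independent uniform choices from the
hyperparameter grids (1–4 layers; units 1, 100–1000 by 100, 2000–5000 by
1000; keep rate 0.5–0.9 or 1; $\lambda$ from 0 to 0.1 in steps of 0.0025 —
one grid entry printed as 0.3000 in the source table is read as 0.0300,
the value consistent with the rest of the sequence), trains each with the
same protocol, and selects by tuning-set prediction correlation, breaking
ties by lower tuning MSE and then draw order. Candidates whose predictions
are constant on the tuning set rank last rather than erroring.

# Evaluation design

`chronological_split()` assigns the newest generations to testing, the
next-newest to tuning and the remainder to training — forward prediction of
young selection candidates from older reference animals, which is the
setting the method is used in. `nested_subsamples()` draws one permutation
of the training ids and takes prefixes at each ladder fraction (default 1,
3, 5, 7, 10, 15, 20, 30, 40, 50, 60, 70, 80, 90, 100 %; sizes round half
away from zero), so the nesting invariant holds by construction.
`run_comparison()` fits, per fraction: the Bayesian models on the subset,
their WT variants on subset $\cup$ tuning set (levelling the data advantage
the network gets from the tuning set), and the MLP on the subset with
early stopping on the tuning set — no model fit ever sees test phenotypes.
Metrics: Pearson prediction correlation, MSEP, the OLS slope of
$\mathbf{y}^*$ on $\hat{\mathbf{y}}$ as predictive bias (1 = unbiased;
regressing this direction matches reading slopes $> 1$ as deflated,
"inflation-style" predictions; the converse direction is available via
`reverse`), relative gain $(r_1 - r_2)/r_2 \times 100$, Spearman
correlation of mid-ranks between methods, and top-ranked agreement.
Because a literal top-10 overlap can only move in steps of 10 %, top-ranked
agreement defaults to the top 10 % of the test set (`k_fraction = 0.10`)
with a literal `k` also supported. Markers are standardized once on the
full genotyped panel: allele frequencies are population quantities known
for all candidates, and a shared transform keeps small sub-samples — where
single markers are often monomorphic — on the same scale as the test set.

# The synthetic population

`simulate_population()` generates: a discrete-generation pedigree (founders,
then offspring of sires and dams drawn from the previous generation; 75
dams and 25 sires per generation by default, enough dam reuse to estimate
the maternal fraction while keeping within-generation relatedness modest);
genotypes gene-dropped through that pedigree (founders Binomial(2, $p_j$)
with $p_j \sim U(0.05, 0.5)$, descendants by Mendelian transmission), so
relatives' genotypes — and hence breeding values — are correlated according
to the pedigree while markers stay mutually independent (no LD, which no
formula in the package requires); and phenotypes built from a sparse set of
QTL (10 % of markers by default), dam effects, an i.i.d. residual, a 300 g
sex dimorphism, hatch-batch effects, and a 2141.8 g mean with 18,939.6 g²
of random-part variance. Targets $h^2 = 0.23$ and $c^2 = 0.05$.

Each random component is rescaled by its realized SD so the variance
targets are hit per replicate rather than only in expectation. For the
additive component the target carries the relatedness correction
$\kappa = (\mathrm{tr}(\mathbf{A}) - \mathbf{1}'\mathbf{A}\mathbf{1}/n)/(n-1)$:
among relatives the sample variance of $\mathbf{u}$ underestimates
$\sigma^2_u$ by exactly this factor, and without the correction
pedigree-REML would systematically overestimate $h^2$ (by about +0.04 under
strong family structure in our measurements). What the generator does not
emulate: linkage disequilibrium, selection, genotyping error, overlapping
generations. Passing tests therefore demonstrate correctness of the
estimators and design under the assumed variance structure — not robustness
to LD-driven redundancy among markers or to selection-induced drift, both
present in real commercial lines.

# Problem sizes and numerical choices

The package's documented study sizes are chosen for a desk-scale machine:
REML recovery uses 50 replicates of 1,500-animal populations (1,200
records, 400 markers), where the mean of $\hat h^2$ and $\hat c^2$ across
replicates lands within ±0.03 of the generating values; the Bayes C$\pi$
sparsity study uses 10 QTL among 500 markers on 1,500 records; the
learning-curve check runs a 6-step ladder over 5 replicate populations.
Dense linear algebra throughout (an explicit $\mathbf{A}^{-1}$ for the MME,
Cholesky-based inverses in REML) is deliberate at these sizes; pedigrees
beyond roughly 5,000 animals would need the sparse-inverse machinery of
dedicated animal-breeding software, which is out of scope. Degenerate
inputs are handled explicitly: monomorphic or all-missing markers are
caught by QC (all-missing columns fail the call-rate filter; the HWE test
returns P = 1 where no departure is testable), zero-variance columns make
standardization error rather than divide by zero, singleton contemporary
groups are kept with a warning, and constant prediction vectors yield NA
metrics rather than spurious numbers.

# Interface

The package's functions are the interface; the numbered scripts under
`analysis/` (simulate → QC → pre-adjust → Bayesian fits → network search →
ladder evaluation) are thin narrative drivers over them and write their
tables under `results/`. `load_config()` / `run_pipeline()` bind the whole
chain to one validated YAML configuration with the protocol defaults, a
global seed fanned out per stage (so changing the method list never
perturbs the simulated data), and a provenance manifest sufficient to
relaunch an identical run. `scripts/acceptance.R` recomputes the package's
headline quantities from scratch and writes them as JSON.

# Known limitations

Point estimates only for variance components (no standard errors); no
single-step or genomic-relationship REML; the HWE filter uses the 1-df
chi-square test rather than the exact test (at the extreme threshold of
$10^{-10}$ the decisions coincide for non-degenerate counts); imputation is
marker-mean only; the network is a plain MLP without convolutional or
multi-task variants; and architecture search is sequential.
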