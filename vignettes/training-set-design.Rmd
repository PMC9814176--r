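---
title: "Designing optimized training sets for multi-trait multi-environment genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing optimized training sets for multi-trait multi-environment genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpdesign)
```

## The problem

Phenotyping is the expensive step of hybrid breeding: every
genotype x environment x trait cell of a multi-environment trial costs
field plots and labor, while genotyping the parental inbreds is cheap and
done once. If a prediction model can carry information across genotypes
(through marker-based kinship), across environments (through
environmental-covariate similarity) and across traits (through their
genetic covariance), then only a fraction of the cells needs to be
phenotyped. The question this package addresses is *which* fraction: how
large must a selectively-phenotyped training set be, and which exact cells
should be in it, so that the whole panel can be predicted with acceptable
accuracy at minimum cost.

The workflow mirrors how this is done in practice for single-cross maize
hybrids:

1. QC parental SNPs, build hybrid genotypes in silico, form additive
   (VanRaden) and dominance (Vitezica) relationship matrices
   (`qc_markers()`, `synthesize_hybrids()`, `additive_grm()`,
   `dominance_grm()`).
2. Summarize daily weather into phenology-window environmental covariates
   and the enviromic kernel $K_E = WW' / (\mathrm{tr}(WW')/q)$
   (`summarize_env_covariates()`, `env_kernel()`).
3. Stage-1 analysis: per-environment genotype BLUEs, the ear-height
   ideotype transform, z-standardization, broad-sense heritability and the
   trait covariance $\Sigma_T$ (`fit_stage1_blues()` and friends).
4. Build a Kronecker kernel over all cells —
   $\Sigma_G \otimes \Sigma_E \otimes \Sigma_T$ ("GET", identity
   environment factor) or $\Sigma_G \otimes K_E \otimes \Sigma_T$
   ("GWT") — size the training set by the spectral 98%-variance rule, and
   pick the cells with a look-ahead genetic algorithm minimizing mean
   prediction error variance (`composite_kernel()`, `apy_core_size()`,
   `optimize_training_set()`).
5. Fit a multi-kernel Bayesian GBLUP (models M1–M5) on the selected cells
   and predict every cell (`fit_gblup()`, `predict_cells()`).
6. Score prediction ability per trait x environment and convert it into
   genetic gain per 10,000 USD (`prediction_ability()`,
   `response_per_investment()`).

## Models

All models act on standardized stage-1 BLUEs $y$ over cells, with fixed
environment (x trait) intercepts and random terms whose covariances are
Kronecker products over the cell grid (genotype-major, trait fastest):

| term | covariance | meaning |
|------|-----------|---------|
| A | $G_a \otimes J_q$ | additive main effect, constant across environments |
| D | $G_d \otimes J_q$ | dominance main effect |
| W | $J_g \otimes K_E$ | enviromic environment effect |
| AE, DE | $G_a \otimes I_q$, $G_d \otimes I_q$ | environment-specific (block-diagonal) G x E |
| AW, DW | $G_a \otimes K_E$, $G_d \otimes K_E$ | reaction-norm G x W |

M1 = {A, D}; M2 = M1 + {AE, DE}; M3 = M1 + {W}; M4 = M3 + {AE, DE};
M5 = M3 + {AW, DW}. The $J$ (all-ones) and $I$ forms are exactly what the
Hadamard products $[Z_G G_a Z_G'] \odot [Z_E Z_E']$ reduce to under the
cell ordering, which the test-suite verifies against dense oracles. With
$K_E = I$ the G x W structures degenerate to the G x E ones, a property
also under test.

## The Gibbs sampler

`fit_gblup()` is a from-scratch Gibbs sampler. Each random term is
re-parameterized in the eigenbasis of its covariance restricted to the
*observed* cells; because each observed cell is observed once, the
homoscedastic full conditionals are then diagonal and a sweep costs
$O(n \cdot r)$ per term ($r$ = retained rank; eigenvalues below
$10^{-8}$ of the largest are dropped). Heteroscedastic residuals
(multi-trait mode) fall back to a dense $r \times r$ solve. Variance
components have scaled-inverse-$\chi^2$ full conditionals with prior
degrees of freedom 5 and scales that split half of $\mathrm{var}(y)$
equally across terms; the residual gets the other half. Defaults are
10,000 iterations, 1,000 burn-in, thinning 2; fits are bit-reproducible
given the seed.

Posterior means of cell-level genetic values are accumulated
Rao-Blackwellized (conditional means given the current state rather than
raw draws), which cuts their Monte Carlo error enough that the
fixed-variance sampler matches the closed-form ridge solution
$(K + \lambda I)^{-1} K y$ to near machine precision. Unobserved cells
are predicted through the kernel relationships,
$\hat u_U = K_{UT} K_{TT}^{-} \bar u_T$, computed in the same eigenbasis.

Two design choices depart from what a full multivariate treatment would
do, both made for conjugacy under likelihood *restriction* (missing cells
are dropped, never imputed):

* the multi-trait residual is a set of per-trait variances, not an
  unstructured trait covariance. Cross-trait information still flows
  through $\Sigma_T$ in every genetic term; an unstructured residual
  would force dense per-iteration solves over all observed cells for a
  second-order refinement.
* in multi-trait mode $\Sigma_T$ is supplied (typically the trait
  covariance of the full panel's standardized BLUEs, the "known
  covariance" convention for sparse training sets); when omitted it is
  estimated once from the observed cells, not sampled.

## Training-set size and selection

The spectral rule takes the composite kernel's eigenvalues — computed as
all products of factor eigenvalues, never materializing the full matrix —
and returns the smallest $n$ whose top eigenvalues capture 98% of the
trace. This is the "core" size in APY-style thinking: the effective
dimensionality of the panel. The rule says how many cells to phenotype
but not which; that is delegated to a genetic algorithm over cell subsets
of size $n$ with fitness
$$\mathrm{PEV}(T) = \frac{1}{|U|}\sum_{i \in U}
  \left[K_{ii} - K_{iT}(K_{TT} + \lambda I)^{-1}K_{Ti}\right],$$
$\lambda = 1$ by default (a 0.5 heritability on the standardized scale).
The GA uses elitism, union-crossover with uniform down-sampling, per-cell
swap mutation (rate 0.1), a bounded FIFO tabu set of visited subsets
(capacity 10,000) that diverts re-proposed solutions to a perturbed
neighbour, and a look-ahead step: one steepest single-swap refinement of
the incumbent per generation (swap enumeration capped at
`lookahead_cap`, sampled beyond that). PEV is monotone non-increasing
under training-set inclusion, and on the bundled 6-cell toy kernel the GA
recovers the exhaustively enumerated optimum; both are under test.

A designated check genotype — one hybrid with complete phenotypes in
every environment x trait — always rides on top of the budget, creating
the connectivity that multi-trait fits on sparse cells require. Three
independent GA runs give the smallest scenario (OTS1); pairwise unions
and the full union give the two larger scenarios (OTS2, OTS3), with
deduplication, so union sizes are sub-additive when runs overlap.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the pipeline assumes: inbred
founders (dosage 0/2, allele frequencies uniform on [0.05, 0.95]),
partial-diallel F1 hybrids, daily weather (rainfall, temperature,
humidity) over a 120-day season summarized into ECs, three traits (GY
t/ha, PH cm, EH cm) with a target genetic correlation matrix, additive +
dominance (default dominance share 0.15) main effects, G x E deviations,
block effects and residual noise, in an RCBD or augmented-block layout
with check hybrids.

Calibration choices worth knowing:

* the combined genetic main effects are recolored to the *exact* target
  covariance, so realized variances and trait correlations equal their
  targets regardless of kinship-induced sampling noise;
* G x E deviations are drawn with genotype covariance $G_a$ and
  environment covariance $K_E$ by default ("driven by $K_E$"), so the
  enviromic kernel genuinely structures the interaction and GWT models
  have signal to find — or compound symmetry $\rho_E$ when a neutral
  interaction is wanted;
* the residual variance is solved from the target entry-mean
  heritability $H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/n_E +
  \sigma^2_e/(n_E n_{rep}))$, which caps attainable $H^2$ at
  $\sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/n_E)$ — infeasible targets
  error out rather than being silently truncated.

What the generator does **not** emulate: linkage maps and LD decay (loci
are independent), selection history, spatial field trends, outliers, and
multi-year genetic trend. Passing tests therefore demonstrate that the
algorithms are implemented correctly and behave as the theory predicts on
data obeying the model's assumptions — not that identical numbers would
be obtained on any particular real dataset.

A known limitation surfaced by the tests: with a $K_E$-driven
interaction over few environments, scaled EC columns make $K_E$ rows sum
to roughly zero (strong negative environment correlations), and the
iid-interaction variance model behind the entry-mean $H^2$ formula then
partitions variance poorly — $H^2$ estimates on small strongly
interactive panels are unstable and biased low. The recovery tests use a
compound-symmetry interaction for exactly this reason, and the pipeline
clamps $H^2$ into $[0.1, 1]$ before it enters the economics divisor
$\sqrt{H^2}$.

## Problem sizes and numerical choices

The bundled fixtures are deliberately small: `mini-hel` (30 hybrids from
10 founders, 3 environments, 3 traits, RCBD, strong $K_E$-driven G x E),
`mini-usp` (50 hybrids, 4 environments, augmented blocks) and `toy6`
(six cells, for exhaustive GA verification). End-to-end experiments in
the tests and the acceptance script run 10 seeds with 1,500–2,000 Gibbs
iterations per fit — chain lengths chosen because, at these panel sizes,
effective sample sizes of the variance components are already in the
hundreds and posterior means of genetic values are Rao-Blackwellized;
production analyses on real panels should keep the 10,000-iteration
default.

Other numerical conventions: factor matrices must be symmetric within
$10^{-10}$ and PSD within a $-10^{-8}$ eigenvalue tolerance; reported
prediction abilities are rounded half-up to 2 decimals and percentages to
1 decimal; zero-variance EC columns are dropped, zero-variance PA groups
are dropped with a warning; the QC order is fixed (call rate, parental
heterozygosity, monomorphism, MAF) with strict thresholds (a marker *at*
the threshold is removed); missing marker dosages are imputed at the
observed per-marker mean code, which for the additive coding equals the
usual $2p_i$ rule.

## Design decisions that were genuinely open

* **BLUE scope.** Stage-1 BLUEs can be fitted per environment or across
  environments; prediction consumes environment-specific values, so
  `per_environment` is the default and `across_environments` is provided
  for completeness.
* **Which relationship enters the selection kernel.** The additive GRM:
  it is the selection-relevant kinship, and the additive+dominance sum is
  available via the `g` argument for users who want the total-genetic
  version.
* **PEV form.** No closed-form criterion is canonical for Kronecker cell
  selection; the GBLUP PEV above is the standard choice, with
  $\lambda$ exposed.
* **Plant-height scaling.** PH receives the same z-score standardization
  as the other traits; no rank-based normalization is applied.
* **Phenotypic-selection accuracy.** The economics module follows the
  convention accuracy $= PA/\sqrt{H^2}$ with $PA = 1$ for phenotypic
  selection, which exceeds 1 for $H^2 < 1$; `ps_accuracy = "sqrt_h2"`
  offers the conventional alternative.
* **Genotyping base.** Costs charge genotyping per *parental inbred* by
  default (F1 genotypes are synthesized in silico); `n_samples` is an
  explicit argument because charging per hybrid is an equally defensible
  convention.
* **Selection-kernel choice for the optimized-vs-random comparison.**
  The GWT kernel concentrates its budget on environments with large
  $K_E$ self-similarity and can starve low-variance environments on very
  small panels; the GET kernel spreads cells evenly. Both are exposed;
  the end-to-end comparisons in the acceptance suite use GET, the
  cleaner instance of the optimized-beats-random property.

## A worked example

```{r example, eval = FALSE}
library(gpdesign)

d <- golden_fixture("mini-hel")
res <- run_pipeline(data = d, out_dir = tempfile("gpdesign"),
                    kernel_kind = "GET", seed = 11)

res$n_core          # spectral training-set size
res$pa$ots          # prediction ability of the optimized design
res$pa$random       # ... and of the size-matched random control
res$econ            # cost and gain per 10,000 USD for both
```

Every artifact (QC log, GRM, enviromic kernel, BLUEs, heritability,
trait covariance, designs, variance components, predictions, prediction
abilities, economics) is also written as CSV with an MD5 manifest;
re-running with the same seed reproduces the manifest hash-for-hash.
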