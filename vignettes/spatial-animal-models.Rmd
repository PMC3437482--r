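---
title: "Separating genes from shared space in the animal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating genes from shared space in the animal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatqg)
```

## The problem

In philopatric wild populations, relatives live near one another throughout
their lives. When habitat quality varies at a fine spatial scale, relatives
then resemble each other for two confounded reasons: shared alleles and
shared space. An animal model — a linear mixed model in which an
individual-level random effect has covariance proportional to the
pedigree-derived additive relationship matrix $\mathbf{A}$ — attributes all
of the covariance it can to the genetic term unless the shared-space signal
is modelled explicitly, so additive genetic variance $V_A$ and heritability
$h^2 = V_A / \sum_k V_k$ are inflated.

`spatqg` implements both of the standard remedies and the machinery to
compare them:

1. **Spatial autocorrelation (SAC)**: individuals' average lifetime
   locations are snapped to a 100-m lattice and a spatial random effect is
   given the separable first-order autoregressive covariance
   $\mathrm{Cov}[(r_1,c_1),(r_2,c_2)] =
   \sigma^2\,\phi_{row}^{|r_1-r_2|}\,\phi_{col}^{|c_1-c_2|}$ (AR1 $\times$
   AR1), the submatrix of a Kronecker product restricted to occupied cells.
2. **Home-range overlap (the S matrix)**: each individual's utilization
   distribution (UD) is estimated by kernel density estimation from its
   lifetime census fixes, pairwise overlap is summarized by Bhattacharyya's
   affinity $BA = \sum_{cells} \sqrt{m_1 m_2} \in [0,1]$, and the resulting
   symmetric unit-diagonal matrix $\mathbf{S}$ is fitted as the covariance
   of a second individual-level random effect, exactly parallel to
   $\mathbf{A}$. The 0–1 scale of BA is what makes the variance attached to
   $\mathbf{S}$ directly comparable to $V_A$.

Both spatial terms enter the same restricted-likelihood machinery, so each
trait can be fitted with no spatial term, with single-axis or two-axis SAC,
or with the S matrix, and the variants compared by likelihood-ratio tests
and AIC.

## The model and the fitter

Every model has the form
$$\mathbf{y} = \mathbf{X\beta} + \sum_k \mathbf{Z}_k \mathbf{u}_k +
\mathbf{e}, \qquad \mathbf{u}_k \sim N(\mathbf{0},\ \theta_k \mathbf{G}_k),
\qquad \mathbf{e} \sim N(\mathbf{0},\ \theta_e \mathbf{I}),$$
where $\mathbf{G}_k$ is the identity (permanent environment, year,
maternal), $\mathbf{A}$ (animal), $\mathbf{S}$ (overlap), or the AR1
$\times$ AR1 cell covariance. Estimation maximizes the restricted
log-likelihood
$$\ell_R = -\tfrac12\left(\log|\mathbf{V}| +
\log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}| +
\mathbf{y}'\mathbf{P}\mathbf{y}\right),
\qquad \mathbf{V} = \sum_k \theta_k \mathbf{Z}_k\mathbf{G}_k\mathbf{Z}_k' +
\theta_e\mathbf{I},$$
with $\mathbf{P}$ the usual REML projection. Numerically:

* Variance components are optimized on the log scale (hence bound at zero
  externally) and AR1 correlations on a scaled logit of their search
  interval, by bounded quasi-Newton (L-BFGS-B) with analytic gradients from
  the REML score equations, plus seeded random restarts (3 by default).
  A final Newton refinement using the average-information matrix sharpens
  interior optima to near machine precision; on balanced one-way designs
  the estimates agree with the closed-form ANOVA estimators to better than
  $10^{-6}$, and on crossed identity-covariance designs they match `lme4`.
* Standard errors come from the inverse average-information matrix;
  standard errors of variance *proportions* and of $h^2$ use the delta
  method on that parameter covariance (they agree with a parametric
  bootstrap to within 15% on small designs, which is the accuracy the
  asymptotic approximation can promise there).
* An estimate is flagged *bound* when a variance reaches (a fraction
  $10^{-6}$ of the phenotypic variance of) zero or a correlation comes
  within $10^{-3}$ of its search bound, mirroring the convention of
  printing bound components in italics in comparative tables.
* The default $\phi$ search interval is $[0, 0.999]$; widen it to
  $(-0.999, 0.999)$ through `sac_term(phi_bounds =)` when negative
  (competition-like) autocorrelation should be representable.
* Convergence is declared from the projected-gradient optimality
  conditions, not from the optimizer's status code alone; non-convergence
  is reported, never silent, and non-converged fits are excluded from AIC
  rankings.

Likelihood-ratio tests for added random terms use the naive convention
`df = number of added (co)variance parameters` (df = 1 for the S matrix,
df = 3 for variance-plus-two-correlations SAC). The truth lies on the
boundary under the null, so this convention is conservative — our null
simulations reject at well under the nominal 5% — and the 50:50
$\chi^2_0{:}\chi^2_1$ mixture is available via `lrt(boundary = TRUE)` for
the single-component case. REML AICs
($-2\ell_R + 2\,\#\text{covariance parameters}$) are only comparable
between models with identical fixed effects; `aic_table()` enforces this.

## Pedigrees and the A matrix

`additive_relationship()` implements the tabular recursion in topological
order, with inbreeding-adjusted diagonals
$a_{ii} = 1 + \tfrac12 a_{dam,sire}$. Whether a field study's published
analysis used inbreeding-adjusted diagonals is often unknowable for
partially unknown pedigrees; we always apply the standard adjustment, which
reduces to diagonal 1 whenever either parent is unknown. Parents never
listed as individuals become implicit founders (unrelated, non-inbred), the
closure a field pedigree with hundreds of parent-unknown individuals needs.
The independent validator `gene_drop_kinship()` drops founder alleles
through the pedigree and estimates relatedness as twice the probability of
identity by descent; the tabular matrix agrees with it elementwise within
Monte-Carlo error on random pedigrees.

Matrices are stored dense with an ordered id vector — at the scale of
a few thousand individuals this is a few hundred megabytes at most, and all
study problems here are far smaller — and are exchanged as lower-triangle
`row col value` triplet text plus an id sidecar, the de-facto dialect of
mixed-model software.

## Home ranges, overlap, and their tunables

* **Jitter** (`jitter_fixes`, default ±20 m): census fixes recorded to the
  nearest 100 m stack on identical coordinates, which breaks kernel
  estimators; uniform jitter within the grid cell's scale restores a
  continuous point pattern.
* **Bandwidth**: the reference ("href") rule
  $h = \sigma_{pooled}\, n^{-1/6}$ with
  $\sigma_{pooled} = \sqrt{(\mathrm{var}(x)+\mathrm{var}(y))/2}$, the
  default of the classical home-range packages; a fixed bandwidth can be
  forced. UDs are stored as exact per-cell masses (the kernel integrated
  over each cell via normal CDF differences), so discretization conserves
  mass by construction.
* **Grid cell** (default 10 m) and **extent pad** (default three
  bandwidths): chosen so the closed-form checks — the 95% isopleth area of
  a circular Gaussian ($\pi \chi^2_{2,0.95} \sigma^2$) and the Gaussian BA
  closed form $\exp(-d^2/8\sigma^2)$ — reproduce within 2% and $10^{-3}$
  respectively. Widen the pad when tail mass matters.
* **Isopleth** (default 0.95): the area of the smallest set of cells
  holding 95% of the UD mass defines the core range; descending-density
  accumulation with stable tie-breaking makes the area deterministic.
* **Minimum fixes** (default 10) applies to both annual and lifetime
  estimation; excluded groups are returned in an exclusion log, never
  dropped silently.
* **Overlap convention**: the S matrix uses lifetime UDs (all fixes pooled
  across years); annual seasonal UDs are used for range *sizes*. Whether to
  jitter before overlap estimation is exposed as a choice; the pipeline
  jitters by default for consistency with size estimation. Individuals
  without sufficient fixes enter the S matrix as spatially unrelated
  (diagonal 1, off-diagonals 0) — the conservative convention, since
  missing overlap information can only understate the spatial variance.
* **PSD repair** (`psd = "clip"`): an assembled S matrix can be slightly
  indefinite; REML needs an invertible covariance. Clipping raises
  eigenvalues below $10^{-8}$ (with headroom, since re-fixing the unit
  diagonal shaves them slightly) and records the largest shift applied.
  Repair is opt-in and flagged, never silent.
* When UDs live on different grids, BA aligns them by mass-conserving
  rebinning onto the union bounding box at the finer cell size.

The SAC lattice is indexed by *occupied cells*: individuals sharing a cell
share one spatial effect, which keeps the covariance at the number of
distinct cells. (Indexing by individual-within-cell would duplicate rows of
a rank-deficient covariance and costs identifiability; the full-Kronecker
construction is retained as a test oracle.)

## What the synthetic populations emulate

`sim_config()` describes a female-philopatric, matrilineally clustered
population: founder matrilines uniform on a 2 km × 2 km study area,
daughters settling an isotropic Gaussian displacement (default SD 100 m)
from their mothers, within-individual fix scatter of SD 150 m, two census
seasons, and an external, partially unrecorded sire pool (default 20%
unknown fathers). Defaults give ~300 study females over four generations —
the scale of a long-term individual-based ungulate study — with
mother–daughter range overlap near 0.95 and cross-matriline overlap near
zero, which is precisely the gene–space confounding under study.
Phenotypes are drawn from the generative mirror of the fitted model; the
spatial effect can be carried either by an overlap matrix or by an AR1
$\times$ AR1 field on the lattice, so SAC-versus-S-matrix contrasts are
testable. `true_overlap_matrix()` provides the exact closed-form BA of the
generative Gaussian ranges, free of kernel-estimation noise — parameter
recovery experiments use it as "the correct model", while the
kernel-estimation pipeline is validated against it separately.

What the generator deliberately does **not** emulate: demography (survival,
density dependence), male ranging, temporal change in ranges, non-Gaussian
space use, and habitat maps. Passing recovery tests on these simulations
therefore shows the estimator is correct *given the model*, not that any
real population satisfies the model.

Named presets (`preset_config("rhr" | "shr" | "bw" | "lbs")`) provide
illustrative variance mixes for the four archetypal traits — two
log-scale repeated range-size traits dominated by spatial variance, a
repeated maternal trait with weak spatial variance, and a single-measure
log-scale fitness trait with strong cohort and spatial variance. They are
qualitative archetypes, not estimates from any real population. For
single-measure traits the permanent-environment term is dropped (it is not
identifiable) and the year effect is indexed by birth cohort rather than
measurement year.

## Problem sizes and verification

The test suite validates, at sizes chosen to keep a full run in a few
minutes on one core: the tabular A matrix against $10^5$ gene drops on
twenty random pedigrees of up to 50 individuals; BA against the Gaussian
closed form at 5-m cells; occupied-cell AR1 $\times$ AR1 against explicit
Kronecker products; REML against closed-form ANOVA estimators on fifty
balanced designs (to $10^{-6}$) and against `lme4` on unbalanced crossed
designs; variance-component recovery and the heritability-inflation
direction on 100 replicates of the ~300-female confounded population
(true $V_A = 0.3$, $V_{Smatrix} = 0.5$, $V_{Residual} = 0.2$); null
calibration of the overlap LRT on 500 small replicates; and byte-identical
end-to-end determinism under fixed seeds. `scripts/acceptance.R` recomputes
the headline quantities from scratch at a caller-supplied seed.

Two conventions in those checks deserve a note. The gene-dropping
comparison uses the distribution-free elementwise bound
$1/\sqrt{n_{drops}}$ on the Monte-Carlo standard error (each per-drop
relatedness contribution lies in $[0,2]$): with thousands of elementwise
comparisons, a band based on the much smaller empirical standard errors
would be crossed somewhere by chance alone in essentially every run. And
the balanced-design oracle uses the *constrained* closed form: when
$MS_{between} < MS_{within}$ the REML optimum sits on the boundary with the
residual equal to the total variance around the grand mean, not to
$MS_{within}$.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, trait_design = "single_measure")
dat <- simulate_dataset(cfg, s_matrix = "true")

naive <- reml_fit(model_spec("y", ~1, list(animal_term(dat$A))),
                  dat$phenotypes)
spatial <- reml_fit(model_spec("y", ~1, list(animal_term(dat$A),
                                             smatrix_term(dat$S))),
                    dat$phenotypes)
partition(naive)$h2      # inflated: genes credited with shared space
partition(spatial)$h2    # near the generative 30%
lrt(naive, spatial)      # df = 1 test of the overlap term
```

Or, at the workflow level, `run_trait_analysis()` fits the no-spatial
baseline and every requested spatial variant, assembles LRTs, AICs,
variance partitions, and flags any variant whose total variance (Sum V)
departs from the baseline's by more than a factor of 3 — a large jump in
Sum V is the signature of a poorly estimated spatial model (single-axis SAC
fits with a correlation pinned at its bound are the usual offenders), and
such fits should not be interpreted even when they formally converge.

## Known limitations

* Single-trait models only; no dominance or genetic-group structures.
* SAC and the S matrix are fitted as alternatives by the workflow;
  simultaneous fitting is possible through the `model_spec()` interface
  but is not validated here and typically demands more data structure
  than a single philopatric population provides.
* Delta-method standard errors of proportions are asymptotic and degrade
  near boundaries (where the proportion itself is flagged bound).
* The LRT df convention at the boundary is the naive one described above;
  p-values for spatial terms are conservative.
* Home-range estimation assumes enough fixes that the reference bandwidth
  is sensible; with very few fixes per individual the S matrix inherits
  kernel noise, which attenuates the spatial variance it can explain and
  makes the resulting heritability correction conservative.
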