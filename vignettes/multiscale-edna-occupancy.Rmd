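---
title: "Multi-scale occupancy modelling of ddPCR eDNA surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale occupancy modelling of ddPCR eDNA surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`ednaocc` implements the inferential chain of a paired environmental-DNA
(eDNA) survey quantified by droplet digital PCR (ddPCR): droplet counts are
turned into absolute concentrations, screened against negative controls, and
the resulting detection histories are fit with a three-level Bayesian
occupancy model. This vignette is the package's account of the science: the
model, its assumptions, the tunable parameters, the synthetic-data
generator, and the numerical choices made where the design was open.

## The observation problem

An eDNA survey of this kind has observational error at three nested scales.
A site (here, a tree island with or without a wading-bird breeding colony)
may or may not contain target eDNA; a 1-litre water sample from an occupied
site may or may not capture any of it, because eDNA is patchy; and a PCR
replicate of an eDNA-bearing sample may or may not amplify, because template
molecules are scarce and inhibitors are common. Ignoring any of these layers
biases occupancy estimates downward and confounds detectability with
presence.

## The model

For site $i$, sample $j$ within the site, and PCR replicate $k$:

$$z_i \sim \mathrm{Bernoulli}(\psi_i), \qquad
  \mathrm{logit}(\psi_i) = x_i^\top\beta$$
$$a_{ij} \mid z_i = 1 \sim \mathrm{Bernoulli}(\theta_{ij}), \qquad
  \mathrm{logit}(\theta_{ij}) = w_{ij}^\top\alpha$$
$$y_{ijk} \mid a_{ij} = 1 \sim \mathrm{Bernoulli}(p_{ijk}), \qquad
  \mathrm{logit}(p_{ijk}) = v_{ijk}^\top\delta$$

with $a_{ij} = 0$ forced when $z_i = 0$ and $y_{ijk} = 0$ forced when
$a_{ij} = 0$. The binary $y_{ijk}$ records whether replicate $k$ amplified
(at least one positive droplet, after limit-of-blank filtering).

Covariates enter each level on the logit scale. The categorical island type
(colony vs. control) is **cell-means coded** — one coefficient per type, no
global intercept — so that each type's occupancy has its own directly
interpretable coefficient; the occurrence and detection levels carry an
intercept plus centred and scaled numeric covariates. Numeric covariates
are standardized (sd with denominator $n-1$) over the units *at their own
level*: a sample covariate used at the detection level is standardized over
replicate units. Scaling metadata is kept so fitted curves can be mapped
back to natural units.

Reported derived quantities follow the conventions of this survey
literature: $\psi$ per island type (inverse logit at the type's design
row), $\bar\theta$ (posterior mean occurrence probability averaged over all
*observed* samples) and $\bar p$ (averaged over all observed replicates).
Averaging over observed units, rather than evaluating at covariate means,
was an open design choice; we average over units because it answers the
operational question — what fraction of samples like *these* carry eDNA —
and is invariant to how covariates are coded.

### Priors and sampling

All coefficients have independent $\mathrm{Normal}(0, \sigma_0^2)$ priors
with $\sigma_0 = 2$ by default (`prior_sd`). On the probability scale this
is weakly informative: it keeps $\mathrm{logit}^{-1}$ of a draw spread over
most of $(0,1)$ without piling mass at the extremes, and it regularizes the
separation problems that small occupancy datasets routinely produce (e.g. a
type in which every site yields detections).

The sampler is a Gibbs scheme written in C++:

1. **Latent states.** $a_{ij}$ given $z_i$ and the data, then $z_i$ given
   the $a_{ij}$. The full conditionals are
   $P(a_{ij}=1 \mid z_i=1, y_{ij\cdot}=0) = \theta q/(\theta q + 1-\theta)$
   with $q = \prod_k (1-p_{ijk})$, and
   $P(z_i=1 \mid a_{i\cdot}=0) = \psi r/(\psi r + 1-\psi)$ with
   $r = \prod_j (1-\theta_{ij})$; a positive replicate forces
   $a_{ij} = 1$ and hence $z_i = 1$. These conditionals are exposed as
   `latent_conditionals()` and are tested against exhaustive enumeration of
   the joint distribution.
2. **Coefficients.** Conjugate logistic updates via Pólya-Gamma
   augmentation: for each active unit, $\omega \sim \mathrm{PG}(1, \eta)$,
   after which the coefficient block is multivariate normal. $\delta$ is
   updated on replicates of samples with $a = 1$, $\alpha$ on samples of
   sites with $z = 1$, and $\beta$ on all sites with response $z$. The
   PG(1, z) sampler (`rpg()`) is the exact alternating-series rejection
   sampler; its moments are verified in the tests against
   $E[\mathrm{PG}(1,z)] = \tanh(z/2)/(2z)$. An adaptive random-walk
   Metropolis fallback (`sampler = "rw"`, componentwise, adapted toward
   0.44 acceptance during burn-in) is provided and agrees with the PG
   sampler in distribution.

The update order within an iteration is fixed ($a$, $z$, $\delta$,
$\alpha$, $\beta$) for reproducibility; chains are initialized at the
observed minimum ($z_i = 1$ iff the site has any detection, likewise
$a_{ij}$) with coefficients at zero. Runs are deterministic given a seed.
No thinning is applied; all post-burn-in draws are kept. Defaults are
100,000 iterations with burn-in 5,000, matching the protocol of the surveys
this package models; simulation studies in the tests use shorter chains
(3,000–15,000 iterations) because those designs mix within a few hundred
iterations, as the diagnostics (`occu_diagnostics()`: lag-1..50
autocorrelation, 50-batch Monte Carlo standard errors) confirm.

When a coefficient block has no active units (for instance $\delta$ in a
dataset with no occupied samples, or any block in a design with sites but
no samples), the conjugate update reduces to a draw from the prior — the
mathematically correct limit, which the tests exploit as a prior-recovery
check.

### Numerical choices

Linear predictors are clipped at $\pm 35$ before the logistic transform;
$\mathrm{logit}^{-1}(35) = 1 - 6.3\times10^{-16}$, so the clip is inert at
double precision but prevents overflow in `exp()`. Posterior intervals are
equal-tailed with percentiles by linear interpolation between order
statistics. Likelihood averages across draws use log-sum-exp.

## WAIC model comparison

Candidate models (the model-string grammar `psi(...)theta(...)p(...)`
mirrors how such model sets are written in the survey literature) are
ranked by WAIC computed from the **site-level marginal likelihood** — the
probability of a site's whole detection history with both latent states
integrated out:

$$L_i = \psi_i \prod_j B_{ij} + (1-\psi_i)\,I(y_{i\cdot\cdot}=0), \quad
  B_{ij} = \theta_{ij} \prod_k p_{ijk}^{y_{ijk}}(1-p_{ijk})^{1-y_{ijk}}
  + (1-\theta_{ij})\,I(y_{ij\cdot}=0).$$

Sites are the exchangeable unit of the design, and WAIC needs a predictive
density per independent unit; conditioning on sampled latent states instead
would make the "likelihood" depend on the imputation. Per site,
$\mathrm{lppd}_i = \log(\mathrm{mean}_s L_i^{(s)})$ and the penalty is
$\mathrm{var}_s(\log L_i^{(s)})$; the reported decomposition is lack of fit
$-2\sum_i \mathrm{lppd}_i$ plus predictive variance $2\sum_i
\mathrm{var}_i$, which sum to WAIC exactly by construction.

## ddPCR quantification and the limit of blank

Each reaction partitions into $m$ droplets of volume $v$ (nominally
0.00085 µL; the platform count is 15,000–20,000 droplets). Under Poisson
partitioning of template, the concentration estimate from $m_1$ positive
droplets is $\hat\lambda = -\log(1 - m_1/m)/v$ with delta-method standard
error $\sqrt{m_1/(m(m-m_1))}/v$. The default 95% interval is Wald on
$\log\hat\lambda$, back-transformed — it respects positivity, which matters
at the low concentrations typical of eDNA; a plain Wald interval is
available (`ci_method = "wald"`). A saturated reaction ($m_1 = m$) leaves
the estimator undefined and is an error, not a number.

Within a run, PCR replicates are pooled at the droplet level before
estimation. Samples re-run after additional inhibitor-removal (IRK)
treatments keep the run with the **highest** pooled concentration — the
convention for minimum-occurrence reporting, since IRK treatment can only
lose template — with ties broken toward the latest run.

The limit of blank (LOB) is the maximum pooled concentration across all
negative controls (field, filtration, extraction, no-template). Samples at
or below the LOB are zeroed — concentration and all replicate detections —
and within retained samples a replicate counts as a detection if it has at
least one positive droplet. Whether the original surveys zeroed whole
samples or individual replicates at the LOB is ambiguous ("zeroed all
samples" suggests sample level); we default to sample level and expose
`level = "replicate"` in `apply_lob()`, which additionally zeroes
individual replicates whose own single-replicate estimate is at or below
the threshold. PCR inhibition, measured as the fractional loss of the
internal positive control against the standards (`inhibition_ratio()`), is
carried as QC metadata only and never gates detections — target assays
routinely amplify in wells whose IPC is suppressed.

## Field statistics

Pre-model computations mirror the survey protocol: missing water
temperatures (thermometer failures) are imputed by OLS of temperature on
collection time over the measured samples — a deliberately simple model,
flagged per sample so analyses can exclude imputed rows; colony–control
pairs whose control median temperature is at least 8 °C above the colony
median are excluded from concentration comparisons (the boundary case is
excluded); the naive summary counts positives and averages **site totals**
(the sum of post-LOB sample concentrations within a site, zero sites
included — the reading consistent with a site-range maximum exceeding the
largest single sample); and the paired comparison is a classical paired
t-test on colony-minus-control site totals. The subtraction direction is
fixed as colony minus control and documented, since only the sign of $t$
depends on it. Percentages print at one decimal with round-half-to-even;
"before 11AM" means strictly before 660 minutes.

## The synthetic-data generator

`generate_dataset()` simulates the full design with known truth, down to
droplet counts — so the quantification chain, not just the model, is
exercised end to end:

* **Design defaults** are the study conditions of the paired surveys this
  package models: 15 colony–control pairs, 8–10 samples per site, 5 PCR
  replicates per sample, 15,000–20,000 droplets per reaction.
* **Truth defaults** are the coefficient scale such surveys report:
  occupancy cell means 1.17 (colony) / −0.19 (control), occurrence
  intercept $\mathrm{logit}(0.14)$, detection intercept
  $\mathrm{logit}(0.61)$ with time slope −0.33.
* **Covariate emulation** is simple by design: collection times drawn per
  site visit within 08:00–13:00, temperature linear in time plus Gaussian
  noise, depth a site-level value, date shared within a pair. No published
  generative model exists for these; only their structure (which level
  carries which covariate) matters for testing.
* **Detections run through droplets.** For a replicate of an occupied
  sample the effective amplifiable concentration is attenuated to
  $\lambda_{\mathrm{eff}} = -\log(1-p_{ijk})/(v m)$ so that
  $P(m_1 \ge 1) = p_{ijk}$ exactly, and $m_1 \sim
  \mathrm{Binomial}(m, 1-e^{-\lambda_{\mathrm{eff}} v})$. This keeps
  droplet counts the single source of detections (rather than adding a
  separate Bernoulli layer) while giving the recovery tests an exactly
  logit-linear detection probability. The sample's log-normal "true"
  concentration is recorded separately as ground truth.
* **False positives** are a per-replicate spurious burst: with probability
  `false_amp_rate`, an eDNA-free replicate receives
  $1 + \mathrm{Binomial}(m-1, 1-e^{-\lambda_0 v})$ positive droplets with
  $\lambda_0$ = `spurious_conc` (default 0.15 copies/µL, deliberately
  below a typical LOB so the filter catches most of them). With
  `false_amp_rate = 0` the hierarchy is exact: no detection without
  occurrence.

What the generator does **not** emulate: spatial correlation between
sites, eDNA transport between islands, concentration-dependent detection
within occupied samples (detection probability is driven by the covariates,
not by the drawn concentration), plate effects, or inhibition-induced
censoring. Passing recovery tests therefore demonstrate that the sampler
estimates the model it claims to fit — not that the model captures every
feature of real surveys.

The deterministic companion, `survey_fixture()`, is a fully specified
30-site survey whose count-level summaries are pinned by construction (19/137
and 5/128 positive samples, 10/15 and 4/15 positive sites, concentration
ranges 0.26–38.29 and 0.26–0.39 copies/µL, site-total means 3.20 and 0.11,
a 0.258 copies/µL no-template control, 97/137 and 91/128 samples before
11AM, 218/265 samples within 20.3–27.8 °C, exactly 3 temperature-excluded
pairs). Positive samples carry droplet counts obtained by inverting the
partition mean, so re-quantifying them reproduces the pinned values at
their printed precision; filler concentrations between the pinned endpoints
(≈0.556 and ≈0.338 copies/µL) are arbitrary up to the sum/mean constraints
and are documented as such. Integer droplet granularity (~0.015 copies/µL
per droplet at 80,000 pooled droplets) means one pinned value (0.39) needs
20,000-droplet replicates rather than 16,000. The fixture makes no attempt
to match dispersion statistics or model-based estimates — those depend on
the unpublished raw data.

## Worked example

```{r, eval = FALSE}
library(ednaocc)

fx <- survey_fixture()
quant <- pool_and_select(fx$replicates)
lob <- compute_lob(quantify_controls(fx$neg_controls))
filt <- apply_lob(quant, fx$replicates, lob)

fit <- occu_ms(list(sites = fx$sites, samples = fx$samples,
                    detections = filt$detections),
               model = "psi(type)theta(.)p(time)",
               n_iter = 20000, burn_in = 2000, seed = 1)
summary(fit)
compute_waic(fit)
plot(fit, "detection")
```

## Problem sizes and calibration checks

The simulation studies shipped with the package use 150-site surveys (75
pairs, 6 samples per site, 5 replicates) fit with 15,000-iteration chains
for interval calibration, and 3,000-iteration chains for the WAIC
comparison study; these sizes give stable Monte Carlo behaviour for designs
of this sparsity while keeping the full suite quick to run. Across
replicate surveys, 95% credible intervals for all coefficient families
cover their generating values at close to nominal rate, the fitted
colony/control occupancy ordering matches the simulated ordering, and WAIC
prefers the model containing a real detection-time effect
($\delta_{\mathrm{time}} = -0.8$) over the null in the large majority of
replicates. The exact acceptance thresholds live in
`tests/testthat/test-acceptance.R`, and `scripts/acceptance.R` recomputes
the headline quantities from scratch.

## Known limitations

* One season, closed sites: no colonization/extinction dynamics.
* No spatial dependence between sites or samples.
* Concentration informs detection only through the LOB filter; a joint
  concentration-detection model is out of scope.
* The WAIC unit is the site; sample-level cross-validation would answer a
  different predictive question.
* The temperature imputation is a convenience regression, not a calibrated
  micro-climate model; imputed flags are always carried so downstream
  analyses can drop those samples.
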