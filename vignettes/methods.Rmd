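---
title: "Gene-level CNV calling from amplicon counts: model, inference and QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level CNV calling from amplicon counts: model, inference and QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
generative model and the assumptions behind it, the parameters a user may
need to touch, what the synthetic-data generator does and does not emulate,
the numerical choices made where the design was genuinely open, and the
known limitations. Commands are shown unevaluated; every number quoted here
is computed by the test suite or by `scripts/acceptance.R`, not by this
document.

## From counts to lCNRs

The pipeline starts from per-amplicon read counts for a case sample and a
CNV-neutral reference processed under the same assay conditions. Four
assumptions motivate the transformations:

1. **Linearity** — expected read counts scale linearly with copy number: a
   four-copy locus yields on average twice the reads of a two-copy locus.
2. **Composition invariance** — tumor-derived DNA is processed like
   background DNA, so copy ratios, not tumor fraction, are the estimand.
3. **Stable amplicon effects** — per-amplicon amplification efficiency is a
   property of the assay, shared by process-matched samples; dividing by the
   reference count cancels it.
4. **Sparsity** — most amplicons are copy-neutral, so a robust location
   estimate of the log ratios identifies the sample-level offset.

Hence `compute_lcnr()` forms the natural-log ratio of case to reference
counts (after `filter_amplicons()` removes amplicons with a count below
`min_count` in either channel; the default `min_count = 1` removes exactly
the zero counts — amplicons that failed to amplify). `median_center()`
subtracts the panel median (assumption 4), absorbing depth and DNA-input
differences; with an even number of amplicons the usual
midpoint-of-central-values median is used. No pseudocounts are added
anywhere: failed amplicons are filtered, not smoothed.

When no matched normal exists, `build_batch_reference()` approximates one by
the mean profile across the samples of a batch. The mean is geometric
(arithmetic in log space), consistent with every downstream quantity living
on the log scale; an arithmetic mean would be biased upward by the skew of
count distributions. An amplicon contributes to the reference only from
samples where it passed filtering, and one that failed everywhere is marked
missing and excluded downstream. Whether the batch mean is computed before
or after depth normalization is immaterial here: per-sample depth enters as
a common factor that median centering removes.

`prepare_dataset()` composes these steps and groups the centered lCNRs by
gene. A gene retaining fewer than `min_gene_amplicons = 2` amplicons is set
aside — with one amplicon its gene-level noise scale is unidentifiable —
and resurfaces in the call report as a `no-call` with the reason recorded.
The exclusion happens before centering so that the centering identity
(median of retained values exactly 0 for odd counts) holds for the data
actually modeled.

## The hierarchical model

With `x_ig` the centered lCNR of amplicon `i` in gene `g`:

\[
\mu_0 \sim N(0, \nu),\quad
\sigma^2 \sim \mathrm{IG}(\alpha_\sigma, \beta_\sigma),\quad
\tau_0^2 \sim \mathrm{IG}(\alpha_{\tau_0}, \beta_{\tau_0}),
\]
\[
\mu_g \mid \mu_0, \sigma^2 \sim N(\mu_0, \sigma^2),\qquad
z_g \sim \mathrm{IG}(\alpha_\tau, \beta_\tau),
\]
\[
x_{ig} \mid \mu_g, \tau_0^2, z_g \sim
\mathrm{SoftLaplace}\!\left(\mu_g,\; \tau_g^2 = \tau_0^2 z_g^2\right).
\]

`mu_g` is the quantity of clinical interest: the gene-level lCNR, reported
as copy ratio `exp(mu_g)` and absolute copies `2 exp(mu_g)` under a diploid
baseline. The global level `mu_0` and variance `sigma^2` pool information
across genes; the per-gene noise multiplier `z_g` lets an erratic gene
inflate its own noise instead of corrupting its neighbors, and doubles as a
QC readout.

**SoftLaplace parameterization.** We use the hyperbolic-secant density
\(p(x \mid \mu, s) = \mathrm{sech}((x-\mu)/s)/(\pi s)\): Laplace-like
\(e^{-|x|/s}\) tails for robustness to amplification outliers, but smooth
everywhere — including the origin, where the Laplace density's kink breaks
gradient-based samplers. The model's \(\tau_g^2\) is interpreted as the
*squared scale* \(s^2\), so the observation scale is
\(s_g = \sqrt{\tau_0^2}\, z_g\). The main alternative reading —
\(\tau_g^2\) as the *variance*, which for this density equals
\((\pi^2/4) s^2\) — differs only by the constant \(\pi/2\) absorbed into
the noise hyperpriors; calibrated noise magnitudes under the other reading
would shift by that constant. `dsoftlaplace()` evaluates the log density as
\(\log(2/\pi) - \log s - (|z| + \log(1 + e^{-2|z|}))\), which is exact and
overflow-safe for any argument.

**Default hyperparameters** (all configurable through
`hyperparameters()`): \(\nu = 1\) (lCNRs live well inside ±1);
\((\alpha_\sigma, \beta_\sigma) = (\alpha_{\tau_0}, \beta_{\tau_0}) =
(3, 0.5)\), placing prior mass on dispersions of order 0.01–1 with finite
prior variance; \((\alpha_\tau, \beta_\tau) = (3, 2)\), concentrating
`z_g` near 1 (prior mean 1, mode 0.5) so that \(\tau_g \approx \tau_0\)
absent evidence. These are weakly informative: with hundreds of amplicons
the likelihood dominates all of them.

## Inference

`sample_posterior()` runs the No-U-Turn Sampler — self-tuning Hamiltonian
Monte Carlo that simulates the trajectory forward and backward and stops at
a U-turn, removing trajectory-length tuning — implemented in C++ with
analytic gradients. Two reparameterizations flatten the posterior geometry:

* non-centered gene means, \(\mu_g = \mu_0 + \sqrt{\sigma^2}\,\eta_g\) with
  \(\eta_g \sim N(0,1)\), removing the funnel between \(\sigma^2\) and the
  \(\mu_g\);
* log transforms of \(\sigma^2\), \(\tau_0^2\) and every \(z_g\) (with the
  Jacobians in the target), so the sampler works on an unconstrained space.

Warmup adapts the step size by dual averaging toward
`target_accept = 0.8` — the midpoint of the 0.6–0.9 band considered healthy
for HMC — and a diagonal mass matrix over doubling windows (75-iteration
initial buffer, 25-iteration base window, 50-iteration terminal buffer),
with step-size re-initialization after each metric update. Initial states
are jittered prior-typical values (log-scale parameters start at the prior
mode's neighborhood rather than the inverse-gamma tail); a non-finite log
density or gradient at initialization aborts with the offending component
named. All sampler randomness comes from a dedicated 64-bit generator
seeded from `sampler_config(seed)` (chain `c` uses `seed + c − 1`), so a
fixed seed reproduces draws bit for bit; simulation functions likewise
restore the caller's RNG state.

Defaults follow the method's published practice: 10,000 kept iterations
("iterations" read as post-warmup draws) and a single chain, with 1,000
warmup iterations as the adaptation budget. Multi-chain runs are supported
and recommended when wall-clock allows; they enable split-R-hat.
`check_convergence()` warns — it never blocks output — when the mean
acceptance probability leaves [0.6, 0.9], when any divergent transition
occurred, when the minimum effective sample size falls below the
configurable floor of 400 (our convention; no published threshold exists),
or when split-R-hat exceeds 1.01. ESS uses the standard between/within
decomposition with Geyer's initial monotone positive-sequence truncation;
R-hat is the split-chain form. Note that an acceptance rate *above* 0.9
also triggers the band warning: it signals an overly small step size (wasted
computation), not wrong answers.

## Calling

`call_genes()` applies two criteria to the marginal posterior of each
`mu_g`:

* **effect size** — posterior mean above \(\log T\) (gains) or below
  \(-\log T\) (losses), with `ratio_threshold` \(T = 1.5\) by default,
  i.e. three copies against diploid;
* **confidence** — posterior neutral-band probability
  \(\Pr(|\mu_g| < \delta) < \epsilon\), defaults \(\delta = 0.1\)
  (≈ ±10% copy-ratio band) and \(\epsilon = 0.05\).

\(\delta\) and \(\epsilon\) have no published numeric values; the defaults
are stated prominently in the report header and both criteria are
monotone — raising \(T\) or lowering \(\epsilon\) never adds calls, and
\(\epsilon > 1\) reduces calling to the effect-size rule alone. Losses use
the symmetric threshold \(-\log T\); a separate loss threshold was the other
candidate, but symmetric is the parsimonious choice and loss calling in
cfDNA assays is less validated either way (flagged in the docs). Reported
intervals are central 90% credible intervals, and `summarize_gene()`
requires at least 100 draws before it will summarize anything.

## Evidence-based sample QC

The marginal likelihood \(Z = \int p(x\mid\theta) p(\theta)\, d\theta\)
measures model–data fit with the parameters integrated out; degraded input
material produces data the model cannot explain at any \(\theta\), so its
evidence collapses. `ti_log_evidence()` estimates \(\log Z\) by
thermodynamic integration over power posteriors
\(p_\beta \propto p(x\mid\theta)^\beta p(\theta)\):

\[
\log Z = \int_0^1 E_{\theta \sim p_\beta}[\log p(x \mid \theta)]\, d\beta ,
\]

approximated on a ladder of `K = 20` inverse temperatures by the
trapezoidal rule with the *sum* of adjacent rung means,
\(\sum_k \tfrac{\beta_{k+1}-\beta_k}{2}(\hat\mu_k + \hat\mu_{k+1})\). The
sum form is the standard trapezoidal rule and the only form satisfying the
constant-integrand identity (\(\hat\mu \equiv c \Rightarrow \log\hat Z = c\));
a difference of adjacent means sometimes seen in print is treated as a
typographical slip and deliberately not implemented. Ladder spacing is
power-law, \(\beta_k = ((k-1)/(K-1))^5\): the integrand rises steepest near
\(\beta = 0\), so rungs concentrate there (exponent 1 recovers a uniform
grid). Each rung warm-starts from the previous rung's final state and runs
500 warmup + 1,000 kept draws by default; rungs with divergences or low
acceptance carry warnings but are never silently dropped. The integrand's
derivative in \(\beta\) is \(\mathrm{Var}_\beta[\log p(x\mid\theta)] \ge 0\),
so rung means must be non-decreasing; a decrease beyond 3 combined Monte
Carlo standard errors marks the estimate suspect. The reported standard
error combines per-rung errors (each \(\mathrm{sd}/\sqrt{\mathrm{ESS}}\))
through the trapezoid weights; it covers Monte Carlo error, not ladder
discretization, which the refinement test bounds separately.

`harmonic_mean_log_evidence()` implements the harmonic-mean estimator from
posterior draws via log-sum-exp. It is included **only** as a documented
baseline: dominated by rare low-likelihood draws, it can have infinite
variance, and its output carries an "unreliable" annotation. Use TI for
decisions.

`qc_evaluate()` fails a sample iff \(\log \hat Z\) falls strictly below a
threshold (equality passes). The threshold is panel-specific — it scales
with amplicon count and noise level — so none is shipped; without one the
verdict is "not evaluated". The whole TI machinery also runs on a built-in
conjugate normal–normal model (`ti_log_evidence_normal()`) whose evidence
is known in closed form, which is how the tests validate the estimator
end-to-end.

## The synthetic-data generator

`simulate_sample()` emulates the generative structure of a targeted
amplicon assay: lognormal amplicon efficiencies (`efficiency_sd = 0.5`, a
typical several-fold spread, shared between case and normal per assumption
3 and reusable across samples via the `efficiencies` argument), expected
depth 2,000 reads per amplicon (typical for CNV-grade targeted panels),
gene-level copy-ratio shifts scaling expected counts linearly, SoftLaplace
lCNR noise in the case channel (`noise_scale = 0.1`), Poisson counts around
the scaled expectations, and case-channel amplicon dropout. The default
panel layout — 10 genes × 40 amplicons — mirrors a several-hundred-amplicon
liquid-biopsy panel with ten CNV genes. A `deterministic` count mode rounds
the normal expectation and scales it exactly by the copy ratio, so unit
tests can assert exact doubling. `degraded_sample()` models damaged (e.g.
FFPE) input as noise × multiplier plus dropout; `dilution_series()` titrates
designated genes over a ratio grid with the efficiency profile held fixed
within a replicate, re-creating an in-silico dilution design; `lod_study()`
runs the full pipeline over the series and reports detection probabilities,
echoing a noise-scale estimate from the CNV-neutral genes
(\(\hat s = \mathrm{sd}/( \pi/2)\)) the way real studies calibrate noise to
empirically neutral genes.

What the generator does **not** emulate: GC-content bias curves, read- or
fragment-level artifacts, correlated amplicon failures, real panels'
uneven amplicons-per-gene, or the noise spectrum of any particular assay.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative structure — not clinical performance
on any specific panel, which must be established per assay.

## Calibration is on the estimand scale

Median centering defines the estimand: `mu_g` is the gene's lCNR *relative
to the panel median*. With a noticeable fraction of the panel amplified
(e.g. one gene of ten at ratio 2, i.e. 10% of amplicons), the realized
median sits at the ~56th percentile of the neutral noise distribution, so
every centered value — and every `mu_g` — is offset from the nominal truth
by a small amount (about −0.018 at noise scale 0.1). This is a property of
the centering convention, not an estimation error: the package's
calibration tests therefore measure credible-interval coverage against the
centered truth \(\log r_g - \mathrm{median}(\tilde x)\), where the posterior
is calibrated, and separately bound the nominal-scale bias of the amplified
gene's estimate. Practical consequences: copy ratios are mildly compressed
toward 1 when much of the panel is amplified (the same compression any
median-normalized method exhibits), and detection at a target ratio exactly
equal to the call threshold \(T\) is rare, since the estimate sits slightly
below \(\log T\) — the dilution-series tests show the detection probability
rising from ≈0 at ratio 1.0 to ≈1 at ratio 2.0 with the transition between
1.5 and 2 under the default conditions.

## Problem sizes used by the tests and acceptance script

Chosen to make the full suite a coffee-break run on one CPU while keeping
Monte Carlo error well inside the tested tolerances: recovery/calling
studies use 20 panels (10 genes × 40 amplicons, depth 2,000) at 500 warmup
+ 2,500 kept draws each; dilution series use 6 ratios × 10 replicates at
300 + 600 draws; evidence studies use 10 clean + 10 degraded samples at
K = 12 rungs × (250 + 500) draws; the conjugate-model validation uses
K = 20 × 1,000 draws. The acceptance script scales these to 10 panels,
5 replicates and 5 + 5 samples. All are reduced-size versions of the same
study designs; the model's production default remains 10,000 iterations.

## Known limitations

* Gene-level resolution only: no segment- or amplicon-level calls, no
  tumor-fraction deconvolution.
* Loss (deletion) calling uses the symmetric threshold and is less
  validated than gain calling.
* The median-centering offset above grows with the amplified fraction of
  the panel; panels where CNV targets dominate the amplicon count violate
  the sparsity assumption outright.
* Evidence values are comparable only within a panel and preprocessing
  convention; QC thresholds must be established per assay from known-good
  and known-bad samples.
* Single-chain defaults match the published practice; rhat-based checks
  require `num_chains > 1`.
* The TI standard error does not include ladder-discretization bias; the
  tests bound it by ladder refinement on the conjugate model.
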