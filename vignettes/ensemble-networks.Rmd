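---
title: "Ensemble network models and virtual knockdown trials for RA cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble network models and virtual knockdown trials for RA cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ravnet)
```

## The modelling problem

ravnet reverse-engineers an *ensemble* of causal Bayesian network
structures from three layers of rheumatoid-arthritis cohort data — SNP
genotypes, whole-blood transcript expression, and the four DAS28
disease-activity components (tender joint count TJ, swollen joint count
SJ, pain VAS, C-reactive protein) — and then interrogates the ensemble
with per-subject in-silico gene knockdowns to rank transcripts by their
predicted clinical impact.

The key identification idea is genetic anchoring: genotypes arise from
meiosis and are not caused by expression or disease state, so network
fragments that include SNPs are constrained to have the SNP upstream.
Expression and clinical variables may causally affect each other in
either direction, so all orderings among them are scored and the
*ensemble* — not any single best network — carries the directional
evidence.

## The local model: conditional linear-Gaussian fragments

Every non-SNP variable $X_i$ gets a set of candidate *fragments*: $X_i$
plus at most `max_parents` (default 2) parents and a fitted conditional
distribution.  With continuous parents $Y_{j}$,

$$X_i \sim \mathcal{N}\!\Big(\theta_0 + \sum_j \theta_j Y_j,\ \sigma^2\Big),$$

fitted by per-state ordinary least squares with the maximum-likelihood
residual SD.  Discrete parents (genotype dosages 0/1/2) contribute no
linear term; their joint state switches the whole parameter set, so an
eQTL fragment stores one $(\theta_0, \theta_j, \sigma)$ row per observed
genotype state.  Each fragment is scored by its BIC energy

$$S = -\log \hat L + \tfrac{\kappa}{2}\log N,$$

with lower scores more probable.  $\kappa$ counts, per state, one
intercept, one coefficient per continuous parent, and one residual SD —
the per-state-$\sigma$ convention, matching the rule that a discrete
state switches the *entire* parameter set.  A whole network's score is
the sum of its fragments' scores, because the joint likelihood
factorises over the local conditionals.

Two numerical guards matter in practice:

* **Residual-SD floor.**  $\hat\sigma$ is clamped below at
  $10^{-6}\,\mathrm{SD}(X_i)$ so that duplicated or collinear data
  cannot produce an infinitely good score.
* **State support.**  A joint discrete-parent state is only usable if it
  contains strictly more observations than the per-state mean
  parameters.  Without this rule a 2-subject genotype state fitted with
  an intercept and one slope is interpolated exactly, hits the SD floor,
  and acquires an enormous spurious likelihood that would dominate every
  library; with it, the rule reduces to the natural
  "at least two observations" requirement for intercept-only states.

`build_fragments()` enumerates all parent sets of size 0..2 per child
(SNPs are never children; by default phenotypes may not parent
transcripts, while transcript ↔ phenotype edges are allowed in both
directions) and retains the `fragments_per_child` best per child — 16 by
default, a compromise between move-space richness for the sampler and
library size; the parentless root fragment is always kept so every child
can be a source.

## Sampling the structure posterior

Networks are assembled by assigning exactly one library fragment to each
child, subject to global acyclicity.  A Metropolis chain proposes, at
each step, one uniformly chosen child and one uniformly chosen
alternative fragment for it — a single symmetric move type that covers
edge addition, deletion and replacement, so no Hastings correction is
needed.  Cyclic candidates are rejected outright (and still count as
steps, which keeps the chain correct).  At temperature $T$ a move is
accepted with probability $\min(1, e^{-\Delta S/T})$.

Cooling follows an adaptive simulated-annealing schedule: at each stage
the mean and variance of the score are estimated from the equilibrated
half of the stage, and the temperature step $\Delta T$ is chosen so that
the predicted score distribution at $T + \Delta T$ keeps an overlap
coefficient of 0.8 with the current one (the overlap coefficient of two
normal approximations; for equal variances the corresponding mean shift
is $2\,\Phi^{-1}(0.6)\,\mathrm{SD} \approx 0.507\,\mathrm{SD}$).  The
mean's temperature sensitivity comes from finite differences across
stages, or from the fluctuation–dissipation identity
$\mathrm{Var}(S)/T^2$ at the first stage.  Cooling stops exactly at
$T = 1$, where the Boltzmann distribution *is* the structure posterior;
going below 1 would overfit.  The initial temperature is probed upward
until at least 90% of moves are accepted; zero-variance stages fall back
to geometric cooling (factor 0.9).

At $T = 1$ the chain burns in for 10 accepted moves per child and then
records one member every (number of children) steps until the quota is
reached; `ensemble_size` (default 1024) members are collected round-robin
from `n_chains` independent chains with seeds derived from one master
seed, so a fixed `(seed, n_chains)` gives bit-identical ensembles.
`convergence_check()` compares replicate ensembles by per-edge frequency
differences, the diagnostic used to confirm that independent random
starting conditions agree.

A structural caveat the package deliberately exposes: two directions of
a purely continuous edge are likelihood-equivalent, and the single-
fragment move kernel cannot pass between them without visiting a much
worse intermediate state.  On such systems replicate chains can freeze
in different modes — `convergence_check()` flags this, and the
acceptance-rate warning fires.  Genetic anchoring is what breaks the tie
in the intended use.

## Simulation and knockdown semantics

`forward_sample()` sweeps a model in topological order, drawing each
unclamped variable from its fragment's state-matched normal conditional;
one full sweep yields one sample of all variables.  A knockdown of
transcript $g$ is graph surgery: the fragment that outputs to $g$ is
removed ($g$ becomes a root) and $g$ is clamped at the subject's
observed log-scale expression minus $\log(\mathrm{fold})$ — transcripts
are treated as natural-log expression, so a 10-fold knockdown is a
$-\log 10$ shift and exactly a factor 10 on the linear scale.

Per subject and gene, `simulate_subject()`/`run_trial()` draw one
ensemble member uniformly per replicate (model averaging), clamp the
subject's genotypes and all *other* transcript values — the
subject-conditioning rule — and sample the four phenotypes; 30
replicates per subject and gene are summarised by their median.  The
default conditioning clamps downstream transcripts too, so indirect
transcript-mediated effects are deliberately blocked and only direct
(and phenotype-mediated) paths register; `propagate_transcripts = TRUE`
switches to full do-operator semantics in which descendants of the
target respond.  Which convention an analysis wants depends on whether
the other transcript measures are viewed as fixed subject covariates or
as downstream consequences; both are first-class here, and the
ground-truth oracle `analytic_intervention_effect()` (path-coefficient
sums) corresponds to the propagating mode.

The untreated baseline is *simulated* with the same machinery and no
intervention — not read off the data — so that knockdown-vs-baseline
contrasts compare like with like.

## The virtual clinical trial

Per-subject medians are inverse-transformed to the clinical scale
(counts rounded to their integer grids only at this reporting step) and
compared with the baseline medians:

* **TJ, SJ** — a paired sign-pattern chi-square: among subjects whose
  count changed, the split of decreases vs increases against 50:50 with
  1 df.  This operationalises "a significant number of patients respond
  in a consistent direction"; an alternative contingency construction
  would bin count changes, but the sign form is the least parametric
  reading.
* **Pain, CRP** — paired two-sided Student's t-tests.
* **DAS28** — per-subject DAS28-CRP composed from the four medians,
  $0.56\sqrt{TJ} + 0.28\sqrt{SJ} + 0.36\log(CRP+1) + 0.014\,Pain +
  0.96$ (the standard clinical equation, with the pain VAS standing in
  for the global-health VAS), then a paired t-test.

Raw p-values at $\alpha = 0.05$ drive the ranking, mirroring the
screening character of the analysis; Benjamini–Hochberg q-values are
reported in clearly separated extra columns as an extension.  Categories:
genes significant on DAS28 are category 1 (novel role) or 2 (alternative
to TNF-α blockade) when an annotation table resolves them, otherwise
"1/2 (unresolved)"; genes significant on TJ or SJ but *not* DAS28 are
category 3 (impact joint health but not overall disease activity);
everything else is "none".  The partition is exhaustive and exclusive.

## The synthetic cohort generator

Because the original cohort data are not redistributable, every stage is
validated against `generate_ground_truth()` / `generate_cohort()`.  The
generator emulates the assumed data-generating process: SNPs in
Hardy-Weinberg equilibrium (MAF uniform on 0.10–0.40, dosage binomial),
cis-eQTL effects of one SNP per transcript (probability 0.8, effect
0.6–1.2 per allele), a sparse linear-Gaussian transcript cascade
(pairwise edge probability 0.08, in-degree capped at 2, residual SD 0.5
on the natural-log scale), and "planted" causal transcripts with direct
coefficient-0.8 edges into the phenotype latents (residual SD 0.6; CRP
latent centred at 1 so CRP ≈ 2.7 mg/L).  Latents map to the clinical
scale exactly inversely to the preprocessing transforms — bounded counts
through the inverse of $\mathrm{logit}((c+0.5)/(m+1))$ with rounding,
CRP through $\exp$ — so the pipeline's own modelling assumptions hold by
construction and recovery tests are fair.  The default study conditions
are 20 SNPs, 30 transcripts, 4 phenotypes and 100 subjects with 3
planted causes.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, batch or array effects, heavy-tailed expression noise,
missing-data mechanisms beyond MCAR, and the ~10⁴-variable scale of a
real cohort.  Passing recovery tests therefore show correctness of the
machinery under its own assumptions at desk scale, not field performance
on real data.

## Problem sizes and reproducibility choices

The bundled validation runs use desk-scale problem sizes chosen as the
package's own defaults for a laptop-class machine: fragment libraries
over the full 54-variable synthetic cohort (~45,000 candidate fragments),
ensembles of 256 members from 2 chains for the recovery and null
analyses, the full 1024-member default exercised on a compact
3-variable system, 30 replicates per subject and gene, and 50,000
Metropolis steps for the exact-posterior comparison.  All randomness
flows from explicit integer seeds; chains derive per-chain seeds from
the master seed, so every reported number is bit-reproducible.

## Known limitations

* BIC structure learning at $N \approx 100$ admits occasional spurious
  transcript → phenotype edges (a sample correlation above ~0.22 beats
  the penalty), and the downstream paired-median tests then flag those
  transcripts with near-certainty.  Calibration of the *trial
  statistics* is therefore assessed against the null model itself; the
  learned-ensemble false-positive rate on a null cohort is reported
  separately as a property of the whole pipeline, and on cohorts of this
  size it can sit well above the nominal level.  Users should read the
  ranking as a screening tool, exactly as the category system suggests.
* The fragment move kernel changes one child at a time; strongly coupled
  likelihood-equivalent modes mix slowly without genetic anchoring (see
  above).
* Fragment fitting assumes complete data; subjects with missing values
  in modelling variables are dropped with a logged count.
* Only knockdown (fold ≥ 1) interventions are exercised; overexpression
  works by `fold < 1` but is untested, and multi-gene combination
  interventions are out of scope.
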