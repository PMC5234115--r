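---
title: "Methods: models, generator design and numerical choices in microtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generator design and numerical choices in microtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microtrace` asks a forensic question of household microbiome data: can a
surface community be matched back to the occupants whose skin seeded it,
and how does that identifiability decay with the interval between skin and
surface sampling? This vignette is the package's own account of the models
it fits, the synthetic study generator that makes the pipeline testable,
and the numerical decisions taken where the design was genuinely open.

## 1. The source apportionment model

A surface sample (the *sink*) with reads $x_1,\dots,x_N$ is modelled as a
mixture of $V$ known source environments plus a latent *Unknown* source.
Each read carries a latent label $z_i \in \{1,\dots,V,\,U\}$ sampled by
collapsed Gibbs:

$$ P(z_i = v \mid z_{-i}) \;\propto\; P(x_i \mid v)\,\bigl(n_v^{(-i)} + \beta\bigr) $$

For a known source $v$, $P(x_i\mid v) = (m_{v,x_i} + \alpha_1)\,/\,(\sum_t
m_{v,t} + T\alpha_1)$, where $m_v$ are the pooled (summed, not averaged)
counts of the environment's member samples and $T$ is the number of OTUs.
The Unknown source has no training counts: its likelihood uses the sink
reads currently assigned to it with smoothing $\alpha_2$, so it adapts to
whatever the known sources cannot explain. The estimate reported is the
posterior-mean occupancy $n_v/N$, averaged over independent restarts.

Defaults are the cited tool family's v1.0 defaults: $\alpha_1 = 0.001$,
$\alpha_2 = 0.1$, $\beta = 10$, 10 restarts, 100 burn-in sweeps, one
retained draw per restart (`st_params()`). All are configurable. Internal
rarefaction is deliberately disabled: tables arrive pre-rarefied from
`rarefy()`, and subsampling twice would only add noise. Sources are
re-ordered to a canonical (alphabetical) order before sampling, which makes
the estimate exactly invariant to the order in which sources are supplied
under a fixed seed. The per-read sweep is written in C++ and driven by R's
RNG, so `set.seed()` governs the chains.

Two properties of this sampler matter for interpretation. First, the
Unknown source is greedy: because it learns the sink's own composition, any
systematic difference between the sink's profile and the source profiles is
absorbed by Unknown rather than split among the near-miss sources. A
perfect 0.6/0.2/0.2 mixture at depth 1000 is recovered as roughly
0.57/0.18/0.20 with ~5% Unknown — the estimator shrinks towards Unknown by
a few points even in the ideal case. Second, pooled sources must actually
resemble the sink's components: a surface trace that is a renormalised
*subset* of the skin profile (e.g. under a strong deposition bottleneck)
can lose most of its reads to Unknown despite originating from skin. Both
behaviours shaped the generator defaults (section 3).

## 2. Matching, delay and scoring

One input table is built per (target residence, source season) pair: sinks
are the residence's surface samples from *all* seasons; sources are the
skin samples of *every* residence in the source season, grouped into one
candidate environment per residence occupant group (per-individual grouping
is available). The 10% prevalence filter is applied within each input
table, not globally. A sink counts as accurately matched when its own
residence's contribution is *strictly* greater than every other
candidate's: exact ties score as incorrect, and the Unknown source can
never win a match. Sinks whose known-source proportions are all zero
(everything assigned to Unknown) are likewise scored incorrect rather than
dropped. Sampling delay is sink season minus source season, an integer in
$[-(S-1), S-1]$, positive when the surface was sampled after the skin.
Accuracy is computed per sink sample, not per residence.

The candidate-subset experiment re-runs delay-0 matching against random
candidate pools of sizes 2, 4, 6 and 8 that always contain the correct
group, with 50 random subsets per size by default (the repeat count is a
package choice; the design itself does not fix one).

## 3. The synthetic household generator

`generate_study()` emulates the study design the package targets: 9
residences housing occupant groups of sizes $\{1,1,2,2,2,2,3,3,3\}$ (19
individuals), 4 ordered seasons (winter = 1), 5 skin sites per individual,
8 surface and 4 air sites per residence, 9 kit controls — 380 skin, 288
surface and 144 air samples. Read depths are drawn uniformly from
1381–3000 (the design's most depauperate sample had 1381 reads; the upper
bound is a package choice).

OTU classes and dynamics:

* **Core** OTUs are drawn per individual from a cohort-wide pool twice the
  per-individual count, so core membership overlaps between individuals and
  private features are predominantly identifying/transient. Cores and
  household-**shared** OTUs are permanent.
* **Transient** OTUs are acquired per individual per season and survive
  season-to-season with `skin_retention_prob` (default 0.85).
* **Identifying** OTUs are private to one individual, present from season
  1, and subject to the same retention process as transients — so the
  regime in which identifying features are preferentially lost is a
  generator property, not something hard-coded in the analysis.
* **Environment** OTUs form a seasonal pool: air samples and the surface
  air/residual components draw from a rotating window covering half the
  pool, with 50% carryover between consecutive seasons (outdoor-derived
  communities turn over with the seasons).
* **Contaminant** OTUs dominate kit controls and appear at low mass in the
  surface residual component year-round.

Base abundances are log-normal (default $\mu = 0$, $\sigma = 1.5$) shared
across seasons with per-sample multiplicative log-normal noise (sd 0.5).
Identifying and transient OTUs are drawn from a lower, tighter distribution
($\mu - 1$, $\sigma/2$): established residents dominate abundance while
seasonal acquisitions are numerous but individually minor. This reproduces
the regime the analyses presuppose — a heavy-tailed rank-abundance curve in
which the stable minority of OTUs carries most of the mass (and which the
99th-percentile abundance bin is designed around), and a persistent-OTU
abundance share slightly higher on skin than on surfaces.

Surfaces are mixtures: `mix_weights` (default 0.6 skin / 0.17 air / 0.23
residual, the attribution the emulated study reports) over (i) the pooled
occupant-skin profile restricted to OTUs that have been deposited and
retained, (ii) the residence's seasonal air profile, and (iii) a random
residual draw. Deposition is a per-season, per-surface-site Bernoulli trial
with probability `deposition_prob_base * relab^deposition_abundance_exponent`
(defaults 1 and 0.05): near-certain deposition over a three-month season
with a mild abundance penalty. We deliberately rejected a stronger
bottleneck: it renormalises the surface trace away from the pooled skin
sources, and the Unknown source then swallows the skin contribution (9%
attributed skin under base 0.9/exponent 0.15 versus ~50% under the
default, against a configured 60%). The cost of the saturated-deposition
default is that the *deposition* hazard model is nearly uninformative under
default conditions — almost every observed skin OTU deposits in its first
season — so studies of deposition hazards should lower
`deposition_prob_base` or raise the exponent, accepting weaker source
attribution in exchange.

The generator records its latent truth: OTU classes and owners, the
per-surface-sample effective mixing proportions, deposition and loss
schedules, and each sample's latent support (the mixture's OTU set before
multinomial read sampling). Deterministic-limit tests assert on the latent
support, because at finite depth the multinomial can drop rare members from
the realised counts. `degrade_over_seasons()` exposes the turnover
mechanism in isolation, re-normalising changed samples to their original
depths by largest-remainder rounding (which preserves presence/absence).

What the generator does *not* emulate: read-level sequencing error,
chimeras, primer bias, compositional correlation between OTUs, or
phylogenetic signal in ecological class (the tree is a random topology with
exponential branch lengths, sufficient for UniFrac correctness but carrying
no habitat structure). Passing tests therefore demonstrate that the
pipeline's logic is correct under known ground truth, not that real
households behave like the generator.

## 4. UniFrac

Unweighted UniFrac is the fraction of branch length leading exclusively to
leaves present in one of the two samples; weighted UniFrac is
$\sum_b \ell_b\,|p_A(b) - p_B(b)|$ over branches, with $p_X(b)$ the
fraction of $X$'s reads below branch $b$. The default weighted variant is
the raw (non-normalised) form, mirroring the cited pipeline's defaults; the
normalised form (invariant to uniform branch-length scaling) is available
by flag, and both are checked against an independent per-branch enumeration
oracle to 1e-10. Distances are computed on rarefied tables. Delay profiles
aggregate all pairwise skin x surface combinations within a residence.
With exponential branch lengths the raw weighted distances are on an
arbitrary scale (typically ~5–15 here); only comparisons carry meaning.

### Persistence accounting

First-observation mapping and persistence counting are context-level: a
skin OTU lives on an (individual, body site) pair and a surface OTU on a
(residence, surface site) pair, so the same OTU can be "new" on one site
while long-established on another. Persistence counts *distinct* seasons
of observation with gaps allowed — an OTU seen in winter and summer but
not spring counts two seasons — consistent with the survival module's rule
that an interim absence is not a loss event. Pooling an individual's sites
before attribution was considered and rejected: the per-site account is
what the survival models consume, and mixing the two granularities would
make the persistence shares and the loss hazards answer subtly different
questions.

## 5. Identifiability: IndVal and hitting sets

For OTU $o$ and individual $i$ within one season, specificity is $i$'s mean
relative abundance of $o$ across body-site samples divided by the sum of
those means over individuals; fidelity is the fraction of $i$'s site
samples containing $o$; IndVal is their product. Significance comes from
permuting individual labels over site samples (default 999 permutations)
with the add-one estimator $(b+1)/(B+1)$, so p-values are never zero;
non-significant values are masked to 0 before binning.

Hitting sets are built greedily: candidates are OTUs the target carries at
relative abundance $\ge$ `detect_threshold` (default 1e-3); a candidate
resolves a confounder whose abundance is below `detect_threshold /
demotion_factor` (default 2); the candidate resolving the most unresolved
confounders is added, ties broken by higher target abundance then
lexicographic OTU id. Both thresholds are declared package defaults — the
original relab-mode script's exact values are not reproduced in the source
material — and are exposed as arguments. Re-identification requires *every*
member OTU at or above the detection threshold, so a complete set yields no
false positives at build time by construction, and degradation across
seasons manifests first as false negatives.

## 6. Survival models

Counting-format records: one subject per (OTU, context), one interval per
season transition from first observation, covariates evaluated at the
season opening the interval. The loss event is placed on the transition
*out of* the last observed season (the "first absence"), so single-season
subjects contribute one at-risk interval; the alternative reading — ending
the record at the last observation — is available via `loss_at =
"last_observed"`. Interim absences are not loss events and take the lowest
abundance bin. Subjects first observed in the final season have no
transition and contribute no record. Abundance percentile bins
(0–69/70–89/90–98/99, computed among OTUs present in the context-season),
IndVal bins (0–0.2/0.2–0.6/0.6–0.9/0.9–1, right-open, masked values), and
hitting-set membership fixed at the first-observed season. Surface models
include only OTUs also seen on an occupant's skin, take the maximum IndVal
among occupants and membership in any occupant's hitting set. Deposition
subjects are skin (OTU, body site) observations; the event is the first
surface observation in the same or a later season (same-season events land
on the first interval, which cannot be zero-length); OTUs on a surface
before their first skin observation are excluded.

`cox_fit()` maximises the Efron-corrected partial likelihood by
Newton-Raphson with step halving, converging when the gradient norm falls
below 1e-8 (50 iterations maximum). The step-halving acceptance margin
scales with $|\ell|$ so floating-point noise near the optimum cannot veto
full Newton steps. Breslow tie handling is available (`ties = "breslow"`);
the classic duplicated-data invariant (coefficients unchanged, $z$ scaled
by $\sqrt2$) is exact under Breslow and approximate under Efron. Complete
separation — an indicator constant among event intervals while varying
overall — is detected before fitting; the fit proceeds best-effort and the
affected coefficients are flagged `unstable` with a warning rather than
failing, since all-or-no-event levels (e.g. a 99th-percentile bin whose
OTUs are never lost) are expected outcomes, not errors. Reference levels
carry no coefficient: lowest abundance bin, lowest IndVal bin,
non-membership. One pooled model is fitted per family; the continuous
masked-IndVal covariate can be added via `covariates =` but defaults off,
as it largely duplicates the binned term.

## 7. Problem sizes and determinism

The test suite and `scripts/acceptance.R` run every experiment at reduced
design sizes chosen as the package's own working scale: 3–4 residences,
5–6 occupants, 3–4 sites per class, read depths of 300–1200, 3–10 sampler
restarts with 50–100 burn-in sweeps, 10-seed replication for
direction-only checks, and 50–100 replicates for the Cox calibration
studies. The full 9-residence default design generates in ~1 second;
matching experiments dominate runtime through the Gibbs sweeps. Every
stochastic step takes an explicit seed (`withr::with_seed` internally, so
the caller's RNG state is never disturbed), and regeneration with the same
configuration is bit-identical.

## 8. Known limitations

* The Unknown source absorbs a few percent of genuinely attributable reads
  even under perfect mixtures, and same-season sources cannot claim
  old-trace mass, so estimated skin contributions sit ~5–10 points below
  the generator's instantaneous mixing weight in later seasons. This
  mirrors the delay phenomenon under study rather than contradicting it.
* Under default (saturated) deposition the deposition hazard model is
  nearly degenerate; see section 3.
* The Cox implementation fits fixed and time-varying covariates in the
  counting format but provides no stratification, frailty terms, or
  proportional-hazards diagnostics.
* Percentile binning uses mid-rank percentiles of within-context
  abundance; with very few OTUs present in a context the 99th-percentile
  bin can be empty, in which case its indicator column is dropped from the
  fit with a message.
* IndVal permutation p-values are computed per (OTU, individual) cell;
  with the default 0.05 mask and hundreds of OTUs, some masked values
  survive by multiplicity. The emulated analysis applied the same
  per-cell masking, so this is retained deliberately.
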