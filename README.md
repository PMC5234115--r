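# microtrace

Humans shed individually distinctive skin microbiota onto the surfaces they
touch, and these "microbiota traces" have been proposed as a forensic
analogue of fingerprints. Unlike fingerprints, though, both skin communities
and their deposited traces change over time — so a trace collected long
before or after the skin sample it is compared against may no longer point
to the right person. `microtrace` implements an end-to-end analysis of this
problem for a multi-season household study design: can surface communities
be matched to household occupants, how fast does matching accuracy decay
with the sampling delay between skin and surface collection, and are the
OTUs that make people identifiable the very ones that are lost fastest?

The package is aimed at microbiome researchers working with OTU tables
(samples x OTUs with taxonomy), sample metadata and a rooted OTU phylogeny.
Because the emulated study design is fully specified, a synthetic
household-microbiome generator with known ground truth ships as a
first-class module, so every stage can be exercised and tested without any
external data.

## What it implements

* **Synthetic household studies** — `household_config()` /
  `generate_study()` emulate a 9-residence, 19-occupant, 4-season design
  (380 skin, 288 surface, 144 air samples, 9 kit controls) with
  configurable source-mixing weights, seasonal OTU turnover, skin-to-surface
  deposition and per-individual identifying OTUs; the latent ground truth
  (OTU classes, mixing proportions, deposition/loss schedules) is returned
  alongside the data.
* **Preprocessing** — `flag_contaminants()` (an OTU at >= 5% relative
  abundance in any kit control is a likely contaminant), `rarefy()`
  (subsampling without replacement to the most depauperate sample's depth),
  `prevalence_filter()` (OTUs present in < 10% of an input table's samples
  are excluded), `family_source_composition()` (abundance share of
  user-supplied indicator families per candidate source).
* **Phylogenetic distances** — `unifrac()` computes weighted (raw or
  normalised) and unweighted UniFrac; `delay_distance_profile()` aggregates
  skin-surface distances within residences by signed sampling delay;
  `group_compare()` wraps the Mann-Whitney and Kruskal-Wallis tests.
* **Source apportionment** — `gibbs_apportion()` is a collapsed Gibbs
  sampler over per-read latent source labels (known source environments
  plus an Unknown source; Dirichlet smoothing alpha1 = 0.001, alpha2 = 0.1,
  assignment prior beta = 10, 10 restarts, 100 burn-in sweeps), the model
  family used by Bayesian microbial source-tracking tools. The per-read
  sweep is implemented in C++.
* **Microbiota matching** — `run_matching()` builds one input table per
  (residence, season) pair — surface sinks from all seasons against pooled
  occupant-skin sources from one season — scores a sink as matched when its
  true residence receives a strictly greater contribution than every other
  candidate, and `accuracy_by_delay()` / `subset_size_experiment()` resolve
  accuracy by sampling delay and candidate-pool size.
* **Persistence** — `first_observation_map()`,
  `seasonal_origin_fractions()` and `persistence_share()` map each OTU in
  each context (individual x body site, or residence x surface site) to the
  season it was first observed and measure how much abundance persistent
  OTUs carry.
* **Identifiability** — `indval()` (specificity x fidelity with permutation
  p-values), `build_hitting_set()` (greedy minimal OTU sets that uniquely
  identify an individual) and `reidentify()` (re-identification across
  seasons, with true-positive / false-negative / false-positive accounting).
* **Survival models of OTU loss and deposition** — `build_loss_records()`
  and `build_deposition_records()` construct right-censored counting-format
  interval tables (abundance percentile bins 0–69/70–89/90–98/99, IndVal
  bins 0–0.2/0.2–0.6/0.6–0.9/0.9–1, hitting-set membership fixed at first
  observation; interim absences are not loss events), and `cox_fit()`
  maximises the Efron-corrected partial likelihood by Newton-Raphson,
  reporting hazard ratios with Wald 95% CIs. `hazard_report()` combines the
  skin-loss, surface-loss and deposition fits.

## The model at the core

For a surface (sink) sample with reads x_1..x_N and source environments
v = 1..V with pooled OTU counts m_v, each read carries a latent label
z_i ∈ {1..V, Unknown} sampled by collapsed Gibbs:

    P(z_i = v | z_-i)  ∝  P(x_i | v) · (n_v^(-i) + β)

with P(x_i | v) = (m_{v,x_i} + α1) / (Σ_t m_{v,t} + T·α1) for known
sources, and the Unknown source's likelihood computed from the sink reads
currently assigned to it with prior α2. The mixing proportion estimate is
the posterior-mean occupancy n_v/N averaged over restarts. Matching then
asks whether the sink's own residence wins that decomposition.

OTU loss is modelled as a proportional-hazards process on season
transitions: an interval (s, s+1] per subject (OTU in a context) with
covariates evaluated at season s, an event on the transition out of the
last observed season, and right-censoring in the final season. `cox_fit()`
maximises the Efron partial likelihood; a hazard ratio below 1 for the 99th
abundance percentile means abundant OTUs are lost more rarely than the
0–69th-percentile baseline.

## Worked example

```r
library(microtrace)

cfg <- household_config(
  n_residences = 3, occupants_per_residence = c(1, 2, 2),
  skin_sites = c("palm", "forearm", "forehead"),
  surface_sites = c("desk", "tv", "fridge"),
  air_sites = "bedroom_air", n_controls = 3,
  read_depth_range = c(400, 600),
  n_core_otus_per_individual = 10, n_shared_household_otus = 5,
  n_transient_otus_per_season = 6, n_identifying_otus_per_individual = 4,
  n_environment_otus = 40, n_contaminant_otus = 10, rng_seed = 11L)
study <- generate_study(cfg)

tab <- rarefy(study$table, seed = 1)
contam <- flag_contaminants(tab, study$meta$sample_id[study$meta$type == "control"])
tab <- subset_table(tab, otus = setdiff(colnames(tab$values), contam))

res <- run_matching(tab, study$meta,
                    params = st_params(restarts = 5, burnin = 50), seed = 3)
accuracy_by_delay(res)
#>   delay  n accuracy
#> 1    -3  9        1
#> 2    -2 18        1
#> 3    -1 27        1
#> 4     0 36        1
#> 5     1 27        1
#> 6     2 18        1
#> 7     3  9        1
```

Each row is one sampling delay (surface season minus skin-source season;
positive means the surface was sampled after the skin), `n` the number of
surface sinks scored at that delay, and `accuracy` the fraction whose own
residence received the strictly largest estimated skin contribution. Under
this compact high-signal configuration every sink is matched at every
delay; under turnover-heavy conditions (lower retention probabilities,
transient-dominated skin) accuracy decays from ~0.86 at delay 0 to ~0.43 at
|delay| = 3 — the degradation pattern the package exists to quantify.

A Cox fit on the same study:

```r
ann <- survival_annotations(tab, study$meta, n_perm = 199, seed = 5)
fit <- cox_fit(build_loss_records(tab, study$meta, "skin", ann))
print(fit)
#> Cox proportional-hazards fit (Efron ties): 547 subjects, 109 events
#>                      coef exp(coef)     se       z      p
#> abund_bin:p70_89  -0.5172    0.5962 0.2975 -1.7384 0.0821
#> abund_bin:p90_98  -1.3714    0.2538 0.7457 -1.8390 0.0659
#> abund_bin:p99     -0.8605    0.4230 1.0340 -0.8322 0.4053
#> indval_bin:v02_06 -0.8670    0.4202 1.1186 -0.7750 0.4383
#> indval_bin:v06_09  2.0850    8.0447 0.5779  3.6081 0.0003
#> indval_bin:v09_1   2.4415   11.4899 0.5122  4.7666 0.0000
#> hs_member:TRUE    -0.1258    0.8818 0.5584 -0.2253 0.8217
#> log partial likelihood: -615.0241 (7 iterations)
```

Read this as: OTUs in higher abundance percentiles are lost less often than
the 0–69th-percentile baseline (hazard ratios below 1), while OTUs that are
strong indicators of one occupant (IndVal above 0.6) are lost an order of
magnitude more often — identifiability and longevity trade off.

`summary(fit)` tabulates each covariate level's hazard ratio, 95% CI, Wald
z and p; levels with all-or-no events are flagged `unstable` (complete
separation) rather than reported as converged estimates.

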