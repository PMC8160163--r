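---
title: "Methods: correlation networks for judo match performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation networks for judo match performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(judonet)
```

## The model

`judonet` analyses the performance of judo athletes under three
inspiratory-muscle pre-activation conditions — no pre-activation (`CON`),
and pre-activation at 15% and 40% of maximal inspiratory pressure
(`IMPA15`, `IMPA40`) — as three correlation networks over a fixed
52-parameter vocabulary. Per scenario, every unordered pair of parameters
is tested for Spearman correlation across the athletes; an undirected edge
joins the pair when the two-sided p-value does not exceed the significance
level `alpha` (default 0.05). Edge weight is `|rho|`; the sign is kept as
an attribute. Node importance is summarised by Degree (incident-edge
count, unweighted) and by PageRank (the stationary distribution of a
damped weighted random walk), and per metric the tie-aware top five nodes
(10% of 52) are reported. Connectivity across scenarios is compared
through the percent change in edge count relative to `CON`.

The statistical assumptions are deliberately weak: Spearman correlation
only assumes monotone association, and the scenario comparison
(`friedman_rank_test`) is a rank-based repeated-measures test. The
stronger — and openly stated — assumption is an inferential one: edges use
*raw per-pair p-values with no multiple-testing correction* across the
1326 pairs. With 10 athletes per scenario, per-pair power is low and a
corrected threshold would empty the graph; the uncorrected p <= 0.05 rule
defines the network descriptively, which is why every report emitted by
the package flags the threshold as uncorrected. Roughly 5% of null pairs
(about 66 of 1326) will be spurious edges; cross-scenario edge-count
differences smaller than that noise floor should not be interpreted.

## The 52-parameter catalog

The vocabulary has five categories: athlete profile (2), physical /
anthropometric (13), physiological (17), psychophysiological (4) and
technical-tactical (16). Two conventions deserve note. First, the seven
inspiratory measures (MIP, S-index mean/peak, peak inspiratory flow
mean/peak, inspired volume mean/peak) are assigned to the *physiological*
category: they are capacity measures of a physiological system, and this
keeps the physical group at exactly the 13 anthropometric/body-composition
parameters. Second, rest-moment values of lactate, heart rate and RPE are
not catalog parameters — the networks use pre, post, delta, peak,
time-to-peak and rate-of-decay statistics; the rest values exist only
inside the simulated recovery series. The 22 profile, anthropometric and
inspiratory parameters are measured once per athlete and must be
numerically identical across the three scenario tables
(`validate_datasets` enforces this).

## The cohort simulator

No raw per-athlete data are published for this design, so the generator
is a first-class, tested component that emulates the study conditions: 10
male athletes, 4-minute matches, three scenarios, recovery sampled at
rest, pre, post and every 2 min to 10 min.

**Matches** are built from alternating structure, not summary statistics:
combat blocks (a standing phase, optionally followed by one groundwork
phase) alternate with pauses, starting and ending on a combat block, so
the pause count is one less than the combat frequency. Phase durations are
gamma-distributed (shape 4, i.e. coefficient of variation 0.5) with
scenario-specific means; blocks are appended until the accumulated combat
time reaches 240 s and the final phase is truncated to hit the total
exactly — matches last 4 minutes of combat independent of score, and never
terminate early on ippon. Because the time-motion parameters are computed
from the segments, every structural identity (TSCT + TGCT = 240, CF·ACT =
TSCT + TGCT, APT = TPT/(CF − 1), E:P = ACT/APT) holds on every generated
record by construction, which makes the derived-metric layer testable
end-to-end. Attack onsets follow a Poisson process on the combat clock
(rate about one attack per 15 s of combat); each attack independently
scores ippon or wazari with scenario-shifted probabilities.

Three conventions the summary statistics do not pin down were fixed once:
ACT is the mean *combat-block* duration (standing plus its groundwork),
ASCT/AGCT are means over the standing and groundwork phases separately
(AGCT over blocks that contain one); time between attacks is the mean gap
between consecutive onsets on the combat clock, with fewer than two
attacks defined as the full combat time; and the pause count is CF − 1,
the only choice consistent with total and average pause times of roughly
52 s and 7.5 s at a combat frequency of 8.

**Physiology.** Lactate (mM), heart rate (bpm) and RPE (6–20 Borg scale,
integers) are generated as rest baseline → pre-combat rise → post = pre +
response → recovery. The response magnitude is the scenario default scaled
by the athlete's anaerobic-capacity factor plus noise. Recovery follows a
rise to a peak (lactate may peak 0–4 min after combat; heart rate and RPE
peak at the post moment) and then an exponential decay toward the rest
baseline, evaluated at the 2-min sampling grid — so the series is monotone
after its peak by construction and peak, time-to-peak and rate-of-decay
(100·(max − min)/max, subtraction before division — the only reading on a
percent scale) are well defined. Decay constants (lactate ≈ 0.04/min,
heart rate ≈ 0.145/min, RPE ≈ 0.2/min) were chosen so the implied decay
rates land near the reported group means.

**Latent factors.** Each athlete draws three standard-normal factors —
body size, anaerobic/inspiratory capacity, technical skill. The 22 shared
parameters are `mean + sd·(l·z + r·eps)` with unit-variance normalisation
(`r = sqrt(1 − |l|²)`), with means and SDs taken from the reported group
means and SEM-derived standard deviations (SD = SEM·√10). Body mass and
thigh circumference both load 0.95 on body size, planting a population
Pearson correlation of about 0.90 (population Spearman ≈ 0.89): this is
the pair the network must recover, and the package's acceptance suite
verifies it appears as an edge in at least 80% of seeded cohorts while
independent null pairs stay at the nominal 5% edge rate. Skill shifts the
attack rate and ippon probability; anaerobic capacity scales the
physiological responses.

Calibration targets group means within about one standard error of the
reported values, not exact reproduction; the table of means is itself not
perfectly self-consistent (e.g. a mean combat frequency of 9 with mean
combat time 32.5 s cannot both hold at 240 s of combat — a mean-of-ratios
versus ratio-of-means artefact), and the generator resolves this by
enforcing the identities per match and letting the means follow.

What the generator does *not* emulate: any mechanistic model of
inspiratory-load physiology or the metaboreflex (scenario effects are
phenomenological shifts), opponent interaction, within-match fatigue
drift, or non-normal tails in the anthropometrics. Passing tests therefore
show that the inference chain recovers planted structure under realistic
noise — not that the physiological claims hold in real athletes.

**Reproducibility.** All draws descend from one integer seed; each
(athlete, scenario) pair runs in its own deterministically derived
substream, so cohorts are byte-identical across runs and invariant to
evaluation order.

## Statistical engine

Spearman's rho is computed as the product-moment correlation of
average-rank vectors (tie-safe; the 6Σd² shortcut is biased under ties).
Three p-value methods are provided; the default picks full permutation
enumeration for n ≤ 8 (at most 40 320 permutations) and the Student-t
approximation above, so 10-athlete cohorts use the t approximation. The
original analysis does not state its p-value algorithm; near the 0.05
boundary the two methods can classify an edge differently, which is why
the method is explicit, switchable, and cross-checked: enumeration serves
as the oracle for the t approximation (they agree within 0.05 absolute at
n = 7), and an independent reference implementation is compared against in
the test suite. Monte-Carlo permutation (default 10 000 replicates) uses
an explicit seed and the add-one estimator. Missing values (e.g.
effectiveness with zero attacks, which is 0/0 and deliberately *not*
zero) are deleted pairwise; an edge requires at least 4 remaining pairs.
Constant columns have undefined correlation and simply acquire no edges —
the node stays in the graph.

The Friedman statistic uses the tie-corrected form
`(k−1)·Σ(R_j − n(k+1)/2)² / (A − C)`, which reduces to the classical
`12/(nk(k+1))·ΣR_j² − 3n(k+1)` without ties and is defined as 0 when all
within-block values tie (A = C). The post-hoc is concretised as pairwise
Wilcoxon signed-rank with Bonferroni adjustment `min(1, m·p)` over the
k(k−1)/2 pairs.

## Numerical choices

- **PageRank**: power iteration from the uniform vector; damping 0.85;
  convergence when the L1 change drops below `tol = 1e-9`; hard error with
  diagnostics after 1000 iterations. Isolated nodes are dangling and
  redistribute their mass uniformly over all nodes — the standard
  convention, stated here because the graph tool originally used for this
  analysis does not document its internals. Edge weights must be
  nonnegative for the random walk, hence `|rho|` with the sign kept as an
  attribute; Degree deliberately ignores weights ("number of edges").
  Tests verify the returned vector is stationary (residual < 10·tol)
  and matches closed-form solutions and an independent implementation.
- **Top-k ties**: competition ranks (equal values share the rank of their
  first member); the cut after rank k extends to every node tying the
  k-th value — exactly for integer metrics, within 1e-9 relative for
  real-valued ones.
- **Degenerate inputs**: a single-block match has undefined APT and E:P;
  a match with fewer than two attacks has TAtt defined as the combat
  time; zero attacks give missing effectiveness; an all-zero column (e.g.
  no shido in the cohort) is constant and isolated; `alpha` must be in
  (0, 1], and shrinking it can only remove edges (monotonicity is
  tested).
- **Percent change**: exact arithmetic on integer counts, display-rounded
  to one decimal; a zero baseline is undefined (NA with a warning),
  except that the pipeline reports 0% when both scenarios have zero
  edges.

## Problem sizes

The test suite simulates cohorts of 5–10 athletes; the planted-pair
recovery property runs 200 cohorts and 2000 null pairs; oracle-equivalence
checks enumerate 7! permutations for 100 random pairs; PageRank
stationarity is verified on 50 random graphs of up to 20 nodes. The full
default pipeline (three 52-node networks, 3 × 1326 Spearman tests,
centralities, rankings, exports) runs in a few seconds on one CPU.

## Known limitations

- The networks are descriptive: uncorrected per-pair significance, n = 10,
  and shared columns repeated across scenarios (so cross-scenario edge
  sets are not independent samples).
- Scenario effects are calibrated shifts; no claim about mechanism is
  encoded or testable here.
- Degree/PageRank are the only centralities; layout (e.g.
  Fruchterman–Reingold) is delegated to external tools via GraphML/GEXF
  export.
- The exact permutation method is capped at n = 8 by factorial growth;
  larger cohorts rely on the t approximation or Monte-Carlo.
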