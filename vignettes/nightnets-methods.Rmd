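---
title: "Day/night proximity networks: models, null hypotheses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Day/night proximity networks: models, null hypotheses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightnets)
```

`nightnets` turns raw dyadic proximity-logger records into
permutation-tested contrasts of daytime versus nighttime social
structure. This vignette is the package's account of the science behind
each stage: the models and their assumptions, the parameters that matter,
what the synthetic generator does and does not emulate, the numerical
conventions, and the places where the design was genuinely open and a
choice had to be made.

## From records to proximity events

A proximity logger stores one record per encounter: the reporting collar,
the partner, a start time, and a duration in seconds (floor 11 s). When
both collars of a dyad survive the field season, the encounter is stored
twice; `deduplicate()` drops one collar's records per dyad and calendar
date, the side chosen uniformly at random under a seed, so re-analysis
with another seed probes robustness to the retained subset. Dyads with
one lost collar keep the surviving collar's records.

`discretize()` divides the study span into fixed 300-second intervals
from the study epoch. A record generates one event in *every* interval it
overlaps by at least one second. We chose this any-overlap rule over a
majority-overlap rule because the downstream encoding is binary (a dyad
either was or was not in proximity during the interval) and any-overlap
is the simplest monotone rule; the choice only shifts weight at interval
boundaries. Events of the same dyad falling in one interval are merged,
the longest parent record winning, so at most one event exists per
(dyad, interval).

The social **context** of a contact — *active* (≤ 25 min; animals awake
and choosing to stay together) versus *passive* (> 25 min; proximity
carried over into sleep) — is classified on the *raw record duration*,
not per interval, because the threshold describes a property of the
encounter. All child events inherit the parent's label. The 25-minute
default can be replaced by the value suggested by `threshold_scan()`
(below).

**Phases.** The day of date *d* runs from `day_start` to `day_end`
(default 06:00–19:30, consistent with a ~13.5–14 h summer daylight
window at a low-latitude field site); the night of date *d* runs from
`day_end` of *d* to `day_start` of *d* + 1 and is one period. Events are
assigned by their interval's start time, closed on the left, so an
interval starting exactly at dawn is day and local midnight belongs to
the preceding date's night. A study of 27 full days therefore has exactly
54 periods, and "consecutive periods" (day 1, night 1, day 2, ...) are
well defined for the transition tests. The exact astronomical definition
of dusk and dawn is a field decision; the defaults are constant clock
times, overridable per date, and a contact that straddles a boundary is
truncated at it by the generator (phase transitions — emerging from or
returning to the den — interrupt contacts).

## Association networks

Within one period and context, the simple ratio index of a dyad is the
number of intervals with an event divided by the number of intervals in
the period. Proximity loggers record continuously, so every collar is
"sampled" in every interval and the general SRI denominator (intervals
where at least one of the pair was observed) collapses to the period's
total interval count; intervals where neither collar reported are true
zeros, not missing observations. If a deployment starts or stops
mid-study this assumption breaks and per-individual deployment windows
would have to shrink the denominator — the package does not model that.
The roster is fixed across all periods, including silent individuals, so
the 54 matrices are conformable for cosine comparison and neighbour
stability.

## Overlapping link communities and permutation groups

Social groups are detected once, on the all-context network aggregated
over the whole study. We cluster *edges*, not nodes: two edges sharing a
node are as similar as the Jaccard overlap of the inclusive
neighbourhoods of their non-shared endpoints; single-linkage
agglomeration (deterministic lexicographic edge order) builds a
dendrogram that is cut at the height maximizing partition density
$D = \tfrac{2}{M}\sum_c m_c \, \tfrac{m_c - n_c + 1}{(n_c - 2)(n_c - 1)}$,
where community $c$ has $m_c$ edges over $n_c$ nodes — 0 for a tree, 1
for a clique, with single-edge communities contributing 0. Ties between
cuts go to fewer communities, which is conservative for the permutation
strata (larger blocks permit more rewirings). Edge similarity is computed
on the binary structure by default — the common default of the method —
with a Tanimoto variant on weights behind a flag; whether the original
analyses weighted this step is unknown, so both are available and the
default is stated.

A node belongs to every community its edges belong to.
`membership_fractions()` reports the share of each node's interaction
weight per community (the "pie chart" view), and `assign_groups()` gives
each node a *group*: the union of all its communities' member sets. These
groups are the spatial strata of the null model — the claim they encode
is "these individuals plausibly meet by sharing space", so permuting
associations within them simulates random association among individuals
with overlapping space use.

## The data-stream permutation null

The null hypothesis throughout is that, given where and when individuals
were active, *which* group-mate an individual associated with is random.
`datastream_permute()` realizes it by elementary swaps: pick two events
of the same (date, group) block with four distinct individuals — i–j at
interval $t_1$ and k–l at $t_2$ — and rewire to (i–l, $t_1$), (k–j,
$t_2$) (or the mirror pairing), rejecting proposals that would duplicate
an existing (dyad, interval) event. Swaps never cross dates (temporal
structure is preserved) nor groups (spatial structure is preserved);
events whose dyad lies in no group are frozen. Each sample conserves
every individual's event count per block, the total event count, and the
interval multiset; phase and context labels travel with the interval.
Sampling is chained: consecutive samples differ by `swaps_per_step`
proposals (default: the number of events, preceded by an equal burn-in).
A "swap" is counted as one *proposal* — rejected proposals leave the
state unchanged — which keeps degenerate blocks (a single dyad, nothing
to swap) well-defined without special cases. Doubling the swap count
changes no conclusion on the test fixture, which is the practical check
that the chain mixes.

Permutation p-values follow the strict-exceedance convention,
p = #(observed > null)/n, read at both 5% tails: an observed statistic in
the upper tail (p ≥ 0.95) is larger than the spatial null predicts, in
the lower tail (p ≤ 0.05) smaller. Benjamini–Hochberg FDR adjustment is
applied whenever one network is compared to many.

## Day/night contrasts and the combination of dependent p-values

For each network trait we form the per-period series over the 54 active
networks and take absolute differences between consecutive periods. Each
observed |Δ| is ranked within the pooled set of itself and its null
replicates (upper tail, add-one convention), giving one p-value per
transition — small when the observed day/night change exceeds what random
within-group association produces. These per-transition p-values are
strongly dependent (nulls share the ensemble; consecutive transitions
share a period), so Fisher's statistic $S = -2\sum\log p$ is *not*
chi-square distributed. Instead, the same self-inclusive ranks are
computed for every null replicate, yielding the empirical null
distribution of $S$ with the dependence structure it actually has; the
combined p is the rank of the observed $S$ in that distribution. Because
observed and null streams are treated symmetrically, the combined p is
exactly uniform when the data satisfy the permutation null — we verified
a 4.5–7% rejection rate at the 5% level over 200 null datasets. The
analytic chi-square Fisher p is also reported (and `combine_dependent_pvalues()`
exposes the generic empirical-Fisher form, with observed zeros replaced
by 1/(n+1) before the log); the empirical and analytic forms agree on
independent uniform p-values, which is the cross-check in the test suite.

Two reporting conventions deserve a note. First, the per-transition
p-values are upper-tail (small = larger than chance); the raw
strict-exceedance formula would make *large* observed differences yield
p near 1 and the Fisher combination would then read them as unremarkable,
inverting the test. Second, the trait series average strength, degree and
eigenvector over the individuals observed interacting in each period
rather than the full roster: the full-roster mean strength is a constant
of the permutation (interval totals are conserved), so its contrast would
be degenerate by construction. `trait_table()` still reports full-roster
values with explicit flags for undefined entries.

### Traits

Degree counts binarized ties; strength sums weights; eigenvector
centrality is the leading eigenvector of the weighted matrix, nonnegative
and scaled to maximum 1 (computed on the full matrix when the network is
disconnected — the dominant component carries the mass — and flagged).
Individual selectivity is the coefficient of variation of a node's
weights to *all* its group-mates, structural zeros included: sparse daily
networks put many zeros in these vectors, which lowers CVs, and the null
model reproduces exactly that sparsity, so zeros must stay in. Social
differentiation is the CV over all within-group dyadic weights.
Neighbour stability is the Jaccard overlap of a node's binarized
neighbour sets in consecutive periods (undefined when both are empty, and
excluded from averages). All CVs and SDs use the sample (n − 1)
convention by default with a population variant behind a flag; the
convention was not fixed by the analyses this package follows, and the
flag keeps both comparable. Betweenness and closeness are deliberately
absent — too sensitive to the sparsity of daily networks.

### Cosine comparisons

Networks are compared by the cosine of their vectorized upper triangles
(row-major, fixed roster order): the dot product over the product of
Euclidean norms, amplitude-free, undefined (and flagged) for empty
networks. Cosines are computed between the four phase × context
aggregates and between all 54 × 54 period pairs, in weighted and binary
mode. Raw cosines on sparse graphs are inflated by shared structural
zeros, so they are only interpreted relative to the permutation null —
and the null, which spreads weight uniformly within groups, produces
*higher* cosines than concentrated observed networks; observed
similarities below the null are therefore the expected signature of
partner selectivity, not an artifact. Binary cosines exceed weighted
cosines on average for the same reason (agreement on the support is
easier than agreement on the weights); the paired sign-flip test on the
matrix cells (exhaustive enumeration up to 20 pairs, Monte Carlo above)
quantifies the difference.

### Threshold scan

`threshold_scan()` rebuilds the full-study network from contacts of
duration ≤ T for an increasing grid of candidates and tracks mean
strength and the cosine to the shortest-candidate baseline. The chosen
threshold is the candidate immediately before the largest single-step
drop of the cosine curve; when the largest drop is below half the curve's
range (configurable), a no-drop flag is raised instead of a threshold.
Largest-single-step-drop is the simplest operationalization of a "sudden"
drop and the rule is pluggable. The scan resolves a boundary only when
the duration mixture has a tight long component and the grid jumps the
inter-mode gap in few steps; on the default generator mixture (a broad
log-normal long component) the curve declines gradually and the scan
honestly reports no drop.

## The synthetic study

The generator emulates the design this pipeline targets: 28 collared
individuals in 4 groups tracked 27 consecutive days, day 06:00–19:30.
Encounters are a homogeneous Poisson process per individual per phase
window (defaults 4.84 by day, 2.23 by night — totals of roughly 135 and
62 per window), the simplest process producing more daytime contacts
without inventing micro-dynamics the data cannot constrain. Partners come
from per-individual, per-phase symmetric Dirichlet weights over
group-mates, drawn once per phase and held for the study (partner
structure persists across days, as the observed high neighbour stability
requires); lower concentration means more concentrated partner choice,
with `Inf` meaning exactly uniform. A `shared_preferences` switch reuses
the daytime weights at night for scenarios where the two phases share
structure. Between-group encounters occur with probability 5 × 10⁻⁴
(observed cross-community contacts are of order 0.05–0.1%). Durations are
a two-component log-normal mixture — active median 300 s (log-sd 0.9),
passive median 3600 s (log-sd 0.6) — strictly positive and heavy-tailed;
the contact-level passive weights (0.027 day, 0.102 night) are calibrated
so the *event-level* passive shares land near 20% by day and 45% by
night, since one hour-long contact contributes 10–15 events. Contacts are
truncated at their phase boundary. Under the default seed this yields
roughly 16,000 proximity events, passive shares of 24%/46%, mean
weighted/binary period cosines of 0.45/0.60 and mean neighbour stability
of 0.37 — the magnitudes a real deployment of this design produces.

What the generator does *not* emulate: logger detection physics (range,
RSSI, inter-logger variability), clock drift, spatial movement, diurnal
rate variation within a phase, and any dependence of partner choice on
past contacts. Passing tests therefore certify the statistical pipeline,
not the hardware pathway from proximity to stored record.

Reproducibility: a single master seed derives deterministic child seeds
per stream (preferences, encounters, deduplication, permutation), so any
stage can be re-run alone and byte-identical outputs indicate identical
inputs — the pipeline manifest records md5 checksums for exactly this
purpose.

## Calibration: what was measured and under which regime

The permutation null treats the 5-minute interval tokens as exchangeable
within (date, group) blocks. A contact that spans several intervals
violates that exchangeability *by construction*: its events share a dyad
in consecutive intervals, a persistence that uniform rewiring destroys.
On data with multi-interval contacts and no day/night effect the
contrast test consequently rejects far above nominal — correctly, in the
sense that the stream really is non-random at the interval level, but
uninformatively for day/night questions. Calibration of the machinery is
therefore measured in the regime where the generative process satisfies
the null: uniform partner preferences and contacts confined to single
intervals (`slot_contacts = TRUE`, a first-class generator mode). There
the rejection rate at the 5% rule over 200 simulated datasets with 200
permutations each was 0.045–0.06, inside the binomial 95% interval. Users
analysing real data should read small combined p-values with this in
mind: contact persistence contributes to them, which is one reason the
per-trait day/night contrasts are also reported with their day and night
means, so the direction and size of the effect can be judged alongside
the p-value.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data:
module tests on a 12-individual, 3-group, 6-day fixture with 100–200
permutations; the calibration study on 200 such datasets; the headline
computation at the full design scale (28 individuals, 27 days, ~16,000
events) with a 200-sample ensemble. These sizes make every result
recomputable in minutes on one CPU while keeping the Monte-Carlo error of
each check below its decision margin.

## Known limitations

- The SRI denominator assumes always-on loggers; mid-study deployment
  changes are not modelled.
- Group-level conclusions inherit the community detection: the union
  definition of groups can splice groups through rare cross-group edges,
  making permutation strata slightly larger than the underlying social
  units (conservative for the null).
- The day/night contrast conditions on interval occupancy; effects that
  express themselves purely through *when* individuals are active (not
  with whom) are invisible to it.
- The threshold scan assumes a gap-like duration mixture; smoothly
  overlapping mixtures yield an honest no-drop flag rather than a
  boundary.
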