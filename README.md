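# nightnets

Day/night contrasts of animal social networks from dyadic
proximity-logger records.

Most of what we know about the social structure of diurnal mammals comes
from daytime observation, yet the choice of nighttime sleeping partners is
a social decision with real fitness stakes. Proximity biologging records
encounters around the clock, which makes the question tractable: does the
social network animals express at night differ from the one they express
by day — and if so, in which traits? `nightnets` implements the full
analysis path for this question, from raw collar records to
permutation-tested day/night contrasts, for researchers analysing
continuous proximity-logger deployments on group-living species. A
synthetic-data generator with known ground truth (group structure,
day/night encounter rates, a short/long contact-duration mixture,
tunable nighttime partner selectivity) makes every stage testable without
field data.

## The pipeline

1. **Preprocessing.** Paired collars store mirrored duplicates of each
   encounter; one side per dyad and date is dropped at random. Records are
   discretized into 5-minute intervals — a dyad seen in an interval is one
   *proximity event* — and labelled by phase (day/night, with the night of
   date *d* spanning dusk of *d* to dawn of *d + 1*) and by social context:
   *active* contacts (≤ 25 min, awake interaction) vs *passive* contacts
   (> 25 min, proximity carried into sleep). A threshold-scan procedure
   checks the 25-minute boundary against the data.
2. **Networks.** Events aggregate into weighted networks per period with
   the simple ratio index; under continuous deployment the SRI weight is

   $$w_{ij} = \frac{\text{intervals with an } i\text{–}j \text{ event}}{\text{intervals in the period}}$$

   A study of 27 full days yields 54 day/night networks on a fixed roster.
3. **Communities.** Overlapping link communities (edge clustering by
   Jaccard similarity of the non-shared endpoints' inclusive
   neighbourhoods, single linkage, dendrogram cut at maximum partition
   density) define social groups; a multi-community individual's group is
   the union of its communities' members.
4. **Null model.** Focal data-stream permutations restricted within
   (date × group) blocks: repeated partner-exchange swaps
   (i–j, k–l) → (i–l, k–j) that preserve every individual's event count
   per block, the total event count and the interval multiset. All
   p-values are permutation p-values against this spatial null.
5. **Comparisons.** Node and group traits (degree, strength, eigenvector
   centrality, edge density, individual selectivity = CV of a node's
   within-group edge weights, social differentiation, neighbour-stability
   Jaccard, within-group SDs); cosine similarity between the four
   phase × context networks and between all pairs of the 54 period
   networks (weighted and binary); day/night trait contrasts combining
   the dependent per-transition permutation p-values with an empirical
   Fisher procedure.

## Worked example

```r
library(nightnets)

cfg  <- sim_config(n_individuals = 12, group_sizes = c(4, 4, 4), n_days = 6,
                   selectivity_day = 5, selectivity_night = 0.2, seed = 7)
sim  <- simulate_study(cfg)
pcfg <- phase_config(cfg$start_date, cfg$n_days)
ev   <- preprocess_records(sim$records, pcfg, retrieved = sim$truth$roster,
                           seed = 7, roster = sim$truth$roster)

full   <- build_sri(transform(ev, period = 1), 1, "all", sim$truth$roster,
                    sum(pcfg$windows$n_slots))
groups <- assign_groups(link_communities(full))
ens    <- datastream_permute(ev, groups, perm_config(n_perm = 200, seed = 8))
ct     <- daynight_trait_contrast(ev, ens, pcfg, sim$truth$roster, groups,
                                  "selectivity")
cat(sprintf("selectivity day %.2f night %.2f, combined p = %.3g\n",
            ct$day_mean, ct$night_mean, ct$combined$p))
```

```
selectivity day 0.70 night 1.19, combined p = 0.00498
```

The generator gave this population concentrated nighttime partner choice
(Dirichlet concentration 0.2 at night vs 5 by day). The pipeline recovers
it: mean individual selectivity — the coefficient of variation of an
individual's edge weights to its group-mates — is much higher at night
(1.19 vs 0.70), and the combined permutation p-value (0.005, the floor at
200 permutations) says day/night changes of this size do not arise from
random association within groups.

The numbered scripts under `analysis/` run the same stages at the
reference design scale (28 individuals, 4 groups, 27 days) and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R            --seed 1
Rscript analysis/02_preprocess.R          --seed 1
Rscript analysis/03_threshold_scan.R      --seed 1
Rscript analysis/04_communities.R         --seed 1
Rscript analysis/05_daynight_traits.R     --seed 1 --n-perm 200
Rscript analysis/06_temporal_similarity.R --seed 1 --n-perm 200
```

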