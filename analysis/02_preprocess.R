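#!/usr/bin/env Rscript
# Stage 2 — records to labelled proximity events, plus the preliminary
# day/night comparisons.
#
# Mirror deduplication (one collar per dyad-date), discretization into
# 5-minute intervals, phase labelling over the 54 day/night periods, and
# the 25-minute active/passive context split. Then the classical paired
# comparisons of the paper's preliminary exploration: day vs night
# encounter counts (paired t + sign-flip permutation, after a portmanteau
# autocorrelation check) and day vs night contact durations (Wilcoxon).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

records <- read_records(res_path("records.csv"))
issues <- validate_inputs(res_path("records.csv"), ROSTER, PCFG)
cat(nrow(issues), "validation issues\n")

events <- preprocess_records(records, PCFG, retrieved = ROSTER,
                             seed = SEED, roster = ROSTER)
write_events(events, res_path("events.tsv"))
cat(sprintf("%d proximity events over %d periods\n",
            nrow(events), length(unique(events$period))))
for (ph in c("day", "night"))
  cat(sprintf("  %s: %d events, %.1f%% passive\n", ph,
              sum(events$phase == ph),
              100 * mean(events$context[events$phase == ph] == "passive")))

# dedup'd records carry one row per encounter: count and average by phase
rec <- deduplicate(records, retrieved = ROSTER, seed = SEED, roster = ROSTER)
ev1 <- label_phase(discretize(rec, PCFG$epoch), PCFG)
per_rec <- unique(data.frame(key = paste(ev1$dyad_a, ev1$dyad_b,
                                         ev1$source_duration_s),
                             period = ev1$period, phase = ev1$phase,
                             dur = ev1$source_duration_s))
n_day <- as.numeric(table(factor(per_rec$period[per_rec$phase == "day"],
                                 levels = PCFG$windows$period[PCFG$windows$phase == "day"])))
n_night <- as.numeric(table(factor(per_rec$period[per_rec$phase == "night"],
                                   levels = PCFG$windows$period[PCFG$windows$phase == "night"])))

pm <- portmanteau_autocorr(c(rbind(n_day, n_night)), max_lag = 5)
cat(sprintf("portmanteau on the per-period contact counts: Q = %.2f, p = %.3f\n",
            pm$statistic, pm$p))
cnt <- paired_location_tests(n_day, n_night, alternative = "greater")
cat(sprintf("more contacts by day?  t p = %.2g, sign-flip p = %.2g\n",
            cnt$t_p, cnt$perm_p))

dur_day <- tapply(per_rec$dur[per_rec$phase == "day"],
                  per_rec$period[per_rec$phase == "day"], mean)
dur_night <- tapply(per_rec$dur[per_rec$phase == "night"],
                    per_rec$period[per_rec$phase == "night"], mean)
k <- min(length(dur_day), length(dur_night))
dur <- paired_location_tests(dur_night[seq_len(k)], dur_day[seq_len(k)],
                             alternative = "greater")
cat(sprintf("longer contacts by night?  Wilcoxon p = %.2g, sign-flip p = %.2g\n",
            dur$wilcoxon_p, dur$perm_p))

utils::write.table(
  data.frame(test = c("portmanteau_counts", "counts_day_gt_night_t",
                      "counts_day_gt_night_perm",
                      "duration_night_gt_day_wilcoxon",
                      "duration_night_gt_day_perm"),
             p = c(pm$p, cnt$t_p, cnt$perm_p, dur$wilcoxon_p, dur$perm_p)),
  res_path("preliminary_tests.tsv"), sep = "\t", row.names = FALSE,
  quote = FALSE)
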