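#!/usr/bin/env Rscript
# Stage 6 — social structure across contexts and across the month.
#
# (a) Cosine similarity between the four phase x context networks
#     (active/passive x day/night), each against its permutation null.
# (b) The 54 x 54 cosine matrix between per-period 'active' networks,
#     weighted and binary, with per-cell permutation p-values (BH
#     adjusted) and the paired weighted-vs-binary comparison.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

events <- load_events()
groups <- load_groups(events)
ens <- build_ensemble(events, groups)

ctx <- context_correlations(events, ens, PCFG, ROSTER)
cat("context cosine matrix:\n")
print(round(ctx$cosine, 3))
cat("BH-adjusted two-sided permutation p:\n")
print(round(ctx$p_two_adj, 3))
utils::write.table(round(ctx$cosine, 5), res_path("context_cosine.tsv"),
                   sep = "\t", quote = FALSE)
utils::write.table(round(ctx$p_two_adj, 5), res_path("context_p_adj.tsv"),
                   sep = "\t", quote = FALSE)

simW <- temporal_similarity(events, ens, PCFG, ROSTER, "weighted")
simB <- temporal_similarity(events, ens, PCFG, ROSTER, "binary")
for (s in list(simW, simB))
  cat(sprintf("%-8s mean cosine %.3f | of %d entries: %d above chance, %d below, %d n.s., %d undefined\n",
              s$mode, s$mean_cosine, s$n_entries, s$n_more, s$n_less,
              s$n_ns, s$n_undefined))
wb <- weighted_vs_binary_test(simW, simB, seed = SEED + 2L)
cat(sprintf("binary minus weighted mean cosine: %+.3f (paired sign-flip p = %.3g, %d pairs)\n",
            wb$mean_diff, wb$p, wb$n_pairs))

write_mat <- function(m, name) {
  utils::write.table(round(m, 5), res_path(name), sep = "\t", quote = FALSE)
}
write_mat(simW$cosine, "temporal_cosine_weighted.tsv")
write_mat(simB$cosine, "temporal_cosine_binary.tsv")
write_mat(simW$p_more_adj, "temporal_p_more_weighted.tsv")
write_mat(simB$p_more_adj, "temporal_p_more_binary.tsv")
utils::write.table(
  data.frame(mode = c("weighted", "binary"),
             mean_cosine = c(simW$mean_cosine, simB$mean_cosine),
             n_more = c(simW$n_more, simB$n_more),
             n_less = c(simW$n_less, simB$n_less),
             n_ns = c(simW$n_ns, simB$n_ns),
             wb_p = wb$p),
  res_path("temporal_summary.tsv"), sep = "\t", row.names = FALSE,
  quote = FALSE)
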