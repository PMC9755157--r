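#!/usr/bin/env Rscript
# Stage 4 — overlapping link communities on the full-study network.
#
# Edge communities with node multi-membership, cut at maximum partition
# density; a multi-community individual's permutation group is the union
# of all its communities' members. These groups are the strata of every
# data-stream permutation downstream.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

events <- load_events()
full <- build_sri(transform(events, period = 1L), 1L, "all", ROSTER,
                  sum(PCFG$windows$n_slots))
cover <- link_communities(full)
groups <- assign_groups(cover)

cat(sprintf("%d link communities, partition density %.3f\n",
            cover$n_communities, cover$partition_density))
multi <- names(which(lengths(cover$node_communities) > 1))
cat(sprintf("%d multi-community individuals: %s\n", length(multi),
            paste(multi, collapse = " ")))
cat(sprintf("%d permutation groups (sizes: %s)\n", length(groups$members),
            paste(lengths(groups$members), collapse = " ")))

mf <- cover$membership_fraction
utils::write.table(
  data.frame(node = rep(names(mf), lengths(mf)),
             community = unlist(lapply(mf, names)),
             share = round(unlist(mf), 4)),
  res_path("communities.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(
  data.frame(group = rep(seq_along(groups$members),
                         lengths(groups$members)),
             node = unlist(groups$members)),
  res_path("groups.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)

# cross-group events are frozen during permutation; report how rare they are
blk <- nightnets:::event_blocks(events, groups)
cat(sprintf("%d of %d events (%.2f%%) cross groups and stay frozen\n",
            sum(blk == 0), length(blk), 100 * mean(blk == 0)))
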