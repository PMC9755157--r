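# Focal data-stream permutations restricted within (date x group) blocks,
# permutation p-values, and FDR adjustment.

#' Permutation configuration
#'
#' @param n_perm number of null samples (the reference analysis uses 1000;
#'   scale down for desk-size fixtures).
#' @param swaps_per_step elementary swap proposals between consecutive
#'   samples; default = number of events in the stream.
#' @param burn_in proposals before the first sample; default =
#'   `swaps_per_step`.
#' @param seed integer seed.
#' @return a `perm_config` list.
#' @export
perm_config <- function(n_perm = 1000L, swaps_per_step = NULL,
                        burn_in = NULL, seed = 1L) {
  stopifnot(n_perm >= 1, is.null(swaps_per_step) || swaps_per_step >= 1)
  structure(list(n_perm = as.integer(n_perm),
                 swaps_per_step = swaps_per_step,
                 burn_in = burn_in, seed = as.integer(seed)),
            class = "perm_config")
}

# Stratum of each event: the smallest group whose member set contains both
# endpoints, crossed with the event date. Events whose dyad lies in no
# group (cross-group contacts) get block 0 and are frozen.
event_blocks <- function(events, groups) {
  stopifnot(inherits(groups, "group_assignment"))
  gsets <- groups$members
  gid <- rep(0L, nrow(events))
  for (g in seq_along(gsets)) {
    hit <- events$dyad_a %in% gsets[[g]] & events$dyad_b %in% gsets[[g]]
    gid[hit & gid == 0L] <- g
  }
  datef <- as.integer(factor(as.character(events$date)))
  block <- ifelse(gid == 0L, 0L, (datef - 1L) * length(gsets) + gid)
  # compress to consecutive ids, keeping 0 for frozen
  pos <- block > 0
  block[pos] <- as.integer(factor(block[pos]))
  block
}

#' Focal data-stream permutation of a proximity-event stream
#'
#' Chained (sequential) sampling: every emitted sample differs from the
#' previous one by `swaps_per_step` elementary swap proposals. A swap picks
#' two events of the same (date, group) block with four distinct
#' individuals — i-j at slot t1 and k-l at t2 — and rewires them to
#' (i-l, t1), (k-j, t2) (or the mirror pairing), rejecting proposals that
#' would duplicate an existing (dyad, slot) event. Phase, context and
#' period labels travel with the slot. Conserved on every sample: each
#' individual's event count per block, the total event count, and the slot
#' multiset. Cross-group events are frozen.
#'
#' @param events labelled event table.
#' @param groups a [assign_groups()] result defining the strata.
#' @param config a [perm_config()].
#' @param roster ordered roster; defaults to the group assignment's.
#' @return a `null_ensemble`: `samples` (list of 2-column matrices of
#'   roster indices, one row per event), `events` (the observed template),
#'   `roster`, `block`, `config`, acceptance counts.
#' @export
datastream_permute <- function(events, groups, config = perm_config(),
                               roster = NULL) {
  if (is.null(roster)) roster <- names(groups$group_of)
  a <- match(events$dyad_a, roster)
  b <- match(events$dyad_b, roster)
  if (anyNA(a) || anyNA(b)) stop("event references an individual off roster")
  block <- event_blocks(events, groups)
  sps <- config$swaps_per_step
  if (is.null(sps)) sps <- max(1L, nrow(events))
  burn <- config$burn_in
  if (is.null(burn)) burn <- sps
  samples <- with_seed(child_seed(config$seed, "permute"),
                       .permute_chain(a, b, as.integer(events$interval_index),
                                      as.integer(block), length(roster),
                                      config$n_perm, as.integer(sps),
                                      as.integer(burn)))
  structure(list(samples = samples, events = events, roster = roster,
                 a = a, b = b, block = block, config = config,
                 accepted = attr(samples, "accepted"),
                 proposed = attr(samples, "proposed")),
            class = "null_ensemble")
}

#' Materialize one permuted event table
#' @param ens a `null_ensemble`.
#' @param r replicate index (0 returns the observed stream).
#' @return event table with permuted dyads.
#' @export
ensemble_events <- function(ens, r) {
  ev <- ens$events
  if (r == 0) return(ev)
  s <- ens$samples[[r]]
  ev$dyad_a <- ens$roster[s[, 1]]
  ev$dyad_b <- ens$roster[s[, 2]]
  ev
}

#' Check the permutation conservation laws on one sample
#'
#' Verifies that per-individual event counts within every block, the total
#' event count, the slot multiset, and the within-block restriction hold.
#'
#' @param ens a `null_ensemble`.
#' @param r replicate index.
#' @return TRUE invisibly, or an error describing the violated law.
#' @export
check_conservation <- function(ens, r) {
  s <- ens$samples[[r]]
  if (nrow(s) != nrow(ens$events)) stop("event count not conserved")
  counts <- function(a, b, block) {
    tab <- table(factor(c(block, block)),
                 factor(c(a, b), levels = seq_along(ens$roster)))
    tab
  }
  if (!identical(counts(s[, 1], s[, 2], ens$block),
                 counts(ens$a, ens$b, ens$block)))
    stop("per-individual per-block event counts not conserved")
  frozen <- ens$block == 0
  if (!all(s[frozen, 1] == ens$a[frozen] & s[frozen, 2] == ens$b[frozen]))
    stop("frozen cross-group events were modified")
  key <- paste(s[, 1], s[, 2], ens$events$interval_index)
  if (anyDuplicated(key)) stop("duplicate (dyad, slot) event produced")
  invisible(TRUE)
}

#' Permutation p-value
#'
#' Fraction of null replicates the observed statistic STRICTLY exceeds:
#' p = #(observed > null_i) / n. Ties count as "not larger". Under the
#' two-tailed 5% convention a statistic is noteworthy when p <= 0.05
#' (observed smaller than nearly all nulls) or p >= 0.95 (larger).
#'
#' @param observed scalar statistic.
#' @param nulls numeric vector of null statistics.
#' @return p in \[0, 1\].
#' @export
perm_pvalue <- function(observed, nulls) {
  stopifnot(length(nulls) > 0)
  sum(observed > nulls) / length(nulls)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values (order-preserving, adjusted >= raw).
#' @export
fdr_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}
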