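# Shared fixtures and independent oracles for the test suite.
# All fixtures are generated in code; the cache avoids re-simulating the
# same dataset across test files.

.fixture_cache <- new.env(parent = emptyenv())

# Desk-scale study: 12 individuals in 3 groups tracked 6 days, with the
# generator's study-condition rates and duration mixture.
fixture_config <- function(seed = 42L, ...) {
  sim_config(n_individuals = 12L, group_sizes = c(4L, 4L, 4L), n_days = 6L,
             seed = seed, ...)
}

# Generator configuration satisfying the data-stream permutation null:
# uniform partner choice and contacts confined to single intervals.
null_regime_config <- function(seed) {
  fixture_config(seed = seed,
                 selectivity_day = Inf, selectivity_night = Inf,
                 dur_active = c(median_s = 60, sdlog = 0.4),
                 p_passive_day = 0, p_passive_night = 0,
                 slot_contacts = TRUE)
}

# Simulate + preprocess + communities for a config; cached by key.
fixture_data <- function(key = "default", cfg = fixture_config()) {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sim <- simulate_study(cfg)
  pcfg <- phase_config(cfg$start_date, cfg$n_days, cfg$day_start, cfg$day_end)
  roster <- sim$truth$roster
  ev <- preprocess_records(sim$records, pcfg, retrieved = roster,
                           seed = cfg$seed, roster = roster)
  full <- build_sri(transform(ev, period = 1L), 1L, "all", roster,
                    sum(pcfg$windows$n_slots))
  cover <- link_communities(full)
  groups <- assign_groups(cover)
  out <- list(cfg = cfg, sim = sim, pcfg = pcfg, roster = roster,
              events = ev, full = full, cover = cover, groups = groups)
  .fixture_cache[[key]] <- out
  out
}

# --- independent oracles -----------------------------------------------------

# adjusted Rand index between two labelled partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# brute-force SRI: literal slot counting over an event table
brute_sri <- function(events, period_id, context, roster, n_slots) {
  n <- length(roster)
  w <- matrix(0, n, n, dimnames = list(roster, roster))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$period != period_id) next
    if (context != "all" && e$context != context) next
    w[e$dyad_a, e$dyad_b] <- w[e$dyad_a, e$dyad_b] + 1
    w[e$dyad_b, e$dyad_a] <- w[e$dyad_b, e$dyad_a] + 1
  }
  w / n_slots
}

# independent partition-density arithmetic for an edge->community labelling
oracle_partition_density <- function(edges_a, edges_b, comm) {
  M <- length(edges_a)
  total <- 0
  for (cc in unique(comm)) {
    sel <- comm == cc
    m <- sum(sel)
    nodes <- unique(c(edges_a[sel], edges_b[sel]))
    nc <- length(nodes)
    if (nc > 2)
      total <- total + m * (m - nc + 1) / ((nc - 2) * (nc - 1))
  }
  2 * total / M
}

# a small named adjacency matrix from an edge list
adj_from_edges <- function(edges, nodes = NULL, w = 1) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    wi <- if (length(w) > 1) w[i] else w
    m[edges[i, 1], edges[i, 2]] <- wi
    m[edges[i, 2], edges[i, 1]] <- wi
  }
  m
}

# random toy event table on <= n_ind individuals and n_slot slots
random_toy_events <- function(n_ind, n_slot, n_events) {
  roster <- sprintf("T%02d", seq_len(n_ind))
  pair <- t(replicate(n_events, sort(sample(roster, 2))))
  ev <- data.frame(dyad_a = pair[, 1], dyad_b = pair[, 2],
                   interval_index = sample.int(n_slot, n_events,
                                               replace = TRUE) - 1L,
                   source_duration_s = sample(c(60L, 3000L), n_events,
                                              replace = TRUE))
  ev <- ev[!duplicated(ev[, c("dyad_a", "dyad_b", "interval_index")]), ]
  ev$context <- classify_context(ev$source_duration_s)
  ev$period <- 1L
  ev$date <- as.Date("2020-01-01")
  ev$phase <- "day"
  list(events = ev, roster = roster, n_slots = n_slot)
}
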