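# Synthetic proximity-logger study generator.
#
# Emulates a biologging deployment on a small, group-living, mainly diurnal
# mammal population: a handful of social groups tracked continuously for a
# number of consecutive days, with more (and shorter) encounters during the
# day than at night, a short/long duration mixture (awake "active" contacts
# vs carried-over "passive" contacts), and tunable nighttime partner
# selectivity. Ground truth (group membership, per-phase partner
# preferences, every realized encounter) is returned alongside the records
# so downstream inference can be tested for recovery.

#' Configuration for a synthetic proximity-logger study
#'
#' Defaults emulate the study design the package targets: 28 collared
#' individuals in 4 groups tracked 27 consecutive days, a ~13.5 h daylight
#' window, population-level encounter totals of roughly 135 per day and 62
#' per night, a log-normal short/long duration mixture split around the
#' 25-minute active/passive boundary, and stronger partner selectivity at
#' night than during the day.
#'
#' @param n_individuals number of collared individuals.
#' @param group_sizes integer vector summing to `n_individuals`; one entry
#'   per social group.
#' @param n_days number of consecutive study days.
#' @param day_start,day_end clock times ("HH:MM") bounding the daytime
#'   phase; the night of date d runs from `day_end` of d to `day_start` of
#'   d + 1.
#' @param rate_day,rate_night expected encounters initiated per individual
#'   per phase window (homogeneous Poisson within the window).
#' @param p_passive_day,p_passive_night probability an encounter's duration
#'   is drawn from the long ("passive") mixture component. A long contact
#'   spans many 5-minute intervals, so these contact-level weights are set
#'   well below the passive shares observed at the EVENT level (a passive
#'   contact of ~1 h contributes ~10-15 events); the defaults are
#'   calibrated so passive EVENT shares land near 20% by day and 45% by
#'   night.
#' @param dur_active,dur_passive named vectors `c(median_s=, sdlog=)` of the
#'   log-normal duration components; the active component should sit below
#'   the 25-minute threshold region and the passive one above it.
#' @param selectivity_day,selectivity_night symmetric Dirichlet
#'   concentrations for partner choice among group-mates; lower values
#'   concentrate an individual's encounters on fewer partners.
#' @param p_between_group probability an encounter crosses group
#'   boundaries (near 0 in strongly territorial populations).
#' @param shared_preferences reuse the daytime partner preferences at
#'   night (drawn with `selectivity_day`); by default the two phases get
#'   independent Dirichlet draws.
#' @param slot_contacts confine every contact to a single 5-minute
#'   interval (duration capped just under the interval, start placed so
#'   the contact ends inside its interval). This makes each encounter one
#'   interval token, i.e. a record stream that exactly satisfies the
#'   exchangeability assumption of the data-stream permutation null —
#'   the regime in which the permutation machinery's calibration is
#'   meaningfully measurable. Default FALSE: contacts cross interval
#'   boundaries as real logger records do.
#' @param lost_loggers character vector of individual ids whose own collars
#'   are never retrieved: records reported by them are discarded.
#' @param min_duration_s shortest storable record, seconds.
#' @param start_date first study date.
#' @param seed master integer seed; all child streams derive from it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_individuals = 28L,
                       group_sizes = NULL,
                       n_days = 27L,
                       day_start = "06:00",
                       day_end = "19:30",
                       rate_day = 4.84,
                       rate_night = 2.23,
                       p_passive_day = 0.027,
                       p_passive_night = 0.102,
                       dur_active = c(median_s = 300, sdlog = 0.9),
                       dur_passive = c(median_s = 3600, sdlog = 0.6),
                       selectivity_day = 5,
                       selectivity_night = 1,
                       p_between_group = 0.0005,
                       shared_preferences = FALSE,
                       slot_contacts = FALSE,
                       lost_loggers = character(),
                       min_duration_s = 11L,
                       start_date = as.Date("2017-07-15"),
                       seed = 1L) {
  if (is.null(group_sizes)) {
    k <- 4L
    base <- n_individuals %/% k
    group_sizes <- rep(base, k)
    extra <- n_individuals - sum(group_sizes)
    if (extra > 0) group_sizes[seq_len(extra)] <- group_sizes[seq_len(extra)] + 1L
  }
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    group_sizes = as.integer(group_sizes),
    n_days = as.integer(n_days),
    day_start = day_start, day_end = day_end,
    rate_day = rate_day, rate_night = rate_night,
    p_passive_day = p_passive_day, p_passive_night = p_passive_night,
    dur_active = dur_active, dur_passive = dur_passive,
    selectivity_day = selectivity_day, selectivity_night = selectivity_night,
    p_between_group = p_between_group,
    shared_preferences = isTRUE(shared_preferences),
    slot_contacts = isTRUE(slot_contacts),
    lost_loggers = as.character(lost_loggers),
    min_duration_s = as.integer(min_duration_s),
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (sum(cfg$group_sizes) != cfg$n_individuals)
    stop("group_sizes must sum to n_individuals")
  if (any(cfg$group_sizes < 1L)) stop("group sizes must be >= 1")
  if (cfg$rate_day < 0 || cfg$rate_night < 0) stop("rates must be >= 0")
  probs <- c(cfg$p_passive_day, cfg$p_passive_night, cfg$p_between_group)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$selectivity_day <= 0 || cfg$selectivity_night <= 0)
    stop("selectivity concentrations must be > 0")
  if (clock_s(cfg$day_start) >= clock_s(cfg$day_end))
    stop("day_start must precede day_end")
  rate_pos <- cfg$rate_day > 0 || cfg$rate_night > 0
  if (rate_pos && any(cfg$group_sizes == 1L) &&
      (cfg$p_between_group == 0 || length(cfg$group_sizes) == 1L))
    stop("impossible config: an individual with no group-mates and no ",
         "between-group encounters cannot realize a positive encounter rate")
  invisible(cfg)
}

# "HH:MM" -> seconds after local midnight
clock_s <- function(x) {
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  p[1] * 3600L + p[2] * 60L
}

# Phase window table: one row per day and night of the study, with absolute
# second offsets from the study epoch (day_start of date 1).
phase_windows <- function(cfg) {
  d_start <- clock_s(cfg$day_start)
  d_end <- clock_s(cfg$day_end)
  day0 <- as.numeric(as.POSIXct(paste(cfg$start_date, cfg$day_start),
                                tz = "UTC"))
  rows <- lapply(seq_len(cfg$n_days), function(d) {
    base <- (d - 1) * 86400
    data.frame(
      period = c(2L * d - 1L, 2L * d),
      phase = c("day", "night"),
      date = cfg$start_date + (d - 1),
      start_s = day0 + base + c(0, d_end - d_start),
      end_s = day0 + base + c(d_end - d_start, 86400)
    )
  })
  do.call(rbind, rows)
}

# symmetric Dirichlet draw; infinite concentration means exactly uniform
# partner weights (the no-preference null the permutation machinery assumes)
rdirichlet1 <- function(alpha) {
  if (any(!is.finite(alpha))) return(rep(1 / length(alpha), length(alpha)))
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}

#' Simulate a proximity-logger study
#'
#' Draws, for every individual and phase window, a Poisson number of
#' initiated encounters; partners come from the initiator's phase-specific
#' Dirichlet preference weights over group-mates (or, with probability
#' `p_between_group`, uniformly from non-group-mates); start times are
#' uniform within the phase window, durations from the phase's
#' two-component log-normal mixture, truncated at the end of the window
#' (phase transitions interrupt contacts). Every encounter is emitted as
#' two mirrored logger records unless a collar is in `lost_loggers`.
#'
#' @param cfg a [sim_config()].
#' @return list with `records` (data.frame: reporter, partner, start
#'   (POSIXct UTC), duration_s), `truth` (class `sim_truth`: `group_of`,
#'   per-phase `preferences` matrices, the realized `encounters` table,
#'   `roster`, `config`).
#' @export
simulate_study <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_individuals
  roster <- sprintf("H%02d", seq_len(n))
  group_of <- rep(seq_along(cfg$group_sizes), cfg$group_sizes)
  names(group_of) <- roster
  wins <- phase_windows(cfg)

  truth_pref <- with_seed(child_seed(cfg$seed, "preferences"), {
    prefs <- lapply(c(day = "day", night = "night"), function(ph) {
      conc <- if (ph == "day") cfg$selectivity_day else cfg$selectivity_night
      pref <- matrix(0, n, n, dimnames = list(roster, roster))
      for (i in seq_len(n)) {
        mates <- which(group_of == group_of[i])
        mates <- setdiff(mates, i)
        if (length(mates) > 0)
          pref[i, mates] <- rdirichlet1(rep(conc, length(mates)))
      }
      pref
    })
    if (cfg$shared_preferences) prefs$night <- prefs$day
    prefs
  })

  enc <- with_seed(child_seed(cfg$seed, "encounters"), {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      rate <- ifelse(wins$phase == "day", cfg$rate_day, cfg$rate_night)
      k <- rpois(nrow(wins), rate)
      K <- sum(k)
      if (K == 0) { out[[i]] <- NULL; next }
      widx <- rep(seq_len(nrow(wins)), k)
      ph <- wins$phase[widx]
      # partner choice
      partner <- integer(K)
      between <- runif(K) < cfg$p_between_group
      outsiders <- which(group_of != group_of[i])
      if (length(outsiders) == 0) between[] <- FALSE
      for (s in c("day", "night")) {
        sel <- which(ph == s & !between)
        if (length(sel) > 0) {
          w <- truth_pref[[s]][i, ]
          if (sum(w) == 0)
            stop("individual ", roster[i], " has no group-mates to draw from")
          partner[sel] <- sample.int(n, length(sel), replace = TRUE, prob = w)
        }
      }
      if (any(between))
        partner[between] <- outsiders[sample.int(length(outsiders),
                                                 sum(between), replace = TRUE)]
      # timing and duration
      w0 <- wins$start_s[widx]
      w1 <- wins$end_s[widx]
      passive <- runif(K) < ifelse(ph == "day", cfg$p_passive_day,
                                   cfg$p_passive_night)
      dur <- ifelse(passive,
                    rlnorm(K, log(cfg$dur_passive[["median_s"]]),
                           cfg$dur_passive[["sdlog"]]),
                    rlnorm(K, log(cfg$dur_active[["median_s"]]),
                           cfg$dur_active[["sdlog"]]))
      if (cfg$slot_contacts) {
        # one interval token per contact: pick a slot of the window, then
        # place the (capped) contact fully inside it
        dur <- pmax(cfg$min_duration_s, pmin(round(dur), SLOT_S - 1L))
        n_sl <- (w1 - w0) / SLOT_S
        sl <- floor(runif(K) * n_sl)
        start <- w0 + sl * SLOT_S + runif(K) * (SLOT_S - dur)
        start <- floor(start)
      } else {
        start <- floor(w0 + runif(K) * (w1 - w0 - cfg$min_duration_s))
        dur <- pmax(cfg$min_duration_s, pmin(round(dur), floor(w1 - start)))
      }
      out[[i]] <- data.frame(
        initiator = roster[i], partner = roster[partner],
        period = wins$period[widx], phase = ph,
        date = wins$date[widx],
        start = start, duration_s = as.integer(dur),
        between_group = between
      )
    }
    do.call(rbind, out)
  })
  if (is.null(enc))
    enc <- data.frame(initiator = character(), partner = character(),
                      period = integer(), phase = character(),
                      date = as.Date(character()), start = numeric(),
                      duration_s = integer(), between_group = logical())
  enc <- enc[order(enc$start, enc$initiator, enc$partner), , drop = FALSE]
  rownames(enc) <- NULL

  # mirrored emission, one record per surviving collar
  rec <- rbind(
    data.frame(reporter = enc$initiator, partner = enc$partner,
               start = enc$start, duration_s = enc$duration_s),
    data.frame(reporter = enc$partner, partner = enc$initiator,
               start = enc$start, duration_s = enc$duration_s)
  )
  rec <- rec[!(rec$reporter %in% cfg$lost_loggers), , drop = FALSE]
  rec <- rec[order(rec$start, rec$reporter, rec$partner), , drop = FALSE]
  rec$start <- as.POSIXct(rec$start, origin = "1970-01-01", tz = "UTC")
  rownames(rec) <- NULL

  truth <- structure(list(group_of = group_of, preferences = truth_pref,
                          encounters = enc, roster = roster, config = cfg),
                     class = "sim_truth")
  list(records = rec, truth = truth)
}

#' Summarise simulation ground truth
#'
#' One row per individual and phase: number of potential within-group
#' partners, the sample-CV of the preference weights (the generator's
#' expected selectivity; 0 for uniform weights, `sqrt(k)` for a one-hot
#' weight among k group-mates), and realized encounter tallies.
#'
#' @param truth a `sim_truth`.
#' @return data.frame: individual, phase, n_groupmates, pref_cv,
#'   n_initiated, n_received, total_duration_s.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if (length(truth$roster) == 0)
    return(data.frame(individual = character(), phase = character(),
                      n_groupmates = integer(), pref_cv = numeric(),
                      n_initiated = integer(), n_received = integer(),
                      total_duration_s = numeric()))
  rows <- lapply(c("day", "night"), function(ph) {
    pref <- truth$preferences[[ph]]
    e <- truth$encounters[truth$encounters$phase == ph, , drop = FALSE]
    do.call(rbind, lapply(truth$roster, function(id) {
      mates <- names(which(truth$group_of == truth$group_of[id]))
      mates <- setdiff(mates, id)
      w <- pref[id, mates]
      data.frame(
        individual = id, phase = ph, n_groupmates = length(mates),
        pref_cv = if (length(w) >= 2) cv(w) else NA_real_,
        n_initiated = sum(e$initiator == id),
        n_received = sum(e$partner == id),
        total_duration_s = sum(e$duration_s[e$initiator == id | e$partner == id])
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read logger records as CSV
#'
#' Columns: `logger_a` (reporting collar), `logger_b` (partner),
#' `start_iso8601` (UTC), `duration_s`.
#'
#' @param records data.frame as returned by [simulate_study()].
#' @param path file path.
#' @export
write_records <- function(records, path) {
  out <- data.frame(
    logger_a = records$reporter,
    logger_b = records$partner,
    start_iso8601 = format(records$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    duration_s = records$duration_s
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("logger_a", "logger_b", "start_iso8601", "duration_s")
  if (!all(need %in% names(x)))
    stop("records file must have columns: ", paste(need, collapse = ", "))
  data.frame(
    reporter = as.character(x$logger_a),
    partner = as.character(x$logger_b),
    start = as.POSIXct(x$start_iso8601, format = "%Y-%m-%dT%H:%M:%SZ",
                       tz = "UTC"),
    duration_s = as.integer(x$duration_s)
  )
}
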