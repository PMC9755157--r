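# Raw record -> proximity event preprocessing: mirror deduplication,
# 5-minute discretization, phase labelling, active/passive classification.

#' Day/night phase configuration
#'
#' Defines the day and night windows of a study: the day of date d runs
#' from `day_start` to `day_end` (closed-left), the night of date d from
#' `day_end` of d to `day_start` of d + 1 and counts as ONE period attached
#' to date d. Periods are numbered day 1, night 1, day 2, ... so a study of
#' n full days has 2n periods. Boundaries must sit on the 5-minute grid.
#'
#' @param start_date first study date.
#' @param n_days number of full study days.
#' @param day_start,day_end clock times "HH:MM" (recycled to `n_days` if
#'   scalar, one per date otherwise).
#' @return a `phase_config`: window table (period, phase, date, start_s,
#'   end_s, n_slots) plus the study epoch (start of day 1).
#' @export
phase_config <- function(start_date, n_days, day_start = "06:00",
                         day_end = "19:30") {
  start_date <- as.Date(start_date)
  n_days <- as.integer(n_days)
  day_start <- rep_len(day_start, n_days)
  day_end <- rep_len(day_end, n_days)
  rows <- lapply(seq_len(n_days), function(d) {
    s0 <- clock_s(day_start[d]); s1 <- clock_s(day_end[d])
    if (s0 >= s1) stop("day_start must precede day_end on date ",
                       start_date + d - 1)
    next_start <- clock_s(day_start[min(d + 1L, n_days)])
    base <- as.numeric(as.POSIXct(paste(start_date + d - 1, "00:00"),
                                  tz = "UTC"))
    data.frame(period = c(2L * d - 1L, 2L * d),
               phase = c("day", "night"),
               date = start_date + d - 1,
               start_s = base + c(s0, s1),
               end_s = base + c(s1, 86400 + next_start))
  })
  w <- do.call(rbind, rows)
  if (any((w$end_s - w$start_s) %% SLOT_S != 0) ||
      any((w$start_s - w$start_s[1]) %% SLOT_S != 0))
    stop("phase boundaries must align to the ", SLOT_S, "-second grid")
  w$n_slots <- as.integer((w$end_s - w$start_s) / SLOT_S)
  structure(list(windows = w, epoch = w$start_s[1], n_days = n_days,
                 start_date = start_date),
            class = "phase_config")
}

#' Remove mirrored duplicate records
#'
#' A pair of proximity loggers stores its encounter twice, once per collar.
#' For every dyad whose two collars were both retrieved, one collar's
#' records for that dyad are dropped per calendar date, the side chosen
#' uniformly at random under `seed`. Dyads with one lost collar keep the
#' surviving collar's records unchanged.
#'
#' @param records data.frame (reporter, partner, start, duration_s).
#' @param retrieved character vector of ids whose collars were retrieved.
#' @param seed integer seed for the per-dyad-date side choice.
#' @param roster optional full roster; ids outside it raise an error.
#' @return the retained records.
#' @export
deduplicate <- function(records, retrieved, seed, roster = NULL) {
  ids <- unique(c(records$reporter, records$partner))
  if (!is.null(roster) && !all(ids %in% roster))
    stop("records reference unknown individuals: ",
         paste(setdiff(ids, roster), collapse = ", "))
  if (any(records$reporter == records$partner))
    stop("self-referencing records (reporter == partner)")
  a <- pmin(records$reporter, records$partner)
  b <- pmax(records$reporter, records$partner)
  date <- as.Date(records$start, tz = "UTC")
  key <- paste(a, b, date, sep = "|")
  both <- records$reporter %in% retrieved & records$partner %in% retrieved
  keys <- unique(key[both])
  if (length(keys) == 0) return(records)
  drop_first <- with_seed(child_seed(seed, "dedup"),
                          runif(length(keys)) < 0.5)
  names(drop_first) <- keys
  ka <- sub("\\|.*", "", keys)                       # the smaller id
  kb <- sub("^[^|]*\\|([^|]*)\\|.*", "\\1", keys)    # the larger id
  dropped_reporter <- ifelse(drop_first, ka, kb)
  names(dropped_reporter) <- keys
  keep <- !(both & records$reporter == dropped_reporter[key])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a contact as active or passive
#'
#' Encounters at most `threshold_s` long are "active" (awake interaction);
#' longer ones are "passive" (proximity carried over into sleep). The
#' default threshold is 25 minutes; [threshold_scan()] can suggest a
#' data-driven value.
#'
#' @param duration_s record duration(s), seconds.
#' @param threshold_s active/passive boundary, seconds.
#' @return character vector, "active" or "passive".
#' @export
classify_context <- function(duration_s, threshold_s = 1500) {
  ifelse(duration_s <= threshold_s, "active", "passive")
}

#' Discretize records into 5-minute proximity events
#'
#' The study span is divided into fixed slots of `interval_s` seconds from
#' `epoch`. A record generates one event for every slot it overlaps by at
#' least one second; events of the same dyad falling in the same slot are
#' merged into one (the longest parent record wins, and its duration
#' defines the event's active/passive context).
#'
#' @param records deduplicated records.
#' @param epoch study start (POSIXct or numeric seconds); slot 0 starts
#'   here.
#' @param interval_s slot length, seconds.
#' @param threshold_s active/passive boundary passed to
#'   [classify_context()].
#' @return data.frame: dyad_a, dyad_b, interval_index, source_duration_s,
#'   context — one row per (dyad, slot).
#' @export
discretize <- function(records, epoch, interval_s = SLOT_S,
                       threshold_s = 1500) {
  if (nrow(records) == 0)
    return(data.frame(dyad_a = character(), dyad_b = character(),
                      interval_index = integer(),
                      source_duration_s = integer(), context = character()))
  if (any(records$duration_s <= 0)) stop("non-positive record duration")
  s <- round(as.numeric(records$start) - as.numeric(epoch))
  if (any(s < 0)) stop("record starts before the study epoch")
  d <- as.numeric(records$duration_s)
  k0 <- s %/% interval_s
  k1 <- (s + d - 1) %/% interval_s
  nrep <- as.integer(k1 - k0 + 1)
  idx <- rep(seq_len(nrow(records)), nrep)
  slot <- as.integer(unlist(lapply(seq_len(nrow(records)),
                                   function(i) k0[i]:k1[i])))
  ev <- data.frame(
    dyad_a = pmin(records$reporter, records$partner)[idx],
    dyad_b = pmax(records$reporter, records$partner)[idx],
    interval_index = slot,
    source_duration_s = records$duration_s[idx]
  )
  # merge duplicates per (dyad, slot), longest parent record wins
  ev <- ev[order(ev$dyad_a, ev$dyad_b, ev$interval_index,
                 -ev$source_duration_s), , drop = FALSE]
  dup <- duplicated(ev[, c("dyad_a", "dyad_b", "interval_index")])
  ev <- ev[!dup, , drop = FALSE]
  ev$context <- classify_context(ev$source_duration_s, threshold_s)
  rownames(ev) <- NULL
  ev
}

#' Label events with phase and aggregation period
#'
#' Each event is assigned day or night by its slot START time under the
#' phase configuration (closed-left at every boundary: a slot starting
#' exactly at day-start is day; a slot at local midnight belongs to the
#' preceding date's night period).
#'
#' @param events output of [discretize()].
#' @param pcfg a [phase_config()]; its epoch must be the one used for
#'   discretization.
#' @return events with phase, period, date columns added.
#' @export
label_phase <- function(events, pcfg) {
  stopifnot(inherits(pcfg, "phase_config"))
  w <- pcfg$windows
  t <- pcfg$epoch + events$interval_index * SLOT_S
  i <- findInterval(t, w$start_s)
  bad <- i < 1 | t >= w$end_s[pmax(i, 1)]
  if (any(bad))
    stop(sum(bad), " event(s) fall outside the configured study span")
  events$phase <- w$phase[i]
  events$period <- w$period[i]
  events$date <- w$date[i]
  events
}

#' Full preprocessing chain
#'
#' [deduplicate()] then [discretize()] then [label_phase()].
#'
#' @inheritParams deduplicate
#' @inheritParams discretize
#' @param pcfg a [phase_config()].
#' @return labelled event table.
#' @export
preprocess_records <- function(records, pcfg, retrieved, seed,
                               threshold_s = 1500, roster = NULL) {
  rec <- deduplicate(records, retrieved, seed, roster = roster)
  ev <- discretize(rec, epoch = pcfg$epoch, threshold_s = threshold_s)
  label_phase(ev, pcfg)
}

#' Write / read a labelled event table as TSV
#' @param events labelled event table.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  x
}
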