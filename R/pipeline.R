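# End-to-end orchestration: simulate (optional) -> preprocess -> networks
# -> communities -> permutations -> traits -> comparisons, with a manifest
# recording seed, configuration hash and per-stage output checksums.
# The numbered scripts under analysis/ drive these stages one at a time;
# run_pipeline() chains them for a single reproducible run.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if missing).
#' @param records_path CSV of logger records; NULL simulates instead.
#' @param sim a [sim_config()] used when simulating (also supplies the
#'   roster and retrieval status).
#' @param pcfg a [phase_config()]; derived from `sim` when NULL.
#' @param threshold_s active/passive boundary, seconds.
#' @param n_perm permutation count.
#' @param traits traits to contrast between day and night.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, records_path = NULL, sim = sim_config(),
                       pcfg = NULL, threshold_s = 1500, n_perm = 1000L,
                       traits = c("strength", "degree", "eigenvector",
                                  "selectivity", "density"),
                       seed = 1L) {
  if (is.null(pcfg))
    pcfg <- phase_config(sim$start_date, sim$n_days, sim$day_start,
                         sim$day_end)
  structure(list(out_dir = out_dir, records_path = records_path, sim = sim,
                 pcfg = pcfg, threshold_s = threshold_s,
                 n_perm = as.integer(n_perm), traits = traits,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Validate pipeline input files
#'
#' Schema check of the records CSV, id cross-reference against the roster,
#' duration floor, and study-span coverage. Malformed rows are listed, not
#' silently dropped.
#'
#' @param records_path logger records CSV.
#' @param roster character vector of collared ids.
#' @param pcfg a [phase_config()].
#' @param min_duration_s duration floor, seconds.
#' @return data.frame of issues (zero rows when clean).
#' @export
validate_inputs <- function(records_path, roster, pcfg,
                            min_duration_s = 11L) {
  issues <- list()
  note <- function(row, what) issues[[length(issues) + 1]] <<-
    data.frame(row = row, issue = what)
  if (!file.exists(records_path)) {
    note(NA, paste("records file not found:", records_path))
  } else {
    rec <- read_records(records_path)
    bad_id <- which(!(rec$reporter %in% roster) | !(rec$partner %in% roster))
    for (i in bad_id) note(i, "unknown individual id")
    for (i in which(rec$reporter == rec$partner)) note(i, "reporter == partner")
    for (i in which(rec$duration_s < min_duration_s))
      note(i, sprintf("duration below the %d s floor", min_duration_s))
    t0 <- as.numeric(rec$start)
    span <- range(pcfg$windows$start_s[1], max(pcfg$windows$end_s))
    for (i in which(t0 < span[1])) note(i, "record before study start")
    for (i in which(t0 >= span[2])) note(i, "record after study end")
  }
  if (length(issues) == 0)
    return(data.frame(row = integer(), issue = character()))
  do.call(rbind, issues)
}

#' Run the full analysis pipeline
#'
#' @param cfg a [run_config()].
#' @return invisibly, the manifest (also written as manifest.json in
#'   `out_dir`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  outputs <- character()
  save_tsv <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    utils::write.table(x, p, sep = "\t", row.names = FALSE, quote = FALSE)
    outputs <<- c(outputs, p)
    p
  }

  # --- records ---------------------------------------------------------------
  roster <- sprintf("H%02d", seq_len(cfg$sim$n_individuals))
  truth <- NULL
  records <- stage("records", {
    if (is.null(cfg$records_path)) {
      sim <- simulate_study(cfg$sim)
      truth <- sim$truth
      p <- file.path(cfg$out_dir, "records.csv")
      write_records(sim$records, p)
      outputs <- c(outputs, p)
      sim$records
    } else {
      if (!file.exists(cfg$records_path))
        stop("records path does not exist: ", cfg$records_path)
      read_records(cfg$records_path)
    }
  })
  retrieved <- setdiff(roster, cfg$sim$lost_loggers)

  # --- preprocess ------------------------------------------------------------
  events <- stage("preprocess", {
    ev <- preprocess_records(records, cfg$pcfg, retrieved,
                             seed = child_seed(cfg$seed, "dedup"),
                             threshold_s = cfg$threshold_s, roster = roster)
    save_tsv(ev, "events.tsv")
    ev
  })

  # --- communities on the full-study network --------------------------------
  groups <- stage("communities", {
    slots <- sum(cfg$pcfg$windows$n_slots)
    full <- build_sri(transform(events, period = 1L), 1L, "all", roster, slots)
    cover <- link_communities(full)
    save_tsv(data.frame(node = rep(names(cover$membership_fraction),
                                   lengths(cover$membership_fraction)),
                        community = unlist(lapply(cover$membership_fraction, names)),
                        share = unlist(cover$membership_fraction)),
             "communities.tsv")
    ga <- assign_groups(cover)
    save_tsv(data.frame(node = names(ga$group_of), group = ga$group_of),
             "groups.tsv")
    ga
  })

  # --- permutation ensemble --------------------------------------------------
  ens <- stage("permute",
    datastream_permute(events, groups,
                       perm_config(n_perm = cfg$n_perm,
                                   seed = child_seed(cfg$seed, "perm")),
                       roster = roster))

  # --- traits and day/night contrasts ---------------------------------------
  contrasts <- stage("metrics", {
    nets <- period_networks(events, cfg$pcfg, roster, context = "active")
    save_tsv(trait_table(nets, groups), "traits.tsv")
    res <- lapply(cfg$traits, function(tr)
      daynight_trait_contrast(events, ens, cfg$pcfg, roster, groups, tr))
    names(res) <- cfg$traits
    save_tsv(data.frame(trait = cfg$traits,
                        day_mean = vapply(res, `[[`, 0, "day_mean"),
                        night_mean = vapply(res, `[[`, 0, "night_mean"),
                        combined_p = vapply(res, function(x) x$combined$p, 0)),
             "daynight_contrasts.tsv")
    res
  })

  # --- similarity comparisons ------------------------------------------------
  sims <- stage("compare", {
    ctx <- context_correlations(events, ens, cfg$pcfg, roster)
    save_tsv(as.data.frame(ctx$cosine), "context_cosine.tsv")
    simW <- temporal_similarity(events, ens, cfg$pcfg, roster, "weighted")
    simB <- temporal_similarity(events, ens, cfg$pcfg, roster, "binary")
    save_tsv(as.data.frame(simW$cosine), "temporal_cosine_weighted.tsv")
    save_tsv(as.data.frame(simB$cosine), "temporal_cosine_binary.tsv")
    wb <- weighted_vs_binary_test(simW, simB,
                                  seed = child_seed(cfg$seed, "wb"))
    list(context = ctx, weighted = simW, binary = simB, wb = wb)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("nightnets")),
    seed = cfg$seed,
    n_perm = cfg$n_perm,
    threshold_s = cfg$threshold_s,
    config_hash = unname(config_hash(cfg)),
    outputs = as.list(stats::setNames(
      as.character(tools::md5sum(outputs)), basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, events = events, groups = groups,
                 contrasts = contrasts, similarity = sims, truth = truth))
}

# md5 of the serialized scientific configuration (seed included, output
# location excluded so relocated runs hash identically)
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg$out_dir <- NULL
  writeLines(utils::capture.output(utils::str(cfg, digits.d = 12)), tmp)
  tools::md5sum(tmp)
}
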