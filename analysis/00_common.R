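# Shared setup for the numbered analysis scripts: command-line seed and
# permutation count, output location, and the study-scale configuration.
# Every script can be re-run on its own; stages that need upstream outputs
# read them from results/.

suppressPackageStartupMessages(library(nightnets))

.args <- commandArgs(trailingOnly = TRUE)
arg_or <- function(flag, default) {
  i <- which(.args == flag)
  if (length(i) == 1 && i < length(.args)) .args[i + 1] else default
}

SEED <- as.integer(arg_or("--seed", "1"))
N_PERM <- as.integer(arg_or("--n-perm", "200"))
RESULTS <- arg_or("--out", "results")
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

STUDY <- sim_config(seed = SEED)
PCFG <- phase_config(STUDY$start_date, STUDY$n_days, STUDY$day_start,
                     STUDY$day_end)
ROSTER <- sprintf("H%02d", seq_len(STUDY$n_individuals))

res_path <- function(name) file.path(RESULTS, name)

load_events <- function() {
  p <- res_path("events.tsv")
  if (!file.exists(p)) stop("run analysis/02_preprocess.R first (missing ", p, ")")
  read_events(p)
}

load_groups <- function(events) {
  full <- build_sri(transform(events, period = 1L), 1L, "all", ROSTER,
                    sum(PCFG$windows$n_slots))
  assign_groups(link_communities(full))
}

build_ensemble <- function(events, groups) {
  datastream_permute(events, groups,
                     perm_config(n_perm = N_PERM, seed = SEED + 1L),
                     roster = ROSTER)
}
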