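# Synthetic proximity-logger generator

test_that("zero encounter rates yield an empty record stream", {
  cfg <- fixture_config(rate_day = 0, rate_night = 0)
  sim <- simulate_study(cfg)
  expect_equal(nrow(sim$records), 0L)
  expect_equal(nrow(sim$truth$encounters), 0L)
})

test_that("the generator is deterministic under its seed", {
  cfg <- fixture_config(seed = 11L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$encounters, s2$truth$encounters)
  s3 <- simulate_study(fixture_config(seed = 12L))
  expect_false(identical(s1$records, s3$records))
})

test_that("every encounter with both collars present is mirrored", {
  sim <- fixture_data()$sim
  rec <- sim$records
  expect_equal(nrow(rec), 2L * nrow(sim$truth$encounters))
  key <- paste(rec$reporter, rec$partner, as.numeric(rec$start),
               rec$duration_s)
  mirror <- paste(rec$partner, rec$reporter, as.numeric(rec$start),
                  rec$duration_s)
  expect_true(all(mirror %in% key))
})

test_that("lost loggers report nothing but still appear as partners", {
  cfg <- fixture_config(lost_loggers = c("H01", "H07"))
  sim <- simulate_study(cfg)
  expect_false(any(sim$records$reporter %in% c("H01", "H07")))
  expect_true(any(sim$records$partner %in% c("H01", "H07")))
})

test_that("lower nighttime Dirichlet concentration concentrates partner choice", {
  hits <- 0L
  for (k in 1:20) {
    cfg <- fixture_config(seed = 300L + k, selectivity_day = 5,
                          selectivity_night = 0.2)
    enc <- simulate_study(cfg)$truth$encounters
    alloc_cv <- function(ph) {
      e <- enc[enc$phase == ph & !enc$between_group, ]
      mean(tapply(seq_len(nrow(e)), e$initiator, function(ix) {
        cnt <- table(e$partner[ix])
        if (length(cnt) < 2) return(NA)
        sd(cnt) / mean(cnt)
      }), na.rm = TRUE)
    }
    if (alloc_cv("night") > alloc_cv("day")) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("per-phase encounter counts are Poisson-consistent with the rates", {
  # per-individual per-window counts pooled over 50 small replicates,
  # chi-square GOF against the configured Poisson law
  counts_day <- c(); counts_night <- c()
  for (k in 1:50) {
    cfg <- sim_config(n_individuals = 6L, group_sizes = c(3L, 3L),
                      n_days = 2L, rate_day = 2, rate_night = 1,
                      seed = 500L + k)
    enc <- simulate_study(cfg)$truth$encounters
    for (ph in c("day", "night")) {
      grid <- expand.grid(id = sprintf("H%02d", 1:6),
                          period = unique(enc$period[enc$phase == ph]))
      cnt <- mapply(function(i, p)
        sum(enc$initiator == i & enc$period == p), grid$id, grid$period)
      if (ph == "day") counts_day <- c(counts_day, cnt)
      else counts_night <- c(counts_night, cnt)
    }
  }
  gof <- function(x, lambda) {
    brk <- 0:max(3, stats::qpois(0.999, lambda))
    obs <- table(factor(pmin(x, max(brk)), levels = brk))
    pr <- stats::dpois(brk, lambda)
    pr[length(pr)] <- 1 - sum(pr[-length(pr)])
    keep <- pr * length(x) >= 1
    suppressWarnings(stats::chisq.test(obs[keep], p = pr[keep],
                                       rescale.p = TRUE)$p.value)
  }
  expect_gt(gof(counts_day, 2), 0.01)
  expect_gt(gof(counts_night, 1), 0.01)
})

test_that("between-group encounter fraction matches its probability", {
  cfg <- fixture_config(seed = 77L, p_between_group = 0.05)
  truth <- simulate_study(cfg)$truth
  enc <- truth$encounters
  frac <- mean(enc$between_group)
  se <- sqrt(0.05 * 0.95 / nrow(enc))
  expect_lt(abs(frac - 0.05), 3 * se)
  # the flag agrees with realized group crossing
  realized <- truth$group_of[enc$initiator] != truth$group_of[enc$partner]
  expect_equal(unname(realized), enc$between_group)
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(n_individuals = 3L, group_sizes = c(2L, 1L),
                          p_between_group = 0),
               "impossible config")
  expect_error(sim_config(group_sizes = c(10L, 10L)), "sum")
  expect_error(sim_config(rate_day = -1), "rates")
  expect_error(sim_config(selectivity_day = 0), "concentrations")
})

test_that("truth_summary reports expected selectivity in closed form", {
  mk_truth <- function(pref_row, mates) {
    roster <- c("A", mates)
    group_of <- stats::setNames(rep(1L, length(roster)), roster)
    pref <- matrix(0, length(roster), length(roster),
                   dimnames = list(roster, roster))
    pref["A", mates] <- pref_row
    enc <- data.frame(initiator = character(), partner = character(),
                      period = integer(), phase = character(),
                      date = as.Date(character()), start = numeric(),
                      duration_s = integer(), between_group = logical())
    structure(list(group_of = group_of,
                   preferences = list(day = pref, night = pref),
                   encounters = enc, roster = roster,
                   config = NULL), class = "sim_truth")
  }
  # uniform weights -> CV 0
  tu <- truth_summary(mk_truth(rep(1 / 3, 3), c("B", "C", "D")))
  expect_equal(tu$pref_cv[tu$individual == "A"], c(0, 0))
  # one-hot among k = 4 mates -> sample-CV sqrt(k)
  t1 <- truth_summary(mk_truth(c(1, 0, 0, 0), c("B", "C", "D", "E")))
  expect_equal(t1$pref_cv[t1$individual == "A"], rep(sqrt(4), 2))
  # empty truth -> empty table
  empty <- structure(list(group_of = stats::setNames(integer(), character()),
                          preferences = list(), encounters = NULL,
                          roster = character(), config = NULL),
                     class = "sim_truth")
  expect_equal(nrow(truth_summary(empty)), 0L)
})

test_that("records survive a CSV round trip", {
  sim <- fixture_data()$sim
  p <- withr::local_tempfile(fileext = ".csv")
  write_records(sim$records, p)
  back <- read_records(p)
  expect_equal(back$reporter, sim$records$reporter)
  expect_equal(as.numeric(back$start), as.numeric(sim$records$start))
  expect_equal(back$duration_s, sim$records$duration_s)
})
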