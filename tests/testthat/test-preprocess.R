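# Deduplication, 5-minute discretization, context and phase labelling

rec_df <- function(reporter, partner, start, duration_s) {
  data.frame(reporter = reporter, partner = partner,
             start = as.POSIXct(start, tz = "UTC"),
             duration_s = as.integer(duration_s))
}

test_that("mirrored records collapse to one per dyad-date; lost collars keep theirs", {
  r <- rec_df(c("A", "B"), c("B", "A"),
              rep("2020-01-01 10:00:00", 2), c(60L, 60L))
  kept <- deduplicate(r, retrieved = c("A", "B"), seed = 1L)
  expect_equal(nrow(kept), 1L)
  # B's collar lost: A's records all kept
  one_sided <- rec_df("A", "B", c("2020-01-01 10:00:00",
                                  "2020-01-02 11:00:00"), c(60L, 90L))
  expect_equal(deduplicate(one_sided, retrieved = "A", seed = 1L), one_sided)
  # determinism
  many <- rec_df(rep(c("A", "B"), 10), rep(c("B", "A"), 10),
                 as.POSIXct("2020-01-01 06:00:00", tz = "UTC") + (1:20) * 3600,
                 rep(30L, 20))
  expect_identical(deduplicate(many, c("A", "B"), seed = 5L),
                   deduplicate(many, c("A", "B"), seed = 5L))
  # the dedup side is drawn independently per date
  expect_error(deduplicate(rec_df("A", "Z", "2020-01-01 10:00:00", 60L),
                           retrieved = "A", seed = 1L, roster = c("A", "B")),
               "unknown")
})

test_that("discretization follows the any-overlap slot rule", {
  epoch <- as.POSIXct("2020-01-01 06:00:00", tz = "UTC")
  # 11 s inside one slot -> 1 event
  ev <- discretize(rec_df("A", "B", "2020-01-01 06:01:00", 11L), epoch)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$interval_index, 0L)
  # 120 s straddling a slot boundary -> 2 events
  ev2 <- discretize(rec_df("A", "B", "2020-01-01 06:04:00", 120L), epoch)
  expect_equal(ev2$interval_index, c(0L, 1L))
  # the study's longest printed record, starting on a boundary -> 86 slots
  ev3 <- discretize(rec_df("A", "B", "2020-01-01 06:00:00", 25605L), epoch)
  expect_equal(nrow(ev3), 86L)
  # overlap by a single trailing second still counts
  ev4 <- discretize(rec_df("A", "B", "2020-01-01 06:04:59", 62L), epoch)
  expect_equal(ev4$interval_index, c(0L, 1L))
  expect_error(discretize(rec_df("A", "B", "2020-01-01 06:00:00", 0L), epoch),
               "non-positive")
})

test_that("events of one dyad merge per slot, longest parent wins", {
  epoch <- as.POSIXct("2020-01-01 06:00:00", tz = "UTC")
  r <- rec_df(c("A", "A"), c("B", "B"),
              c("2020-01-01 06:00:10", "2020-01-01 06:02:00"),
              c(20L, 2000L))
  ev <- discretize(r, epoch)
  slot0 <- ev[ev$interval_index == 0L, ]
  expect_equal(nrow(slot0), 1L)
  expect_equal(slot0$source_duration_s, 2000L)
  expect_equal(slot0$context, "passive")
})

test_that("event counts match brute-force overlap enumeration", {
  set.seed(9)
  epoch <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  for (rep in 1:25) {
    n <- sample(1:8, 1)
    r <- rec_df(rep("A", n), rep("B", n),
                epoch + sample.int(3000, n), sample.int(900, n))
    brute <- unique(unlist(lapply(seq_len(n), function(i) {
      s <- as.numeric(r$start[i]) - as.numeric(epoch)
      slots <- seq.int(0, 3600 %/% 300)
      slots[300 * slots < s + r$duration_s[i] & s < 300 * (slots + 1)]
    })))
    expect_setequal(discretize(r, epoch)$interval_index, brute)
  }
})

test_that("the 25-minute rule splits active from passive contacts", {
  expect_equal(classify_context(1500), "active")
  expect_equal(classify_context(1501), "passive")
  expect_equal(classify_context(11), "active")
  ev <- fixture_data()$events
  expect_true(all(ev$context %in% c("active", "passive")))
  expect_equal(ev$context, classify_context(ev$source_duration_s))
})

test_that("phase labelling yields ordered day/night periods with closed-left bounds", {
  pcfg <- phase_config("2020-06-01", 3)
  epoch <- pcfg$epoch
  ev <- data.frame(dyad_a = "A", dyad_b = "B",
                   interval_index = c(0L,            # 06:00 day 1
                                      161L,          # 19:25, last day slot
                                      162L,          # 19:30 -> night 1
                                      216L,          # midnight -> night 1
                                      288L),         # 06:00 day 2
                   source_duration_s = 60L, context = "active")
  lab <- label_phase(ev, pcfg)
  expect_equal(lab$phase, c("day", "day", "night", "night", "day"))
  expect_equal(lab$period, c(1L, 1L, 2L, 2L, 3L))
  expect_equal(lab$date[4], as.Date("2020-06-01"))  # midnight -> preceding date
  out <- ev; out$interval_index <- 10000L
  expect_error(label_phase(out, pcfg), "outside")
})

test_that("phase partition is exhaustive over the configured span", {
  fd <- fixture_data()
  expect_false(any(is.na(fd$events$phase)))
  expect_equal(sort(unique(fd$events$period)),
               seq_len(2L * fd$cfg$n_days)[seq_len(2L * fd$cfg$n_days) %in%
                                             fd$events$period])
  # every slot of the span is assignable
  all_slots <- data.frame(dyad_a = "H01", dyad_b = "H02",
                          interval_index = seq.int(0, sum(fd$pcfg$windows$n_slots) - 1L),
                          source_duration_s = 60L, context = "active")
  expect_silent(label_phase(all_slots, fd$pcfg))
})
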