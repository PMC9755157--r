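# Cosine comparisons, threshold scan, paired tests, p-value combination,
# day/night contrasts

test_that("cosine similarity matches arithmetic and flags degeneracies", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(1:3, 1:4), "length")
  expect_true(is.na(cosine_similarity(c(0, 0), c(1, 1))))
})

test_that("sign-flip permutation p matches exhaustive enumeration", {
  d <- c(0.3, -0.1, 0.4)
  # independent enumeration of all 2^3 assignments
  signs <- expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))
  sums <- as.matrix(signs) %*% d
  expect_equal(nightnets:::signflip_test(d, "greater")$p,
               mean(sums >= sum(d)))
  expect_equal(nightnets:::signflip_test(d, "two.sided")$p,
               mean(abs(sums) >= abs(sum(d))))
})

test_that("paired location tests agree with their oracles", {
  x <- c(5.1, 4.9, 6.2, 5.7); y <- c(4.0, 5.0, 5.1, 5.2)
  res <- paired_location_tests(x, y, alternative = "greater")
  expect_equal(res$t_p, t.test(x, y, paired = TRUE,
                               alternative = "greater")$p.value)
  d <- x - y
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  expect_equal(res$perm_p, mean(signs %*% d >= sum(d)))
  # identical series: nothing significant, Wilcoxon flagged
  same <- paired_location_tests(x, x)
  expect_gte(same$t_p, 0.5)
  expect_true(is.na(same$wilcoxon_p))
  expect_equal(same$perm_p, 1)
  # strong constant shift is detected
  set.seed(2)
  z <- rnorm(20)
  expect_lt(paired_location_tests(z + 2, z)$t_p, 0.001)
})

test_that("weighted vs binary comparison is a paired sign-flip test", {
  A <- matrix(c(1, .5, .4, .5, 1, .6, .4, .6, 1), 3, 3)
  expect_equal(weighted_vs_binary_test(A, A)$p, 1)
  B <- A; B[upper.tri(B)] <- A[upper.tri(A)] + c(.2, .3, .25)
  B[lower.tri(B)] <- t(B)[lower.tri(B)]
  res <- weighted_vs_binary_test(A, B)
  d <- (B - A)[upper.tri(A)]
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 3)))
  expect_equal(res$p, mean(abs(signs %*% d) >= abs(sum(d)) - 1e-12))
  expect_true(res$exhaustive)
  # a large systematic difference on the fixture grid is significant
  set.seed(3)
  W <- matrix(runif(100, .3, .5), 10, 10); W <- (W + t(W)) / 2; diag(W) <- 1
  B2 <- W + 0.3; diag(B2) <- 1
  expect_lt(weighted_vs_binary_test(W, B2)$p, 0.05)
})

test_that("portmanteau test matches the Ljung-Box formula and detects AR(1)", {
  x <- c(2.1, 1.9, 3.0, 2.5, 2.2, 2.8, 3.1, 2.0, 2.4, 2.6)
  res <- portmanteau_autocorr(x, max_lag = 3)
  n <- length(x)
  rho <- stats::acf(x, lag.max = 3, plot = FALSE)$acf[2:4]
  lb <- n * (n + 2) * sum(rho^2 / (n - 1:3))
  expect_equal(res$statistic, lb, tolerance = 1e-10)
  expect_equal(res$p, stats::pchisq(lb, 3, lower.tail = FALSE))
  expect_true(is.na(portmanteau_autocorr(rep(1, 10), 2)$p))
  # white noise: rejection rate compatible with the nominal 5%
  set.seed(14)
  rej <- mean(vapply(1:200, function(k)
    portmanteau_autocorr(rnorm(54), 5)$p < 0.05, logical(1)))
  expect_gte(rej, qbinom(0.025, 200, 0.05) / 200)
  expect_lte(rej, qbinom(0.975, 200, 0.05) / 200)
  set.seed(4)
  hits <- sum(vapply(1:5, function(k) {
    ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 200))
    portmanteau_autocorr(ar, 5)$p < 0.05
  }, logical(1)))
  expect_gte(hits, 4L)
})

test_that("threshold scan finds the gap of a bimodal duration mixture", {
  # short mode ~5 min, tight long mode ~60 min; the candidate grid starts
  # above the short mode (a baseline inside it is too sparse to be stable)
  # and jumps the gap so the long component floods in within one step
  hits <- 0L
  cands <- c(900, 1200, 1500, 1800, 2400, 4800)
  for (k in 1:10) {
    cfg <- fixture_config(seed = 800L + k,
                          dur_active = c(median_s = 300, sdlog = 0.3),
                          dur_passive = c(median_s = 3600, sdlog = 0.1))
    sim <- simulate_study(cfg)
    pcfg <- phase_config(cfg$start_date, cfg$n_days)
    rec <- deduplicate(sim$records, retrieved = sim$truth$roster, seed = k)
    sc <- threshold_scan(rec, cands, pcfg, sim$truth$roster, phase = "night")
    if (!sc$no_drop && sc$chosen >= 900 && sc$chosen <= 2400) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("threshold scan flags curves without a sudden drop", {
  rec <- data.frame(reporter = "H01", partner = "H02",
                    start = as.POSIXct("2017-07-15 20:00:00", tz = "UTC") +
                      (0:19) * 3600 * 5,
                    duration_s = 600L)
  pcfg <- phase_config("2017-07-15", 6)
  # identical durations above the smallest candidate: flat unit curve
  sc <- threshold_scan(rec, c(900, 1200, 1500, 2100), pcfg,
                       c("H01", "H02"), phase = "all")
  expect_true(sc$no_drop)
  expect_true(is.na(sc$chosen))
  expect_equal(sc$curve$cosine, rep(1, 4))
  # an empty baseline defines no curve at all
  sc2 <- threshold_scan(rec, c(300, 900, 1500, 2100), pcfg,
                        c("H01", "H02"), phase = "all")
  expect_true(sc2$no_drop)
  expect_error(threshold_scan(rec, 300, pcfg, c("H01", "H02")), ">= 2")
  expect_error(threshold_scan(rec, c(900, 300), pcfg, c("H01", "H02")),
               "increasing")
})

test_that("the largest single-step drop selects the preceding candidate", {
  # geometry: engineered records so that contacts longer than 25 min flood
  # one extra dyad, collapsing the cosine to the short-contact baseline
  pcfg <- phase_config("2017-07-15", 6)
  epoch <- as.POSIXct("2017-07-15 06:00:00", tz = "UTC")
  short <- data.frame(reporter = "H01", partner = "H02",
                      start = epoch + (0:39) * 7200, duration_s = 120L)
  long <- data.frame(reporter = "H03", partner = "H04",
                     start = epoch + 3600 + (0:39) * 7200,
                     duration_s = 3000L)
  sc <- threshold_scan(rbind(short, long), c(600, 1200, 1500, 3600),
                       pcfg, sprintf("H%02d", 1:4), phase = "all")
  expect_false(sc$no_drop)
  expect_equal(sc$chosen, 1500)
})

test_that("empirical Fisher combination is exact in rank and matches analytic form", {
  set.seed(5)
  # single p: combined p equals its (add-one) rank among null replicates
  R <- 199
  obs <- 0.03
  nulls <- matrix(runif(R), ncol = 1)
  res <- combine_dependent_pvalues(obs, nulls, n_perm = R)
  expect_equal(res$p, mean(-2 * log(nulls) >= -2 * log(obs)))
  # all observed p at the floor, uniform nulls -> combined p at the floor
  k <- 6
  nulls_k <- matrix(runif(400 * k), ncol = k)
  res2 <- combine_dependent_pvalues(rep(0, k), nulls_k, n_perm = 400)
  expect_lte(res2$p, 1 / 400)
  expect_equal(res2$n_zero_replaced, k)
  # independent uniforms: empirical and chi-square Fisher agree
  res3 <- combine_dependent_pvalues(rep(0.2, 3), matrix(runif(2000 * 3),
                                                        ncol = 3),
                                    n_perm = 2000, analytic = TRUE)
  se <- sqrt(res3$analytic_p * (1 - res3$analytic_p) / 2000)
  expect_lt(abs(res3$p - res3$analytic_p), 2 * se + 0.02)
})

test_that("day/night contrast is inert on identical traits and calibrated machinery", {
  set.seed(6)
  obs <- rep(2, 13)                        # identical day and night traits
  nulls <- matrix(2 + rnorm(200 * 13, sd = 0.3), 200, 13)
  res <- daynight_contrast(obs, nulls)
  expect_true(all(res$p_transitions == 1))  # nulls always at least as large
  expect_gte(res$combined$p, 0.9)
  # a large observed change dominates its nulls
  obs2 <- rep(c(0, 5), length.out = 13)
  res2 <- daynight_contrast(obs2, nulls)
  expect_true(all(res2$p_transitions == 1 / 201))
  expect_equal(res2$combined$p, 1 / 201)
})

test_that("context networks correlate with themselves and with shared structure", {
  fd <- fixture_data()
  ens <- datastream_permute(fd$events, fd$groups,
                            perm_config(n_perm = 20, seed = 7))
  cc <- context_correlations(fd$events, ens, fd$pcfg, fd$roster)
  expect_equal(unname(diag(cc$cosine)), rep(1, 4))
  expect_true(isSymmetric(cc$cosine))
  ut <- upper.tri(cc$p_two_adj)
  expect_true(all(cc$p_two_adj[ut] >= 0 & cc$p_two_adj[ut] <= 1, na.rm = TRUE))
})

test_that("shared day/night preference structure raises the day-night cosine", {
  # generator property: when the same Dirichlet partner preferences drive
  # both phases, the active-day vs active-night cosine exceeds the value
  # under independently drawn preferences of the same concentration
  cos_ad_an <- function(cfg) {
    sim <- simulate_study(cfg)
    pcfg <- phase_config(cfg$start_date, cfg$n_days)
    ev <- preprocess_records(sim$records, pcfg, retrieved = sim$truth$roster,
                             seed = cfg$seed, roster = sim$truth$roster)
    nn <- context_networks(ev, pcfg, sim$truth$roster)
    cosine_similarity(vectorize_upper(nn$active_day),
                      vectorize_upper(nn$active_night))
  }
  wins <- 0L
  for (k in 1:10) {
    shared <- cos_ad_an(fixture_config(seed = 900L + k,
                                       selectivity_day = 0.5,
                                       selectivity_night = 0.5,
                                       shared_preferences = TRUE))
    indep <- cos_ad_an(fixture_config(seed = 900L + k,
                                      selectivity_day = 0.5,
                                      selectivity_night = 0.5))
    if (!is.na(shared) && !is.na(indep) && shared > indep) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
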