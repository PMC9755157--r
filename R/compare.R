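# Comparison machinery: cosine similarity across contexts and across
# aggregation periods, active/passive threshold discovery, day/night trait
# contrasts with an empirical Fisher combination of dependent permutation
# p-values, and the basic paired location tests.

#' Cosine similarity between two vectors
#'
#' Dot product divided by the product of Euclidean norms. Interpreted like
#' a correlation coefficient but insensitive to vector amplitude; for
#' nonnegative association weights it lies in \[0, 1\].
#'
#' @param u,v equal-length numeric vectors.
#' @return cosine; NA (flagged) when either vector is all-zero.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    out <- NA_real_
    attr(out, "flags") <- "zero vector: cosine undefined"
    return(out)
  }
  sum(u * v) / (nu * nv)
}

# Cosine similarity matrix between the columns of V; all-zero columns
# yield NA rows/cols. Diagonal is 1 for non-empty columns.
cosine_matrix <- function(V) {
  nrm <- sqrt(colSums(V^2))
  C <- crossprod(V)
  C <- C / outer(nrm, nrm)
  C[, nrm == 0] <- NA
  C[nrm == 0, ] <- NA
  C
}

# --- per-period vectorized networks -----------------------------------------

# Slot-count vectors per period for one context, as a P x n_periods matrix
# (P = n(n-1)/2 dyads in vectorize_upper order). `a`, `b` are roster
# indices; dividing column p by n_slots[p] gives the SRI vectors.
context_count_matrix <- function(a, b, period, context, which_context,
                                 n, n_periods) {
  sel <- if (which_context == "all") rep(TRUE, length(a)) else context == which_context
  dyad_period_counts(a[sel], b[sel], period[sel], n, n_periods)
}

#' Build all per-period SRI networks from a labelled event stream
#'
#' @param events labelled event table.
#' @param pcfg the [phase_config()].
#' @param roster ordered roster.
#' @param context "active", "passive" or "all".
#' @return named list of [assoc_matrix()] (names "1".."2n", the period
#'   ids), each with the period's slot count as denominator.
#' @export
period_networks <- function(events, pcfg, roster, context = "active") {
  w <- pcfg$windows
  n <- length(roster)
  cnt <- context_count_matrix(match(events$dyad_a, roster),
                              match(events$dyad_b, roster),
                              events$period, events$context, context,
                              n, nrow(w))
  cells <- dyad_upper_cells(n)
  out <- lapply(seq_len(nrow(w)), function(p) {
    m <- matrix(0, n, n, dimnames = list(roster, roster))
    m[cells] <- cnt[, p] / w$n_slots[p]
    assoc_matrix(m + t(m), roster, period_id = w$period[p],
                 context = context, n_slots = w$n_slots[p])
  })
  names(out) <- as.character(w$period)
  out
}

#' Aggregate phase x context networks over the full study
#'
#' Four networks — active-day, passive-day, active-night, passive-night —
#' each with the total slot count of its phase as SRI denominator.
#'
#' @inheritParams period_networks
#' @return named list of four [assoc_matrix()].
#' @export
context_networks <- function(events, pcfg, roster) {
  n <- length(roster)
  cells <- dyad_upper_cells(n)
  out <- list()
  for (ph in c("day", "night")) for (cx in c("active", "passive")) {
    sel <- events$phase == ph & events$context == cx
    slots <- sum(pcfg$windows$n_slots[pcfg$windows$phase == ph])
    cnt <- dyad_period_counts(match(events$dyad_a[sel], roster),
                              match(events$dyad_b[sel], roster),
                              rep(1L, sum(sel)), n, 1L)
    m <- matrix(0, n, n, dimnames = list(roster, roster))
    m[cells] <- cnt[, 1] / slots
    out[[paste(cx, ph, sep = "_")]] <-
      assoc_matrix(m + t(m), roster, period_id = ph, context = cx,
                   n_slots = slots)
  }
  out
}

# --- context correlations ----------------------------------------------------

#' Cosine similarity between the four phase x context networks
#'
#' All pairwise cosines between active-day, passive-day, active-night and
#' passive-night networks, each compared with its null distribution from
#' the data-stream permutation ensemble; two-sided permutation p-values
#' are BH-adjusted across the 6 comparisons.
#'
#' @param events labelled event table.
#' @param ens a [datastream_permute()] ensemble built on `events`.
#' @param pcfg the [phase_config()].
#' @param roster ordered roster.
#' @return list: `cosine` (4x4), `p_raw` (fraction of nulls the observed
#'   strictly exceeds), `p_two_adj` (BH-adjusted two-sided), flags.
#' @export
context_correlations <- function(events, ens, pcfg, roster) {
  vecs <- function(ev) {
    nets <- context_networks(ev, pcfg, roster)
    vapply(nets, vectorize_upper, numeric(length(roster) * (length(roster) - 1) / 2))
  }
  Vobs <- vecs(events)
  obs <- cosine_matrix(Vobs)
  nm <- colnames(Vobs)
  pairs <- which(upper.tri(obs), arr.ind = TRUE)
  null_cos <- array(NA_real_, c(ens$config$n_perm, nrow(pairs)))
  for (r in seq_len(ens$config$n_perm)) {
    Cr <- cosine_matrix(vecs(ensemble_events(ens, r)))
    null_cos[r, ] <- Cr[pairs]
  }
  p_raw <- matrix(NA_real_, 4, 4, dimnames = dimnames(obs))
  p_two <- p_raw
  for (q in seq_len(nrow(pairs))) {
    o <- obs[pairs[q, , drop = FALSE]]
    nn <- null_cos[, q]
    if (is.na(o) || all(is.na(nn))) next
    nn <- nn[!is.na(nn)]
    p_raw[pairs[q, 1], pairs[q, 2]] <- perm_pvalue(o, nn)
    p_two[pairs[q, 1], pairs[q, 2]] <-
      min(1, 2 * min(mean(nn >= o), mean(nn <= o)))
  }
  adj <- p_two
  adj[upper.tri(adj)] <- fdr_adjust(p_two[upper.tri(p_two)])
  p_raw[lower.tri(p_raw)] <- t(p_raw)[lower.tri(p_raw)]
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  list(cosine = obs, p_raw = p_raw, p_two_adj = adj,
       flagged_empty = nm[sqrt(colSums(Vobs^2)) == 0])
}

# --- temporal similarity -----------------------------------------------------

#' Cosine similarity between every pair of per-period networks
#'
#' The full n_periods x n_periods matrix of cosine indexes between the
#' per-period "active" networks (weighted or binary mode), each entry
#' compared against its permutation null distribution; one-sided
#' permutation p-values are BH-adjusted across entries, and entries
#' significantly more / less correlated than chance are counted.
#'
#' @param events labelled event table.
#' @param ens a [datastream_permute()] ensemble.
#' @param pcfg the [phase_config()].
#' @param roster ordered roster.
#' @param mode "weighted" or "binary".
#' @param context which event context to aggregate (default "active").
#' @return list: `cosine` (full matrix), `p_raw` (strict-exceed fraction),
#'   `p_more_adj`, `p_less_adj` (BH-adjusted one-sided), `n_entries`,
#'   `n_more`, `n_less`, `n_ns`, `n_undefined`, `mean_cosine`.
#' @export
temporal_similarity <- function(events, ens, pcfg, roster,
                                mode = c("weighted", "binary"),
                                context = "active") {
  mode <- match.arg(mode)
  n <- length(roster)
  nP <- nrow(pcfg$windows)
  slots <- pcfg$windows$n_slots
  vecs <- function(a, b) {
    V <- context_count_matrix(a, b, events$period, events$context, context,
                              n, nP)
    V <- sweep(V, 2, slots, "/")
    if (mode == "binary") V <- (V > 0) + 0
    V
  }
  obs <- cosine_matrix(vecs(match(events$dyad_a, roster),
                            match(events$dyad_b, roster)))
  cells <- which(upper.tri(obs, diag = TRUE), arr.ind = TRUE)
  null_cos <- matrix(NA_real_, ens$config$n_perm, nrow(cells))
  for (r in seq_len(ens$config$n_perm)) {
    s <- ens$samples[[r]]
    Cr <- cosine_matrix(vecs(s[, 1], s[, 2]))
    null_cos[r, ] <- Cr[cells]
  }
  p_raw <- p_more <- p_less <- matrix(NA_real_, nP, nP)
  for (q in seq_len(nrow(cells))) {
    o <- obs[cells[q, , drop = FALSE]]
    nn <- null_cos[, q]
    nn <- nn[!is.na(nn)]
    if (is.na(o) || length(nn) == 0) next
    i <- cells[q, 1]; j <- cells[q, 2]
    p_raw[i, j] <- perm_pvalue(o, nn)
    p_more[i, j] <- mean(nn >= o)   # small when observed larger than chance
    p_less[i, j] <- mean(nn <= o)
  }
  mirror <- function(M) { M[lower.tri(M)] <- t(M)[lower.tri(M)]; M }
  adj <- function(M) {
    ut <- upper.tri(M, diag = TRUE)
    M[ut] <- fdr_adjust(M[ut])
    mirror(M)
  }
  p_raw <- mirror(p_raw)
  p_more_adj <- adj(p_more)
  p_less_adj <- adj(p_less)
  defined <- !is.na(obs)
  list(cosine = obs, p_raw = p_raw,
       p_more_adj = p_more_adj, p_less_adj = p_less_adj,
       n_entries = length(obs),
       n_more = sum(p_more_adj <= 0.05 & defined, na.rm = TRUE),
       n_less = sum(p_less_adj <= 0.05 & defined, na.rm = TRUE),
       n_ns = sum(p_more_adj > 0.05 & p_less_adj > 0.05 & defined,
                  na.rm = TRUE),
       n_undefined = sum(!defined),
       mean_cosine = mean(obs[upper.tri(obs)], na.rm = TRUE),
       mode = mode)
}

#' Paired permutation test: weighted vs binary similarity matrices
#'
#' Sign-flip permutation test on the paired differences of the two cosine
#' matrices' off-diagonal entries (exhaustive enumeration up to 20 pairs).
#'
#' @param simW,simB results of [temporal_similarity()] in weighted and
#'   binary mode (or plain matrices on the same period grid).
#' @param n_mc Monte-Carlo flips when enumeration is infeasible.
#' @param seed integer seed for the Monte-Carlo path.
#' @return list: `p` (two-sided), `mean_diff` (binary minus weighted).
#' @export
weighted_vs_binary_test <- function(simW, simB, n_mc = 10000, seed = 1L) {
  W <- if (is.list(simW)) simW$cosine else simW
  B <- if (is.list(simB)) simB$cosine else simB
  if (!all(dim(W) == dim(B))) stop("matrices not on the same period grid")
  ut <- upper.tri(W)
  d <- (B - W)[ut]
  d <- d[!is.na(d)]
  res <- signflip_test(d, alternative = "two.sided", n_mc = n_mc, seed = seed)
  list(p = res$p, mean_diff = mean(d), n_pairs = length(d),
       exhaustive = res$exhaustive)
}

# Sign-flip permutation test on paired differences d; statistic = sum(d).
# Exhaustive over all 2^n sign assignments when n <= 20 (meet-in-the-middle
# enumeration), Monte Carlo otherwise. The identity assignment is included,
# so exhaustive p-values are never 0.
signflip_test <- function(d, alternative = c("greater", "less", "two.sided"),
                          n_mc = 10000, seed = 1L) {
  alternative <- match.arg(alternative)
  n <- length(d)
  s_obs <- sum(d)
  if (n == 0) return(list(p = NA_real_, exhaustive = TRUE))
  if (n <= 20) {
    half <- function(x) {
      s <- 0
      for (el in x) s <- c(s + el, s - el)
      s
    }
    k <- n %/% 2
    sums <- as.vector(outer(half(d[seq_len(k)]),
                            half(d[seq.int(k + 1, length.out = n - k)]), "+"))
    exhaustive <- TRUE
  } else {
    sums <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n * n_mc, replace = TRUE), n_mc, n)
      as.vector(signs %*% d)
    })
    sums <- c(s_obs, sums)   # include the identity
    exhaustive <- FALSE
  }
  p <- switch(alternative,
              greater = mean(sums >= s_obs),
              less = mean(sums <= s_obs),
              two.sided = mean(abs(sums) >= abs(s_obs) - 1e-12))
  list(p = p, exhaustive = exhaustive)
}

# --- threshold scan ----------------------------------------------------------

#' Scan candidate active/passive duration thresholds
#'
#' For each candidate threshold T, aggregates the contacts of duration
#' <= T (within the chosen phase) into one full-study SRI network and
#' records its mean strength and its cosine similarity to the baseline
#' network built from the smallest candidate. If a behavioural boundary
#' between short "active" and long carried-over "passive" contacts exists,
#' the cosine curve shows a sudden drop once contacts beyond the boundary
#' enter the network; the chosen threshold is the candidate immediately
#' before the largest single-step drop. A no-drop flag is raised when the
#' largest drop is below `min_drop_frac` of the curve's range.
#'
#' @param records deduplicated records.
#' @param candidates strictly increasing candidate thresholds, seconds.
#' @param pcfg the [phase_config()].
#' @param roster ordered roster.
#' @param phase restrict to "night" (default), "day" or "all" contacts.
#' @param min_drop_frac fraction of the cosine range the largest drop must
#'   reach to count as a sudden drop.
#' @return a `threshold_scan`: `curve` (data.frame threshold_s,
#'   mean_strength, cosine, drop), `chosen`, `no_drop`.
#' @export
threshold_scan <- function(records, candidates, pcfg, roster,
                           phase = "night", min_drop_frac = 0.5) {
  if (length(candidates) < 2) stop("need >= 2 candidate thresholds")
  if (any(diff(candidates) <= 0)) stop("candidates must be strictly increasing")
  ev <- label_phase(discretize(records, epoch = pcfg$epoch), pcfg)
  if (phase != "all") ev <- ev[ev$phase == phase, , drop = FALSE]
  slots <- sum(pcfg$windows$n_slots[
    if (phase == "all") TRUE else pcfg$windows$phase == phase])
  n <- length(roster)
  vec_at <- function(T) {
    e <- ev[ev$source_duration_s <= T, , drop = FALSE]
    cnt <- dyad_period_counts(match(e$dyad_a, roster),
                              match(e$dyad_b, roster),
                              rep(1L, nrow(e)), n, 1L)[, 1]
    cnt / slots
  }
  V <- matrix(vapply(candidates, vec_at, numeric(n * (n - 1) / 2)),
              ncol = length(candidates))
  base <- V[, 1]
  strengths <- vapply(seq_along(candidates), function(k) {
    cells <- dyad_upper_cells(n)
    m <- matrix(0, n, n); m[cells] <- V[, k]
    mean(rowSums(m + t(m)))
  }, numeric(1))
  cosines <- vapply(seq_along(candidates), function(k) {
    as.numeric(cosine_similarity(V[, k], base))
  }, numeric(1))
  drop <- c(NA, -diff(cosines))
  if (all(is.na(cosines)) || all(is.na(drop))) {
    # an empty baseline (or empty networks throughout) defines no curve
    no_drop <- TRUE
  } else {
    rng <- diff(range(cosines, na.rm = TRUE))
    no_drop <- !is.finite(rng) || rng == 0 ||
      max(drop, na.rm = TRUE) < min_drop_frac * rng
  }
  chosen <- if (no_drop) NA else candidates[which.max(drop) - 1L]
  structure(list(curve = data.frame(threshold_s = candidates,
                                    mean_strength = strengths,
                                    cosine = cosines, drop = drop),
                 chosen = chosen, no_drop = no_drop),
            class = "threshold_scan")
}

# --- day/night contrasts -----------------------------------------------------

#' Combine dependent permutation p-values (empirical Fisher)
#'
#' Fisher's statistic S = -2 sum log p on the observed p-value list is
#' compared against the empirical distribution of S over the same p-values
#' recomputed on each null replicate; because every null replicate went
#' through the identical pipeline, the dependence between the combined
#' p-values is preserved without being modelled. Zero p-values are
#' replaced by 1/(n_perm + 1) before the log (logged in the result).
#'
#' @param pvals observed p-values, one per (dependent) test.
#' @param null_pvals matrix, one row per null replicate, of the same
#'   p-values computed on that replicate.
#' @param n_perm the permutation count behind the p-values (sets the zero
#'   replacement); defaults to `nrow(null_pvals)`.
#' @param analytic also return the independent-Fisher chi-square reference
#'   p (cross-check only; ignores dependence).
#' @return list: `p` (empirical), `statistic`, `analytic_p`,
#'   `n_zero_replaced`.
#' @export
combine_dependent_pvalues <- function(pvals, null_pvals,
                                      n_perm = nrow(null_pvals),
                                      analytic = FALSE) {
  stopifnot(is.matrix(null_pvals), ncol(null_pvals) == length(pvals))
  eps <- 1 / (n_perm + 1)
  nz <- sum(pvals == 0)
  fix <- function(p) pmax(p, eps)
  S_obs <- -2 * sum(log(fix(pvals)))
  S_null <- -2 * rowSums(log(fix(null_pvals)))
  list(p = mean(S_null >= S_obs),
       statistic = S_obs,
       analytic_p = if (analytic)
         pchisq(S_obs, df = 2 * length(pvals), lower.tail = FALSE)
       else NA_real_,
       n_zero_replaced = nz)
}

#' Day/night contrast of a per-period trait series
#'
#' Computes the absolute difference of the trait between every pair of
#' consecutive aggregation periods (day 1 -> night 1 -> day 2 -> ...),
#' compares each observed |difference| to its null distribution over the
#' permutation ensemble (upper-tail p with the add-one Monte-Carlo
#' convention: the share of the pooled observed + null differences at
#' least as large, so SMALL p means the observed day/night change exceeds
#' what random within-group association predicts), and combines the
#' dependent per-transition p-values with the empirical Fisher procedure,
#' ranking the observed Fisher statistic within the null statistics
#' computed the same self-inclusive way — exactly calibrated under
#' exchangeability.
#'
#' @param observed numeric per-period trait series (ordered by period).
#' @param nulls matrix: one row per permutation replicate, per-period
#'   trait series computed on that replicate.
#' @return list: `p_transitions` (upper-tail per-transition p-values),
#'   `combined` (result of [combine_dependent_pvalues()]), `obs_delta`,
#'   `n_skipped` (transitions dropped for undefined traits).
#' @export
daynight_contrast <- function(observed, nulls) {
  stopifnot(is.matrix(nulls), ncol(nulls) == length(observed))
  obs_d <- abs(diff(observed))
  null_d <- abs(nulls[, -1, drop = FALSE] - nulls[, -ncol(nulls), drop = FALSE])
  ok <- !is.na(obs_d) & colSums(is.na(null_d)) == 0
  n_skipped <- sum(!ok)
  obs_d <- obs_d[ok]
  null_d <- null_d[, ok, drop = FALSE]
  if (length(obs_d) == 0) stop("no defined transitions")
  R <- nrow(null_d)
  # pooled self-inclusive upper-tail ranks: the observed stream and every
  # null replicate are treated symmetrically, so under exchangeability the
  # Fisher statistic of the observed list is a uniform draw from the pooled
  # set and the combined p-value is exactly calibrated (add-one Monte-Carlo
  # convention; p-values can never be 0)
  P <- vapply(seq_along(obs_d), function(t) {
    v <- c(obs_d[t], null_d[, t])
    (length(v) - rank(v, ties.method = "min") + 1) / length(v)
  }, numeric(R + 1))
  if (!is.matrix(P)) P <- matrix(P, nrow = R + 1)
  S <- -2 * rowSums(log(P))
  p_comb <- sum(S >= S[1]) / (R + 1)
  comb <- list(p = p_comb, statistic = S[1],
               analytic_p = pchisq(S[1], df = 2 * length(obs_d),
                                   lower.tail = FALSE),
               n_zero_replaced = 0L)
  list(p_transitions = P[1, ], combined = comb, obs_delta = obs_d,
       n_skipped = n_skipped)
}

#' Paired location tests (t, Wilcoxon, sign-flip permutation)
#'
#' One-sided paired Student t-test, one-sided Wilcoxon signed-rank test,
#' and a sign-flip permutation test on the paired differences (exhaustive
#' up to 20 pairs).
#'
#' @param x,y equal-length paired series.
#' @param alternative "greater" tests x > y.
#' @param n_mc,seed Monte-Carlo settings for the permutation test.
#' @return list: `t_p`, `wilcoxon_p`, `perm_p`, `flags`.
#' @export
paired_location_tests <- function(x, y, alternative = "greater",
                                  n_mc = 10000, seed = 1L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  flags <- character()
  degenerate_p <- function() {
    # essentially constant differences: the t statistic is 0/0 (all zero)
    # or infinite (constant shift); resolve by direction
    flags <<- c(flags, "zero-variance differences: t-test degenerate")
    m <- mean(d)
    tol <- 1e-10 * max(1, abs(m))
    switch(alternative,
           greater = if (m > tol) 0 else 1,
           less = if (m < -tol) 0 else 1,
           two.sided = if (abs(m) <= tol) 1 else 0)
  }
  t_p <- if (sd(d) == 0) degenerate_p() else
    tryCatch(t.test(x, y, paired = TRUE, alternative = alternative)$p.value,
             error = function(e) degenerate_p())
  w_p <- if (all(d == 0)) {
    flags <- c(flags, "all differences zero: Wilcoxon undefined")
    NA_real_
  } else {
    suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                 alternative = alternative)$p.value)
  }
  perm <- signflip_test(d, alternative = alternative, n_mc = n_mc, seed = seed)
  list(t_p = t_p, wilcoxon_p = w_p, perm_p = perm$p, flags = flags)
}

#' Portmanteau (Ljung-Box) autocorrelation test
#'
#' @param series numeric time series.
#' @param max_lag number of lags pooled into the statistic.
#' @return list: `statistic`, `df`, `p`; NA (flagged) on constant series.
#' @export
portmanteau_autocorr <- function(series, max_lag = 5) {
  stopifnot(length(series) > max_lag + 1)
  if (sd(series) == 0) {
    return(list(statistic = NA_real_, df = max_lag, p = NA_real_,
                flags = "constant series: autocorrelation undefined"))
  }
  bt <- Box.test(series, lag = max_lag, type = "Ljung-Box")
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p = bt$p.value, flags = character())
}
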