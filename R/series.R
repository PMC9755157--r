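# Per-period trait series, vectorized over periods and permutation
# replicates. The day/night contrast machinery recomputes every trait on
# hundreds of permuted event streams; these helpers work directly on the
# P x n_periods dyad count matrices rather than materializing matrices.

# Precomputed incidence structures for a roster and group assignment.
series_env <- function(roster, groups) {
  n <- length(roster)
  P <- n * (n - 1) / 2
  cells <- dyad_upper_cells(n)
  E <- matrix(0, n, P)
  E[cbind(cells[, 1], seq_len(P))] <- 1
  E[cbind(cells[, 2], seq_len(P))] <- 1
  # group-mate dyads per node (for selectivity): dyads containing the node
  # whose other endpoint is one of its group's members
  G <- matrix(0, n, P)
  for (i in seq_len(n)) {
    mem <- groups$members[[groups$group_of[[roster[i]]]]]
    midx <- match(setdiff(mem, roster[i]), roster)
    other <- ifelse(cells[, 1] == i, cells[, 2],
                    ifelse(cells[, 2] == i, cells[, 1], NA))
    G[i, which(other %in% midx)] <- 1
  }
  # within-group dyads per group (for differentiation)
  ng <- length(groups$members)
  H <- matrix(0, ng, P)
  for (g in seq_len(ng)) {
    midx <- match(groups$members[[g]], roster)
    H[g, cells[, 1] %in% midx & cells[, 2] %in% midx] <- 1
  }
  mem_idx <- lapply(groups$members, match, roster)
  list(n = n, P = P, cells = cells, E = E, G = G, H = H,
       k_node = rowSums(G), k_group = rowSums(H), mem_idx = mem_idx)
}

# column-wise sample CV from mask M (units x P), weight matrix W (P x nP)
masked_cv <- function(M, k, W) {
  SUM <- M %*% W
  SSQ <- M %*% W^2
  mu <- SUM / k
  v <- (SSQ - k * mu^2) / (k - 1)
  out <- sqrt(pmax(v, 0)) / mu
  out[!is.finite(out)] <- NA
  out[k < 2, ] <- NA
  out
}

col_sd <- function(X) {
  m <- nrow(X)
  if (m < 2) return(rep(NA_real_, ncol(X)))
  sqrt(pmax(colSums(X^2) - colSums(X)^2 / m, 0) / (m - 1))
}

#' Per-period trait series from a dyad weight matrix
#'
#' @param W P x n_periods matrix of SRI weights (P dyads in
#'   [vectorize_upper()] order).
#' @param env precomputed `series_env()` structures.
#' @param trait one of "strength", "degree", "eigenvector", "selectivity",
#'   "density", "differentiation", "sd_strength", "sd_degree",
#'   "sd_eigenvector", "stability". Node/group traits are averaged over
#'   defined units per period; "stability" is the mean neighbour Jaccard
#'   between a period and its predecessor (NA for the first period).
#' @return numeric vector, one value per period.
#' @keywords internal
trait_series <- function(W, env, trait) {
  nP <- ncol(W)
  Bin <- (W > 0) + 0
  # node traits are averaged over individuals observed interacting in the
  # period: the full-roster mean strength is invariant under dyad swaps
  # (slot totals are fixed), so including isolates would make the series
  # untestable against the permutation null
  active_mean <- function(X) {
    S <- env$E %*% W
    X[S == 0] <- NA
    colMeans(X, na.rm = TRUE)
  }
  switch(trait,
    strength = active_mean(env$E %*% W),
    degree = active_mean(env$E %*% Bin),
    density = colMeans(Bin),
    selectivity = colMeans(masked_cv(env$G, env$k_node, W), na.rm = TRUE),
    differentiation = colMeans(masked_cv(env$H, env$k_group, W), na.rm = TRUE),
    sd_strength = {
      S <- env$E %*% W
      rowMeans(vapply(env$mem_idx, function(ix) col_sd(S[ix, , drop = FALSE]),
                      numeric(nP)), na.rm = TRUE)
    },
    sd_degree = {
      S <- env$E %*% Bin
      rowMeans(vapply(env$mem_idx, function(ix) col_sd(S[ix, , drop = FALSE]),
                      numeric(nP)), na.rm = TRUE)
    },
    sd_eigenvector = {
      EV <- eigenvector_cols(W, env)
      rowMeans(vapply(env$mem_idx, function(ix) col_sd(EV[ix, , drop = FALSE]),
                      numeric(nP)), na.rm = TRUE)
    },
    eigenvector = active_mean(eigenvector_cols(W, env)),
    stability = stability_series(Bin, env),
    stop("unknown trait: ", trait)
  )
}

# per-period eigenvector centralities (n x nP), max-1 scaling, zeros for
# empty periods
eigenvector_cols <- function(W, env) {
  nP <- ncol(W)
  out <- matrix(0, env$n, nP)
  for (p in seq_len(nP)) {
    if (all(W[, p] == 0)) next
    m <- matrix(0, env$n, env$n)
    m[env$cells] <- W[, p]
    m <- m + t(m)
    v <- abs(eigen(m, symmetric = TRUE)$vectors[, 1])
    out[, p] <- v / max(v)
  }
  out
}

# mean neighbour-set Jaccard between consecutive periods; first entry NA
stability_series <- function(Bin, env) {
  nP <- ncol(Bin)
  adj <- function(p) {
    m <- matrix(FALSE, env$n, env$n)
    m[env$cells] <- Bin[, p] > 0
    m | t(m)
  }
  out <- rep(NA_real_, nP)
  prev <- adj(1)
  for (p in 2:nP) {
    cur <- adj(p)
    inter <- rowSums(prev & cur)
    uni <- rowSums(prev | cur)
    out[p] <- mean((inter / uni)[uni > 0])
    prev <- cur
  }
  out
}

#' Day/night contrast of a network trait over a permutation ensemble
#'
#' Builds the observed per-period trait series and its null distribution
#' from the data-stream permutation ensemble, then runs
#' [daynight_contrast()].
#'
#' @param events labelled event table.
#' @param ens a [datastream_permute()] ensemble built on `events`.
#' @param pcfg the [phase_config()].
#' @param roster ordered roster.
#' @param groups a [assign_groups()] result.
#' @param trait trait name (see [trait_series()]).
#' @param context event context to aggregate (default "active").
#' @return the [daynight_contrast()] result, plus `series` (observed),
#'   `day_mean`, `night_mean`.
#' @export
daynight_trait_contrast <- function(events, ens, pcfg, roster, groups,
                                    trait, context = "active") {
  env <- series_env(roster, groups)
  nP <- nrow(pcfg$windows)
  slots <- pcfg$windows$n_slots
  mk <- function(a, b) {
    W <- context_count_matrix(a, b, events$period, events$context, context,
                              env$n, nP)
    sweep(W, 2, slots, "/")
  }
  obs <- trait_series(mk(match(events$dyad_a, roster),
                         match(events$dyad_b, roster)), env, trait)
  nulls <- t(vapply(seq_len(ens$config$n_perm), function(r) {
    s <- ens$samples[[r]]
    trait_series(mk(s[, 1], s[, 2]), env, trait)
  }, numeric(nP)))
  res <- daynight_contrast(obs, nulls)
  is_day <- pcfg$windows$phase == "day"
  res$series <- obs
  res$day_mean <- mean(obs[is_day], na.rm = TRUE)
  res$night_mean <- mean(obs[!is_day], na.rm = TRUE)
  res$trait <- trait
  res
}
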