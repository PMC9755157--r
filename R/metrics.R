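# Node- and group-level network traits: degree, strength, eigenvector
# centrality, edge density, individual selectivity (CV of a node's edge
# weights to its group-mates, structural zeros included), group social
# differentiation (CV of all within-group dyadic weights), neighbours'
# stability (Jaccard), and within-group trait SDs.
#
# Betweenness and closeness are deliberately absent: daily networks are
# sparse and those measures are too sensitive to sparsity.

#' Degree, strength and eigenvector centrality
#'
#' Degree is counted on the binarized structure; strength is the row sum
#' of weights; eigenvector centrality is the leading eigenvector of the
#' weighted matrix, nonnegative and scaled to max = 1. On an empty network
#' all three are 0 (flagged). On a disconnected network the eigenvector is
#' computed on the full matrix — the dominant component carries the mass —
#' and the result is flagged.
#'
#' @param m an [assoc_matrix()] or symmetric matrix.
#' @return data.frame: node, degree, strength, eigenvector; attribute
#'   `flags` lists anything degenerate.
#' @export
node_centralities <- function(m) {
  w <- if (inherits(m, "assoc_matrix")) m$weights else m
  if (max(abs(w - t(w))) > 1e-12) stop("asymmetric input")
  n <- nrow(w)
  roster <- rownames(w)
  if (is.null(roster)) roster <- as.character(seq_len(n))
  flags <- character()
  deg <- rowSums(w > 0)
  str <- rowSums(w)
  if (all(w == 0)) {
    ev <- rep(0, n)
    flags <- c(flags, "empty network: centralities set to 0")
  } else {
    e <- eigen(w, symmetric = TRUE)
    v <- abs(e$vectors[, 1])
    ev <- v / max(v)
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected"))
    if (comp$no > sum(deg == 0) + 1)
      flags <- c(flags, "disconnected network: eigenvector mass sits on the dominant component")
  }
  out <- data.frame(node = roster, degree = as.integer(deg),
                    strength = str, eigenvector = ev)
  rownames(out) <- NULL
  attr(out, "flags") <- flags
  out
}

#' Edge density over a roster subset
#'
#' Existing ties among the subset divided by the number of potential
#' connections C(n, 2).
#'
#' @param m an [assoc_matrix()] or symmetric matrix.
#' @param subset node ids; default the full roster.
#' @return density in \[0, 1\]; NA (flagged) for subsets of size < 2.
#' @export
edge_density <- function(m, subset = NULL) {
  w <- if (inherits(m, "assoc_matrix")) m$weights else m
  if (is.null(subset)) subset <- rownames(w)
  k <- length(subset)
  if (k < 2) {
    out <- NA_real_
    attr(out, "flags") <- "subset of size < 2: density undefined"
    return(out)
  }
  ww <- w[subset, subset, drop = FALSE]
  sum(ww[upper.tri(ww)] > 0) / (k * (k - 1) / 2)
}

#' Individual selectivity: CV of a node's within-group edge weights
#'
#' Sample CV (sd/mean, n-1 denominator by default) over the node's weights
#' to ALL its group-mates, structural zeros included; high values mean the
#' individual concentrates its associations on few partners.
#'
#' @param m an [assoc_matrix()] or symmetric matrix.
#' @param node node id.
#' @param group ids of the node's group (including the node).
#' @param population use the population (1/n) variance instead.
#' @return CV, or NA (flagged) when the mean weight is 0 or the group has
#'   fewer than 3 members.
#' @export
selectivity_cv <- function(m, node, group, population = FALSE) {
  w <- if (inherits(m, "assoc_matrix")) m$weights else m
  mates <- setdiff(group, node)
  if (length(mates) < 2) {
    out <- NA_real_
    attr(out, "flags") <- "group of size < 3: selectivity undefined"
    return(out)
  }
  x <- w[node, mates]
  v <- cv(x, population = population)
  if (is.na(v)) attr(v, "flags") <- "zero mean weight: selectivity undefined"
  v
}

#' Group social differentiation: CV of all within-group dyadic weights
#'
#' @inheritParams selectivity_cv
#' @param group ids of the group members.
#' @return CV over the C(n, 2) within-group weights, zeros included; NA
#'   (flagged) when all-zero or the group has fewer than 3 members.
#' @export
social_differentiation <- function(m, group, population = FALSE) {
  w <- if (inherits(m, "assoc_matrix")) m$weights else m
  if (length(group) < 3) {
    out <- NA_real_
    attr(out, "flags") <- "group of size < 3: differentiation undefined"
    return(out)
  }
  ww <- w[group, group, drop = FALSE]
  x <- ww[upper.tri(ww)]
  v <- cv(x, population = population)
  if (is.na(v)) attr(v, "flags") <- "all-zero weights: differentiation undefined"
  v
}

#' Neighbours' stability between consecutive periods
#'
#' Jaccard index of a node's (binarized) neighbour sets in two networks.
#'
#' @param net_t,net_next conformable [assoc_matrix()] objects or matrices.
#' @param node node id.
#' @return Jaccard in \[0, 1\]; NA (flagged, excluded from averages) when
#'   both neighbour sets are empty.
#' @export
neighbour_stability <- function(net_t, net_next, node) {
  w1 <- if (inherits(net_t, "assoc_matrix")) net_t$weights else net_t
  w2 <- if (inherits(net_next, "assoc_matrix")) net_next$weights else net_next
  if (!identical(rownames(w1), rownames(w2))) stop("rosters not conformable")
  n1 <- names(which(w1[node, ] > 0))
  n2 <- names(which(w2[node, ] > 0))
  u <- union(n1, n2)
  if (length(u) == 0) {
    out <- NA_real_
    attr(out, "flags") <- "both neighbour sets empty: stability undefined"
    return(out)
  }
  length(intersect(n1, n2)) / length(u)
}

#' Within-group standard deviation of a trait
#'
#' @param values trait values of the group's members (NAs dropped).
#' @return sample SD; NA (flagged) with fewer than 2 defined values.
#' @export
group_sd <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2) {
    out <- NA_real_
    attr(out, "flags") <- "fewer than 2 defined values: SD undefined"
    return(out)
  }
  sd(x)
}

#' Tidy trait table over a list of period networks
#'
#' Computes, for every period network, the node-level traits (degree,
#' strength, eigenvector, selectivity) and group/network-level traits
#' (edge density per group, social differentiation per group, within-group
#' SDs of the three centralities), in long format.
#'
#' @param nets named list of [assoc_matrix()] (one per period).
#' @param groups a [assign_groups()] result.
#' @return data.frame: period, context, unit ("node", "group"), id, trait,
#'   value, defined.
#' @export
trait_table <- function(nets, groups) {
  rows <- list()
  gsets <- groups$members
  for (pid in names(nets)) {
    m <- nets[[pid]]
    cent <- node_centralities(m)
    sel <- vapply(cent$node, function(v) {
      g <- gsets[[groups$group_of[[v]]]]
      as.numeric(selectivity_cv(m, v, g))
    }, numeric(1))
    node_rows <- data.frame(
      period = pid, context = m$context, unit = "node",
      id = rep(cent$node, 4),
      trait = rep(c("degree", "strength", "eigenvector", "selectivity"),
                  each = nrow(cent)),
      value = c(cent$degree, cent$strength, cent$eigenvector, sel)
    )
    grp_rows <- do.call(rbind, lapply(seq_along(gsets), function(g) {
      mem <- gsets[[g]]
      vals <- c(
        density = as.numeric(edge_density(m, mem)),
        differentiation = as.numeric(social_differentiation(m, mem)),
        sd_degree = as.numeric(group_sd(cent$degree[cent$node %in% mem])),
        sd_strength = as.numeric(group_sd(cent$strength[cent$node %in% mem])),
        sd_eigenvector = as.numeric(group_sd(cent$eigenvector[cent$node %in% mem]))
      )
      data.frame(period = pid, context = m$context, unit = "group",
                 id = as.character(g), trait = names(vals), value = vals)
    }))
    rows[[pid]] <- rbind(node_rows, grp_rows)
  }
  out <- do.call(rbind, rows)
  out$defined <- !is.na(out$value)
  rownames(out) <- NULL
  out
}
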