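# Overlapping link-community detection.
#
# Communities of EDGES rather than nodes: edges sharing a node are scored
# by the Jaccard similarity of the inclusive neighbourhoods of their
# non-shared endpoints, clustered by single linkage, and the dendrogram is
# cut at the level maximizing partition density. A node inherits the
# communities of its incident edges and can belong to several, which is
# what makes these covers suitable strata for data-stream permutations:
# a multi-community individual's "group" is the union of all its
# communities' members.

#' Detect overlapping link communities
#'
#' Edge similarity is computed on the binary structure by default
#' (`weighted = TRUE` switches to the Tanimoto variant on edge weights).
#' Single-linkage agglomeration uses deterministic lexicographic edge
#' order; the cut maximizes partition density, ties broken toward fewer
#' communities.
#'
#' @param network an [assoc_matrix()] (or symmetric weighted matrix with
#'   dimnames) with at least one edge.
#' @param weighted use Tanimoto similarity on weights instead of binary
#'   Jaccard.
#' @return a `link_community_cover`: `edges` (data.frame a, b, weight,
#'   community), `node_communities` (named list), `membership_fraction`
#'   (named list of per-community shares), `partition_density`,
#'   `n_communities`, and the edge dendrogram (`tree`).
#' @export
link_communities <- function(network, weighted = FALSE) {
  w <- if (inherits(network, "assoc_matrix")) network$weights else network
  roster <- rownames(w)
  if (is.null(roster)) roster <- as.character(seq_len(nrow(w)))
  cells <- dyad_upper_cells(nrow(w))
  keep <- w[cells] > 0
  if (!any(keep)) stop("link_communities requires a network with >= 1 edge")
  ea <- cells[keep, 1]; eb <- cells[keep, 2]
  ew <- w[cells][keep]
  M <- length(ea)

  adj <- (w > 0)
  nb_inc <- lapply(seq_len(nrow(w)), function(v) {
    x <- which(adj[v, ]); union(x, v)   # inclusive neighbourhood n+(v)
  })

  sim <- matrix(0, M, M)
  if (M > 1) {
    inc <- lapply(seq_len(nrow(w)), function(v) which(ea == v | eb == v))
    for (v in seq_len(nrow(w))) {
      es <- inc[[v]]
      if (length(es) < 2) next
      for (x in seq_len(length(es) - 1)) for (y in (x + 1):length(es)) {
        e1 <- es[x]; e2 <- es[y]
        i <- if (ea[e1] == v) eb[e1] else ea[e1]   # non-shared endpoints
        j <- if (ea[e2] == v) eb[e2] else ea[e2]
        s <- if (weighted) {
          ai <- w[i, ]; aj <- w[j, ]
          ai[i] <- mean(w[i, adj[i, ]]); aj[j] <- mean(w[j, adj[j, ]])
          num <- sum(ai * aj)
          num / (sum(ai^2) + sum(aj^2) - num)
        } else {
          length(intersect(nb_inc[[i]], nb_inc[[j]])) /
            length(union(nb_inc[[i]], nb_inc[[j]]))
        }
        sim[e1, e2] <- max(sim[e1, e2], s)
        sim[e2, e1] <- sim[e1, e2]
      }
    }
  }

  if (M == 1) {
    comm <- 1L
    pd <- 0
  } else {
    d <- as.dist(1 - sim)
    # edges that never share a node keep similarity 0 -> distance 1; they
    # can only merge at the top of the dendrogram
    tree <- hclust(d, method = "single")
    dens <- vapply(seq_len(M), function(k) {
      partition_density_assign(cutree(tree, k = k), ea, eb)
    }, numeric(1))
    best <- max(dens)
    k_best <- min(which(dens >= best - 1e-12))   # ties -> fewer communities
    comm <- cutree(tree, k = k_best)
    pd <- dens[k_best]
  }

  edges <- data.frame(a = roster[ea], b = roster[eb], weight = ew,
                      community = as.integer(comm))
  node_comm <- lapply(seq_along(roster), function(v) {
    sort(unique(comm[ea == v | eb == v]))
  })
  names(node_comm) <- roster
  cover <- structure(list(edges = edges, roster = roster,
                          node_communities = node_comm,
                          partition_density = pd,
                          n_communities = length(unique(comm)),
                          tree = if (M > 1) tree else NULL),
                     class = "link_community_cover")
  cover$membership_fraction <- membership_fractions(cover, network)
  cover
}

# Partition density for an edge->community assignment over edges (ea, eb):
# D = (2/M) sum_c m_c (m_c - n_c + 1) / ((n_c - 2)(n_c - 1)); a community
# that is a tree (or a single edge, n_c = 2) contributes 0.
partition_density_assign <- function(comm, ea, eb) {
  M <- length(ea)
  contrib <- vapply(unique(comm), function(cc) {
    sel <- comm == cc
    m <- sum(sel)
    n <- length(unique(c(ea[sel], eb[sel])))
    if (n <= 2) return(0)
    m * (m - n + 1) / ((n - 2) * (n - 1))
  }, numeric(1))
  2 / M * sum(contrib)
}

#' Partition density of a link-community cover
#'
#' Edge-weighted average of each community's internal density, normalized
#' between a spanning tree (0) and a clique (1); single-edge communities
#' contribute 0.
#'
#' @param cover a `link_community_cover`.
#' @param network unused (kept for call symmetry); density depends only on
#'   the cover's edges.
#' @return scalar in \[0, 1\].
#' @export
partition_density <- function(cover, network = NULL) {
  ea <- match(cover$edges$a, cover$roster)
  eb <- match(cover$edges$b, cover$roster)
  partition_density_assign(cover$edges$community, ea, eb)
}

#' Node shares of interaction per community
#'
#' Share of node v in community c = (sum of v's edge weights inside c) /
#' (v's strength). Zero-strength nodes get an empty share vector and are
#' flagged.
#'
#' @param cover a `link_community_cover`.
#' @param network the network the cover was computed on.
#' @return named list: per node, a named numeric vector of community
#'   shares summing to 1 (attribute `flagged` lists zero-strength nodes).
#' @export
membership_fractions <- function(cover, network) {
  w <- if (inherits(network, "assoc_matrix")) network$weights else network
  roster <- cover$roster
  flagged <- character()
  out <- lapply(roster, function(v) {
    sel <- cover$edges$a == v | cover$edges$b == v
    if (!any(sel)) { flagged <<- c(flagged, v); return(numeric()) }
    ew <- cover$edges$weight[sel]
    cc <- cover$edges$community[sel]
    tot <- sum(ew)
    if (tot == 0) { flagged <<- c(flagged, v); return(numeric()) }
    shares <- tapply(ew, cc, sum) / tot
    out <- as.numeric(shares); names(out) <- names(shares)
    out
  })
  names(out) <- roster
  attr(out, "flagged") <- flagged
  out
}

#' Dominant community per node
#'
#' The community receiving the largest share of a node's interaction
#' weight (ties broken toward the smaller community id); nodes with no
#' edges get NA. This is the "main slice of the pie" reading of a
#' multi-membership cover.
#'
#' @param cover a `link_community_cover`.
#' @return named integer vector over the roster.
#' @export
primary_communities <- function(cover) {
  out <- vapply(cover$roster, function(v) {
    sh <- cover$membership_fraction[[v]]
    if (length(sh) == 0) return(NA_integer_)
    as.integer(names(sh)[which.max(sh)])
  }, integer(1))
  names(out) <- cover$roster
  out
}

#' Assign each node to a permutation group
#'
#' A node in a single community is grouped with that community's members;
#' a multi-community node's group is the union of all its communities'
#' members. Nodes with no edges become singleton groups (flagged). Group
#' ids index the distinct member sets and are stable under community
#' relabelling.
#'
#' @param cover a `link_community_cover`.
#' @return a `group_assignment`: `group_of` (named integer), `members`
#'   (list of member id vectors per group), `flagged_isolates`.
#' @export
assign_groups <- function(cover) {
  roster <- cover$roster
  comm_members <- lapply(sort(unique(cover$edges$community)), function(cc) {
    sel <- cover$edges$community == cc
    sort(unique(c(cover$edges$a[sel], cover$edges$b[sel])))
  })
  names(comm_members) <- sort(unique(cover$edges$community))
  sets <- lapply(roster, function(v) {
    cs <- cover$node_communities[[v]]
    if (length(cs) == 0) return(v)   # isolate -> singleton group
    sort(unique(unlist(comm_members[as.character(cs)])))
  })
  key <- vapply(sets, paste, character(1), collapse = "|")
  uk <- unique(key)
  group_of <- match(key, uk)
  names(group_of) <- roster
  members <- sets[match(uk, key)]
  names(members) <- seq_along(members)
  isolates <- roster[vapply(cover$node_communities, length, 1L) == 0]
  structure(list(group_of = group_of, members = members,
                 flagged_isolates = isolates),
            class = "group_assignment")
}
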