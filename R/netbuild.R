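# Aggregation of labelled proximity events into simple-ratio-index (SRI)
# association networks, one per aggregation period and social context.
#
# Under continuous logger deployment every collar is "sampled" in every
# 5-minute slot of a period, so the SRI denominator collapses to the total
# number of slots in the period: weight(i, j) = slots with an i-j event /
# slots in the period.

#' Construct an association matrix container
#' @param weights symmetric numeric matrix, zero diagonal.
#' @param roster ordered individual ids (row/col names of `weights`).
#' @param period_id aggregation period identifier.
#' @param context "active", "passive" or "all".
#' @param n_slots number of 5-minute slots in the period.
#' @return an `assoc_matrix`.
#' @export
assoc_matrix <- function(weights, roster, period_id = NA, context = "all",
                         n_slots = NA_integer_) {
  stopifnot(is.matrix(weights), nrow(weights) == length(roster))
  if (max(abs(weights - t(weights))) > 1e-12) stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  dimnames(weights) <- list(roster, roster)
  structure(list(weights = weights, roster = roster, period_id = period_id,
                 context = context, n_slots = n_slots),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("SRI network: %d nodes, %d edges, period %s, context %s, %s slots\n",
              length(x$roster), sum(x$weights[upper.tri(x$weights)] > 0),
              as.character(x$period_id), x$context, as.character(x$n_slots)))
  invisible(x)
}

#' Build a simple-ratio-index network for one period and context
#'
#' @param events labelled event table ([preprocess_records()]).
#' @param period_id the aggregation period to build.
#' @param context "active", "passive" or "all".
#' @param roster full ordered roster (kept even for silent individuals so
#'   matrices stay conformable across periods).
#' @param n_slots number of slots in the period (SRI denominator).
#' @return an [assoc_matrix()] with weights in \[0, 1\].
#' @export
build_sri <- function(events, period_id, context, roster, n_slots) {
  stopifnot(n_slots > 0)
  e <- events[events$period == period_id, , drop = FALSE]
  if (context != "all") e <- e[e$context == context, , drop = FALSE]
  if (!all(c(e$dyad_a, e$dyad_b) %in% roster))
    stop("event references an individual not on the roster")
  n <- length(roster)
  w <- matrix(0, n, n, dimnames = list(roster, roster))
  if (nrow(e) > 0) {
    ia <- match(e$dyad_a, roster)
    ib <- match(e$dyad_b, roster)
    cnt <- table(dyad_index(ia, ib, n))
    pos <- as.integer(names(cnt))
    ut <- which(upper.tri(w))
    # dyad_index is row-major above the diagonal; map to column-major cells
    ij <- dyad_upper_cells(n)
    w[ij[pos, , drop = FALSE]] <- as.numeric(cnt) / n_slots
    w <- w + t(w)
  }
  assoc_matrix(w, roster, period_id, context, as.integer(n_slots))
}

# (row, col) cells of the upper triangle in dyad_index (row-major) order
dyad_upper_cells <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
  cbind(i, j)
}

#' Binarize an association matrix
#'
#' @param m an `assoc_matrix` (or plain matrix).
#' @return same type with weights > 0 set to 1.
#' @export
binarize <- function(m) {
  if (inherits(m, "assoc_matrix")) {
    m$weights <- (m$weights > 0) + 0
    m
  } else {
    (m > 0) + 0
  }
}

#' Vectorize the upper triangle of an association matrix
#'
#' Row-major above-diagonal order, fixed by the roster, so vectors from
#' different periods are comparable position by position.
#'
#' @param m an `assoc_matrix` or plain symmetric matrix.
#' @param roster if given, checked against the matrix roster.
#' @return numeric vector of length n(n-1)/2.
#' @export
vectorize_upper <- function(m, roster = NULL) {
  w <- if (inherits(m, "assoc_matrix")) m$weights else m
  if (!is.null(roster)) {
    rn <- if (inherits(m, "assoc_matrix")) m$roster else rownames(w)
    if (!identical(as.character(rn), as.character(roster)))
      stop("roster mismatch between matrices being compared")
  }
  n <- nrow(w)
  w[dyad_upper_cells(n)]
}

#' Per-period dyad slot counts as a matrix of vectorized networks
#'
#' Fast path used by the permutation machinery: returns an n(n-1)/2 x
#' n_periods matrix of slot counts (row = dyad in [vectorize_upper()]
#' order), for a given context. Dividing each column by its period's slot
#' count gives the SRI vectors.
#'
#' @param a,b individual indices (1-based into the roster) per event.
#' @param period period id per event (1..n_periods).
#' @param n roster size.
#' @param n_periods number of periods.
#' @return integer matrix.
#' @keywords internal
dyad_period_counts <- function(a, b, period, n, n_periods) {
  P <- n * (n - 1) / 2
  if (length(a) == 0) return(matrix(0L, P, n_periods))
  pos <- dyad_index(a, b, n) + (period - 1L) * P
  matrix(tabulate(pos, nbins = P * n_periods), nrow = P)
}

#' Write an association matrix as a weighted edge list (TSV)
#' @param m an `assoc_matrix`.
#' @param path file path.
#' @export
write_edgelist <- function(m, path) {
  cells <- dyad_upper_cells(length(m$roster))
  w <- m$weights[cells]
  keep <- w > 0
  out <- data.frame(node_a = m$roster[cells[keep, 1]],
                    node_b = m$roster[cells[keep, 2]],
                    weight = w[keep])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
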