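#' Newman-Girvan modularity of a partitioned town network
#'
#' Computes \eqn{Q = \sum_k [ L_k^w / L - (L_k / 2L)^2 ]}, where \eqn{L} is the
#' number of edges, \eqn{L_k^w} the number of edges with both endpoints in
#' community \eqn{k}, and \eqn{L_k} the sum of degrees of the members of
#' \eqn{k} (each within-community edge contributes two degree endpoints, each
#' boundary edge one). This is the standard unweighted modularity of the
#' configuration-model null.
#'
#' @param g A [build_graph()] `town_network` with at least one edge.
#' @param partition Named vector mapping every node of `g` to a community
#'   label.
#' @return Modularity `Q`, a dimensionless number in \eqn{[-1, 1)}.
#' @seealso [max_modularity()], [fragmentation_index()]
#' @export
modularity_q <- function(g, partition) {
  counts <- community_edge_counts(g, partition)
  L <- n_edges(g)
  sum(counts$L_k_w / L - (counts$L_k / (2 * L))^2)
}

#' Theoretical maximum modularity for a partition
#'
#' The modularity the same partition would attain if every edge were internal
#' to its community while community degree totals were held fixed:
#' \eqn{Q_{max} = 1 - \sum_k (L_k / 2L)^2}. Used as the size normalizer of the
#' fragmentation index. A single-community partition gives `Q_max = 0`.
#'
#' @inheritParams modularity_q
#' @return `Q_max` in \eqn{[0, 1)}.
#' @export
max_modularity <- function(g, partition) {
  counts <- community_edge_counts(g, partition)
  L <- n_edges(g)
  1 - sum((counts$L_k / (2 * L))^2)
}

#' Fragmentation index F = Q / Qmax
#'
#' A size-adjusted modularity: the ratio of the observed modularity to the
#' maximum attainable with the same community degree totals. `F = 1` exactly
#' when no edge crosses community boundaries, and `F <= 1` always. Because
#' networks of different sizes have different attainable modularity, `F` is
#' comparable across towns where raw `Q` is not.
#'
#' @inheritParams modularity_q
#' @return Fragmentation index `F <= 1`.
#' @section Degenerate partitions:
#' When `Q_max = 0` (single community, where the ratio is 0/0) the index is
#' undefined and an error is raised; the calling pipeline records fragmentation
#' as missing for that town.
#' @export
fragmentation_index <- function(g, partition) {
  q_max <- max_modularity(g, partition)
  if (q_max <= .Machine$double.eps) {
    stop("fragmentation index undefined: Q_max = 0 (degenerate single-community partition)")
  }
  modularity_q(g, partition) / q_max
}

#' Full modularity report for one town
#'
#' @inheritParams modularity_q
#' @return A list of class `modularity_report`: `Q`, `Q_max`, `F` (`NA` if
#'   undefined), `n_communities`, and `per_community`, a data frame with one
#'   row per community giving `L_k` (degree endpoints adjacent to the
#'   community) and `L_k_w` (within-community edge count).
#' @export
modularity_report <- function(g, partition) {
  counts <- community_edge_counts(g, partition)
  L <- n_edges(g)
  q <- sum(counts$L_k_w / L - (counts$L_k / (2 * L))^2)
  q_max <- 1 - sum((counts$L_k / (2 * L))^2)
  structure(
    list(
      town_id = g$town_id,
      Q = q,
      Q_max = q_max,
      F = if (q_max > .Machine$double.eps) q / q_max else NA_real_,
      n_communities = nrow(counts),
      per_community = counts
    ),
    class = "modularity_report"
  )
}

#' @export
print.modularity_report <- function(x, ...) {
  cat(sprintf(
    "<modularity_report '%s': Q = %.4f, Q_max = %.4f, F = %s, %d communities>\n",
    x$town_id, x$Q, x$Q_max,
    if (is.na(x$F)) "undefined" else sprintf("%.4f", x$F),
    x$n_communities
  ))
  invisible(x)
}

# Per-community edge accounting shared by Q, Q_max and the report.
# Validates the partition: every node must carry exactly one label.
community_edge_counts <- function(g, partition) {
  stopifnot(inherits(g, "town_network"))
  if (n_edges(g) == 0L) stop("modularity undefined for a graph with no edges (L = 0)")
  missing_nodes <- setdiff(g$nodes, names(partition))
  if (length(missing_nodes) > 0L) {
    stop(
      "partition does not cover all nodes; missing: ",
      paste(utils::head(missing_nodes, 5L), collapse = ", ")
    )
  }
  lab <- as.character(partition[g$nodes])
  names(lab) <- g$nodes
  communities <- sort(unique(lab))
  from_c <- lab[g$edges[, 1L]]
  to_c <- lab[g$edges[, 2L]]
  # degree endpoints per community: each edge contributes one endpoint to the
  # community of each end (so an internal edge contributes 2 to its community)
  L_k <- table(factor(c(from_c, to_c), levels = communities))
  within <- from_c == to_c
  L_k_w <- table(factor(from_c[within], levels = communities))
  data.frame(
    community = communities,
    L_k = as.integer(L_k),
    L_k_w = as.integer(L_k_w),
    stringsAsFactors = FALSE
  )
}

#' Louvain community detection
#'
#' Heuristic modularity maximization via the Louvain two-phase algorithm
#' (local moves, then community aggregation), as implemented in
#' \pkg{igraph}. The run is seeded and therefore deterministic given
#' `(graph, seed, resolution)`.
#'
#' @param g A `town_network` with at least one edge.
#' @param seed Integer RNG seed controlling the algorithm's randomized visit
#'   order.
#' @param resolution Resolution parameter of the modularity objective
#'   (default 1, the classical objective).
#' @return Named vector mapping each node of `g` to an integer community
#'   label. Labels are canonicalized to first-appearance order over the sorted
#'   node vector, so identical groupings always yield identical labelings.
#' @export
louvain_partition <- function(g, seed = 1L, resolution = 1) {
  stopifnot(inherits(g, "town_network"))
  if (n_edges(g) == 0L) stop("Louvain requires at least one edge (L = 0)")
  stopifnot(resolution > 0)
  ig <- as_igraph(g)
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(ig, resolution = resolution)
  memb <- igraph::membership(comm)
  lab <- as.integer(memb[g$nodes])
  canonical <- match(lab, unique(lab))
  stats::setNames(canonical, g$nodes)
}

#' Fragmentation of a town via Louvain
#'
#' Convenience wrapper: detect communities with [louvain_partition()] and
#' return the [modularity_report()].
#'
#' @inheritParams louvain_partition
#' @return A `modularity_report`.
#' @export
town_fragmentation <- function(g, seed = 1L, resolution = 1) {
  modularity_report(g, louvain_partition(g, seed = seed, resolution = resolution))
}
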