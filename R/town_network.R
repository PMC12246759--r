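#' Build a simple undirected town network from raw edge pairs
#'
#' Constructs the canonical graph object used throughout the package: a simple
#' (no self-loops, no multi-edges) undirected graph for one town. Self-loops
#' and duplicate pairs (in either orientation) are silently dropped; the number
#' of dropped records is recorded in the object so data-quality issues remain
#' auditable. Node identifiers are treated as opaque strings -- no integer
#' contiguity is assumed.
#'
#' @param edge_pairs A two-column matrix or data frame of node identifier
#'   pairs, or a list of length-2 vectors. May be empty.
#' @param town_id Identifier for the town (coerced to character).
#' @param nodes Optional vector of additional node identifiers to include even
#'   if they touch no edge (isolated nodes survive, e.g. seeds with no
#'   observed friends).
#' @return An object of class `town_network`: a list with elements
#'   `town_id`, `nodes` (character vector, sorted), `edges` (two-column
#'   character matrix, each row sorted within and rows sorted), `n_dropped_self`
#'   and `n_dropped_dup`.
#' @examples
#' g <- build_graph(rbind(c(1, 2), c(2, 1), c(3, 3)), "demo")
#' n_edges(g)  # 1: the (2,1) duplicate and (3,3) self-loop are dropped
#' @export
build_graph <- function(edge_pairs, town_id = "town", nodes = NULL) {
  if (is.null(edge_pairs) || (is.list(edge_pairs) && !is.data.frame(edge_pairs))) {
    edge_pairs <- do.call(rbind, lapply(edge_pairs, function(p) {
      if (length(p) != 2L) stop("each edge pair must have exactly two endpoints")
      as.character(p)
    }))
  }
  if (is.data.frame(edge_pairs)) edge_pairs <- as.matrix(edge_pairs)
  if (is.null(edge_pairs) || length(edge_pairs) == 0L) {
    edge_pairs <- matrix(character(0), ncol = 2L)
  }
  if (ncol(edge_pairs) != 2L) stop("edge_pairs must have exactly two columns")
  storage.mode(edge_pairs) <- "character"

  self <- edge_pairs[, 1L] == edge_pairs[, 2L]
  kept <- edge_pairs[!self, , drop = FALSE]
  a <- pmin(kept[, 1L], kept[, 2L])
  b <- pmax(kept[, 1L], kept[, 2L])
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  edges <- cbind(a[!dup], b[!dup])
  if (nrow(edges) > 1L) edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  colnames(edges) <- c("from", "to")

  all_nodes <- sort(unique(c(as.vector(edge_pairs), as.character(nodes))))

  structure(
    list(
      town_id = as.character(town_id)[1L],
      nodes = all_nodes,
      edges = edges,
      n_dropped_self = sum(self),
      n_dropped_dup = sum(dup)
    ),
    class = "town_network"
  )
}

#' @export
print.town_network <- function(x, ...) {
  cat(sprintf(
    "<town_network '%s': %d nodes, %d edges>\n",
    x$town_id, length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Number of edges / nodes in a town network
#' @param g A `town_network`.
#' @return Integer count.
#' @export
n_edges <- function(g) nrow(g$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(g) length(g$nodes)

#' Node degrees of a town network
#' @param g A `town_network`.
#' @return Named integer vector over all nodes (isolated nodes have degree 0).
#' @export
node_degrees <- function(g) {
  d <- table(factor(as.vector(g$edges), levels = g$nodes))
  stats::setNames(as.integer(d), g$nodes)
}

# Convert to an igraph object (internal). Vertex names carry the node ids.
as_igraph <- function(g) {
  stopifnot(inherits(g, "town_network"))
  igraph::graph_from_data_frame(
    as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE)
  )
}

#' Read a town edge list from delimited text
#'
#' One file per town; two columns per line separated by whitespace or commas;
#' lines starting with `#` (and blank lines) are ignored. The filename stem is
#' used as the town id unless overridden.
#'
#' @param path Path to the edge-list file.
#' @param town_id Town identifier; defaults to the filename stem.
#' @return A [build_graph()] `town_network`.
#' @export
read_edge_list <- function(path, town_id = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  if (is.null(town_id)) town_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(build_graph(NULL, town_id))
  parts <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "malformed edge-list line %d in '%s': expected two columns, got %d",
      idx[bad[1L]], path, length(parts[[bad[1L]]])
    ))
  }
  build_graph(do.call(rbind, parts), town_id)
}

#' Write a town edge list as two-column delimited text
#'
#' Round-trip safe with [read_edge_list()]: writing and re-reading reproduces
#' the canonicalized edge set.
#'
#' @param g A `town_network`.
#' @param path Output path.
#' @param sep Column separator (default comma).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, sep = ",") {
  stopifnot(inherits(g, "town_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# town_id: %s", g$town_id), con)
  if (nrow(g$edges) > 0L) {
    writeLines(paste(g$edges[, 1L], g$edges[, 2L], sep = sep), con)
  }
  invisible(path)
}

#' Write a partition as a `node,community` CSV
#'
#' @param partition Named vector mapping node id to community label.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(
    data.frame(
      node = names(partition),
      community = unname(partition),
      stringsAsFactors = FALSE
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}
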