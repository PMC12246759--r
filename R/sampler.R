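#' Seed-account selection criteria
#'
#' Mirrors the stratified crawl design: candidate accounts are grouped into
#' age-by-gender strata and must have enough same-town friends to plausibly
#' live in the town, but not so many total friends that they are likely
#' public pages or bots.
#'
#' @param n_age_groups Number of age strata spanning `age_range` (default 3).
#' @param age_range Two-element inclusive age span (default 18--65).
#' @param min_same_town_friends Minimum same-town degree (default 100).
#' @param max_total_friends Maximum total degree (default 500).
#' @param n_rounds Number of selection rounds; each round draws at most one
#'   fresh account per stratum (default 3, so at most
#'   `n_age_groups * 2 * n_rounds = 18` seeds).
#' @return A list of class `seed_criteria`.
#' @export
seed_criteria <- function(n_age_groups = 3L,
                          age_range = c(18L, 65L),
                          min_same_town_friends = 100L,
                          max_total_friends = 500L,
                          n_rounds = 3L) {
  stopifnot(
    n_age_groups >= 1L, n_rounds >= 1L,
    length(age_range) == 2L, age_range[1L] < age_range[2L],
    min_same_town_friends <= max_total_friends
  )
  structure(
    list(
      n_age_groups = as.integer(n_age_groups),
      age_range = as.integer(age_range),
      min_same_town_friends = as.integer(min_same_town_friends),
      max_total_friends = as.integer(max_total_friends),
      n_rounds = as.integer(n_rounds)
    ),
    class = "seed_criteria"
  )
}

# Equal-span age-group index within the criteria range; NA outside the range.
age_stratum <- function(age, criteria) {
  lo <- criteria$age_range[1L]
  hi <- criteria$age_range[2L]
  idx <- findInterval(
    age,
    seq(lo, hi + 1L, length.out = criteria$n_age_groups + 1L),
    rightmost.closed = TRUE
  )
  idx[age < lo | age > hi] <- NA_integer_
  idx
}

#' Select stratified seed accounts from a roster
#'
#' For each age-group-by-gender stratum and each round, one uniformly random
#' eligible account not yet chosen is selected. Eligibility: at least
#' `min_same_town_friends` same-town friends, at most `max_total_friends`
#' total friends, age inside the criteria range. Strata that run out of fresh
#' candidates simply yield fewer seeds -- never an error.
#'
#' @param roster Data frame with columns `node`, `age`, `gender`,
#'   `same_town_degree`, `total_degree` (see [generate_roster()]).
#' @param criteria A [seed_criteria()] object.
#' @param rng_seed Integer seed for reproducible draws.
#' @return Character vector of selected node ids (possibly empty), at most
#'   `n_age_groups * 2 * n_rounds` long.
#' @export
select_seed_accounts <- function(roster, criteria = seed_criteria(), rng_seed = 1L) {
  stopifnot(is.data.frame(roster), nrow(roster) >= 1L)
  needed <- c("node", "age", "gender", "same_town_degree", "total_degree")
  if (!all(needed %in% names(roster))) {
    stop("roster must have columns: ", paste(needed, collapse = ", "))
  }
  eligible <- roster$same_town_degree >= criteria$min_same_town_friends &
    roster$total_degree <= criteria$max_total_friends
  stratum <- age_stratum(roster$age, criteria)
  eligible <- eligible & !is.na(stratum)

  genders <- sort(unique(as.character(roster$gender)))
  set.seed(as.integer(rng_seed))
  chosen <- character(0)
  for (round in seq_len(criteria$n_rounds)) {
    for (a in seq_len(criteria$n_age_groups)) {
      for (gender in genders) {
        pool <- which(
          eligible & stratum == a & roster$gender == gender &
            !(as.character(roster$node) %in% chosen)
        )
        if (length(pool) > 0L) {
          pick <- pool[sample.int(length(pool), 1L)]
          chosen <- c(chosen, as.character(roster$node[pick]))
        }
      }
    }
  }
  chosen
}

#' Breadth-first ego-network sample
#'
#' Emulates friend-list crawling from one seed account: all nodes within
#' `depth` hops are sampled, and an edge is observed when at least one of its
#' endpoints lies strictly inside the frontier (distance `< depth`), because
#' only those nodes' adjacency lists are fetched. Edges between two nodes both
#' exactly at the frontier are therefore invisible and excluded.
#'
#' @param g Full `town_network`.
#' @param seed_node Node id to start from; must exist in `g`.
#' @param depth Number of hops (default 2: friends and friends-of-friends).
#' @return A list of class `ego_sample`: `seed`, `depth`, `nodes` (character
#'   vector) and `edges` (two-column character matrix).
#' @export
bfs_ego_sample <- function(g, seed_node, depth = 2L) {
  stopifnot(inherits(g, "town_network"), depth >= 0L)
  seed_node <- as.character(seed_node)
  if (!seed_node %in% g$nodes) stop("unknown seed node: ", seed_node)
  if (depth == 0L || n_edges(g) == 0L) {
    return(structure(
      list(
        seed = seed_node, depth = as.integer(depth),
        nodes = seed_node, edges = matrix(character(0), ncol = 2L)
      ),
      class = "ego_sample"
    ))
  }
  ig <- as_igraph(g)
  dist <- as.vector(igraph::distances(ig, v = seed_node))
  names(dist) <- igraph::V(ig)$name
  inside <- names(dist)[dist <= depth]
  d_from <- dist[g$edges[, 1L]]
  d_to <- dist[g$edges[, 2L]]
  keep <- pmax(d_from, d_to) <= depth & pmin(d_from, d_to) < depth
  structure(
    list(
      seed = seed_node,
      depth = as.integer(depth),
      nodes = sort(inside),
      edges = g$edges[keep, , drop = FALSE]
    ),
    class = "ego_sample"
  )
}

#' @export
print.ego_sample <- function(x, ...) {
  cat(sprintf(
    "<ego_sample seed '%s', depth %d: %d nodes, %d edges>\n",
    x$seed, x$depth, length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Merge ego samples into one observed town network
#'
#' Union of node sets and edge sets, deduplicated. Monotone: adding a sample
#' never shrinks the result.
#'
#' @param samples List of [bfs_ego_sample()] results (at least one).
#' @param town_id Town identifier for the merged network.
#' @return A `town_network`.
#' @export
merge_samples <- function(samples, town_id = "merged") {
  stopifnot(length(samples) >= 1L)
  edges <- do.call(rbind, lapply(samples, `[[`, "edges"))
  nodes <- unique(unlist(lapply(samples, `[[`, "nodes"), use.names = FALSE))
  build_graph(edges, town_id = town_id, nodes = nodes)
}

#' Crawl a town: select seeds, BFS-sample each, merge
#'
#' Convenience composition of [select_seed_accounts()], [bfs_ego_sample()] and
#' [merge_samples()] used by the pipeline and the sampling-fidelity analyses.
#'
#' @param g Full `town_network`.
#' @param roster Account roster for `g` (see [generate_roster()]).
#' @param criteria A [seed_criteria()].
#' @param depth BFS depth (default 2).
#' @param rng_seed Seed for the stratified selection.
#' @param max_seeds Optional cap on how many of the selected seeds are used
#'   (in selection order); `NULL` uses all.
#' @return List with `network` (merged `town_network`), `seeds` and
#'   `n_seeds`.
#' @export
sample_town <- function(g, roster, criteria = seed_criteria(), depth = 2L,
                        rng_seed = 1L, max_seeds = NULL) {
  seeds <- select_seed_accounts(roster, criteria, rng_seed = rng_seed)
  if (!is.null(max_seeds)) seeds <- utils::head(seeds, max_seeds)
  if (length(seeds) == 0L) {
    return(list(network = build_graph(NULL, g$town_id), seeds = character(0), n_seeds = 0L))
  }
  samples <- lapply(seeds, function(s) bfs_ego_sample(g, s, depth = depth))
  list(
    network = merge_samples(samples, town_id = g$town_id),
    seeds = seeds,
    n_seeds = length(seeds)
  )
}

#' Node and edge coverage bounds of a sampled network
#'
#' Coverage of the crawl relative to two reference populations: all citizens
#' of the town (lower bounds) and the platform's user base in that town (upper
#' bounds). Edge denominators take the expected number of ties as
#' `population * avg_degree / 2`; the platform-restricted denominator is
#' additionally scaled by the user share and the average share of a user's
#' friends living in the same town.
#'
#' @param n_nodes_sampled Number of distinct nodes in the merged sample.
#' @param n_edges_sampled Number of distinct edges in the merged sample.
#' @param population Town population (persons), > 0.
#' @param user_share Share of the population on the platform, in (0, 1].
#' @param avg_degree Assumed average number of social ties per person
#'   (default 100, of the order of the Dunbar number).
#' @param same_town_share Average share of a user's friends from the same
#'   town, in (0, 1].
#' @return A list of class `coverage_report` with fractions `node_lower`,
#'   `node_upper`, `edge_lower`, `edge_upper`, and the audit fields
#'   `node_lower_den`, `node_upper_den`, `edge_lower_den`, `edge_upper_den`.
#' @examples
#' cb <- coverage_bounds(88750, 688859, population = 435663,
#'                       user_share = 0.6261, same_town_share = 0.3972)
#' round(100 * cb$node_lower, 2)  # 20.37
#' @export
coverage_bounds <- function(n_nodes_sampled, n_edges_sampled, population,
                            user_share, avg_degree = 100, same_town_share = 1) {
  stopifnot(
    n_nodes_sampled >= 0, n_edges_sampled >= 0,
    population > 0, user_share > 0, user_share <= 1,
    avg_degree > 0, same_town_share > 0, same_town_share <= 1
  )
  node_lower_den <- population
  node_upper_den <- population * user_share
  edge_lower_den <- population * avg_degree / 2
  edge_upper_den <- edge_lower_den * user_share * same_town_share
  if (any(c(node_upper_den, edge_lower_den, edge_upper_den) <= 0)) {
    stop("coverage denominator is zero; check population/user_share/avg_degree")
  }
  structure(
    list(
      node_lower = n_nodes_sampled / node_lower_den,
      node_upper = n_nodes_sampled / node_upper_den,
      edge_lower = n_edges_sampled / edge_lower_den,
      edge_upper = n_edges_sampled / edge_upper_den,
      node_lower_den = node_lower_den,
      node_upper_den = node_upper_den,
      edge_lower_den = edge_lower_den,
      edge_upper_den = edge_upper_den
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "<coverage_report: nodes %.2f%%-%.2f%%, edges %.2f%%-%.2f%%>\n",
    100 * x$node_lower, 100 * x$node_upper, 100 * x$edge_lower, 100 * x$edge_upper
  ))
  invisible(x)
}
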