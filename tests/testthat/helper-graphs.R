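# Graph fixtures and independent oracles shared across test files.

two_triangles <- function() {
  build_graph(rbind(
    c("a", "b"), c("b", "c"), c("a", "c"),
    c("d", "e"), c("e", "f"), c("d", "f")
  ), town_id = "two_tri")
}

triangle_partition <- function() {
  setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "d", "e", "f"))
}

bridged_triangles <- function() {
  build_graph(rbind(
    c("a", "b"), c("b", "c"), c("a", "c"),
    c("d", "e"), c("e", "f"), c("d", "f"),
    c("c", "d")
  ), town_id = "bridged")
}

# `k` complete cliques of size `m`, consecutive cliques joined by one bridge
# edge, closing into a ring.
ring_of_cliques <- function(k = 4L, m = 4L) {
  edges <- NULL
  for (c_idx in seq_len(k)) {
    ids <- sprintf("c%d_%d", c_idx, seq_len(m))
    edges <- rbind(edges, t(combn(ids, 2L)))
  }
  for (c_idx in seq_len(k)) {
    nxt <- if (c_idx == k) 1L else c_idx + 1L
    edges <- rbind(edges, c(sprintf("c%d_1", c_idx), sprintf("c%d_2", nxt)))
  }
  build_graph(edges, town_id = "ring")
}

# All set partitions of n elements into at most kmax blocks, as integer
# label vectors in restricted-growth form.
partitions_up_to_k <- function(n, kmax) {
  out <- list()
  recurse <- function(labels, used) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(min(used + 1L, kmax))) {
      recurse(c(labels, lab), max(used, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Independent modularity oracle: igraph's own edge-counting implementation.
oracle_modularity <- function(g, partition) {
  ig <- igraph::graph_from_data_frame(
    as.data.frame(g$edges), directed = FALSE,
    vertices = data.frame(name = g$nodes)
  )
  igraph::modularity(ig, membership = as.integer(factor(partition[g$nodes])))
}

# Independent Qmax oracle: computed from igraph degrees, not from the
# package's community_edge_counts path.
oracle_qmax <- function(g, partition) {
  ig <- igraph::graph_from_data_frame(
    as.data.frame(g$edges), directed = FALSE,
    vertices = data.frame(name = g$nodes)
  )
  deg <- igraph::degree(ig)
  L <- igraph::ecount(ig)
  lab <- partition[igraph::V(ig)$name]
  1 - sum(tapply(deg, lab, sum)^2) / (2 * L)^2
}

random_town_graph <- function(n, p, seed, town_id = "rnd") {
  set.seed(seed)
  pairs <- t(combn(paste0("v", seq_len(n)), 2L))
  keep <- runif(nrow(pairs)) < p
  build_graph(pairs[keep, , drop = FALSE], town_id = town_id,
              nodes = paste0("v", seq_len(n)))
}

# Minimal valid survey data frame; `enc` and `lik` are 9-column matrices.
make_survey <- function(enc, lik, town_id = "t1") {
  enc <- matrix(enc, ncol = 9L)
  lik <- matrix(lik, ncol = 9L)
  colnames(enc) <- paste0("enc_", 1:9)
  colnames(lik) <- paste0("lik_", 1:9)
  cbind(
    data.frame(
      respondent_id = sprintf("r%03d", seq_len(nrow(enc))),
      town_id = rep_len(town_id, nrow(enc)),
      stringsAsFactors = FALSE
    ),
    as.data.frame(enc), as.data.frame(lik)
  )
}

# Respondent-level design shared by the recovery/calibration simulations:
# outcome columns bound to survey covariates and town covariates.
study_design <- function(study, outcomes = c("share_fake_enc", "share_true_enc")) {
  out <- derive_outcomes(study$survey)
  d <- cbind(
    out[outcomes],
    study$survey[c(
      "town_id", "vk_use", "gender", "education", "income", "age",
      "fear_covid", "hh_covid", "trust_president", "tv_news"
    )]
  )
  merge(d, study$towns, by = "town_id")
}

study_rhs <- paste(
  "~ fragmentation + vk_use + gender + education + income + age +",
  "fear_covid + hh_covid + trust_president + tv_news +",
  "log_wage + log_pop + log_net_size"
)
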