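test_that("seed selection enforces degree bounds and stratified exhaustion", {
  # one eligible account per stratum; an over-connected account is never picked
  strata_age <- c(20, 40, 60)
  roster <- data.frame(
    node = sprintf("s%d", 1:7),
    age = c(rep(strata_age, 2), 25),
    gender = c(rep(c("F", "M"), each = 3), "F"),
    same_town_degree = c(rep(150L, 6), 400L),
    total_degree = c(rep(200L, 6), 600L),
    stringsAsFactors = FALSE
  )
  sel <- select_seed_accounts(roster, seed_criteria(), rng_seed = 1)
  expect_setequal(sel, sprintf("s%d", 1:6))  # 3 rounds find no fresh candidates
  expect_false("s7" %in% sel)                # total_degree 600 > 500

  none <- roster
  none$same_town_degree <- 10L
  expect_length(select_seed_accounts(none, seed_criteria(), rng_seed = 1), 0L)
})

test_that("seed selection is reproducible and respects both bounds at scale", {
  set.seed(31)
  roster <- data.frame(
    node = sprintf("a%04d", 1:2000),
    age = sample(16:70, 2000, replace = TRUE),
    gender = sample(c("F", "M"), 2000, replace = TRUE),
    same_town_degree = rpois(2000, 120),
    total_degree = NA_integer_,
    stringsAsFactors = FALSE
  )
  roster$total_degree <- roster$same_town_degree + rpois(2000, 250)
  s1 <- select_seed_accounts(roster, seed_criteria(), rng_seed = 9)
  s2 <- select_seed_accounts(roster, seed_criteria(), rng_seed = 9)
  expect_identical(s1, s2)
  expect_lte(length(s1), 18L)
  picked <- roster[roster$node %in% s1, ]
  expect_true(all(picked$same_town_degree >= 100L))
  expect_true(all(picked$total_degree <= 500L))
  expect_true(all(picked$age >= 18L & picked$age <= 65L))
})

test_that("BFS ego sample matches hop-count definitions", {
  path <- build_graph(cbind(1:4, 2:5))
  s <- bfs_ego_sample(path, "1", depth = 2)
  expect_setequal(s$nodes, c("1", "2", "3"))
  expect_equal(nrow(s$edges), 2L)

  s0 <- bfs_ego_sample(path, "3", depth = 0)
  expect_identical(s0$nodes, "3")
  expect_equal(nrow(s0$edges), 0L)

  expect_error(bfs_ego_sample(path, "99", 2), "unknown seed")
})

test_that("BFS ball equals all-pairs shortest-path oracle; deep BFS is exhaustive", {
  for (seed in 1:4) {
    g <- random_town_graph(50, 0.08, 900 + seed)
    ig <- igraph::graph_from_data_frame(
      as.data.frame(g$edges), directed = FALSE,
      vertices = data.frame(name = g$nodes)
    )
    dist <- igraph::distances(ig, v = "v1")[1, ]
    for (depth in 1:2) {
      s <- bfs_ego_sample(g, "v1", depth)
      expect_setequal(s$nodes, names(dist)[dist <= depth])
    }
    if (all(is.finite(dist))) {
      s_all <- bfs_ego_sample(g, "v1", depth = max(dist) + 1)
      expect_setequal(s_all$nodes, g$nodes)
      expect_equal(nrow(s_all$edges), n_edges(g))
    }
  }
})

test_that("frontier-frontier edges are invisible to the crawl", {
  # triangle hanging off a center: b and c are both at the frontier (depth 1
  # from a); their mutual edge is seen from a's adjacency only at depth >= 2
  g <- build_graph(rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  s1 <- bfs_ego_sample(g, "a", depth = 1)
  expect_setequal(s1$nodes, c("a", "b", "c"))
  got <- apply(s1$edges, 1L, paste, collapse = "-")
  expect_setequal(got, c("a-b", "a-c"))  # b-c excluded: both endpoints at depth 1
  s2 <- bfs_ego_sample(g, "a", depth = 2)
  expect_equal(nrow(s2$edges), 3L)
})

test_that("merging ego samples is an idempotent, monotone union", {
  g <- random_town_graph(40, 0.1, 77)
  s <- bfs_ego_sample(g, "v1", 2)
  m_twice <- merge_samples(list(s, s))
  expect_setequal(m_twice$nodes, s$nodes)
  expect_equal(n_edges(m_twice), nrow(s$edges))

  a <- list(seed = "x1", depth = 1L, nodes = c("x1", "x2", "x3", "x4"),
            edges = rbind(c("x1", "x2"), c("x1", "x3"), c("x1", "x4")))
  b <- list(seed = "y1", depth = 1L, nodes = paste0("y", 1:5),
            edges = cbind(rep("y1", 4), paste0("y", 2:5)))
  expect_equal(n_edges(merge_samples(list(a, b))), 7L)

  seeds <- intersect(paste0("v", 1:12), g$nodes)
  acc <- list()
  prev_edges <- -1L
  for (sd in seeds) {
    acc <- c(acc, list(bfs_ego_sample(g, sd, 2)))
    m <- merge_samples(acc)
    expect_gte(n_edges(m), prev_edges)
    prev_edges <- n_edges(m)
  }
})

test_that("edge gain per extra ego sample diminishes on a synthetic town", {
  gen <- generate_sbm_town(sbm_config(rep(60L, 4L), 0.6, 0.02), rng_seed = 3)
  crit <- seed_criteria(min_same_town_friends = 30)
  roster <- generate_roster(gen$network, rng_seed = 4, criteria = crit)
  seeds <- select_seed_accounts(roster, crit, rng_seed = 5)
  expect_gte(length(seeds), 12L)
  samples <- lapply(seeds, function(s) bfs_ego_sample(gen$network, s, 2))
  counts <- vapply(seq_along(samples), function(k) {
    n_edges(merge_samples(samples[seq_len(k)]))
  }, numeric(1))
  gains <- diff(counts)
  half <- floor(length(gains) / 2)
  expect_gt(mean(gains[seq_len(half)]), mean(gains[-seq_len(half)]))
})

test_that("BFS oversamples high-degree nodes", {
  for (seed in 1:5) {
    gen <- generate_sbm_town(sbm_config(rep(40L, 4L), 0.25, 0.02),
                             rng_seed = 400 + seed)
    g <- gen$network
    deg <- node_degrees(g)
    seed_node <- names(deg)[deg > 0][1L]
    s <- bfs_ego_sample(g, seed_node, 1)
    expect_gte(mean(deg[s$nodes]), mean(deg))
  }
})

test_that("coverage bounds follow their definitions and guard degenerate input", {
  cb <- coverage_bounds(0, 0, population = 1000, user_share = 0.5)
  expect_equal(cb$node_lower, 0)
  expect_equal(cb$edge_upper, 0)

  cb2 <- coverage_bounds(300, 5000, population = 1000, user_share = 0.5,
                         avg_degree = 100, same_town_share = 0.4)
  expect_equal(cb2$node_lower, 0.3)
  expect_equal(cb2$node_upper, 0.6)
  expect_equal(cb2$edge_lower, 5000 / 50000)
  expect_equal(cb2$edge_upper, 5000 / (50000 * 0.5 * 0.4))
  expect_lte(cb2$node_lower, cb2$node_upper)

  expect_error(coverage_bounds(1, 1, population = 0, user_share = 0.5))
  expect_error(coverage_bounds(1, 1, population = 10, user_share = 0))
})
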