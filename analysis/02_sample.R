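# 02: crawl each town the way the platform study did.
#
# Stratified seed-account selection (age x gender strata, friend-count
# bounds), breadth-first sampling to depth 2 from each seed, merging, and
# node/edge coverage bounds against the town's citizen population and its
# platform users.

source("analysis/00_config.R")

sampled_dir <- file.path(STUDY_DIR, "sampled_edges")
dir.create(sampled_dir, showWarnings = FALSE)

rows <- list()
for (i in seq_len(N_TOWNS)) {
  tid <- TOWN_IDS[i]
  g <- read_edge_list(file.path(STUDY_DIR, "edges", paste0(tid, ".csv")), tid)
  roster <- read.csv(file.path(STUDY_DIR, "rosters", paste0(tid, ".csv")),
                     colClasses = c(node = "character"))
  crawl <- sample_town(g, roster, criteria = CRITERIA, depth = BFS_DEPTH,
                       rng_seed = stage_seed(STUDY_SEED, 20L, i))
  write_edge_list(crawl$network, file.path(sampled_dir, paste0(tid, ".csv")))
  cb <- coverage_bounds(
    n_nodes(crawl$network), n_edges(crawl$network),
    population = n_nodes(g) * POPULATION_SCALE,
    user_share = USER_SHARE, avg_degree = AVG_DEGREE,
    same_town_share = SAME_TOWN_SHARE
  )
  rows[[i]] <- data.frame(
    town_id = tid, n_seeds = crawl$n_seeds,
    n_nodes_sampled = n_nodes(crawl$network),
    n_edges_sampled = n_edges(crawl$network),
    node_lower = cb$node_lower, node_upper = cb$node_upper,
    edge_lower = cb$edge_lower, edge_upper = cb$edge_upper
  )
}
coverage <- do.call(rbind, rows)
write.csv(coverage, file.path(STUDY_DIR, "coverage.csv"), row.names = FALSE)

cat(sprintf(
  "crawled %d towns with %d-%d seeds; edge coverage (upper bound) %.1f%%-%.1f%%, mean %.1f%%\n",
  N_TOWNS, min(coverage$n_seeds), max(coverage$n_seeds),
  100 * min(coverage$edge_upper), 100 * max(coverage$edge_upper),
  100 * mean(coverage$edge_upper)
))
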