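# 01: generate the synthetic towns.
#
# Each town is a planted-partition graph; the between-community mixing
# probability increases across towns so the study spans a wide range of
# fragmentation. Every town also gets an account roster (ages, genders,
# friend counts) feeding the crawl stage, and town-level covariates.

source("analysis/00_config.R")

edges_dir <- file.path(STUDY_DIR, "edges")
rosters_dir <- file.path(STUDY_DIR, "rosters")
dir.create(edges_dir, showWarnings = FALSE)
dir.create(rosters_dir, showWarnings = FALSE)

summary_rows <- list()
for (i in seq_len(N_TOWNS)) {
  cfg <- sbm_config(BLOCK_SIZES_BY_TOWN[[i]], P_IN, P_OUT_GRID[i], town_id = TOWN_IDS[i])
  gen <- generate_sbm_town(cfg, rng_seed = stage_seed(STUDY_SEED, 10L, i))
  roster <- generate_roster(gen$network,
    rng_seed = stage_seed(STUDY_SEED, 11L, i), criteria = CRITERIA
  )
  write_edge_list(gen$network, file.path(edges_dir, paste0(TOWN_IDS[i], ".csv")))
  write.csv(roster, file.path(rosters_dir, paste0(TOWN_IDS[i], ".csv")),
            row.names = FALSE)
  summary_rows[[i]] <- data.frame(
    town_id = TOWN_IDS[i], p_out = P_OUT_GRID[i],
    n_nodes = n_nodes(gen$network), n_edges = n_edges(gen$network),
    n_eligible = sum(roster$same_town_degree >= CRITERIA$min_same_town_friends &
                       roster$total_degree <= CRITERIA$max_total_friends)
  )
}
towns <- do.call(rbind, summary_rows)
covars <- generate_town_covariates(TOWN_IDS, rng_seed = stage_seed(STUDY_SEED, 12L))
write.csv(merge(towns, covars, by = "town_id"),
          file.path(STUDY_DIR, "towns.csv"), row.names = FALSE)

cat(sprintf(
  "simulated %d towns (%d-%d nodes), edge counts %d-%d, seed-eligible accounts per town %d-%d\n",
  N_TOWNS, min(towns$n_nodes), max(towns$n_nodes), min(towns$n_edges),
  max(towns$n_edges), min(towns$n_eligible), max(towns$n_eligible)
))
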