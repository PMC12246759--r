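# fragnet

Tools for studying how the fragmentation of town-level online social
networks relates to individual exposure to, and beliefs about, true and
fake health-related statements — the "infodemic" question of whether
community-structured friendship graphs amplify misinformation spread.

The package is aimed at computational social scientists and
infodemiology/health-communication researchers who combine crawled social
graphs with survey microdata, and at anyone needing a tested implementation
of a size-adjusted modularity index with its surrounding survey/regression
machinery.

## What it computes

For an undirected simple graph with *L* edges partitioned into communities
*k*, with *L<sub>k</sub><sup>w</sup>* within-community edges and
*L<sub>k</sub>* degree endpoints adjacent to community *k*:

* **Modularity** Q = Σ<sub>k</sub> [ L<sub>k</sub><sup>w</sup>/L −
  (L<sub>k</sub>/2L)² ] (Newman–Girvan, configuration-model null);
* **Theoretical maximum** Q<sub>max</sub> = 1 − Σ<sub>k</sub>
  (L<sub>k</sub>/2L)², the value if every edge were internal with community
  degree totals fixed;
* **Fragmentation index** F = Q/Q<sub>max</sub> ≤ 1, a size-adjusted
  modularity comparable across towns, with F = 1 exactly when no edge
  crosses a community boundary. Partitions come from seeded Louvain
  community detection.

Around the index, the package implements the full study chain:

* stratified seed-account selection, breadth-first ego sampling to depth 2
  (with crawl-realistic frontier-edge visibility) and node/edge coverage
  bounds (`select_seed_accounts()`, `bfs_ego_sample()`, `merge_samples()`,
  `coverage_bounds()`);
* the eight survey-derived outcomes: encounter shares, −2..+2 recoded
  attitude sums, agreement shares, the fake-minus-true attitude difference,
  and the misinformation error score (`recode_attitude()`,
  `derive_outcomes()`, `filter_towns()`);
* OLS with town-clustered CR1 robust standard errors, worked-example effect
  contrasts, a paired one-tailed stability t-test and an edge-coverage
  robustness subset (`fit_ols_cluster()`, `predicted_contrast()`,
  `paired_t_one_tailed()`, `robustness_subset()`);
* a synthetic-study generator — planted-partition town graphs, account
  rosters, and respondent surveys that follow a linear-probability encounter
  model and ordered-logit attitudes with known effect sizes
  (`generate_sbm_town()`, `generate_roster()`, `generate_respondents()`,
  `simulate_study()`), plus an end-to-end pipeline (`run_pipeline()`).

## Worked example

```r
library(fragnet)

# two triangles joined by one bridge edge
g <- build_graph(rbind(
  c("a","b"), c("b","c"), c("a","c"),
  c("d","e"), c("e","f"), c("d","f"), c("c","d")
), town_id = "demo")
p <- louvain_partition(g, seed = 1)
modularity_report(g, p)
#> <modularity_report 'demo': Q = 0.3571, Q_max = 0.5000, F = 0.7143, 2 communities>
```

Q = 5/14: each triangle holds 3 of the 7 edges and half the degree
endpoints. Q<sub>max</sub> = 1/2, so F = 5/7 — the bridge edge costs the
partition 2/7 of its attainable modularity. With the bridge removed F would
be exactly 1.

A six-town synthetic study, crawled, surveyed and fitted in one call:

```r
res <- run_pipeline(study_config(out_dir = "pipeline_out", seed = 5))
res$fragmentation[, c("town_id", "p_out", "F_full", "F_sampled")]
#>   town_id p_out    F_full F_sampled
#> 1 town001 0.005 0.9476657 0.9468060
#> 2 town002 0.020 0.7994257 0.7964567
#> 3 town003 0.035 0.7033949 0.7027419
#> 4 town004 0.050 0.6266038 0.6258230
#> 5 town005 0.065 0.5329126 0.5324341
#> 6 town006 0.080 0.4819107 0.4819107
```

Fragmentation falls as between-community mixing (`p_out`) rises, and the
18-seed crawl (`F_sampled`) tracks the full-graph index closely. The
`analysis/` directory holds the full 166-town workflow as numbered scripts
(`01_simulate.R` … `06_report.R`, run in order from the repository root);
its regression stage prints, for each outcome, the fragmentation
coefficient with its town-clustered SE — e.g. on the default seeded run the
fake-encounter share model recovers `beta_frag = 0.0563 (SE 0.0101)`
against a generating slope of 0.057, with all eight fitted signs matching
the generating configuration.

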