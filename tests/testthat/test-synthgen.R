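test_that("SBM generation is deterministic and respects planted structure", {
  cfg <- sbm_config(rep(25L, 4L), p_in = 0.5, p_out = 0.02)
  g1 <- generate_sbm_town(cfg, rng_seed = 8)
  g2 <- generate_sbm_town(cfg, rng_seed = 8)
  expect_identical(g1$network$edges, g2$network$edges)
  expect_equal(n_nodes(g1$network), 100L)
  expect_equal(sort(unique(unname(g1$partition))), 1:4)

  # no between-community edges -> all Louvain communities are edge-disjoint
  g0 <- generate_sbm_town(sbm_config(rep(20L, 3L), 0.5, 0), rng_seed = 2)
  p <- louvain_partition(g0$network, seed = 1)
  expect_equal(fragmentation_index(g0$network, p), 1)

  expect_warning(
    generate_sbm_town(sbm_config(rep(10L, 2L), 0.01, 0.01), rng_seed = 1),
    "mean degree"
  )
})

test_that("without planted structure Louvain F matches an equal-density random graph", {
  f_sbm <- f_er <- numeric(20)
  for (r in 1:20) {
    flat <- generate_sbm_town(sbm_config(rep(25L, 4L), 0.08, 0.08),
                              rng_seed = 300 + r)
    f_sbm[r] <- town_fragmentation(flat$network, seed = r)$F
    er <- generate_sbm_town(sbm_config(100L, 0.08, 0), rng_seed = 600 + r)
    f_er[r] <- town_fragmentation(er$network, seed = r)$F
  }
  expect_gt(t.test(f_sbm, f_er)$p.value, 0.01)
})

test_that("roster reflects graph degrees and covers seed strata when possible", {
  gen <- generate_sbm_town(sbm_config(rep(60L, 4L), 0.6, 0.02), rng_seed = 3)
  crit <- seed_criteria(min_same_town_friends = 30)
  r1 <- generate_roster(gen$network, rng_seed = 11, criteria = crit)
  r2 <- generate_roster(gen$network, rng_seed = 11, criteria = crit)
  expect_identical(r1, r2)
  expect_equal(
    setNames(r1$same_town_degree, r1$node)[gen$network$nodes],
    node_degrees(gen$network)
  )
  expect_true(all(r1$total_degree >= r1$same_town_degree))
  # every age-by-gender stratum has an eligible candidate
  eligible <- r1$same_town_degree >= 30 & r1$total_degree <= 500 &
    r1$age >= 18 & r1$age <= 65
  strat <- paste(findInterval(r1$age, c(18, 34, 50, 66)), r1$gender)
  expect_equal(length(unique(strat[eligible])), 6L)

  sparse <- build_graph(cbind(paste0("u", 1:30), paste0("u", c(2:30, 1))))
  expect_message(generate_roster(sparse, rng_seed = 1), "no seed-eligible")
})

test_that("null effects reproduce the base encounter rates", {
  eff <- effect_config(
    beta_frag_fake_enc = 0, beta_frag_true_enc = 0,
    beta_vk_fake_enc = 0, beta_vk_true_enc = 0,
    gamma_fake = numeric(0), gamma_true = numeric(0)
  )
  sv <- generate_respondents(
    setNames(runif(10, 0.3, 0.8), paste0("t", 1:10)),
    n_per_town = 1000, effects = eff, rng_seed = 21
  )
  for (s in 1:9) {
    base <- if (s <= 5) eff$base_fake[s] else eff$base_true[s - 5]
    rate <- mean(sv[[paste0("enc_", s)]])
    moe <- 4 * sqrt(base * (1 - base) / nrow(sv))  # ~99.99% binomial CI
    expect_lt(abs(rate - base), moe)
  }
})

test_that("fragmentation slope on encounter shares matches the analytic expectation", {
  eff <- effect_config(beta_frag_fake_enc = 0.1)
  frag <- rep(c(0.3, 0.8), each = 25)
  sv <- generate_respondents(
    setNames(frag, paste0("t", 1:50)),
    n_per_town = 200, effects = eff, rng_seed = 5
  )
  out <- derive_outcomes(sv)
  hi <- out$town_id %in% paste0("t", 26:50)
  gap <- mean(out$share_fake_enc[hi]) - mean(out$share_fake_enc[!hi])
  expect_equal(gap, 0.1 * 0.5, tolerance = 0.1)  # ~0.05 +- simulation noise
})

test_that("survey generation is deterministic and internally consistent", {
  frag <- setNames(c(0.35, 0.6), c("a", "b"))
  s1 <- generate_respondents(frag, c(30, 40), rng_seed = 17)
  s2 <- generate_respondents(frag, c(30, 40), rng_seed = 17)
  expect_identical(s1, s2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(s1, f1, row.names = FALSE); write.csv(s2, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))

  lik <- as.matrix(s1[paste0("lik_", 1:9)])
  enc <- as.matrix(s1[paste0("enc_", 1:9)])
  expect_true(all(is.na(lik[enc == 0L])))          # never encountered -> not asked
  expect_true(all(lik[enc == 1L] %in% 0:4))        # asked -> 1-4 or DK

  expect_warning(
    generate_respondents(setNames(5, "t"), 200,
      effects = effect_config(beta_frag_fake_enc = 1), rng_seed = 1
    ),
    "clamped"
  )
})

test_that("simulate_study assembles a coherent study object", {
  st <- simulate_study(n_towns = 12, rng_seed = 3)
  expect_equal(nrow(st$towns), 12L)
  expect_true(all(st$towns$fragmentation >= 0.293 & st$towns$fragmentation <= 0.799))
  counts <- table(st$survey$town_id)
  expect_true(all(counts >= 11 & counts <= 200))
  expect_setequal(unique(st$survey$town_id), st$towns$town_id)
})
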