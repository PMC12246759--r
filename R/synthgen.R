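#' Planted-partition (stochastic block model) configuration
#'
#' @param block_sizes Integer vector of community sizes (each >= 2).
#' @param p_in Within-block edge probability.
#' @param p_out Between-block edge probability (`p_out <= p_in`).
#' @param town_id Identifier for the generated town.
#' @return A list of class `sbm_config`.
#' @export
sbm_config <- function(block_sizes, p_in, p_out, town_id = "sbm") {
  stopifnot(
    length(block_sizes) >= 1L, all(block_sizes >= 2L),
    p_out >= 0, p_in <= 1, p_out <= p_in
  )
  structure(
    list(
      n_blocks = length(block_sizes),
      block_sizes = as.integer(block_sizes),
      p_in = p_in, p_out = p_out,
      town_id = as.character(town_id)
    ),
    class = "sbm_config"
  )
}

#' Generate a community-structured synthetic town graph
#'
#' Draws a stochastic block model: each within-block pair is edged
#' independently with `p_in`, each between-block pair with `p_out`. The
#' planted partition is returned alongside the graph so community-recovery
#' and fragmentation oracles can be checked against ground truth.
#'
#' @param cfg An [sbm_config()].
#' @param rng_seed Integer seed; the same `(cfg, rng_seed)` always yields the
#'   same edge set.
#' @return List with `network` (a `town_network`, node ids `"n1"..."nN"`) and
#'   `partition` (named integer vector, the planted blocks).
#' @export
generate_sbm_town <- function(cfg, rng_seed = 1L) {
  stopifnot(inherits(cfg, "sbm_config"))
  n <- sum(cfg$block_sizes)
  pref <- matrix(cfg$p_out, cfg$n_blocks, cfg$n_blocks)
  diag(pref) <- cfg$p_in
  mean_deg <- (cfg$p_in * (mean(cfg$block_sizes) - 1) +
    cfg$p_out * (n - mean(cfg$block_sizes)))
  if (mean_deg < 1) {
    warning("expected mean degree < 1; the graph will be mostly isolated nodes")
  }
  set.seed(as.integer(rng_seed))
  ig <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = cfg$block_sizes)
  ids <- paste0("n", seq_len(n))
  el <- igraph::as_edgelist(ig, names = FALSE)
  edges <- cbind(ids[el[, 1L]], ids[el[, 2L]])
  g <- build_graph(edges, town_id = cfg$town_id, nodes = ids)
  planted <- stats::setNames(rep(seq_len(cfg$n_blocks), cfg$block_sizes), ids)
  list(network = g, partition = planted)
}

#' Generate a synthetic account roster for a town graph
#'
#' Ages are uniform on 16--70, genders balanced, the same-town degree equals
#' the graph degree, and the total friend count adds non-negative noise for
#' out-of-town friends. When the graph has nodes of degree >= 100 the roster
#' is patched so that every age-by-gender stratum contains at least one
#' seed-eligible account; if the graph has no such node a message records the
#' shortfall.
#'
#' @param g A `town_network`.
#' @param rng_seed Integer seed.
#' @param criteria [seed_criteria()] used to define eligibility when patching
#'   strata coverage.
#' @param out_of_town_lambda Poisson mean of the out-of-town friend count
#'   (default 30).
#' @return Data frame with columns `node`, `age`, `gender`,
#'   `same_town_degree`, `total_degree`.
#' @export
generate_roster <- function(g, rng_seed = 1L, criteria = seed_criteria(),
                            out_of_town_lambda = 30) {
  stopifnot(inherits(g, "town_network"), n_nodes(g) >= 1L)
  set.seed(as.integer(rng_seed))
  n <- n_nodes(g)
  deg <- node_degrees(g)
  roster <- data.frame(
    node = g$nodes,
    age = sample(16:70, n, replace = TRUE),
    gender = sample(c("F", "M"), n, replace = TRUE),
    same_town_degree = unname(deg),
    total_degree = unname(deg) + stats::rpois(n, out_of_town_lambda),
    stringsAsFactors = FALSE
  )
  eligible <- roster$same_town_degree >= criteria$min_same_town_friends &
    roster$total_degree <= criteria$max_total_friends
  if (!any(eligible)) {
    message(
      "roster for town '", g$town_id,
      "': no seed-eligible accounts (max same-town degree ",
      max(roster$same_town_degree), ")"
    )
    return(roster)
  }
  # ensure every stratum has an eligible member where degree allows
  lo <- criteria$age_range[1L]
  hi <- criteria$age_range[2L]
  breaks <- seq(lo, hi + 1L, length.out = criteria$n_age_groups + 1L)
  mids <- as.integer(floor((breaks[-length(breaks)] + breaks[-1L] - 1) / 2))
  claimed <- rep(FALSE, n)
  for (a in seq_len(criteria$n_age_groups)) {
    for (gender in c("F", "M")) {
      have <- eligible & roster$gender == gender &
        !is.na(age_stratum(roster$age, criteria)) &
        age_stratum(roster$age, criteria) == a
      if (any(have)) {
        claimed[which(have)[1L]] <- TRUE
        next
      }
      free <- which(eligible & !claimed)
      if (length(free) == 0L) {
        message("roster for town '", g$town_id, "': stratum (", a, ",", gender,
                ") has no eligible account")
        next
      }
      roster$age[free[1L]] <- mids[a]
      roster$gender[free[1L]] <- gender
      claimed[free[1L]] <- TRUE
    }
  }
  roster
}

#' Effect configuration of the synthetic survey generator
#'
#' Defines the data-generating process for respondent outcomes: a linear
#' probability model per statement for encounters, and an ordered-logit
#' latent shift for attitudes. The fragmentation and platform-use effects
#' enter centered (at `frag_center`, `vk_center`), so the per-statement base
#' probabilities are also the expected pooled encounter rates and the slopes
#' are unchanged. The defaults reproduce the observed study conditions: base
#' encounter rates matching the per-statement "never came across" pattern of
#' the real nine-item battery, fragmentation slopes +0.057 (fake) and -0.068
#' (true) on the encounter shares, platform-use slopes +0.044 and +0.030, a
#' strongly negative fragmentation shift on true-statement attitudes and a
#' weak positive one on fake-statement attitudes.
#'
#' @param beta_frag_fake_enc,beta_frag_true_enc Change in each fake/true
#'   statement's encounter probability per unit of fragmentation.
#' @param beta_vk_fake_enc,beta_vk_true_enc Same for platform use.
#' @param base_fake,base_true Per-statement baseline encounter probabilities
#'   (lengths 5 and 4).
#' @param gamma_fake,gamma_true Named numeric vectors of control-covariate
#'   coefficients on the encounter probability (names must be covariate
#'   columns; covariates enter centered at their generator means).
#' @param attitude_shift_frag_fake,attitude_shift_frag_true Latent
#'   (logit-scale) attitude shift per unit fragmentation.
#' @param attitude_shift_vk_fake,attitude_shift_vk_true Latent attitude shift
#'   for platform users.
#' @param mu_fake,mu_true Latent attitude centers per statement.
#' @param dk_prob Probability that an encountered statement is answered
#'   "difficult to say" (coded 0).
#' @param frag_center,vk_center Centering constants for the two focal
#'   regressors.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(beta_frag_fake_enc = 0.057,
                          beta_frag_true_enc = -0.068,
                          beta_vk_fake_enc = 0.044,
                          beta_vk_true_enc = 0.030,
                          base_fake = c(0.966, 0.337, 0.471, 0.332, 0.222),
                          base_true = c(0.780, 0.488, 0.629, 0.082),
                          gamma_fake = c(tv_news = 0.02, fear_covid = 0.01),
                          gamma_true = c(tv_news = 0.02, education = 0.01),
                          attitude_shift_frag_fake = 0.3,
                          attitude_shift_frag_true = -1.0,
                          attitude_shift_vk_fake = -0.3,
                          attitude_shift_vk_true = 0.1,
                          mu_fake = c(-1.6, -0.3, -0.5, -0.8, -0.6),
                          mu_true = c(1.3, 1.0, 1.0, 0.5),
                          dk_prob = 0.05,
                          frag_center = 0.546,
                          vk_center = 0.617) {
  stopifnot(
    length(base_fake) == 5L, length(base_true) == 4L,
    length(mu_fake) == 5L, length(mu_true) == 4L,
    dk_prob >= 0, dk_prob < 1
  )
  structure(
    list(
      beta_frag_fake_enc = beta_frag_fake_enc,
      beta_frag_true_enc = beta_frag_true_enc,
      beta_vk_fake_enc = beta_vk_fake_enc,
      beta_vk_true_enc = beta_vk_true_enc,
      base_fake = base_fake, base_true = base_true,
      gamma_fake = gamma_fake, gamma_true = gamma_true,
      attitude_shift_frag_fake = attitude_shift_frag_fake,
      attitude_shift_frag_true = attitude_shift_frag_true,
      attitude_shift_vk_fake = attitude_shift_vk_fake,
      attitude_shift_vk_true = attitude_shift_vk_true,
      mu_fake = mu_fake, mu_true = mu_true,
      dk_prob = dk_prob,
      frag_center = frag_center, vk_center = vk_center
    ),
    class = "effect_config"
  )
}

# Generator means of the respondent covariates, used to center control terms.
covariate_centers <- c(
  gender = 0.620, education = 4.247, income = 3.403, age = 36.6,
  fear_covid = 2.936, hh_covid = 0.124, trust_president = 3.020,
  tv_news = 0.566
)

# Draw respondent-level control covariates with realistic marginals.
draw_covariates <- function(n) {
  data.frame(
    gender = stats::rbinom(n, 1L, 0.620),
    education = sample(1:5, n, replace = TRUE, prob = c(0.02, 0.05, 0.13, 0.26, 0.54)),
    income = sample(1:5, n, replace = TRUE, prob = c(0.03, 0.07, 0.45, 0.37, 0.08)),
    age = pmin(pmax(round(stats::rnorm(n, 36.6, 9.7)), 18L), 80L),
    fear_covid = sample(1:4, n, replace = TRUE, prob = c(0.08, 0.20, 0.42, 0.30)),
    hh_covid = stats::rbinom(n, 1L, 0.124),
    trust_president = sample(1:5, n, replace = TRUE, prob = c(0.25, 0.15, 0.20, 0.13, 0.27)),
    tv_news = stats::rbinom(n, 1L, 0.566)
  )
}

# Ordered 4-category draw from a logistic latent with mean `latent` and
# fixed cutpoints; returns integers 1..4.
draw_likert <- function(latent) {
  cuts <- c(-1.5, 0, 1.5)
  u <- stats::runif(length(latent))
  p1 <- stats::plogis(cuts[1L] - latent)
  p2 <- stats::plogis(cuts[2L] - latent)
  p3 <- stats::plogis(cuts[3L] - latent)
  1L + (u > p1) + (u > p2) + (u > p3)
}

#' Generate synthetic survey respondents for towns of known fragmentation
#'
#' Per respondent: platform use is Bernoulli; each statement is encountered
#' with probability `clamp(base_s + beta_frag (F - frag_center) + beta_vk (VK
#' - vk_center) + gamma' (x - x_center))`; conditional on encounter, a 4-point
#' Likert answer is drawn from an ordered logit whose latent mean shifts with
#' fragmentation and platform use (or "difficult to say" with probability
#' `dk_prob`, coded 0). Never-encountered statements carry `NA` Likert codes.
#'
#' @param town_frag Named numeric vector: fragmentation index per town id.
#' @param n_per_town Respondent counts, recycled to the number of towns.
#' @param effects An [effect_config()].
#' @param rng_seed Integer seed.
#' @param vk_prob Platform-use probability (default 0.617).
#' @return Data frame with one row per respondent: `respondent_id`,
#'   `town_id`, `vk_use`, the eight control covariates, `enc_1..enc_9`
#'   (binary) and `lik_1..lik_9` (1--4, 0 = "difficult to say", `NA` = not
#'   asked). A warning is raised if more than 5% of encounter probabilities
#'   needed clamping (misconfigured effects).
#' @export
generate_respondents <- function(town_frag, n_per_town, effects = effect_config(),
                                 rng_seed = 1L, vk_prob = 0.617) {
  stopifnot(inherits(effects, "effect_config"), length(town_frag) >= 1L)
  if (is.null(names(town_frag))) {
    names(town_frag) <- paste0("town", seq_along(town_frag))
  }
  n_per_town <- rep_len(as.integer(n_per_town), length(town_frag))
  set.seed(as.integer(rng_seed))

  n <- sum(n_per_town)
  town_id <- rep(names(town_frag), n_per_town)
  frag <- rep(unname(town_frag), n_per_town)
  covars <- draw_covariates(n)
  vk_use <- stats::rbinom(n, 1L, vk_prob)

  frag_c <- frag - effects$frag_center
  vk_c <- vk_use - effects$vk_center
  gamma_term <- function(gamma) {
    if (length(gamma) == 0L) return(rep(0, n))
    out <- rep(0, n)
    for (nm in names(gamma)) {
      out <- out + gamma[[nm]] * (covars[[nm]] - covariate_centers[[nm]])
    }
    out
  }
  ctrl_fake <- gamma_term(effects$gamma_fake)
  ctrl_true <- gamma_term(effects$gamma_true)

  enc <- matrix(NA_integer_, n, N_STATEMENTS)
  lik <- matrix(NA_integer_, n, N_STATEMENTS)
  n_clamped <- 0L
  for (s in seq_len(N_STATEMENTS)) {
    is_fake <- s %in% FAKE_STATEMENTS
    if (is_fake) {
      p <- effects$base_fake[s] +
        effects$beta_frag_fake_enc * frag_c +
        effects$beta_vk_fake_enc * vk_c + ctrl_fake
      latent <- effects$mu_fake[s] +
        effects$attitude_shift_frag_fake * frag_c +
        effects$attitude_shift_vk_fake * vk_c
    } else {
      p <- effects$base_true[s - 5L] +
        effects$beta_frag_true_enc * frag_c +
        effects$beta_vk_true_enc * vk_c + ctrl_true
      latent <- effects$mu_true[s - 5L] +
        effects$attitude_shift_frag_true * frag_c +
        effects$attitude_shift_vk_true * vk_c
    }
    p <- clamp01(p)
    n_clamped <- n_clamped + attr(p, "n_clamped")
    enc[, s] <- stats::rbinom(n, 1L, p)
    asked <- enc[, s] == 1L
    if (any(asked)) {
      ans <- draw_likert(latent[asked])
      dk <- stats::runif(sum(asked)) < effects$dk_prob
      ans[dk] <- 0L
      lik[asked, s] <- ans
    }
  }
  if (n_clamped > 0.05 * n * N_STATEMENTS) {
    warning(sprintf(
      "%.1f%% of encounter probabilities fell outside [0,1] and were clamped; check effect sizes",
      100 * n_clamped / (n * N_STATEMENTS)
    ))
  }

  colnames(enc) <- paste0("enc_", seq_len(N_STATEMENTS))
  colnames(lik) <- paste0("lik_", seq_len(N_STATEMENTS))
  out <- cbind(
    data.frame(
      respondent_id = sprintf("r%06d", seq_len(n)),
      town_id = town_id,
      vk_use = vk_use,
      stringsAsFactors = FALSE
    ),
    covars, as.data.frame(enc), as.data.frame(lik)
  )
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Generate town-level covariates
#'
#' Log wage and log population follow the observed town-level marginals; the
#' log network size tracks log population with noise (larger towns yield
#' larger crawled networks).
#'
#' @param town_ids Character vector of town ids.
#' @param rng_seed Integer seed.
#' @return Data frame `town_id`, `log_wage`, `log_pop`, `log_net_size`.
#' @export
generate_town_covariates <- function(town_ids, rng_seed = 1L) {
  set.seed(as.integer(rng_seed))
  n <- length(town_ids)
  log_pop <- stats::rnorm(n, 13.310, 0.819)
  data.frame(
    town_id = as.character(town_ids),
    log_wage = stats::rnorm(n, 10.743, 0.147),
    log_pop = log_pop,
    log_net_size = log_pop - 1.58 + stats::rnorm(n, 0, 0.25),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic study
#'
#' Draws town fragmentation indices spanning the observed range, town
#' covariates, and a respondent survey following the configured effects --
#' everything the outcome-construction and inference stages need, with known
#' ground truth.
#'
#' @param n_towns Number of towns (default 166).
#' @param n_per_town Respondent counts per town; default draws uniformly on
#'   11--200 (eligibility floor respected).
#' @param frag_range Range the town fragmentation indices span (default the
#'   observed 0.293--0.799).
#' @param effects An [effect_config()].
#' @param rng_seed Integer seed.
#' @return List with `survey` (respondent data frame, see
#'   [generate_respondents()]), `towns` (town covariates plus
#'   `fragmentation`), and `effects`.
#' @export
simulate_study <- function(n_towns = 166L, n_per_town = NULL,
                           frag_range = c(0.293, 0.799),
                           effects = effect_config(), rng_seed = 1L) {
  set.seed(stage_seed(rng_seed, 1L))
  town_ids <- sprintf("town%03d", seq_len(n_towns))
  frag <- stats::runif(n_towns, frag_range[1L], frag_range[2L])
  if (is.null(n_per_town)) n_per_town <- sample(11:200, n_towns, replace = TRUE)
  towns <- generate_town_covariates(town_ids, rng_seed = stage_seed(rng_seed, 2L))
  towns$fragmentation <- frag
  survey <- generate_respondents(
    stats::setNames(frag, town_ids), n_per_town,
    effects = effects, rng_seed = stage_seed(rng_seed, 3L)
  )
  list(survey = survey, towns = towns, effects = effects)
}
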