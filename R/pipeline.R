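#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], optionally
#' overridden by a YAML file and/or by explicitly supplied values. The
#' default describes a small six-town synthetic study that runs end to end in
#' well under a minute.
#'
#' @param yaml_path Optional path to a YAML file whose top-level keys override
#'   the defaults.
#' @param ... Further `name = value` overrides (applied after the YAML).
#' @return Named list of class `study_config`.
#' @export
study_config <- function(yaml_path = NULL, ...) {
  cfg <- list(
    out_dir = "pipeline_out",
    seed = 1L,
    n_towns = 6L,
    block_sizes = c(30L, 30L, 30L, 30L),
    p_in = 0.4,
    p_out_range = c(0.005, 0.08),
    depth = 2L,
    n_rounds = 3L,
    min_same_town_friends = 10L,
    max_total_friends = 500L,
    respondents_range = c(20L, 60L),
    population_scale = 3,
    user_share = 0.4,
    avg_degree = 100,
    same_town_share = 0.4,
    louvain_resolution = 1,
    effects = list(),
    outcomes = c(
      "share_fake_enc", "share_true_enc", "att_true", "att_fake",
      "share_true_agree", "share_fake_agree", "att_diff", "misinfo_error"
    ),
    min_respondents = 10L
  )
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) stop("config file not found: ", yaml_path)
    over <- yaml::read_yaml(yaml_path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = c("study_config", "list"))
}

#' Read a survey CSV written by the pipeline
#'
#' @param path CSV path with the respondent schema of
#'   [generate_respondents()].
#' @return Data frame; Likert columns keep `NA` for never-asked items.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a named list of tables as CSV files
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# Order-dependent checksum of a config, for the manifest.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 12))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%010d", as.integer(h))
}

#' Run the full synthetic study pipeline
#'
#' Orchestrates simulate -> sample -> fragment -> derive -> fit -> report on
#' synthetic towns: planted-partition graphs with between-community mixing
#' spread over `p_out_range` (so towns span a range of fragmentation),
#' account rosters, a stratified BFS crawl of each town, Louvain
#' fragmentation of both the full and the crawled graph, a respondent survey
#' driven by the crawled fragmentation, outcome derivation, and
#' town-clustered regressions of each configured outcome on fragmentation.
#' Every stage writes CSV artifacts under `cfg$out_dir` and the manifest
#' records the config hash and all derived seeds, so identical config + seed
#' reproduces identical outputs.
#'
#' @param cfg A [study_config()].
#' @param resume If `TRUE`, stages whose outputs already exist are skipped.
#' @return Invisibly, a list with the manifest, the fragmentation table, and
#'   the list of fitted models.
#' @export
run_pipeline <- function(cfg = study_config(), resume = FALSE) {
  stopifnot(is.list(cfg))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, done_paths, fn) {
    if (resume && length(done_paths) > 0L && all(file.exists(done_paths))) {
      message("stage '", name, "': outputs exist, skipped")
      return(NULL)
    }
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  criteria <- seed_criteria(
    min_same_town_friends = cfg$min_same_town_friends,
    max_total_friends = cfg$max_total_friends,
    n_rounds = cfg$n_rounds
  )
  town_ids <- sprintf("town%03d", seq_len(cfg$n_towns))
  p_outs <- seq(cfg$p_out_range[1L], cfg$p_out_range[2L], length.out = cfg$n_towns)

  ## simulate: graphs + rosters + town covariates -----------------------------
  edges_dir <- file.path(out, "edges")
  rosters_dir <- file.path(out, "rosters")
  dir.create(edges_dir, showWarnings = FALSE)
  dir.create(rosters_dir, showWarnings = FALSE)
  towns_env <- new.env()
  run_stage("simulate", character(0), function() {
    graphs <- list()
    rosters <- list()
    for (i in seq_len(cfg$n_towns)) {
      scfg <- sbm_config(cfg$block_sizes, cfg$p_in, p_outs[i], town_id = town_ids[i])
      gen <- generate_sbm_town(scfg, rng_seed = stage_seed(cfg$seed, 10L, i))
      graphs[[town_ids[i]]] <- gen$network
      rosters[[town_ids[i]]] <- generate_roster(
        gen$network,
        rng_seed = stage_seed(cfg$seed, 11L, i), criteria = criteria
      )
      write_edge_list(gen$network, file.path(edges_dir, paste0(town_ids[i], ".csv")))
      utils::write.csv(rosters[[town_ids[i]]],
        file.path(rosters_dir, paste0(town_ids[i], ".csv")),
        row.names = FALSE
      )
    }
    towns_env$graphs <- graphs
    towns_env$rosters <- rosters
    towns_env$covariates <- generate_town_covariates(
      town_ids,
      rng_seed = stage_seed(cfg$seed, 12L)
    )
    NULL
  })

  ## sample: stratified BFS crawl per town ------------------------------------
  sampled_dir <- file.path(out, "sampled_edges")
  dir.create(sampled_dir, showWarnings = FALSE)
  run_stage("sample", character(0), function() {
    towns_env$crawls <- lapply(town_ids, function(tid) {
      sample_town(
        towns_env$graphs[[tid]], towns_env$rosters[[tid]],
        criteria = criteria, depth = cfg$depth,
        rng_seed = stage_seed(cfg$seed, 20L, match(tid, town_ids))
      )
    })
    names(towns_env$crawls) <- town_ids
    for (tid in town_ids) {
      write_edge_list(
        towns_env$crawls[[tid]]$network,
        file.path(sampled_dir, paste0(tid, ".csv"))
      )
    }
    NULL
  })

  ## fragment: Louvain F on full and sampled graphs ---------------------------
  run_stage("fragment", character(0), function() {
    rows <- lapply(seq_along(town_ids), function(i) {
      tid <- town_ids[i]
      g_full <- towns_env$graphs[[tid]]
      g_samp <- towns_env$crawls[[tid]]$network
      rep_full <- town_fragmentation(
        g_full,
        seed = stage_seed(cfg$seed, 30L, i), resolution = cfg$louvain_resolution
      )
      rep_samp <- if (n_edges(g_samp) > 0L) {
        town_fragmentation(
          g_samp,
          seed = stage_seed(cfg$seed, 31L, i), resolution = cfg$louvain_resolution
        )
      } else {
        NULL
      }
      population <- n_nodes(g_full) * cfg$population_scale
      cov <- coverage_bounds(
        n_nodes(g_samp), n_edges(g_samp),
        population = population, user_share = cfg$user_share,
        avg_degree = cfg$avg_degree, same_town_share = cfg$same_town_share
      )
      data.frame(
        town_id = tid, p_out = p_outs[i],
        F_full = rep_full$F,
        F_sampled = if (is.null(rep_samp)) NA_real_ else rep_samp$F,
        n_nodes_full = n_nodes(g_full), n_edges_full = n_edges(g_full),
        n_nodes_sampled = n_nodes(g_samp), n_edges_sampled = n_edges(g_samp),
        n_seeds = towns_env$crawls[[tid]]$n_seeds,
        edge_coverage_upper = cov$edge_upper,
        stringsAsFactors = FALSE
      )
    })
    towns_env$fragmentation <- do.call(rbind, rows)
    utils::write.csv(towns_env$fragmentation, file.path(out, "fragmentation.csv"),
      row.names = FALSE
    )
    NULL
  })

  ## derive: survey generation + outcome construction -------------------------
  run_stage("derive", character(0), function() {
    frag <- stats::setNames(towns_env$fragmentation$F_sampled, town_ids)
    if (anyNA(frag)) stop("sampled fragmentation undefined for some towns")
    set.seed(stage_seed(cfg$seed, 40L))
    n_per_town <- sample(
      cfg$respondents_range[1L]:cfg$respondents_range[2L],
      cfg$n_towns,
      replace = TRUE
    )
    effects <- do.call(effect_config, cfg$effects)
    survey <- generate_respondents(frag, n_per_town,
      effects = effects,
      rng_seed = stage_seed(cfg$seed, 41L)
    )
    survey <- filter_towns(survey, cfg$min_respondents)
    outcomes <- derive_outcomes(survey)
    towns_env$survey <- survey
    towns_env$outcomes <- outcomes
    utils::write.csv(survey, file.path(out, "survey.csv"), row.names = FALSE)
    utils::write.csv(towns_env$covariates, file.path(out, "towns.csv"), row.names = FALSE)
    utils::write.csv(outcomes, file.path(out, "outcomes.csv"), row.names = FALSE)
    NULL
  })

  ## fit: town-clustered regressions per outcome ------------------------------
  fits_dir <- file.path(out, "fits")
  dir.create(fits_dir, showWarnings = FALSE)
  run_stage("fit", character(0), function() {
    d <- merge(towns_env$outcomes, towns_env$survey, by = c("respondent_id", "town_id"))
    d <- merge(d, towns_env$covariates, by = "town_id")
    d <- merge(d, towns_env$fragmentation[c("town_id", "F_sampled")], by = "town_id")
    names(d)[names(d) == "F_sampled"] <- "fragmentation"
    rhs <- paste(
      "fragmentation + vk_use + gender + education + income + age +",
      "fear_covid + hh_covid + trust_president + tv_news + log_wage + log_pop"
    )
    towns_env$fits <- lapply(cfg$outcomes, function(outc) {
      fit <- fit_ols_cluster(
        stats::as.formula(paste(outc, "~", rhs)), d,
        cluster = "town_id"
      )
      utils::write.csv(tidy_cluster_ols(fit),
        file.path(fits_dir, paste0(outc, ".csv")),
        row.names = FALSE
      )
      fit
    })
    names(towns_env$fits) <- cfg$outcomes
    NULL
  })

  ## report: manifest ----------------------------------------------------------
  manifest <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    towns = town_ids,
    fragmentation = stats::setNames(
      as.list(towns_env$fragmentation$F_sampled),
      town_ids
    ),
    stage_seeds = list(
      simulate = stage_seed(cfg$seed, 10L, 1L),
      sample = stage_seed(cfg$seed, 20L, 1L),
      fragment = stage_seed(cfg$seed, 30L, 1L),
      derive = stage_seed(cfg$seed, 40L)
    ),
    files = list.files(out, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(
    manifest = manifest,
    fragmentation = towns_env$fragmentation,
    fits = towns_env$fits
  ))
}
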