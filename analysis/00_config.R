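# Shared configuration for the analysis scripts. Each numbered script is a
# thin driver over the fragnet package; state passes between scripts as CSV
# files under results/study/.

library(fragnet)

STUDY_SEED <- 20260928L
STUDY_DIR <- "results/study"

N_TOWNS <- 166L
# four communities per town; towns vary in size so network size is a real
# covariate downstream
BLOCK_SIZES_BY_TOWN <- lapply(seq_len(N_TOWNS), function(i) {
  rep(52L + ((i - 1L) %% 40L) * 2L, 4L)
})
P_IN <- 0.6                       # within-community tie probability
P_OUT_GRID <- seq(0.01, 0.15, length.out = N_TOWNS)  # between-community mixing

CRITERIA <- seed_criteria(min_same_town_friends = 30L)  # crawl eligibility
BFS_DEPTH <- 2L

POPULATION_SCALE <- 20            # citizens per crawled account
USER_SHARE <- 0.4                 # share of citizens on the platform
AVG_DEGREE <- 100                 # assumed ties per citizen
SAME_TOWN_SHARE <- 0.4            # share of a user's friends from the town

RESPONDENTS_RANGE <- c(11L, 200L)
COVERAGE_THRESHOLD <- 0.15        # robustness subset cut on edge coverage

TOWN_IDS <- sprintf("town%02d", seq_len(N_TOWNS))
dir.create(STUDY_DIR, showWarnings = FALSE, recursive = TRUE)
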