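# 04: survey generation and outcome construction.
#
# Respondents are drawn per town with encounter probabilities and attitudes
# driven by the town's *sampled* fragmentation (the quantity a platform
# study can measure). The eight derived outcomes are then constructed:
# encounter shares, attitude sums on the recoded -2..+2 scale, agreement
# shares, the fake-minus-true attitude difference, and the misinformation
# error. Towns with 10 or fewer respondents are dropped.

source("analysis/00_config.R")

frag <- read.csv(file.path(STUDY_DIR, "fragmentation.csv"))
set.seed(stage_seed(STUDY_SEED, 40L))
n_per_town <- sample(RESPONDENTS_RANGE[1L]:RESPONDENTS_RANGE[2L], N_TOWNS,
                     replace = TRUE)

survey <- generate_respondents(
  setNames(frag$F_sampled, frag$town_id), n_per_town,
  effects = effect_config(), rng_seed = stage_seed(STUDY_SEED, 41L)
)
survey <- filter_towns(survey)
outcomes <- derive_outcomes(survey)

write.csv(survey, file.path(STUDY_DIR, "survey.csv"), row.names = FALSE)
write.csv(outcomes, file.path(STUDY_DIR, "outcomes.csv"), row.names = FALSE)

cat(sprintf(
  "generated %d respondents in %d towns; mean fake-encounter share %.3f, mean true %.3f\n",
  nrow(outcomes), length(unique(outcomes$town_id)),
  mean(outcomes$share_fake_enc), mean(outcomes$share_true_enc)
))
cat(sprintf(
  "mean attitude: fake %.2f, true %.2f; mean misinformation error %.3f\n",
  mean(outcomes$att_fake), mean(outcomes$att_true), mean(outcomes$misinfo_error)
))
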