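#' Recode a 4-point Likert reliability answer to the -2..+2 attitude scale
#'
#' The survey asks how reliable a statement is on a 1--4 scale (1 = absolutely
#' not reliable, 4 = absolutely reliable). Attitudes are recoded symmetrically
#' around zero, skipping 0: `1 -> -2, 2 -> -1, 3 -> +1, 4 -> +2`. "Difficult
#' to say" (coded 0) and never-encountered / not-asked (`NA`) both map to 0,
#' which neutralizes skipped items while retaining the respondent.
#'
#' @param likert Integer vector with values in `{1,2,3,4}`, 0 for "difficult
#'   to say", or `NA` for not asked.
#' @return Integer vector with values in `{-2,-1,0,1,2}`.
#' @export
recode_attitude <- function(likert) {
  bad <- !is.na(likert) & !(likert %in% 0:4)
  if (any(bad)) {
    stop("invalid Likert code(s): ", paste(unique(likert[bad]), collapse = ", "),
         " (expected 1-4, 0 = don't know, NA = not asked)")
  }
  map <- c(`0` = 0L, `1` = -2L, `2` = -1L, `3` = 1L, `4` = 2L)
  out <- unname(map[as.character(likert)])
  out[is.na(likert)] <- 0L
  out
}

#' Construct the eight derived outcome variables from survey responses
#'
#' For each respondent: the share of fake (of 5) and true (of 4) statements
#' encountered; attitude sums over the recoded -2..+2 scale (fake in
#' \eqn{[-10, 10]}, true in \eqn{[-8, 8]}); agreement shares (agree = Likert 3
#' or 4, i.e. weak or strong); the attitude difference `att_fake - att_true`
#' (individual-level polarization); and the misinformation error, the share of
#' fake statements agreed with plus the share of true statements disagreed
#' with (disagree = Likert 1 or 2), in \eqn{[0, 2]}.
#'
#' @param survey Data frame with columns `enc_1..enc_9` (binary) and
#'   `lik_1..lik_9` (1--4, 0 = don't know, `NA` = not asked), plus any id
#'   columns, as produced by [generate_respondents()] or [read_survey()].
#' @param drop_dk If `TRUE`, respondents with any "difficult to say" answer
#'   are dropped before derivation; the default retains them with those items
#'   contributing 0 to attitude sums and nothing to agreement.
#' @return Data frame with `respondent_id`/`town_id` (when present) and the
#'   derived columns `share_fake_enc`, `share_true_enc`, `att_fake`,
#'   `att_true`, `share_fake_agree`, `share_true_agree`, `att_diff`,
#'   `misinfo_error`.
#' @export
derive_outcomes <- function(survey, drop_dk = FALSE) {
  enc_cols <- paste0("enc_", seq_len(N_STATEMENTS))
  lik_cols <- paste0("lik_", seq_len(N_STATEMENTS))
  missing_cols <- setdiff(c(enc_cols, lik_cols), names(survey))
  if (length(missing_cols) > 0L) {
    stop("survey is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  enc <- as.matrix(survey[enc_cols])
  lik <- as.matrix(survey[lik_cols])
  if (anyNA(enc) || !all(enc %in% 0:1)) {
    bad <- which(rowSums(is.na(enc) | !(enc == 0L | enc == 1L)) > 0L)[1L]
    stop("malformed encounter flags for respondent ",
         if ("respondent_id" %in% names(survey)) survey$respondent_id[bad] else bad)
  }
  asked_bad <- !is.na(lik) & enc == 0L
  if (any(asked_bad)) {
    bad <- which(rowSums(asked_bad) > 0L)[1L]
    stop("Likert answer present for never-encountered statement (respondent ",
         if ("respondent_id" %in% names(survey)) survey$respondent_id[bad] else bad, ")")
  }
  if (drop_dk) {
    keep <- rowSums(!is.na(lik) & lik == 0L) == 0L
    survey <- survey[keep, , drop = FALSE]
    enc <- enc[keep, , drop = FALSE]
    lik <- lik[keep, , drop = FALSE]
  }

  att <- matrix(
    recode_attitude(as.vector(lik)),
    nrow = nrow(lik), ncol = ncol(lik)
  )
  agree <- !is.na(lik) & lik >= 3L
  disagree <- !is.na(lik) & lik >= 1L & lik <= 2L

  fk <- FAKE_STATEMENTS
  tr <- TRUE_STATEMENTS
  out <- data.frame(
    share_fake_enc = rowSums(enc[, fk, drop = FALSE]) / length(fk),
    share_true_enc = rowSums(enc[, tr, drop = FALSE]) / length(tr),
    att_fake = rowSums(att[, fk, drop = FALSE]),
    att_true = rowSums(att[, tr, drop = FALSE]),
    share_fake_agree = rowSums(agree[, fk, drop = FALSE]) / length(fk),
    share_true_agree = rowSums(agree[, tr, drop = FALSE]) / length(tr)
  )
  out$att_diff <- out$att_fake - out$att_true
  out$misinfo_error <- out$share_fake_agree +
    rowSums(disagree[, tr, drop = FALSE]) / length(tr)

  id_cols <- intersect(c("respondent_id", "town_id"), names(survey))
  cbind(survey[id_cols], out)
}

#' Filter out towns with too few respondents
#'
#' Retains respondents whose town has strictly more than `min_respondents`
#' respondents (default 10, the study eligibility floor). Excluded town ids
#' are reported via `message()` and attached as an attribute.
#'
#' @param responses Data frame with a `town_id` column.
#' @param min_respondents Strict lower bound on town size (default 10).
#' @return The filtered data frame, with attribute `excluded_towns`.
#' @export
filter_towns <- function(responses, min_respondents = 10L) {
  stopifnot("town_id" %in% names(responses))
  counts <- table(responses$town_id)
  excluded <- names(counts)[counts <= min_respondents]
  if (length(excluded) > 0L) {
    message(
      "excluding ", length(excluded), " town(s) with <= ", min_respondents,
      " respondents: ", paste(utils::head(excluded, 10L), collapse = ", "),
      if (length(excluded) > 10L) ", ..." else ""
    )
  }
  out <- responses[!(responses$town_id %in% excluded), , drop = FALSE]
  attr(out, "excluded_towns") <- excluded
  out
}
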