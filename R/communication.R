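#' The five sentiment-and-outlook questions
#'
#' The between-round communication protocol consists of up to five anonymous
#' yes/no questions. Q1 and Q2 appear in every round; Q3 and Q4 from the
#' second round (they need at least one round of history); Q5 from the sixth
#' round (its relevance grows as the end approaches). After all group members
#' answer, only the majority's response per question is displayed.
#'
#' @return A tibble with columns `id`, `text`, `first_round`.
#' @examples
#' crd_questions()
#' @export
crd_questions <- function() {
  tibble(
    id = c("Q1", "Q2", "Q3", "Q4", "Q5"),
    text = c(
      "Do you think that your group will reach the prescribed target?",
      "Are you satisfied with your group's performance in the current round?",
      "Are you satisfied with your group's overall performance so far?",
      "Would you like your group's investment to increase?",
      "Do you think your group could lose everything if it fails to reach the prescribed target?"
    ),
    first_round = c(1L, 1L, 2L, 2L, 6L)
  )
}

#' Questions scheduled for a given round
#'
#' @param round Round number, between 1 and `n_rounds`.
#' @param n_rounds Total rounds in the game (default 10).
#' @return A tibble of scheduled questions (subset of [crd_questions()]),
#'   in Q1..Q5 order.
#' @examples
#' questions_for_round(1)$id  # Q1 Q2
#' questions_for_round(6)$id  # Q1 .. Q5
#' @export
questions_for_round <- function(round, n_rounds = 10) {
  if (length(round) != 1L || is.na(round) || round < 1 || round > n_rounds ||
      round != round(round)) {
    abort(sprintf("`round` must be an integer in 1..%d.", n_rounds))
  }
  q <- crd_questions()
  q[q$first_round <= round, ]
}

#' Majority verdict over one group's answers to one question
#'
#' Groups have an odd number of members precisely so that a strict majority
#' always exists. Answers may contain `NA` (timeouts in human data); these are
#' treated as abstentions and excluded from the count, and a resulting tie is
#' resolved as "no" with a warning.
#'
#' @param answers Logical vector of yes (`TRUE`) / no (`FALSE`) answers, one
#'   per group member.
#' @param allow_even Permit an even number of *valid* answers (used for the
#'   abstention path); an even number of supplied answers is always an error
#'   because the group itself must be odd-sized.
#' @return A one-row tibble: `yes_count`, `n`, `majority_answer`, `tie`.
#' @examples
#' majority(c(TRUE, TRUE, FALSE))$majority_answer  # TRUE
#' @export
majority <- function(answers, allow_even = TRUE) {
  if (!is.logical(answers) || length(answers) == 0L) {
    abort("`answers` must be a non-empty logical vector.")
  }
  if (length(answers) %% 2L == 0L) {
    abort("Groups must have an odd number of members; even-sized votes can tie.")
  }
  valid <- answers[!is.na(answers)]
  if (length(valid) == 0L) {
    abort("All answers are missing; no majority can be formed.")
  }
  yes <- sum(valid)
  n <- length(valid)
  tie <- (2L * yes) == n
  if (tie && !allow_even) {
    abort("Tie among valid answers.")
  }
  if (tie) {
    warn("Tie among valid answers after abstentions; resolved as 'no'.")
  }
  tibble(
    yes_count = yes,
    n = n,
    majority_answer = !tie && yes > n / 2,
    tie = tie
  )
}

#' Majority summaries for a questionnaire table
#'
#' Aggregates a long questionnaire table (one row per player-round-question)
#' into the per-group, per-round, per-question majority verdicts that players
#' actually saw.
#'
#' @param questionnaire A data frame with columns `group_id`, `round`,
#'   `question`, `player_id`, `answer` (0/1 or logical).
#' @return A tibble keyed by `group_id`, `round`, `question` with `yes_count`,
#'   `n`, `majority_answer`.
#' @export
majority_summaries <- function(questionnaire) {
  required <- c("group_id", "round", "question", "player_id", "answer")
  missing <- setdiff(required, names(questionnaire))
  if (length(missing) > 0) {
    abort(paste0("Questionnaire is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  questionnaire |>
    dplyr::group_by(.data$group_id, .data$round, .data$question) |>
    dplyr::summarise(
      yes_count = sum(as.logical(.data$answer), na.rm = TRUE),
      n = sum(!is.na(.data$answer)),
      .groups = "drop"
    ) |>
    dplyr::mutate(majority_answer = .data$yes_count > .data$n / 2)
}

#' Validate a questionnaire table against the round schedule
#'
#' Checks that every stored answer belongs to a question actually scheduled
#' for its round.
#'
#' @param questionnaire Long questionnaire table (see [majority_summaries()]).
#' @param n_rounds Total rounds (default 10).
#' @return Invisibly `TRUE`; errors describing offending rows otherwise.
#' @export
validate_schedule <- function(questionnaire, n_rounds = 10) {
  sched <- crd_questions()
  first <- setNames(sched$first_round, sched$id)
  bad_q <- !questionnaire$question %in% sched$id
  if (any(bad_q)) {
    abort(paste0("Unknown question id(s): ",
                 paste(unique(questionnaire$question[bad_q]), collapse = ", ")))
  }
  off <- questionnaire$round < first[questionnaire$question] |
    questionnaire$round > n_rounds
  if (any(off)) {
    i <- which(off)[1]
    abort(sprintf(
      "Answer to %s recorded in round %d, outside its schedule.",
      questionnaire$question[i], questionnaire$round[i]
    ))
  }
  invisible(TRUE)
}
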