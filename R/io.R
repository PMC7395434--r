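#' Read and validate a gameplay CSV
#'
#' The gameplay schema is long format, one row per player-round: columns
#' `session_id`, `arm`, `group_id`, `group_size`, `round`, `player_id`,
#' `investment`, `capital_after` (UTF-8, comma-separated, header required).
#' Validation enforces the contribution menu, the round range, and the
#' capital accounting `capital_after = endowment - cumsum(investment)` per
#' player, citing the first offending player/round on failure.
#'
#' @param path Path to a CSV file.
#' @param endowment Initial capital per player (default 40).
#' @param n_rounds Rounds per game (default 10).
#' @param choices Allowed investments (default `c(0, 2, 4)`).
#' @return A validated tibble.
#' @export
read_gameplay <- function(path, endowment = 40, n_rounds = 10,
                          choices = c(0, 2, 4)) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  validate_gameplay(dat, endowment = endowment, n_rounds = n_rounds,
                    choices = choices)
  dat
}

#' @rdname read_gameplay
#' @param gameplay A gameplay tibble (validated before writing).
#' @export
write_gameplay <- function(gameplay, path, endowment = 40, n_rounds = 10,
                           choices = c(0, 2, 4)) {
  validate_gameplay(gameplay, endowment = endowment, n_rounds = n_rounds,
                    choices = choices)
  readr::write_csv(gameplay, path)
  invisible(path)
}

#' @rdname read_gameplay
#' @export
validate_gameplay <- function(gameplay, endowment = 40, n_rounds = 10,
                              choices = c(0, 2, 4)) {
  required <- c("session_id", "arm", "group_id", "group_size", "round",
                "player_id", "investment", "capital_after")
  missing <- setdiff(required, names(gameplay))
  if (length(missing) > 0) {
    abort(paste0("Gameplay schema violation; missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_arm <- !gameplay$arm %in% c("control", "treatment")
  if (any(bad_arm)) {
    abort(sprintf("Unknown arm '%s' (row %d).",
                  gameplay$arm[which(bad_arm)[1]], which(bad_arm)[1]))
  }
  bad_inv <- !gameplay$investment %in% choices
  if (any(bad_inv)) {
    i <- which(bad_inv)[1]
    abort(sprintf(
      "Investment %s outside the menu {%s} (player %s, round %d).",
      format(gameplay$investment[i]), paste(choices, collapse = ","),
      gameplay$player_id[i], gameplay$round[i]
    ))
  }
  bad_round <- gameplay$round < 1 | gameplay$round > n_rounds |
    gameplay$round != round(gameplay$round)
  if (any(bad_round)) {
    i <- which(bad_round)[1]
    abort(sprintf("Round %s out of range 1..%d (player %s).",
                  format(gameplay$round[i]), n_rounds, gameplay$player_id[i]))
  }
  acc <- gameplay |>
    dplyr::arrange(.data$player_id, .data$round) |>
    dplyr::group_by(.data$player_id) |>
    dplyr::mutate(expected = endowment - cumsum(.data$investment)) |>
    dplyr::ungroup()
  bad_acc <- acc$capital_after != acc$expected
  if (any(bad_acc)) {
    i <- which(bad_acc)[1]
    abort(sprintf(
      "Capital accounting violated for player %s, round %d: capital_after %s, expected %s.",
      acc$player_id[i], acc$round[i], format(acc$capital_after[i]),
      format(acc$expected[i])
    ))
  }
  invisible(TRUE)
}

#' Read and write questionnaire CSVs
#'
#' Schema: `session_id`, `arm`, `group_id`, `round`, `player_id`,
#' `question` (Q1–Q5), `answer` (0/1). Answers are validated against the
#' question round schedule.
#'
#' @param path Path to a CSV file.
#' @param n_rounds Rounds per game (default 10).
#' @return A validated tibble with a logical `answer` column.
#' @export
read_questionnaire <- function(path, n_rounds = 10) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("session_id", "arm", "group_id", "round", "player_id",
                "question", "answer")
  missing <- setdiff(required, names(dat))
  if (length(missing) > 0) {
    abort(paste0("Questionnaire schema violation; missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dat$answer <- as.logical(dat$answer)
  validate_schedule(dat, n_rounds = n_rounds)
  dat
}

#' @rdname read_questionnaire
#' @param questionnaire A questionnaire tibble.
#' @export
write_questionnaire <- function(questionnaire, path, n_rounds = 10) {
  validate_schedule(questionnaire, n_rounds = n_rounds)
  out <- questionnaire
  out$answer <- as.integer(as.logical(out$answer))
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a synthetic experiment to disk
#'
#' Writes the gameplay, questionnaire and true-type CSVs plus a JSON manifest
#' recording the design, seed and package version, so a run can be
#' reproduced bit-identically.
#'
#' @param experiment A [simulate_experiment()] result.
#' @param dir Output directory (created if absent).
#' @param seed The seed used to generate the experiment (stored in the
#'   manifest).
#' @return Invisibly, the named vector of written paths.
#' @export
write_experiment <- function(experiment, dir, seed = NULL) {
  stopifnot(inherits(experiment, "crd_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    gameplay = file.path(dir, "gameplay.csv"),
    questionnaire = file.path(dir, "questionnaire.csv"),
    types = file.path(dir, "true_types.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_gameplay(experiment$gameplay, paths[["gameplay"]])
  write_questionnaire(experiment$questionnaire, paths[["questionnaire"]])
  readr::write_csv(experiment$types, paths[["types"]])
  man <- experiment$manifest
  jsonlite::write_json(
    list(
      package = man$package,
      version = man$version,
      seed = seed,
      n_rounds = man$n_rounds,
      arms = man$design$arms,
      prosocial_prevalence = as.list(man$design$prosocial_prevalence),
      cooperator_share = man$design$cooperator_share,
      files = as.list(basename(paths[names(paths) != "manifest"]))
    ),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' One-shot analysis report for an experiment
#'
#' Chains the full pipeline on one dataset: success contingency table and
#' log-linear model selection, two-way ANOVA of mean investment, clustering
#' into behavioural types, per-type trends, and (for treatment data) the MCA
#' solution and the Q5 binomial test.
#'
#' @param experiment A `crd_experiment` (or a list with `gameplay` and
#'   `questionnaire` tibbles).
#' @return A list of class `crd_report` with components `success_table`,
#'   `loglinear` (ranking + selected model), `anova`, `types`, `trends`,
#'   `mca`, `q5`.
#' @examples
#' rep <- crd_report(simulate_experiment(seed = 1))
#' rep$loglinear$selected
#' @export
crd_report <- function(experiment) {
  gameplay <- experiment$gameplay
  ctab <- success_table(gameplay)
  fits <- fit_all_loglinear(ctab)
  selected <- select_loglinear(fits)
  cl <- cluster_players(gameplay)
  trends <- type_trends(gameplay, cl$assignment)
  qn <- experiment$questionnaire
  has_answers <- !is.null(qn) && nrow(qn) > 0
  mca_sol <- if (has_answers) fit_mca(build_indicator(qn)) else NULL
  q5 <- if (has_answers && any(qn$question == "Q5")) {
    q5a <- qn[qn$question == "Q5", ]
    q5_binomial_test(sum(as.logical(q5a$answer)), nrow(q5a))
  } else NULL
  structure(
    list(
      success_table = ctab,
      loglinear = list(selected = as.character(selected),
                       ranking = attr(selected, "ranking"),
                       fits = fits),
      anova = mean_investment_anova(gameplay),
      types = cl,
      trends = trends,
      mca = mca_sol,
      q5 = q5
    ),
    class = "crd_report"
  )
}

#' @export
print.crd_report <- function(x, ...) {
  cat("<crd_report>\n  selected log-linear model:", x$loglinear$selected, "\n")
  cat("  type counts:\n")
  print(dplyr::count(x$types$assignment, .data$type))
  if (!is.null(x$q5)) {
    cat(sprintf("  Q5: %.1f%% yes (p = %.3g)\n",
                100 * x$q5$proportion, x$q5$p_value))
  }
  invisible(x)
}
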