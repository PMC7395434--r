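#' Design of a synthetic collective-risk experiment
#'
#' Encodes the study design to emulate: how many groups of each size in each
#' arm, and the behavioural-type mixture per arm. The defaults reproduce the
#' original sessions — control: 11 groups of 3, 8 of 7, 8 of 11 (177
#' players); treatment: 10 of 3, 8 of 7, 8 of 11 (174 players) — with
#' prosocial (cooperator + altruist) prevalence 57.5% in treatment and 42.5%
#' in control, split 2:1 cooperator:altruist within the prosocial pool. The
#' prevalences are read as within-arm proportions; the 2:1 split is a
#' generator choice (cooperators are the commonest type) and both are
#' arguments.
#'
#' @param arms A tibble with columns `arm`, `group_size`, `n_groups`.
#' @param prosocial_prevalence Named numeric: probability that a player is
#'   prosocial, per arm.
#' @param cooperator_share Proportion of prosocial players who are
#'   cooperators (the rest are altruists).
#' @param type_params Behavioural-type parameter table
#'   ([default_type_params()] by default).
#' @return A list of class `crd_design`.
#' @examples
#' experiment_design()
#' @export
experiment_design <- function(
    arms = tibble(
      arm = rep(c("control", "treatment"), each = 3),
      group_size = rep(c(3L, 7L, 11L), 2),
      n_groups = c(11L, 8L, 8L, 10L, 8L, 8L)
    ),
    prosocial_prevalence = c(control = 0.425, treatment = 0.575),
    cooperator_share = 2 / 3,
    type_params = default_type_params()) {
  stopifnot(all(c("arm", "group_size", "n_groups") %in% names(arms)))
  if (any(arms$group_size %% 2L == 0L)) {
    abort("Group sizes must be odd (majority votes cannot tie).")
  }
  if (!all(unique(arms$arm) %in% names(prosocial_prevalence))) {
    abort("`prosocial_prevalence` must name every arm in `arms`.")
  }
  structure(
    list(
      arms = as_tibble(arms),
      prosocial_prevalence = prosocial_prevalence,
      cooperator_share = cooperator_share,
      type_params = type_params
    ),
    class = "crd_design"
  )
}

#' Type mixture implied by a design, per arm
#'
#' @param design A [experiment_design()].
#' @return A tibble with columns `arm`, `type`, `prob` (summing to 1 per arm).
#' @export
type_mixture <- function(design) {
  stopifnot(inherits(design, "crd_design"))
  purrr::map_dfr(names(design$prosocial_prevalence), function(a) {
    p <- design$prosocial_prevalence[[a]]
    tibble(
      arm = a,
      type = c("cooperator", "altruist", "free_rider"),
      prob = c(p * design$cooperator_share,
               p * (1 - design$cooperator_share),
               1 - p)
    )
  })
}

#' Simulate a full synthetic experiment
#'
#' Generates one complete dataset with the design's arms and group counts:
#' behavioural types are assigned i.i.d. from the arm mixture, every group
#' plays the full game with type-policy investments, treatment players answer
#' the scheduled questionnaire, and failing groups go through the loss
#' lottery. Output is byte-identical for identical `seed`.
#'
#' @param design A [experiment_design()].
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @return An object of class `crd_experiment`: a list of tibbles
#'   \describe{
#'     \item{gameplay}{one row per player-round: `session_id`, `arm`,
#'       `group_id`, `group_size`, `round`, `player_id`, `investment`,
#'       `capital_after`.}
#'     \item{questionnaire}{one row per treatment player-round-question:
#'       adds `question`, `answer`.}
#'     \item{types}{planted truth: `player_id`, `arm`, `group_id`, `type`.}
#'     \item{groups}{per group: `group_id`, `arm`, `group_size`, `target`,
#'       `total_investment`, `success`, `capital_lost`.}
#'     \item{settlements}{per player: `player_id`, `savings`, `payout`.}
#'     \item{manifest}{a list recording design, seed and package version.}
#'   }
#' @examples
#' ex <- simulate_experiment(seed = 1)
#' dplyr::count(ex$types, arm, type)
#' @export
simulate_experiment <- function(design = experiment_design(), seed = NULL) {
  stopifnot(inherits(design, "crd_design"))
  run <- function() simulate_experiment_impl(design)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_experiment_impl <- function(design) {
  n_rounds <- 10L
  mix <- type_mixture(design)
  params <- design$type_params

  groups <- design$arms |>
    dplyr::rowwise() |>
    dplyr::reframe(
      arm = .data$arm,
      group_size = .data$group_size,
      idx = seq_len(.data$n_groups)
    ) |>
    dplyr::mutate(group_id = sprintf(
      "%s_n%02d_g%02d", substr(.data$arm, 1, 1), .data$group_size, .data$idx
    )) |>
    dplyr::select("group_id", "arm", "group_size")

  players <- groups |>
    dplyr::rowwise() |>
    dplyr::reframe(
      group_id = .data$group_id,
      arm = .data$arm,
      group_size = .data$group_size,
      player = seq_len(.data$group_size)
    ) |>
    dplyr::mutate(player_id = sprintf("%s_p%02d", .data$group_id, .data$player))

  # i.i.d. type assignment from the arm mixture
  players <- players |>
    dplyr::group_by(.data$arm) |>
    dplyr::mutate(type = {
      pr <- mix$prob[mix$arm == .data$arm[1]]
      ty <- mix$type[mix$arm == .data$arm[1]]
      ty[sample.int(length(ty), dplyr::n(), replace = TRUE, prob = pr)]
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(params, by = "type")

  gameplay <- tidyr::expand_grid(players, round = seq_len(n_rounds)) |>
    dplyr::mutate(
      q = pmin(pmax(.data$intercept + .data$slope * .data$round, 0), 4) / 4,
      investment = 2 * rbinom(dplyr::n(), 2L, .data$q)
    ) |>
    dplyr::group_by(.data$player_id) |>
    dplyr::mutate(capital_after = 40 - cumsum(.data$investment)) |>
    dplyr::ungroup() |>
    dplyr::mutate(session_id = paste0("synthetic_", .data$arm)) |>
    dplyr::select("session_id", "arm", "group_id", "group_size", "round",
                  "player_id", "investment", "capital_after")

  group_totals <- gameplay |>
    dplyr::group_by(.data$group_id, .data$arm, .data$group_size) |>
    dplyr::summarise(total_investment = sum(.data$investment),
                     .groups = "drop") |>
    dplyr::mutate(
      target = 2 * n_rounds * .data$group_size,
      success = .data$total_investment >= .data$target,
      # one shared lottery draw per failing group
      capital_lost = !.data$success & (stats::runif(dplyr::n()) < 0.5)
    )

  settlements <- gameplay |>
    dplyr::filter(.data$round == n_rounds) |>
    dplyr::select("player_id", "group_id", savings = "capital_after") |>
    dplyr::left_join(
      dplyr::select(group_totals, "group_id", "success", "capital_lost"),
      by = "group_id"
    ) |>
    dplyr::mutate(payout = 15 + ifelse(.data$capital_lost, 0, 2 * .data$savings)) |>
    dplyr::select("player_id", "savings", "success", "capital_lost", "payout")

  treat <- players[players$arm == "treatment", ]
  questionnaire <- if (nrow(treat) == 0) {
    tibble(session_id = character(), arm = character(), group_id = character(),
           round = integer(), player_id = character(), question = character(),
           answer = logical())
  } else {
    sched <- crd_questions()
    tidyr::expand_grid(treat, round = seq_len(n_rounds)) |>
      dplyr::inner_join(
        tidyr::expand_grid(round = seq_len(n_rounds), sched) |>
          dplyr::filter(.data$first_round <= .data$round) |>
          dplyr::select("round", question = "id"),
        by = "round", relationship = "many-to-many"
      ) |>
      dplyr::mutate(
        yes_prob = dplyr::case_when(
          question == "Q1" ~ .data$q1, question == "Q2" ~ .data$q2,
          question == "Q3" ~ .data$q3, question == "Q4" ~ .data$q4,
          TRUE ~ .data$q5
        ),
        answer = stats::runif(dplyr::n()) < .data$yes_prob,
        session_id = "synthetic_treatment"
      ) |>
      dplyr::arrange(.data$group_id, .data$round, .data$player_id, .data$question) |>
      dplyr::select("session_id", "arm", "group_id", "round", "player_id",
                    "question", "answer")
  }

  structure(
    list(
      gameplay = gameplay,
      questionnaire = questionnaire,
      types = dplyr::select(players, "player_id", "arm", "group_id", "type"),
      groups = dplyr::select(group_totals, "group_id", "arm", "group_size",
                             "target", "total_investment", "success",
                             "capital_lost"),
      settlements = settlements,
      manifest = list(
        package = "crdgame",
        version = as.character(utils::packageVersion("crdgame")),
        design = design,
        n_rounds = n_rounds
      )
    ),
    class = "crd_experiment"
  )
}

#' @export
print.crd_experiment <- function(x, ...) {
  cat("<crd_experiment>\n")
  cat(sprintf("  %d groups, %d players, %d gameplay rows, %d answers\n",
              nrow(x$groups), nrow(x$types), nrow(x$gameplay),
              nrow(x$questionnaire)))
  succ <- x$groups |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(rate = mean(.data$success))
  for (i in seq_len(nrow(succ))) {
    cat(sprintf("  %s success rate: %.2f\n", succ$arm[i], succ$rate[i]))
  }
  invisible(x)
}
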