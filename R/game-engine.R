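#' Game configuration for the collective-risk dilemma
#'
#' Builds the rule set of the threshold public-goods game: each of
#' `group_size` players starts with `endowment` units of capital and invests
#' one element of `choices` per round over `n_rounds` rounds. The group
#' succeeds if cumulative investment reaches the target, which is derived as
#' `fair_share * n_rounds * group_size` — i.e. the target is exactly reached
#' when every player invests the fair share (2 units) in every round, giving
#' targets of 60, 140 and 220 units for groups of 3, 7 and 11. On failure,
#' all savings are wiped with probability `loss_probability`; on success (or a
#' lucky lottery draw) savings convert to money at `payout_rate` per unit on
#' top of the `show_up_fee`.
#'
#' @param group_size Number of players. Must be a positive integer; the
#'   communication protocol additionally requires an odd number (so majority
#'   votes cannot tie), which is warned about but not enforced here because
#'   control groups never vote.
#' @param n_rounds Number of investment rounds (default 10).
#' @param endowment Initial capital per player (default 40).
#' @param choices Ordered menu of per-round investments (default `c(0, 2, 4)`).
#' @param fair_share Per-player per-round investment that exactly meets the
#'   target (default 2).
#' @param loss_probability Probability that a failing group loses all retained
#'   capital (default 0.5).
#' @param payout_rate Currency units paid per unit of retained capital
#'   (default 2).
#' @param show_up_fee Unconditional participation payment (default 15).
#' @param per_player_lottery If `TRUE`, the failure lottery is drawn
#'   independently per player rather than once per group. The default `FALSE`
#'   reflects the shared-risk framing ("your group could lose everything").
#'
#' @return A list of class `crd_config` with the fields above plus the derived
#'   `target`.
#' @examples
#' game_config(3)$target   # 60
#' game_config(11)$target  # 220
#' @export
game_config <- function(group_size,
                        n_rounds = 10,
                        endowment = 40,
                        choices = c(0, 2, 4),
                        fair_share = 2,
                        loss_probability = 0.5,
                        payout_rate = 2,
                        show_up_fee = 15,
                        per_player_lottery = FALSE) {
  if (length(group_size) != 1L || !is.numeric(group_size) ||
      is.na(group_size) || group_size < 1 || group_size != round(group_size)) {
    abort("`group_size` must be a positive integer.")
  }
  if (n_rounds < 1 || n_rounds != round(n_rounds)) {
    abort("`n_rounds` must be a positive integer.")
  }
  choices <- sort(unique(as.numeric(choices)))
  if (!0 %in% choices) {
    abort("`choices` must contain 0 (investing nothing is always allowed).")
  }
  if (loss_probability < 0 || loss_probability > 1) {
    abort("`loss_probability` must be in [0, 1].")
  }
  cfg <- structure(
    list(
      group_size = as.integer(group_size),
      n_rounds = as.integer(n_rounds),
      endowment = endowment,
      choices = choices,
      fair_share = fair_share,
      target = fair_share * n_rounds * group_size,
      loss_probability = loss_probability,
      payout_rate = payout_rate,
      show_up_fee = show_up_fee,
      per_player_lottery = isTRUE(per_player_lottery)
    ),
    class = "crd_config"
  )
  cfg
}

#' @export
print.crd_config <- function(x, ...) {
  cat("<crd_config> threshold public-goods game\n")
  cat(sprintf("  %d players, %d rounds, endowment %g, menu {%s}\n",
              x$group_size, x$n_rounds, x$endowment,
              paste(x$choices, collapse = ",")))
  cat(sprintf("  target %g (fair share %g/round), loss prob %g, payout %g/unit + %g fee\n",
              x$target, x$fair_share, x$loss_probability,
              x$payout_rate, x$show_up_fee))
  invisible(x)
}

#' Affordable investment choices given remaining capital
#'
#' Subset of the contribution menu a player can afford. Under the default
#' rules this never binds: the endowment (40) equals the maximum possible
#' total spend (4 x 10), so every choice is affordable in every round. The
#' guard exists so non-default configurations keep honest accounting.
#'
#' @param capital Remaining capital (non-negative scalar or vector).
#' @param config A [game_config()].
#' @return For scalar `capital`, a numeric vector of affordable choices
#'   (always containing 0); for vector input, a list of such vectors.
#' @examples
#' feasible_choices(40, game_config(3))  # 0 2 4
#' feasible_choices(3, game_config(3))   # 0 2
#' @export
feasible_choices <- function(capital, config) {
  stopifnot(inherits(config, "crd_config"))
  if (any(is.na(capital)) || any(capital < 0)) {
    abort("`capital` must be non-negative.")
  }
  one <- function(k) config$choices[config$choices <= k]
  if (length(capital) == 1L) one(capital) else lapply(capital, one)
}

#' Surplus/deficit trajectory of a group
#'
#' Computes, per round, the group's cumulative investment and its signed
#' distance from the on-track benchmark `fair_share * group_size * round`.
#' A group on the all-fair-share path has surplus identically zero; the final
#' surplus equals cumulative investment minus the target, so `success` is
#' `surplus >= 0` at the last round.
#'
#' @param investments Numeric matrix, players in rows and rounds in columns;
#'   entries must be drawn from the configuration's menu.
#' @param config A [game_config()] with matching `group_size` and `n_rounds`.
#' @return A tibble with columns `round`, `cumulative`, `surplus`, and the
#'   scalar attribute-like column `success` repeated per row is avoided:
#'   success is `attr(x, "success")` and also trivially `surplus[n] >= 0`.
#' @examples
#' cfg <- game_config(3)
#' fair <- matrix(2, 3, 10)
#' surplus_series(fair, cfg)  # surplus identically 0, success
#' @export
surplus_series <- function(investments, config) {
  stopifnot(inherits(config, "crd_config"))
  investments <- as.matrix(investments)
  if (nrow(investments) != config$group_size ||
      ncol(investments) != config$n_rounds) {
    abort(sprintf(
      "`investments` must be %d players x %d rounds, got %d x %d.",
      config$group_size, config$n_rounds,
      nrow(investments), ncol(investments)
    ))
  }
  if (anyNA(investments) || !all(investments %in% config$choices)) {
    abort("All investments must be drawn from the configuration's menu.")
  }
  cumulative <- cumsum(colSums(investments))
  rounds <- seq_len(config$n_rounds)
  surplus <- cumulative - config$fair_share * config$group_size * rounds
  out <- tibble(
    round = rounds,
    cumulative = cumulative,
    surplus = surplus
  )
  attr(out, "success") <- surplus[config$n_rounds] >= 0
  out
}

#' Settle a finished game: savings, lottery, and monetary payouts
#'
#' Applies the end-of-game accounting. Each player's savings are
#' `endowment - sum(investments)`. If the group reached the target every
#' player is paid `show_up_fee + payout_rate * savings`. If not, a Bernoulli
#' draw with the configured loss probability decides whether savings are
#' wiped; by default one draw is shared by the whole group (set
#' `per_player_lottery = TRUE` in the config for independent draws). Payouts
#' are therefore always within `[show_up_fee, show_up_fee +
#' payout_rate * endowment]` — 15 to 95 under the defaults.
#'
#' @param investments Player-by-round matrix of investments (a complete game).
#' @param config A [game_config()].
#' @return A tibble with one row per player: `player`, `savings`, `success`,
#'   `capital_lost`, `payout`.
#' @examples
#' cfg <- game_config(3)
#' set.seed(1)
#' settle(matrix(2, 3, 10), cfg)  # success: everyone saves 20, earns 55
#' @export
settle <- function(investments, config) {
  stopifnot(inherits(config, "crd_config"))
  investments <- as.matrix(investments)
  if (ncol(investments) != config$n_rounds) {
    abort("Trajectory incomplete: settlement requires all rounds played.")
  }
  traj <- surplus_series(investments, config)
  success <- attr(traj, "success")
  savings <- config$endowment - rowSums(investments)
  if (any(savings < 0)) {
    abort("Negative savings: investments exceed the endowment.")
  }
  if (success) {
    lost <- rep(FALSE, config$group_size)
  } else if (config$per_player_lottery) {
    lost <- stats::runif(config$group_size) < config$loss_probability
  } else {
    lost <- rep(stats::runif(1) < config$loss_probability, config$group_size)
  }
  payout <- config$show_up_fee +
    ifelse(lost, 0, config$payout_rate * savings)
  tibble(
    player = seq_len(config$group_size),
    savings = savings,
    success = success,
    capital_lost = lost,
    payout = payout
  )
}
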