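#' Exact distribution of a group's cumulative investment under i.i.d. play
#'
#' Dynamic-programming (iterated convolution) computation of the distribution
#' of the sum of `n_players * n_rounds` independent draws from the
#' contribution menu. The default per-draw distribution is the uniform
#' random-play null.
#'
#' @param n_players Number of players.
#' @param n_rounds Number of rounds (default 10).
#' @param choices Menu values (default `c(0, 2, 4)`).
#' @param probs Per-draw probabilities over `choices` (default uniform).
#' @return A tibble of class `crd_sumdist` with columns `sum`, `probability`,
#'   and attributes `n_players`, `n_rounds`.
#' @examples
#' sum_distribution(1, 2)  # sums 0..8 with masses (1,2,3,2,1)/9
#' @export
sum_distribution <- function(n_players, n_rounds = 10,
                             choices = c(0, 2, 4),
                             probs = rep(1 / length(choices), length(choices))) {
  if (length(probs) != length(choices) || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-9) {
    abort("`probs` must be a probability distribution over `choices`.")
  }
  if (any(choices < 0) || any(choices != round(choices))) {
    abort("`choices` must be non-negative integers.")
  }
  n_draws <- n_players * n_rounds
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  step <- Reduce(gcd2, c(choices[choices > 0], max(choices)))
  step <- max(step, 1)
  width <- max(choices) / step
  # pmf over the lattice 0, step, 2*step, ...
  base <- numeric(width + 1)
  base[choices / step + 1] <- probs
  pmf <- 1
  for (i in seq_len(n_draws)) {
    pmf <- convolve_pmf(pmf, base)
  }
  out <- tibble(
    sum = step * (seq_along(pmf) - 1),
    probability = pmf
  )
  attr(out, "n_players") <- n_players
  attr(out, "n_rounds") <- n_rounds
  class(out) <- c("crd_sumdist", class(out))
  out
}

convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (j in seq_along(b)) {
    if (b[j] > 0) {
      idx <- seq_along(a) + j - 1
      out[idx] <- out[idx] + a * b[j]
    }
  }
  out
}

#' Probability that random play reaches the target
#'
#' Exact success probability `P(sum >= target)` of an i.i.d.-play group,
#' from [sum_distribution()]. For the uniform null the per-draw distribution
#' is symmetric about the fair share, so the sum is symmetric about the
#' target and the probability equals `(1 + P(sum == target)) / 2` — slightly
#' above one half for any group size.
#'
#' @param n_players Number of players.
#' @param config A [game_config()]; defaults to the standard rules for
#'   `n_players`.
#' @param probs Per-draw probabilities over the menu (default uniform).
#' @return A single probability.
#' @examples
#' success_probability(3)  # a little over 0.5
#' @export
success_probability <- function(n_players, config = game_config(n_players),
                                probs = NULL) {
  stopifnot(inherits(config, "crd_config"))
  if (is.null(probs)) probs <- rep(1 / length(config$choices),
                                   length(config$choices))
  d <- sum_distribution(n_players, config$n_rounds, config$choices, probs)
  sum(d$probability[d$sum >= config$target])
}

#' Significance envelope of unsuccessful random-playing groups
#'
#' Simulates `reps` groups playing the uniform null, keeps those that end in
#' failure, and reports for each round the lower `(1 - level)` quantile of
#' the surplus distribution among them. An observed group whose surplus dips
#' below this curve runs a deficit deeper than `level` (by default 95%) of
#' unsuccessful random play — the evidence used to argue that failed
#' uncommunicative groups "gave up" rather than drifted.
#'
#' @param n_players Number of players.
#' @param config A [game_config()].
#' @param reps Number of simulated groups (default 1e5, minimum 1000).
#' @param level Envelope level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of class `crd_envelope` with columns `round`,
#'   `lower`, and attributes `level`, `reps`, `seed`, `n_players`,
#'   `n_failing`.
#' @examples
#' env <- failure_envelope(3, reps = 2000, seed = 1)
#' env$lower[10] < 0  # failing groups end in deficit
#' @export
failure_envelope <- function(n_players, config = game_config(n_players),
                             reps = 1e5, level = 0.95, seed = NULL) {
  stopifnot(inherits(config, "crd_config"))
  if (reps < 1000) abort("`reps` must be at least 1000.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  run <- function() {
    n_rounds <- config$n_rounds
    k <- length(config$choices)
    # per-round group totals for all reps at once
    totals <- matrix(0, reps, n_rounds)
    for (r in seq_len(n_rounds)) {
      draws <- config$choices[sample.int(k, reps * n_players, replace = TRUE)]
      totals[, r] <- colSums(matrix(draws, n_players, reps))
    }
    cum <- t(apply(totals, 1, cumsum))
    bench <- config$fair_share * n_players * seq_len(n_rounds)
    surplus <- sweep(cum, 2, bench)
    failing <- surplus[, n_rounds] < 0
    if (!any(failing)) {
      abort("No failing groups among the simulated replicates; increase `reps`.")
    }
    lower <- apply(surplus[failing, , drop = FALSE], 2, quantile,
                   probs = 1 - level, names = FALSE, type = 7)
    out <- tibble(round = seq_len(n_rounds), lower = lower)
    attr(out, "level") <- level
    attr(out, "reps") <- reps
    attr(out, "seed") <- seed
    attr(out, "n_players") <- n_players
    attr(out, "n_failing") <- sum(failing)
    class(out) <- c("crd_envelope", class(out))
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Flag rounds where a trajectory falls beyond the envelope
#'
#' @param surplus Numeric vector of per-round surpluses for one group (e.g.
#'   the `surplus` column of [surplus_series()]).
#' @param envelope A [failure_envelope()] for the same group size and rules.
#' @return Logical vector: `TRUE` where the observed surplus is strictly
#'   below the envelope curve.
#' @export
flag_beyond_envelope <- function(surplus, envelope) {
  stopifnot(inherits(envelope, "crd_envelope"))
  if (length(surplus) != nrow(envelope)) {
    abort(sprintf("Surplus series has %d rounds but the envelope has %d.",
                  length(surplus), nrow(envelope)))
  }
  surplus < envelope$lower
}
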