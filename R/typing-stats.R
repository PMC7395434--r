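#' Two-way ANOVA of mean per-capita investment
#'
#' For each group, computes the average per-capita investment in one round
#' (total investment / (group size x rounds)) and decomposes its variance by
#' arm, group size (categorical) and their interaction. Type II sums of
#' squares are used because the design is mildly unbalanced (11 vs. 10 small
#' groups).
#'
#' @param gameplay Long gameplay table.
#' @param n_rounds Rounds per game (default 10).
#' @return A tibble with one row per term (`arm`, `group_size`,
#'   `arm:group_size`, `Residuals`): `term`, `sumsq`, `df`, `statistic`,
#'   `p.value`. The per-group means are attached as `attr(, "group_means")`.
#' @examples
#' ex <- simulate_experiment(seed = 1)
#' mean_investment_anova(ex$gameplay)
#' @export
mean_investment_anova <- function(gameplay, n_rounds = 10) {
  means <- gameplay |>
    dplyr::group_by(.data$group_id, .data$arm, .data$group_size) |>
    dplyr::summarise(
      mean_investment = sum(.data$investment) /
        (.data$group_size[1] * n_rounds),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      arm = factor(.data$arm),
      size_f = factor(.data$group_size)
    )
  cells <- means |> dplyr::count(.data$arm, .data$size_f)
  if (any(cells$n < 2) ||
      nrow(cells) < dplyr::n_distinct(means$arm) * dplyr::n_distinct(means$size_f)) {
    empty <- tidyr::expand_grid(arm = unique(means$arm),
                                size_f = unique(means$size_f)) |>
      dplyr::anti_join(cells[cells$n >= 2, c("arm", "size_f")],
                       by = c("arm", "size_f"))
    abort(sprintf("Cell %s x size %s has fewer than 2 groups.",
                  as.character(empty$arm[1]), as.character(empty$size_f[1])))
  }
  fit <- lm(mean_investment ~ arm * size_f, data = means)
  if (sum(stats::residuals(fit)^2) < 1e-12) {
    abort("Residual variance is zero; F ratios are undefined for these data.")
  }
  a2 <- car::Anova(fit, type = 2)
  out <- tibble(
    term = sub("size_f", "group_size", rownames(a2)),
    sumsq = a2$`Sum Sq`,
    df = a2$Df,
    statistic = a2$`F value`,
    p.value = a2$`Pr(>F)`
  )
  attr(out, "group_means") <- means
  out
}

#' Cluster players into behavioural types
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward linkage)
#' of each player's complete investment vector across rounds, with the tree
#' cut at `k` clusters. For `k = 3` the clusters are labelled by ascending
#' mean investment: `free_rider` (lowest), `cooperator` (middle), `altruist`
#' (highest). The labelling is invariant to player order and to the
#' arbitrary cluster ids returned by the tree cut.
#'
#' @param gameplay Long gameplay table; every player must have one investment
#'   per round.
#' @param k Number of clusters (default 3).
#' @param n_rounds Rounds per game (default 10).
#' @return An object of class `crd_types`: a list with `assignment` (tibble
#'   `player_id`, `cluster`, `type`, `mean_investment`), `tree` (the
#'   `hclust` object), and `features` (the player-by-round matrix).
#' @examples
#' ex <- simulate_experiment(seed = 1)
#' cl <- cluster_players(ex$gameplay)
#' dplyr::count(cl$assignment, type)
#' @export
cluster_players <- function(gameplay, k = 3, n_rounds = 10) {
  wide <- gameplay |>
    dplyr::select("player_id", "round", "investment") |>
    tidyr::pivot_wider(names_from = "round", values_from = "investment",
                       names_prefix = "r")
  if (anyNA(wide) || ncol(wide) != n_rounds + 1) {
    abort("Every player needs a complete investment vector over all rounds.")
  }
  if (nrow(wide) < k) {
    abort(sprintf("Need at least %d players to form %d clusters.", k, k))
  }
  feat <- as.matrix(wide[, -1])
  rownames(feat) <- wide$player_id
  tree <- stats::hclust(stats::dist(feat), method = "ward.D2")
  cl <- stats::cutree(tree, k = k)
  cl_means <- tapply(rowMeans(feat), cl, mean)
  ord <- order(cl_means)  # ascending mean investment
  labels <- if (k == 3) {
    c("free_rider", "cooperator", "altruist")
  } else {
    paste0("type_", seq_len(k))
  }
  type_of <- setNames(labels, as.character(ord))
  assignment <- tibble(
    player_id = wide$player_id,
    cluster = unname(cl),
    type = unname(type_of[as.character(cl)]),
    mean_investment = rowMeans(feat)
  )
  structure(
    list(assignment = assignment, tree = tree, features = feat),
    class = "crd_types"
  )
}

#' @export
print.crd_types <- function(x, ...) {
  cat("<crd_types> hierarchical clustering (Euclidean, Ward)\n")
  print(dplyr::count(x$assignment, .data$type))
  invisible(x)
}

#' Per-type investment trends and ANCOVA
#'
#' Given a type assignment (clustered or planted), estimates for each
#' behavioural type the population mean per-round investment with a
#' normal-approximation 95% CI, and the ordinary least-squares slope of
#' investment on round with its 95% CI. A covariance analysis on the pooled
#' player-round records — nested linear models `investment ~ type * round` —
#' supplies F statistics for type, round and their interaction.
#'
#' @param gameplay Long gameplay table.
#' @param assignment A tibble with `player_id` and `type` (e.g.
#'   `cluster_players(...)$assignment` or the planted `types` table).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `crd_trends`: list with `per_type` (tibble:
#'   `type`, `n_players`, `mean`, `mean_low`, `mean_high`, `slope`,
#'   `slope_low`, `slope_high`) and `ancova` (tibble: `term`, `df`, `sumsq`,
#'   `statistic`, `p.value`).
#' @examples
#' ex <- simulate_experiment(seed = 1)
#' type_trends(ex$gameplay, ex$types)
#' @export
type_trends <- function(gameplay, assignment, conf_level = 0.95) {
  if (!all(c("player_id", "type") %in% names(assignment))) {
    abort("`assignment` needs columns `player_id` and `type`.")
  }
  dat <- gameplay |>
    dplyr::inner_join(assignment[, c("player_id", "type")], by = "player_id")
  uncovered <- setdiff(unique(gameplay$player_id), assignment$player_id)
  if (length(uncovered) > 0) {
    warn(sprintf("%d player(s) without a type assignment were dropped.",
                 length(uncovered)))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  per_type <- dat |>
    dplyr::group_by(.data$type) |>
    dplyr::group_modify(function(d, key) {
      n_players <- dplyr::n_distinct(d$player_id)
      m <- mean(d$investment)
      se <- sd(d$investment) / sqrt(nrow(d))
      if (n_players < 2) {
        warn(sprintf("Type '%s' has fewer than 2 players; CIs undefined.",
                     key$type))
      }
      slope_fit <- lm(investment ~ round, data = d)
      b <- coef(slope_fit)[["round"]]
      ci <- tryCatch(confint(slope_fit, "round", level = conf_level),
                     error = function(e) matrix(c(NA_real_, NA_real_), 1))
      zero_width <- sd(d$investment) < 1e-12
      if (zero_width) {
        warn(sprintf("Type '%s' has constant investments; zero-width CI.",
                     key$type))
      }
      tibble(
        n_players = n_players,
        mean = m, mean_low = m - z * se, mean_high = m + z * se,
        slope = b, slope_low = ci[1, 1], slope_high = ci[1, 2]
      )
    }) |>
    dplyr::ungroup()
  # with a single type the type terms drop out of the covariance analysis
  full <- if (dplyr::n_distinct(dat$type) > 1) {
    lm(investment ~ type * round, data = dat)
  } else {
    lm(investment ~ round, data = dat)
  }
  aov_tab <- anova(full)
  ancova <- tibble(
    term = rownames(aov_tab),
    df = aov_tab$Df,
    sumsq = aov_tab$`Sum Sq`,
    statistic = aov_tab$`F value`,
    p.value = aov_tab$`Pr(>F)`
  )
  structure(list(per_type = per_type, ancova = ancova, model = full),
            class = "crd_trends")
}

#' @export
print.crd_trends <- function(x, ...) {
  cat("<crd_trends> per-type means and round slopes\n")
  print(x$per_type)
  invisible(x)
}

#' Multinomial logistic model of the investment choice
#'
#' Models the per-round choice among 0, 2 and 4 units with the fair share
#' (2) as the reference category, via maximum likelihood
#' ([nnet::multinom()]). Default covariates: round centred at its midpoint
#' (5.5), arm as an indicator, and group size as a categorical factor. A
#' positive coefficient on an outcome means that outcome gains probability
#' relative to fair investment.
#'
#' @param gameplay Long gameplay table with `investment`, `round`, `arm`,
#'   `group_size`.
#' @param covariates Character subset of `c("round", "arm", "size")`;
#'   `character(0)` fits an intercept-only model.
#' @param center_round Value subtracted from `round` (default 5.5).
#' @param maxit Optimiser iteration cap.
#' @return An object of class `crd_multinom` wrapping the `nnet` fit, with a
#'   tidy coefficient table in `$coefficients` (columns `outcome`, `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`).
#' @examples
#' ex <- simulate_experiment(seed = 1)
#' fit <- multinomial_choice_model(ex$gameplay)
#' head(fit$coefficients)
#' @export
multinomial_choice_model <- function(gameplay,
                                     covariates = c("round", "arm", "size"),
                                     center_round = 5.5,
                                     maxit = 500) {
  if (!all(gameplay$investment %in% c(0, 2, 4))) {
    abort("Investments outside the menu {0, 2, 4}.")
  }
  present <- sort(unique(gameplay$investment))
  if (length(present) < 2) {
    abort(paste0(
      "Only category ", present, " is observed: the outcome is perfectly ",
      "predicted (complete separation). Fit on richer data or switch to a ",
      "regularised model."
    ))
  }
  dat <- tibble(
    choice = factor(gameplay$investment, levels = c(2, 0, 4)),
    round_c = gameplay$round - center_round,
    arm = if ("arm" %in% names(gameplay)) factor(gameplay$arm) else NULL,
    size_f = if ("group_size" %in% names(gameplay)) {
      factor(gameplay$group_size)
    } else NULL
  )
  terms <- c(
    if ("round" %in% covariates) "round_c",
    if ("arm" %in% covariates && "arm" %in% names(dat) &&
        nlevels(dat$arm) > 1) "arm",
    if ("size" %in% covariates && "size_f" %in% names(dat) &&
        nlevels(dat$size_f) > 1) "size_f"
  )
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  form <- stats::as.formula(paste("choice ~", rhs))
  fit <- nnet::multinom(form, data = dat, trace = FALSE, maxit = maxit,
                        Hess = TRUE)
  if (fit$convergence != 0) {
    abort("Multinomial fit did not converge; increase `maxit`.")
  }
  s <- summary(fit)
  est <- s$coefficients
  se <- s$standard.errors
  if (is.null(dim(est))) {  # single non-reference outcome never happens here
    est <- matrix(est, nrow = 1, dimnames = list(fit$lab[-1], names(est)))
    se <- matrix(se, nrow = 1, dimnames = dimnames(est))
  }
  if (any(!is.finite(se)) || any(se > 1e3)) {
    abort(paste0(
      "Huge or non-finite standard errors suggest separation (a category ",
      "perfectly predicted); switch to a regularised model."
    ))
  }
  coefs <- as_tibble(est, rownames = "outcome") |>
    tidyr::pivot_longer(-"outcome", names_to = "term", values_to = "estimate") |>
    dplyr::left_join(
      as_tibble(se, rownames = "outcome") |>
        tidyr::pivot_longer(-"outcome", names_to = "term",
                            values_to = "std.error"),
      by = c("outcome", "term")
    ) |>
    dplyr::mutate(
      statistic = .data$estimate / .data$std.error,
      p.value = 2 * stats::pnorm(-abs(.data$statistic))
    )
  structure(
    list(fit = fit, coefficients = coefs, reference = "2",
         formula = form, n = nrow(dat)),
    class = "crd_multinom"
  )
}

#' @export
print.crd_multinom <- function(x, ...) {
  cat(sprintf("<crd_multinom> choice ~ %s (reference: fair share 2), n = %d\n",
              deparse(x$formula[[3]]), x$n))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Exact one-sided binomial test for the risk-perception question
#'
#' With the loss probability known to be one half, roughly half of Q5
#' answers should be "yes" under unbiased risk perception. This computes the
#' exact upper tail `P(X >= yes_count)` for `X ~ Binomial(n, 1/2)`,
#' numerically stable for n in the thousands.
#'
#' @param yes_count Number of positive answers.
#' @param n Total answers.
#' @param p Null yes-probability (default 0.5, the known loss probability).
#' @return A one-row tibble: `yes_count`, `n`, `proportion`, `p_value`.
#' @examples
#' q5_binomial_test(527, 870)  # p well below 1e-6
#' @export
q5_binomial_test <- function(yes_count, n, p = 0.5) {
  if (yes_count < 0 || yes_count > n || n < 1 ||
      yes_count != round(yes_count) || n != round(n)) {
    abort("`yes_count` must be an integer in 0..n.")
  }
  tail <- pbinom(yes_count - 1, n, p, lower.tail = FALSE)
  tibble(
    yes_count = yes_count,
    n = n,
    proportion = yes_count / n,
    p_value = tail
  )
}
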