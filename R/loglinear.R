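#' Success contingency table by arm and group size
#'
#' Tallies each group once into the arm x success x size cross-classification
#' that the log-linear analysis consumes. Success is recomputed from the
#' gameplay records (cumulative investment vs. the derived target), not taken
#' on trust.
#'
#' @param gameplay Long gameplay table (one row per player-round) with
#'   columns `group_id`, `arm`, `group_size`, `round`, `investment`.
#' @param n_rounds Expected number of rounds per group (default 10); groups
#'   with missing rounds are an error.
#' @return A tibble with one row per `arm` x `success` x `group_size` cell
#'   and the count `n` (zero-filled), of class `crd_ctab`.
#' @examples
#' ex <- simulate_experiment(seed = 1)
#' success_table(ex$gameplay)
#' @export
success_table <- function(gameplay, n_rounds = 10) {
  required <- c("group_id", "arm", "group_size", "round", "investment")
  missing <- setdiff(required, names(gameplay))
  if (length(missing) > 0) {
    abort(paste0("Gameplay is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(gameplay) > 0) {
    chk <- gameplay |>
      dplyr::distinct(.data$group_id, .data$round) |>
      dplyr::count(.data$group_id)
    bad <- chk$group_id[chk$n != n_rounds]
    if (length(bad) > 0) {
      abort(sprintf("Group %s has incomplete rounds (%d of %d).",
                    bad[1], chk$n[chk$group_id == bad[1]], n_rounds))
    }
  }
  per_group <- gameplay |>
    dplyr::group_by(.data$group_id, .data$arm, .data$group_size) |>
    dplyr::summarise(total = sum(.data$investment), .groups = "drop") |>
    dplyr::mutate(success = .data$total >= 2 * n_rounds * .data$group_size)
  sizes <- sort(unique(gameplay$group_size))
  if (length(sizes) == 0) sizes <- c(3L, 7L, 11L)
  out <- tidyr::expand_grid(
    arm = c("control", "treatment"),
    success = c(TRUE, FALSE),
    group_size = sizes
  ) |>
    dplyr::left_join(
      dplyr::count(per_group, .data$arm, .data$success, .data$group_size),
      by = c("arm", "success", "group_size")
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  class(out) <- c("crd_ctab", class(out))
  out
}

#' Convert a tidy contingency table to a 3-way array
#'
#' @param ctab A tidy count table as returned by [success_table()].
#' @return A named `table`-like array with dimensions
#'   `arm` x `success` x `size`.
#' @export
contingency_array <- function(ctab) {
  arms <- sort(unique(ctab$arm))
  succ <- c("no", "yes")
  sizes <- sort(unique(ctab$group_size))
  arr <- array(
    0,
    dim = c(length(arms), 2, length(sizes)),
    dimnames = list(arm = arms, success = succ, size = as.character(sizes))
  )
  for (i in seq_len(nrow(ctab))) {
    arr[ctab$arm[i], if (ctab$success[i]) "yes" else "no",
        as.character(ctab$group_size[i])] <-
      arr[ctab$arm[i], if (ctab$success[i]) "yes" else "no",
          as.character(ctab$group_size[i])] + ctab$n[i]
  }
  arr
}

#' The nine hierarchical log-linear models for a three-way table
#'
#' The standard hierarchy for factors arm (A), success (S) and size (Z):
#' mutual independence, the three joint-independence models, the three
#' conditional-independence models, homogeneous association, and the
#' saturated model. `cond_arm.size_given_success` — arm and size independent
#' given success, i.e. the two-way terms arm x success and size x success —
#' is the model the success data select.
#'
#' @return A named list; each element is the list of sufficient margins
#'   (character vectors of factor names) defining one model.
#' @export
loglinear_models <- function() {
  list(
    mutual_independence = list("arm", "success", "size"),
    joint_arm.success = list(c("arm", "success"), "size"),
    joint_arm.size = list(c("arm", "size"), "success"),
    joint_success.size = list(c("success", "size"), "arm"),
    cond_success.size_given_arm = list(c("arm", "success"), c("arm", "size")),
    cond_arm.size_given_success = list(c("arm", "success"), c("success", "size")),
    cond_arm.success_given_size = list(c("arm", "size"), c("success", "size")),
    homogeneous_association = list(c("arm", "success"), c("arm", "size"),
                                   c("success", "size")),
    saturated = list(c("arm", "success", "size"))
  )
}

#' Fit one log-linear model by iterative proportional fitting
#'
#' Fits the model's expected cell counts by IPF (via [stats::loglin()]) until
#' every sufficient margin of the fitted table matches the observed margin to
#' within `eps`, and reports the likelihood-ratio statistic
#' `G^2 = 2 * sum(obs * log(obs / fitted))` over non-empty cells, its degrees
#' of freedom, the chi-squared p-value, and the AIC difference relative to
#' the saturated model (`G^2 - 2 df`).
#'
#' @param ctab A tidy count table ([success_table()]) or a 3-way array with
#'   dimnames `arm`, `success`, `size`.
#' @param model A model id from [loglinear_models()], or a list of margins.
#' @param eps Maximum allowed deviation between fitted and observed margins
#'   (default 1e-10).
#' @param iter Iteration cap for IPF (default 200).
#' @return An object of class `crd_loglin`.
#' @examples
#' ex <- simulate_experiment(seed = 1)
#' fit <- fit_loglinear(success_table(ex$gameplay), "cond_arm.size_given_success")
#' glance(fit)
#' @export
fit_loglinear <- function(ctab, model, eps = 1e-10, iter = 200) {
  arr <- if (is.array(ctab)) ctab else contingency_array(ctab)
  models <- loglinear_models()
  if (is.character(model)) {
    if (!model %in% names(models)) {
      abort(paste0("Unknown model id '", model, "'. Available: ",
                   paste(names(models), collapse = ", ")))
    }
    margins <- models[[model]]
    model_id <- model
  } else {
    margins <- model
    model_id <- paste(vapply(model, paste, "", collapse = ":"), collapse = " + ")
  }
  fit <- loglin(arr, margin = margins, fit = TRUE, eps = eps, iter = iter,
                print = FALSE)
  # confirm the IPF fixed point: every sufficient margin matches
  for (m in margins) {
    dev <- max(abs(apply(fit$fit, match(m, names(dimnames(arr))), sum) -
                     apply(arr, match(m, names(dimnames(arr))), sum)))
    if (dev > eps * max(1, sum(arr))) {
      abort(sprintf(
        "IPF did not converge for model '%s': margin {%s} deviates by %.3g.",
        model_id, paste(m, collapse = ","), dev
      ))
    }
  }
  nz <- arr > 0
  g2 <- 2 * sum(arr[nz] * log(arr[nz] / fit$fit[nz]))
  structure(
    list(
      model = model_id,
      margins = margins,
      observed = arr,
      fitted = fit$fit,
      g2 = g2,
      df = fit$df,
      p_value = if (fit$df > 0) pchisq(g2, fit$df, lower.tail = FALSE) else 1,
      aic = g2 - 2 * fit$df
    ),
    class = "crd_loglin"
  )
}

#' Fit all nine log-linear models
#'
#' @inheritParams fit_loglinear
#' @return A named list of `crd_loglin` fits, one per model in
#'   [loglinear_models()].
#' @export
fit_all_loglinear <- function(ctab, eps = 1e-10, iter = 200) {
  purrr::map(
    setNames(nm = names(loglinear_models())),
    function(m) fit_loglinear(ctab, m, eps = eps, iter = iter)
  )
}

#' Select the most parsimonious adequate log-linear model
#'
#' Among the nine fits, picks the most parsimonious model (largest residual
#' degrees of freedom) whose G-squared p-value against the chi-squared
#' reference exceeds `alpha`; ties are broken by fewer parameters. The
#' saturated model (G^2 = 0) is always admissible, so selection never fails.
#'
#' @param fits A list of `crd_loglin` objects ([fit_all_loglinear()]).
#' @param alpha Adequacy threshold on the goodness-of-fit p-value
#'   (default 0.05).
#' @return The selected model id (character), with the full ranking in
#'   `attr(, "ranking")`.
#' @export
select_loglinear <- function(fits, alpha = 0.05) {
  ranking <- purrr::map_dfr(fits, function(f) {
    tibble(model = f$model, g2 = f$g2, df = f$df, p_value = f$p_value,
           aic = f$aic)
  }) |>
    dplyr::arrange(dplyr::desc(.data$df), .data$g2)
  ok <- ranking[ranking$p_value > alpha, ]
  sel <- ok$model[1]
  attr(sel, "ranking") <- ranking
  sel
}

#' @export
print.crd_loglin <- function(x, ...) {
  cat(sprintf("<crd_loglin> %s\n  G2 = %.4f on %d df, p = %.4g, dAIC = %.3f\n",
              x$model, x$g2, x$df, x$p_value, x$aic))
  invisible(x)
}
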