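#' Tidy a log-linear fit
#'
#' @param x A `crd_loglin` object.
#' @param ... Unused.
#' @return A tibble with one row per cell: `arm`, `success`, `size`,
#'   `observed`, `fitted`, `residual` (Pearson).
#' @export
tidy.crd_loglin <- function(x, ...) {
  obs <- as.data.frame.table(x$observed, responseName = "observed")
  fit <- as.data.frame.table(x$fitted, responseName = "fitted")
  dplyr::left_join(obs, fit, by = c("arm", "success", "size")) |>
    as_tibble() |>
    dplyr::mutate(residual = (.data$observed - .data$fitted) /
                    sqrt(pmax(.data$fitted, 1e-300)))
}

#' @rdname tidy.crd_loglin
#' @export
glance.crd_loglin <- function(x, ...) {
  tibble(model = x$model, g2 = x$g2, df = x$df, p.value = x$p_value,
         aic = x$aic)
}

#' Tidy a behavioural-type clustering
#'
#' @param x A `crd_types` object.
#' @param ... Unused.
#' @return The assignment tibble (`player_id`, `cluster`, `type`,
#'   `mean_investment`).
#' @export
tidy.crd_types <- function(x, ...) x$assignment

#' @rdname tidy.crd_types
#' @export
glance.crd_types <- function(x, ...) {
  x$assignment |>
    dplyr::count(.data$type, name = "n_players") |>
    tidyr::pivot_wider(names_from = "type", values_from = "n_players")
}

#' Tidy per-type trend estimates
#'
#' @param x A `crd_trends` object.
#' @param ... Unused.
#' @return The per-type tibble of means, slopes and confidence bounds.
#' @export
tidy.crd_trends <- function(x, ...) x$per_type

#' @rdname tidy.crd_trends
#' @export
glance.crd_trends <- function(x, ...) {
  x$ancova |>
    dplyr::filter(.data$term != "Residuals") |>
    dplyr::select("term", "statistic", "p.value") |>
    tidyr::pivot_wider(names_from = "term",
                       values_from = c("statistic", "p.value"))
}

#' Tidy a multinomial choice model
#'
#' @param x A `crd_multinom` object.
#' @param ... Unused.
#' @return The coefficient tibble (`outcome`, `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @export
tidy.crd_multinom <- function(x, ...) x$coefficients

#' @rdname tidy.crd_multinom
#' @export
glance.crd_multinom <- function(x, ...) {
  tibble(
    n = x$n,
    edf = x$fit$edf,
    deviance = x$fit$deviance,
    AIC = x$fit$AIC
  )
}

#' Tidy an MCA solution
#'
#' @param x A `crd_mca` object.
#' @param ... Unused.
#' @return The category (column) principal coordinates with inertia columns.
#' @export
tidy.crd_mca <- function(x, ...) x$col_coords

#' @rdname tidy.crd_mca
#' @export
glance.crd_mca <- function(x, ...) {
  tibble(
    total_inertia = x$total_inertia,
    n_dims = nrow(x$inertias),
    inertia_dim1 = x$inertias$inertia[1],
    inertia_dim2 = if (nrow(x$inertias) >= 2) x$inertias$inertia[2] else NA_real_
  )
}
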