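#' Build the indicator matrix for multiple correspondence analysis
#'
#' One-hot expands the yes/no answers to Q1–Q4 into an indicator matrix with
#' one column per question-category (Q1_yes, Q1_no, ..., Q4_no). Q5 is
#' excluded by design: it appears late in the game and asks about risk
#' perception rather than sentiment/outlook. Rows are either player-rounds
#' (each answered round is one observation, the default) or players (modal
#' answer per question, ties resolved to "no" with a warning).
#'
#' @param questionnaire Long questionnaire table (`player_id`, `round`,
#'   `question`, `answer`).
#' @param aggregation `"player_round"` (default) or `"player"`.
#' @param questions Questions to include (default Q1–Q4).
#' @return An object of class `crd_indicator`: a 0/1 matrix with row
#'   identifiers as rownames and an attribute `aggregation`.
#' @examples
#' ex <- simulate_experiment(seed = 1)
#' ind <- build_indicator(ex$questionnaire)
#' dim(ind)
#' @export
build_indicator <- function(questionnaire,
                            aggregation = c("player_round", "player"),
                            questions = c("Q1", "Q2", "Q3", "Q4")) {
  aggregation <- match.arg(aggregation)
  dat <- questionnaire |>
    dplyr::filter(.data$question %in% questions) |>
    dplyr::mutate(answer = as.logical(.data$answer))
  if (nrow(dat) == 0) {
    abort("No answers to the selected questions (control arms have none).")
  }
  if (aggregation == "player") {
    dat <- dat |>
      dplyr::group_by(.data$player_id, .data$question) |>
      dplyr::summarise(
        yes = sum(.data$answer), total = dplyr::n(), .groups = "drop"
      )
    ties <- dat$yes * 2 == dat$total
    if (any(ties)) {
      warn(sprintf("%d player-question tie(s) in modal aggregation resolved as 'no'.",
                   sum(ties)))
    }
    dat <- dat |>
      dplyr::mutate(answer = .data$yes * 2 > .data$total,
                    row_id = .data$player_id)
  } else {
    dat <- dat |>
      dplyr::mutate(row_id = paste(.data$player_id, .data$round, sep = ":"))
  }
  wide <- dat |>
    dplyr::select("row_id", "question", "answer") |>
    tidyr::pivot_wider(names_from = "question", values_from = "answer")
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    inform(sprintf("%d row(s) with incomplete answers excluded.",
                   sum(!complete)))
    wide <- wide[complete, ]
  }
  qs <- intersect(questions, names(wide))
  cols <- lapply(qs, function(q) {
    cbind(as.integer(wide[[q]]), as.integer(!wide[[q]]))
  })
  ind <- do.call(cbind, cols)
  colnames(ind) <- as.vector(rbind(paste0(qs, "_yes"), paste0(qs, "_no")))
  rownames(ind) <- wide$row_id
  attr(ind, "aggregation") <- aggregation
  attr(ind, "questions") <- qs
  class(ind) <- c("crd_indicator", class(ind))
  ind
}

#' Multiple correspondence analysis of an indicator matrix
#'
#' Correspondence analysis applied to the indicator matrix: the matrix is
#' scaled to a correspondence matrix P = N / n.., the standardized residuals
#' `S = Dr^{-1/2} (P - r c') Dc^{-1/2}` are decomposed by singular value
#' decomposition, principal inertias are the squared singular values, and
#' principal coordinates are the mass-rescaled singular vectors times the
#' singular values. For a complete indicator of Q binary questions the total
#' inertia is exactly `J/Q - 1` (J = number of categories), here
#' `8/4 - 1 = 1`, and there are at most `J - Q` non-trivial dimensions. The
#' optional Benzecri correction rescales inertias above `1/Q` (off by
#' default).
#'
#' @param indicator A [build_indicator()] matrix (any non-negative matrix
#'   with at least two rows works).
#' @param n_dims Number of dimensions to retain (default: all non-trivial).
#' @param benzecri Apply the Benzecri inertia correction (default `FALSE`).
#' @return An object of class `crd_mca`: list with `inertias` (tibble
#'   `dim`, `inertia`, `proportion`), `row_coords`, `col_coords` (tibbles of
#'   principal coordinates), `total_inertia`, `row_masses`, `col_masses`,
#'   and `svd` internals.
#' @examples
#' ex <- simulate_experiment(seed = 1)
#' sol <- fit_mca(build_indicator(ex$questionnaire))
#' sol$inertias
#' @export
fit_mca <- function(indicator, n_dims = NULL, benzecri = FALSE) {
  N <- unclass(indicator)
  if (!is.matrix(N) || nrow(N) < 2) {
    abort("`indicator` must be a matrix with at least 2 rows.")
  }
  if (any(N < 0)) abort("Indicator entries must be non-negative.")
  total <- sum(N)
  P <- N / total
  r <- rowSums(P)
  c_mass <- colSums(P)
  if (any(c_mass == 0)) {
    keep <- c_mass > 0
    warn(sprintf("%d empty category column(s) dropped.", sum(!keep)))
    N <- N[, keep, drop = FALSE]
    P <- N / sum(N)
    r <- rowSums(P)
    c_mass <- colSums(P)
  }
  S <- diag(1 / sqrt(r)) %*% (P - tcrossprod(r, c_mass)) %*%
    diag(1 / sqrt(c_mass))
  dec <- svd(S)
  tol <- 1e-12
  nontrivial <- dec$d^2 > tol
  if (!any(nontrivial)) {
    warn("All rows identical: no non-trivial inertia.")
  }
  d <- dec$d[nontrivial]
  U <- dec$u[, nontrivial, drop = FALSE]
  V <- dec$v[, nontrivial, drop = FALSE]
  if (!is.null(n_dims)) {
    n_dims <- min(n_dims, length(d))
    d <- d[seq_len(n_dims)]
    U <- U[, seq_len(n_dims), drop = FALSE]
    V <- V[, seq_len(n_dims), drop = FALSE]
  }
  inertia <- d^2
  reported <- inertia
  if (benzecri) {
    q <- length(attr(indicator, "questions"))
    if (q < 2) abort("Benzecri correction needs the question count (>= 2).")
    above <- inertia > 1 / q
    reported <- ifelse(above, (q / (q - 1))^2 * (inertia - 1 / q)^2, 0)
  }
  row_pc <- diag(1 / sqrt(r)) %*% U %*% diag(d, nrow = length(d))
  col_pc <- diag(1 / sqrt(c_mass)) %*% V %*% diag(d, nrow = length(d))
  dim_names <- paste0("dim", seq_along(d))
  colnames(row_pc) <- dim_names
  colnames(col_pc) <- dim_names
  structure(
    list(
      inertias = tibble(
        dim = seq_along(d),
        inertia = reported,
        proportion = reported / sum(reported)
      ),
      raw_inertias = inertia,
      total_inertia = sum(dec$d^2),
      row_coords = dplyr::bind_cols(
        tibble(row_id = rownames(N) %||% as.character(seq_len(nrow(N)))),
        as_tibble(row_pc)
      ),
      col_coords = dplyr::bind_cols(
        tibble(category = colnames(N) %||% as.character(seq_len(ncol(N)))),
        as_tibble(col_pc)
      ),
      row_masses = r,
      col_masses = c_mass,
      svd = list(d = d, u = U, v = V),
      benzecri = benzecri
    ),
    class = "crd_mca"
  )
}

#' @export
print.crd_mca <- function(x, ...) {
  cat(sprintf("<crd_mca> total inertia %.4f, %d non-trivial dimension(s)\n",
              x$total_inertia, nrow(x$inertias)))
  print(x$inertias)
  invisible(x)
}

#' Category map with behavioural-type overlays
#'
#' Combines the category coordinates on the first two principal dimensions
#' with the centroid of each behavioural type's rows, the representation
#' behind "prosocial types answer yes-Q1 / no-Q2 / no-Q3 / yes-Q4".
#'
#' @param solution A [fit_mca()] result with at least 2 dimensions.
#' @param types A tibble with `player_id` and `type` (clustered or planted).
#' @return A tibble with columns `label`, `kind` (`"category"` or
#'   `"type_centroid"`), `dim1`, `dim2`.
#' @export
category_map <- function(solution, types) {
  stopifnot(inherits(solution, "crd_mca"))
  if (length(solution$svd$d) < 2) {
    abort("Need at least 2 MCA dimensions for a category map.")
  }
  cats <- solution$col_coords |>
    dplyr::transmute(label = .data$category, kind = "category",
                     dim1 = .data$dim1, dim2 = .data$dim2)
  rows <- solution$row_coords |>
    dplyr::mutate(player_id = sub(":.*$", "", .data$row_id)) |>
    dplyr::inner_join(types[, c("player_id", "type")], by = "player_id")
  centroids <- rows |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(dim1 = mean(.data$dim1), dim2 = mean(.data$dim2),
                     .groups = "drop") |>
    dplyr::transmute(label = .data$type, kind = "type_centroid",
                     dim1 = .data$dim1, dim2 = .data$dim2)
  dplyr::bind_rows(cats, centroids)
}
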