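balanced_indicator <- function() {
  # all 16 yes/no patterns over 4 questions, equally weighted: the questions
  # are independent and balanced by construction
  patterns <- expand.grid(Q1 = c(TRUE, FALSE), Q2 = c(TRUE, FALSE),
                          Q3 = c(TRUE, FALSE), Q4 = c(TRUE, FALSE))
  qn <- do.call(rbind, lapply(seq_len(nrow(patterns)), function(i) {
    data.frame(
      player_id = sprintf("p%02d", i),
      round = 2L,
      question = paste0("Q", 1:4),
      answer = as.logical(patterns[i, ])
    )
  }))
  build_indicator(tibble::as_tibble(qn))
}

test_that("the indicator one-hot expands answers and excludes Q5", {
  qn <- tibble::tibble(
    player_id = "p1", round = 6L,
    question = paste0("Q", 1:5),
    answer = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  ind <- build_indicator(qn)
  expect_equal(dim(ind), c(1L, 8L))
  expect_equal(
    as.numeric(ind[1, ]),
    c(1, 0, 1, 0, 1, 0, 1, 0)
  )
  expect_equal(colnames(ind)[1:2], c("Q1_yes", "Q1_no"))
  expect_false(any(grepl("Q5", colnames(ind))))
  # control input (no answers) errors
  expect_error(build_indicator(qn[0, ]), "No answers")
  # modal player aggregation with a tie resolves to no, with a warning
  qn2 <- tibble::tibble(
    player_id = "p1", round = rep(2:3, each = 4),
    question = rep(paste0("Q", 1:4), 2),
    answer = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  expect_warning(ind2 <- build_indicator(qn2, aggregation = "player"),
                 "tie")
  expect_equal(as.numeric(ind2[1, c("Q1_yes", "Q3_yes")]), c(0, 0))
  expect_equal(as.numeric(ind2[1, c("Q2_yes", "Q4_yes")]), c(1, 1))
})

test_that("independent balanced questions give equal inertias of 1/4", {
  sol <- fit_mca(balanced_indicator())
  expect_equal(sol$total_inertia, 1, tolerance = 1e-10)
  expect_equal(sol$raw_inertias, rep(0.25, 4), tolerance = 1e-10)
})

test_that("total inertia of complete 4-question data is J/Q - 1 = 1", {
  ex <- simulate_experiment(seed = 4)
  ind <- build_indicator(ex$questionnaire)
  sol <- fit_mca(ind)
  expect_equal(sol$total_inertia, 1, tolerance = 1e-10)
  expect_equal(sum(sol$raw_inertias), 1, tolerance = 1e-10)
  # inertias are non-negative and non-increasing
  expect_true(all(diff(sol$raw_inertias) <= 1e-12))
  expect_true(all(sol$raw_inertias >= 0))
})

test_that("two perfectly correlated questions load one dimension", {
  # Q1 = Q2 on every row; 2-question MCA has inertias (1, 0)
  n <- 12
  ans <- rep(c(TRUE, FALSE), length.out = n)
  qn <- tibble::tibble(
    player_id = rep(sprintf("p%02d", 1:n), each = 2),
    round = 1L,
    question = rep(c("Q1", "Q2"), n),
    answer = rep(ans, each = 2)
  )
  ind <- build_indicator(qn, questions = c("Q1", "Q2"))
  sol <- fit_mca(ind)
  expect_equal(sol$raw_inertias[1], 1, tolerance = 1e-10)
  expect_lt(sum(sol$raw_inertias[-1]), 1e-10)
})

test_that("coordinate clouds are centred and reconstruct the residuals", {
  ex <- simulate_experiment(seed = 8)
  ind <- build_indicator(ex$questionnaire)
  sol <- fit_mca(ind)
  rc <- as.matrix(sol$row_coords[, -1])
  cc <- as.matrix(sol$col_coords[, -1])
  expect_lt(max(abs(colSums(rc * sol$row_masses))), 1e-10)
  expect_lt(max(abs(colSums(cc * sol$col_masses))), 1e-10)
  # retaining all dimensions reproduces the standardized residual matrix
  N <- unclass(ind)
  P <- N / sum(N)
  r <- rowSums(P); cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - tcrossprod(r, cm)) %*% diag(1 / sqrt(cm))
  S_hat <- sol$svd$u %*% diag(sol$svd$d) %*% t(sol$svd$v)
  expect_lt(max(abs(S - S_hat)), 1e-8)
})

test_that("MCA agrees with an independent correspondence-analysis oracle", {
  skip_if_not_installed("MASS")
  ind <- balanced_indicator()
  # perturb to break the exact tie between dimensions
  set.seed(3)
  rows <- sample(nrow(ind), 40, replace = TRUE)
  ind2 <- unclass(ind)[rows, ]
  sol <- fit_mca(ind2)
  ca <- MASS::corresp(ind2, nf = 3)
  expect_equal(sol$svd$d[1:3], ca$cor[1:3], tolerance = 1e-6)
})

test_that("the category map places prosocial optimism together", {
  hits <- vapply(1:5, function(s) {
    ex <- simulate_experiment(seed = 600 + s)
    sol <- fit_mca(build_indicator(ex$questionnaire))
    cm <- category_map(sol, ex$types)
    q1 <- cm$dim1[cm$label == "Q1_yes"]
    q4 <- cm$dim1[cm$label == "Q4_yes"]
    coop <- cm$dim1[cm$label == "cooperator"]
    alt <- cm$dim1[cm$label == "altruist"]
    fr <- cm$dim1[cm$label == "free_rider"]
    all(sign(c(q1, q4, alt)) == sign(coop)) && sign(fr) != sign(coop)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # single-type data: centroid coincides with the origin
  ex <- simulate_experiment(seed = 9)
  one_type <- ex$types
  one_type$type <- "cooperator"
  sol <- fit_mca(build_indicator(ex$questionnaire))
  cm <- category_map(sol, one_type)
  cent <- cm[cm$kind == "type_centroid", ]
  expect_lt(max(abs(c(cent$dim1, cent$dim2))), 1e-10)
})
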