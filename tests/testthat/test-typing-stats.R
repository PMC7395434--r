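test_that("two-way ANOVA matches hand-computed sums of squares", {
  # balanced 2 x 2 design (arm x size), 2 groups per cell, constant-rate
  # investments so each group's mean is known exactly
  groups <- list(
    c1 = matrix(2, 3, 10), c2 = matrix(0, 3, 10),
    c3 = matrix(2, 7, 10), c4 = matrix(4, 7, 10),
    t1 = matrix(4, 3, 10), t2 = matrix(2, 3, 10),
    t3 = matrix(2, 7, 10), t4 = matrix(0, 7, 10)
  )
  arms <- rep(c("control", "treatment"), each = 4)
  gameplay <- make_gameplay(groups, arms)
  out <- mean_investment_anova(gameplay)
  # oracle: balanced two-way ANOVA from the 8 cell observations
  y <- c(2, 0, 2, 4, 4, 2, 2, 0)
  a <- factor(arms)
  b <- factor(rep(c(3, 3, 7, 7), 2))
  grand <- mean(y)
  ss_a <- 4 * sum((tapply(y, a, mean) - grand)^2)
  ss_b <- 4 * sum((tapply(y, b, mean) - grand)^2)
  cell <- tapply(y, list(a, b), mean)
  ss_cells <- 2 * sum((cell - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((y - cell[cbind(as.character(a), as.character(b))])^2)
  f_a <- (ss_a / 1) / (ss_res / 4)
  f_b <- (ss_b / 1) / (ss_res / 4)
  f_ab <- (ss_ab / 1) / (ss_res / 4)
  expect_equal(out$sumsq, c(ss_a, ss_b, ss_ab, ss_res), tolerance = 1e-10)
  expect_equal(out$statistic[1:3], c(f_a, f_b, f_ab), tolerance = 1e-10)
  # degenerate data (zero residual variance) are refused
  same <- make_gameplay(
    list(g1 = matrix(2, 3, 10), g2 = matrix(2, 3, 10),
         g3 = matrix(2, 7, 10), g4 = matrix(2, 7, 10),
         g5 = matrix(2, 3, 10), g6 = matrix(2, 3, 10),
         g7 = matrix(2, 7, 10), g8 = matrix(2, 7, 10)),
    rep(c("control", "treatment"), each = 4)
  )
  expect_error(mean_investment_anova(same), "Residual variance")
  # an empty/underfilled cell is named
  expect_error(mean_investment_anova(gameplay[gameplay$group_id != "t4", ]),
               "fewer than 2")
})

test_that("clustering recovers well-separated archetypes perfectly", {
  mats <- c(
    replicate(10, matrix(0, 1, 10), simplify = FALSE),
    replicate(10, matrix(2, 1, 10), simplify = FALSE),
    replicate(10, matrix(4, 1, 10), simplify = FALSE)
  )
  names(mats) <- sprintf("g%02d", 1:30)
  gameplay <- make_gameplay(mats, rep("control", 30))
  cl <- cluster_players(gameplay)
  truth <- rep(c("free_rider", "cooperator", "altruist"), each = 10)
  expect_equal(cl$assignment$type, truth)
  # exactly three players -> singleton clusters
  three <- make_gameplay(
    list(a = matrix(0, 1, 10), b = matrix(2, 1, 10), c = matrix(4, 1, 10)),
    rep("control", 3)
  )
  cl3 <- cluster_players(three)
  expect_equal(as.numeric(table(cl3$assignment$cluster)), rep(1, 3))
  expect_error(cluster_players(three[three$player_id != "a_p01", ]),
               "at least 3")
  # label map is invariant to permuting player order
  shuffled <- withr::with_seed(1, gameplay[sample(nrow(gameplay)), ])
  cl_s <- cluster_players(shuffled)
  merged <- dplyr::left_join(cl$assignment, cl_s$assignment,
                             by = "player_id")
  expect_equal(merged$type.x, merged$type.y)
})

test_that("planted-type trends recover the generating parameters", {
  design <- experiment_design(
    arms = tibble::tibble(
      arm = c("control", "treatment"), group_size = 11L, n_groups = 30L
    )
  )
  ex <- simulate_experiment(design, seed = 77)
  tr <- type_trends(ex$gameplay, ex$types)
  params <- default_type_params()
  z95 <- stats::qnorm(0.975)
  for (ty in params$type) {
    row <- tr$per_type[tr$per_type$type == ty, ]
    truth <- params[params$type == ty, ]
    # generating mean/slope within 3.5 Monte-Carlo standard errors
    se_mean <- (row$mean_high - row$mean_low) / (2 * z95)
    se_slope <- (row$slope_high - row$slope_low) / (2 * z95)
    expect_lt(abs(row$mean - truth$mean_investment), 3.5 * se_mean)
    expect_lt(abs(row$slope - truth$slope), 3.5 * se_slope)
  }
  expect_equal(tr$ancova$term,
               c("type", "round", "type:round", "Residuals"))
  expect_true(all(tr$ancova$statistic[1:2] > 10))
})

test_that("ANCOVA F ratios match a nested-RSS oracle on small data", {
  set.seed(42)
  small <- data.frame(
    player_id = rep(sprintf("p%02d", 1:5), each = 10),
    round = rep(1:10, 5),
    investment = sample(c(0, 2, 4), 50, replace = TRUE)
  )
  assignment <- data.frame(
    player_id = sprintf("p%02d", 1:5),
    type = c("a", "a", "b", "b", "b")
  )
  tr <- suppressWarnings(type_trends(small, assignment))
  y <- small$investment
  type <- assignment$type[match(small$player_id, assignment$player_id)]
  rss0 <- rss_oracle(design_cols(type, small$round, character(0)), y)
  rss1 <- rss_oracle(design_cols(type, small$round, "type"), y)
  rss2 <- rss_oracle(design_cols(type, small$round, c("type", "round")), y)
  rss3 <- rss_oracle(
    design_cols(type, small$round, c("type", "round", "type:round")), y
  )
  df_res <- 50 - 4
  ms_res <- rss3 / df_res
  f_oracle <- c((rss0 - rss1) / 1, (rss1 - rss2) / 1, (rss2 - rss3) / 1) /
    ms_res
  expect_equal(tr$ancova$statistic[1:3], f_oracle, tolerance = 1e-8)
})

test_that("constant investments give zero slope and a warning", {
  flat <- make_gameplay(
    list(g1 = matrix(2, 3, 10)), "control"
  )
  assignment <- data.frame(
    player_id = unique(flat$player_id), type = "cooperator"
  )
  w <- testthat::capture_warnings(tr <- type_trends(flat, assignment))
  expect_true(any(grepl("constant", w)))
  expect_equal(tr$per_type$slope, 0)
  expect_equal(tr$per_type$mean, 2)
})

test_that("multinomial intercepts equal log frequency ratios", {
  dat <- tibble::tibble(
    investment = rep(c(0, 2, 2, 4), 250),
    round = rep(1:10, 100)
  )
  fit <- multinomial_choice_model(dat, covariates = character(0))
  ints <- fit$coefficients$estimate[fit$coefficients$term == "(Intercept)"]
  expect_equal(ints, rep(log(0.25 / 0.5), 2), tolerance = 1e-4)
  # single-category data are flagged as separation
  expect_error(
    multinomial_choice_model(tibble::tibble(investment = rep(2, 50),
                                            round = rep(1:10, 5))),
    "separation"
  )
  expect_error(
    multinomial_choice_model(tibble::tibble(investment = c(1, 2),
                                            round = c(1, 2))),
    "menu"
  )
})

test_that("multinomial fit recovers known generating coefficients", {
  # generate choices from a known multinomial logit in round only
  b0 <- c(`0` = -0.4, `4` = -0.8)   # intercepts vs reference 2
  b1 <- c(`0` = 0.15, `4` = -0.10)  # round (centred) coefficients
  n <- 4000
  dat <- withr::with_seed(9, {
    round <- sample(1:10, n, replace = TRUE)
    rc <- round - 5.5
    e0 <- exp(b0[["0"]] + b1[["0"]] * rc)
    e4 <- exp(b0[["4"]] + b1[["4"]] * rc)
    den <- 1 + e0 + e4
    u <- stats::runif(n)
    inv <- ifelse(u < e0 / den, 0, ifelse(u < (e0 + e4) / den, 4, 2))
    tibble::tibble(investment = inv, round = round)
  })
  fit <- multinomial_choice_model(dat, covariates = "round")
  co <- fit$coefficients
  for (oc in c("0", "4")) {
    for (tm in c("(Intercept)", "round_c")) {
      truth <- if (tm == "(Intercept)") b0[[oc]] else b1[[oc]]
      row <- co[co$outcome == oc & co$term == tm, ]
      expect_lt(abs(row$estimate - truth), 3.5 * row$std.error)
    }
  }
  expect_gt(glance(fit)$n, 0)
})

test_that("the exact binomial tail behaves at the boundaries", {
  expect_equal(q5_binomial_test(10, 10)$p_value, 0.5^10)
  expect_gt(q5_binomial_test(5, 10)$p_value, 0.5)
  expect_equal(q5_binomial_test(0, 10)$p_value, 1)
  # the reconstructed Q5 count: 60.6% of 870 answers
  res <- q5_binomial_test(527, 870)
  expect_equal(res$proportion, 527 / 870)
  expect_lt(res$p_value, 1e-6)
  expect_error(q5_binomial_test(11, 10), "0..n")
})
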