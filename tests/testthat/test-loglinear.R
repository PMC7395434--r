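toy_table <- function() {
  arr <- array(
    c(10, 3, 4, 7, 2, 9, 8, 5),
    dim = c(2, 2, 2),
    dimnames = list(arm = c("control", "treatment"),
                    success = c("no", "yes"),
                    size = c("3", "7"))
  )
  arr
}

test_that("success_table counts each group once with zero-filled cells", {
  ex <- simulate_experiment(seed = 1)
  ct <- success_table(ex$gameplay)
  expect_equal(sum(ct$n), 53)
  expect_equal(nrow(ct), 12)  # 2 arms x 2 outcomes x 3 sizes
  arr <- contingency_array(ct)
  expect_equal(dim(arr), c(2, 2, 3))
  expect_equal(sum(arr), 53)
  # an all-fair dataset is all-success
  fair <- make_gameplay(
    list(g1 = matrix(2, 3, 10), g2 = matrix(2, 3, 10)),
    arms = c("control", "treatment")
  )
  ctf <- success_table(fair)
  expect_equal(sum(ctf$n[ctf$success]), 2)
  expect_equal(sum(ctf$n[!ctf$success]), 0)
  # incomplete groups are rejected
  expect_error(success_table(fair[fair$round <= 9, ]), "incomplete")
  # empty input gives an all-zero table
  expect_equal(sum(success_table(fair[0, ])$n), 0)
})

test_that("the model family is the standard 9-model hierarchy", {
  models <- loglinear_models()
  expect_length(models, 9)
  n_terms <- vapply(models, length, integer(1))
  expect_equal(unname(n_terms),
               c(3, 2, 2, 2, 2, 2, 2, 3, 1))
})

test_that("saturated fit reproduces any table exactly", {
  arr <- toy_table()
  fit <- fit_loglinear(arr, "saturated")
  expect_equal(fit$fitted, arr, tolerance = 1e-10)
  expect_equal(fit$g2, 0, tolerance = 1e-10)
  expect_equal(fit$df, 0)
})

test_that("mutual independence is exact on an outer-product table", {
  pa <- c(0.3, 0.7); pb <- c(0.6, 0.4); pc <- c(0.2, 0.3, 0.5)
  arr <- array(outer(outer(pa, pb), pc) * 1000,
               dim = c(2, 2, 3),
               dimnames = list(arm = c("control", "treatment"),
                               success = c("no", "yes"),
                               size = c("3", "7", "11")))
  fit <- fit_loglinear(arr, "mutual_independence")
  expect_equal(fit$g2, 0, tolerance = 1e-8)
})

test_that("IPF agrees with the brute-force oracle on the toy table", {
  arr <- toy_table()
  margins <- list(c("arm", "success"), c("success", "size"))
  oracle_fit <- ipf_oracle(arr, margins)
  fit <- fit_loglinear(arr, "cond_arm.size_given_success")
  expect_equal(fit$fitted, oracle_fit, tolerance = 1e-8)
  expect_equal(fit$g2, g2_oracle(arr, oracle_fit), tolerance = 1e-8)
  # closed form for this model: fit[a,s,z] = n[a,s,+] n[+,s,z] / n[+,s,+]
  closed <- arr
  for (a in 1:2) for (s in 1:2) for (z in 1:2) {
    closed[a, s, z] <- sum(arr[a, s, ]) * sum(arr[, s, z]) / sum(arr[, s, ])
  }
  expect_equal(fit$fitted, closed, tolerance = 1e-8)
})

test_that("every included margin of every fitted model matches observed", {
  ex <- simulate_experiment(seed = 2)
  arr <- contingency_array(success_table(ex$gameplay))
  fits <- fit_all_loglinear(arr)
  dims <- names(dimnames(arr))
  for (f in fits) {
    for (m in f$margins) {
      idx <- match(m, dims)
      expect_equal(apply(f$fitted, idx, sum), apply(arr, idx, sum),
                   tolerance = 1e-10)
    }
  }
})

test_that("deviance is non-increasing along nested model chains", {
  ex <- simulate_experiment(seed = 3)
  fits <- fit_all_loglinear(success_table(ex$gameplay))
  g2 <- vapply(fits, function(f) f$g2, numeric(1))
  chains <- list(
    c("mutual_independence", "joint_arm.success",
      "cond_success.size_given_arm", "homogeneous_association", "saturated"),
    c("mutual_independence", "joint_success.size",
      "cond_arm.size_given_success", "homogeneous_association", "saturated"),
    c("mutual_independence", "joint_arm.size",
      "cond_arm.success_given_size", "homogeneous_association", "saturated")
  )
  for (chain in chains) {
    expect_true(all(diff(g2[chain]) <= 1e-9))
  }
})

test_that("selection picks the most parsimonious adequate model", {
  # independence-structured data select mutual independence
  pa <- c(0.4, 0.6); pb <- c(0.5, 0.5); pc <- c(0.3, 0.3, 0.4)
  indep <- array(outer(outer(pa, pb), pc) * 600,
                 dim = c(2, 2, 3),
                 dimnames = list(arm = c("control", "treatment"),
                                 success = c("no", "yes"),
                                 size = c("3", "7", "11")))
  sel <- select_loglinear(fit_all_loglinear(indep))
  expect_equal(as.character(sel), "mutual_independence")
  # all three two-way associations strong -> homogeneous or saturated
  arr <- array(c(200, 10, 10, 100, 20, 120, 150, 30),
               dim = c(2, 2, 2),
               dimnames = list(arm = c("control", "treatment"),
                               success = c("no", "yes"),
                               size = c("3", "7")))
  sel2 <- select_loglinear(fit_all_loglinear(arr))
  expect_true(as.character(sel2) %in% c("homogeneous_association", "saturated"))
  ranking <- attr(sel2, "ranking")
  expect_equal(nrow(ranking), 9)
  expect_true(all(diff(ranking$df) <= 0))
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_loglinear(toy_table(), "homogeneous_association")
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_named(td, c("arm", "success", "size", "observed", "fitted",
                     "residual"))
  expect_equal(sum(td$fitted), sum(toy_table()), tolerance = 1e-8)
  gl <- glance(fit)
  expect_equal(gl$df, 1)
  expect_gte(gl$g2, 0)
})
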