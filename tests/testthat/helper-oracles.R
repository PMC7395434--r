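# Independent oracles used to cross-check the package's implementations.

# Brute-force iterative proportional fitting for a 3-way array, written
# directly from the IPF update rule (no stats::loglin).
ipf_oracle <- function(obs, margins, tol = 1e-12, max_iter = 1000) {
  fit <- array(sum(obs) / length(obs), dim = dim(obs), dimnames = dimnames(obs))
  dims <- names(dimnames(obs))
  for (it in seq_len(max_iter)) {
    before <- fit
    for (m in margins) {
      idx <- match(m, dims)
      obs_m <- apply(obs, idx, sum)
      fit_m <- apply(fit, idx, sum)
      ratio <- obs_m / fit_m
      ratio[fit_m == 0] <- 0
      # expand the margin ratio back over the full array
      perm <- c(idx, setdiff(seq_along(dims), idx))
      full <- array(rep(ratio, times = prod(dim(obs)[-idx])),
                    dim = dim(obs)[perm])
      fit <- fit * aperm(full, order(perm))
    }
    if (max(abs(fit - before)) < tol) break
  }
  fit
}

g2_oracle <- function(obs, fit) {
  nz <- obs > 0
  2 * sum(obs[nz] * log(obs[nz] / fit[nz]))
}

# Ordinary least squares by normal equations on an explicitly built design
# matrix; returns the residual sum of squares. Used to verify ANCOVA F ratios
# through nested-model RSS comparisons without going through lm/anova.
rss_oracle <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}

# Design-matrix builders for the ANCOVA oracle (treatment-contrast dummies).
design_cols <- function(type, round, terms) {
  lv <- sort(unique(type))
  X <- matrix(1, length(type), 1)
  if ("type" %in% terms) {
    for (l in lv[-1]) X <- cbind(X, as.numeric(type == l))
  }
  if ("round" %in% terms) X <- cbind(X, round)
  if ("type:round" %in% terms) {
    for (l in lv[-1]) X <- cbind(X, as.numeric(type == l) * round)
  }
  X
}

# Build a valid long gameplay table from a named list of player-by-round
# investment matrices, one per group.
make_gameplay <- function(groups, arms, endowment = 40) {
  rows <- lapply(seq_along(groups), function(i) {
    inv <- groups[[i]]
    gid <- names(groups)[i]
    do.call(rbind, lapply(seq_len(nrow(inv)), function(p) {
      data.frame(
        session_id = paste0("s_", arms[i]),
        arm = arms[i],
        group_id = gid,
        group_size = nrow(inv),
        round = seq_len(ncol(inv)),
        player_id = sprintf("%s_p%02d", gid, p),
        investment = inv[p, ],
        capital_after = endowment - cumsum(inv[p, ])
      )
    }))
  })
  tibble::as_tibble(do.call(rbind, rows))
}
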