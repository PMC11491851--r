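# Shared fixtures and independent oracles used across the suite.

# small simulation used by property tests (kept well below the study-scale
# defaults so many seeds stay cheap)
small_cfg <- function(seed = 1, ...) {
  args <- list(
    n_runs_per_participant = 3,
    n_gaming_per_block = 24,
    n_neutral_per_block = 12,
    volumes_per_run = 160,
    n_voxels = 40,
    n_informative_voxels = 6,
    n_dead_voxels = 2,
    n_noisy_voxels = 2,
    seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# hand-rolled run_series (raw by default)
toy_run <- function(data, tr_s = 1.75, blocks = NULL, participant = "sub01",
                    run = 1, normalized = FALSE, retained = NULL) {
  if (is.null(blocks)) {
    blocks <- tibble::tibble(block = 1L, start = 0L, end = ncol(data))
  }
  side <- ceiling(nrow(data)^(1 / 3))
  coords <- arrayInd(seq_len(nrow(data)), .dim = c(side, side, side))
  decabt:::new_run_series(data, tr_s, blocks, coords, participant, run,
                          normalized = normalized, retained = retained)
}

# hand-rolled feature set
toy_features <- function(X, y, run, direction = rep("approach", nrow(X)),
                         condition = "gaming", participant = "sub01") {
  meta <- tibble::tibble(
    participant_id = participant, run = run, block = run,
    trial = seq_len(nrow(X)), condition = condition, direction = direction,
    label = ifelse(y == 1, "positive", "negative"), y = as.integer(y)
  )
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  decabt:::new_bias_features(X, meta, seq_len(ncol(X)), shift_tr = 3)
}

# Brute-force trial labeller written directly from the baseline rule:
# positive iff an approach trial is faster than the block's neutral approach
# mean, or an avoidance trial slower than the neutral avoidance mean; the
# strict opposite is negative; ties and undefined baselines are excluded.
oracle_label_gaming <- function(trials) {
  out <- character(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (tr$condition != "gaming") { out[i] <- NA_character_; next }
    if (tr$valid != 1) { out[i] <- "excluded"; next }
    neut <- trials[trials$participant_id == tr$participant_id &
                     trials$run == tr$run & trials$block == tr$block &
                     trials$condition == "neutral" &
                     trials$direction == tr$direction & trials$valid == 1, ]
    if (nrow(neut) == 0) { out[i] <- "excluded"; next }
    bl <- mean(neut$rt_ms)
    if (tr$rt_ms == bl) {
      out[i] <- "excluded"
    } else if (tr$direction == "approach") {
      out[i] <- if (tr$rt_ms < bl) "positive" else "negative"
    } else {
      out[i] <- if (tr$rt_ms > bl) "positive" else "negative"
    }
  }
  out
}

# Independent Laplace-evidence oracle for Bayesian logistic regression at
# fixed prior precisions: plain (undamped) Newton to the MAP, then
# log evidence = loglik(w) - w'Aw/2 + log det(A)/2 - log det(H)/2.
oracle_evidence <- function(X, y, alphas, intercept_alpha = 1e-6,
                            n_newton = 100) {
  X1 <- cbind(1, X)
  a <- c(intercept_alpha, alphas)
  w <- numeric(ncol(X1))
  for (i in seq_len(n_newton)) {
    eta <- drop(X1 %*% w)
    mu <- plogis(eta)
    g <- drop(crossprod(X1, y - mu)) - a * w
    H <- crossprod(X1, X1 * (mu * (1 - mu))) + diag(a, length(a))
    step <- solve(H, g)
    w <- w + step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- drop(X1 %*% w)
  mu <- plogis(eta)
  ll <- sum(y * eta - log1p(exp(eta)))
  H <- crossprod(X1, X1 * (mu * (1 - mu))) + diag(a, length(a))
  ll - 0.5 * sum(a * w^2) + 0.5 * sum(log(a)) - 0.5 * determinant(H)$modulus[1]
}

# features with k class-conditionally independent informative columns
# (standardized mean separation `effect`) among p columns
informative_design <- function(n, p, k, effect = 1, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  while (min(table(factor(y, levels = 0:1))) < 2) y <- rbinom(n, 1, 0.5)
  X <- matrix(rnorm(n * p), n, p)
  X[, seq_len(k)] <- X[, seq_len(k)] + outer(ifelse(y == 1, effect / 2, -effect / 2),
                                             rep(1, k))
  list(X = X, y = y)
}

expect_tibble_equal <- function(a, b, tolerance = 1e-12) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b),
                         tolerance = tolerance)
}
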