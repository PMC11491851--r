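sep_features <- function(n_per_run = 16, runs = 3, p = 4, effect = 3,
                         seed = 1, direction_mode = "mixed") {
  set.seed(seed)
  purrr::map(seq_len(runs), function(r) {
    y <- rep(c(0, 1), n_per_run / 2)
    X <- matrix(rnorm(n_per_run * p, sd = 1), n_per_run, p)
    X[, 1] <- X[, 1] + ifelse(y == 1, effect / 2, -effect / 2)
    dir <- switch(direction_mode,
      mixed = rep(c("approach", "avoidance"), each = n_per_run / 2),
      approach = rep("approach", n_per_run)
    )
    toy_features(X, y, run = r, direction = dir)
  }) |> merge_feature_sets()
}

merge_feature_sets <- function(sets) {
  X <- do.call(rbind, lapply(sets, `[[`, "X"))
  meta <- dplyr::bind_rows(lapply(sets, `[[`, "meta"))
  decabt:::new_bias_features(X, meta, sets[[1]]$voxel_ids, sets[[1]]$shift_tr)
}

test_that("balancing resamples draw equal class counts without replacement", {
  set.seed(1)
  for (i in 1:20) {
    pos <- sample(1000, sample(5:40, 1))
    neg <- setdiff(sample(1000, sample(5:40, 1)), pos)
    bal <- decabt:::balance_downsample(pos, neg)
    got_pos <- sum(bal %in% pos)
    got_neg <- sum(bal %in% neg)
    expect_equal(got_pos, got_neg)
    expect_equal(got_pos, min(length(pos), length(neg)))
    expect_equal(anyDuplicated(bal), 0)
  }
})

test_that("with balanced classes downsampling is a no-op and resamples agree", {
  f <- sep_features(seed = 2)
  cv <- loro_cv(f, n_resamples = 3, seed = 7)
  per <- cv$per_fold
  spread <- per |>
    dplyr::group_by(fold) |>
    dplyr::summarise(d = diff(range(accuracy)))
  expect_true(all(spread$d == 0))
})

test_that("separable synthetic data decodes almost perfectly, permuted labels at chance", {
  cfg <- small_cfg(seed = 51, signal_effect = 1.5)
  sim <- simulate_trials(cfg)
  runs <- simulate_run_series(sim)
  trials <- filter_trials(sim$trials)
  lab <- label_trials(trials, block_baselines(trials), "gaming")
  f <- build_features(runs, lab)
  cv <- loro_cv(f, n_resamples = 3, seed = 5)
  expect_gt(cv$accuracy, 0.9)
  # aggregate really is the mean over folds of the mean over resamples
  agg <- cv$per_fold |>
    dplyr::group_by(fold) |>
    dplyr::summarise(a = mean(accuracy))
  expect_equal(cv$accuracy, mean(agg$a))
  expect_true(all(cv$per_fold$accuracy >= 0 & cv$per_fold$accuracy <= 1))
})

test_that("self-crossing equals leave-one-run-out with the same seed", {
  f <- sep_features(seed = 3)
  a <- loro_cv(f, n_resamples = 2, seed = 11)
  b <- cross_condition_decode(f, f, n_resamples = 2, seed = 11)
  expect_equal(a$accuracy, b$accuracy)
  expect_identical(a$per_trial, b$per_trial)
})

test_that("condition crossings expose which condition carries signal", {
  # gaming features carry signal, neutral features are noise with the same
  # voxel space and runs
  gaming <- sep_features(seed = 4, effect = 3)
  set.seed(99)
  neutral <- merge_feature_sets(purrr::map(1:3, function(r) {
    y <- rep(c(0, 1), 8)
    toy_features(matrix(rnorm(16 * 4), 16, 4), y, run = r,
                 direction = rep(c("approach", "avoidance"), each = 8),
                 condition = "neutral")
  }))
  grid <- decode_condition_grid(gaming, neutral, n_resamples = 2, seed = 21)
  expect_equal(grid$condition,
               c("gaming", "gaming->neutral", "neutral", "neutral->gaming"))
  expect_equal(nrow(grid), 4)
  acc <- setNames(grid$accuracy, grid$condition)
  expect_gt(acc["gaming"], acc["neutral->gaming"])
  expect_gt(acc["gaming"], 0.85)
  expect_lt(acc["neutral"], 0.75)
})

test_that("direction-split accuracies reconstruct the pooled accuracy", {
  # avoidance trials separable, approach trials pure noise
  set.seed(6)
  f <- merge_feature_sets(purrr::map(1:3, function(r) {
    y <- rep(c(0, 1), 10)
    X <- matrix(rnorm(20 * 3), 20, 3)
    avoid <- 11:20
    X[avoid, 1] <- ifelse(y[avoid] == 1, 2.5, -2.5) + rnorm(10, sd = 0.3)
    toy_features(X, y, run = r,
                 direction = rep(c("approach", "avoidance"), each = 10))
  }))
  cv <- loro_cv(f, n_resamples = 2, seed = 31)
  ds <- direction_split_accuracy(cv)
  expect_gt(ds$accuracy[ds$direction == "avoidance"],
            ds$accuracy[ds$direction == "approach"])
  overall <- attr(ds, "overall")
  expect_equal(overall,
               sum(ds$n * ds$accuracy) / sum(ds$n))
  # all-correct degenerate case
  cv2 <- cv
  cv2$per_trial$correct <- TRUE
  ds2 <- direction_split_accuracy(cv2)
  expect_equal(ds2$accuracy, c(1, 1))
})

test_that("group tests mirror the BH step-up rule over the declared family", {
  # 7 ROIs x 4 conditions with 8 participants each: family of 28 tests
  set.seed(12)
  cells <- tidyr::expand_grid(roi = paste0("roi", 1:7),
                              condition = c("gaming", "gaming->neutral",
                                            "neutral", "neutral->gaming"))
  acc <- tidyr::expand_grid(cells, participant_id = paste0("s", 1:8)) |>
    dplyr::mutate(accuracy = 0.5 + rnorm(dplyr::n(), sd = 0.06) +
                    ifelse(roi == "roi1" & condition == "gaming", 0.12, 0))
  gt <- group_tests(acc)
  expect_equal(nrow(gt), 28)
  # brute-force step-up on the raw p values
  m <- nrow(gt)
  ord <- order(gt$p)
  stepped <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, gt$p[ord[i]] * m / i)
    stepped[ord[i]] <- prev
  }
  expect_equal(gt$p_fdr, stepped, tolerance = 1e-12)
  expect_true(all(gt$p_fdr >= gt$p - 1e-15))
})

test_that("degenerate accuracy vectors yield t = 0 or NA, not errors", {
  acc <- tibble::tibble(participant_id = paste0("s", 1:6), roi = "r1",
                        condition = "gaming", accuracy = 0.5)
  gt <- group_tests(acc)
  expect_equal(gt$t, 0)
  expect_equal(gt$p, 1)
  acc$accuracy <- 0.6
  gt2 <- group_tests(acc)
  expect_true(is.na(gt2$t))
  expect_error(group_tests(acc[1, ]), "2 participants")
})

test_that("one-sample t vs chance keeps its nominal type-I rate on null data", {
  set.seed(42)
  n_sims <- 500
  rejections <- vapply(seq_len(n_sims), function(i) {
    acc <- tibble::tibble(
      participant_id = paste0("s", 1:15),
      accuracy = rbinom(15, 40, 0.5) / 40
    )
    gt <- group_tests(acc)
    !is.na(gt$p) && gt$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.025)
  expect_lte(rate, 0.075)
})

test_that("the bootstrap subsample test matches its exhaustive enumeration", {
  a <- c(1, 3, 5, 7)
  b <- c(3.9, 4.1)
  ex <- bootstrap_balance_test(a, b, n_sub = 2, method = "exhaustive")
  # enumeration of all 6 subsets of size 2: means 2,3,4,4,5,6 minus mean(b)=4
  stats <- combn(4, 2, function(ix) mean(a[ix]) - 4)
  expect_equal(ex$n_draws, 6)
  expect_equal(ex$p_value, min(1, 2 * min(sum(stats <= 0), sum(stats >= 0)) / 6))
  # resampling agrees within Monte-Carlo error
  rs <- bootstrap_balance_test(a, b, n_sub = 2, B = 4000, seed = 2)
  expect_lt(abs(rs$p_value - ex$p_value), 0.05)
})

test_that("bootstrap p-values hit the null and extreme regimes", {
  vals <- c(0.52, 0.48, 0.55, 0.45, 0.5, 0.53, 0.47)
  null_p <- bootstrap_balance_test(vals, vals, n_sub = 4, B = 2000, seed = 3)
  expect_gt(null_p$p_value, 0.5)
  a <- 10:16
  b <- 1:3
  extreme <- bootstrap_balance_test(a, b, n_sub = 3, B = 2000, seed = 4)
  expect_equal(extreme$p_value, 1 / 2001)
  expect_error(bootstrap_balance_test(1:3, 1:2, n_sub = 5), "exceeds")
})

test_that("decoding accuracy rises with the planted signal effect", {
  acc_at <- function(effect, seed) {
    cfg <- small_cfg(seed = seed, signal_effect = effect)
    sim <- simulate_trials(cfg)
    runs <- simulate_run_series(sim)
    trials <- filter_trials(sim$trials)
    lab <- label_trials(trials, block_baselines(trials), "gaming")
    loro_cv(build_features(runs, lab), n_resamples = 1, seed = seed)$accuracy
  }
  grid <- vapply(c(0, 0.6, 1.5), function(e) {
    mean(vapply(1:20, function(s) acc_at(e, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(grid) >= 0))
  expect_gt(grid[3] - grid[1], 0.1)
})

test_that("search-ROI sweeps localize a planted signal and report dead regions", {
  cfg <- small_cfg(seed = 61, n_voxels = 64, n_informative_voxels = 6,
                   n_dead_voxels = 8, n_noisy_voxels = 0)
  sim <- simulate_trials(cfg)
  parc <- simulate_parcellation(c(4, 4, 4), n_regions = 8, seed = 2)
  # voxel v sits at lattice coordinate arrayInd(v): plant informative voxels
  # inside region 3 and dead voxels covering all of region 5
  lab_of <- as.vector(parc)
  r3 <- which(lab_of == 3)
  r5 <- which(lab_of == 5)
  sim$truth$informative_voxel_ids <- r3[seq_len(min(6, length(r3)))]
  sim$truth$dead_voxel_ids <- r5
  sim$truth$noisy_voxel_ids <- integer(0)
  runs <- simulate_run_series(sim)
  trials <- filter_trials(sim$trials)
  lab <- label_trials(trials, block_baselines(trials), "gaming")
  sweep <- search_roi_sweep(runs, lab, parc, n_resamples = 1, seed = 9)
  expect_equal(nrow(sweep), 8)
  expect_false(sweep$decodable[sweep$region == 5])
  dec <- sweep[sweep$decodable, ]
  expect_equal(dec$region[which.max(dec$accuracy)], 3)

  # a single-region parcellation reproduces whole-mask decoding
  one <- search_roi_sweep(runs, lab, rep(1L, cfg$n_voxels),
                          n_resamples = 1, seed = 9)
  whole <- loro_cv(build_features(runs, lab), n_resamples = 1, seed = 9)
  expect_equal(one$accuracy, whole$accuracy)
})
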