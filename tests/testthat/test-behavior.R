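make_trials <- function(rt, condition, direction, participant = "p1",
                        run = 1L, block = 1L, valid = 1L) {
  tibble::tibble(
    participant_id = participant, run = run, block = block,
    trial = seq_along(rt), condition = condition, direction = direction,
    rt_ms = rt, onset_volume = 14L + (seq_along(rt) - 1L) * 4L,
    iti_onset_volume = 12L + (seq_along(rt) - 1L) * 4L,
    response_correct = TRUE, valid = valid
  )
}

test_that("trial filters catch anticipations, misses and slow outliers", {
  tr <- make_trials(c(100, rep(500, 5)), "gaming", rep(c("approach", "avoidance"), 3))
  out <- filter_trials(tr)
  expect_equal(out$valid[1], 0L)
  expect_equal(out$filter_reason[1], "rt_below_floor")

  tr$rt_ms[2] <- NA
  tr$response_correct[3] <- FALSE
  out <- filter_trials(tr)
  expect_equal(out$filter_reason[2:3], c("bad_response", "bad_response"))

  # 10 RTs with one far above the others' mean + 4 s.d.: exactly that one goes
  x9 <- c(480, 490, 495, 500, 505, 510, 515, 520, 525)
  outlier <- mean(x9) + 4 * sd(x9)
  tr10 <- make_trials(c(x9, outlier), "gaming", rep("approach", 10))
  out <- filter_trials(tr10)
  expect_equal(sum(out$valid == 0), 1L)
  expect_equal(out$filter_reason[10], "rt_outlier")
})

test_that("filtering is idempotent and a no-op on clean tables", {
  tr <- make_trials(c(400, 450, 500, 550, 600, 480),
                    rep(c("gaming", "neutral"), 3),
                    rep(c("approach", "avoidance"), 3))
  once <- filter_trials(tr)
  expect_equal(once$valid, rep(1L, 6))
  twice <- filter_trials(once)
  expect_identical(once, twice)
  # with an outlier present, a second pass changes nothing either
  tr10 <- make_trials(c(480, 490, 495, 500, 505, 510, 515, 520, 525, 800),
                      "gaming", rep("approach", 10))
  once <- filter_trials(tr10)
  expect_identical(once, filter_trials(once))
})

test_that("block baselines are per-direction neutral means and degrade to NA", {
  tr <- dplyr::bind_rows(
    make_trials(c(500, 600), "neutral", c("approach", "approach")),
    make_trials(c(520, 580, 640), "neutral", rep("avoidance", 3)),
    make_trials(c(450), "gaming", "approach")
  )
  tr$trial <- seq_len(nrow(tr))
  bl <- block_baselines(tr)
  expect_equal(bl$BL_app, 550)
  expect_equal(bl$BL_avo, mean(c(520, 580, 640)))
  expect_equal(bl$n_app, 2L)
  expect_equal(bl$n_avo, 3L)

  no_avo <- make_trials(c(500, 510), "neutral", c("approach", "approach"))
  bl2 <- block_baselines(no_avo)
  expect_true(is.na(bl2$BL_avo))
  expect_equal(bl2$n_avo, 0L)
})

test_that("the labelling rule follows the baseline comparisons exactly", {
  tr <- dplyr::bind_rows(
    make_trials(c(550, 600), "neutral", c("approach", "avoidance")),
    make_trials(c(500, 650, 550, 560, 590), "gaming",
                c("approach", "avoidance", "approach", "avoidance", "avoidance"))
  )
  tr$trial <- seq_len(nrow(tr))
  bl <- block_baselines(tr)
  lab <- label_trials(tr, bl, "gaming")
  # approach 500 < BL_app 550 -> positive; avoidance 650 > BL_avo 600 -> positive
  expect_equal(lab$label[lab$rt_ms == 500], "positive")
  expect_equal(lab$label[lab$rt_ms == 650], "positive")
  # tie with the baseline is excluded, not assigned
  expect_equal(lab$label[lab$rt_ms == 550], "excluded")
  expect_equal(lab$exclusion_reason[lab$rt_ms == 550], "tie_with_baseline")
  # avoidance 560 < 600 -> negative
  expect_equal(lab$label[lab$rt_ms == 560], "negative")
  expect_equal(lab$deviation_ms[lab$rt_ms == 590], -10)
})

test_that("an undefined baseline excludes trials instead of erroring", {
  tr <- dplyr::bind_rows(
    make_trials(c(550), "neutral", "approach"),
    make_trials(c(500, 650), "gaming", c("approach", "avoidance"))
  )
  tr$trial <- seq_len(nrow(tr))
  lab <- label_trials(tr, block_baselines(tr), "gaming")
  expect_equal(lab$label[lab$direction == "avoidance"], "excluded")
  expect_equal(lab$exclusion_reason[lab$direction == "avoidance"],
               "undefined_baseline")
})

test_that("labels agree with a brute-force re-derivation on random small tables", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(8:20, 1)
    tr <- make_trials(round(runif(n, 350, 800)),
                      sample(c("gaming", "neutral"), n, replace = TRUE,
                             prob = c(0.6, 0.4)),
                      sample(c("approach", "avoidance"), n, replace = TRUE))
    lab <- label_trials(tr, block_baselines(tr), "gaming")
    oracle <- oracle_label_gaming(tr)
    got <- lab$label[order(lab$trial)]
    expect_equal(got, oracle[tr$condition == "gaming"])
  }
})

test_that("every valid gaming trial with a baseline is labelled exactly once with coherent signs", {
  sim <- simulate_trials(small_cfg(seed = 9))
  trials <- filter_trials(sim$trials)
  lab <- label_trials(trials, block_baselines(trials), "gaming")
  valid_gaming <- sum(trials$condition == "gaming" & trials$valid == 1)
  expect_equal(nrow(lab), sum(sim$trials$condition == "gaming"))
  expect_equal(sum(lab$label %in% c("positive", "negative", "excluded")
                   & lab$valid == 1), valid_gaming)
  pos <- lab[lab$label == "positive", ]
  neg <- lab[lab$label == "negative", ]
  expect_true(all(pos$deviation_ms[pos$direction == "approach"] < 0))
  expect_true(all(pos$deviation_ms[pos$direction == "avoidance"] > 0))
  expect_true(all(neg$deviation_ms[neg$direction == "approach"] > 0))
  expect_true(all(neg$deviation_ms[neg$direction == "avoidance"] < 0))
})

test_that("the fake index reuses the neutral baselines, optionally leave-one-out", {
  tr <- dplyr::bind_rows(
    make_trials(c(500, 540, 560, 600), "neutral",
                c("approach", "approach", "avoidance", "avoidance")),
    make_trials(c(450), "gaming", "approach")
  )
  tr$trial <- seq_len(nrow(tr))
  bl <- block_baselines(tr)
  fake <- label_trials(tr, bl, "neutral")
  expect_true(all(fake$index_kind == "fake"))
  # self-inclusive baseline: deviations within a block/direction sum to zero
  expect_equal(sum(fake$deviation_ms[fake$direction == "approach"]), 0)
  # leave-one-out variant compares each trial to the *other* neutral trials
  loo <- label_trials(tr, bl, "neutral", fake_loo = TRUE)
  expect_equal(loo$deviation_ms[loo$rt_ms == 500], 500 - 540)
  expect_equal(loo$deviation_ms[loo$rt_ms == 560], 560 - 600)
})

test_that("split-half reliability applies the Spearman-Brown step-up", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)

  # five participants, two positive trials each: half means are the two
  # deviations, built so cor(half1, half2) = 0.5 exactly
  x <- c(-2, -1, 0, 1, 2)
  z <- c(1, -2, 0, 2, -1)      # orthogonal to x, same variance
  y <- x + sqrt(3) * z          # => cor(x, y) = 0.5
  lab <- purrr::map_dfr(1:5, function(i) {
    tibble::tibble(participant_id = paste0("p", i), run = 1L, block = 1L,
                   trial = 1:2, label = "positive",
                   deviation_ms = c(x[i], y[i]))
  })
  lab_neg <- dplyr::mutate(lab, label = "negative",
                           deviation_ms = rep(c(1, 2, 3, 4, 5), each = 2))
  rel <- split_half_reliability(dplyr::bind_rows(lab, lab_neg))
  pos <- rel[rel$label == "positive", ]
  expect_equal(pos$r_half, 0.5, tolerance = 1e-12)
  expect_equal(pos$rho_sb, 2 / 3, tolerance = 1e-12)
  # identical halves give perfect reliability
  neg <- rel[rel$label == "negative", ]
  expect_equal(neg$r_half, 1)
  expect_equal(neg$rho_sb, 1)
})

test_that("split-half reliability degrades loudly on inadequate input", {
  lab <- tibble::tibble(participant_id = c("p1", "p2"), run = 1L, block = 1L,
                        trial = 1L, label = "positive", deviation_ms = c(1, 2))
  expect_error(suppressWarnings(split_half_reliability(lab)),
               ">= 3 participants")
  # a participant with a single positive trial lacks a second half
  lab3 <- purrr::map_dfr(1:4, function(i) {
    k <- if (i == 4) 1 else 4
    tibble::tibble(participant_id = paste0("p", i), run = 1L, block = 1L,
                   trial = seq_len(k), label = "positive",
                   deviation_ms = seq_len(k) * i)
  })
  lab3_neg <- purrr::map_dfr(1:4, function(i) {
    tibble::tibble(participant_id = paste0("p", i), run = 1L, block = 1L,
                   trial = 1:4, label = "negative", deviation_ms = (1:4) * i)
  })
  expect_warning(split_half_reliability(dplyr::bind_rows(lab3, lab3_neg)),
                 "lack")
})
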