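test_that("log2 fold changes are fold changes of replicate means vs 0 min", {
  tc <- make_tc(list(
    up = list(WT = trace_reps(c(10, 15, 10, 10, 10)), OB = flat_reps(10)),
    flat = list(WT = flat_reps(4), OB = flat_reps(4)),
    down = list(WT = trace_reps(c(10, 5, 10, 10, 10)), OB = flat_reps(10))))
  fc <- log2_fold_changes(tc)
  pick <- function(id, g, t) fc$log2fc[fc$molecule_id == id & fc$genotype == g & fc$time == t]
  expect_equal(pick("up", "WT", 20), 0.585, tolerance = 1e-3)  # 1.5-fold
  expect_equal(pick("flat", "WT", 60), 0)
  expect_equal(pick("down", "WT", 20), -1)
})

test_that("zero baselines flag fold changes as undefined", {
  tc <- make_tc(list(z = list(WT = trace_reps(c(0, 5, 5, 5, 5)), OB = flat_reps(3))))
  fc <- log2_fold_changes(tc)
  expect_true(all(is.na(fc$log2fc[fc$genotype == "WT"])))
  expect_true(all(fc$log2fc[fc$genotype == "OB"] == 0))
})

test_that("responsiveness is the q AND fold-change conjunction at any time", {
  post <- c(20, 60, 120, 240)
  r <- call_responsiveness(c(0.2, 0.7, 0.1, 0.0), c(0.5, 0.05, 0.5, 0.5), post)
  expect_true(r$responsive)
  expect_equal(r$earliest_sig_time, 60)
  expect_equal(r$direction, "increase")
  # direction follows the earliest significant time, not the largest change
  r2 <- call_responsiveness(c(-0.8, 0.1, 0.9, 0.2), c(0.01, 0.5, 0.01, 0.5), post)
  expect_equal(r2$direction, "decrease")
  r3 <- call_responsiveness(c(0.2, 0.3, 0.1, 0.0), c(0.5, 0.2, 0.5, 0.5), post)
  expect_false(r3$responsive)
  expect_equal(r3$direction, "none")
  # boundary values count (<= and >=)
  r4 <- call_responsiveness(c(0.585, 0, 0, 0), c(0.1, 1, 1, 1), post)
  expect_true(r4$responsive)
  r5 <- call_responsiveness(c(0.584, 0, 0, 0), c(0.1, 1, 1, 1), post)
  expect_false(r5$responsive)
})

test_that("relaxing thresholds never revokes a responsive call", {
  set.seed(11)
  post <- c(20, 60, 120, 240)
  strict <- pipeline_config(q_threshold = 0.05, fc_threshold_log2 = 0.8)
  loose <- pipeline_config(q_threshold = 0.2, fc_threshold_log2 = 0.4)
  for (i in 1:50) {
    fc <- rnorm(4); q <- runif(4)
    a <- call_responsiveness(fc, q, post, strict)
    b <- call_responsiveness(fc, q, post, loose)
    if (a$responsive) expect_true(b$responsive)
  }
})

test_that("half-time interpolates the first crossing of half amplitude", {
  times <- c(0, 20, 60, 120, 240)
  # decreasing trace: amplitude -8, half level at -4, crossing in (20, 60)
  expect_equal(half_time(c(10, 10, 4, 2, 2), times, "decrease"),
               20 + (10 - 6) / (10 - 4) * 40, tolerance = 1e-12)
  expect_equal(half_time(c(10, 10, 4, 2, 2), times, "decrease"), 46.667,
               tolerance = 1e-3)
  # immediate plateau: crossing interpolated inside the first interval
  expect_equal(half_time(c(0, 100, 100, 100, 100), times, "increase"), 10)
  # linear ramp peaking at the last sample: T1/2 at mid-ramp
  expect_equal(half_time(c(0, 20, 60, 120, 240), times, "increase"), 120)
  expect_warning(ht <- half_time(c(5, 5, 5, 5, 5), times, "increase"), "flat")
  expect_true(is.na(ht))
})

test_that("half-time of monotone traces stays within the sampled window", {
  set.seed(12)
  times <- c(0, 20, 60, 120, 240)
  for (i in 1:50) {
    tr <- cumsum(c(0, runif(4)))
    ht <- half_time(tr, times, "increase")
    expect_gte(ht, 0)
    expect_lte(ht, 240)
  }
  # extremum already at the first post-baseline sample
  for (i in 1:20) {
    peak <- runif(1, 1, 5)
    tr <- c(0, peak, peak * runif(3, 0.2, 1))
    expect_lte(half_time(tr, times, "increase"), 20)
  }
})

test_that("speed classes use strict 20/60 cutoffs with boundaries intermediate", {
  expect_equal(speed_class(c(5, 19.99, 20, 45, 60, 60.01, NA)),
               c("rapid", "rapid", "intermediate", "intermediate",
                 "intermediate", "slow", "undefined"))
})

test_that("cross-genotype classes follow the four-way rule", {
  expect_equal(response_class(TRUE, "decrease", FALSE, "none"), "WT_specific")
  expect_equal(response_class(TRUE, "increase", TRUE, "increase"), "common")
  expect_equal(response_class(TRUE, "decrease", TRUE, "increase"), "opposite")
  expect_equal(response_class(FALSE, "none", TRUE, "decrease"), "OB_specific")
  expect_equal(response_class(FALSE, "none", FALSE, "none"), "none")
})

test_that("layer-level calls recover a deterministic planted responder", {
  # noiseless 2-fold increase in WT from 60 min on, flat OB; many flat
  # molecules with jitter keep the q machinery well behaved
  set.seed(13)
  mols <- list(hit = list(WT = trace_reps(c(10, 10, 20, 20, 20)) *
                            matrix(exp(rnorm(25, 0, 0.01)), 5, 5),
                          OB = flat_reps(10) * matrix(exp(rnorm(25, 0, 0.01)), 5, 5)))
  for (i in 1:30)
    mols[[paste0("bg", i)]] <- list(
      WT = flat_reps(8) * matrix(exp(rnorm(25, 0, 0.01)), 5, 5),
      OB = flat_reps(8) * matrix(exp(rnorm(25, 0, 0.01)), 5, 5))
  tc <- make_tc(mols)
  calls <- suppressMessages(responsiveness_calls(tc))
  hit_wt <- calls[calls$molecule_id == "hit" & calls$genotype == "WT", ]
  expect_true(hit_wt$responsive)
  expect_equal(hit_wt$direction, "increase")
  expect_equal(hit_wt$earliest_sig_time, 60)
  # half-level of the log2 step is crossed between 20 and 60 min
  expect_gt(hit_wt$t_half, 20); expect_lt(hit_wt$t_half, 60)
  expect_equal(hit_wt$speed, "intermediate")
  hit_ob <- calls[calls$molecule_id == "hit" & calls$genotype == "OB", ]
  expect_false(hit_ob$responsive)
  cmap <- response_class_map(calls)
  expect_equal(cmap$class[cmap$molecule_id == "hit"], "WT_specific")
})

test_that("null data keep the responsive-call rate near zero", {
  sim <- generate_timecourses(n_metabolites = 150, n_genes = 0, n_phospho = 0,
                              frac_responsive = c(metabolite = 0),
                              seed = 99)
  calls <- suppressMessages(responsiveness_calls(sim$timecourses$metabolite))
  rate <- mean(calls$responsive)
  expect_lte(rate, 0.1 + 3 * sqrt(0.1 * 0.9 / nrow(calls)))
})
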