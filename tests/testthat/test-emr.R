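test_that("exposure episodes span earliest start to latest end", {
  rx <- tibble::tibble(
    patient_id = "P1", drug = "d",
    start_date = c("2020-01-01", "2020-02-01"),
    end_date = c("2020-01-10", "2020-03-15"))
  ep <- build_exposure_episodes(rx)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start, as.Date("2020-01-01"))
  expect_equal(ep$end, as.Date("2020-03-15"))
  expect_equal(ep$duration_days, 74)
})

test_that("the 30-day exposure rule is inclusive and bad rows are rejected", {
  rx <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"), drug = "d",
    start_date = as.Date("2020-01-01"),
    end_date = as.Date("2020-01-01") + c(29, 30, -5))
  expect_warning(ep <- build_exposure_episodes(rx), "end < start")
  expect_equal(ep$patient_id, "P2")  # 29 days dropped, 30 kept
})

test_that("window means use half-open windows anchored at start and end", {
  ep <- tibble::tibble(patient_id = c("P1", "P2"), drug = "d",
                       start = as.Date("2020-06-01"),
                       end = as.Date("2020-08-01"), duration_days = 61L)
  labs <- tibble::tibble(
    patient_id = c("P1", "P1", "P1", "P1", "P1", "P2"),
    date = as.Date(c("2020-06-01",   # on start: belongs to neither window
                     "2020-03-01", "2020-04-01",  # pre
                     "2020-08-01",  # on end: not post (strictly after)
                     "2020-09-01",  # post
                     "2020-01-15")),# P2 has pre only -> excluded
    value = c(9, 0.2, 0.4, 9, 0.5, 0.3))
  wm <- window_means(ep, labs, window_days = 183)
  expect_equal(wm$patient_id, "P1")
  expect_equal(wm$pre_mean, 0.3)
  expect_equal(wm$post_mean, 0.5)
  expect_equal(wm$n_pre, 2)
  expect_equal(wm$n_post, 1)
  expect_error(window_means(ep, dplyr::mutate(labs, value = -1), 183),
               "non-negative")
})

test_that("the paired screen matches a textbook t computation", {
  d <- c(0.1, 0.2, 0.15, 0.05, 0.1)
  pairs <- tibble::tibble(drug = "d", patient_id = sprintf("P%d", 1:5),
                          pre_mean = 0.5, post_mean = 0.5 + d)
  res <- paired_screen(pairs)
  # frozen from the hand computation: t = mean/ (sd/sqrt(n)), upper tail t4
  expect_equal(res$mean_diff, 0.12)
  expect_equal(res$p_one_sided, 0.00463084838, tolerance = 1e-9)
  expect_equal(res$ci_low, 0.04921426115, tolerance = 1e-9)
  expect_equal(res$ci_high, 0.1907857388, tolerance = 1e-9)
  expect_true(res$flagged)
})

test_that("the paired screen handles degenerate and undersized inputs", {
  # all differences zero: symmetric null, p = 0.5
  p0 <- tibble::tibble(drug = "d", pre_mean = rep(0.4, 6),
                       post_mean = rep(0.4, 6))
  expect_equal(paired_screen(p0)$p_one_sided, 0.5)
  # zero variance, positive mean difference
  p1 <- tibble::tibble(drug = "d", pre_mean = rep(0.4, 6),
                       post_mean = rep(0.5, 6))
  expect_warning(res1 <- paired_screen(p1), "zero-variance")
  expect_equal(res1$p_one_sided, 0)
  # four patients with min_patients = 5: untestable, never flagged
  p2 <- tibble::tibble(drug = "d", pre_mean = rep(0.4, 4),
                       post_mean = c(0.8, 0.9, 0.85, 0.95))
  res2 <- paired_screen(p2, min_patients = 5)
  expect_false(res2$testable)
  expect_false(res2$flagged)
})

test_that("the EMR screen is invariant to row order and flags the responder", {
  cfg <- small_cfg(seed = 13)
  emr <- sim_emr(cfg)
  scr <- emr_screen(emr$prescriptions, emr$labs, windows = 365L)
  set.seed(2)
  scr2 <- emr_screen(emr$prescriptions[sample(nrow(emr$prescriptions)), ],
                     emr$labs[sample(nrow(emr$labs)), ], windows = 365L)
  expect_equal(as.data.frame(scr), as.data.frame(scr2))
  expect_true(scr$flagged[scr$drug == cfg$responder_drug_ids])
})

test_that("the false-flag rate of null drugs stays near the nominal level", {
  # three seeded cohorts x 9 non-responder drugs = 27 null tests per window
  flags <- unlist(lapply(1:3, function(s) {
    cfg <- small_cfg(seed = 300 + s)
    emr <- sim_emr(cfg)
    scr <- emr_screen(emr$prescriptions, emr$labs, windows = 365L)
    scr$flagged[!scr$drug %in% cfg$responder_drug_ids]
  }))
  n <- length(flags)
  expect_lt(abs(mean(flags) - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 1e-9)
})
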