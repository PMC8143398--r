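test_that("combined participant pools the requested cell", {
  spec <- cohort_spec(groups = list(
    NT = list(n = 3, lambda = rep(12, 3), omega = rep(0.4, 3)),
    ASD = list(n = 2, lambda = rep(9, 3), omega = rep(0.4, 3))),
    trials_per_block = 10, seed = 1)
  d <- simulate_cohort(spec)
  pooled <- combined_participant(d, "NT", "woFB")
  expect_equal(nrow(pooled), 30)
  expect_true(all(pooled$group == "NT" & pooled$block == "woFB"))
  expect_error(combined_participant(d, "NT", "wFB9"),
               class = "orienc_empty_error")
})

test_that("bootstrap of a constant statistic has zero spread", {
  d <- tibble::tibble(value = rep(2.5, 40))
  bs <- bootstrap_statistic(d, function(x) mean(x$value), n_reps = 50,
                            seed = 3)
  expect_equal(bs$point, 2.5)
  expect_equal(diff(bs$ci95), 0)
  expect_equal(bs$se, 0)
})

test_that("bootstrap draws are reproducible and p-values sign-invariant", {
  set.seed(4)
  d <- tibble::tibble(value = rnorm(60, 0.3))
  stat <- function(x) mean(x$value)
  b1 <- bootstrap_statistic(d, stat, n_reps = 200, seed = 7)
  b2 <- bootstrap_statistic(d, stat, n_reps = 200, seed = 7)
  expect_identical(b1$samples, b2$samples)
  b3 <- bootstrap_statistic(d, function(x) -mean(x$value), n_reps = 200,
                            seed = 7)
  expect_equal(b1$p_two_sided, b3$p_two_sided)
  expect_gte(b1$p_two_sided, 1 / 201)
  expect_true(all(b1$samples >= b1$ci95[1] - 1e-12 |
                    b1$samples <= b1$ci95[2] + 1e-12))
})

test_that("stratified resampling preserves per-stratum sizes", {
  d <- tibble::tibble(value = rnorm(50),
                      grp = rep(c("a", "b"), c(20, 30)))
  bs <- bootstrap_statistic(d, function(x) sum(x$grp == "a"),
                            n_reps = 30, seed = 5, strata = "grp")
  expect_equal(unique(bs$samples), 20)
})

test_that("group contrasts report the difference of point estimates", {
  set.seed(6)
  a <- tibble::tibble(value = rnorm(80, 1.0, 0.2))
  b <- tibble::tibble(value = rnorm(80, 0.4, 0.2))
  gc <- group_contrast(a, b, function(x) mean(x$value), n_reps = 300,
                       seed = 8)
  expect_equal(gc$delta, mean(a$value) - mean(b$value))
  expect_lt(gc$p_two_sided, 0.05)
  expect_gt(gc$se, 0)
})

test_that("bootstrap median contrast recovers a configured RT shift", {
  set.seed(9)
  rt_a <- tibble::tibble(rt = rlnorm(400, log(2.6), 0.35))
  rt_b <- tibble::tibble(rt = rlnorm(400, log(2.6), 0.35) - 0.0)
  rt_b$rt <- rlnorm(400, log(2.0), 0.35)   # true median shift 0.6
  gc <- group_contrast(rt_a, rt_b, function(x) stats::median(x$rt),
                       n_reps = 400, seed = 10)
  expect_equal(gc$delta, 0.6, tolerance = 0.25)
  expect_lt(gc$p_two_sided, 0.05)
})

test_that("flexibility regression is exact on collinear input and guarded", {
  df <- tibble::tibble(lambda_wofb = c(10, 12, 14, 16),
                       omega_wfb2 = 0.9 - 0.03 * c(10, 12, 14, 16))
  fr <- suppressWarnings(flexibility_regression(df))
  expect_equal(fr$r2, 1)
  expect_equal(fr$slope, -0.03)
  expect_error(flexibility_regression(df[1:2, ]),
               class = "orienc_insufficient_data")
  degen <- tibble::tibble(lambda_wofb = rep(10, 5),
                          omega_wfb2 = runif(5))
  expect_error(flexibility_regression(degen),
               class = "orienc_degenerate_error")
})

test_that("capacity-coupled learning produces a negative regression slope", {
  spec <- study_cohort_spec(seed = 11)
  d <- simulate_cohort(spec)
  fits <- fit_participants(d)
  wide <- dplyr::inner_join(
    dplyr::filter(fits, block == "woFB")[, c("participant_id", "lambda")],
    dplyr::filter(fits, block == "wFB2")[, c("participant_id", "omega")],
    by = "participant_id")
  names(wide) <- c("participant_id", "lambda_wofb", "omega_wfb2")
  fr <- flexibility_regression(wide)
  expect_lt(fr$slope, 0)
  expect_lt(fr$p, 0.01)
  expect_gt(fr$r2, 0.1)
})

test_that("within-block segments cover every trial and track drift", {
  spec <- cohort_spec(groups = list(
    NT = list(n = 12, lambda = rep(15, 3), omega = c(0.5, 0.6, 0.5))),
    omega_drift = 0.35, seed = 12)
  d <- simulate_cohort(spec)
  tr <- within_block_trends(d, "NT", "wFB1")
  expect_equal(tr$start[1], 0)
  expect_equal(max(tr$end), 199)
  covered <- unlist(Map(seq, tr$start, tr$end))
  expect_setequal(intersect(0:199, covered), 0:199)
  # omega declines linearly within the drifting block
  expect_lt(tr$omega[nrow(tr)], tr$omega[1])
  expect_error(within_block_trends(d, "NT", "wFB1", seg_width = 10),
               class = "orienc_insufficient_data")
})

test_that("RT summaries report medians or an explicit missing marker", {
  d <- tiny_trials()
  d$rt_s <- c(1, 2, 3, 1, 2, 3)
  s <- rt_summary(d)
  expect_true(s$available)
  expect_equal(s$median_rt_s, 2)
  expect_equal(sum(s$counts), 6)
  d$rt_s <- NA_real_
  s2 <- rt_summary(d)
  expect_false(s2$available)
  expect_true(is.na(s2$median_rt_s))
  expect_equal(s2$n, 0L)
})
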