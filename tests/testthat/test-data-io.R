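test_that("angle reduction wraps into [0, 180) and is idempotent", {
  expect_equal(wrap_ori(c(181, -5, 0, 179.5, 360)), c(1, 175, 0, 179.5, 0))
  set.seed(1)
  x <- runif(200, -720, 720)
  expect_equal(wrap_ori(wrap_ori(x)), wrap_ori(x))
  expect_true(all(wrap_ori(x) >= 0 & wrap_ori(x) < 180))
})

test_that("signed circular differences live in [-90, 90)", {
  expect_equal(circ_diff_ori(175, 5), -10)
  expect_equal(circ_diff_ori(5, 175), 10)
  expect_equal(circ_diff_ori(135, 45), -90)   # half-open at +90
  set.seed(2)
  d <- circ_diff_ori(runif(200, 0, 180), runif(200, 0, 180))
  expect_true(all(d >= -90 & d < 90))
})

test_that("read_trials validates, angle-reduces, and tags provenance", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,group,block,trial_index,target_deg,response_deg,rt_s",
               "p01,NT,woFB,0,181.0,-5.0,1.2",
               "p01,NT,woFB,1,45,44,0.9",
               "p02,ASD,wFB2,0,90,92,1.1"), path)
  d <- read_trials(path)
  expect_s3_class(d, "trial_data")
  expect_equal(nrow(d), 3)
  expect_equal(d$target_deg[1], 1)
  expect_equal(d$response_deg[1], 175)
  expect_equal(attr(d, "provenance"), path)
})

test_that("schema and parse errors name the offending column or row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,group,block,trial_index,target_deg,rt_s",
               "p01,NT,woFB,0,10,1.0"), path)
  expect_error(read_trials(path), "response_deg",
               class = "orienc_schema_error")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,group,block,trial_index,target_deg,response_deg,rt_s",
               "p01,NT,woFB,0,10,oops,1.0"), path2)
  expect_error(read_trials(path2), class = "orienc_parse_error")
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,group,block,trial_index,target_deg,response_deg,rt_s",
             path3)
  expect_error(read_trials(path3), class = "orienc_empty_error")
})

test_that("column mapping is case-insensitive and configurable", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Participant_ID,GROUP,block,trial_index,orientation,resp,rt_s",
               "p01,NT,woFB,0,30,32,1.0"), path)
  d <- read_trials(path, col_map = c(target_deg = "orientation",
                                     response_deg = "resp"))
  expect_equal(d$target_deg, 30)
  expect_equal(d$response_deg, 32)
})

test_that("trial data round-trips through CSV", {
  d <- tiny_trials()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(d, path)
  d2 <- read_trials(path)
  expect_equal(tibble::as_tibble(d2)[orienc:::trial_columns],
               tibble::as_tibble(d)[orienc:::trial_columns],
               ignore_attr = "provenance")
  expect_equal(attr(d2, "provenance"), path)
})

test_that("invalid labels and duplicate trial keys are rejected", {
  base <- tibble::as_tibble(tiny_trials())
  bad <- base; bad$block[2] <- "block9"
  expect_error(as_trial_data(bad), class = "orienc_schema_error")
  dup <- base; dup$trial_index[2] <- 0
  expect_error(as_trial_data(dup), class = "orienc_schema_error")
})

test_that("profiles round-trip through CSV with full precision", {
  d <- sim_observer_data(n = 3000, seed = 5)
  prof <- sliding_profile(d, window_deg = 18)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile(prof, path)
  prof2 <- read_profile(path)
  expect_equal(prof2$bias_deg, prof$bias_deg)
  expect_equal(prof2$kappa, prof$kappa)
  expect_equal(attr(prof2, "window_deg"), attr(prof, "window_deg"))
  expect_equal(attr(prof2, "period_deg"), attr(prof, "period_deg"))
  fp <- extract_sqrt_fi(prof)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_profile(fp, path2)
  fp2 <- read_profile(path2)
  expect_equal(fp2$sqrt_fi, fp$sqrt_fi)
  expect_equal(attr(fp2, "total"), attr(fp, "total"))
})

test_that("profile writer refuses empty or non-finite profiles", {
  d <- sim_observer_data(n = 3000, seed = 6)
  prof <- sliding_profile(d, window_deg = 18)
  bad <- prof; bad$bias_deg[3] <- Inf
  path <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_profile(bad, path), class = "orienc_validation_error")
  empty <- prof[0, ]
  attr(empty, "window_deg") <- 18; attr(empty, "period_deg") <- 180
  class(empty) <- class(prof)
  expect_error(write_profile(empty, path), class = "orienc_empty_error")
  expect_error(write_profile(tibble::tibble(a = 1), path),
               class = "orienc_type_error")
})

test_that("analysis_config enforces its invariants", {
  cfg <- analysis_config()
  expect_equal(cfg$window_individual_deg, 18)
  expect_equal(cfg$window_combined_deg, 4)
  expect_equal(cfg$n_bootstrap, 5000L)
  expect_true(cfg$enforce_period_90)
  expect_error(analysis_config(window_combined_deg = 0.5))
  expect_error(analysis_config(n_bootstrap = 0))
  expect_equal(orienc:::cardinal_norm_const(), 1 / (pi - 2))
  expect_equal(orienc:::cardinal_norm_const(
    analysis_config(cardinal_norm = "printed")), 0.877)
})
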