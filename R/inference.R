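# Group-level inference: combined-participant construction, bootstrap
# statistics and contrasts, the capacity-flexibility regression,
# within-block trend analysis, and response-time summaries.

#' Pool all trials of a group and block into a combined participant
#'
#' @param data a `trial_data` tibble.
#' @param group group label ("NT" or "ASD").
#' @param block block label ("woFB", "wFB1" or "wFB2").
#' @return the pooled `trial_data` subset; downstream profiling should use
#'   the combined-participant window (4 degrees).
#' @export
combined_participant <- function(data, group, block) {
  out <- data[data$group == group & data$block == block, ]
  if (nrow(out) == 0) {
    rlang::abort(sprintf("no trials for group %s, block %s", group, block),
                 class = "orienc_empty_error")
  }
  out
}

#' Bootstrap a statistic of a dataset
#'
#' Resamples rows with replacement (within strata when given -- e.g.
#' participants' pooled trials stratified by participant for hierarchical
#' schemes) and recomputes the statistic. The two-sided p-value treats the
#' statistic as a difference and asks how much of the bootstrap
#' distribution falls on either side of zero:
#' `p = 2 * min(Pr(s* <= 0), Pr(s* >= 0))`, floored at `1/(n_reps + 1)` so
#' it is never reported as exactly zero.
#'
#' @param data a data frame; rows are the resampling unit.
#' @param statistic function of a data frame returning a scalar.
#' @param n_reps number of bootstrap resamples.
#' @param seed integer seed.
#' @param strata optional column name; resampling is done within strata.
#' @param statistic_name label carried in the result.
#' @param retry_cap redraws allowed when the statistic fails on a
#'   resample.
#' @return list of class `bootstrap_result`: `statistic_name`, `point`,
#'   `samples`, `ci95`, `se`, `p_two_sided`, `seed`.
#' @export
bootstrap_statistic <- function(data, statistic, n_reps = 5000, seed = 1L,
                                strata = NULL, statistic_name = "statistic",
                                retry_cap = 3L) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  n <- nrow(data)
  idx_groups <- if (is.null(strata)) list(seq_len(n)) else
    split(seq_len(n), data[[strata]])
  point <- statistic(data)
  samples <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    val <- NA_real_
    for (try in seq_len(retry_cap)) {
      idx <- unlist(lapply(idx_groups,
                           function(ix) ix[sample.int(length(ix),
                                                      replace = TRUE)]),
                    use.names = FALSE)
      val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                      error = function(e) NA_real_)
      if (is.finite(val)) break
    }
    if (!is.finite(val)) {
      rlang::abort("statistic failed on resamples beyond the retry cap",
                   class = "orienc_bootstrap_error")
    }
    samples[r] <- val
  }
  p <- 2 * min(mean(samples <= 0), mean(samples >= 0))
  p <- min(max(p, 1 / (n_reps + 1)), 1)
  structure(list(statistic_name = statistic_name, point = point,
                 samples = samples,
                 ci95 = stats::quantile(samples, c(0.025, 0.975),
                                        names = FALSE),
                 se = stats::sd(samples), p_two_sided = p,
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' Bootstrap contrast between two datasets
#'
#' Computes `statistic(data_a) - statistic(data_b)`, resampling each side
#' independently (trials within each pooled set), and reports the
#' bootstrap SE and two-sided p-value of the difference.
#'
#' @param data_a,data_b data frames (e.g. combined participants).
#' @param statistic function of a data frame returning a scalar.
#' @param n_reps,seed bootstrap controls.
#' @param statistic_name label carried in the result.
#' @return list of class `group_contrast`: `delta`, `se`, `ci95`,
#'   `p_two_sided`, `point_a`, `point_b`.
#' @export
group_contrast <- function(data_a, data_b, statistic, n_reps = 5000,
                           seed = 1L, statistic_name = "contrast") {
  both <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(data_a), .side = "a"),
    dplyr::mutate(tibble::as_tibble(data_b), .side = "b"))
  contrast_stat <- function(d) {
    statistic(d[d$.side == "a", , drop = FALSE]) -
      statistic(d[d$.side == "b", , drop = FALSE])
  }
  bs <- bootstrap_statistic(both, contrast_stat, n_reps = n_reps,
                            seed = seed, strata = ".side",
                            statistic_name = statistic_name)
  structure(list(statistic_name = statistic_name,
                 delta = bs$point, se = bs$se, ci95 = bs$ci95,
                 p_two_sided = bs$p_two_sided,
                 point_a = statistic(data_a), point_b = statistic(data_b),
                 samples = bs$samples),
            class = "group_contrast")
}

#' Capacity-flexibility regression
#'
#' Ordinary least squares of each participant's resource-allocation weight
#' after feedback (omega at wFB2) on their encoding capacity before
#' feedback (lambda at woFB). This is the one analysis whose p-value comes
#' from the regression itself rather than the bootstrap.
#'
#' @param per_participant data frame with columns `lambda_wofb` and
#'   `omega_wfb2` (one row per participant).
#' @return list with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
flexibility_regression <- function(per_participant) {
  df <- per_participant[is.finite(per_participant$lambda_wofb) &
                          is.finite(per_participant$omega_wfb2), ]
  if (nrow(df) < 3) {
    rlang::abort("need at least 3 participants with both quantities",
                 class = "orienc_insufficient_data")
  }
  if (stats::var(df$lambda_wofb) == 0) {
    rlang::abort("degenerate predictor: lambda has zero variance",
                 class = "orienc_degenerate_error")
  }
  fit <- stats::lm(omega_wfb2 ~ lambda_wofb, data = df)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = nrow(df))
}

#' Fit the encoding model per participant and block
#'
#' Runs the individual-participant pipeline (18-degree window profile,
#' then the (lambda, omega) fit) for every participant x block present.
#'
#' @param data a `trial_data` tibble.
#' @param config an `orienc_config`.
#' @return tibble with `participant_id`, `group`, `block`, `lambda`,
#'   `omega`, `r2`, `converged`.
#' @export
fit_participants <- function(data, config = analysis_config()) {
  cells <- dplyr::distinct(tibble::as_tibble(data)[, c("participant_id",
                                                       "group", "block")])
  res <- purrr::pmap(cells, function(participant_id, group, block) {
    sub <- data[data$participant_id == participant_id &
                  data$block == block, ]
    prof <- suppressWarnings(
      sliding_profile(sub, config$window_individual_deg,
                      config$grid_step_deg,
                      fold_90 = config$enforce_period_90,
                      kappa_cap = config$kappa_cap))
    fit <- fit_fi_params(prof, c_norm = cardinal_norm_const(config))
    tibble::tibble(participant_id = participant_id, group = group,
                   block = block, lambda = fit$lam, omega = fit$omega,
                   r2 = fit$r2, converged = fit$converged)
  })
  dplyr::bind_rows(res)
}

#' Combined-participant pipeline for one group and block
#'
#' Pools the group's trials, profiles them with the combined-participant
#' window, extracts the Fisher profile, and fits the parametric model.
#'
#' @param data a `trial_data` tibble.
#' @param group,block cell selector.
#' @param config an `orienc_config`.
#' @return list with `profile`, `fisher`, `params`, `rmse`.
#' @export
fit_group_block <- function(data, group, block,
                            config = analysis_config()) {
  pooled <- combined_participant(data, group, block)
  prof <- sliding_profile(pooled, config$window_combined_deg,
                          config$grid_step_deg,
                          fold_90 = config$enforce_period_90,
                          kappa_cap = config$kappa_cap)
  fisher <- extract_sqrt_fi(prof)
  params <- fit_fi_params(prof, c_norm = cardinal_norm_const(config))
  rmse <- rmse_profile(pooled, config$window_combined_deg,
                       config$grid_step_deg)
  list(profile = prof, fisher = fisher, params = params, rmse = rmse)
}

#' Within-block learning trends
#'
#' Splits a block into overlapping trial segments (100-trial windows
#' stepped by 25 by default) and runs the combined-participant pipeline on
#' each, tracking bias magnitude, response dispersion, and the fitted
#' (lambda, omega) across the block.
#'
#' @param data a `trial_data` tibble.
#' @param group,block cell selector.
#' @param config an `orienc_config`.
#' @param seg_width,seg_step segment width and step in trials.
#' @return tibble with one row per segment: `start`, `end`,
#'   `mean_abs_bias_deg`, `mean_sigma`, `lambda`, `omega`, `n_trials`.
#' @export
within_block_trends <- function(data, group, block,
                                config = analysis_config(),
                                seg_width = 100, seg_step = 25) {
  if (seg_width < 25) {
    rlang::abort("segments need at least 25 trials for profile estimation",
                 class = "orienc_insufficient_data")
  }
  pooled <- combined_participant(data, group, block)
  max_index <- max(pooled$trial_index)
  starts <- seq(0, max_index + 1 - seg_width, by = seg_step)
  res <- purrr::map(starts, function(s) {
    seg <- pooled[pooled$trial_index >= s &
                    pooled$trial_index < s + seg_width, ]
    prof <- suppressWarnings(
      sliding_profile(seg, config$window_combined_deg,
                      config$grid_step_deg,
                      fold_90 = config$enforce_period_90,
                      kappa_cap = config$kappa_cap))
    fit <- fit_fi_params(prof, c_norm = cardinal_norm_const(config))
    tibble::tibble(start = s, end = s + seg_width - 1,
                   mean_abs_bias_deg = mean(abs(prof$bias_deg),
                                            na.rm = TRUE),
                   mean_sigma = mean(sqrt(prof$variance), na.rm = TRUE),
                   lambda = fit$lam, omega = fit$omega,
                   n_trials = nrow(seg))
  })
  dplyr::bind_rows(res)
}

#' Response-time summary
#'
#' @param data a `trial_data` tibble.
#' @param group,block optional cell selector (NULL keeps everything).
#' @param bin_width histogram bin width in seconds.
#' @return list with `available`, `median_rt_s`, `n`, `n_missing`, and
#'   histogram `breaks`/`counts`; when no response times are present the
#'   result is an explicit missing-data marker, not zeros.
#' @export
rt_summary <- function(data, group = NULL, block = NULL, bin_width = 0.25) {
  sub <- tibble::as_tibble(data)
  if (!is.null(group)) sub <- sub[sub$group == group, ]
  if (!is.null(block)) sub <- sub[sub$block == block, ]
  rt <- sub$rt_s[is.finite(sub$rt_s)]
  if (length(rt) == 0) {
    return(list(available = FALSE, median_rt_s = NA_real_, n = 0L,
                n_missing = nrow(sub), breaks = numeric(0),
                counts = integer(0)))
  }
  breaks <- seq(0, ceiling(max(rt) / bin_width) * bin_width, by = bin_width)
  h <- graphics::hist(rt, breaks = breaks, plot = FALSE)
  list(available = TRUE, median_rt_s = stats::median(rt), n = length(rt),
       n_missing = nrow(sub) - length(rt), breaks = h$breaks,
       counts = h$counts)
}
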