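#!/usr/bin/env Rscript
# Stage 4: bootstrap group inference.
#
# Bootstrap contrasts of the headline statistics (variance, total
# sqrt-FI, lambda, omega) between groups and blocks, the
# capacity-flexibility regression across participants, median response
# times, and the within-block learning trends. The bootstrap rep count is
# reduced from the 5000 used for final inference via ORIENC_BOOT to keep
# the driver quick; pass ORIENC_BOOT=5000 for full precision.

suppressPackageStartupMessages({library(orienc); library(dplyr)})

cohort <- read_trials("results/trials.csv")
config <- analysis_config()
n_boot <- as.integer(Sys.getenv("ORIENC_BOOT", "500"))
seed <- as.integer(Sys.getenv("ORIENC_SEED", "1"))

pool <- function(g, b) combined_participant(cohort, g, b)
stat_var <- function(d) {
  mean(sliding_profile(d, config$window_combined_deg,
                       fold_90 = TRUE)$variance, na.rm = TRUE)
}
stat_total <- function(d) {
  total_resource(extract_sqrt_fi(
    sliding_profile(d, config$window_combined_deg, fold_90 = TRUE)))
}
stat_lambda <- function(d) {
  fit_fi_params(sliding_profile(d, config$window_combined_deg,
                                fold_90 = TRUE))$lam
}
stat_omega <- function(d) {
  fit_fi_params(sliding_profile(d, config$window_combined_deg,
                                fold_90 = TRUE))$omega
}

contrasts <- list(
  list("variance NT-ASD @woFB", pool("NT", "woFB"), pool("ASD", "woFB"),
       stat_var),
  list("total sqrt-FI NT-ASD @woFB", pool("NT", "woFB"),
       pool("ASD", "woFB"), stat_total),
  list("total sqrt-FI NT wFB2-woFB", pool("NT", "wFB2"),
       pool("NT", "woFB"), stat_total),
  list("lambda NT-ASD @woFB", pool("NT", "woFB"), pool("ASD", "woFB"),
       stat_lambda),
  list("lambda NT wFB2-woFB", pool("NT", "wFB2"), pool("NT", "woFB"),
       stat_lambda),
  list("omega NT woFB-wFB2", pool("NT", "woFB"), pool("NT", "wFB2"),
       stat_omega),
  list("omega ASD woFB-wFB2", pool("ASD", "woFB"), pool("ASD", "wFB2"),
       stat_omega))

rows <- lapply(seq_along(contrasts), function(i) {
  cs <- contrasts[[i]]
  gc <- group_contrast(cs[[2]], cs[[3]], cs[[4]], n_reps = n_boot,
                       seed = seed + i, statistic_name = cs[[1]])
  cat(sprintf("%-28s delta = %+.3f +/- %.3f, p = %.4g\n",
              cs[[1]], gc$delta, gc$se, gc$p_two_sided))
  tibble::tibble(statistic = cs[[1]], delta = gc$delta, se = gc$se,
                 ci_lo = gc$ci95[1], ci_hi = gc$ci95[2],
                 p_two_sided = gc$p_two_sided, n_boot = n_boot)
})
readr::write_csv(bind_rows(rows), "results/contrasts.csv")

# capacity-flexibility regression (per-participant, OLS p-value)
pfits <- readr::read_csv("results/params_participants.csv",
                         show_col_types = FALSE)
wide <- inner_join(
  filter(pfits, block == "woFB") |> select(participant_id, lambda),
  filter(pfits, block == "wFB2") |> select(participant_id, omega),
  by = "participant_id") |>
  rename(lambda_wofb = lambda, omega_wfb2 = omega)
fr <- flexibility_regression(wide)
cat(sprintf("\nflexibility regression: slope %.4f, R^2 = %.3f, p = %.3g (n = %d)\n",
            fr$slope, fr$r2, fr$p, fr$n))

# response times
for (g in c("NT", "ASD")) {
  m1 <- rt_summary(cohort, g, "woFB")$median_rt_s
  m3 <- rt_summary(cohort, g, "wFB2")$median_rt_s
  cat(sprintf("median RT %s: woFB %.2f s -> wFB2 %.2f s (change %+.2f s)\n",
              g, m1, m3, m3 - m1))
}

# within-block trends (100-trial segments stepped by 25)
trends <- bind_rows(lapply(c("woFB", "wFB2"), function(b) {
  mutate(within_block_trends(cohort, "NT", b, config), block = b)
}))
readr::write_csv(trends, "results/within_block_trends_nt.csv")
cat("\nwithin-block trends (NT) written to results/within_block_trends_nt.csv\n")
cat("wrote results/contrasts.csv\n")
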