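#!/usr/bin/env Rscript
# Stage 3: parametric (lambda, omega) modelling.
#
# Fits the two-parameter sqrt-FI model -- lambda scaling the total
# resource, omega mixing a cardinal-peaked density with the uniform -- to
# the observed bias of every combined participant and of every individual
# participant x block (18-degree window).

suppressPackageStartupMessages({library(orienc); library(dplyr)})

cohort <- read_trials("results/trials.csv")
config <- analysis_config()

cells <- expand.grid(group = c("NT", "ASD"),
                     block = c("woFB", "wFB1", "wFB2"),
                     stringsAsFactors = FALSE)
combined <- bind_rows(lapply(seq_len(nrow(cells)), function(i) {
  g <- cells$group[i]; b <- cells$block[i]
  p <- fit_group_block(cohort, g, b, config)$params
  tibble::tibble(group = g, block = b, lambda = p$lam, omega = p$omega,
                 r2 = p$r2, converged = p$converged)
}))
readr::write_csv(combined, "results/params_combined.csv")
cat("combined-participant fits:\n")
print(as.data.frame(combined), digits = 3)

participants <- fit_participants(cohort, config)
readr::write_csv(participants, "results/params_participants.csv")
cat(sprintf("\nper-participant fits: mean R^2 NT %.3f, ASD %.3f\n",
            mean(participants$r2[participants$group == "NT"]),
            mean(participants$r2[participants$group == "ASD"])))
cat("wrote results/params_{combined,participants}.csv\n")
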