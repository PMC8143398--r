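#!/usr/bin/env Rscript
# Stage 0: generate the synthetic study cohort.
#
# Two groups (25 neurotypical, 17 ASD observers) complete three 200-trial
# orientation-estimation blocks (woFB without feedback, then wFB1/wFB2
# with feedback). Observers are efficient-coding encoder-decoder models
# whose capacity (lambda) and resource allocation (omega) follow the
# group schedules documented in ?study_cohort_spec. Writes the canonical
# trial CSV consumed by the later stages.

suppressPackageStartupMessages(library(orienc))

seed <- as.integer(Sys.getenv("ORIENC_SEED", "1"))
dir.create("results", showWarnings = FALSE)

spec <- study_cohort_spec(seed = seed)
cohort <- simulate_cohort(spec)
write_trials(cohort, "results/trials.csv")

cat(sprintf("simulated %d trials (%d observers x 3 blocks x %d trials), seed %d\n",
            nrow(cohort), length(unique(cohort$participant_id)),
            spec$trials_per_block, seed))
cat("wrote results/trials.csv\n")
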