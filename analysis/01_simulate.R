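#!/usr/bin/env Rscript
# Simulate trial-level datasets for the three random-dot-motion designs, plus
# difficulty-design datasets with each candidate session effect injected.
# Writes CSV datasets and ground-truth sidecars under results/data/.

library(scanlba)
library(jsonlite)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# Illustrative datasets for each design at the study trial schedules
for (design in c("bias", "sat", "difficulty")) {
  g <- generate_experiment(design, account = "none", n_participants = 4,
                           seed = 100)
  write_dataset(g$trials, file.path(out_dir, paste0(design, "_null.csv")))
  cat(sprintf("%s: %d trials, %d participants\n", design, nrow(g$trials),
              length(unique(g$trials$participant))))
}

# Difficulty-design datasets under each account (the analysis chain's inputs);
# 6 participants at half the trial schedule keep the fit stage desk-sized.
accounts <- c("none", "motor_slowing", "caution", "arousal", "focus")
for (i in seq_along(accounts)) {
  g <- generate_experiment("difficulty", account = accounts[i],
                           n_participants = 6, trials_scale = 0.5,
                           seed = 200 + i)
  write_dataset(g$trials,
                file.path(out_dir, paste0("difficulty_", accounts[i], ".csv")))
  truth <- list(account = g$truth$account, magnitude = g$truth$magnitude,
                spec = g$truth$spec$id, seed = g$truth$seed,
                params = lapply(g$truth$params, as.list))
  write_json(truth, file.path(out_dir, paste0("difficulty_", accounts[i],
                                              "_truth.json")),
             auto_unbox = TRUE, digits = NA)
  n_none <- sum(g$trials$response == "none")
  cat(sprintf("difficulty/%s: %d trials (%d non-terminating)\n",
              accounts[i], nrow(g$trials), n_none))
}
cat("datasets written to", out_dir, "\n")
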