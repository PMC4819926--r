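#!/usr/bin/env Rscript
# Model selection and AIC-weight model averaging: group-summed AIC per model,
# AIC weights, model-averaged parameter estimates, and the four account
# diagnostics (t0, b, v_c + v_e, v_c - v_e) per participant x session.

library(scanlba)

design <- build_design("difficulty")
top <- reduced_top_model(design)

accounts <- c("none", "motor_slowing", "caution", "arousal", "focus")
score_rows <- list(); diag_rows <- list()
for (account in accounts) {
  fits <- readRDS(file.path("scratch", paste0("fits_", account, ".rds")))
  scores <- score_models(fits)
  w <- aic_weights(scores)
  cat(sprintf("%s: best model %s (w_AIC = %.3f)\n", account, w$model[1],
              w$weight[1]))
  w$account <- account
  score_rows[[account]] <- merge(w, scores[c("model", "k", "bic")])
  averaged <- model_average(fits, w, top)
  acc <- account_quantities(averaged, top)
  acc$account <- account
  diag_rows[[account]] <- acc
}
write.csv(do.call(rbind, score_rows), "results/model_scores.csv",
          row.names = FALSE)
write.csv(do.call(rbind, diag_rows), "results/account_diagnostics.csv",
          row.names = FALSE)
cat("wrote results/model_scores.csv and results/account_diagnostics.csv\n")
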