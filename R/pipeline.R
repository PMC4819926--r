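# End-to-end orchestration: fit hierarchy -> select/average -> account
# diagnostics -> Bayes-factor ANOVAs -> report.

#' Run the full session-effect analysis on a trial dataset
#'
#' Fits a nested LBA model hierarchy per participant (warm-started maximum
#' likelihood), computes group-summed AIC weights, model-averages the
#' parameter estimates, derives the four account diagnostics (t0, b,
#' v_c + v_e, v_c - v_e) per participant and session, and runs Bayes-factor
#' ANOVAs with Session as the focal factor on behavior (mean correct RT,
#' error rate) and on each diagnostic. A diagnostic with `BF_Session` above
#' `flag_threshold` is flagged and mapped to its account (motor slowing,
#' response caution, arousal, attentional focus).
#'
#' @param trials trial data.frame (see [generate_experiment()] /
#'   [read_dataset()]).
#' @param design an [build_design()] object or design name.
#' @param hierarchy an [enumerate_hierarchy()] object; default is the reduced
#'   32-node session hierarchy of [reduced_top_model()].
#' @param seed integer seed governing fitting restarts, Bayes-factor Monte
#'   Carlo, and report simulation.
#' @param bf_nsamples Monte-Carlo draws per marginal likelihood.
#' @param flag_threshold Bayes-factor threshold for flagging a diagnostic
#'   (default 3, conventional moderate evidence).
#' @param n_restarts random restarts per hierarchy node.
#' @param max_starts starts optimized per node after ranking (see
#'   [fit_model()]).
#' @param behavior_factors fixed-effect terms for the behavioral ANOVA;
#'   default: the design's condition factors plus Session (and Cue:Direction
#'   for the bias design).
#' @return object of class `scanlba_result` with elements `scores`, `weights`,
#'   `averaged`, `accounts`, `bf_behavior`, `bf_diagnostics`, `flags`,
#'   `supported_accounts`, `config`.
#' @export
run_pipeline <- function(trials, design, hierarchy = NULL, seed = 1L,
                         bf_nsamples = 10000, flag_threshold = 3,
                         n_restarts = 1, max_starts = 2,
                         behavior_factors = NULL) {
  if (is.character(design)) design <- build_design(design)
  hierarchy <- hierarchy %||%
    enumerate_hierarchy(reduced_top_model(design),
                        locked = list(v = "resptype", sv = "resptype"))
  seeds <- derive_seeds(seed, 8)

  n_none <- sum(trials$response == "none", na.rm = TRUE)
  scanlba_log("stage fit: ", length(unique(trials$participant)),
              " participants, ", length(hierarchy$nodes), " models (",
              n_none, " 'none' trials excluded)")
  fits <- tryCatch(
    fit_participants(trials, hierarchy, seed = seeds[1],
                     n_restarts = n_restarts, max_starts = max_starts),
    error = function(e) stop("stage [fit]: ", conditionMessage(e), call. = FALSE))

  scores <- score_models(fits)
  weights <- aic_weights(scores)
  top <- hierarchy$nodes[[which(hierarchy$ids == hierarchy$top_id)]]$spec
  averaged <- tryCatch(model_average(fits, weights, top),
    error = function(e) stop("stage [average]: ", conditionMessage(e), call. = FALSE))
  accounts <- account_quantities(averaged, top)

  cond_factors <- setdiff(names(design$factors), "session")
  behavior_factors <- behavior_factors %||% {
    bf <- c("session", cond_factors)
    if (design$name == "bias") bf <- c(bf, "cue:direction")
    bf
  }
  cm <- cell_means(trials, intersect(names(design$factors), names(trials)))
  bf_behavior <- do.call(rbind, lapply(c("rt_mean", "error_rate"), function(v)
    tryCatch(
      bf_omit_factor(cm, v, behavior_factors, "session",
                     nsamples = bf_nsamples, seed = seeds[2]),
      error = function(e) stop("stage [anova-behavior]: ", conditionMessage(e),
                               call. = FALSE))))

  diagnostics <- c("t0", "b", "v_sum", "v_diff")
  bf_diagnostics <- do.call(rbind, lapply(seq_along(diagnostics), function(i)
    tryCatch(
      bf_omit_factor(accounts, diagnostics[i], "session", "session",
                     nsamples = bf_nsamples, seed = seeds[2 + i]),
      error = function(e) stop("stage [anova-diagnostics]: ",
                               conditionMessage(e), call. = FALSE))))

  flags <- setNames(bf_diagnostics$bf > flag_threshold, diagnostics)
  account_map <- c(t0 = "motor_slowing", b = "caution", v_sum = "arousal",
                   v_diff = "focus")
  structure(list(
    design = design, scores = scores, weights = weights, fits = fit_table(fits),
    averaged = averaged, accounts = accounts, bf_behavior = bf_behavior,
    bf_diagnostics = bf_diagnostics, flags = flags,
    supported_accounts = unname(account_map[names(flags)[flags]]),
    config = list(seed = seed, bf_nsamples = bf_nsamples,
                  flag_threshold = flag_threshold, n_restarts = n_restarts,
                  n_models = length(hierarchy$nodes),
                  behavior_factors = behavior_factors,
                  n_none_excluded = n_none),
    top = top), class = "scanlba_result")
}

#' @export
print.scanlba_result <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' RT-quantile fit summary
#'
#' The .1/.5/.9 quantiles of correct-response RTs per condition cell, in the
#' data and as predicted from each participant's model-averaged parameters
#' (forward simulation), averaged across participants.
#'
#' @param result a [run_pipeline()] result.
#' @param trials the analyzed trials.
#' @param n_sim simulated trials per participant and cell (default 2000).
#' @param seed integer seed for the forward simulation.
#' @return data.frame: cell factors, `source` (`data` / `model`), `q10`,
#'   `q50`, `q90`, `accuracy`.
#' @export
quantile_summary <- function(result, trials, n_sim = 2000, seed = 1L) {
  design <- result$design
  top <- result$top
  fnames <- names(design$factors)
  obs <- trials[!is.na(trials$correct), , drop = FALSE]
  key <- function(df) do.call(paste, c(df[fnames], sep = "\r"))
  cells <- design$cells
  qrow <- function(rt, correct) {
    q <- quantile(rt[correct], c(.1, .5, .9), names = FALSE, na.rm = TRUE)
    c(q10 = q[1], q50 = q[2], q90 = q[3], accuracy = mean(correct))
  }
  dat <- t(vapply(key(cells), function(k) {
    i <- key(obs) == k
    qrow(obs$rt[i], obs$correct[i])
  }, numeric(4)))
  sim_seeds <- derive_seeds(seed, length(result$averaged))
  pred <- 0
  for (j in seq_along(result$averaged)) {
    theta <- result$averaged[[j]]
    simq <- t(vapply(cells$cell_id, function(ci) {
      race <- resolve_params(top, theta, ci)
      s <- simulate_trials(race, n_sim, seed = sim_seeds[j] + ci)
      s <- s[!is.na(s$rt), , drop = FALSE]
      qrow(s$rt, s$correct)
    }, numeric(4)))
    pred <- pred + simq / length(result$averaged)
  }
  out <- rbind(cbind(cells[fnames], source = "data", as.data.frame(dat)),
               cbind(cells[fnames], source = "model", as.data.frame(pred)))
  rownames(out) <- NULL
  out
}

#' Plain-text report of a pipeline run
#'
#' @param result a [run_pipeline()] result.
#' @return character vector of report lines.
#' @export
report_text <- function(result) {
  w <- result$weights
  top10 <- head(w, 10)
  lines <- c(
    sprintf("Session-effect analysis (%s design, %d participants, %d models)",
            result$design$name, length(result$averaged),
            result$config$n_models),
    "",
    "Top models by group-summed AIC:",
    sprintf("  %-55s dAIC %8.2f  w_AIC %.3f",
            top10$model, top10$delta_aic, top10$weight),
    "",
    "Bayes factors, Session factor (full vs. omitting Session):",
    sprintf("  BF_Session (%s) = %.3g", result$bf_behavior$value,
            result$bf_behavior$bf),
    sprintf("  BF_Session (%s) = %.3g%s", result$bf_diagnostics$value,
            result$bf_diagnostics$bf,
            ifelse(result$flags, "  *flagged*", "")),
    "",
    if (length(result$supported_accounts))
      paste("Supported account(s):",
            paste(result$supported_accounts, collapse = ", "))
    else "No account flagged: data consistent with no session effect.")
  lines
}

#' Machine-readable report
#'
#' @param result a [run_pipeline()] result.
#' @return a list serializable to JSON (stable schema: `design`, `weights`,
#'   `bf_behavior`, `bf_diagnostics`, `flags`, `supported_accounts`,
#'   `config`).
#' @export
report_json <- function(result) {
  list(design = result$design$name,
       weights = head(result$weights, 10),
       bf_behavior = result$bf_behavior,
       bf_diagnostics = result$bf_diagnostics,
       flags = as.list(result$flags),
       supported_accounts = result$supported_accounts,
       config = result$config)
}
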