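# Model selection and AIC-weight model averaging.
#
# The best model across participants is determined by summing per-participant
# AIC scores; AIC weights w = exp(-dAIC/2) / sum exp(-dAIC/2) are then used to
# average each model's parameter estimates (expanded to the top model's cell
# structure) into selection-uncertainty-aware estimates. BIC is reported
# alongside but never drives the averaging.

#' Group-summed information criteria per model
#'
#' @param fits output of [fit_participants()].
#' @return data.frame with one row per model: `model`, `k`, `aic` (summed
#'   across participants), `bic`, `n_failed` (participants whose fit failed;
#'   any failure makes the summed scores `NA`).
#' @export
score_models <- function(fits) {
  models <- names(fits[[1]])
  out <- do.call(rbind, lapply(models, function(m) {
    aics <- vapply(fits, function(pf) pf[[m]]$aic, numeric(1))
    bics <- vapply(fits, function(pf) pf[[m]]$bic, numeric(1))
    oks <- vapply(fits, function(pf) pf[[m]]$ok, logical(1))
    data.frame(model = m, k = fits[[1]][[m]]$k,
               aic = if (all(oks)) sum(aics) else NA_real_,
               bic = if (all(oks)) sum(bics) else NA_real_,
               n_failed = sum(!oks), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' AIC weights of a model set
#'
#' `w_i = exp(-dAIC_i / 2) / sum_j exp(-dAIC_j / 2)`, with `dAIC` relative to
#' the best (smallest) summed AIC; invariant to adding a constant to every
#' AIC. Models with non-finite scores get weight 0.
#'
#' @param scores numeric vector of (summed) AIC scores, or a data.frame from
#'   [score_models()] (its `aic` column is used).
#' @return data.frame (`model`, `aic`, `delta_aic`, `weight`), weights summing
#'   to 1, sorted by `delta_aic`; input order preserved in the `model` column
#'   names when `scores` is unnamed.
#' @export
aic_weights <- function(scores) {
  if (is.data.frame(scores)) {
    aic <- setNames(scores$aic, scores$model)
  } else {
    aic <- scores
    if (is.null(names(aic))) names(aic) <- paste0("model", seq_along(aic))
  }
  ok <- is.finite(aic)
  if (!any(ok)) stop("no model has a finite score", call. = FALSE)
  delta <- aic - min(aic[ok])
  w <- ifelse(ok, exp(-delta / 2), 0)
  w <- w / sum(w)
  out <- data.frame(model = names(aic), aic = unname(aic),
                    delta_aic = unname(delta), weight = unname(w),
                    stringsAsFactors = FALSE)
  out[order(out$delta_aic), , drop = FALSE]
}

#' AIC-weight model averaging of parameter estimates
#'
#' For each participant, every model's estimates are expanded to the top
#' model's cell structure (a parameter fixed across a factor contributes its
#' single value to every level) and averaged with the group-level AIC weights.
#' Failed fits carry zero weight after renormalization within the
#' participant.
#'
#' Models with negligible weight are dropped before averaging
#' (`weight_floor`, renormalized): beyond the usual Occam's-window argument,
#' this guarantees that a parameter on which every surviving model agrees is
#' *exactly* constant in the average, rather than perturbed by floating-point
#' dust from near-zero-weight contributions — which matters because the
#' scale-invariant Bayes factors downstream would otherwise read systematic
#' rounding residue as a consistent effect.
#'
#' @param fits output of [fit_participants()].
#' @param weights an [aic_weights()] table (or `NULL` to compute it from
#'   [score_models()]).
#' @param top the top `lba_model_spec` (default: the fitted model with the
#'   largest k).
#' @param weight_floor models below this AIC weight are excluded from the
#'   average (default 1e-6).
#' @param per_participant if `TRUE`, each participant is averaged with
#'   weights from their own AICs instead of the shared group-summed weights
#'   (useful when different models suit different individuals); default
#'   `FALSE`, matching group-level selection.
#' @return named list, one natural-scale vector (top-model cells) per
#'   participant.
#' @export
model_average <- function(fits, weights = NULL, top = NULL,
                          weight_floor = 1e-6, per_participant = FALSE) {
  if (inherits(fits[[1]], "lba_fit")) fits <- list(`1` = fits)
  weights <- weights %||% aic_weights(score_models(fits))
  w <- setNames(weights$weight, weights$model)
  if (is.null(top)) {
    ks <- vapply(fits[[1]], `[[`, numeric(1), "k")
    top <- fits[[1]][[which.max(ks)]]$spec
  }
  lapply(fits, function(pf) {
    wm <- if (per_participant) {
      aics <- vapply(pf, `[[`, numeric(1), "aic")
      wp <- aic_weights(aics)
      setNames(wp$weight, wp$model)[names(pf)]
    } else {
      w[names(pf)]
    }
    ok <- vapply(pf, `[[`, logical(1), "ok")
    wm[!ok] <- 0
    wm[wm < weight_floor] <- 0
    if (sum(wm) <= 0)
      stop("all weight mass on failed fits for a participant", call. = FALSE)
    wm <- wm / sum(wm)
    avg <- NULL
    for (m in names(pf)) {
      if (wm[[m]] == 0) next
      ex <- expand_theta(pf[[m]]$estimates, pf[[m]]$spec, top)
      avg <- if (is.null(avg)) wm[[m]] * ex else avg + wm[[m]] * ex
    }
    avg
  })
}

#' Account diagnostics from averaged estimates
#'
#' Derives, per participant and session, the four quantities that index the
#' candidate explanations of a scanner-session effect: non-decision time `t0`
#' (motor slowing), threshold `b = A + (b - A)` of the stimulus-matching
#' accumulator (response caution), drift-rate sum `v_c + v_e` (arousal) and
#' drift-rate difference `v_c - v_e` (attentional focus). Nuisance factors
#' (cue, SAT, coherence, ITI) are collapsed by unweighted mean over their
#' levels.
#'
#' @param averaged output of [model_average()] (list of natural-scale vectors
#'   on the top model's cells).
#' @param top the top `lba_model_spec`.
#' @return data.frame: `participant`, `session`, `t0`, `b`, `v_sum`,
#'   `v_diff`.
#' @export
account_quantities <- function(averaged, top) {
  design <- top$design
  ptab <- design$paramtab
  sessions <- design$factors$session
  if (is.null(sessions)) stop("design has no session factor", call. = FALSE)
  out <- do.call(rbind, lapply(names(averaged), function(p) {
    vals <- resolve_rowvalues(top, averaged[[p]])
    do.call(rbind, lapply(sessions, function(s) {
      ic <- which(ptab$session == s & ptab$acc == 1L)  # correct accumulator
      ie <- ic + 1L                                     # its error counterpart
      data.frame(participant = p, session = s,
                 t0 = mean(vals$t0[ic]),
                 b = mean(vals$A[ic] + vals$b_minus_A[ic]),
                 v_sum = mean(vals$v[ic] + vals$v[ie]),
                 v_diff = mean(vals$v[ic] - vals$v[ie]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
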