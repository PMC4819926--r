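# Bayes-factor ANOVA for repeated-measures cell means.
#
# The Bayes factor compares the full ANOVA model (all fixed factors and
# interactions, Participant as an additive random factor) against the model
# that omits one term, under default standardized-effect g-priors: each term's
# coefficients are N(0, sigma^2 g) with g ~ InvGamma(1/2, r^2/2), r = 0.5 for
# fixed effects and r = 1 for the participant effect, sum-to-zero contrasts.
# The marginal likelihood conditional on g is available in closed form after
# integrating the grand mean (flat) and sigma^2 (Jeffreys); the g's are
# integrated by Monte Carlo. A BIC-based approximation is provided as a
# cross-check.

#' Per-participant cell means of behavior
#'
#' One row per participant x condition cell: mean RT of correct responses,
#' error rate (errors / (correct + errors)), and trial count. Trials with
#' response `"none"` are excluded.
#'
#' @param trials trial data.frame with `participant`, the factor columns,
#'   `rt` (s) and `correct`.
#' @param factors character vector of factor column names defining the cells.
#' @return data.frame: `participant`, factor columns, `rt_mean`,
#'   `error_rate`, `n`. Cells with no trials get `NA` means and a warning.
#' @export
cell_means <- function(trials, factors) {
  stopifnot(all(c("participant", "rt", "correct", factors) %in% names(trials)))
  lev <- c(list(participant = sort(unique(trials$participant))),
           lapply(trials[factors], function(x) unique(x)))
  if (!is.null(trials$response))
    trials <- trials[is.na(trials$response) | trials$response != "none", , drop = FALSE]
  trials <- trials[!is.na(trials$correct), , drop = FALSE]
  grid <- expand.grid(lev, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  key <- function(df) do.call(paste, c(df[c("participant", factors)], sep = "\r"))
  idx <- split(seq_len(nrow(trials)), factor(key(trials), levels = key(grid)))
  grid$rt_mean <- vapply(idx, function(i) {
    ok <- i[trials$correct[i]]
    if (length(ok)) mean(trials$rt[ok]) else NA_real_
  }, numeric(1))
  grid$error_rate <- vapply(idx, function(i)
    if (length(i)) mean(!trials$correct[i]) else NA_real_, numeric(1))
  grid$n <- lengths(idx)
  if (any(grid$n == 0L))
    warning(sum(grid$n == 0L), " empty cell(s): rows emitted with missing means",
            call. = FALSE)
  rownames(grid) <- NULL
  grid
}

#' Within-subject standard errors of cell means
#'
#' Loftus-Masson normalization: each participant's values are shifted by the
#' grand mean minus that participant's mean (removing additive subject
#' effects), then the per-cell SE is the SD of the centered values divided by
#' the square root of the number of participants.
#'
#' @param table a cell-means table (e.g. from [cell_means()]).
#' @param variable name of the value column.
#' @param participant name of the participant column.
#' @param cell_cols columns defining the cells (default: everything except
#'   the participant and value columns and `n`).
#' @return data.frame of cells with column `se`.
#' @export
within_subject_se <- function(table, variable, participant = "participant",
                              cell_cols = NULL) {
  cell_cols <- cell_cols %||%
    setdiff(names(table), c(participant, variable, "n", "rt_mean",
                            "error_rate"))
  y <- table[[variable]]
  p <- table[[participant]]
  if (length(unique(p)) < 2L)
    stop("within-subject SEs need >= 2 participants", call. = FALSE)
  centered <- y - ave(y, p) + mean(y)
  key <- do.call(paste, c(table[cell_cols], sep = "\r"))
  cells <- table[!duplicated(key), cell_cols, drop = FALSE]
  n_subj <- length(unique(p))
  cells$se <- vapply(unique(key), function(k)
    sd(centered[key == k]) / sqrt(n_subj), numeric(1))
  rownames(cells) <- NULL
  cells
}

# Sum-to-zero coded columns of one term (main effect or `a:b` interaction).
term_columns <- function(df, term) {
  comps <- strsplit(term, ":", fixed = TRUE)[[1]]
  M <- NULL
  for (f in comps) {
    if (is.null(df[[f]])) stop("unknown factor `", f, "`", call. = FALSE)
    x <- factor(df[[f]])
    if (nlevels(x) < 2L) stop("factor `", f, "` has a single level", call. = FALSE)
    C <- contr.sum(nlevels(x))
    Xf <- C[as.integer(x), , drop = FALSE]
    M <- if (is.null(M)) Xf else {
      out <- matrix(0, nrow(Xf), ncol(M) * ncol(Xf))
      k <- 0L
      for (i in seq_len(ncol(M))) for (j in seq_len(ncol(Xf))) {
        k <- k + 1L
        out[, k] <- M[, i] * Xf[, j]
      }
      out
    }
  }
  M
}

term_contains <- function(term, inner) {
  all(strsplit(inner, ":", fixed = TRUE)[[1]] %in%
        strsplit(term, ":", fixed = TRUE)[[1]])
}

logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# Log marginal likelihood (up to factors common in y and n) of the g-prior
# linear model. `groups` is a list of column matrices sharing one g each;
# `g_draws` a matrix of Monte-Carlo draws of g (one column per group). The
# caller draws g so that marginals being compared can share draws for their
# common groups (common random numbers): near-degenerate responses — e.g.
# between-participant variance orders of magnitude above within — make the
# integrand spike on rare large participant-g draws, and sharing those draws
# lets the spikes cancel in the Bayes-factor ratio instead of inflating one
# marginal arbitrarily.
jzs_log_marginal <- function(y, groups, g_draws) {
  n <- length(y)
  if (!length(groups)) {
    Q <- sum(y^2) - sum(y)^2 / n
    return(-((n - 1) / 2) * log(Q))
  }
  X <- do.call(cbind, groups)
  gmap <- rep(seq_along(groups), vapply(groups, ncol, integer(1)))
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  Xt1 <- drop(crossprod(X, rep(1, n)))
  yty <- sum(y^2)
  sy <- sum(y)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: aliased terms among the model columns",
         call. = FALSE)
  logm <- vapply(seq_len(nrow(g_draws)), function(i) {
    gvec <- g_draws[i, gmap]
    M <- XtX
    diag(M) <- diag(M) + 1 / gvec
    R <- chol(M)
    logdetV <- 2 * sum(log(diag(R))) + sum(log(gvec))
    Ma <- backsolve(R, forwardsolve(t(R), Xt1))
    Mb <- backsolve(R, forwardsolve(t(R), Xty))
    s1 <- n - sum(Xt1 * Ma)
    syy <- yty - sum(Xty * Mb)
    s1y <- sy - sum(Xt1 * Mb)
    Q <- syy - s1y^2 / s1
    -0.5 * logdetV - 0.5 * log(s1 / n) - ((n - 1) / 2) * log(Q)
  }, numeric(1))
  logmeanexp(logm)
}

build_anova_terms <- function(table, value, factors, omit, participant) {
  stopifnot(all(c(value, participant) %in% names(table)))
  if (!omit %in% factors)
    stop("omitted term `", omit, "` is not in the full model", call. = FALSE)
  dropped <- factors[vapply(factors, term_contains, logical(1), inner = omit)]
  if (length(dropped) > 1L)
    scanlba_log("omitting `", omit, "` also drops containing interaction(s): ",
                paste(setdiff(dropped, omit), collapse = ", "))
  keep <- setdiff(factors, dropped)
  tab <- table[!is.na(table[[value]]), , drop = FALSE]
  list(table = tab, keep = keep, dropped = dropped)
}

#' Bayes factor for omitting one term from the full ANOVA model
#'
#' Computes `BF = m(full) / m(restricted)` where the full model contains every
#' term in `factors` plus an additive participant random effect, and the
#' restricted model omits `omit` together with any interaction containing it
#' (the model hierarchy is respected). `BF > 1` favors keeping the term.
#'
#' @param table long-format data.frame of responses (one row per participant x
#'   cell), e.g. a [cell_means()] table.
#' @param value name of the response column.
#' @param factors character vector of fixed-effect terms, interactions written
#'   `"a:b"`.
#' @param omit the term to omit.
#' @param participant name of the participant column (always retained as a
#'   random effect).
#' @param nsamples Monte-Carlo draws of g per marginal likelihood.
#' @param seed integer seed recorded in the result.
#' @param rscale_fixed,rscale_random prior scales of the standardized effects.
#' @param transform response transform: `"identity"` (default) or `"logit"`
#'   (for proportions such as error rates; values are clamped away from 0/1
#'   by half the smallest observable increment).
#' @return one-row data.frame: `value`, `omitted`, `bf`, `method`
#'   (`"jzs-mc"`), `nsamples`, `seed`.
#' @export
bf_omit_factor <- function(table, value, factors, omit,
                           participant = "participant", nsamples = 10000,
                           seed = NULL, rscale_fixed = 0.5,
                           rscale_random = 1,
                           transform = c("identity", "logit")) {
  transform <- match.arg(transform)
  at <- build_anova_terms(table, value, factors, omit, participant)
  tab <- at$table
  y <- as.numeric(tab[[value]])
  if (transform == "logit") {
    eps <- min(0.5 / max(table$n %||% 100, na.rm = TRUE), 0.01)
    y <- pmin(pmax(y, eps), 1 - eps)
    y <- log(y / (1 - y))
  }
  part_cols <- term_columns(tab, participant)
  full_groups <- c(list(part_cols), lapply(factors, term_columns, df = tab))
  full_scales <- c(rscale_random, rep(rscale_fixed, length(factors)))
  keep_idx <- c(1L, 1L + match(at$keep, factors))
  # one shared set of g draws over the full model's groups; the restricted
  # marginal reuses the draws of the groups it retains (common random numbers)
  g_all <- with_seed(seed %||% 1L, {
    matrix(rep(full_scales^2, each = nsamples) /
             rchisq(nsamples * length(full_groups), df = 1),
           nrow = nsamples)
  })
  lm_full <- jzs_log_marginal(y, full_groups, g_all)
  lm_restr <- jzs_log_marginal(y, full_groups[keep_idx],
                               g_all[, keep_idx, drop = FALSE])
  data.frame(value = value, omitted = omit, bf = exp(lm_full - lm_restr),
             method = "jzs-mc", nsamples = nsamples,
             seed = seed %||% NA_integer_, stringsAsFactors = FALSE)
}

#' BIC approximation to the omit-one-term Bayes factor
#'
#' `BF ~ exp((BIC_restricted - BIC_full) / 2)` from least-squares fits with
#' participant as an additive factor; a fast cross-check expected to agree in
#' direction with [bf_omit_factor()] on well-powered data.
#'
#' @inheritParams bf_omit_factor
#' @return one-row data.frame with `method = "bic-approx"`.
#' @export
bf_bic_approx <- function(table, value, factors, omit,
                          participant = "participant") {
  at <- build_anova_terms(table, value, factors, omit, participant)
  tab <- at$table
  tab$.y <- as.numeric(tab[[value]])
  for (f in unique(unlist(strsplit(c(factors, participant), ":"))))
    tab[[f]] <- factor(tab[[f]])
  form <- function(terms) as.formula(paste(
    ".y ~", paste(c(participant, terms, "1"), collapse = " + ")))
  bic_f <- stats::BIC(stats::lm(form(factors), data = tab))
  bic_r <- stats::BIC(stats::lm(form(at$keep), data = tab))
  data.frame(value = value, omitted = omit, bf = exp((bic_r - bic_f) / 2),
             method = "bic-approx", nsamples = NA_integer_,
             seed = NA_integer_, stringsAsFactors = FALSE)
}
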