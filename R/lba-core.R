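#' Single-accumulator LBA parameters
#'
#' Bundles the parameters of one linear ballistic accumulator: mean drift rate
#' `v` (evidence/s), between-trial drift standard deviation `sv`, start-point
#' range `A` (start points uniform on `[0, A]`), threshold `b`, and
#' non-decision time `t0` (s). The threshold is stored as `b_minus_A = b - A`
#' so that `b >= A` holds by construction.
#'
#' @param v mean drift rate.
#' @param sv between-trial drift SD, must be `> 0`.
#' @param A start-point range upper bound, `>= 0`.
#' @param b threshold; supply either `b` or `b_minus_A`.
#' @param b_minus_A distance from start-point range to threshold, `>= 0`.
#' @param t0 non-decision time in seconds, `>= 0`.
#' @return an object of class `lba_params`.
#' @examples
#' accumulator_params(v = 2, sv = 1, A = 0.5, b = 1)
#' @export
accumulator_params <- function(v, sv, A, b = NULL, b_minus_A = NULL, t0 = 0) {
  if (is.null(b_minus_A)) {
    if (is.null(b)) stop("supply either `b` or `b_minus_A`", call. = FALSE)
    b_minus_A <- b - A
  }
  p <- structure(
    list(v = as.numeric(v), sv = as.numeric(sv), A = as.numeric(A),
         b_minus_A = as.numeric(b_minus_A), t0 = as.numeric(t0)),
    class = "lba_params"
  )
  validate_lba_params(p)
  p
}

validate_lba_params <- function(p) {
  if (!is.finite(p$sv) || p$sv <= 0) stop("sv must be > 0", call. = FALSE)
  if (!is.finite(p$A) || p$A < 0) stop("A must be >= 0", call. = FALSE)
  if (!is.finite(p$b_minus_A) || p$b_minus_A < 0)
    stop("threshold b must be >= start-point range A (b_minus_A >= 0)", call. = FALSE)
  if (!is.finite(p$t0) || p$t0 < 0) stop("t0 must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.lba_params <- function(x, ...) {
  cat(sprintf("LBA accumulator: v=%.3f sv=%.3f A=%.3f b=%.3f t0=%.3f\n",
              x$v, x$sv, x$A, x$A + x$b_minus_A, x$t0))
  invisible(x)
}

#' Threshold of an accumulator
#' @param p an `lba_params` object.
#' @return numeric threshold `b = A + (b - A)`.
#' @export
lba_threshold <- function(p) p$A + p$b_minus_A

#' Race parameters for a multi-alternative LBA decision
#'
#' An ordered set of accumulators, one per response alternative, racing to
#' threshold. Exactly one accumulator is flagged as matching the stimulus
#' (drift `v_c`); the others are error accumulators (`v_e`). A shared
#' non-decision time `t0` applies to the race.
#'
#' @param accumulators list of [accumulator_params()] objects (length >= 2).
#' @param correct index of the stimulus-matching accumulator.
#' @param t0 shared non-decision time (s); overrides any per-accumulator `t0`.
#' @return an object of class `lba_race`.
#' @export
race_params <- function(accumulators, correct = 1L, t0 = 0) {
  if (length(accumulators) < 2L)
    stop("a race needs at least two accumulators", call. = FALSE)
  lapply(accumulators, validate_lba_params)
  correct <- as.integer(correct)
  if (correct < 1L || correct > length(accumulators))
    stop("`correct` must index one of the accumulators", call. = FALSE)
  if (!is.finite(t0) || t0 < 0) stop("t0 must be >= 0", call. = FALSE)
  structure(list(accumulators = accumulators, correct = correct,
                 t0 = as.numeric(t0)),
            class = "lba_race")
}

#' @export
print.lba_race <- function(x, ...) {
  cat(sprintf("LBA race: %d accumulators (correct = %d), t0 = %.3f s\n",
              length(x$accumulators), x$correct, x$t0))
  invisible(x)
}

#' LBA finishing-time CDF
#'
#' Probability that a single linear ballistic accumulator has reached its
#' threshold by decision time `t` (time measured from accumulation onset;
#' non-decision time is not included). Because drifts can be negative, the
#' distribution is defective: the limit as `t -> Inf` is `pnorm(v / sv)`.
#'
#' @param t decision time(s) in seconds (vectorized).
#' @param p an [accumulator_params()] object.
#' @return probabilities in `[0, 1]`, 0 for `t <= 0`.
#' @examples
#' lba_cdf(1, accumulator_params(v = 2, sv = 1, A = 0, b = 1)) # pnorm(1)
#' @export
lba_cdf <- function(t, p) {
  validate_lba_params(p)
  .lba_cdf_cpp(as.numeric(t), p$v, p$sv, p$A, lba_threshold(p))
}

#' LBA finishing-time density
#'
#' Density (1/s) of a single accumulator's threshold-crossing time at decision
#' time `t`; the derivative of [lba_cdf()].
#'
#' @inheritParams lba_cdf
#' @return non-negative densities, 0 for `t <= 0`.
#' @export
lba_pdf <- function(t, p) {
  validate_lba_params(p)
  .lba_pdf_cpp(as.numeric(t), p$v, p$sv, p$A, lba_threshold(p))
}

#' Defective density of responding with a given alternative at time rt
#'
#' The race semantics: the density that accumulator `response` finishes at
#' decision time `rt - t0` while every other accumulator is still below
#' threshold. Integrates over rt to the choice probability of that
#' alternative (< 1), and summed over alternatives to the total termination
#' probability.
#'
#' @param rt observed response time(s), seconds (vectorized).
#' @param response index of the responding accumulator.
#' @param race an [race_params()] object.
#' @return defective density values (1/s); 0 for `rt <= t0`.
#' @export
defective_density <- function(rt, response, race) {
  stopifnot(inherits(race, "lba_race"))
  response <- as.integer(response)
  m <- length(race$accumulators)
  if (length(response) != 1L || is.na(response) || response < 1L || response > m)
    stop("unknown response index", call. = FALSE)
  dt <- as.numeric(rt) - race$t0
  pr <- race$accumulators[[response]]
  g <- .lba_pdf_cpp(dt, pr$v, pr$sv, pr$A, lba_threshold(pr))
  for (j in seq_len(m)[-response]) {
    pj <- race$accumulators[[j]]
    g <- g * (1 - .lba_cdf_cpp(dt, pj$v, pj$sv, pj$A, lba_threshold(pj)))
  }
  g
}

#' Simulate ballistic race trials
#'
#' Draws one drift per accumulator per trial from `N(v, sv)` and one start
#' point from `U(0, A)`, computes deterministic crossing times, and records
#' the winner and its RT (crossing time plus `t0`). Trials on which every
#' sampled drift is `<= 0` never terminate and are flagged with response `NA`
#' ("none").
#'
#' @param race an [race_params()] object.
#' @param n number of trials (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with columns `response` (accumulator index, `NA` for
#'   non-terminating trials), `rt` (seconds, `NA` for non-terminating trials)
#'   and `correct` (logical).
#' @export
simulate_trials <- function(race, n, seed = NULL) {
  stopifnot(inherits(race, "lba_race"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  m <- length(race$accumulators)
  with_seed(seed, {
    finish <- matrix(Inf, nrow = n, ncol = m)
    for (j in seq_len(m)) {
      p <- race$accumulators[[j]]
      drift <- rnorm(n, p$v, p$sv)
      start <- if (p$A > 0) runif(n, 0, p$A) else rep(0, n)
      dist <- p$A + p$b_minus_A - start
      ok <- drift > 0
      finish[ok, j] <- dist[ok] / drift[ok]
    }
    winner <- max.col(-finish, ties.method = "first")
    tmin <- finish[cbind(seq_len(n), winner)]
    none <- !is.finite(tmin)
    winner[none] <- NA_integer_
    rt <- tmin + race$t0
    rt[none] <- NA_real_
    data.frame(response = winner, rt = rt,
               correct = !none & winner == race$correct)
  })
}

#' Log-likelihood of observed trials under per-trial race parameters
#'
#' Sums the log defective density over trials. Trials whose RT is at or below
#' the non-decision time, or whose density underflows to zero, contribute a
#' large finite floor (-1e10) rather than `-Inf`, keeping maximum-likelihood
#' search well defined near the `t0` boundary.
#'
#' @param rt numeric vector of response times (s).
#' @param response integer vector of responding-accumulator indices.
#' @param races either a single [race_params()] applied to every trial, or a
#'   list of races, one per trial.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(rt, response, races) {
  n <- length(rt)
  if (n == 0L) stop("empty trial set", call. = FALSE)
  if (inherits(races, "lba_race")) races <- rep(list(races), n)
  if (length(races) != n) stop("need one race per trial", call. = FALSE)
  m <- length(races[[1]]$accumulators)
  if (m == 2L) {
    get <- function(f) vapply(races, f, numeric(1))
    w <- as.integer(response); l <- 3L - w
    acc <- function(i, field) vapply(seq_len(n), function(k)
      races[[k]]$accumulators[[i[k]]][[field]], numeric(1))
    vw <- acc(w, "v"); svw <- acc(w, "sv"); Aw <- acc(w, "A")
    bw <- Aw + acc(w, "b_minus_A")
    vl <- acc(l, "v"); svl <- acc(l, "sv"); Al <- acc(l, "A")
    bl <- Al + acc(l, "b_minus_A")
    t0 <- get(function(r) r$t0)
    return(.lba_loglik2_cpp(rt, t0, vw, svw, Aw, bw, vl, svl, Al, bl))
  }
  ll <- 0
  for (k in seq_len(n)) {
    g <- defective_density(rt[k], response[k], races[[k]])
    ll <- ll + max(if (g > 0) log(g) else -1e10, -1e10)
  }
  ll
}
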