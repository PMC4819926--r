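# Per-participant maximum-likelihood estimation over a model hierarchy.
#
# The LBA likelihood is cheap but non-smooth near the t0 boundary, so models
# are fit with derivative-free simplex search from several starts: a naive
# default, any warm starts supplied by the caller (in hierarchy sweeps, the
# solutions of the immediately nested models expanded to the finer cell
# structure), and seeded random perturbations of the best start.

#' Naive default starting values for a spec
#'
#' Conventional starting region: `t0 = 0.8 * min(RT)`, `v_c = 2`, `v_e = 1`
#' (1.5 when drift does not vary by response type), `sv = 1`, `A = 0.5`,
#' `b - A = 0.5`. Overridden by warm starts everywhere except the simplest
#' hierarchy node.
#'
#' @param trials data.frame with an `rt` column (seconds).
#' @param spec an `lba_model_spec`.
#' @return named natural-scale parameter vector.
#' @export
default_init <- function(trials, spec) {
  sk <- theta_skeleton(spec)
  min_rt <- min(trials$rt, na.rm = TRUE)
  vals <- numeric(nrow(sk))
  for (i in seq_len(nrow(sk))) {
    type <- sk$type[i]; nm <- sk$cell_name[i]
    vals[i] <- switch(type,
      v = if (!"resptype" %in% spec$factors$v) 1.5
          else if (endsWith(nm, ".correct")) 2 else 1,
      sv = 1, A = 0.5, b_minus_A = 0.5, t0 = 0.8 * min_rt)
  }
  setNames(vals, sk$cell_name)
}

#' Fit one model to one participant's trials by maximum likelihood
#'
#' Runs Nelder-Mead simplex search on the unconstrained free scale from the
#' default start, each supplied init, and `n_restarts` seeded random
#' perturbations of the best of those, keeping the best solution. Trials with
#' response `"none"` (no accumulator terminated) are excluded with a logged
#' count before fitting.
#'
#' @param trials one participant's trials: data.frame with the design factor
#'   columns, `rt` (s) and `correct` (logical); optionally `response`.
#' @param spec an `lba_model_spec`.
#' @param inits optional list of natural-scale named vectors used as warm
#'   starts.
#' @param n_restarts number of random restarts around the best start.
#' @param seed integer seed for the restarts.
#' @param maxit,reltol control parameters passed to [stats::optim()].
#' @param max_starts optimize only this many starts, keeping those with the
#'   best initial likelihood (default: all). Hierarchy sweeps use 2, since
#'   the warm starts carry most of the information.
#' @param nm_cycles maximum simplex restarts from the incumbent solution per
#'   start (guards against premature simplex collapse).
#' @return an `lba_fit` list: `spec_id`, `k`, `n`, `logL`, `aic`, `bic`,
#'   `estimates` (natural scale), `convergence`, `restarts_used`, `ok`.
#' @export
fit_model <- function(trials, spec, inits = NULL, n_restarts = 3,
                      seed = NULL, maxit = 2000, reltol = 1e-8,
                      max_starts = NULL, nm_cycles = 3) {
  n_none <- if (!is.null(trials$response)) sum(trials$response == "none", na.rm = TRUE) else 0L
  if (n_none > 0)
    scanlba_log("excluding ", n_none, " non-terminating trial(s) before fitting")
  ll <- compile_loglik(trials, spec)
  d <- attr(ll, "data")
  n <- d$n_trials
  starts <- list(natural_to_free(default_init(trials, spec), spec))
  for (init in inits %||% list())
    starts <- c(starts, list(natural_to_free(init, spec)))
  obj <- function(free) -ll(free)
  vals <- vapply(starts, obj, numeric(1))
  best0 <- starts[[which.min(vals)]]
  if (n_restarts > 0) {
    jitter <- with_seed(seed, lapply(seq_len(n_restarts), function(i)
      best0 + rnorm(length(best0), 0, 0.3)))
    starts <- c(starts, jitter)
    vals <- c(vals, vapply(jitter, obj, numeric(1)))
  }
  if (!is.null(max_starts) && length(starts) > max_starts)
    starts <- starts[order(vals)][seq_len(max_starts)]
  # seeded random orientation of the initial simplex: on flat likelihood
  # directions the search stalls near its start, and a fixed orientation
  # would leave identically-signed micro-offsets in every participant
  k <- length(best0)
  signs <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                     sample(c(-1, 1), k, replace = TRUE))
  if (is.null(seed)) signs <- rep(1, k)
  nm <- function(st) .lba_nm_fit_cpp(unname(st), signs, d$rt, d$iv_w, d$isv_w,
                                     d$iA_w, d$ibA_w, d$iv_l, d$isv_l,
                                     d$iA_l, d$ibA_l, d$it0, d$log_scale,
                                     as.integer(d$free_slots),
                                     maxit = as.integer(maxit),
                                     reltol = reltol)
  best <- NULL
  used <- 0L
  for (st in starts) {
    fit <- tryCatch({
      f <- nm(st)
      # simplex search can stall on a collapsed simplex: restart from the
      # incumbent until no further improvement
      for (cycle in seq_len(nm_cycles)) {
        f2 <- nm(f$par)
        if (f$value - f2$value < 1e-6) { f <- if (f2$value < f$value) f2 else f; break }
        f <- f2
      }
      f
    }, error = function(e) NULL)
    used <- used + 1L
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    warning("all starts failed for model ", spec$id, call. = FALSE)
    return(structure(list(spec_id = spec$id, spec = spec, k = spec$k, n = n,
                          logL = NA_real_, aic = NA_real_, bic = NA_real_,
                          estimates = NULL, convergence = NA_integer_,
                          restarts_used = used, ok = FALSE),
                     class = "lba_fit"))
  }
  logL <- -best$value
  structure(list(spec_id = spec$id, spec = spec, k = spec$k, n = n,
                 logL = logL,
                 aic = 2 * spec$k - 2 * logL,
                 bic = spec$k * log(n) - 2 * logL,
                 estimates = free_to_natural(best$par, spec),
                 convergence = best$convergence,
                 restarts_used = used, ok = TRUE),
            class = "lba_fit")
}

#' @export
print.lba_fit <- function(x, ...) {
  cat(sprintf("<lba_fit> %s: logL = %.3f, k = %d, n = %d, AIC = %.2f%s\n",
              x$spec_id, x$logL, x$k, x$n, x$aic,
              if (!x$ok) " [FAILED]" else ""))
  invisible(x)
}

#' Fit every node of a model hierarchy to one participant, with warm starts
#'
#' Traverses the lattice in ascending free-parameter count. Each node is
#' started from the naive default plus the solutions of its immediately nested
#' predecessors expanded to the finer cell structure, which reduces the impact
#' of local minima; fit failures are propagated per node without aborting the
#' sweep.
#'
#' @param trials one participant's trials.
#' @param hierarchy an [enumerate_hierarchy()] object.
#' @param n_restarts random restarts per node (default 1 in sweeps; the warm
#'   starts do most of the work).
#' @param max_starts starts actually optimized per node after ranking by
#'   initial likelihood (default 2).
#' @param seed integer seed.
#' @param ... passed to [fit_model()].
#' @return named list of `lba_fit`, one per node id, in lattice order.
#' @export
fit_hierarchy <- function(trials, hierarchy, n_restarts = 1, seed = NULL,
                          max_starts = 2, nm_cycles = 1, ...) {
  stopifnot(inherits(hierarchy, "lba_hierarchy"))
  seeds <- derive_seeds(seed %||% 1L, length(hierarchy$nodes))
  fits <- list()
  for (i in seq_along(hierarchy$nodes)) {
    node <- hierarchy$nodes[[i]]
    inits <- list()
    for (cid in node$children) {
      f <- fits[[cid]]
      if (!is.null(f) && f$ok)
        inits <- c(inits, list(expand_theta(f$estimates, f$spec, node$spec)))
    }
    fits[[node$id]] <- fit_model(trials, node$spec, inits = inits,
                                 n_restarts = n_restarts, seed = seeds[i],
                                 max_starts = max_starts,
                                 nm_cycles = nm_cycles, ...)
  }
  fits
}

#' Fit a hierarchy for every participant
#'
#' @param trials trial data.frame with a `participant` column.
#' @param hierarchy an [enumerate_hierarchy()] object.
#' @param seed integer seed (one child seed per participant).
#' @param ... passed to [fit_hierarchy()].
#' @return list (participants) of named lists (models) of `lba_fit`.
#' @export
fit_participants <- function(trials, hierarchy, seed = NULL, ...) {
  ids <- sort(unique(trials$participant))
  seeds <- derive_seeds(seed %||% 1L, length(ids))
  out <- lapply(seq_along(ids), function(i) {
    scanlba_log("fitting participant ", ids[i])
    fit_hierarchy(trials[trials$participant == ids[i], , drop = FALSE],
                  hierarchy, seed = seeds[i], ...)
  })
  names(out) <- as.character(ids)
  out
}

#' Tidy table of fit results
#'
#' @param fits output of [fit_participants()] (or a single participant's named
#'   fit list).
#' @return data.frame with one row per participant x model.
#' @export
fit_table <- function(fits) {
  if (inherits(fits[[1]], "lba_fit")) fits <- list(`1` = fits)
  do.call(rbind, lapply(names(fits), function(p) {
    do.call(rbind, lapply(fits[[p]], function(f)
      data.frame(participant = p, model = f$spec_id, k = f$k, n = f$n,
                 logL = f$logL, aic = f$aic, bic = f$bic, ok = f$ok,
                 stringsAsFactors = FALSE)))
  }))
}
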