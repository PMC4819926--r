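# Trial-level synthetic data with the statistical structure the analysis
# assumes: participants drawn from Gaussian population distributions around
# design-specific generating parameters, trials simulated from the ballistic
# race, and a session effect injected in the MRI session under one of the four
# candidate accounts (motor slowing -> t0, response caution -> b - A,
# arousal -> v_c + v_e, attentional focus -> v_c - v_e).

ACCOUNTS <- c("none", "motor_slowing", "caution", "arousal", "focus")

default_magnitude <- function(account) {
  switch(account, none = 0, motor_slowing = 0.1, caution = 0.35,
         arousal = 0.8, focus = 0.8)
}

#' Map motion coherence to drift rates
#'
#' The drift-rate difference grows with coherence while the summed drift is
#' constant by default: `v_diff = v_diff_max * (coherence/80)^exponent`,
#' `v_c = (v_sum + v_diff)/2`, `v_e = (v_sum - v_diff)/2`.
#'
#' @param coherence coherence percentage(s) in (0, 100].
#' @param v_sum summed drift `v_c + v_e` (default 3.0).
#' @param v_diff_max drift difference at 80 \% coherence (default 2.4).
#' @param exponent curvature of the coherence-drift mapping (default 0.7).
#' @return data.frame with columns `coherence`, `v_c`, `v_e`.
#' @export
coherence_drift_map <- function(coherence, v_sum = 3.0, v_diff_max = 2.4,
                                exponent = 0.7) {
  coherence <- as.numeric(coherence)
  stopifnot(all(coherence > 0 & coherence <= 100))
  v_diff <- v_diff_max * (coherence / 80)^exponent
  data.frame(coherence = coherence, v_c = (v_sum + v_diff) / 2,
             v_e = (v_sum - v_diff) / 2)
}

# Generating spec and population means for each built-in design (behavioral
# session baseline; the session factor is added when an account is injected).
# With condition_effects = FALSE the condition manipulations are silenced and
# the generating model is exactly a node of the reduced session hierarchy
# (used for model-selection consistency studies).
generating_setup <- function(design, condition_effects = TRUE) {
  base <- c(v_c = 2.8, v_e = 1.2, sv = 1, A = 0.6, b_minus_A = 0.6, t0 = 0.25)
  if (!condition_effects) {
    spec <- model_spec(design, v = "resptype", sv = "resptype")
    means <- c(v.correct = unname(base["v_c"]), v.error = unname(base["v_e"]),
               sv.correct = 1, sv.error = 1,
               A = unname(base["A"]), b_minus_A = unname(base["b_minus_A"]),
               t0 = unname(base["t0"]))
  } else if (design$name == "bias") {
    spec <- model_spec(design, v = "resptype", sv = "resptype",
                       b_minus_A = "cueacc")
    means <- c(v.correct = unname(base["v_c"]), v.error = unname(base["v_e"]),
               sv.correct = 1, sv.error = 1,
               A = unname(base["A"]),
               b_minus_A.neutral = 0.6, b_minus_A.toward = 0.42,
               b_minus_A.against = 0.78,
               t0 = unname(base["t0"]))
  } else if (design$name == "sat") {
    spec <- model_spec(design, v = "resptype", sv = "resptype",
                       b_minus_A = "sat")
    means <- c(v.correct = unname(base["v_c"]), v.error = unname(base["v_e"]),
               sv.correct = 1, sv.error = 1,
               A = unname(base["A"]),
               b_minus_A.speed = 0.3, b_minus_A.neutral = 0.6,
               b_minus_A.accuracy = 0.9,
               t0 = unname(base["t0"]))
  } else if (design$name == "difficulty") {
    spec <- model_spec(design, v = c("coherence", "resptype"),
                       sv = "resptype")
    cmap <- coherence_drift_map(as.numeric(design$factors$coherence))
    means <- c(setNames(as.vector(rbind(cmap$v_c, cmap$v_e)),
                        paste0("v.", rep(design$factors$coherence, each = 2),
                               c(".correct", ".error"))),
               sv.correct = 1, sv.error = 1,
               A = unname(base["A"]), b_minus_A = unname(base["b_minus_A"]),
               t0 = unname(base["t0"]))
  } else {
    stop("no generating setup for design `", design$name, "`", call. = FALSE)
  }
  sk <- theta_skeleton(spec)
  if (!setequal(sk$cell_name, names(means)))
    stop("internal: generating means do not match spec cells")
  list(spec = spec, means = means[sk$cell_name])
}

# Trial schedule per design: rows of (session, <factors>, n trials), matching
# the study designs: probabilistic cueing 840 behavioral / 240 MRI trials per
# participant; SAT cueing likewise; difficulty 200 trials per block, 2 ITI
# blocks per session, 2 sessions = 800 trials.
trial_schedule <- function(design) {
  cells <- design$cells
  if (design$name %in% c("bias", "sat")) {
    per_session <- c(behavioral = 840, mri = 240)
    if (design$name == "bias") {
      # equal trials per cue; direction split by cue validity
      validity <- c(L9 = 0.9, L7 = 0.7, N = 0.5, R7 = 0.7, R9 = 0.9)
      toward_left <- c(L9 = TRUE, L7 = TRUE, N = NA, R7 = FALSE, R9 = FALSE)
      n <- numeric(nrow(cells))
      for (i in seq_len(nrow(cells))) {
        n_cue <- per_session[[cells$session[i]]] / length(design$factors$cue)
        v <- validity[[cells$cue[i]]]
        p_left <- if (is.na(toward_left[[cells$cue[i]]])) 0.5
                  else if (toward_left[[cells$cue[i]]]) v else 1 - v
        n[i] <- round(n_cue * if (cells$direction[i] == "left") p_left else 1 - p_left)
      }
      cells$n <- n
    } else {
      cells$n <- per_session[cells$session] / length(design$factors$sat)
    }
  } else if (design$name == "difficulty") {
    cells$n <- 200 / length(design$factors$coherence)  # 40 per coherence/block
  } else {
    stop("no trial schedule for design `", design$name, "`", call. = FALSE)
  }
  cells
}

default_n_participants <- function(design) {
  switch(design$name, bias = 19L, sat = 19L, difficulty = 20L, 20L)
}

# Add the session factor to the generating spec for the parameter type the
# account targets, with the MRI-side shift applied.
inject_account <- function(spec, theta, account, magnitude) {
  design <- spec$design
  shift_type <- switch(account, none = NULL, motor_slowing = "t0",
                       caution = "b_minus_A", arousal = "v", focus = "v")
  if (is.null(shift_type)) return(list(spec = spec, theta = theta))
  fac <- spec$factors
  fac[[shift_type]] <- intersect(FACTOR_ORDER, c(fac[[shift_type]], "session"))
  spec2 <- model_spec(design, v = fac$v, sv = fac$sv, A = fac$A,
                      b_minus_A = fac$b_minus_A, t0 = fac$t0)
  theta2 <- expand_theta(theta, spec, spec2)
  cells <- spec_type_cells(spec2, shift_type)
  mri <- cells$cell_name[cells$session == "mri"]
  if (account == "motor_slowing") {
    theta2[mri] <- theta2[mri] + magnitude
  } else if (account == "caution") {
    theta2[mri] <- theta2[mri] + magnitude
  } else if (account == "arousal") {
    theta2[mri] <- theta2[mri] + magnitude / 2  # v_c and v_e move equally
  } else if (account == "focus") {
    corr <- mri[cells$resptype[cells$session == "mri"] == "correct"]
    err <- setdiff(mri, corr)
    theta2[corr] <- theta2[corr] - magnitude / 2  # v_c - v_e drops by magnitude
    theta2[err] <- theta2[err] + magnitude / 2
  }
  list(spec = spec2, theta = theta2)
}

#' Generate a synthetic experiment
#'
#' Draws participant-level parameters from Gaussian population distributions
#' (SD a fixed fraction of each mean, truncated to validity), injects the
#' requested session effect in the MRI session, and simulates every trial
#' through the ballistic race. Trial counts follow the study designs: 840
#' behavioral + 240 MRI trials per participant for the cueing designs, 2
#' sessions x 2 ITI blocks x 200 trials for the difficulty design. Session
#' order is counterbalanced for the difficulty design and behavioral-first
#' otherwise; order and ITI are generated as inert factors.
#'
#' @param design a design name (`"bias"`, `"sat"`, `"difficulty"`) or an
#'   [build_design()] object.
#' @param account session-effect account: one of `"none"`, `"motor_slowing"`,
#'   `"caution"`, `"arousal"`, `"focus"`.
#' @param magnitude additive MRI-session shift on the account's quantity
#'   (seconds for `t0`, evidence units otherwise); defaults per account.
#' @param n_participants number of participants (defaults: 19 for the cueing
#'   designs, 20 for difficulty).
#' @param population_sd population SD as a fraction of each parameter mean
#'   (default 0.15).
#' @param trials_scale optional multiplier on the per-cell trial counts (e.g.
#'   0.5 halves every cell; counts are rounded); default 1 = the study
#'   schedule.
#' @param condition_effects if `FALSE`, the condition manipulations (cue, SAT,
#'   coherence) are silenced so the generating model is exactly a node of the
#'   reduced session hierarchy; default `TRUE`.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return list with `trials` (data.frame of TrialRecords) and `truth`
#'   (generating spec, per-participant true parameter vectors, account and
#'   magnitude).
#' @export
generate_experiment <- function(design, account = "none", magnitude = NULL,
                                n_participants = NULL, population_sd = 0.15,
                                trials_scale = 1, condition_effects = TRUE,
                                seed = 1L) {
  if (is.character(design)) design <- build_design(design)
  stopifnot(inherits(design, "lba_design"))
  account <- match.arg(account, ACCOUNTS)
  magnitude <- magnitude %||% default_magnitude(account)
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  if (population_sd < 0) stop("population_sd must be >= 0", call. = FALSE)
  n_participants <- as.integer(n_participants %||% default_n_participants(design))
  setup <- generating_setup(design, condition_effects)
  sched <- trial_schedule(design)
  if (trials_scale != 1) sched$n <- round(sched$n * trials_scale)
  # The LBA evidence scale is arbitrary within participant, so the anchored sv
  # cell stays at 1 for everyone; population variability on it would only
  # rescale, not change, each participant's data-generating process.
  anchored <- theta_skeleton(setup$spec)$anchored

  with_seed(seed, {
    truth_params <- list()
    trials <- vector("list", n_participants)
    for (p in seq_len(n_participants)) {
      # participant-level parameters, truncated to validity by redrawing
      th <- setup$means
      for (j in seq_along(th)) {
        if (anchored[j]) next
        repeat {
          cand <- rnorm(1, setup$means[j], population_sd * abs(setup$means[j]))
          if (!startsWith(names(th)[j], "v") && cand <= POSITIVE_FLOOR) next
          th[j] <- cand
          break
        }
      }
      inj <- inject_account(setup$spec, th, account, magnitude)
      truth_params[[p]] <- inj$theta
      session_order <- if (design$name == "difficulty") {
        if (p %% 2L == 1L) "behavioral_first" else "mri_first"
      } else "behavioral_first"
      rows <- vector("list", nrow(sched))
      for (i in seq_len(nrow(sched))) {
        n <- sched$n[i]
        if (n < 1) next
        race <- resolve_params(inj$spec, inj$theta, sched$cell_id[i])
        sim <- simulate_trials(race, n)
        rec <- sched[rep(i, n), setdiff(names(sched), c("n", "cell_id")),
                     drop = FALSE]
        rec$participant <- p
        rec$session_order <- session_order
        if (is.null(rec$direction))
          rec$direction <- sample(design$responses, n, replace = TRUE)
        rec$response <- ifelse(is.na(sim$response), "none",
                        ifelse(sim$response == race$correct, rec$direction,
                               ifelse(rec$direction == "left", "right", "left")))
        rec$rt <- sim$rt
        rec$correct <- ifelse(rec$response == "none", NA, sim$correct)
        rows[[i]] <- rec
      }
      trials[[p]] <- do.call(rbind, rows)
    }
    trials <- do.call(rbind, trials)
    front <- c("participant", "session", "session_order")
    trials <- trials[c(front, setdiff(names(trials), front))]
    rownames(trials) <- NULL
    n_none <- sum(trials$response == "none")
    if (n_none > 0)
      scanlba_log(n_none, " non-terminating trial(s) generated (response = 'none')")
    list(trials = trials,
         truth = list(design = design$name, spec = inj$spec,
                      base_spec = setup$spec, params = truth_params,
                      account = account, magnitude = magnitude,
                      population_sd = population_sd, seed = seed))
  })
}

#' Write a trial dataset to CSV
#'
#' RTs are written in seconds under the header `rt`.
#'
#' @param trials trial data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial dataset from CSV
#'
#' Accepts an `rt` column in seconds or an `rt_ms` column in milliseconds
#' (converted at this boundary). If a design is supplied, factor levels are
#' validated and offending rows/columns named.
#'
#' @param path CSV file path.
#' @param design optional [build_design()] object for level validation.
#' @return trial data.frame with `rt` in seconds.
#' @export
read_dataset <- function(path, design = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("rt_ms" %in% names(df) && !"rt" %in% names(df)) {
    df$rt <- df$rt_ms / 1000
    df$rt_ms <- NULL
  }
  required <- c("participant", "session", "response", "rt", "correct")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("dataset schema error; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.null(design)) {
    for (nm in names(design$factors)) {
      if (is.null(df[[nm]]))
        stop("dataset schema error; missing factor column `", nm, "`",
             call. = FALSE)
      bad <- which(!(df[[nm]] %in% design$factors[[nm]]) & !is.na(df[[nm]]))
      if (length(bad))
        stop("malformed factor level in column `", nm, "`, row ", bad[1],
             ": `", df[[nm]][bad[1]], "`", call. = FALSE)
    }
  }
  df
}
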