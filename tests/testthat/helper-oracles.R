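# Shared oracles and fixture builders (all fixtures are built in code).

# Monte-Carlo finishing-time CDF of a single ballistic accumulator: the
# simulation oracle that the closed forms are checked against.
mc_cdf_oracle <- function(t, p, n = 1e6, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    set.seed(seed)
    drift <- rnorm(n, p$v, p$sv)
    start <- if (p$A > 0) runif(n, 0, p$A) else rep(0, n)
    finish <- ifelse(drift > 0, (p$A + p$b_minus_A - start) / drift, Inf)
    vapply(t, function(ti) mean(finish <= ti), numeric(1))
  })
}

# Random valid accumulator parameters in a plausible regime.
random_params <- function(seed) {
  set.seed(seed)
  accumulator_params(v = runif(1, 0.5, 3.5), sv = runif(1, 0.4, 1.6),
                     A = runif(1, 0.1, 1), b_minus_A = runif(1, 0.1, 1))
}

random_race <- function(seed) {
  set.seed(seed)
  race_params(list(
    accumulator_params(v = runif(1, 1.5, 3.5), sv = runif(1, 0.6, 1.4),
                       A = runif(1, 0.2, 0.8), b_minus_A = runif(1, 0.2, 0.9)),
    accumulator_params(v = runif(1, 0.2, 1.5), sv = runif(1, 0.6, 1.4),
                       A = runif(1, 0.2, 0.8), b_minus_A = runif(1, 0.2, 0.9))),
    correct = 1L, t0 = runif(1, 0.15, 0.35))
}

# Pure-R reimplementation of the defective race density (independent of the
# compiled path) used as a per-trial likelihood oracle.
defective_density_R <- function(rt, response, race) {
  dt <- rt - race$t0
  F1 <- function(t, p) {
    if (t <= 0) return(0)
    b <- p$A + p$b_minus_A
    z1 <- (b - p$A - t * p$v) / (t * p$sv)
    z2 <- (b - t * p$v) / (t * p$sv)
    min(max(1 + ((b - p$A - t * p$v) / p$A) * pnorm(z1) -
              ((b - t * p$v) / p$A) * pnorm(z2) +
              (t * p$sv / p$A) * (dnorm(z1) - dnorm(z2)), 0), 1)
  }
  f1 <- function(t, p) {
    if (t <= 0) return(0)
    b <- p$A + p$b_minus_A
    z1 <- (b - p$A - t * p$v) / (t * p$sv)
    z2 <- (b - t * p$v) / (t * p$sv)
    max((1 / p$A) * (-p$v * pnorm(z1) + p$sv * dnorm(z1) +
                       p$v * pnorm(z2) - p$sv * dnorm(z2)), 0)
  }
  g <- f1(dt, race$accumulators[[response]])
  for (j in seq_along(race$accumulators)[-response])
    g <- g * (1 - F1(dt, race$accumulators[[j]]))
  g
}

# Trials data.frame for a single-condition custom design simulated from a
# known race, for recovery and likelihood tests.
make_flat_trials <- function(race, n, seed, session = "behavioral") {
  sim <- simulate_trials(race, n, seed = seed)
  data.frame(participant = 1L, session = session,
             response = ifelse(is.na(sim$response), "none",
                               ifelse(sim$response == 1L, "left", "right")),
             rt = sim$rt,
             correct = ifelse(is.na(sim$response), NA, sim$correct))
}

flat_design <- function() {
  build_design("custom", config = list(
    name = "flat", factors = list(session = c("behavioral", "mri"))))
}

reduced_hierarchy <- function(design = build_design("difficulty")) {
  enumerate_hierarchy(reduced_top_model(design),
                      locked = list(v = "resptype", sv = "resptype"))
}
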