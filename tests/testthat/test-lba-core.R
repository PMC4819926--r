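test_that("finishing-time CDF has correct limits, bounds and monotonicity", {
  p <- accumulator_params(v = 1.5, sv = 0.8, A = 0.6, b = 1.2)
  expect_identical(lba_cdf(-1, p), 0)
  expect_identical(lba_cdf(0, p), 0)

  # degenerate-drift limit: finishing time uniform on [(b-A)/v, b/v]
  pu <- accumulator_params(v = 2, sv = 1e-9, A = 0.5, b = 1)
  expect_equal(lba_cdf(0.375, pu), 0.5)
  expect_equal(lba_cdf(0.25, pu), 0)
  expect_equal(lba_cdf(0.5, pu), 1)

  # A -> 0 limit: Gaussian closed form
  pg <- accumulator_params(v = 2, sv = 1, A = 0, b = 1)
  expect_equal(lba_cdf(1, pg), pnorm(1), tolerance = 1e-12)

  # termination probability: lim t -> Inf F = pnorm(v / sv)
  expect_equal(lba_cdf(1e6, p), pnorm(p$v / p$sv), tolerance = 1e-6)

  # bounds and monotonicity over random valid parameter sets
  tt <- seq(0, 5, length.out = 200)
  for (s in 1:20) {
    pr <- random_params(s)
    Fv <- lba_cdf(tt, pr)
    expect_true(all(Fv >= 0 & Fv <= 1))
    expect_true(all(diff(Fv) >= -1e-12))
  }
})

test_that("closed-form CDF matches the ballistic simulation oracle", {
  p <- accumulator_params(v = 1.5, sv = 0.8, A = 0.6, b = 1.2)
  # frozen from mc_cdf_oracle(0.9, p, n = 1e6, seed = 42): 0.72808
  expect_equal(lba_cdf(0.9, p), 0.72808, tolerance = 0.002)
  expect_equal(lba_cdf(0.9, p), mc_cdf_oracle(0.9, p, n = 1e5, seed = 7),
               tolerance = 0.005)
})

test_that("closed-form limits agree with the limit laws near the guards", {
  # sv -> 0: uniform law, checked at sv = 1e-6 against the exact uniform CDF
  p <- accumulator_params(v = 2, sv = 1e-6, A = 0.5, b = 1)
  tt <- seq(0.2, 0.6, by = 0.01)
  unif <- pmin(pmax((tt * 2 - 0.5) / 0.5, 0), 1)
  expect_lt(max(abs(lba_cdf(tt, p) - unif)), 1e-4)

  # A -> 0: Gaussian law, checked at A = 1e-8 against the exact form
  pa <- accumulator_params(v = 2, sv = 1, A = 1e-8, b = 1)
  tt <- seq(0.1, 3, by = 0.05)
  gauss <- pnorm((2 - 1 / tt) / 1)
  expect_lt(max(abs(lba_cdf(tt, pa) - gauss)), 1e-4)
})

test_that("density is the derivative of the CDF and integrates to the termination probability", {
  p <- accumulator_params(v = 1.5, sv = 0.8, A = 0.6, b = 1.2)
  expect_identical(lba_pdf(0, p), 0)
  expect_identical(lba_pdf(-0.3, p), 0)
  h <- 1e-5
  for (t in c(0.3, 0.5, 0.9, 1.5, 3)) {
    fd <- (lba_cdf(t + h, p) - lba_cdf(t - h, p)) / (2 * h)
    expect_equal(lba_pdf(t, p), fd, tolerance = 1e-6)
  }
  p2 <- accumulator_params(v = 1, sv = 1, A = 0.5, b = 1)
  q <- integrate(function(t) lba_pdf(t, p2), 0, Inf, rel.tol = 1e-9)$value
  expect_equal(q, pnorm(1), tolerance = 1e-4)
})

test_that("defective density has race semantics", {
  # symmetry of identical accumulators: each response gets half the
  # termination mass (1 - pnorm(-v/sv)^2) / 2
  acc <- accumulator_params(v = 1.2, sv = 1, A = 0.5, b = 1)
  race <- race_params(list(acc, acc), correct = 1L, t0 = 0.2)
  p1 <- integrate(function(t) defective_density(t, 1, race), 0.2, Inf,
                  rel.tol = 1e-8)$value
  p2 <- integrate(function(t) defective_density(t, 2, race), 0.2, Inf,
                  rel.tol = 1e-8)$value
  expect_equal(p1, p2, tolerance = 1e-8)
  expect_equal(p1, (1 - pnorm(-1.2)^2) / 2, tolerance = 1e-6)

  expect_identical(defective_density(0.2, 1, race), 0)  # rt = t0
  expect_error(defective_density(0.5, 3, race), "response")

  # evidence-scale invariance: scaling (A, b, v, sv) by c leaves g unchanged
  r1 <- race_params(list(accumulator_params(v = 2.5, sv = 1, A = 0.5, b = 1),
                         accumulator_params(v = 1.0, sv = 1, A = 0.5, b = 1)),
                    correct = 1L, t0 = 0.2)
  for (c in c(2, 0.37, 11)) {
    r2 <- race_params(lapply(r1$accumulators, function(a)
      accumulator_params(v = c * a$v, sv = c * a$sv, A = c * a$A,
                         b_minus_A = c * a$b_minus_A)), correct = 1L, t0 = 0.2)
    tt <- seq(0.25, 2.5, by = 0.05)
    expect_lt(max(abs(defective_density(tt, 1, r1) -
                        defective_density(tt, 1, r2))), 1e-10)
  }

  # choice probability matches large-n simulation
  pc <- integrate(function(t) defective_density(t, 1, r1), 0.2, Inf,
                  rel.tol = 1e-9)$value
  s <- simulate_trials(r1, 1e6, seed = 7)
  expect_equal(pc, mean(s$correct), tolerance = 0.002)
})

test_that("simulated trials respect t0, dominance and the analytic defective CDF", {
  race <- random_race(11)
  s <- simulate_trials(race, 10, seed = 1)
  expect_true(all(is.na(s$rt) | s$rt >= race$t0))

  dom <- race_params(list(accumulator_params(v = 10, sv = 0.1, A = 0.5, b = 1),
                          accumulator_params(v = 0.1, sv = 0.1, A = 0.5, b = 1)),
                     correct = 1L, t0 = 0.2)
  sd1 <- simulate_trials(dom, 1e4, seed = 2)
  expect_gt(mean(sd1$correct), 0.99)

  # empirical CDF of simulated correct RTs vs analytic defective CDF
  s <- simulate_trials(race, 1e5, seed = 3)
  rt_c <- s$rt[!is.na(s$response) & s$response == 1L]
  tt <- seq(race$t0, max(rt_c) + 0.5, length.out = 300)
  emp <- ecdf(rt_c)(tt) * length(rt_c) / nrow(s)
  ana <- vapply(tt, function(t) integrate(function(u)
    defective_density(u, 1, race), race$t0, t, rel.tol = 1e-7)$value,
    numeric(1))
  expect_lt(max(abs(emp - ana)), 0.01)

  # reproducibility
  expect_identical(simulate_trials(race, 50, seed = 9),
                   simulate_trials(race, 50, seed = 9))
})

test_that("log-likelihood sums per-trial log defective densities", {
  race <- random_race(5)
  d <- defective_density(0.6, 1, race)
  expect_equal(log_likelihood(0.6, 1L, race), log(d), tolerance = 1e-12)

  # additivity over concatenated trial sets
  rt <- c(0.5, 0.7, 0.9, 1.1); resp <- c(1L, 2L, 1L, 1L)
  ll_all <- log_likelihood(rt, resp, race)
  ll_split <- log_likelihood(rt[1:2], resp[1:2], race) +
    log_likelihood(rt[3:4], resp[3:4], race)
  expect_equal(ll_all, ll_split, tolerance = 1e-10)

  # independent pure-R oracle per trial
  ll_R <- sum(vapply(seq_along(rt), function(i)
    log(defective_density_R(rt[i], resp[i], race)), numeric(1)))
  expect_equal(ll_all, ll_R, tolerance = 1e-8)

  # rt <= t0 contributes the finite floor, not -Inf
  ll_floor <- log_likelihood(c(0.6, race$t0 - 0.01), c(1L, 1L), race)
  expect_true(is.finite(ll_floor))
  expect_lt(ll_floor, -1e9)

  expect_error(log_likelihood(numeric(0), integer(0), race), "empty")
})

test_that("parameter validation rejects invalid accumulators", {
  expect_error(accumulator_params(v = 1, sv = 0, A = 0.5, b = 1), "sv")
  expect_error(accumulator_params(v = 1, sv = 1, A = -0.1, b = 1), "A")
  expect_error(accumulator_params(v = 1, sv = 1, A = 0.5, b = 0.3),
               "threshold")
  expect_error(accumulator_params(v = 1, sv = 1, A = 0.5, b = 1, t0 = -1),
               "t0")
  expect_error(race_params(list(accumulator_params(v = 1, sv = 1, A = 0, b = 1))),
               "two accumulators")
})
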