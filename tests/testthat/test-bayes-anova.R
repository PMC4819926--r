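test_that("cell means compute correct-RT means and error rates", {
  tr <- data.frame(participant = 1L, session = "behavioral",
                   response = c("left", "left", "right", "left"),
                   rt = c(0.4, 0.6, 0.5, 0.7),
                   correct = c(TRUE, TRUE, FALSE, TRUE))
  cm <- cell_means(tr, "session")
  expect_equal(cm$error_rate, 0.25)
  expect_equal(cm$rt_mean, mean(c(0.4, 0.6, 0.7)))

  tr2 <- data.frame(participant = 1L, session = "behavioral",
                    response = c("left", "left"), rt = c(0.4, 0.6),
                    correct = TRUE)
  expect_equal(cell_means(tr2, "session")$rt_mean, 0.5)

  # 'none' responses are excluded; empty cells warn
  tr3 <- rbind(tr, data.frame(participant = 1L, session = "mri",
                              response = "none", rt = NA, correct = NA))
  expect_warning(cm3 <- cell_means(tr3, "session"), "empty")
  expect_true(is.na(cm3$rt_mean[cm3$session == "mri"]))
  expect_equal(cm3$n[cm3$session == "mri"], 0L)
})

test_that("within-subject SEs remove additive subject effects", {
  cells <- expand.grid(participant = 1:2, cond = c("a", "b", "c"))
  cells$y <- c(1, 3, 2, 4, 5, 7)  # participant 2 = participant 1 + 2
  se <- within_subject_se(cells, "y", cell_cols = "cond")
  expect_equal(se$se, rep(0, 3))

  # centering leaves cell means unchanged
  y <- cells$y
  centered <- y - ave(y, cells$participant) + mean(y)
  expect_equal(tapply(centered, cells$cond, mean),
               tapply(y, cells$cond, mean))

  # brute-force two-step oracle on a random 5 x 4 table
  set.seed(31)
  tab <- expand.grid(participant = 1:5, cond = letters[1:4])
  tab$y <- rnorm(20)
  se2 <- within_subject_se(tab, "y", cell_cols = "cond")
  pm <- tapply(tab$y, tab$participant, mean)
  adj <- tab$y - pm[tab$participant] + mean(tab$y)
  oracle <- tapply(adj, tab$cond, sd) / sqrt(5)
  expect_equal(se2$se, as.vector(oracle[se2$cond]), tolerance = 1e-12)

  expect_error(within_subject_se(tab[tab$participant == 1, ], "y",
                                 cell_cols = "cond"), "participants")
})

test_that("the conditional g-prior marginal matches direct numerical integration", {
  # for fixed g, the closed-form marginal (grand mean and sigma^2 integrated
  # out) must match brute-force quadrature over (mu, sigma^2); checked as a
  # ratio between two nested designs so constants cancel
  set.seed(3)
  n <- 6
  y <- rnorm(n, 1, 1.3)
  closed <- function(X, G) {
    V <- diag(n) + X %*% G %*% t(X)
    Vi <- solve(V)
    s1 <- sum(Vi); s1y <- sum(Vi %*% y); syy <- drop(t(y) %*% Vi %*% y)
    Q <- syy - s1y^2 / s1
    -0.5 * as.numeric(determinant(V)$modulus) - 0.5 * log(s1 / n) -
      ((n - 1) / 2) * log(Q)
  }
  numint <- function(X, G) {
    V <- diag(n) + X %*% G %*% t(X)
    Vi <- solve(V); ld <- as.numeric(determinant(V)$modulus)
    f <- function(mu, s2) {
      r <- y - mu
      exp(-0.5 * ld - (n / 2) * log(2 * pi * s2) -
            drop(t(r) %*% Vi %*% r) / (2 * s2)) / s2
    }
    log(integrate(Vectorize(function(mu)
      integrate(function(s2v) vapply(s2v, function(s2) f(mu, s2), numeric(1)),
                0, Inf, rel.tol = 1e-10)$value),
      -40, 40, rel.tol = 1e-10)$value)
  }
  X1 <- matrix(rep(c(1, -1), 3), ncol = 1)
  X2 <- cbind(X1, c(1, 1, -1, -1, 0, 0))
  G1 <- diag(0.3, 1); G2 <- diag(c(0.3, 0.8))
  expect_equal(closed(X2, G2) - closed(X1, G1),
               numint(X2, G2) - numint(X1, G1), tolerance = 1e-6)
})

test_that("the MC marginal agrees with an independent dense-matrix implementation", {
  set.seed(12)
  tab <- expand.grid(participant = 1:6, cond = c("a", "b", "c"))
  tab$y <- rnorm(18) + rep(rnorm(6), 3)
  y <- tab$y
  n <- length(y)
  Xp <- scanlba:::term_columns(tab, "participant")
  Xc <- scanlba:::term_columns(tab, "cond")
  groups <- list(Xp, Xc); scales <- c(1, 0.5)
  set.seed(99)
  gmat <- matrix(rep(scales^2, each = 500) / rchisq(1000, df = 1), nrow = 500)
  fast <- scanlba:::jzs_log_marginal(y, groups, gmat)
  # brute force: same g draws, dense V per draw
  X <- cbind(Xp, Xc)
  gmap <- rep(1:2, c(ncol(Xp), ncol(Xc)))
  logm <- vapply(1:500, function(i) {
    V <- diag(n) + X %*% diag(gmat[i, gmap]) %*% t(X)
    Vi <- solve(V)
    s1 <- sum(Vi); s1y <- sum(Vi %*% y); syy <- drop(t(y) %*% Vi %*% y)
    Q <- syy - s1y^2 / s1
    -0.5 * as.numeric(determinant(V)$modulus) - 0.5 * log(s1 / n) -
      ((n - 1) / 2) * log(Q)
  }, numeric(1))
  brute <- max(logm) + log(mean(exp(logm - max(logm))))
  expect_equal(fast, brute, tolerance = 1e-8)
})

test_that("Bayes factors are scale invariant, reciprocal-consistent and MC-stable", {
  set.seed(8)
  tab <- expand.grid(participant = 1:10, session = c("a", "b"))
  tab$y <- rnorm(20) + rep(rnorm(10), 2) + ifelse(tab$session == "b", 0.5, 0)

  bf <- bf_omit_factor(tab, "y", "session", "session", nsamples = 2000,
                       seed = 5)
  tab$y10 <- tab$y * 10
  bf10 <- bf_omit_factor(tab, "y10", "session", "session", nsamples = 2000,
                         seed = 5)
  # exact up to floating-point rounding under shared g draws
  expect_equal(bf$bf, bf10$bf, tolerance = 1e-10)

  # reciprocal identity with independent draws
  bf_a <- bf_omit_factor(tab, "y", "session", "session", nsamples = 20000,
                         seed = 101)$bf
  bf_b <- bf_omit_factor(tab, "y", "session", "session", nsamples = 20000,
                         seed = 202)$bf
  expect_equal(bf_a * (1 / bf_b), 1, tolerance = 0.1)

  # doubling the MC samples moves log BF by < 0.1
  bf_1 <- bf_omit_factor(tab, "y", "session", "session", nsamples = 10000,
                         seed = 7)$bf
  bf_2 <- bf_omit_factor(tab, "y", "session", "session", nsamples = 20000,
                         seed = 8)$bf
  expect_lt(abs(log(bf_1) - log(bf_2)), 0.1)
})

test_that("the logit transform option maps proportions before analysis", {
  set.seed(14)
  tab <- expand.grid(participant = 1:10, session = c("a", "b"))
  tab$y <- plogis(rnorm(20) + rep(rnorm(10), 2) +
                    ifelse(tab$session == "b", 1.5, 0))
  tab$n <- 100
  b_id <- bf_omit_factor(tab, "y", "session", "session", nsamples = 1000,
                         seed = 3)
  b_lo <- bf_omit_factor(tab, "y", "session", "session", nsamples = 1000,
                         seed = 3, transform = "logit")
  expect_gt(b_lo$bf, 1)   # effect still detected on the logit scale
  expect_false(identical(b_id$bf, b_lo$bf))
})

test_that("omitting a main effect drops its interactions, and misuse errors", {
  set.seed(9)
  tab <- expand.grid(participant = 1:8, a = c("x", "y"), b = c("p", "q"))
  tab$y <- rnorm(32)
  terms <- c("a", "b", "a:b")
  bf <- bf_omit_factor(tab, "y", terms, "a", nsamples = 500, seed = 1)
  expect_s3_class(bf, "data.frame")
  expect_equal(bf$method, "jzs-mc")
  expect_gt(bf$bf, 0)
  expect_error(bf_omit_factor(tab, "y", terms, "c", nsamples = 100),
               "not in the full model")

  # rank deficiency: duplicated factor columns alias
  tab$a2 <- tab$a
  expect_error(bf_omit_factor(tab, "y", c("a", "a2"), "a", nsamples = 10,
                              seed = 1), "rank-deficient")
})

test_that("the BIC approximation follows its closed form and agrees in direction", {
  set.seed(10)
  tab <- expand.grid(participant = 1:12, session = c("a", "b"))
  tab$y <- rnorm(24) + rep(rnorm(12), 2) + ifelse(tab$session == "b", 1.2, 0)
  full <- lm(y ~ participant + session, transform(tab, participant = factor(participant)))
  restr <- lm(y ~ participant, transform(tab, participant = factor(participant)))
  bb <- bf_bic_approx(tab, "y", "session", "session")
  expect_equal(bb$bf, exp((BIC(restr) - BIC(full)) / 2), tolerance = 1e-10)
  expect_equal(bb$method, "bic-approx")

  # direction agreement with the MC Bayes factor on simulated tables
  set.seed(11)
  agree <- vapply(1:12, function(i) {
    tab <- expand.grid(participant = 1:12, session = c("a", "b"))
    eff <- sample(c(0, 1.5), 1)
    tab$y <- rnorm(24) + rep(rnorm(12), 2) +
      ifelse(tab$session == "b", eff, 0)
    b1 <- bf_omit_factor(tab, "y", "session", "session", nsamples = 2000,
                         seed = i)$bf
    b2 <- bf_bic_approx(tab, "y", "session", "session")$bf
    (b1 > 1) == (b2 > 1)
  }, logical(1))
  expect_gte(mean(agree), 0.75)
})
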