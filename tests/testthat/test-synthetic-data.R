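test_that("trial counts match the study schedules", {
  g3 <- generate_experiment("difficulty", n_participants = 2, seed = 1)
  counts <- table(g3$trials$participant)
  expect_true(all(counts == 800))
  per_block <- table(g3$trials$session, g3$trials$iti,
                     g3$trials$participant)
  expect_true(all(per_block == 200))

  g1 <- generate_experiment("bias", n_participants = 1, seed = 2)
  expect_equal(sum(g1$trials$session == "behavioral"), 840)
  expect_equal(sum(g1$trials$session == "mri"), 240)
  # cue validity: reliable cues are valid on 90 % of trials
  beh <- g1$trials[g1$trials$session == "behavioral" & g1$trials$cue == "L9", ]
  expect_equal(mean(beh$direction == "left"), 0.9, tolerance = 0.01)

  expect_equal(scanlba:::default_n_participants(build_design("difficulty")), 20L)
  expect_equal(scanlba:::default_n_participants(build_design("bias")), 19L)
})

test_that("identical seeds give identical datasets", {
  a <- generate_experiment("sat", n_participants = 2, trials_scale = 0.1,
                           seed = 33)
  b <- generate_experiment("sat", n_participants = 2, trials_scale = 0.1,
                           seed = 33)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth$params, b$truth$params)
  c <- generate_experiment("sat", n_participants = 2, trials_scale = 0.1,
                           seed = 34)
  expect_false(identical(a$trials, c$trials))
})

test_that("null generation makes sessions exchangeable", {
  g <- generate_experiment("difficulty", account = "none",
                           n_participants = 25, trials_scale = 5, seed = 44)
  tr <- g$trials[!is.na(g$trials$rt), ]
  expect_gt(nrow(tr), 9e4)
  rb <- tr$rt[tr$session == "behavioral"]
  rm_ <- tr$rt[tr$session == "mri"]
  qq <- seq(min(tr$rt), quantile(tr$rt, 0.999), length.out = 300)
  expect_lt(max(abs(ecdf(rb)(qq) - ecdf(rm_)(qq))), 0.02)
  expect_lt(abs(mean(tr$correct[tr$session == "mri"]) -
                  mean(tr$correct[tr$session == "behavioral"])), 0.01)
})

test_that("motor slowing shifts the RT distribution by its magnitude and leaves accuracy unchanged", {
  g <- generate_experiment("difficulty", account = "motor_slowing",
                           magnitude = 0.1, n_participants = 25,
                           trials_scale = 5, seed = 45)
  tr <- g$trials[!is.na(g$trials$rt), ]
  # the race RT has a heavy tail (finishing time ~ 1/drift near zero drift),
  # so the sample mean does not concentrate at this n; the median is
  # shift-equivariant and does
  d_rt <- median(tr$rt[tr$session == "mri"]) -
    median(tr$rt[tr$session == "behavioral"])
  expect_lt(abs(d_rt - 0.1), 0.01)
  # the whole quantile function shifts by the injected magnitude
  for (q in c(0.25, 0.75))
    expect_lt(abs(quantile(tr$rt[tr$session == "mri"], q) -
                    quantile(tr$rt[tr$session == "behavioral"], q) - 0.1),
              0.015)
  d_err <- mean(!tr$correct[tr$session == "mri"]) -
    mean(!tr$correct[tr$session == "behavioral"])
  expect_lt(abs(d_err), 0.01)
})

test_that("each account moves its own diagnostic in the stated direction", {
  base <- generate_experiment("difficulty", account = "none",
                              n_participants = 1, trials_scale = 0.02, seed = 1)
  spec0 <- base$truth$base_spec
  th <- base$truth$params[[1]]
  for (account in c("motor_slowing", "caution", "arousal", "focus")) {
    inj <- scanlba:::inject_account(spec0, th, account, 0.5)
    cells <- expand.grid(session = c("behavioral", "mri"),
                         stringsAsFactors = FALSE)
    races <- lapply(cells$session, function(s) resolve_params(
      inj$spec, inj$theta,
      list(session = s, coherence = "20", iti = "short")))
    b <- races[[1]]; m <- races[[2]]
    d_t0 <- m$t0 - b$t0
    d_b <- lba_threshold(m$accumulators[[1]]) - lba_threshold(b$accumulators[[1]])
    d_vsum <- (m$accumulators[[1]]$v + m$accumulators[[2]]$v) -
      (b$accumulators[[1]]$v + b$accumulators[[2]]$v)
    d_vdiff <- (m$accumulators[[1]]$v - m$accumulators[[2]]$v) -
      (b$accumulators[[1]]$v - b$accumulators[[2]]$v)
    moved <- c(motor_slowing = d_t0, caution = d_b, arousal = d_vsum,
               focus = -d_vdiff)
    expect_equal(unname(moved[account]), 0.5, tolerance = 1e-10, info = account)
    expect_true(all(abs(moved[setdiff(names(moved), account)]) < 1e-10),
                info = account)
  }
})

test_that("the focus account raises MRI error rates", {
  g <- generate_experiment("difficulty", account = "focus", magnitude = 0.8,
                           n_participants = 10, trials_scale = 1, seed = 46)
  tr <- g$trials[!is.na(g$trials$rt), ]
  err <- tapply(!tr$correct, tr$session, mean)
  expect_gt(err[["mri"]], err[["behavioral"]] + 0.03)
})

test_that("the coherence-drift map is monotone and propagates to behavior", {
  m <- coherence_drift_map(c(5, 10, 20, 40, 80))
  vd <- m$v_c - m$v_e
  expect_true(all(diff(vd) > 0))
  expect_equal(vd[5], 2.4)
  expect_equal(m$v_c + m$v_e, rep(3, 5), tolerance = 1e-12)
  expect_error(coherence_drift_map(0))

  g <- generate_experiment("difficulty", n_participants = 8,
                           trials_scale = 0.5, seed = 47)
  cm <- cell_means(g$trials, c("session", "coherence"))
  cm$coh_num <- as.numeric(cm$coherence)
  rho_rt <- vapply(split(cm, cm$participant), function(df)
    cor(df$coh_num, df$rt_mean, method = "spearman"), numeric(1))
  rho_err <- vapply(split(cm, cm$participant), function(df)
    cor(df$coh_num, df$error_rate, method = "spearman"), numeric(1))
  expect_lt(median(rho_rt), 0)   # faster at higher coherence
  expect_lt(median(rho_err), 0)  # fewer errors at higher coherence
})

test_that("datasets round-trip through CSV with unit conversion and schema checks", {
  g <- generate_experiment("difficulty", n_participants = 1,
                           trials_scale = 0.05, seed = 50)
  path <- tempfile(fileext = ".csv")
  write_dataset(g$trials, path)
  back <- read_dataset(path, design = build_design("difficulty"))
  back$coherence <- as.character(back$coherence)
  for (nm in names(g$trials))
    expect_equal(back[[nm]], g$trials[[nm]], info = nm)

  # ms-labelled RT column is converted to seconds
  ms <- g$trials
  ms$rt_ms <- ms$rt * 1000
  ms$rt <- NULL
  path2 <- tempfile(fileext = ".csv")
  write.csv(ms, path2, row.names = FALSE)
  back2 <- read_dataset(path2)
  expect_equal(back2$rt, g$trials$rt, tolerance = 1e-9)

  # malformed factor level errors with row and column
  bad <- g$trials
  bad$session[3] <- "lab"
  path3 <- tempfile(fileext = ".csv")
  write.csv(bad, path3, row.names = FALSE)
  expect_error(read_dataset(path3, design = build_design("difficulty")),
               "session.*row 3|row 3.*session")

  # missing required column
  path4 <- tempfile(fileext = ".csv")
  write.csv(g$trials[setdiff(names(g$trials), "rt")], path4, row.names = FALSE)
  expect_error(read_dataset(path4), "rt")
})
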