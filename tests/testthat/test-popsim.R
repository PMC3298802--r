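# Synthetic-trial generator: design validation, IIV draws, residual error,
# interval averaging, retrodialysis and determinism.

test_that("study design validates schedules and reproduces the printed counts", {
  d <- study_design()
  expect_error(study_design(plasma_times = c(5, 5, 10)), "strictly increasing")
  expect_error(study_design(dialysate_windows = cbind(c(0, 5), c(10, 15))),
               "non-overlapping")
  expect_error(study_design(bogus = 1), "unknown design field")
  sim <- simulate_trial(d, seed = 11)
  dat <- as.data.frame(sim$data)
  n_ids <- function(sel) length(unique(dat$ID[sel]))
  expect_equal(n_ids(!is.na(dat$DVID) & dat$DVID == "plasma_LDOPA"), 13)
  expect_equal(n_ids(!is.na(dat$DVID) & dat$DVID == "ecf_LDOPA" &
                       dat$HEMI %in% "control"), 12)
  expect_equal(n_ids(!is.na(dat$DVID) & dat$DVID == "ecf_LDOPA" &
                       dat$HEMI %in% "diseased"), 7)
  expect_equal(n_ids(!is.na(dat$DVID) & dat$DVID == "dial_DOPAC" &
                       dat$HEMI %in% "diseased"), 8)
  expect_equal(length(sim$subjects), 17)
})

test_that("zero omega^2 yields typical values; draws are seed-deterministic", {
  pars <- parameter_set(c(Cl = 30, V1 = 98, V2 = 157, V3 = 599, Q2 = 22,
                          Q3 = 11),
                        omega2 = c(Cl = 0), sigma = c(prop_plasma = 0.087))
  pop <- draw_population(study_design(), list(plasma = pars), seed = 5)
  cls <- vapply(pop, function(s) s$params$plasma$theta[["Cl"]], numeric(1))
  expect_true(all(cls == 30))
  p1 <- draw_population(study_design(), seed = 7)
  p2 <- draw_population(study_design(), seed = 7)
  expect_identical(p1, p2)
  s1 <- simulate_trial(study_design(), seed = 9)
  s2 <- simulate_trial(study_design(), seed = 9)
  expect_identical(s1$data, s2$data)
})

test_that("exponential IIV reproduces the configured log-scale variance", {
  des <- study_design(n_total = c(3334L, 3333L, 3333L))
  pop <- draw_population(des, seed = 21)
  cls <- vapply(pop, function(s) s$params$parent$theta[["Cl"]], numeric(1))
  expect_equal(var(log(cls)), 0.26, tolerance = 0.05)
  kins <- vapply(pop, function(s) s$params$parent$theta[["K_in"]], numeric(1))
  expect_equal(var(log(kins)), 0.94, tolerance = 0.05)
  # diseased-side parameters share the control-side random effect
  v4 <- vapply(pop, function(s) s$params$parent$theta[["V4"]], numeric(1))
  v5 <- vapply(pop, function(s) s$params$parent$theta[["V5"]], numeric(1))
  expect_equal(v4, v5)
})

test_that("missing omega^2 for a flagged parameter is a configuration error", {
  pars <- parameter_set(c(Cl = 30, V1 = 98, V2 = 157, V3 = 599, Q2 = 22,
                          Q3 = 11),
                        omega2 = c(Cl = NA_real_),
                        sigma = c(prop_plasma = 0.087))
  expect_error(draw_population(study_design(), list(plasma = pars), seed = 1),
               "omega")
  expect_error(draw_population(study_design()), "seed")
})

test_that("residual error models give the configured CV and truncate additively", {
  set.seed(123)
  e <- apply_residual_error(rep(100, 1e4), 0.087, "prop")
  expect_equal(sd(e$obs / 100 - 1), 0.087, tolerance = 0.05)
  set.seed(124)
  a <- apply_residual_error(rep(0.001, 1e4), 0.002, "add")
  expect_true(any(a$truncated))
  expect_true(all(a$obs >= 0))
  # truncation rate matches P(pred + eps < 0) for eps ~ N(0, 0.002^2)
  expect_equal(mean(a$truncated), pnorm(-0.001 / 0.002), tolerance = 0.1)
})

test_that("noise-free simulation returns exact interval-averaged predictions", {
  pars <- reference_parameters("parent")
  quiet <- parameter_set(pars$theta[!is.na(pars$theta)],
                         omega2 = c(Cl = 0, V4 = 0, K_in = 0),
                         sigma = c(prop_plasma = 0, prop_ecf = 0))
  des <- study_design(recovery_sd = 0)
  sim <- simulate_trial(des, params = list(parent = quiet), seed = 3,
                        streams = c("ecf_control"))
  dat <- subset(as.data.frame(sim$data), DVID %in% "ecf_LDOPA")
  sys <- build_ode_system(parent_model_spec(), quiet)
  s1 <- sim$subjects[[which(vapply(sim$subjects, function(s)
    "ecf_control" %in% s$streams, logical(1)))[1]]]
  w <- cbind(dat$WSTART[dat$ID == s1$id], dat$WEND[dat$ID == s1$id])
  tr <- solve_trajectory(sys, s1$dose, numeric(), windows = w)
  expect_equal(dat$DV[dat$ID == s1$id], tr$window_avg_conc[, "C4"] * 0.3,
               tolerance = 1e-10)
  # pre-dose windows sit on the flat baseline: average equals the point value
  base <- steady_state(sys)$conc[["C4"]]
  expect_equal(dat$DV[dat$ID == s1$id & dat$WEND <= 0] / 0.3,
               rep(base, 3), tolerance = 1e-6)
})

test_that("window averages integrate consistently over contiguous windows", {
  th <- reference_parameters("parent")$theta
  sys <- build_ode_system(parent_model_spec(), parameter_set(th[!is.na(th)]))
  w <- cbind(seq(0, 110, 10), seq(10, 120, 10))
  tr <- solve_trajectory(sys, dose_event(0, 20, 1.44e5), numeric(), windows = w)
  big <- solve_trajectory(sys, dose_event(0, 20, 1.44e5), numeric(),
                          windows = cbind(0, 120))
  lhs <- unname(sum(10 * tr$window_avg_conc[, "C4"]))
  rhs <- unname(120 * big$window_avg_conc[1, "C4"])
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("retrodialysis fractions carry the configured relative loss", {
  rd <- simulate_retrodialysis(0.30, 100, 6, noise_cv = 0, seed = 1)
  expect_equal(rd$loss, rep(0.30, 6))
  rd0 <- simulate_retrodialysis(0, 50, 4, noise_cv = 0, seed = 1)
  expect_equal(rd0$c_out, rep(50, 4))
  expect_equal(rd0$loss, rep(0, 4))
  expect_error(simulate_retrodialysis(0.3, -1, 6), "perfusate")
  # unbiasedness of the mean loss across many replicates
  set.seed(42)
  means <- replicate(2000, mean(simulate_retrodialysis(0.30, 100, 6,
                                                       noise_cv = 0.05)$loss))
  expect_equal(mean(means), 0.30, tolerance = 0.005)
})

test_that("responder fraction converges to the configured probability", {
  des <- study_design(n_total = c(700L, 700L, 600L),
                      n_ecf_diseased = c(0L, 0L, 0L),
                      n_metab_diseased = c(0L, 0L, 0L))
  pop <- draw_population(des, seed = 31)
  resp <- vapply(pop, function(s) s$responder, logical(1))
  expect_equal(mean(resp), 12 / 17, tolerance = 0.05)
  th <- vapply(pop, function(s) s$th_pct, numeric(1))
  expect_true(all(th[resp] < 40))
  expect_true(all(th[!resp] > 90))
})

test_that("plasma values below the LLQ are flagged", {
  sim <- simulate_trial(study_design(),
                        params = list(plasma = reference_parameters("plasma")),
                        seed = 13, streams = "plasma")
  dat <- subset(as.data.frame(sim$data), DVID %in% "plasma_LDOPA")
  pre <- dat[dat$TIME < 0, ]
  expect_true(all(pre$BLQ == 1))
  expect_true(all(dat$BLQ[dat$DV >= 1] == 0))
  expect_equal(unique(dat$LLOQ), 1)
})

test_that("empirical baseline generator hits the target mean and SEM scale", {
  b <- draw_baseline_population(12, 1.3, 0.17, seed = 2)
  expect_equal(nrow(b), 36)
  expect_true(all(b$WEND <= 0))
  means <- replicate(200, {
    bb <- draw_baseline_population(12, 1.3, 0.17, seed = sample.int(1e6, 1))
    mean(tapply(bb$DV, bb$ID, mean))
  })
  expect_equal(mean(means), 1.3, tolerance = 0.05)
  expect_equal(sd(means), 0.17, tolerance = 0.35)
})
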