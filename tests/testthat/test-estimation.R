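# Mixed-effects estimation engine: objective oracles, fits, the sequential
# metabolite workflow and likelihood-ratio machinery.

make_single_subject <- function(eta = 0.12, sigma = 0.1, seed = 99) {
  set.seed(seed)
  th <- c(Cl = 30, V1 = 100, V2 = 1, V3 = 1, Q2 = 0, Q3 = 0)
  tt <- c(5, 10, 20, 30, 45, 60, 90, 120)
  rate <- 1.44e5
  sys <- build_ode_system(plasma_model_spec(), parameter_set(th))
  tr <- solve_trajectory(sys, dose_event(0, 20, rate), tt)
  yobs <- tr$conc[, "C1"] * exp(eta) * (1 + rnorm(length(tt), 0, sigma))
  d <- data.frame(ID = "S1", TIME = c(0, tt), WSTART = NA, WEND = NA,
                  DVID = c(NA, rep("plasma_LDOPA", length(tt))), HEMI = NA,
                  DV = c(NA, yobs), AMT = c(rate * 20, rep(NA, length(tt))),
                  RATE = c(rate, rep(NA, length(tt))),
                  DUR = c(20, rep(NA, length(tt))),
                  MDV = c(1L, rep(0L, length(tt))))
  list(data = as_ldopa_dataset(d), theta = th, times = tt, rate = rate,
       y = yobs)
}

test_that("Laplace objective matches adaptive quadrature over eta", {
  fx <- make_single_subject()
  pars <- parameter_set(fx$theta, omega2 = c(Cl = 0.1),
                        sigma = c(prop_plasma = 0.1))
  lap <- laplace_objective(fx$data, plasma_model_spec(), pars)
  pred_eta <- function(eta) {
    th2 <- fx$theta
    th2["Cl"] <- th2["Cl"] * exp(eta)
    s2 <- build_ode_system(plasma_model_spec(), parameter_set(th2))
    solve_trajectory(s2, dose_event(0, 20, fx$rate), fx$times)$conc[, "C1"]
  }
  lik <- function(eta) vapply(eta, function(e) {
    f <- pred_eta(e)
    exp(sum(stats::dnorm(fx$y, f, 0.1 * f, log = TRUE)) +
          stats::dnorm(e, 0, sqrt(0.1), log = TRUE))
  }, numeric(1))
  quad <- -2 * log(stats::integrate(lik, -2, 2, rel.tol = 1e-10)$value)
  expect_lt(abs(c(lap) - quad), 0.1)
})

test_that("with all omega^2 = 0 the objective is the naive-pooled -2 log-likelihood", {
  fx <- make_single_subject()
  pars0 <- parameter_set(fx$theta, omega2 = c(Cl = 0),
                         sigma = c(prop_plasma = 0.1))
  lap0 <- laplace_objective(fx$data, plasma_model_spec(), pars0)
  sys <- build_ode_system(plasma_model_spec(), parameter_set(fx$theta))
  f <- solve_trajectory(sys, dose_event(0, 20, fx$rate), fx$times)$conc[, "C1"]
  pooled <- sum(log(2 * pi * (0.1 * f)^2) + (fx$y - f)^2 / (0.1 * f)^2)
  expect_equal(c(lap0), pooled, tolerance = 1e-10)
})

test_that("objective is invariant to subject ordering", {
  sim <- sim_parent_corrected(17)
  d <- as.data.frame(sim$data)
  pars <- reference_parameters("parent")
  o1 <- laplace_objective(as_ldopa_dataset(d), parent_model_spec(), pars)
  ids <- unique(d$ID)
  d2 <- do.call(rbind, lapply(rev(ids), function(i) d[d$ID == i, ]))
  o2 <- laplace_objective(as_ldopa_dataset(d2), parent_model_spec(), pars)
  expect_equal(c(o1), c(o2), tolerance = 1e-10)
})

test_that("fit to near-noise-free data started at truth stays at truth", {
  pars <- reference_parameters("plasma")
  quiet <- parameter_set(pars$theta[!is.na(pars$theta)],
                         omega2 = c(Cl = 1e-4),
                         sigma = c(prop_plasma = 1e-3))
  sim <- simulate_trial(study_design(), params = list(plasma = quiet),
                        seed = 4, streams = "plasma")
  f <- fit_popmodel(sim$data, plasma_model_spec(), quiet,
                    control = list(se = FALSE))
  for (p in c("Cl", "V1", "V2", "V3", "Q2", "Q3"))
    expect_equal(unname(f$params$theta[p]), unname(quiet$theta[p]),
                 tolerance = 0.01)
})

test_that("fits are reproducible bit-for-bit with fixed data, init and control", {
  sim <- simulate_trial(study_design(),
                        params = list(plasma = reference_parameters("plasma")),
                        seed = 6, streams = "plasma")
  f1 <- fit_popmodel(sim$data, plasma_model_spec(),
                     reference_parameters("plasma"), control = list(se = TRUE))
  f2 <- fit_popmodel(sim$data, plasma_model_spec(),
                     reference_parameters("plasma"), control = list(se = TRUE))
  expect_identical(f1$mvof, f2$mvof)
  expect_identical(f1$table, f2$table)
  # Wald machinery: CI brackets the estimate, CV% consistent
  expect_true(all(f1$table$lci < f1$table$estimate &
                    f1$table$estimate < f1$table$uci))
  expect_equal(f1$table$cv_pct, 100 * f1$table$se / f1$table$estimate)
})

test_that("profile objective rises by about 3.84 at the Wald 95% bound", {
  sim <- simulate_trial(study_design(),
                        params = list(plasma = reference_parameters("plasma")),
                        seed = 8, streams = "plasma")
  f <- fit_popmodel(sim$data, plasma_model_spec(),
                    reference_parameters("plasma"), control = list(se = TRUE))
  est <- f$table$estimate[f$table$parameter == "Cl"]
  se <- f$table$se[f$table$parameter == "Cl"]
  spec_fix <- plasma_model_spec()
  spec_fix$free_theta <- setdiff(spec_fix$free_theta, "Cl")
  th <- f$params$theta
  th["Cl"] <- est + 1.96 * se
  init_fix <- parameter_set(th[!is.na(th)], omega2 = f$params$omega2,
                            sigma = f$params$sigma)
  prof <- fit_popmodel(sim$data, spec_fix, init_fix, control = list(se = FALSE))
  rise <- prof$mvof - f$mvof
  expect_gt(rise, 3.84 * 0.75)
  expect_lt(rise, 3.84 * 1.33)
})

test_that("sequential DOPAC fit recovers rate constants from true parent input", {
  des <- study_design(n_ecf_diseased = c(0L, 0L, 0L),
                      n_metab_diseased = c(0L, 0L, 0L))
  sim <- simulate_trial(des,
                        params = list(dopac_control =
                                        reference_parameters("dopac_control")),
                        seed = 12, streams = "metab_control")
  truth <- truth_param_table(sim$subjects, "dopac_control")
  f <- sequential_metabolite_fit(sim$data, truth, "DOPAC", "control",
                                 control = list(se = FALSE))
  expect_equal(unname(f$params$theta["k60"]), 0.0053, tolerance = 0.5)
  expect_equal(unname(f$params$theta["k40"]), 0.53, tolerance = 0.5)
  # subject present in metabolite data but absent from the parent input
  expect_error(sequential_metabolite_fit(sim$data, truth[-1, ], "DOPAC",
                                         "control"),
               "absent from the parent fit")
})

test_that("swapping hemisphere labels swaps the recovered elimination constants", {
  des <- study_design(n_ecf_diseased = c(2L, 2L, 2L),
                      n_metab_diseased = c(2L, 2L, 2L))
  blocks <- reference_parameters("all")[c("dopac_control", "dopac_diseased")]
  sim <- simulate_trial(des, params = blocks, seed = 14,
                        streams = c("metab_control", "metab_diseased"))
  d <- as.data.frame(sim$data)
  dopac <- d[!is.na(d$AMT) | d$DVID %in% "dial_DOPAC", ]
  truth_c <- truth_param_table(sim$subjects, "dopac_control")
  truth_d <- truth_param_table(sim$subjects, "dopac_diseased")
  fc <- sequential_metabolite_fit(as_ldopa_dataset(dopac), truth_c, "DOPAC",
                                  "control", control = list(se = FALSE))
  swapped <- dopac
  swapped$HEMI[swapped$HEMI %in% "control"] <- "x"
  swapped$HEMI[swapped$HEMI %in% "diseased"] <- "control"
  swapped$HEMI[swapped$HEMI %in% "x"] <- "diseased"
  truth_d2 <- truth_d
  names(truth_d2)[names(truth_d2) == "V5"] <- "V4"
  names(truth_d2)[names(truth_d2) == "Q5"] <- "Q4"
  fs <- sequential_metabolite_fit(as_ldopa_dataset(swapped), truth_d2, "DOPAC",
                                  "control", control = list(se = FALSE))
  # the control-slot estimate now reflects the diseased hemisphere's k80
  expect_gt(unname(fs$params$theta["k60"]) / unname(fc$params$theta["k60"]), 3)
})

test_that("a zero formation-constant truth drives the estimate to the boundary", {
  pars <- reference_parameters("dopac_control")
  th <- pars$theta[!is.na(pars$theta)]
  th["k46"] <- 1e-12
  quiet <- parameter_set(th, omega2 = c(k46 = 0, k40 = 0, k60 = 0),
                         sigma = pars$sigma)
  des <- study_design(n_total = c(2L, 2L, 2L), n_metab_diseased = c(0L, 0L, 0L),
                      n_ecf_diseased = c(0L, 0L, 0L))
  sim <- simulate_trial(des, params = list(dopac_control = quiet), seed = 15,
                        streams = "metab_control")
  truth <- truth_param_table(sim$subjects, "dopac_control")
  f <- fit_popmodel(sim$data, metabolite_model_spec("DOPAC", "control"),
                    init = quiet,
                    subject_params = {
                      sp <- lapply(seq_len(nrow(truth)), function(i) {
                        v <- as.numeric(truth[i, -1])
                        names(v) <- names(truth)[-1]
                        v
                      })
                      names(sp) <- truth$ID
                      sp
                    },
                    control = list(se = FALSE, log_bound = 12))
  tb <- f$table
  expect_true(tb$at_boundary[tb$parameter == "k46"] ||
                tb$estimate[tb$parameter == "k46"] < 1e-9)
})

test_that("likelihood-ratio thresholds follow the chi-square criterion", {
  l1 <- lrt_compare(100, 105, df = 1)
  expect_equal(l1$threshold, 10.8)
  expect_false(l1$significant)
  expect_equal(l1$delta, 5)
  l2 <- lrt_compare(100, 100, df = 1)
  expect_equal(l2$delta, 0)
  expect_false(l2$significant)
  l3 <- lrt_compare(100, 120, df = 2)
  expect_equal(l3$threshold, qchisq(0.999, 2), tolerance = 1e-12)
  expect_equal(l3$threshold, 13.82, tolerance = 1e-3)
  expect_true(l3$significant)
  expect_warning(lrt_compare(100, 95, df = 1), "lower objective")
})

test_that("grid cells carry 0 to 3 constraints and report per-cell results", {
  sim <- sim_parent_corrected(19, design = small_grid_design())
  g <- symmetry_grid(sim$data, reference_parameters("parent"),
                     control = list(se = FALSE, outer_rel_tol = 1e-4,
                                    outer_maxit = 120L))
  expect_equal(sort(unique(g$table$n_constraints)), 0:3)
  expect_equal(nrow(g$table), 8)
  expect_true(all(is.finite(g$table$mvof)))
  # constrained (removed) parameters are blanked in the report
  expect_true(is.na(g$table$V5[g$table$assumption == "V5=V4"]))
})
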