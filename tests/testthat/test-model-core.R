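# Structural model: system construction, piecewise-exact solution,
# steady state and unit conversion.

test_that("symmetry constraints each remove one free brain-side parameter", {
  full <- parent_model_spec(constraints = character(0))
  expect_length(full$free_theta, 13)
  one <- parent_model_spec(constraints = "V5=V4")
  expect_length(one$free_theta, 12)
  expect_false("V5" %in% one$free_theta)
  sym <- parent_model_spec()
  expect_length(sym$free_theta, 10)
  expect_setequal(intersect(sym$free_theta, c("V4", "V5", "Q4", "Q5", "k40",
                                              "k50", "K_in")),
                  c("V4", "Q4", "k40", "K_in"))
})

test_that("system construction validates parameters and names the symbol", {
  spec <- plasma_model_spec()
  expect_error(build_ode_system(spec, parameter_set(c(Cl = 30, V1 = 98))),
               "V2")
  bad <- parameter_set(c(Cl = 30, V1 = 98, V2 = 157, V3 = 599, Q2 = 22,
                         Q3 = -1))
  expect_error(build_ode_system(spec, bad), "Q3")
  expect_error(parameter_set(c(Xx = 1)), "unknown parameter")
})

test_that("closed subsystem rate-matrix columns sum to zero (mass conservation)", {
  th <- c(Cl = 0, V1 = 98, V2 = 157, V3 = 599, V4 = 13300, V5 = 13300,
          Q2 = 22, Q3 = 11, Q4 = 22, Q5 = 22, k40 = 0, k50 = 0, K_in = 0)
  sys <- build_ode_system(parent_model_spec(constraints = character(0)),
                          parameter_set(th))
  expect_lt(max(abs(colSums(sys$A))), 1e-12)
})

test_that("Kin = 0 with no dose gives the all-zero steady state and trajectory", {
  th <- c(Cl = 30, V1 = 98, V2 = 157, V3 = 599, V4 = 13300, V5 = 13300,
          Q2 = 22, Q3 = 11, Q4 = 22, Q5 = 22, k40 = 0.175, k50 = 0.175,
          K_in = 0)
  sys <- build_ode_system(parent_model_spec(), parameter_set(th))
  expect_equal(unname(steady_state(sys)$amounts), rep(0, 5))
  tr <- solve_trajectory(sys, list(), c(0, 60, 360))
  expect_equal(max(abs(tr$amounts)), 0)
})

test_that("one-compartment reduction matches the closed-form decline", {
  th <- c(Cl = 30, V1 = 98, V2 = 1, V3 = 1, Q2 = 0, Q3 = 0)
  sys <- build_ode_system(plasma_model_spec(), parameter_set(th))
  rate <- 1.44e5
  tt <- c(20, 30, 60, 120, 240)
  tr <- solve_trajectory(sys, dose_event(0, 20, rate), tt)
  c_end <- tr$conc[1, "C1"]
  expect_equal(tr$conc[, "C1"], c_end * exp(-(30 / 98) * (tt - 20)),
               tolerance = 1e-10)
})

test_that("solver matches an independent matrix-exponential evaluation", {
  skip_if_not_installed("Matrix")
  spec <- parent_model_spec(constraints = character(0))
  th <- reference_parameters("parent")$theta
  sys <- build_ode_system(spec, parameter_set(th[!is.na(th)]))
  tt <- c(-5, 5, 10, 20, 22, 30, 60, 120, 360)
  inf <- cbind(0, 20, 1.44e5)
  x0 <- unname(steady_state(sys)$amounts)
  tr <- solve_trajectory(sys, dose_event(0, 20, 1.44e5), tt)
  oracle <- expm_oracle(sys$A, sys$b_endo, x0, -5, inf, tt)
  expect_lt(max(abs(tr$amounts - oracle)) / max(abs(oracle)), 1e-8)
})

test_that("doubling the infusion rate doubles every amount above baseline", {
  th <- reference_parameters("parent")$theta
  sys <- build_ode_system(parent_model_spec(), parameter_set(th[!is.na(th)]))
  tt <- c(5, 20, 45, 120, 360)
  base <- steady_state(sys)$amounts
  tr1 <- solve_trajectory(sys, dose_event(0, 20, 1e5), tt)
  tr2 <- solve_trajectory(sys, dose_event(0, 20, 2e5), tt)
  d1 <- sweep(tr1$amounts, 2, base)
  d2 <- sweep(tr2$amounts, 2, base)
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("steady state agrees with long-time ODE integration and the sink formula", {
  skip_if_not_installed("deSolve")
  th <- reference_parameters("parent")$theta
  sys <- build_ode_system(parent_model_spec(), parameter_set(th[!is.na(th)]))
  ss <- steady_state(sys)
  f <- function(t, x, p) list(sys$A %*% x + sys$b_endo)
  o <- deSolve::ode(y = rep(0, 5), times = c(0, 1e5), func = f, parms = NULL,
                    rtol = 1e-12, atol = 1e-10)
  expect_equal(unname(ss$amounts), unname(o[2, -1]), tolerance = 1e-6)
  # sink approximation Kin/(k40 V4): accurate to ~1% because plasma recycling
  # of the endogenous input is small but not zero
  expect_equal(unname(ss$conc["C4"]), 5.8 / (0.175 * 13300), tolerance = 0.02)
})

test_that("baseline DOPAC concentration scales linearly in k46", {
  th <- reference_parameters("dopac_control")$theta
  spec <- metabolite_model_spec("DOPAC", "control")
  b1 <- steady_state(build_ode_system(spec, parameter_set(th[!is.na(th)])))
  th2 <- th
  th2["k46"] <- 3 * th["k46"]
  b3 <- steady_state(build_ode_system(spec, parameter_set(th2[!is.na(th2)])))
  expect_equal(unname(b3$conc["C6"]), 3 * unname(b1$conc["C6"]),
               tolerance = 1e-10)
  # singular system: nonzero input with no elimination anywhere
  th0 <- c(Cl = 0, V1 = 98, V2 = 1, V3 = 1, Q2 = 0, Q3 = 0, V4 = 100, Q4 = 0,
           k40 = 0, K_in = 5.8, V5 = 100, Q5 = 0, k50 = 0)
  sys0 <- build_ode_system(parent_model_spec(constraints = character(0)),
                           parameter_set(th0))
  expect_error(steady_state(sys0), "no steady state|singular")
})

test_that("mass balance holds in the closed system after any dose schedule", {
  th <- c(Cl = 0, V1 = 98, V2 = 157, V3 = 599, V4 = 13300, V5 = 13300,
          Q2 = 22, Q3 = 11, Q4 = 22, Q5 = 22, k40 = 0, k50 = 0, K_in = 0)
  sys <- build_ode_system(parent_model_spec(constraints = character(0)),
                          parameter_set(th))
  doses <- data.frame(start = c(0, 100), duration = c(20, 10),
                      rate = c(1e5, 5e4))
  tr <- solve_trajectory(sys, doses, c(30, 90, 150, 400), init = "zero")
  administered <- c(20 * 1e5, 20 * 1e5, 20 * 1e5 + 10 * 5e4, 20 * 1e5 + 10 * 5e4)
  expect_equal(rowSums(tr$amounts), administered, tolerance = 1e-8)
})

test_that("unit conversion follows molar masses and round-trips", {
  expect_equal(convert_units(1, "L-DOPA", "ng/mL", "pmol/mL"), 1000 / 197.19)
  expect_equal(convert_units(5, "HVA", "ng/mL", "ng/mL"), 5)
  x <- 3.7
  y <- convert_units(convert_units(x, "DOPAC", "ng/mL", "pmol/mL"),
                     "DOPAC", "pmol/mL", "ng/mL")
  expect_equal(y, x, tolerance = 1e-12)
  expect_equal(convert_units(10, "L-DOPA", "mg/kg", "ng", weight_kg = 0.288),
               10 * 0.288 * 1e6)
  expect_error(convert_units(1, "serotonin", "ng/mL", "pmol/mL"), "analyte")
  expect_error(convert_units(1, "HVA", "ng/mL", "mol"), "unit")
  expect_error(convert_units(1, "HVA", "mg/kg", "ng"), "weight_kg")
})

test_that("model config serialises Table-style names, units and IIV flags", {
  cfg <- model_config(parent_model_spec(), reference_parameters("parent"))
  nms <- vapply(cfg$parameters, `[[`, character(1), "name")
  expect_true(all(c("Cl", "V1", "V4", "Q4", "k40", "K_in") %in% nms))
  kin <- cfg$parameters[[match("K_in", nms)]]
  expect_true(kin$iiv)
  expect_equal(kin$omega2, 0.94)
  path <- tempfile(fileext = ".yaml")
  model_config(parent_model_spec(), reference_parameters("parent"), path)
  expect_true(file.exists(path))
  back <- yaml::read_yaml(path)
  expect_equal(length(back$parameters), length(cfg$parameters))
})
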