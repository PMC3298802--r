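# Shared fixtures: reduced study designs and simulation helpers used across
# the test files. Everything is generated in code; no stored data.

# scaled-down two-hemisphere design used for the model-selection grid tests
small_grid_design <- function() {
  study_design(
    n_total = c(2L, 2L, 2L), n_plasma = c(2L, 2L, 2L),
    n_ecf_control = c(2L, 2L, 2L), n_ecf_diseased = c(2L, 2L, 2L),
    n_metab_control = c(0L, 0L, 0L), n_metab_diseased = c(0L, 0L, 0L),
    plasma_times = c(5, 10, 20, 24, 28, 45, 60, 90, 120, 240, 360),
    dialysate_windows = rbind(cbind(seq(0, 100, 20), seq(20, 120, 20)),
                              cbind(c(120, 150), c(150, 180)),
                              cbind(c(180, 240, 300), c(240, 300, 360))),
    baseline_windows = cbind(c(-30, -15), c(-15, 0)))
}

# simulate a parent-model trial and return the recovery-corrected dataset
sim_parent_corrected <- function(seed, params = reference_parameters("parent"),
                                 design = study_design(), recovery = 0.3,
                                 streams = c("plasma", "ecf_control",
                                             "ecf_diseased")) {
  sim <- simulate_trial(design, params = list(parent = params), seed = seed,
                        streams = streams)
  list(data = correct_to_ecf(sim$data, recovery), subjects = sim$subjects)
}

# per-subject true parent parameters as a table for sequential fits
truth_param_table <- function(subjects, block,
                              cols = c("Cl", "V1", "V2", "V3", "V4", "V5",
                                       "Q2", "Q3", "Q4", "Q5", "K_in")) {
  do.call(rbind, lapply(subjects, function(s) {
    th <- s$params[[block]]$theta
    out <- data.frame(ID = s$id, stringsAsFactors = FALSE)
    for (p in intersect(cols, names(th)[!is.na(th)])) out[[p]] <- unname(th[p])
    out
  }))
}

# matrix-exponential reference solution (Matrix::expm on the augmented
# system), independent of the package solver's eigendecomposition path
expm_oracle <- function(A, b, x0, t0, infusions, times) {
  n <- nrow(A)
  bps <- sort(unique(c(t0, times, as.vector(infusions[, 1:2, drop = FALSE]))))
  bps <- bps[bps >= t0]
  x <- x0
  out <- matrix(NA_real_, length(times), n)
  for (k in seq_along(bps)[-1]) {
    dt <- bps[k] - bps[k - 1]
    tm <- (bps[k] + bps[k - 1]) / 2
    u <- b
    for (j in seq_len(nrow(infusions)))
      if (infusions[j, 1] < tm && tm < infusions[j, 2])
        u[1] <- u[1] + infusions[j, 3]
    M <- rbind(cbind(A, u), 0)
    z <- as.matrix(Matrix::expm(M * dt)) %*% c(x, 1)
    x <- z[seq_len(n)]
    hit <- which(abs(times - bps[k]) < 1e-9)
    if (length(hit)) out[hit, ] <- rep(x, each = length(hit))
  }
  hit0 <- which(abs(times - t0) < 1e-9)
  if (length(hit0)) out[hit0, ] <- rep(x0, each = length(hit0))
  out
}

# random positive parameter draw, log-uniform over four decades around the
# reference magnitudes
random_parent_params <- function() {
  ref <- c(Cl = 30, V1 = 98, V2 = 157, V3 = 599, V4 = 13300, V5 = 13300,
           Q2 = 22, Q3 = 11, Q4 = 22, Q5 = 22, k40 = 0.175, k50 = 0.175,
           K_in = 5.8, k46 = 4.4e-5, k58 = 5.4e-5, k47 = 2.3e-5,
           k59 = 1.6e-5, k60 = 0.0053, k80 = 0.038, k70 = 0.0044, k90 = 0.011)
  ref * 10^runif(length(ref), -2, 2)
}
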