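# Synthetic-trial generator emulating the microdialysis study design:
# 3 IV dose groups, the printed plasma sampling schedule, interval-collected
# striatal dialysate in two hemispheres, retrodialysis calibration, exponential
# IIV, proportional/additive residual error and TH responder status.

#' Study design for a synthetic L-DOPA microdialysis trial
#'
#' Defaults reproduce the original design: dose groups 10/25/50 mg/kg infused
#' over 20 min, body weight 288 +/- 13 g, the printed plasma sampling schedule,
#' dialysate fractions at 10-min intervals to 120 min, 20-min to 180 min and
#' 30-min to 360 min, a 6-fraction 60-min retrodialysis phase with perfusate
#' L-DOPA 10/100/200 ng/mL by dose group, pre-dose baseline fractions, and the
#' printed per-stream animal counts (13 plasma profiles 4/4/5; control-ECF 12 =
#' 4/3/5; diseased-responder ECF 7 = 1/2/4; control metabolites 12; diseased
#' metabolites 8 = 2/2/4; 17 rats in total).
#'
#' @param ... Named overrides of any design field (see the function body for
#'   the full list).
#' @return A `study_design`.
#' @export
study_design <- function(...) {
  d <- list(
    dose_groups = c(10, 25, 50),                 # mg/kg
    n_total = c(6L, 6L, 5L),
    n_plasma = c(4L, 4L, 5L),
    n_ecf_control = c(4L, 3L, 5L),
    n_ecf_diseased = c(1L, 2L, 4L),
    n_metab_control = c(4L, 3L, 5L),
    n_metab_diseased = c(2L, 2L, 4L),
    weight_mean = 0.288, weight_sd = 0.013,      # kg
    infusion_duration = 20,                      # min
    plasma_times = c(-5, 5, 10, 15, 20, 22, 24, 26, 28, 30, 45, 50,
                     60, 75, 90, 120, 180, 240, 360),
    dialysate_windows = rbind(cbind(seq(0, 110, 10), seq(10, 120, 10)),
                              cbind(seq(120, 160, 20), seq(140, 180, 20)),
                              cbind(seq(180, 330, 30), seq(210, 360, 30))),
    baseline_windows = cbind(seq(-30, -10, 10), seq(-20, 0, 10)),
    retro_windows = cbind(seq(-180, -130, 10), seq(-170, -120, 10)),
    perfusate_conc = c(10, 100, 200),            # ng/mL per dose group
    retro_noise_cv = 0.05,
    recovery_mean = 0.30, recovery_sd = 0.06,
    responder_prob = 12 / 17,
    lloq_plasma = 1,                             # ng/mL
    lloq_dopamine = 0.01,                        # ng/mL (never above it)
    interval_mode = "average")                   # or "midpoint"
  ov <- list(...)
  bad <- setdiff(names(ov), names(d))
  if (length(bad)) stop("unknown design field(s): ", paste(bad, collapse = ", "))
  d[names(ov)] <- ov
  if (is.unsorted(d$plasma_times, strictly = TRUE))
    stop("plasma sampling times must be strictly increasing")
  for (w in list(d$dialysate_windows, d$baseline_windows, d$retro_windows)) {
    if (any(w[, 2] <= w[, 1])) stop("dialysate window end must exceed start")
    if (nrow(w) > 1 && any(w[-1, 1] - w[-nrow(w), 2] < -1e-9))
      stop("dialysate windows must be non-overlapping and contiguous")
  }
  if (!d$interval_mode %in% c("average", "midpoint"))
    stop("interval_mode must be 'average' or 'midpoint'")
  structure(d, class = "study_design")
}

# deterministic per-subject child seeds below 2^31
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw a virtual population
#'
#' Random effects are drawn independently per parameter and subject,
#' `eta ~ N(0, omega^2)`, applied as `theta * exp(eta)` (exponential IIV), for
#' every IIV-flagged parameter of every model block supplied. Responder status
#' is Bernoulli with the design's responder probability; responders get TH%
#' below 40, non-responders above 90. A per-subject true probe recovery is
#' drawn once (normal, truncated to (0, 1]) and shared across both probes.
#'
#' @param design A [study_design()].
#' @param params A named list of `parameter_set`s (model blocks), e.g.
#'   [reference_parameters]`("all")`, or a single `parameter_set`.
#' @param seed Integer seed (required; the generator is deterministic given it).
#' @return List of subject records (class `ldopa_subject`).
#' @export
draw_population <- function(design, params = reference_parameters("all"), seed) {
  if (missing(seed)) stop("seed is required")
  if (inherits(params, "parameter_set")) params <- list(model = params)
  for (blk in names(params)) {
    ps <- params[[blk]]
    miss <- names(ps$omega2)[is.na(ps$omega2)]
    if (length(miss))
      stop("missing omega^2 for IIV parameter(s) in block '", blk, "': ",
           paste(miss, collapse = ", "))
  }
  n_groups <- length(design$dose_groups)
  n <- sum(design$n_total)
  set.seed(seed)
  weights <- rnorm(n, design$weight_mean, design$weight_sd)
  weights <- pmax(weights, 0.1)
  responder <- rbinom(n, 1, design$responder_prob) == 1
  seeds <- sample.int(.Machine$integer.max - 1L, n + 1L)
  recov <- rnorm(n, design$recovery_mean, design$recovery_sd)
  recov <- pmin(pmax(recov, 1e-3), 1)
  th_pct <- ifelse(responder, runif(n, 5, 39.9), runif(n, 90.1, 100))

  subjects <- vector("list", n)
  i <- 0
  for (g in seq_len(n_groups)) {
    for (j in seq_len(design$n_total[g])) {
      i <- i + 1
      streams <- c(
        if (j <= design$n_plasma[g]) "plasma",
        if (j <= design$n_ecf_control[g]) "ecf_control",
        if (j <= design$n_ecf_diseased[g]) "ecf_diseased",
        if (j <= design$n_metab_control[g]) "metab_control",
        if (j <= design$n_metab_diseased[g]) "metab_diseased",
        "retro", "th")
      # diseased-side analysis streams require responder status; the design's
      # printed counts are reproduced exactly, so force consistency
      if (any(c("ecf_diseased", "metab_diseased") %in% streams))
        responder[i] <- TRUE
      subjects[[i]] <- structure(list(
        id = sprintf("R%02d", i), group = design$dose_groups[g], group_idx = g,
        weight = weights[i], responder = responder[i], th_pct = th_pct[i],
        recovery = recov[i], streams = streams,
        dose = dose_event(0, design$infusion_duration,
                          design$dose_groups[g] * weights[i] * 1e6 /
                            design$infusion_duration),
        child_seed = seeds[i]), class = "ldopa_subject")
    }
  }
  # correct TH% for any forced responders
  set.seed(seeds[n + 1L])
  for (k in seq_len(n)) {
    if (subjects[[k]]$responder && subjects[[k]]$th_pct >= 40)
      subjects[[k]]$th_pct <- runif(1, 5, 39.9)
  }
  # individual parameters per model block
  for (k in seq_len(n)) {
    set.seed(subjects[[k]]$child_seed)
    pl <- list()
    for (blk in names(params)) {
      ps <- params[[blk]]
      eta <- rnorm(length(ps$omega2), 0, sqrt(ps$omega2))
      names(eta) <- names(ps$omega2)
      th <- ps$theta
      th[names(eta)] <- th[names(eta)] * exp(eta)
      # hemisphere-shared random effects: the diseased-side parameter inherits
      # the control-side eta when it carries no omega^2 of its own (one brain)
      for (pair in list(c("V5", "V4"), c("Q5", "Q4"), c("k50", "k40"))) {
        if (!pair[1] %in% names(eta) && pair[2] %in% names(eta) &&
            !is.na(th[pair[1]]))
          th[pair[1]] <- th[pair[1]] * exp(eta[[pair[2]]])
      }
      pl[[blk]] <- list(theta = th, eta = eta)
    }
    subjects[[k]]$params <- pl
    subjects[[k]]$sim_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  }
  subjects
}

#' Apply a residual-error model to noise-free predictions
#'
#' Proportional: `obs = pred * (1 + eps)`; additive: `obs = pred + eps`;
#' `eps ~ N(0, sd^2)`. Negative concentrations arising from additive error are
#' truncated at zero and flagged (not resampled, which would bias the error
#' distribution).
#'
#' @param pred Numeric predictions.
#' @param sd Residual standard deviation.
#' @param type `"prop"` or `"add"`.
#' @return Data frame with `obs` and `truncated`.
#' @export
apply_residual_error <- function(pred, sd, type = c("prop", "add")) {
  type <- match.arg(type)
  eps <- rnorm(length(pred), 0, sd)
  obs <- if (type == "prop") pred * (1 + eps) else pred + eps
  trunc <- obs < 0
  obs[trunc] <- 0
  data.frame(obs = obs, truncated = trunc)
}

sim_rows <- function(id, time, wstart, wend, dvid, hemi, dv, lloq = NA,
                     trunc = FALSE, perf = NA) {
  data.frame(ID = id, TIME = if (is.null(time)) NA_real_ else time,
             WSTART = if (is.null(wstart)) NA_real_ else wstart,
             WEND = if (is.null(wend)) NA_real_ else wend,
             DVID = dvid, HEMI = hemi, DV = dv, AMT = NA_real_,
             RATE = NA_real_, DUR = NA_real_, MDV = 0L, LLOQ = lloq,
             BLQ = as.integer(!is.na(lloq) & dv < lloq),
             TRUNC = as.integer(trunc), PERF = perf,
             stringsAsFactors = FALSE)
}

# windowed noise-free predictions of one compartment for one subject
subject_window_pred <- function(subject, spec, theta, windows, design) {
  ps <- parameter_set(theta[!is.na(theta)])
  sys <- build_ode_system(spec, ps)
  if (design$interval_mode == "average") {
    tr <- solve_trajectory(sys, subject$dose, numeric(), windows = windows)
    tr$window_avg_conc
  } else {
    mid <- (windows[, 1] + windows[, 2]) / 2
    tr <- solve_trajectory(sys, subject$dose, mid)
    tr$conc
  }
}

#' Simulate one subject's observation records
#'
#' Fills the subject's observation rows for the streams it carries: plasma
#' L-DOPA points (proportional error, values below the 1 ng/mL LLQ flagged),
#' brain-ECF L-DOPA dialysate windows in each hemisphere (interval-averaged
#' ECF concentration times the subject's probe recovery, proportional error),
#' DOPAC/HVA dialysate windows (interval averages on the dialysate scale,
#' additive error, negative draws truncated at zero and flagged),
#' retrodialysis fractions, and the TH% row. Dialysate values are
#' time-averages of the model concentration over each collection window
#' (exact integrals); midpoint sampling is available via the design's
#' `interval_mode` for sensitivity checks.
#'
#' @param subject An `ldopa_subject` from [draw_population()].
#' @param design The [study_design()].
#' @param seed Optional; defaults to the subject's own child seed.
#' @return Data frame of long-format observation rows.
#' @export
simulate_observations <- function(subject, design, seed = subject$sim_seed) {
  set.seed(seed)
  pr <- subject$params
  rows <- list()
  bw <- design$baseline_windows
  dw <- design$dialysate_windows
  allw <- rbind(bw, dw)
  id <- subject$id

  if ("plasma" %in% subject$streams || any(grepl("^ecf", subject$streams))) {
    if (!is.null(pr$parent)) {
      blk <- pr$parent
      # no symmetry constraints at simulation time: the subject's own theta
      # carries the (possibly asymmetric) truth for V5/Q5/k50
      spec <- parent_model_spec(constraints = character(0))
    } else if (!is.null(pr$plasma)) {
      blk <- pr$plasma
      spec <- plasma_model_spec()
    } else {
      blk <- pr[[1]]
      spec <- if (all(!is.na(blk$theta[c("V4", "Q4", "k40", "K_in")])))
        parent_model_spec() else plasma_model_spec()
    }
    ps <- parameter_set(blk$theta[!is.na(blk$theta)])
    sys <- build_ode_system(spec, ps)
    tr <- solve_trajectory(sys, subject$dose, design$plasma_times, windows = allw)
    if ("plasma" %in% subject$streams) {
      sdp <- attr_sigma(pr, c("parent", "plasma"), "prop_plasma")
      e <- apply_residual_error(tr$conc[, "C1"], sdp, "prop")
      rows[[length(rows) + 1]] <- sim_rows(id, design$plasma_times, NULL, NULL,
                                           "plasma_LDOPA", NA, e$obs,
                                           lloq = design$lloq_plasma,
                                           trunc = e$truncated)
    }
    sde <- attr_sigma(pr, "parent", "prop_ecf")
    for (h in c("control", "diseased")) {
      if (!paste0("ecf_", h) %in% subject$streams) next
      comp <- if (h == "control") "C4" else "C5"
      if (!comp %in% colnames(tr$conc)) next
      pred <- if (design$interval_mode == "average") tr$window_avg_conc[, comp]
              else solve_trajectory(sys, subject$dose,
                                    (allw[, 1] + allw[, 2]) / 2)$conc[, comp]
      dial <- pred * subject$recovery
      e <- apply_residual_error(dial, sde, "prop")
      rows[[length(rows) + 1]] <- sim_rows(id, NULL, allw[, 1], allw[, 2],
                                           "ecf_LDOPA", h, e$obs,
                                           trunc = e$truncated)
    }
  }

  met_blocks <- list(
    metab_control = list(c("dopac_control", "DOPAC", "control"),
                         c("hva_control", "HVA", "control")),
    metab_diseased = list(c("dopac_diseased", "DOPAC", "diseased"),
                          c("hva_diseased", "HVA", "diseased")))
  for (st in names(met_blocks)) {
    if (!st %in% subject$streams) next
    for (mb in met_blocks[[st]]) {
      blk <- pr[[mb[1]]]
      if (is.null(blk)) next
      spec <- metabolite_model_spec(mb[2], mb[3])
      comp <- paste0("C", spec$obs_map$comp[1])
      pred <- subject_window_pred(subject, spec, blk$theta, allw, design)[, comp]
      sdm <- attr_sigma(pr, mb[1], spec$sigma_names)
      e <- apply_residual_error(pred, sdm, "add")
      rows[[length(rows) + 1]] <- sim_rows(
        id, NULL, allw[, 1], allw[, 2],
        if (mb[2] == "DOPAC") "dial_DOPAC" else "dial_HVA", mb[3], e$obs,
        trunc = e$truncated)
    }
  }

  if ("retro" %in% subject$streams) {
    perf <- design$perfusate_conc[subject$group_idx]
    rw <- design$retro_windows
    rd <- simulate_retrodialysis(subject$recovery, perf, nrow(rw),
                                 design$retro_noise_cv,
                                 seed = NULL)  # inherits current RNG stream
    rows[[length(rows) + 1]] <- sim_rows(id, NULL, rw[, 1], rw[, 2],
                                         "retro_LDOPA", NA, rd$c_out,
                                         perf = perf)
  }
  if ("th" %in% subject$streams)
    rows[[length(rows) + 1]] <- sim_rows(id, NA_real_, NULL, NULL, "TH", NA,
                                         subject$th_pct)
  do.call(rbind, rows)
}

# sigma lookup across blocks (first block that defines it wins)
attr_sigma <- function(pr, blocks, name) {
  for (b in blocks) {
    ps <- pr[[b]]
    if (!is.null(ps) && !is.null(ps$sigma_ref) && name %in% names(ps$sigma_ref))
      return(ps$sigma_ref[[name]])
  }
  # fall back to the reference defaults
  for (b in names(pr)) {
    sg <- pr[[b]]$sigma_ref
    if (!is.null(sg) && name %in% names(sg)) return(sg[[name]])
  }
  ref <- do.call(c, lapply(reference_parameters("all"), function(p) p$sigma))
  nm <- sub("^.*\\.", "", names(ref))
  if (name %in% nm) return(unname(ref[match(name, nm)]))
  stop("no residual sd available for error model '", name, "'")
}

#' Simulate retrodialysis calibration fractions
#'
#' The probe is perfused with a known L-DOPA concentration; each fraction's
#' outgoing dialysate concentration is `perfusate * (1 - true relative loss) *
#' (1 + noise)`, and the per-fraction relative loss is recovered as
#' `(in - out) / in`.
#'
#' @param true_loss True relative loss (the in vivo recovery), in (0, 1].
#' @param perfusate_conc Perfusate L-DOPA concentration (ng/mL), > 0.
#' @param n_fractions Number of fractions, >= 1 (study design: 6 over 60 min).
#' @param noise_cv Multiplicative measurement noise SD.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Data frame with `fraction`, `c_in`, `c_out`, `loss`.
#' @export
simulate_retrodialysis <- function(true_loss, perfusate_conc, n_fractions = 6,
                                   noise_cv = 0.05, seed = NULL) {
  if (!is.finite(perfusate_conc) || perfusate_conc <= 0)
    stop("perfusate_conc must be > 0")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  eps <- rnorm(n_fractions, 0, noise_cv)
  c_out <- perfusate_conc * (1 - true_loss) * (1 + eps)
  c_out <- pmax(c_out, 0)
  data.frame(fraction = seq_len(n_fractions), c_in = perfusate_conc,
             c_out = c_out, loss = (perfusate_conc - c_out) / perfusate_conc)
}

#' Simulate a full synthetic trial
#'
#' Draws a virtual population and simulates every observation stream of the
#' study design, returning the long-format dataset plus a truth sidecar with
#' each subject's individual parameters for recovery testing.
#'
#' @param design A [study_design()].
#' @param params Named list of `parameter_set`s per model block
#'   ([reference_parameters]`("all")` by default). Residual-error SDs are taken
#'   from each block's `sigma`.
#' @param seed Integer seed (required).
#' @param streams Optional character vector restricting the simulated streams
#'   (subset of `"plasma"`, `"ecf_control"`, `"ecf_diseased"`,
#'   `"metab_control"`, `"metab_diseased"`, `"retro"`, `"th"`).
#' @return List with `data` (an `ldopa_dataset`), `subjects` (the population,
#'   including true parameters) and `seed`.
#' @export
simulate_trial <- function(design = study_design(),
                           params = reference_parameters("all"), seed,
                           streams = NULL) {
  if (missing(seed)) stop("seed is required")
  if (inherits(params, "parameter_set")) params <- list(parent = params)
  # carry each block's sigma alongside its thetas for the simulator
  pop <- draw_population(design, params, seed)
  for (k in seq_along(pop)) {
    for (blk in names(params))
      pop[[k]]$params[[blk]]$sigma_ref <- as.list(params[[blk]]$sigma)
    if (!is.null(streams))
      pop[[k]]$streams <- intersect(pop[[k]]$streams, streams)
  }
  obs <- do.call(rbind, lapply(pop, simulate_observations, design = design))
  doses <- do.call(rbind, lapply(pop, function(s) {
    data.frame(ID = s$id, TIME = 0, WSTART = NA_real_, WEND = NA_real_,
               DVID = NA_character_, HEMI = NA_character_, DV = NA_real_,
               AMT = s$dose$rate * s$dose$duration, RATE = s$dose$rate,
               DUR = s$dose$duration, MDV = 1L, LLOQ = NA_real_, BLQ = 0L,
               TRUNC = 0L, PERF = NA_real_, stringsAsFactors = FALSE)
  }))
  meta <- do.call(rbind, lapply(pop, function(s)
    data.frame(ID = s$id, GROUP = s$group, WT = s$weight,
               stringsAsFactors = FALSE)))
  dat <- rbind(doses, obs)
  dat <- merge(dat, meta, by = "ID", sort = FALSE)
  dat <- dat[order(dat$ID, is.na(dat$TIME), dat$TIME, dat$WSTART), ]
  rownames(dat) <- NULL
  dat <- as_ldopa_dataset(dat)
  list(data = dat, subjects = pop, seed = seed, design = design)
}

#' Write a simulated trial to disk (long CSV plus truth sidecar)
#'
#' Writes the long-format dataset as CSV (with its units sidecar) and a JSON
#' truth sidecar holding each virtual subject's dose group, weight, responder
#' status, TH%, probe recovery, random-effect draws and individual parameters,
#' for parameter-recovery testing.
#'
#' @param sim The list returned by [simulate_trial()].
#' @param path CSV file path; the truth sidecar is written to
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(sim, path) {
  write_ldopa_dataset(sim$data, path)
  truth <- lapply(sim$subjects, function(s) {
    list(id = s$id, dose_group = s$group, weight_kg = s$weight,
         responder = s$responder, th_pct = s$th_pct, recovery = s$recovery,
         child_seed = s$child_seed,
         params = lapply(s$params, function(b)
           list(theta = as.list(b$theta[!is.na(b$theta)]),
                eta = as.list(b$eta))))
  })
  jsonlite::write_json(list(seed = sim$seed, subjects = truth),
                       paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Draw baseline dialysate fractions from an empirical distribution
#'
#' Generates pre-dose dialysate fractions for `n` virtual hemispheres whose
#' population mean and standard error match a target (e.g. the control
#' hemisphere DOPAC baseline). Per-subject means are lognormal with
#' moment-matched mean `group_mean` and SD `sem * sqrt(n)` (concentrations are
#' positive); fraction-level noise is multiplicative.
#'
#' @param n Number of subjects (hemispheres).
#' @param group_mean Target population mean concentration.
#' @param sem Target standard error of the group mean.
#' @param analyte,hemisphere Labels for the emitted rows.
#' @param n_fractions Pre-dose fractions per subject.
#' @param noise_cv Within-subject fraction noise (CV).
#' @param seed Integer seed.
#' @return Data frame of baseline dialysate rows (`ID`, `WSTART`, `WEND`,
#'   `DVID`, `HEMI`, `DV`).
#' @export
draw_baseline_population <- function(n, group_mean, sem, analyte = "DOPAC",
                                     hemisphere = "control", n_fractions = 3,
                                     noise_cv = 0.05, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  sd_subj <- sem * sqrt(n)
  sdlog <- sqrt(log(1 + (sd_subj / group_mean)^2))
  mu <- log(group_mean) - sdlog^2 / 2
  subj_mean <- exp(rnorm(n, mu, sdlog))
  w <- cbind(seq(-10 * n_fractions, -10, 10), seq(-10 * (n_fractions - 1), 0, 10))
  dvid <- if (analyte == "DOPAC") "dial_DOPAC" else "dial_HVA"
  do.call(rbind, lapply(seq_len(n), function(i) {
    dv <- subj_mean[i] * (1 + rnorm(n_fractions, 0, noise_cv))
    data.frame(ID = sprintf("B%02d", i), WSTART = w[, 1], WEND = w[, 2],
               DVID = dvid, HEMI = hemisphere, DV = pmax(dv, 0),
               stringsAsFactors = FALSE)
  }))
}
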