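# Structural model: linear-system construction, piecewise-exact solution,
# steady-state baselines and unit conversion.

#' Molar masses of the analytes (g/mol)
#' @export
analyte_molar_mass <- function() {
  c("L-DOPA" = 197.19, DOPAC = 168.15, HVA = 182.17, dopamine = 153.18)
}

#' Create an intravenous infusion dose event
#'
#' @param start Start time (min).
#' @param duration Infusion duration (min), > 0; the study design infused over
#'   20 min.
#' @param rate Infusion rate (ng/min), >= 0.
#' @return A `dose_event`.
#' @export
dose_event <- function(start, duration = 20, rate) {
  if (!is.finite(duration) || duration <= 0) stop("infusion duration must be > 0")
  if (!is.finite(rate) || rate < 0) stop("infusion rate must be >= 0")
  structure(list(start = start, duration = duration, rate = rate),
            class = "dose_event")
}

doses_to_matrix <- function(doses) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  if (is.null(doses) || length(doses) == 0)
    return(matrix(numeric(), 0, 3))
  if (is.data.frame(doses))
    doses <- lapply(seq_len(nrow(doses)), function(i)
      dose_event(doses$start[i], doses$duration[i], doses$rate[i]))
  do.call(rbind, lapply(doses, function(d)
    c(d$start, d$start + d$duration, d$rate)))
}

#' Build the linear compartmental system
#'
#' Assembles the rate matrix `A` and endogenous input vector `b` of the
#' (time-invariant between dose events) linear system `x' = A x + b + dose(t)`
#' over the model's active compartments: central elimination `Cl/V1`,
#' plasma-peripheral exchange (`Q2`, `Q3`), plasma to brain-ECF exchange
#' (`Q4`, `Q5`), brain-ECF elimination (`k40`, `k50`), zero-order endogenous
#' L-DOPA input `K_in` into each brain-ECF compartment, metabolite formation
#' from the parent ECF *concentration* (`k46`, `k58`, `k47`, `k59`) and
#' first-order metabolite elimination (`k60`, `k80`, `k70`, `k90`).
#' Compartments 1-5 carry amounts (ng); the metabolite compartments 6-9 are
#' modelled directly on the concentration scale (no estimable volumes).
#'
#' @param spec An `ldopa_model_spec`.
#' @param params A `parameter_set`; symmetry constraints in `spec` are applied
#'   before validation.
#' @return An `ldopa_system`: list with `A`, `b_endo`, `active`, `theta`
#'   (constrained full vector), and `spec`.
#' @export
build_ode_system <- function(spec, params) {
  theta <- apply_constraints(params$theta, spec$constraints)
  req <- required_params(spec$active)
  miss <- req[is.na(theta[req])]
  if (length(miss))
    stop("missing parameter(s) for this model: ", paste(miss, collapse = ", "))
  vols <- intersect(req, c("V1", "V2", "V3", "V4", "V5"))
  if (any(theta[vols] <= 0))
    stop("volumes must be > 0: ",
         paste(vols[theta[vols] <= 0], collapse = ", "))
  rates <- setdiff(req, vols)
  if (any(theta[rates] < 0))
    stop("rate constants and clearances must be >= 0: ",
         paste(rates[theta[rates] < 0], collapse = ", "))
  th <- theta
  th[is.na(th)] <- 0
  sys <- build_system_cpp(unname(th), as.integer(spec$active))
  dimnames(sys$A) <- list(paste0("C", spec$active), paste0("C", spec$active))
  structure(list(A = sys$A, b_endo = drop(sys$b), active = spec$active,
                 theta = theta, spec = spec),
            class = "ldopa_system")
}

# volume used to express a compartment's amount as a concentration (NA for
# metabolite compartments, which are already concentrations)
compartment_volumes <- function(system) {
  v <- rep(1, length(system$active))
  vol_par <- c("V1", "V2", "V3", "V4", "V5")
  amt <- system$active <= 5
  v[amt] <- system$theta[vol_par[system$active[amt]]]
  v
}

#' Endogenous steady state of the system
#'
#' Solves `0 = A x + b` for the endogenous-input-only system (no dose). With
#' `K_in = 0` all baselines are zero. The resulting plasma baseline is far
#' below the 1 ng/mL plasma LLQ, consistent with unmeasurable endogenous
#' plasma L-DOPA.
#'
#' @param system An `ldopa_system`.
#' @return List with `amounts` and `conc` (named by compartment).
#' @export
steady_state <- function(system) {
  if (all(system$b_endo == 0)) {
    x <- rep(0, nrow(system$A))
  } else {
    x <- tryCatch(solve(system$A, -system$b_endo),
                  error = function(e)
                    stop("no steady state: system is singular ",
                         "(zero elimination with nonzero endogenous input)"))
    if (any(!is.finite(x)))
      stop("no steady state: system is singular")
  }
  names(x) <- rownames(system$A)
  conc <- x / compartment_volumes(system)
  list(amounts = x, conc = conc)
}

#' Solve the model over a time grid
#'
#' Piecewise-exact solution of the linear system (eigendecomposition with a
#' matrix-exponential fallback), honouring infusion on/off breakpoints exactly
#' and continuous across them. The initial condition is the endogenous steady
#' state (or zero).
#'
#' @param system An `ldopa_system` from [build_ode_system()].
#' @param doses A `dose_event`, list of them, or data.frame with columns
#'   `start`, `duration`, `rate` (ng/min into the central compartment).
#' @param t_grid Sorted numeric vector of output times (min).
#' @param windows Optional matrix/data.frame with columns `start`, `end`:
#'   collection intervals over which time-averaged amounts/concentrations are
#'   returned (exact integrals, not quadrature).
#' @param init `"steady_state"` (default) or `"zero"`.
#' @return A `state_trajectory`: list with `time`, `amounts` (grid x
#'   compartments; metabolite compartments are concentration-scaled),
#'   `conc`, and when windows are given `window` (the windows),
#'   `window_avg_conc`.
#' @export
solve_trajectory <- function(system, doses, t_grid, windows = NULL,
                             init = c("steady_state", "zero")) {
  init <- match.arg(init)
  if (is.unsorted(t_grid)) stop("t_grid must be sorted increasing")
  inf <- doses_to_matrix(doses)
  if (nrow(inf) > 1 && any(diff(sort(inf[, 1])) < 0)) stop("invalid doses")
  win <- if (is.null(windows)) matrix(numeric(), 0, 2) else {
    w <- as.matrix(as.data.frame(windows)[, 1:2])
    if (any(w[, 2] <= w[, 1])) stop("window end must exceed start")
    w
  }
  x0 <- if (init == "steady_state") steady_state(system)$amounts
        else rep(0, nrow(system$A))
  t0 <- min(c(t_grid, win[, 1], if (nrow(inf)) inf[, 1], 0))
  out <- traj_solve_cpp(system$A, system$b_endo, unname(x0), t0, inf, 0L,
                        as.numeric(t_grid), win)
  vols <- compartment_volumes(system)
  amounts <- out$state
  dimnames(amounts) <- list(NULL, rownames(system$A))
  conc <- sweep(amounts, 2, vols, "/")
  res <- list(time = t_grid, amounts = amounts, conc = conc,
              active = system$active)
  if (nrow(win)) {
    wavg <- out$wavg
    dimnames(wavg) <- list(NULL, rownames(system$A))
    res$window <- win
    res$window_avg_conc <- sweep(wavg, 2, vols, "/")
  }
  structure(res, class = "state_trajectory")
}

#' Convert between the units used in the study
#'
#' Mass/molar concentration conversion uses the analyte's molar mass;
#' `mg/kg` to `ng` (total dose) additionally needs the body weight.
#'
#' @param value Numeric.
#' @param analyte One of `"L-DOPA"`, `"DOPAC"`, `"HVA"`, `"dopamine"`.
#' @param from,to Units among `"ng/mL"`, `"pmol/mL"`, `"mg/kg"`, `"ng"`.
#' @param weight_kg Body weight (kg), required for `mg/kg` conversions.
#' @return Converted numeric value.
#' @export
convert_units <- function(value, analyte, from, to, weight_kg = NULL) {
  mm <- analyte_molar_mass()
  if (!analyte %in% names(mm)) stop("unknown analyte: ", analyte)
  units <- c("ng/mL", "pmol/mL", "mg/kg", "ng")
  if (!from %in% units) stop("unknown unit: ", from)
  if (!to %in% units) stop("unknown unit: ", to)
  if (from == to) return(value)
  m <- mm[[analyte]]
  # to a base representation first
  base <- switch(from,
    "ng/mL" = list(kind = "conc_mass", v = value),
    "pmol/mL" = list(kind = "conc_mass", v = value * m / 1000),
    "ng" = list(kind = "amt_mass", v = value),
    "mg/kg" = {
      if (is.null(weight_kg)) stop("weight_kg required to convert from mg/kg")
      list(kind = "amt_mass", v = value * weight_kg * 1e6)
    })
  switch(to,
    "ng/mL" = if (base$kind == "conc_mass") base$v else
      stop("cannot convert an amount to a concentration"),
    "pmol/mL" = if (base$kind == "conc_mass") base$v * 1000 / m else
      stop("cannot convert an amount to a concentration"),
    "ng" = if (base$kind == "amt_mass") base$v else
      stop("cannot convert a concentration to an amount"),
    "mg/kg" = {
      if (is.null(weight_kg)) stop("weight_kg required to convert to mg/kg")
      if (base$kind != "amt_mass") stop("cannot convert a concentration to mg/kg")
      base$v / (weight_kg * 1e6)
    })
}
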