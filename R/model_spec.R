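# Model specification: compartments, parameter roles, symmetry constraints,
# observation-to-compartment mapping and error-model assignment.

#' Canonical structural parameter names
#'
#' The full parameter vector of the nine-compartment parent-metabolite model,
#' in the fixed order shared with the compiled code. `Cl` is total plasma
#' clearance, `V1`-`V3` plasma central/peripheral volumes, `V4`/`V5` apparent
#' brain-ECF volumes (control/diseased hemisphere), `Q2`-`Q5`
#' inter-compartmental clearances, `k40`/`k50` brain-ECF elimination rate
#' constants, `K_in` the endogenous zero-order formation input of L-DOPA into
#' each brain-ECF compartment, `k46`/`k58` (`k47`/`k59`) formation rate
#' constants of DOPAC (HVA) via dopamine in the control/diseased hemisphere,
#' and `k60`/`k80`/`k70`/`k90` the metabolite elimination rate constants.
#'
#' @return Character vector of length 21.
#' @export
param_names <- function() {
  c("Cl", "V1", "V2", "V3", "V4", "V5", "Q2", "Q3", "Q4", "Q5",
    "k40", "k50", "K_in", "k46", "k58", "k47", "k59", "k60", "k80", "k70", "k90")
}

#' Units of the structural parameters
#'
#' `K_in` is implemented as a zero-order endogenous input in ng/min (the only
#' interpretation that yields a finite nonzero baseline in a linear system);
#' its conventionally printed label "1/min" is kept as metadata.
#'
#' @return Named character vector of units.
#' @export
param_units <- function() {
  u <- c(Cl = "mL/min", V1 = "mL", V2 = "mL", V3 = "mL", V4 = "mL", V5 = "mL",
         Q2 = "mL/min", Q3 = "mL/min", Q4 = "mL/min", Q5 = "mL/min",
         k40 = "1/min", k50 = "1/min", K_in = "ng/min (printed label: 1/min)",
         k46 = "1/min", k58 = "1/min", k47 = "1/min", k59 = "1/min",
         k60 = "1/min", k80 = "1/min", k70 = "1/min", k90 = "1/min")
  u[param_names()]
}

# observation stream identifiers used in long datasets
dvid_levels <- function() {
  c("plasma_LDOPA", "ecf_LDOPA", "dial_DOPAC", "dial_HVA", "retro_LDOPA", "TH")
}

all_constraints <- function() c("Q5=Q4", "V5=V4", "k50=k40")

# map constraint labels to (target, source) parameter names
constraint_pairs <- function(constraints) {
  m <- list("Q5=Q4" = c("Q5", "Q4"), "V5=V4" = c("V5", "V4"),
            "k50=k40" = c("k50", "k40"))
  bad <- setdiff(constraints, names(m))
  if (length(bad))
    stop("unknown symmetry constraint(s): ", paste(bad, collapse = ", "))
  m[constraints]
}

new_model_spec <- function(name, active, obs_map, free_theta, iiv, sigma_names,
                           constraints = character(), subject_fixed = character()) {
  structure(list(name = name, active = as.integer(active), obs_map = obs_map,
                 free_theta = free_theta, iiv = iiv, sigma_names = sigma_names,
                 constraints = constraints, subject_fixed = subject_fixed),
            class = "ldopa_model_spec")
}

#' @export
print.ldopa_model_spec <- function(x, ...) {
  cat("<ldopa_model_spec> ", x$name, "\n", sep = "")
  cat("  compartments: ", paste(x$active, collapse = ", "), "\n", sep = "")
  if (length(x$constraints))
    cat("  constraints:  ", paste(x$constraints, collapse = " & "), "\n", sep = "")
  cat("  free theta:   ", paste(x$free_theta, collapse = ", "), "\n", sep = "")
  cat("  IIV (omega^2):", paste(x$iiv, collapse = ", "), "\n")
  if (length(x$subject_fixed))
    cat("  subject-fixed:", paste(x$subject_fixed, collapse = ", "), "\n")
  invisible(x)
}

obs_map_row <- function(dvid, hemi, comp, err, err_type, type) {
  data.frame(dvid = dvid, hemi = hemi, comp = comp, err = err,
             err_type = err_type, type = type, stringsAsFactors = FALSE)
}

#' Plasma-only model specification
#'
#' Three-compartment disposition model for L-DOPA in plasma (central plus two
#' peripheral compartments), proportional residual error, inter-individual
#' variability on clearance.
#'
#' @return An `ldopa_model_spec`.
#' @export
plasma_model_spec <- function() {
  new_model_spec(
    name = "plasma L-DOPA (3-compartment)",
    active = 1:3,
    obs_map = obs_map_row("plasma_LDOPA", NA, 1L, "prop_plasma", "prop", "point"),
    free_theta = c("Cl", "V1", "V2", "V3", "Q2", "Q3"),
    iiv = "Cl",
    sigma_names = "prop_plasma")
}

#' Parent (plasma + brain-ECF) model specification
#'
#' Simultaneous model for plasma and brain-ECF L-DOPA in both hemispheres:
#' compartments 1-3 (plasma), 4 (control-hemisphere ECF) and 5
#' (diseased-hemisphere ECF), endogenous zero-order formation `K_in` into each
#' ECF compartment, proportional residual errors for plasma and ECF.
#'
#' @param constraints Character subset of `c("Q5=Q4", "V5=V4", "k50=k40")`;
#'   each removes one free parameter by tying the diseased-hemisphere value to
#'   its control-hemisphere counterpart. Defaults to the fully symmetric model.
#' @return An `ldopa_model_spec`.
#' @export
parent_model_spec <- function(constraints = all_constraints()) {
  constraint_pairs(constraints)  # validates
  free <- c("Cl", "V1", "V2", "V3", "V4", "Q2", "Q3", "Q4", "k40", "K_in")
  for (cp in constraint_pairs(setdiff(all_constraints(), constraints)))
    free <- c(free, cp[1])
  om <- rbind(
    obs_map_row("plasma_LDOPA", NA, 1L, "prop_plasma", "prop", "point"),
    obs_map_row("ecf_LDOPA", "control", 4L, "prop_ecf", "prop", "window"),
    obs_map_row("ecf_LDOPA", "diseased", 5L, "prop_ecf", "prop", "window"))
  nm <- if (length(constraints)) paste(constraints, collapse = " & ") else "unconstrained"
  new_model_spec(
    name = paste0("plasma + brain-ECF L-DOPA (", nm, ")"),
    active = 1:5, obs_map = om, free_theta = free,
    iiv = c("Cl", "V4", "K_in"),
    sigma_names = c("prop_plasma", "prop_ecf"),
    constraints = constraints)
}

#' Sequential metabolite sub-model specification
#'
#' Model for DOPAC or HVA microdialysate kinetics in one hemisphere, fitted
#' sequentially with the parent L-DOPA parameters fixed per subject (empirical
#' Bayes estimates from the parent fit). The sub-model re-estimates the
#' brain-ECF elimination rate constant of L-DOPA for its hemisphere (`k40`
#' control, `k50` diseased) together with the metabolite formation and
#' elimination rate constants; the metabolite compartment is modelled on the
#' dialysate concentration scale with additive residual error.
#'
#' @param metabolite `"DOPAC"` or `"HVA"`.
#' @param hemisphere `"control"` or `"diseased"`.
#' @return An `ldopa_model_spec`.
#' @export
metabolite_model_spec <- function(metabolite = c("DOPAC", "HVA"),
                                  hemisphere = c("control", "diseased")) {
  metabolite <- match.arg(metabolite)
  hemisphere <- match.arg(hemisphere)
  key <- paste(tolower(metabolite), hemisphere, sep = "_")
  cfg <- list(
    dopac_control  = list(active = c(1:4, 6), comp = 6L, free = c("k46", "k40", "k60"),
                          iiv = c("k46", "k40", "k60"), err = "add_dopac_control"),
    hva_control    = list(active = c(1:4, 7), comp = 7L, free = c("k47", "k40", "k70"),
                          iiv = c("k47", "k70"), err = "add_hva_control"),
    dopac_diseased = list(active = c(1:3, 5, 8), comp = 8L, free = c("k58", "k50", "k80"),
                          iiv = c("k58", "k50"), err = "add_dopac_diseased"),
    hva_diseased   = list(active = c(1:3, 5, 9), comp = 9L, free = c("k59", "k50", "k90"),
                          iiv = "k59", err = "add_hva_diseased"))[[key]]
  dvid <- if (metabolite == "DOPAC") "dial_DOPAC" else "dial_HVA"
  parent_pars <- c("Cl", "V1", "V2", "V3", "Q2", "Q3", "K_in",
                   if (hemisphere == "control") c("V4", "Q4") else c("V5", "Q5"))
  new_model_spec(
    name = paste(metabolite, hemisphere, "hemisphere (sequential)"),
    active = cfg$active,
    obs_map = obs_map_row(dvid, hemisphere, cfg$comp, cfg$err, "add", "window"),
    free_theta = cfg$free, iiv = cfg$iiv, sigma_names = cfg$err,
    subject_fixed = parent_pars)
}

# ---------------------------------------------------------------------------
# Parameter sets
# ---------------------------------------------------------------------------

#' Construct a population parameter set
#'
#' @param theta Named numeric vector of typical values; names must be a subset
#'   of [param_names()]. Unmentioned parameters are `NA` (absent).
#' @param omega2 Named numeric vector of inter-individual variances (lognormal
#'   random effects, `P_i = theta * exp(eta)`, `eta ~ N(0, omega2)`).
#' @param sigma Named numeric vector of residual-error standard deviations
#'   (one entry per error model, e.g. `prop_plasma`, `add_dopac_control`).
#' @param sigma_type Named character vector (`"prop"` or `"add"`) aligned with
#'   `sigma`; inferred from the name prefix when omitted.
#' @return A `parameter_set`.
#' @export
parameter_set <- function(theta, omega2 = numeric(), sigma = numeric(),
                          sigma_type = NULL) {
  full <- stats::setNames(rep(NA_real_, 21), param_names())
  bad <- setdiff(names(theta), param_names())
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  full[names(theta)] <- theta
  bad <- setdiff(names(omega2), param_names())
  if (length(bad)) stop("unknown omega^2 parameter(s): ", paste(bad, collapse = ", "))
  if (any(!is.na(omega2) & omega2 < 0)) stop("omega^2 must be >= 0")
  if (any(!is.na(sigma) & sigma < 0)) stop("sigma must be >= 0")
  if (is.null(sigma_type))
    sigma_type <- stats::setNames(
      ifelse(grepl("^prop", names(sigma)), "prop", "add"), names(sigma))
  structure(list(theta = full, omega2 = omega2, sigma = sigma,
                 sigma_type = sigma_type),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  th <- x$theta[!is.na(x$theta)]
  cat("  theta: ", paste(sprintf("%s=%g", names(th), th), collapse = ", "), "\n")
  if (length(x$omega2))
    cat("  omega^2:", paste(sprintf("%s=%g", names(x$omega2), x$omega2),
                            collapse = ", "), "\n")
  if (length(x$sigma))
    cat("  sigma: ", paste(sprintf("%s=%g (%s)", names(x$sigma), x$sigma,
                                   x$sigma_type[names(x$sigma)]),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Reference population parameter values
#'
#' Typical values, inter-individual variances and residual-error standard
#' deviations for the L-DOPA rotenone-rat study design the package emulates:
#' the parent plasma + brain-ECF model (fully symmetric hemispheres) and the
#' four sequential metabolite sub-models. These are the generator defaults for
#' synthetic trials and the standard initial values for fits.
#'
#' @param model One of `"parent"`, `"plasma"`, `"dopac_control"`,
#'   `"hva_control"`, `"dopac_diseased"`, `"hva_diseased"`, or `"all"` (a named
#'   list of all six).
#' @return A `parameter_set`, or a named list of them for `model = "all"`.
#' @export
reference_parameters <- function(model = c("parent", "plasma", "dopac_control",
                                           "hva_control", "dopac_diseased",
                                           "hva_diseased", "all")) {
  model <- match.arg(model)
  plasma_theta <- c(Cl = 30, V1 = 98, V2 = 157, V3 = 599, Q2 = 22, Q3 = 11)
  parent_theta <- c(plasma_theta,
                    V4 = 13300, V5 = 13300, Q4 = 22, Q5 = 22,
                    k40 = 0.175, k50 = 0.175, K_in = 5.8)
  sets <- list(
    plasma = parameter_set(plasma_theta, omega2 = c(Cl = 0.26),
                           sigma = c(prop_plasma = 0.087)),
    parent = parameter_set(parent_theta,
                           omega2 = c(Cl = 0.26, V4 = 0.075, K_in = 0.94),
                           sigma = c(prop_plasma = 0.087, prop_ecf = 0.17)),
    dopac_control = parameter_set(
      c(parent_theta[c("Cl", "V1", "V2", "V3", "V4", "Q2", "Q3", "Q4", "K_in")],
        k46 = 0.000044, k40 = 0.53, k60 = 0.0053),
      omega2 = c(k46 = 0.50, k40 = 0.42, k60 = 0.19),
      sigma = c(add_dopac_control = 0.0020)),
    hva_control = parameter_set(
      c(parent_theta[c("Cl", "V1", "V2", "V3", "V4", "Q2", "Q3", "Q4", "K_in")],
        k47 = 0.000023, k40 = 0.19, k70 = 0.0044),
      omega2 = c(k47 = 0.019, k70 = 0.14),
      sigma = c(add_hva_control = 0.0028)),
    dopac_diseased = parameter_set(
      c(parent_theta[c("Cl", "V1", "V2", "V3", "Q2", "Q3", "K_in")],
        V5 = 13300, Q5 = 22, k58 = 0.000054, k50 = 0.36, k80 = 0.038),
      omega2 = c(k58 = 1.0, k50 = 0.53),
      sigma = c(add_dopac_diseased = 0.0014)),
    hva_diseased = parameter_set(
      c(parent_theta[c("Cl", "V1", "V2", "V3", "Q2", "Q3", "K_in")],
        V5 = 13300, Q5 = 22, k59 = 0.000016, k50 = 0.14, k90 = 0.011),
      omega2 = c(k59 = 0.49),
      sigma = c(add_hva_diseased = 0.0034)))
  if (model == "all") sets else sets[[model]]
}

# apply symmetry constraints to a full theta vector
apply_constraints <- function(theta, constraints) {
  for (cp in constraint_pairs(constraints)) theta[cp[1]] <- theta[cp[2]]
  theta
}

# 0-based source index vector for the compiled code (-1 = unconstrained)
constraint_src <- function(constraints) {
  src <- rep(-1L, 21)
  nm <- param_names()
  for (cp in constraint_pairs(constraints))
    src[match(cp[1], nm)] <- match(cp[2], nm) - 1L
  src
}

# parameters that the model structure requires, given active compartments
required_params <- function(active) {
  req <- c("Cl", "V1")
  if (2 %in% active) req <- c(req, "V2", "Q2")
  if (3 %in% active) req <- c(req, "V3", "Q3")
  if (4 %in% active) req <- c(req, "V4", "Q4", "k40", "K_in")
  if (5 %in% active) req <- c(req, "V5", "Q5", "k50", "K_in")
  if (6 %in% active) req <- c(req, "k46", "k60")
  if (7 %in% active) req <- c(req, "k47", "k70")
  if (8 %in% active) req <- c(req, "k58", "k80")
  if (9 %in% active) req <- c(req, "k59", "k90")
  unique(req)
}

#' Serialise / read a model definition as a config list
#'
#' Writes the model structure (active compartments, constraints, parameter
#' values with units, IIV flags, residual-error models) in a YAML/JSON-ready
#' list using the canonical parameter names, and reads it back.
#'
#' @param spec An `ldopa_model_spec`.
#' @param params A `parameter_set`.
#' @param path Optional file path (`.yaml`/`.yml` or `.json`); when given the
#'   config is written there.
#' @return The config as a list, invisibly when written to `path`.
#' @export
model_config <- function(spec, params, path = NULL) {
  th <- params$theta[!is.na(params$theta)]
  cfg <- list(
    model = spec$name,
    compartments = spec$active,
    constraints = spec$constraints,
    parameters = lapply(names(th), function(nm) {
      list(name = nm, value = unname(th[nm]), unit = unname(param_units()[nm]),
           iiv = nm %in% names(params$omega2),
           omega2 = if (nm %in% names(params$omega2))
             unname(params$omega2[nm]) else NULL)
    }),
    residual_error = lapply(names(params$sigma), function(nm) {
      list(name = nm, type = unname(params$sigma_type[nm]),
           sd = unname(params$sigma[nm]))
    }))
  if (!is.null(path)) {
    if (grepl("\\.ya?ml$", path)) yaml::write_yaml(cfg, path)
    else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
    return(invisible(cfg))
  }
  cfg
}
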