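# Nonlinear mixed-effects estimation: Laplace-with-interaction objective,
# outer maximum-likelihood fit on log-transformed parameters, sequential
# parent-then-metabolite workflow, LRT and the hemisphere-symmetry grid.

vol_param_for_comp <- function(comp) {
  # param index (0-based, canonical order) used to scale an amount to a
  # concentration; -1 for concentration-scale metabolite compartments
  v <- c(2L, 3L, 4L, 5L, 6L, -1L, -1L, -1L, -1L)[comp] - 1L
  ifelse(comp >= 6, -1L, v)
}

# Convert a long dataset + spec into the compiled code's subject list.
# subject_params: optional named list (by ID) of full-length-21 named vectors
# providing the subject-fixed parameters (sequential fits).
prepare_subjects <- function(data, spec, params, subject_params = NULL) {
  data <- as.data.frame(data)
  nm <- param_names()
  om <- spec$obs_map
  is_dose <- !is.na(data$AMT)
  keep <- !is_dose & data$DVID %in% om$dvid & data$MDV %in% 0 &
    (is.na(data$BLQ) | data$BLQ == 0)
  # hemisphere matching (NA in obs_map matches any)
  sel_rows <- function(id) {
    idx <- which(keep & data$ID == id)
    map_i <- integer(0); rows <- integer(0)
    for (r in seq_len(nrow(om))) {
      m <- idx[data$DVID[idx] == om$dvid[r] &
                 (is.na(om$hemi[r]) | (!is.na(data$HEMI[idx]) &
                                         data$HEMI[idx] == om$hemi[r]))]
      rows <- c(rows, m); map_i <- c(map_i, rep(r, length(m)))
    }
    list(rows = rows, map = map_i)
  }
  ids <- unique(data$ID[keep])
  if (!length(ids)) stop("no usable observations for this model specification")
  if (length(spec$subject_fixed)) {
    if (is.null(subject_params))
      stop("this model fixes parameters per subject (",
           paste(spec$subject_fixed, collapse = ", "),
           "); supply subject_params (e.g. from a parent fit)")
    missing_ids <- setdiff(ids, names(subject_params))
    if (length(missing_ids))
      stop("subjects present in the data but absent from the parent fit: ",
           paste(missing_ids, collapse = ", "))
  }
  sigma_names <- names(params$sigma)
  subjects <- lapply(ids, function(id) {
    sl <- sel_rows(id)
    d <- data[sl$rows, ]
    r <- om[sl$map, ]
    pt <- r$type == "point"
    drows <- data[is_dose & data$ID == id, , drop = FALSE]
    inf <- if (nrow(drows)) {
      rate <- ifelse(is.na(drows$RATE), drows$AMT / drows$DUR, drows$RATE)
      cbind(drows$TIME, drows$TIME + drows$DUR, rate)
    } else matrix(numeric(), 0, 3)
    base <- stats::setNames(rep(0, 21), nm)
    th0 <- params$theta
    base[!is.na(th0)] <- th0[!is.na(th0)]
    if (!is.null(subject_params) && id %in% names(subject_params)) {
      sp <- subject_params[[id]]
      base[names(sp)[!is.na(sp)]] <- sp[!is.na(sp)]
    }
    state_of <- function(comp) match(comp, spec$active) - 1L
    list(id = id, t0 = min(c(0, d$TIME, d$WSTART, if (nrow(inf)) inf[, 1]),
                           na.rm = TRUE),
         infusions = inf,
         pt_time = as.numeric(d$TIME[pt]),
         pt_state = as.integer(state_of(r$comp[pt])),
         pt_vol = as.integer(vol_param_for_comp(r$comp[pt])),
         win = cbind(as.numeric(d$WSTART[!pt]), as.numeric(d$WEND[!pt])),
         win_state = as.integer(state_of(r$comp[!pt])),
         win_vol = as.integer(vol_param_for_comp(r$comp[!pt])),
         y = c(d$DV[pt], d$DV[!pt]),
         err_id = as.integer(match(c(r$err[pt], r$err[!pt]), sigma_names) - 1L),
         err_prop = as.integer(c(r$err_type[pt], r$err_type[!pt]) == "prop"),
         obs_dvid = c(r$dvid[pt], r$dvid[!pt]),
         obs_hemi = c(r$hemi[pt], r$hemi[!pt]),
         base = unname(base))
  })
  names(subjects) <- ids
  subjects
}

# shared assembly of compiled-code arguments
laplace_args <- function(spec, params) {
  nm <- param_names()
  iiv <- spec$iiv[spec$iiv %in% names(params$omega2)]
  miss <- setdiff(spec$iiv, names(params$omega2))
  if (length(miss))
    stop("missing omega^2 for IIV parameter(s): ", paste(miss, collapse = ", "))
  omega2 <- params$omega2[iiv]
  # omega^2 = 0 means no random effect on that parameter
  iiv <- iiv[omega2 > 0]
  omega2 <- omega2[omega2 > 0]
  miss <- setdiff(spec$sigma_names, names(params$sigma))
  if (length(miss))
    stop("missing residual sigma for error model(s): ",
         paste(miss, collapse = ", "))
  use_theta <- as.integer(!(nm %in% spec$subject_fixed))
  # eta index applied to each of the 21 parameters (-1 = none); the diseased
  # hemisphere shares the control hemisphere's random effect when it has no
  # omega^2 of its own (one brain per animal)
  iiv_apply <- rep(-1L, 21)
  iiv_apply[match(iiv, nm)] <- seq_along(iiv) - 1L
  for (pair in list(c("V5", "V4"), c("Q5", "Q4"), c("k50", "k40"))) {
    ti <- match(pair[1], nm); si <- match(pair[2], nm)
    if (iiv_apply[ti] < 0 && iiv_apply[si] >= 0 && 5 %in% spec$active)
      iiv_apply[ti] <- iiv_apply[si]
  }
  list(use_theta = use_theta,
       cons_src = constraint_src(spec$constraints),
       iiv_apply = iiv_apply,
       iiv = iiv, omega2 = unname(omega2),
       sigma = unname(params$sigma[names(params$sigma)]),
       active = as.integer(spec$active))
}

#' Laplace (FOCE-with-interaction style) marginal-likelihood objective
#'
#' Minus twice the log marginal likelihood, approximated per subject by a
#' Laplace expansion around the conditional mode of the random effects, with
#' the interaction term (residual variance evaluated at the conditional
#' predictions) and Gauss-Newton curvature. Includes the `2*pi` normalising
#' constants, so absolute values differ from NONMEM's objective by a
#' data-dependent constant; only differences between nested models are
#' comparable across software. With all `omega^2 = 0` it reduces to the
#' naive-pooled -2 log-likelihood.
#'
#' @param data An `ldopa_dataset` (below-LOQ rows are excluded, M1 method).
#' @param spec An `ldopa_model_spec`.
#' @param params A `parameter_set` providing theta, `omega^2` and sigma.
#' @param subject_params Per-subject fixed parameters for sequential fits
#'   (named list of named vectors, by subject ID).
#' @return Numeric objective value; attributes `eta` (conditional modes) and
#'   `conv` (per-subject inner convergence flags).
#' @export
laplace_objective <- function(data, spec, params, subject_params = NULL) {
  subjects <- prepare_subjects(data, spec, params, subject_params)
  a <- laplace_args(spec, params)
  th <- params$theta
  th[is.na(th)] <- 0
  r <- laplace_obj_cpp(unname(subjects), unname(th), a$use_theta, a$cons_src,
                       a$iiv_apply, a$omega2, a$sigma, a$active,
                       matrix(0, length(a$iiv), length(subjects)),
                       1e-6, 40L)
  structure(r$value, eta = r$eta, conv = drop(r$conv), names = NULL)
}

fit_control <- function(control = list()) {
  def <- list(se = TRUE, n_starts = 1L, inner_tol = 1e-6, inner_maxit = 40L,
              outer_rel_tol = 1e-5, outer_maxit = 400L, log_bound = 18,
              trace = 0L)
  def[names(control)] <- control
  def
}

#' Fit a population model by approximate maximum likelihood
#'
#' Minimises the [laplace_objective()] over log-transformed free parameters
#' (typical values, inter-individual variances, residual SDs) with `nlminb`.
#' Standard errors come from the inverse Hessian at the optimum (delta method
#' back to the natural scale), confidence intervals as
#' `estimate +/- 1.96 * SE` and CV% as `100 * SE / estimate`. A
#' non-positive-definite Hessian leaves the SEs missing with a warning
#' (minimisation-terminated analogue). Empirical Bayes (post hoc) individual
#' parameters are returned for every subject.
#'
#' @param data An `ldopa_dataset`; ECF L-DOPA rows are expected to be
#'   recovery-corrected already (see [correct_to_ecf()]).
#' @param spec An `ldopa_model_spec`.
#' @param init A `parameter_set` of initial values (all free parameters must
#'   be present and positive).
#' @param subject_params Per-subject fixed parent parameters for sequential
#'   fits.
#' @param control List of optimizer settings: `se` (compute SEs, default TRUE),
#'   `n_starts` (multi-start count; starts beyond the first scale the initial
#'   values by 2 and 1/2 alternately), `inner_tol`, `inner_maxit`,
#'   `outer_rel_tol`, `outer_maxit`, `log_bound`.
#' @return An `ldopa_fit`.
#' @export
fit_popmodel <- function(data, spec, init = NULL, subject_params = NULL,
                         control = list()) {
  ctl <- fit_control(control)
  if (is.null(init)) init <- default_init_for(spec)
  subjects <- prepare_subjects(data, spec, init, subject_params)
  a <- laplace_args(spec, init)
  nm <- param_names()
  th_free <- spec$free_theta
  if (any(is.na(init$theta[th_free])))
    stop("initial values missing for: ",
         paste(th_free[is.na(init$theta[th_free])], collapse = ", "))
  om_free <- a$iiv
  sig_free <- spec$sigma_names
  n_th <- length(th_free); n_om <- length(om_free); n_sig <- length(sig_free)
  sigma_all <- init$sigma
  unpack <- function(p) {
    theta <- init$theta
    theta[th_free] <- exp(p[seq_len(n_th)])
    omega2 <- a$omega2
    if (n_om) omega2 <- exp(p[n_th + seq_len(n_om)])
    sigma <- sigma_all
    sigma[sig_free] <- exp(p[n_th + n_om + seq_len(n_sig)])
    th <- theta; th[is.na(th)] <- 0
    list(theta = th, omega2 = omega2, sigma = unname(sigma))
  }
  env <- new.env()
  env$eta <- matrix(0, length(a$iiv), length(subjects))
  env$inner_fail <- FALSE
  obj <- function(p) {
    u <- unpack(p)
    r <- laplace_obj_cpp(unname(subjects), unname(u$theta), a$use_theta,
                         a$cons_src, a$iiv_apply, u$omega2, u$sigma, a$active,
                         env$eta, ctl$inner_tol, ctl$inner_maxit)
    if (all(is.finite(r$eta))) env$eta <- r$eta
    if (any(r$conv == 0)) env$inner_fail <- TRUE
    r$value
  }
  p0 <- c(log(init$theta[th_free]),
          if (n_om) log(a$omega2),
          log(init$sigma[sig_free]))
  starts <- list(p0)
  if (ctl$n_starts > 1)
    for (s in seq_len(ctl$n_starts - 1))
      starts[[s + 1]] <- p0 + log(2) * (-1)^s
  best <- NULL
  for (st in starts) {
    env$eta[] <- 0
    o <- nlminb(st, obj,
                lower = st - ctl$log_bound, upper = st + ctl$log_bound,
                control = list(rel.tol = ctl$outer_rel_tol,
                               iter.max = ctl$outer_maxit,
                               eval.max = 4 * ctl$outer_maxit,
                               trace = ctl$trace))
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  # final evaluation for eta, convergence flags, exact MVOF
  env$inner_fail <- FALSE
  u <- unpack(best$par)
  fin <- laplace_obj_cpp(unname(subjects), unname(u$theta), a$use_theta,
                         a$cons_src, a$iiv_apply, u$omega2, u$sigma, a$active,
                         env$eta, ctl$inner_tol, ctl$inner_maxit)
  free_names <- c(th_free, if (n_om) paste0("omega2_", om_free),
                  paste0("sigma_", sig_free))
  est_nat <- exp(best$par)
  names(est_nat) <- free_names
  at_bound <- abs(best$par - p0) > ctl$log_bound - 0.5
  names(at_bound) <- free_names
  se_nat <- rep(NA_real_, length(free_names))
  hess_pd <- NA
  if (ctl$se) {
    H <- try(optimHess(best$par, obj), silent = TRUE)
    hess_pd <- FALSE
    if (!inherits(H, "try-error")) {
      ev <- try(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                silent = TRUE)
      if (!inherits(ev, "try-error") && all(ev > 0)) {
        cov_log <- 2 * solve(H)
        se_log <- sqrt(pmax(diag(cov_log), 0))
        se_nat <- se_log * est_nat
        hess_pd <- TRUE
      }
    }
    if (!isTRUE(hess_pd))
      warning("Hessian not positive definite; standard errors omitted")
  }
  ci <- data.frame(parameter = free_names, estimate = unname(est_nat),
                   se = unname(se_nat),
                   cv_pct = 100 * unname(se_nat) / unname(est_nat),
                   lci = unname(est_nat - 1.96 * se_nat),
                   uci = unname(est_nat + 1.96 * se_nat),
                   at_boundary = unname(at_bound))
  theta_hat <- apply_constraints(u$theta, spec$constraints)
  theta_hat[is.na(init$theta)] <- NA
  omega2_hat <- stats::setNames(u$omega2, om_free)
  sigma_hat <- stats::setNames(u$sigma, names(init$sigma))
  eta <- fin$eta
  if (length(a$iiv)) dimnames(eta) <- list(a$iiv, names(subjects))
  post_hoc <- individual_params(theta_hat, eta, spec, subjects)
  structure(list(
    spec = spec, mvof = fin$value,
    params = parameter_set(theta_hat[!is.na(theta_hat)], omega2 = omega2_hat,
                           sigma = sigma_hat,
                           sigma_type = init$sigma_type),
    table = ci, eta = eta, post_hoc = post_hoc,
    convergence = list(code = best$convergence, message = best$message,
                       iterations = best$iterations,
                       inner_ok = all(fin$conv == 1),
                       hessian_pd = hess_pd,
                       any_boundary = any(at_bound)),
    n_subjects = length(subjects), n_obs = sum(vapply(subjects, function(s)
      length(s$y), numeric(1))),
    init = init, control = ctl), class = "ldopa_fit")
}

# empirical Bayes individual parameter table
individual_params <- function(theta_hat, eta, spec, subjects) {
  ids <- names(subjects)
  out <- data.frame(ID = ids, stringsAsFactors = FALSE)
  th <- theta_hat
  # subject-fixed parameters come from each subject's base vector
  for (p in spec$subject_fixed)
    out[[p]] <- vapply(subjects, function(s) s$base[match(p, param_names())],
                       numeric(1))
  pop_pars <- setdiff(intersect(names(th)[!is.na(th)],
                                required_params(spec$active)),
                      spec$subject_fixed)
  for (p in pop_pars) out[[p]] <- rep(unname(th[p]), length(ids))
  if (nrow(eta) > 0)
    for (p in rownames(eta)) out[[p]] <- out[[p]] * exp(eta[p, ids])
  # re-apply symmetry constraints at the individual level
  for (cp in constraint_pairs(spec$constraints))
    if (cp[2] %in% names(out)) out[[cp[1]]] <- out[[cp[2]]]
  rownames(out) <- NULL
  out
}

default_init_for <- function(spec) {
  if (identical(spec$active, 1:3)) return(reference_parameters("plasma"))
  if (identical(spec$active, 1:5)) return(reference_parameters("parent"))
  if (6 %in% spec$active) return(reference_parameters("dopac_control"))
  if (7 %in% spec$active) return(reference_parameters("hva_control"))
  if (8 %in% spec$active) return(reference_parameters("dopac_diseased"))
  if (9 %in% spec$active) return(reference_parameters("hva_diseased"))
  stop("no default initial values for this specification; supply init")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ldopa_fit <- function(x, ...) {
  cat("<ldopa_fit> ", x$spec$name, "\n", sep = "")
  cat(sprintf("  %d subjects, %d observations; MVOF = %.3f\n",
              x$n_subjects, x$n_obs, x$mvof))
  if (!isTRUE(x$convergence$inner_ok) || x$convergence$code != 0)
    cat("  convergence: code", x$convergence$code,
        if (!isTRUE(x$convergence$inner_ok)) "(inner eta search issues)", "\n")
  tb <- x$table
  tb$estimate <- signif(tb$estimate, 3)
  tb$cv_pct <- signif(tb$cv_pct, 3)
  tb$ci <- sprintf("%.3g - %.3g", tb$lci, tb$uci)
  print(tb[, c("parameter", "estimate", "cv_pct", "ci")], row.names = FALSE)
  invisible(x)
}

#' Residual table for a fitted model
#'
#' Population predictions (random effects at zero), individual predictions
#' (at the empirical Bayes modes) and weighted residuals
#' `(obs - ipred) / sd(ipred)` for every observation used in the fit, in the
#' diagnostic-plot convention (observed vs predicted, weighted residuals vs
#' time).
#'
#' @param fit An `ldopa_fit`.
#' @param data The dataset the model was fitted to.
#' @param subject_params Per-subject fixed parameters, as passed to the fit
#'   (sequential fits).
#' @return Data frame with `ID`, `DVID`, `HEMI`, `time` (window midpoint for
#'   interval observations), `obs`, `pred_pop`, `pred_ind`, `wres`.
#' @export
fit_residuals <- function(fit, data, subject_params = NULL) {
  spec <- fit$spec
  params <- fit$params
  subjects <- prepare_subjects(data, spec, params, subject_params)
  a <- laplace_args(spec, params)
  th <- params$theta
  th[is.na(th)] <- 0
  out <- lapply(names(subjects), function(id) {
    s <- subjects[[id]]
    q <- length(a$iiv)
    eta0 <- rep(0, q)
    eta_i <- if (q && id %in% colnames(fit$eta)) fit$eta[, id] else eta0
    ppop <- predict_subject_cpp(s, unname(th), a$use_theta, a$cons_src,
                                a$iiv_apply, eta0, a$active)
    pind <- predict_subject_cpp(s, unname(th), a$use_theta, a$cons_src,
                                a$iiv_apply, eta_i, a$active)
    sdv <- a$sigma[s$err_id + 1]
    sdv <- ifelse(s$err_prop == 1, sdv * abs(pind), sdv)
    tmid <- c(s$pt_time, rowMeans(s$win))
    n_pt <- length(s$pt_time)
    data.frame(ID = id, DVID = s$obs_dvid, HEMI = s$obs_hemi,
               time = tmid, obs = s$y, pred_pop = ppop, pred_ind = pind,
               wres = (s$y - pind) / pmax(sdv, 1e-12),
               type = rep(c("point", "window"), c(n_pt, nrow(s$win))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sequential metabolite fit
#'
#' Fixes each subject's parent L-DOPA trajectory at its empirical Bayes
#' (post hoc) parameters from the parent fit and estimates the metabolite
#' sub-model (formation and elimination rate constants, the hemisphere's
#' brain-ECF L-DOPA elimination, their `omega^2` and the additive residual SD).
#' DOPAC and HVA, and the two hemispheres, are fitted independently.
#'
#' @param data An `ldopa_dataset` containing the metabolite dialysate rows.
#' @param parent Either an `ldopa_fit` of the parent model (its `post_hoc`
#'   table is used) or a data frame with column `ID` plus parent parameter
#'   columns (e.g. true simulated values).
#' @param metabolite `"DOPAC"` or `"HVA"`.
#' @param hemisphere `"control"` or `"diseased"`.
#' @param init Initial `parameter_set` (defaults to the reference values for
#'   the block).
#' @param control See [fit_popmodel()].
#' @return An `ldopa_fit`.
#' @export
sequential_metabolite_fit <- function(data, parent, metabolite = c("DOPAC", "HVA"),
                                      hemisphere = c("control", "diseased"),
                                      init = NULL, control = list()) {
  metabolite <- match.arg(metabolite)
  hemisphere <- match.arg(hemisphere)
  spec <- metabolite_model_spec(metabolite, hemisphere)
  ph <- if (inherits(parent, "ldopa_fit")) parent$post_hoc else as.data.frame(parent)
  if (!"ID" %in% names(ph)) stop("parent parameter table needs an ID column")
  # diseased sub-models take the parent's (symmetric) V4/Q4 as V5/Q5
  if (hemisphere == "diseased") {
    if (!"V5" %in% names(ph) && "V4" %in% names(ph)) ph$V5 <- ph$V4
    if (!"Q5" %in% names(ph) && "Q4" %in% names(ph)) ph$Q5 <- ph$Q4
  }
  need <- spec$subject_fixed
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("parent parameters missing from the parent fit: ",
         paste(miss, collapse = ", "))
  subject_params <- lapply(seq_len(nrow(ph)), function(i) {
    v <- as.numeric(ph[i, need]); names(v) <- need; v
  })
  names(subject_params) <- ph$ID
  if (is.null(init))
    init <- reference_parameters(paste(tolower(metabolite), hemisphere, sep = "_"))
  fit_popmodel(data, spec, init, subject_params = subject_params,
               control = control)
}

#' Likelihood-ratio comparison of nested fits
#'
#' `Delta MVOF = MVOF_reduced - MVOF_full`; the reduction is significantly
#' worse when `Delta >= 10.8` for one constrained parameter (chi-square at
#' p = 0.001, the model-selection criterion used throughout), or the
#' corresponding `chi^2_{0.999}(df)` quantile for `df` constraints.
#'
#' @param fit_full,fit_reduced `ldopa_fit`s (or bare MVOF numbers).
#' @param df Number of constrained parameters; inferred from the fits' free
#'   parameter counts when possible.
#' @return List with `delta`, `df`, `threshold`, `p_value`, `significant`
#'   (TRUE when the reduced model fits significantly worse).
#' @export
lrt_compare <- function(fit_full, fit_reduced, df = NULL) {
  mv <- function(f) if (inherits(f, "ldopa_fit")) f$mvof else as.numeric(f)
  np <- function(f) if (inherits(f, "ldopa_fit")) nrow(f$table) else NA_integer_
  if (is.null(df)) {
    df <- np(fit_full) - np(fit_reduced)
    if (is.na(df) || df < 1)
      stop("df must be supplied when it cannot be inferred from the fits")
  }
  delta <- mv(fit_reduced) - mv(fit_full)
  if (delta < -0.1)
    warning("reduced model has a lower objective than the full model ",
            sprintf("(delta = %.3f); check nesting/convergence", delta))
  threshold <- if (df == 1) 10.8 else qchisq(0.999, df)
  structure(list(delta = delta, df = df, threshold = threshold,
                 p_value = pchisq(max(delta, 0), df, lower.tail = FALSE),
                 significant = delta >= threshold),
            class = "ldopa_lrt")
}

#' @export
print.ldopa_lrt <- function(x, ...) {
  cat(sprintf("Delta MVOF = %.3f on %d df (threshold %.2f, p = %.3g): %s\n",
              x$delta, x$df, x$threshold, x$p_value,
              if (x$significant) "reduced model significantly worse"
              else "no significant difference"))
  invisible(x)
}

#' Hemisphere-symmetry assumption grid
#'
#' Fits all 8 combinations of the symmetry constraints
#' `{Q5=Q4, V5=V4, k50=k40}` to plasma + two-hemisphere ECF L-DOPA data and
#' selects the most parsimonious model that is not significantly worse than
#' the unconstrained one (likelihood-ratio test at p = 0.001,
#' `chi^2(df = number of constraints)`, 10.8 for a single constraint).
#' Constrained fits are warm-started from the unconstrained estimates;
#' per-cell failures are recorded in the cell and the grid continues.
#'
#' @param data An `ldopa_dataset` with recovery-corrected ECF rows.
#' @param init Initial `parameter_set` for the unconstrained fit.
#' @param control See [fit_popmodel()]; `se = FALSE` skips per-cell standard
#'   errors.
#' @return An `ldopa_grid`: list with `cells`, summary `table`, `selected`.
#' @export
symmetry_grid <- function(data, init = reference_parameters("parent"),
                          control = list()) {
  combos <- list(character(0))
  for (k in 1:3) {
    cc <- utils::combn(all_constraints(), k, simplify = FALSE)
    combos <- c(combos, cc)
  }
  cells <- vector("list", length(combos))
  base_fit <- NULL
  for (i in seq_along(combos)) {
    cons <- combos[[i]]
    spec <- parent_model_spec(constraints = cons)
    ini <- init
    if (!is.null(base_fit)) {
      th <- base_fit$params$theta
      ini <- parameter_set(th[!is.na(th)], omega2 = base_fit$params$omega2,
                           sigma = base_fit$params$sigma,
                           sigma_type = init$sigma_type)
    }
    cells[[i]] <- tryCatch(fit_popmodel(data, spec, ini, control = control),
                           error = function(e)
                             structure(list(constraints = cons,
                                            error = conditionMessage(e)),
                                       class = "ldopa_fit_failure"))
    if (i == 1 && inherits(cells[[i]], "ldopa_fit")) base_fit <- cells[[i]]
  }
  # polish: restart the unconstrained fit from the best cell's estimates so
  # the LRT reference is not a stalled local optimum
  ok_cells <- vapply(cells, inherits, logical(1), what = "ldopa_fit")
  if (any(ok_cells)) {
    best_i <- which(ok_cells)[which.min(vapply(cells[ok_cells], function(f)
      f$mvof, numeric(1)))]
    if (best_i != 1 && inherits(cells[[1]], "ldopa_fit") &&
        cells[[best_i]]$mvof < cells[[1]]$mvof - 1e-6) {
      bf <- cells[[best_i]]
      th <- bf$params$theta
      ini <- parameter_set(th[!is.na(th)], omega2 = bf$params$omega2,
                           sigma = bf$params$sigma, sigma_type = init$sigma_type)
      refit <- tryCatch(fit_popmodel(data, parent_model_spec(character(0)),
                                     ini, control = control),
                        error = function(e) NULL)
      if (!is.null(refit) && refit$mvof < cells[[1]]$mvof)
        cells[[1]] <- refit
    }
  }
  label <- vapply(combos, function(cc)
    if (!length(cc)) "NONE" else paste(cc, collapse = " & "), character(1))
  get_th <- function(f, p)
    if (inherits(f, "ldopa_fit")) unname(f$params$theta[p]) else NA_real_
  tab <- data.frame(
    assumption = label,
    n_constraints = vapply(combos, length, integer(1)),
    mvof = vapply(cells, function(f)
      if (inherits(f, "ldopa_fit")) f$mvof else NA_real_, numeric(1)),
    V4 = vapply(cells, get_th, numeric(1), p = "V4"),
    V5 = vapply(cells, get_th, numeric(1), p = "V5"),
    Q4 = vapply(cells, get_th, numeric(1), p = "Q4"),
    Q5 = vapply(cells, get_th, numeric(1), p = "Q5"),
    k40 = vapply(cells, get_th, numeric(1), p = "k40"),
    k50 = vapply(cells, get_th, numeric(1), p = "k50"))
  # blank the constrained (removed) parameters as in the published layout
  for (i in seq_along(combos)) {
    for (cp in constraint_pairs(combos[[i]])) tab[i, cp[1]] <- NA
  }
  mv0 <- tab$mvof[1]
  tab$delta <- tab$mvof - mv0
  tab$threshold <- ifelse(tab$n_constraints == 1, 10.8,
                          ifelse(tab$n_constraints > 0,
                                 qchisq(0.999, tab$n_constraints), NA))
  tab$accepted <- !is.na(tab$mvof) &
    (tab$n_constraints == 0 | tab$delta < tab$threshold)
  cand <- which(tab$accepted)
  sel <- cand[order(-tab$n_constraints[cand], tab$mvof[cand])][1]
  structure(list(cells = cells, table = tab, selected = sel,
                 selected_assumption = tab$assumption[sel]),
            class = "ldopa_grid")
}

#' @export
print.ldopa_grid <- function(x, ...) {
  tb <- x$table
  tb$mvof <- round(tb$mvof, 1)
  for (p in c("V4", "V5", "Q4", "Q5", "k40", "k50"))
    tb[[p]] <- signif(tb[[p]], 3)
  print(tb[, c("assumption", "mvof", "V4", "V5", "Q4", "Q5", "k40", "k50",
               "accepted")], row.names = FALSE)
  cat("selected:", x$selected_assumption, "\n")
  invisible(x)
}
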