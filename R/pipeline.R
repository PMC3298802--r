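# End-to-end pipeline driver: simulate or load a dataset, recovery-correct,
# classify responders, fit the parent model, run the symmetry grid, fit the
# metabolite sub-models, summarise baselines, and emit report tables.

#' Run the full analysis pipeline
#'
#' Stages: (optional) synthetic-trial simulation; retrodialysis recovery
#' estimation and correction of the L-DOPA dialysate rows (pooled across-animal
#' mean recovery, as in the original analysis); TH responder classification,
#' with non-responders excluded from diseased-hemisphere fits (their control
#' hemispheres are retained); parent plasma+ECF fit; hemisphere-symmetry grid
#' (optional); sequential DOPAC and HVA fits per hemisphere; baseline
#' summaries with Welch comparisons; text report tables.
#'
#' @param config A list or path to a YAML/JSON file with entries:
#'   `dataset` (path to a long CSV) *or* `simulate` (list with `seed` and
#'   optional `design` overrides); optional `stages` (character subset of
#'   `c("grid", "metabolites", "baseline")`), `control` (fit control),
#'   `output_dir`.
#' @return A report bundle (list) with the dataset, recovery estimate, TH
#'   table, fits, grid, baseline summary, report tables and the config echo.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stages <- config$stages %||% c("grid", "metabolites", "baseline")
  ctl <- config$control %||% list()
  stage <- "input"
  bundle <- list(config = config,
                 versions = list(ldopapk = as.character(utils::packageVersion("ldopapk")),
                                 R = R.version.string))
  run <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(config$simulate)) {
    stage <- "simulate"
    sim <- run(stage, {
      des <- do.call(study_design, config$simulate$design %||% list())
      simulate_trial(des, seed = config$simulate$seed)
    })
    data <- sim$data
    design <- sim$design
    bundle$truth <- sim$subjects
    bundle$seed <- sim$seed
  } else if (!is.null(config$dataset)) {
    data <- run("read", read_ldopa_dataset(config$dataset))
    design <- do.call(study_design, config$design %||% list())
  } else stop("config needs either a 'dataset' path or a 'simulate' block")
  bundle$data_raw <- data

  # recovery estimation from the retrodialysis phase, pooled across animals
  stage <- "recovery"
  retro <- data[!is.na(data$DVID) & data$DVID == "retro_LDOPA", ]
  if (nrow(retro)) {
    per_animal <- run(stage, lapply(split(retro, retro$ID), function(d)
      estimate_recovery(d$DV, d$PERF[1])$mean))
    rec <- list(mean = mean(unlist(per_animal)),
                sd = sd(unlist(per_animal)), n = length(per_animal))
    data <- run(stage, correct_to_ecf(data, rec$mean))
  } else {
    rec <- list(mean = 1, sd = NA_real_, n = 0L)
  }
  bundle$recovery <- rec

  stage <- "th"
  th <- tryCatch(th_table(data), error = function(e) NULL)
  bundle$th <- th
  nonresponders <- if (is.null(th)) character(0) else th$ID[!th$responder]
  # drop diseased-hemisphere rows of non-responders; keep their control side
  drop <- !is.na(data$HEMI) & data$HEMI == "diseased" &
    data$ID %in% nonresponders
  data_fit <- data[!drop, ]
  bundle$data <- data_fit

  stage <- "parent_fit"
  bundle$parent_fit <- run(stage, fit_popmodel(
    data_fit, parent_model_spec(), reference_parameters("parent"),
    control = ctl))

  if ("grid" %in% stages) {
    stage <- "grid"
    bundle$grid <- run(stage, symmetry_grid(
      data_fit, reference_parameters("parent"),
      control = modifyList(ctl, list(se = ctl$se %||% FALSE))))
  }

  if ("metabolites" %in% stages) {
    stage <- "metabolites"
    mets <- list()
    for (met in c("DOPAC", "HVA")) for (hemi in c("control", "diseased")) {
      key <- paste(tolower(met), hemi, sep = "_")
      dv <- if (met == "DOPAC") "dial_DOPAC" else "dial_HVA"
      has <- any(!is.na(data_fit$DVID) & data_fit$DVID == dv &
                   data_fit$HEMI %in% hemi)
      if (!has) next
      mets[[key]] <- run(stage, sequential_metabolite_fit(
        data_fit, bundle$parent_fit, met, hemi, control = ctl))
    }
    bundle$metabolite_fits <- mets
  }

  if ("baseline" %in% stages) {
    stage <- "baseline"
    bundle$baseline <- run(stage, baseline_summary(data_fit))
  }

  stage <- "report"
  bundle$tables <- list(
    parameter_table = format_parameter_table(
      c(list(`L-DOPA` = bundle$parent_fit), bundle$metabolite_fits)),
    grid_table = if (!is.null(bundle$grid)) format_grid_table(bundle$grid))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_ldopa_dataset(bundle$data,
                        file.path(config$output_dir, "dataset_corrected.csv"))
    writeLines(bundle$tables$parameter_table,
               file.path(config$output_dir, "parameter_table.txt"))
    if (!is.null(bundle$tables$grid_table))
      writeLines(bundle$tables$grid_table,
                 file.path(config$output_dir, "grid_table.txt"))
    if (!is.null(bundle$baseline))
      write.csv(bundle$baseline,
                file.path(config$output_dir, "baseline_summary.csv"),
                row.names = FALSE)
    res <- tryCatch(fit_residuals(bundle$parent_fit, bundle$data),
                    error = function(e) NULL)
    if (!is.null(res))
      write.csv(res, file.path(config$output_dir, "residuals_parent.csv"),
                row.names = FALSE)
    fits <- c(list(parent = bundle$parent_fit), bundle$metabolite_fits)
    jsonlite::write_json(
      lapply(fits, function(f)
        list(model = f$spec$name, mvof = f$mvof, table = f$table)),
      file.path(config$output_dir, "fits.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  bundle
}

#' Text report of population estimates (estimate | CV% | CI)
#'
#' @param fits Named list of `ldopa_fit`s (names become section headers).
#' @return Character vector of report lines.
#' @export
format_parameter_table <- function(fits) {
  lines <- c(sprintf("%-28s %12s %8s  %s", "Parameter", "Estimate", "CV%",
                     "LLCI - ULCI"))
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (!inherits(f, "ldopa_fit")) next
    lines <- c(lines, "", nm)
    tb <- f$table
    for (i in seq_len(nrow(tb))) {
      ci <- if (is.na(tb$se[i])) "-" else
        sprintf("%.3g - %.3g", tb$lci[i], tb$uci[i])
      lines <- c(lines, sprintf("%-28s %12.4g %8s  %s", tb$parameter[i],
                                tb$estimate[i],
                                if (is.na(tb$cv_pct[i])) "-" else
                                  sprintf("%.0f", tb$cv_pct[i]), ci))
    }
  }
  lines
}

#' Text report of the symmetry grid (assumption | MVOF | estimates)
#'
#' @param grid An `ldopa_grid`.
#' @return Character vector of report lines.
#' @export
format_grid_table <- function(grid) {
  tb <- grid$table
  fmt <- function(x, d = 3) ifelse(is.na(x), "-", signif(x, d))
  lines <- sprintf("%-28s %10s %8s %8s %7s %7s %7s %7s",
                   "Assumption", "MVOF", "V4", "V5", "Q4", "Q5", "k40", "k50")
  for (i in seq_len(nrow(tb)))
    lines <- c(lines, sprintf("%-28s %10.1f %8s %8s %7s %7s %7s %7s",
                              tb$assumption[i], tb$mvof[i], fmt(tb$V4[i]),
                              fmt(tb$V5[i]), fmt(tb$Q4[i]), fmt(tb$Q5[i]),
                              fmt(tb$k40[i]), fmt(tb$k50[i])))
  c(lines, "", paste("selected:", grid$selected_assumption))
}
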