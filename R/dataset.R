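# Long-format (NONMEM-style) dataset: construction, validation and CSV I/O
# with a JSON units sidecar.

dataset_columns <- function() {
  c("ID", "TIME", "WSTART", "WEND", "DVID", "HEMI", "DV", "AMT", "RATE",
    "DUR", "MDV", "LLOQ", "BLQ", "TRUNC", "PERF", "GROUP", "WT")
}

dataset_units <- function() {
  list(TIME = "min", WSTART = "min", WEND = "min",
       DV = list(plasma_LDOPA = "ng/mL", ecf_LDOPA = "ng/mL",
                 dial_DOPAC = "ng/mL", dial_HVA = "ng/mL",
                 retro_LDOPA = "ng/mL", TH = "percent"),
       AMT = "ng", RATE = "ng/min", DUR = "min", LLOQ = "ng/mL",
       PERF = "ng/mL", GROUP = "mg/kg", WT = "kg")
}

#' Validate and class a long-format dataset
#'
#' Checks the dataset invariants: dose rows carry `AMT > 0` and no `DV`;
#' observation rows carry either a point `TIME` or a `WSTART`/`WEND` interval
#' (never both); known `DVID` levels; ECF/dialysate rows carry a hemisphere;
#' per-subject observation times are non-decreasing within each stream. Times
#' are minutes from infusion start (pre-dose times negative).
#'
#' @param data A data frame with the long-dataset columns (missing optional
#'   columns are added as `NA`).
#' @return The validated data frame with class `ldopa_dataset`.
#' @export
as_ldopa_dataset <- function(data) {
  for (cl in dataset_columns())
    if (!cl %in% names(data))
      data[[cl]] <- if (cl %in% c("MDV", "BLQ", "TRUNC")) 0L else NA
  data <- data[, dataset_columns()]
  is_dose <- !is.na(data$AMT)
  probs <- character()
  rown <- seq_len(nrow(data))
  bad <- which(is_dose & data$AMT <= 0)
  if (length(bad)) probs <- c(probs, paste0("dose rows with AMT <= 0: rows ",
                                            paste(bad, collapse = ",")))
  bad <- which(is_dose & !is.na(data$DV))
  if (length(bad)) probs <- c(probs, paste0("dose rows must not carry DV: rows ",
                                            paste(bad, collapse = ",")))
  obs <- !is_dose
  bad <- which(obs & !(data$DVID %in% dvid_levels()))
  if (length(bad)) probs <- c(probs, paste0("unknown DVID: rows ",
                                            paste(bad, collapse = ",")))
  has_pt <- !is.na(data$TIME)
  has_win <- !is.na(data$WSTART) & !is.na(data$WEND)
  bad <- which(obs & data$DVID != "TH" & (has_pt == has_win))
  if (length(bad))
    probs <- c(probs, paste0("observation rows need exactly one of point TIME ",
                             "or WSTART/WEND interval: rows ",
                             paste(bad, collapse = ",")))
  bad <- which(has_win & data$WEND <= data$WSTART)
  if (length(bad)) probs <- c(probs, paste0("WEND must exceed WSTART: rows ",
                                            paste(bad, collapse = ",")))
  bad <- which(obs & data$DVID %in% c("ecf_LDOPA", "dial_DOPAC", "dial_HVA") &
                 is.na(data$HEMI))
  if (length(bad)) probs <- c(probs, paste0("ECF/dialysate rows need HEMI: rows ",
                                            paste(bad, collapse = ",")))
  bad <- which(obs & data$BLQ == 1 & is.na(data$LLOQ) & data$DVID == "plasma_LDOPA")
  if (length(bad)) probs <- c(probs, paste0("below-LOQ rows must carry LLOQ: rows ",
                                            paste(bad, collapse = ",")))
  # monotone times per subject and stream
  for (id in unique(data$ID)) {
    for (dv in unique(data$DVID[obs & data$ID == id])) {
      if (is.na(dv)) next
      sel <- which(data$ID == id & data$DVID == dv & obs)
      tt <- ifelse(has_pt[sel], data$TIME[sel], data$WSTART[sel])
      if (any(diff(tt[!is.na(tt)]) < 0))
        probs <- c(probs, paste0("non-monotone times for subject ", id,
                                 ", stream ", dv, ": rows ",
                                 paste(sel, collapse = ",")))
    }
  }
  if (length(probs)) stop("invalid dataset:\n  ", paste(probs, collapse = "\n  "))
  rownames(data) <- NULL
  class(data) <- c("ldopa_dataset", "data.frame")
  data
}

#' Read / write a long dataset as CSV with a units sidecar
#'
#' `write_ldopa_dataset()` writes `<path>` (CSV) and `<path>.units.json`;
#' `read_ldopa_dataset()` requires the sidecar (or a `units` argument) and
#' validates the result, so a write/read round trip is the identity.
#'
#' @param data An `ldopa_dataset` (or coercible data frame).
#' @param path CSV file path.
#' @param units Optional units list overriding the sidecar.
#' @return `read_ldopa_dataset()` returns the validated `ldopa_dataset` with a
#'   `units` attribute; `write_ldopa_dataset()` returns `path` invisibly.
#' @export
write_ldopa_dataset <- function(data, path) {
  data <- as_ldopa_dataset(as.data.frame(data))
  write.csv(data, path, row.names = FALSE, na = "")
  jsonlite::write_json(dataset_units(), paste0(path, ".units.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ldopa_dataset
#' @export
read_ldopa_dataset <- function(path, units = NULL) {
  sidecar <- paste0(path, ".units.json")
  if (is.null(units)) {
    if (!file.exists(sidecar))
      stop("units are required: provide '", sidecar, "' or the units argument")
    units <- jsonlite::read_json(sidecar)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(ID = "character"))
  raw$DVID[raw$DVID == ""] <- NA
  if ("HEMI" %in% names(raw)) raw$HEMI[raw$HEMI == ""] <- NA
  out <- as_ldopa_dataset(raw)
  attr(out, "units") <- units
  out
}
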