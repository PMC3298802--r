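# Tyrosine-hydroxylase staining quantification and responder classification.

#' Construct a staining measurement record
#'
#' Mean grey values (MGV) measured on a stained striatal section: slide
#' background, cortex (control tissue staining), corpus callosum (control
#' non-cellular staining), dorsal striatum (CPu) and ventral striatum (NAcc).
#'
#' @param slide,cortex,corpus_callosum,cpu,nacc Non-negative MGVs.
#' @return A `stain_measurement`.
#' @export
stain_measurement <- function(slide = NA_real_, cortex, corpus_callosum = NA_real_,
                              cpu, nacc = NA_real_) {
  v <- c(slide = slide, cortex = cortex, corpus_callosum = corpus_callosum,
         cpu = cpu, nacc = nacc)
  if (any(v < 0, na.rm = TRUE)) stop("MGVs must be >= 0")
  structure(as.list(v), class = "stain_measurement")
}

#' Background-corrected striatal MGV
#'
#' Subtracts the non-specific staining reference (cortex by default, corpus
#' callosum selectable) from the striatal region's MGV.
#'
#' @param m A `stain_measurement` (or list with the same fields).
#' @param region `"cpu"` (dorsal striatum, default) or `"nacc"`.
#' @param reference `"cortex"` (default) or `"corpus_callosum"`.
#' @return Corrected MGV.
#' @export
corrected_mgv <- function(m, region = c("cpu", "nacc"),
                          reference = c("cortex", "corpus_callosum")) {
  region <- match.arg(region)
  reference <- match.arg(reference)
  if (is.null(m[[region]]) || is.na(m[[region]]))
    stop("missing striatal MGV for region: ", region)
  if (is.null(m[[reference]]) || is.na(m[[reference]]))
    stop("missing reference MGV: ", reference)
  m[[region]] - m[[reference]]
}

#' Percentage of intact TH staining
#'
#' TH% of the rotenone-treated hemisphere relative to the untreated
#' hemisphere: `100 * corrected treated MGV / corrected untreated MGV`,
#' computed on the dorsal striatum (CPu) by default. Scale-invariant:
#' multiplying all MGVs by a constant leaves TH% unchanged.
#'
#' @param treated,untreated `stain_measurement`s for the two hemispheres.
#' @param region,reference Passed to [corrected_mgv()].
#' @return TH% (percent).
#' @export
percent_intact <- function(treated, untreated, region = "cpu",
                           reference = "cortex") {
  den <- corrected_mgv(untreated, region, reference)
  if (!is.finite(den) || den <= 0)
    stop("untreated corrected MGV must be > 0")
  100 * corrected_mgv(treated, region, reference) / den
}

#' Classify a rotenone responder from TH%
#'
#' Responder iff TH% is strictly below 40 (at least 60% of dopaminergic
#' terminals lost); exactly 40 is a non-responder. Values outside the [0, 200]
#' sanity range warn but are still classified.
#'
#' @param th_percent TH% value(s).
#' @return Logical responder flag(s).
#' @export
classify_responder <- function(th_percent) {
  out <- th_percent < 40
  bad <- !is.na(th_percent) & (th_percent < 0 | th_percent > 200)
  if (any(bad))
    warning("TH% outside the [0, 200] sanity range: ",
            paste(signif(th_percent[bad], 3), collapse = ", "))
  out
}

#' Simulate paired TH staining measurements for a subject
#'
#' Generates hemisphere MGV measurements consistent with a subject's true TH%:
#' the untreated corrected striatal MGV is drawn around a typical staining
#' level and the treated hemisphere scaled to the target TH%, with a shared
#' cortical background, so that [percent_intact()] recovers the TH% exactly.
#'
#' @param th_percent True TH% for the treated hemisphere.
#' @param cortex Cortical (background) MGV.
#' @param untreated_corrected Corrected striatal MGV of the untreated side.
#' @return List with `treated` and `untreated` `stain_measurement`s.
#' @export
simulate_th_measurements <- function(th_percent, cortex = 10,
                                     untreated_corrected = 50) {
  untreated <- stain_measurement(cortex = cortex,
                                 cpu = cortex + untreated_corrected,
                                 nacc = cortex + untreated_corrected)
  treated <- stain_measurement(cortex = cortex,
                               cpu = cortex + untreated_corrected * th_percent / 100,
                               nacc = cortex + untreated_corrected * th_percent / 100)
  list(treated = treated, untreated = untreated)
}

#' TH% and responder table from a long dataset
#'
#' Extracts the TH rows of a dataset and returns TH% with responder flags per
#' subject.
#'
#' @param data An `ldopa_dataset` containing `DVID == "TH"` rows.
#' @return Data frame with `ID`, `th_pct`, `responder`.
#' @export
th_table <- function(data) {
  data <- as.data.frame(data)
  th <- data[!is.na(data$DVID) & data$DVID == "TH", ]
  if (!nrow(th)) stop("no TH rows in the dataset")
  data.frame(ID = th$ID, th_pct = th$DV,
             responder = classify_responder(th$DV),
             stringsAsFactors = FALSE)
}
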