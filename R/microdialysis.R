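# Microdialysis probe-recovery estimation/correction and baseline summary
# statistics on dialysate data.

#' Estimate in vivo probe recovery by retrodialysis
#'
#' Per-fraction relative loss is `(C_in - C_out) / C_in`; the estimate is the
#' mean and (unbiased) SD across fractions. Fractions with `C_out > C_in`
#' (apparent gain) are flagged and excluded with a warning.
#'
#' @param fractions Numeric vector of dialysate-out concentrations, or a data
#'   frame with a `c_out` (or `DV`) column.
#' @param perfusate_conc Perfusate concentration (> 0).
#' @return List with `mean`, `sd`, `n`, `losses`, `excluded`.
#' @export
estimate_recovery <- function(fractions, perfusate_conc) {
  if (!is.finite(perfusate_conc) || perfusate_conc <= 0)
    stop("perfusate_conc must be > 0")
  if (is.data.frame(fractions))
    fractions <- if ("c_out" %in% names(fractions)) fractions$c_out
                 else fractions$DV
  if (length(fractions) < 1) stop("at least one fraction is required")
  loss <- (perfusate_conc - fractions) / perfusate_conc
  gain <- loss < 0
  if (any(gain)) {
    warning(sum(gain), " fraction(s) with C_out > C_in (gain instead of loss) ",
            "excluded")
    loss <- loss[!gain]
  }
  if (!length(loss)) stop("no usable fractions after excluding gains")
  list(mean = mean(loss), sd = if (length(loss) > 1) sd(loss) else NA_real_,
       n = length(loss), losses = loss, excluded = sum(gain))
}

#' Correct dialysate concentrations to brain-ECF scale
#'
#' Divides measured dialysate concentrations by the probe recovery (relative
#' loss) to estimate brain extracellular fluid concentrations; the inverse of
#' the generator's forward recovery multiplication.
#'
#' @param obs Numeric vector, or a data frame with a `DV` column (only
#'   `ecf_LDOPA`/`retro_LDOPA`-free observation rows are touched when a `DVID`
#'   column is present: L-DOPA dialysate rows, `DVID == "ecf_LDOPA"`).
#' @param recovery Recovery in (0, 1].
#' @return Corrected vector, or the data frame with corrected `DV` and a
#'   `RECOVERY_CORRECTED` flag column.
#' @export
correct_to_ecf <- function(obs, recovery) {
  if (!is.finite(recovery) || recovery <= 0)
    stop("recovery must be > 0")
  if (recovery > 1) stop("recovery must be <= 1")
  if (is.data.frame(obs)) {
    sel <- if ("DVID" %in% names(obs)) which(obs$DVID %in% "ecf_LDOPA")
           else seq_len(nrow(obs))
    obs$DV[sel] <- obs$DV[sel] / recovery
    obs$RECOVERY_CORRECTED <- 0L
    obs$RECOVERY_CORRECTED[sel] <- 1L
    obs
  } else {
    obs / recovery
  }
}

welch_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  if (nx < 2 || ny < 2) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  if (vx + vy <= 0) {
    # degenerate: both groups constant
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else Inf, df = nx + ny - 2,
                p = if (eq) 1 else 0))
  }
  se2 <- vx / nx + vy / ny
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Baseline dialysate summary with Welch comparison between hemispheres
#'
#' Each subject's baseline is the mean of its pre-dose fractions (windows
#' ending at or before the infusion start); groups are formed by analyte and
#' hemisphere, summarised as mean +/- SEM across subjects, and the two
#' hemispheres are compared per analyte with Welch's unequal-variance t-test
#' (Welch-Satterthwaite degrees of freedom). Groups with a single subject are
#' summarised only, with the test omitted.
#'
#' @param data Data frame of dialysate rows (`ID`, `WSTART`, `WEND`, `DVID`,
#'   `HEMI`, `DV`); rows with `WEND > 0` (post-dose) are ignored.
#' @return Data frame with columns `analyte`, `hemisphere`, `n`, `mean`,
#'   `sem`, and for each analyte the Welch `welch_t`, `df`, `p` (on the first
#'   hemisphere row).
#' @export
baseline_summary <- function(data) {
  data <- as.data.frame(data)
  base <- data[!is.na(data$WEND) & data$WEND <= 0 &
                 data$DVID %in% c("ecf_LDOPA", "dial_DOPAC", "dial_HVA") &
                 !is.na(data$DV), ]
  if (!nrow(base)) stop("no pre-dose dialysate fractions found")
  key <- interaction(base$DVID, base$HEMI, base$ID, drop = TRUE)
  subj <- do.call(rbind, lapply(split(base, key), function(d)
    data.frame(analyte = d$DVID[1], hemisphere = d$HEMI[1], ID = d$ID[1],
               baseline = mean(d$DV), stringsAsFactors = FALSE)))
  out <- list()
  for (an in unique(subj$analyte)) {
    sa <- subj[subj$analyte == an, ]
    hems <- unique(sa$hemisphere)
    gr <- lapply(hems, function(h) sa$baseline[sa$hemisphere == h])
    names(gr) <- hems
    w <- if (length(hems) == 2 && all(lengths(gr) >= 2))
      welch_test(gr[[1]], gr[[2]])
    else {
      if (length(hems) == 2)
        message("group with < 2 subjects for ", an, "; Welch test omitted")
      list(t = NA_real_, df = NA_real_, p = NA_real_)
    }
    for (j in seq_along(hems)) {
      g <- gr[[j]]
      out[[length(out) + 1]] <- data.frame(
        analyte = an, hemisphere = hems[j], n = length(g), mean = mean(g),
        sem = if (length(g) > 1) sd(g) / sqrt(length(g)) else NA_real_,
        welch_t = if (j == 1) w$t else NA_real_,
        df = if (j == 1) w$df else NA_real_,
        p = if (j == 1) w$p else NA_real_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
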