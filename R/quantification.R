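#' Clinical record for one sample
#'
#' @param sample_id Character identifier, unique per timepoint.
#' @param group `"CML"` or `"control"`.
#' @param phase Disease phase: `"chronic"`, `"blast-crisis"` or
#'   `"not-applicable"` (controls).
#' @param sokal Sokal risk: `"low"`, `"intermediate"`, `"high"` or
#'   `"not-applicable"`.
#' @param timepoint `"diagnosis"` or `"followup-6mo"`.
#' @param wbc_per_ul White-cell count in cells/uL; must be positive for any
#'   sample used in absolute quantification.
#' @param subject_id Patient identifier linking diagnosis and follow-up
#'   samples; defaults to `sample_id`.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(sample_id,
                          group = c("CML", "control"),
                          phase = c("chronic", "blast-crisis",
                                    "not-applicable"),
                          sokal = c("low", "intermediate", "high",
                                    "not-applicable"),
                          timepoint = c("diagnosis", "followup-6mo"),
                          wbc_per_ul,
                          subject_id = sample_id) {
  group <- match.arg(group)
  phase <- match.arg(phase)
  sokal <- match.arg(sokal)
  timepoint <- match.arg(timepoint)
  if (!is.numeric(wbc_per_ul) || length(wbc_per_ul) != 1L ||
      !is.finite(wbc_per_ul) || wbc_per_ul <= 0) {
    stop_cd26("wbc_per_ul must be a single positive number",
              class = "cd26_parameter_error")
  }
  structure(
    list(sample_id = as.character(sample_id), group = group, phase = phase,
         sokal = sokal, timepoint = timepoint, wbc_per_ul = wbc_per_ul,
         subject_id = as.character(subject_id)),
    class = "sample_record"
  )
}

#' @export
as.data.frame.sample_record <- function(x, ...) {
  data.frame(sample_id = x$sample_id, subject_id = x$subject_id,
             group = x$group, phase = x$phase, sokal = x$sokal,
             timepoint = x$timepoint, wbc_per_ul = x$wbc_per_ul,
             stringsAsFactors = FALSE)
}

#' Percentage of a nested count
#'
#' `100 * numerator / denominator`, with two safety contracts: a numerator
#' exceeding its denominator violates gate nesting and is an error, and a
#' zero denominator yields `NA` carrying a `cd26_flag` attribute -- a failed
#' gate must never fabricate a negative finding as 0%.
#'
#' @param numerator_count,denominator_count Nonnegative event counts.
#' @return Percentage, or flagged `NA` when the denominator is zero.
#' @export
pct_of <- function(numerator_count, denominator_count) {
  if (numerator_count < 0 || denominator_count < 0) {
    stop_cd26("counts must be nonnegative", class = "cd26_parameter_error")
  }
  if (denominator_count == 0) {
    return(structure(NA_real_, cd26_flag = "undefined_zero_denominator"))
  }
  if (numerator_count > denominator_count) {
    stop_cd26("numerator exceeds denominator: nesting violated",
              class = "cd26_consistency_error")
  }
  100 * numerator_count / denominator_count
}

#' Absolute CD26+ LSC concentration
#'
#' The headline absolute count: white-cell concentration multiplied by the
#' CD26+ LSC percentage of CD45+ events, i.e.
#' `wbc_per_ul * pct_cd26_of_cd45 / 100`, in cells/uL.
#'
#' @param wbc_per_ul White-cell count per uL (positive).
#' @param pct_cd26_of_cd45 CD26+ LSC percentage of CD45+ events in
#'   \[0, 100\]; `NA` propagates.
#' @return Cells per uL.
#' @export
absolute_cd26_count <- function(wbc_per_ul, pct_cd26_of_cd45) {
  if (!is.numeric(wbc_per_ul) || any(wbc_per_ul <= 0)) {
    stop_cd26("wbc_per_ul must be positive", class = "cd26_parameter_error")
  }
  p <- as.numeric(pct_cd26_of_cd45)
  if (any(!is.na(p) & (p < 0 | p > 100))) {
    stop_cd26("pct_cd26_of_cd45 must lie in [0, 100]",
              class = "cd26_parameter_error")
  }
  wbc_per_ul * p / 100
}

#' Quantify CD26+ LSC burden for one sample
#'
#' Assembles the three headline quantities from a gating report and the
#' clinical record: the CD26+ LSC percentage of CD45+ events, the CD26+
#' share of the CD34+/CD38- compartment, and the absolute CD26+ LSC
#' concentration. Reports whose CD26 calibration failed carry undefined
#' (`NA`) quantities with a flag.
#'
#' @param report A `gating_report` from [run_gating_pipeline()].
#' @param record A [sample_record()]; its `sample_id` must match the
#'   report's.
#' @return An object of class `lsc_quant` with fields `pct_cd26_of_cd45`,
#'   `pct_cd26_of_lsc`, `abs_cd26_per_ul`, and `flags`.
#' @export
quantify <- function(report, record) {
  stopifnot(inherits(report, "gating_report"))
  stopifnot(inherits(record, "sample_record"))
  if (!identical(report$sample_id, record$sample_id)) {
    stop_cd26(sprintf("sample_id mismatch: report '%s' vs record '%s'",
                      report$sample_id, record$sample_id),
              class = "cd26_pairing_error")
  }
  flags <- report$flags
  if (!report$cd26_available) {
    return(structure(
      list(sample_id = record$sample_id,
           pct_cd26_of_cd45 = NA_real_, pct_cd26_of_lsc = NA_real_,
           abs_cd26_per_ul = NA_real_,
           flags = unique(c(flags, "cd26_unavailable"))),
      class = "lsc_quant"))
  }
  n_cd45 <- report$counts[["CD45pos"]]
  n_lsc <- report$counts[["LSC"]]
  n_pos <- report$counts[["LSC_CD26pos"]]
  p45 <- pct_of(n_pos, n_cd45)
  plsc <- pct_of(n_pos, n_lsc)
  for (v in list(p45, plsc)) {
    fl <- attr(v, "cd26_flag")
    if (!is.null(fl)) flags <- c(flags, fl)
  }
  abs_count <- if (is.na(p45)) NA_real_
               else absolute_cd26_count(record$wbc_per_ul, as.numeric(p45))
  structure(
    list(sample_id = record$sample_id,
         pct_cd26_of_cd45 = as.numeric(p45),
         pct_cd26_of_lsc = as.numeric(plsc),
         abs_cd26_per_ul = abs_count,
         flags = unique(flags)),
    class = "lsc_quant"
  )
}

#' @export
print.lsc_quant <- function(x, ...) {
  cat(sprintf("LSC quantification for '%s'\n", x$sample_id))
  cat(sprintf("  %%CD26 of CD45+ events     : %s\n",
              format(signif(x$pct_cd26_of_cd45, 3))))
  cat(sprintf("  %%CD26 of CD34+CD38- (LSC) : %s\n",
              format(signif(x$pct_cd26_of_lsc, 3))))
  cat(sprintf("  absolute CD26+ LSC (/uL)  : %s\n",
              format(signif(x$abs_cd26_per_ul, 4))))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.lsc_quant <- function(x, ...) {
  data.frame(sample_id = x$sample_id,
             pct_cd26_of_cd45 = x$pct_cd26_of_cd45,
             pct_cd26_of_lsc = x$pct_cd26_of_lsc,
             abs_cd26_per_ul = x$abs_cd26_per_ul,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
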