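WBC_STRATUM_BOUNDARY <- 150e3  # cells/uL; "low" stratum is <= boundary

normalize_manifest <- function(manifest) {
  if (is.data.frame(manifest)) {
    need <- c("path", "sample_id", "group", "phase", "sokal", "timepoint",
              "wbc_per_ul")
    miss <- setdiff(need, names(manifest))
    if (length(miss)) {
      stop_cd26(paste0("manifest missing columns: ",
                       paste(miss, collapse = ", ")),
                class = "cd26_parameter_error")
    }
    if (is.null(manifest$subject_id)) manifest$subject_id <- manifest$sample_id
    return(lapply(seq_len(nrow(manifest)), function(i) {
      list(source = manifest$path[i],
           record = sample_record(
             sample_id = manifest$sample_id[i], group = manifest$group[i],
             phase = manifest$phase[i], sokal = manifest$sokal[i],
             timepoint = manifest$timepoint[i],
             wbc_per_ul = manifest$wbc_per_ul[i],
             subject_id = manifest$subject_id[i]))
    }))
  }
  if (is.list(manifest)) {
    return(lapply(manifest, function(s) {
      if (is.null(s$record) || !inherits(s$record, "sample_record")) {
        stop_cd26("each cohort entry needs a sample_record",
                  class = "cd26_parameter_error")
      }
      list(source = if (!is.null(s$em)) s$em else s$path, record = s$record)
    }))
  }
  stop_cd26("manifest must be a data frame or a list of samples",
            class = "cd26_parameter_error")
}

#' Gate and quantify a cohort
#'
#' Runs [run_gating_pipeline()] and [quantify()] on every sample of a
#' manifest. A per-sample failure (unreadable file, failed gate stage) is
#' recorded in that sample's row without aborting the cohort. Rows are
#' ordered deterministically by sample id.
#'
#' @param manifest Either a data frame with columns `path`, `sample_id`,
#'   `group`, `phase`, `sokal`, `timepoint`, `wbc_per_ul` (optionally
#'   `subject_id`), or a list of samples as produced by
#'   [simulate_cohort()] (each with `em` or `path`, plus `record`).
#' @param panel Optional [panel_config()].
#' @param gcfg A [gating_config()].
#' @param tcfg A [transform_config()].
#' @return A `cohort_table`: data frame with the clinical record, the WBC
#'   stratum (`<=150e3` vs `>150e3` cells/uL), gate counts, the three
#'   headline quantities, `cd26_available`, `failed` and `flags` columns.
#' @export
build_cohort <- function(manifest, panel = NULL, gcfg = gating_config(),
                         tcfg = transform_config()) {
  entries <- normalize_manifest(manifest)
  if (!length(entries)) {
    stop_cd26("manifest is empty", class = "cd26_parameter_error")
  }
  rows <- lapply(entries, function(e) {
    rec <- e$record
    base <- as.data.frame(rec)
    base$wbc_stratum <- if (rec$wbc_per_ul <= WBC_STRATUM_BOUNDARY) {
      "wbc_le_150k"
    } else "wbc_gt_150k"
    res <- tryCatch({
      em <- if (inherits(e$source, "event_matrix")) e$source
            else read_fcs(e$source)
      em$sample_id <- rec$sample_id
      rep <- run_gating_pipeline(em, panel = panel, cfg = gcfg, tcfg = tcfg)
      q <- quantify(rep, rec)
      data.frame(
        n_cd45 = rep$counts[["CD45pos"]], n_lsc = rep$counts[["LSC"]],
        n_cd26pos = if (rep$cd26_available) {
          rep$counts[["LSC_CD26pos"]]
        } else NA_real_,
        pct_cd26_of_cd45 = q$pct_cd26_of_cd45,
        pct_cd26_of_lsc = q$pct_cd26_of_lsc,
        abs_cd26_per_ul = q$abs_cd26_per_ul,
        cd26_available = rep$cd26_available, failed = FALSE,
        flags = paste(q$flags, collapse = ";"), stringsAsFactors = FALSE)
    }, error = function(err) {
      data.frame(n_cd45 = NA_real_, n_lsc = NA_real_, n_cd26pos = NA_real_,
                 pct_cd26_of_cd45 = NA_real_, pct_cd26_of_lsc = NA_real_,
                 abs_cd26_per_ul = NA_real_, cd26_available = FALSE,
                 failed = TRUE, flags = paste0("failed:", conditionMessage(err)),
                 stringsAsFactors = FALSE)
    })
    cbind(base, res)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$sample_id), , drop = FALSE]
  rownames(tab) <- NULL
  if (all(tab$failed)) {
    stop_cd26("no sample processed successfully",
              class = "cd26_cohort_error")
  }
  dup <- duplicated(tab[, c("sample_id", "timepoint")])
  if (any(dup)) {
    stop_cd26("sample_ids must be unique per timepoint",
              class = "cd26_parameter_error")
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

summary_block <- function(tab, what) {
  x <- tab[[what]]
  x <- x[!is.na(x)]
  if (!length(x)) return(list(n = 0L, flag = "not_computable"))
  summarize_values(x)
}

not_computable <- function(reason) {
  list(flag = "not_computable", reason = reason)
}

#' Detection summary
#'
#' Counts, separately for CML diagnosis samples and for controls, how many
#' evaluable samples carry at least one CD26+ LSC event. Samples whose
#' CD26 calibration failed are not evaluable and are reported in their own
#' column rather than counted as negative.
#'
#' @param table A `cohort_table`.
#' @return List with per-group totals, positives and not-evaluable counts.
#' @export
detection_summary <- function(table) {
  stopifnot(is.data.frame(table))
  cml <- table[table$group == "CML" & table$timepoint == "diagnosis", ]
  ctl <- table[table$group == "control", ]
  count_block <- function(df) {
    evaluable <- df[!df$failed & df$cd26_available, ]
    list(n = nrow(df),
         n_evaluable = nrow(evaluable),
         n_positive = sum(evaluable$n_cd26pos >= 1, na.rm = TRUE),
         n_not_evaluable = nrow(df) - nrow(evaluable))
  }
  list(cml_diagnosis = count_block(cml), control = count_block(ctl))
}

#' Cohort-level analysis
#'
#' Runs the standard clinical analysis layout on a cohort table: median/range
#' summary blocks for the three headline quantities at diagnosis and
#' follow-up; the Kruskal-Wallis comparison of absolute counts across
#' Sokal risk groups; Mann-Whitney comparisons of absolute counts and of
#' percentages between WBC strata (boundary 150 x10^3/uL, inclusive on the
#' low side); Spearman correlation of the absolute count with WBC; paired
#' Wilcoxon signed-rank tests (diagnosis vs six-month follow-up) on both
#' the absolute count and the percentage, restricted to chronic-phase
#' patients with complete pairs; and the detection summary. A comparison
#' whose stratum is empty is emitted as not-computable, never as a
#' fabricated statistic (a cohort without CML diagnosis rows yields a
#' report whose CML blocks are all flagged). Samples with failed CD26
#' calibration are excluded from CD26 statistics.
#'
#' @param table A `cohort_table`.
#' @return An object of class `analysis_report`.
#' @export
analyze_cohort <- function(table) {
  stopifnot(is.data.frame(table))
  ok <- !table$failed & table$cd26_available
  dx <- table[table$group == "CML" & table$timepoint == "diagnosis" & ok, ]
  fu <- table[table$group == "CML" & table$timepoint == "followup-6mo" & ok, ]

  summaries <- list(
    diagnosis = list(
      pct_cd26_of_cd45 = summary_block(dx, "pct_cd26_of_cd45"),
      pct_cd26_of_lsc = summary_block(dx, "pct_cd26_of_lsc"),
      abs_cd26_per_ul = summary_block(dx, "abs_cd26_per_ul")),
    followup = list(
      pct_cd26_of_cd45 = summary_block(fu, "pct_cd26_of_cd45"),
      abs_cd26_per_ul = summary_block(fu, "abs_cd26_per_ul"))
  )

  # Sokal comparison (Kruskal-Wallis on diagnosis absolute counts)
  sk <- dx[dx$sokal %in% c("low", "intermediate", "high"), ]
  sokal_groups <- split(sk$abs_cd26_per_ul, factor(sk$sokal,
                        levels = c("low", "intermediate", "high")))
  sokal_groups <- sokal_groups[lengths(sokal_groups) > 0]
  sokal_test <- if (length(sokal_groups) >= 2) {
    kruskal_wallis(sokal_groups)
  } else not_computable("fewer than 2 nonempty Sokal groups")

  # WBC stratum comparisons (diagnosis)
  lo <- dx[dx$wbc_stratum == "wbc_le_150k", ]
  hi <- dx[dx$wbc_stratum == "wbc_gt_150k", ]
  wbc_tests <- if (nrow(lo) && nrow(hi)) {
    list(abs = mann_whitney(hi$abs_cd26_per_ul, lo$abs_cd26_per_ul),
         pct = mann_whitney(hi$pct_cd26_of_cd45, lo$pct_cd26_of_cd45))
  } else {
    list(abs = not_computable("empty WBC stratum"),
         pct = not_computable("empty WBC stratum"))
  }

  # WBC correlation (diagnosis)
  wbc_spearman <- if (nrow(dx) >= 3) {
    spearman(dx$abs_cd26_per_ul, dx$wbc_per_ul)
  } else not_computable("fewer than 3 diagnosis samples")

  # Paired diagnosis vs follow-up (chronic phase, complete pairs only)
  dxp <- dx[dx$phase == "chronic", ]
  fup <- fu[fu$phase == "chronic", ]
  common <- intersect(dxp$subject_id, fup$subject_id)
  paired_tests <- if (length(common) >= 1) {
    di <- dxp[match(common, dxp$subject_id), ]
    fi <- fup[match(common, fup$subject_id), ]
    list(abs = wilcoxon_signed_rank(di$abs_cd26_per_ul, fi$abs_cd26_per_ul),
         pct = wilcoxon_signed_rank(di$pct_cd26_of_cd45,
                                    fi$pct_cd26_of_cd45),
         n_pairs = length(common))
  } else {
    list(abs = not_computable("no complete chronic-phase pairs"),
         pct = not_computable("no complete chronic-phase pairs"),
         n_pairs = 0L)
  }

  structure(
    list(summaries = summaries,
         sokal_kruskal_wallis = sokal_test,
         wbc_stratum_mann_whitney = wbc_tests,
         wbc_spearman = wbc_spearman,
         paired_wilcoxon = paired_tests,
         detection = detection_summary(table),
         n_rows = nrow(table),
         n_excluded_not_evaluable = sum(!ok)),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  fmt_block <- function(b, label) {
    if (!is.null(b$flag)) {
      cat(sprintf("  %-28s not computable\n", label))
    } else {
      cat(sprintf("  %-28s median %.4g (range %.4g-%.4g, n=%d)\n",
                  label, b$median, b$min, b$max, b$n))
    }
  }
  cat("Cohort analysis report\n")
  cat(" Diagnosis summaries:\n")
  fmt_block(x$summaries$diagnosis$pct_cd26_of_cd45, "%CD26 of CD45+")
  fmt_block(x$summaries$diagnosis$pct_cd26_of_lsc, "%CD26 of CD34+CD38-")
  fmt_block(x$summaries$diagnosis$abs_cd26_per_ul, "absolute CD26+ LSC /uL")
  cat(" Follow-up summaries:\n")
  fmt_block(x$summaries$followup$pct_cd26_of_cd45, "%CD26 of CD45+")
  fmt_block(x$summaries$followup$abs_cd26_per_ul, "absolute CD26+ LSC /uL")
  show <- function(t, label) {
    if (inherits(t, "stat_result")) {
      cat(" ", label, ": ", sep = "")
      print(t)
    } else cat(" ", label, ": not computable\n", sep = "")
  }
  show(x$sokal_kruskal_wallis, "Sokal (KW, abs count)")
  show(x$wbc_stratum_mann_whitney$abs, "WBC strata (MW, abs count)")
  show(x$wbc_stratum_mann_whitney$pct, "WBC strata (MW, %CD26)")
  show(x$wbc_spearman, "Abs count vs WBC (Spearman)")
  show(x$paired_wilcoxon$abs, "Paired dx/fu (Wilcoxon, abs)")
  show(x$paired_wilcoxon$pct, "Paired dx/fu (Wilcoxon, %)")
  d <- x$detection
  cat(sprintf(" Detection: CML dx %d/%d positive (%d not evaluable); controls %d/%d positive\n",
              d$cml_diagnosis$n_positive, d$cml_diagnosis$n_evaluable,
              d$cml_diagnosis$n_not_evaluable,
              d$control$n_positive, d$control$n_evaluable))
  invisible(x)
}

#' Serialize an analysis report as JSON
#'
#' @param report An `analysis_report`.
#' @param path Optional output path.
#' @return JSON string (invisibly when `path` is given).
#' @export
analysis_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  to_plain <- function(x) {
    if (inherits(x, "stat_result")) {
      list(test = x$test, statistic = x$statistic,
           statistic_name = x$statistic_name, z = x$z, df = x$df,
           p_value = x$p_value, mean_ranks = as.list(x$mean_ranks),
           n = as.list(x$n), flags = x$flags)
    } else if (is.list(x)) {
      lapply(x, to_plain)
    } else x
  }
  js <- jsonlite::toJSON(to_plain(unclass(report)), auto_unbox = TRUE,
                         pretty = TRUE, na = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write the per-sample quantification rows as CSV
#'
#' @param table A `cohort_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
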