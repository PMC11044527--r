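#' Gating configuration
#'
#' @param kde_bandwidth_rule Bandwidth selector passed to
#'   [stats::density()]; `"nrd0"` (Silverman's rule) by default.
#' @param min_events_for_kde Minimum number of values required before a
#'   density trough is estimated (default 50, must be at least 10).
#' @param min_lsc_events_warn LSC gates smaller than this get a low-event
#'   warning flag (default 20); results are annotated, never suppressed,
#'   since percentages down to 0.001% imply single-digit event counts.
#' @param manual_overrides Optional named list of fixed thresholds on the
#'   gating scale, replacing the density trough for individual gates; names
#'   among `"debris"`, `"cd45"`, `"cd34"`, `"cd38"`, `"cd26"`.
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(kde_bandwidth_rule = "nrd0",
                          min_events_for_kde = 50,
                          min_lsc_events_warn = 20,
                          manual_overrides = list()) {
  min_events_for_kde <- check_count(min_events_for_kde,
                                    "min_events_for_kde", min = 10)
  bad <- setdiff(names(manual_overrides),
                 c("debris", "cd45", "cd34", "cd38", "cd26"))
  if (length(bad)) {
    stop_cd26(paste0("unknown manual_overrides: ", paste(bad, collapse = ", ")),
              class = "cd26_parameter_error")
  }
  structure(
    list(kde_bandwidth_rule = kde_bandwidth_rule,
         min_events_for_kde = min_events_for_kde,
         min_lsc_events_warn = check_count(min_lsc_events_warn,
                                           "min_lsc_events_warn"),
         manual_overrides = manual_overrides),
    class = "gating_config"
  )
}

# A second density mode is only accepted when the valley separating it
# from the main mode dips below this fraction of the second peak's height;
# an equal two-component normal mixture 3 SD apart has a valley/peak ratio
# of about 0.64, while finite-sample KDE wiggles sit above 0.9.
MODE_VALLEY_RATIO <- 0.75

#' Density-trough threshold between two expression modes
#'
#' Fits a Gaussian-kernel density estimate (Silverman bandwidth, 512-point
#' grid spanning the 0.1-99.9 percentile range of the data), finds the two
#' highest-density modes separated by a genuine valley (grid edges count as
#' candidate modes, so a mode clipped by the grid is still seen; a
#' candidate whose valley does not dip below three quarters of its own
#' height is treated as a sampling wiggle) and returns the grid location of
#' minimum density strictly between them. If several grid points tie at the
#' minimum, the lowest-intensity point is chosen, which consistently avoids
#' calling marginal events positive. A unimodal density falls back to the
#' supplied quantile and raises the `unimodal` flag.
#'
#' @param values Numeric vector on the gating scale.
#' @param cfg A [gating_config()].
#' @param fallback_quantile Quantile of `values` used when no trough exists.
#' @return List of class `cd26_trough`: `threshold`, `unimodal` flag,
#'   `grid_step`, `n_modes`, and `fallback_quantile` used (or `NA`).
#' @export
density_trough <- function(values, cfg = gating_config(),
                           fallback_quantile = 0.5) {
  stopifnot(inherits(cfg, "gating_config"))
  values <- values[is.finite(values)]
  if (length(values) < cfg$min_events_for_kde) {
    stop_cd26(sprintf(
      "density trough needs at least %d events, got %d",
      cfg$min_events_for_kde, length(values)),
      class = "cd26_insufficient_events_error")
  }
  qs <- stats::quantile(values, c(0.001, 0.999), names = FALSE, type = 7)
  fallback <- function() {
    structure(list(
      threshold = stats::quantile(values, fallback_quantile, names = FALSE,
                                  type = 7),
      unimodal = TRUE, grid_step = NA_real_, n_modes = 1L,
      fallback_quantile = fallback_quantile), class = "cd26_trough")
  }
  if (qs[2] - qs[1] <= 0 || stats::sd(values) == 0) return(fallback())
  d <- stats::density(values, bw = cfg$kde_bandwidth_rule, kernel = "gaussian",
                      n = 512, from = qs[1], to = qs[2])
  y <- d$y
  k <- length(y)
  is_max <- logical(k)
  is_max[1] <- y[1] > y[2]
  is_max[k] <- y[k] > y[k - 1]
  mid <- 2:(k - 1)
  is_max[mid] <- y[mid] >= y[mid - 1] & y[mid] >= y[mid + 1] &
    (y[mid] > y[mid - 1] | y[mid] > y[mid + 1])
  modes <- which(is_max)
  if (length(modes) < 2) return(fallback())
  # Candidate second modes are screened for a genuine trough: the density
  # between the main mode and the candidate must dip below
  # MODE_VALLEY_RATIO of the candidate's own height, otherwise the
  # "mode" is a sampling wiggle riding on the main mode's flank.
  ord <- modes[order(y[modes], decreasing = TRUE)]
  main <- ord[1]
  second <- NA_integer_
  for (cand in ord[-1]) {
    lo <- min(main, cand)
    hi <- max(main, cand)
    if (hi - lo < 2) next
    valley <- min(y[(lo + 1):(hi - 1)])
    if (valley <= MODE_VALLEY_RATIO * y[cand]) {
      second <- cand
      break
    }
  }
  if (is.na(second)) return(fallback())
  lo <- min(main, second)
  hi <- max(main, second)
  between <- (lo + 1):(hi - 1)
  j <- between[which.min(y[between])]  # which.min takes the first = lowest x
  structure(list(threshold = d$x[j], unimodal = FALSE,
                 grid_step = d$x[2] - d$x[1],
                 n_modes = length(modes),
                 fallback_quantile = NA_real_), class = "cd26_trough")
}

#' @export
print.cd26_trough <- function(x, ...) {
  cat(sprintf("trough threshold %.4f (%s)\n", x$threshold,
              if (x$unimodal) sprintf("unimodal fallback, q=%g",
                                      x$fallback_quantile)
              else sprintf("%d modes, grid step %.4f",
                           x$n_modes, x$grid_step)))
  invisible(x)
}

gate_result <- function(name, parent, member, parent_member = NULL) {
  if (!is.null(parent_member) && any(member & !parent_member)) {
    stop_cd26(sprintf("gate %s violates nesting within %s", name, parent),
              class = "cd26_consistency_error")
  }
  structure(list(name = name, parent = parent, member = member,
                 count = sum(member)),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("gate %s (parent %s): %d events\n", x$name, x$parent, x$count))
  invisible(x)
}

# Resolve scaled matrix lazily so individual gate ops stay callable on a
# bare event_matrix while the pipeline reuses one scaling pass.
resolve_scaled <- function(em, panel, tcfg, scaled) {
  if (!is.null(scaled)) return(scaled)
  scale_events(em, panel = panel, tcfg = tcfg)
}

threshold_for <- function(key, values, cfg, fallback_quantile) {
  ov <- cfg$manual_overrides[[key]]
  if (!is.null(ov)) {
    return(structure(list(threshold = as.numeric(ov), unimodal = FALSE,
                          grid_step = NA_real_, n_modes = NA_integer_,
                          fallback_quantile = NA_real_, manual = TRUE),
                     class = "cd26_trough"))
  }
  density_trough(values, cfg, fallback_quantile = fallback_quantile)
}

#' Debris-exclusion gate on forward scatter
#'
#' Debris sits near the origin of the scatter axes; events above the FSC
#' density trough are retained. A unimodal (debris-free) sample falls back
#' to the 1st percentile so that essentially all events are kept.
#'
#' @param em An [event_matrix()].
#' @param panel Optional resolved panel mapping.
#' @param cfg A [gating_config()].
#' @param tcfg A [transform_config()].
#' @param scaled Optional pre-computed [scale_events()] matrix.
#' @return List with `gate` (a `gate_result` named `"debris_free"`) and
#'   `trough` (the `cd26_trough` used).
#' @export
gate_debris_free <- function(em, panel = NULL, cfg = gating_config(),
                             tcfg = transform_config(), scaled = NULL) {
  scaled <- resolve_scaled(em, panel, tcfg, scaled)
  tr <- threshold_for("debris", scaled[, "FSC"], cfg, fallback_quantile = 0.01)
  member <- scaled[, "FSC"] > tr$threshold
  list(gate = gate_result("debris_free", "root", member), trough = tr)
}

#' CD45-positive gate within the debris-free population
#'
#' @inheritParams gate_debris_free
#' @param parent The `debris_free` gate.
#' @return List with `gate` (named `"CD45pos"`) and `trough`.
#' @export
gate_cd45 <- function(em, parent, panel = NULL, cfg = gating_config(),
                      tcfg = transform_config(), scaled = NULL) {
  scaled <- resolve_scaled(em, panel, tcfg, scaled)
  vals <- scaled[parent$member, "CD45"]
  tr <- threshold_for("cd45", vals, cfg, fallback_quantile = 0.01)
  member <- parent$member & scaled[, "CD45"] > tr$threshold
  list(gate = gate_result("CD45pos", parent$name, member, parent$member),
       trough = tr)
}

#' CD34-positive gate within CD45+ events
#'
#' CD34+ events are a small minority; when no CD34+ mode is detectable the
#' fallback is the 99.9th percentile of the parent's CD34, so an absent
#' population yields a near-zero count (flagged).
#'
#' @inheritParams gate_cd45
#' @param parent The `CD45pos` gate.
#' @return List with `gate` (named `"CD34pos"`) and `trough`.
#' @export
gate_cd34 <- function(em, parent, panel = NULL, cfg = gating_config(),
                      tcfg = transform_config(), scaled = NULL) {
  scaled <- resolve_scaled(em, panel, tcfg, scaled)
  vals <- scaled[parent$member, "CD34"]
  tr <- threshold_for("cd34", vals, cfg, fallback_quantile = 0.999)
  member <- parent$member & scaled[, "CD34"] > tr$threshold
  list(gate = gate_result("CD34pos", parent$name, member, parent$member),
       trough = tr)
}

#' Split CD34+ events into CD38+ progenitors and the CD38- LSC compartment
#'
#' Partitions the CD34+ parent at the CD38 density trough; the
#' below-threshold child is the stem (LSC) compartment. Parents smaller
#' than `min_events_for_kde` use the fallback median with a flag; an empty
#' parent yields two empty children.
#'
#' @inheritParams gate_cd45
#' @param parent The `CD34pos` gate.
#' @return List with `cd38pos` and `lsc` gate results, `trough`, and
#'   `flags`.
#' @export
split_cd38 <- function(em, parent, panel = NULL, cfg = gating_config(),
                       tcfg = transform_config(), scaled = NULL) {
  scaled <- resolve_scaled(em, panel, tcfg, scaled)
  vals <- scaled[parent$member, "CD38"]
  flags <- character(0)
  if (parent$count == 0) {
    empty <- rep(FALSE, nrow(scaled))
    return(list(cd38pos = gate_result("CD38pos", parent$name, empty),
                lsc = gate_result("LSC", parent$name, empty),
                trough = NULL, flags = "cd38_empty_parent"))
  }
  if (parent$count < cfg$min_events_for_kde) {
    tr <- structure(list(threshold = stats::quantile(vals, 0.5, names = FALSE),
                         unimodal = TRUE, grid_step = NA_real_, n_modes = 1L,
                         fallback_quantile = 0.5), class = "cd26_trough")
    flags <- "cd38_low_events"
  } else {
    tr <- threshold_for("cd38", vals, cfg, fallback_quantile = 0.5)
    if (tr$unimodal) flags <- "cd38_unimodal"
  }
  pos <- parent$member & scaled[, "CD38"] > tr$threshold
  lsc <- parent$member & !pos
  list(cd38pos = gate_result("CD38pos", parent$name, pos, parent$member),
       lsc = gate_result("LSC", parent$name, lsc, parent$member),
       trough = tr, flags = flags)
}

#' CD26 positivity cutoff calibrated on CD3+ lymphocytes
#'
#' The sample's own T lymphocytes act as an internal control: their CD26
#' expression is bimodal, and the density trough between the CD26- and
#' CD26+ modes defines the positivity cutoff that is then applied to the
#' LSC compartment. Lymphocytes are pre-gated as CD45-bright / SSC-low
#' within the debris-free population, and the CD3+ subset is taken above
#' the CD3 density trough. If the CD3+ CD26 distribution is unimodal the
#' cutoff falls back to the 99.9th percentile of CD3+ lymphocyte CD26
#' (their upper tail bounding negativity) and CD26 calls are flagged
#' low-confidence.
#'
#' @inheritParams gate_cd45
#' @param debris_free The `debris_free` gate.
#' @return List of class `cd26_calibration`: `cutoff`, `trough`,
#'   `lymph_gate`, `cd3_gate`, `flags`.
#' @export
cd26_cutoff_from_lymphocytes <- function(em, debris_free, panel = NULL,
                                         cfg = gating_config(),
                                         tcfg = transform_config(),
                                         scaled = NULL) {
  scaled <- resolve_scaled(em, panel, tcfg, scaled)
  flags <- character(0)
  # CD45-bright events within debris-free
  tr45 <- density_trough(scaled[debris_free$member, "CD45"], cfg,
                         fallback_quantile = 0.01)
  bright <- debris_free$member & scaled[, "CD45"] > tr45$threshold
  # SSC-low side of the CD45-bright population
  trssc <- density_trough(scaled[bright, "SSC"], cfg, fallback_quantile = 0.5)
  lymph <- bright & scaled[, "SSC"] <= trssc$threshold
  lymph_gate <- gate_result("lymphocyte", "debris_free", lymph,
                            debris_free$member)
  if (lymph_gate$count < cfg$min_events_for_kde) {
    stop_cd26(sprintf(
      "too few lymphocyte-gate events (%d) for CD26 calibration",
      lymph_gate$count), class = "cd26_calibration_error")
  }
  trcd3 <- density_trough(scaled[lymph, "CD3"], cfg, fallback_quantile = 0.999)
  if (trcd3$unimodal) flags <- c(flags, "cd3_unimodal")
  cd3pos <- lymph & scaled[, "CD3"] > trcd3$threshold
  cd3_gate <- gate_result("CD3pos_lymph", "lymphocyte", cd3pos, lymph)
  if (cd3_gate$count < cfg$min_events_for_kde) {
    stop_cd26(sprintf(
      "too few CD3+ lymphocytes (%d) for CD26 calibration",
      cd3_gate$count), class = "cd26_calibration_error")
  }
  tr26 <- threshold_for("cd26", scaled[cd3pos, "CD26"], cfg,
                        fallback_quantile = 0.999)
  if (tr26$unimodal) flags <- c(flags, "cd26_calibration_unimodal")
  structure(list(cutoff = tr26$threshold, trough = tr26,
                 lymph_gate = lymph_gate, cd3_gate = cd3_gate,
                 flags = flags),
            class = "cd26_calibration")
}

#' Classify the LSC compartment at the CD26 cutoff
#'
#' @inheritParams gate_cd45
#' @param lsc The `LSC` gate.
#' @param cutoff Finite CD26 cutoff on the gating scale.
#' @return List with `cd26pos` and `cd26neg` gate results partitioning the
#'   LSC gate.
#' @export
classify_cd26 <- function(em, lsc, cutoff, panel = NULL,
                          cfg = gating_config(),
                          tcfg = transform_config(), scaled = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    stop_cd26("CD26 cutoff must be a single finite number",
              class = "cd26_parameter_error")
  }
  scaled <- resolve_scaled(em, panel, tcfg, scaled)
  pos <- lsc$member & scaled[, "CD26"] > cutoff
  neg <- lsc$member & !pos
  list(cd26pos = gate_result("LSC_CD26pos", lsc$name, pos, lsc$member),
       cd26neg = gate_result("LSC_CD26neg", lsc$name, neg, lsc$member))
}

#' Run the full sequential gating pipeline
#'
#' Executes, in order: debris exclusion on FSC, CD45+ selection, CD34+
#' selection, the CD38 split into progenitors and the LSC compartment, the
#' CD3+ lymphocyte CD26 calibration, and CD26 classification of the LSC
#' gate. All thresholds are 1D density troughs on the gating scale; the
#' result is deterministic given the inputs. A failed CD26 calibration
#' yields a report whose CD26 fields are marked unavailable rather than
#' silently zero.
#'
#' @param em An [event_matrix()].
#' @param panel Optional [panel_config()] or resolved mapping; resolved
#'   from channel metadata when `NULL`.
#' @param cfg A [gating_config()].
#' @param tcfg A [transform_config()].
#' @return An object of class `gating_report`: `gates` (named list of
#'   `gate_result`), `thresholds`, `counts`, `flags`, `cd26_available`,
#'   `sample_id`.
#' @export
run_gating_pipeline <- function(em, panel = NULL, cfg = gating_config(),
                                tcfg = transform_config()) {
  em <- validate_event_matrix(em)
  if (is.null(panel) || inherits(panel, "panel_config")) {
    panel <- resolve_panel(em, panel)
  }
  scaled <- scale_events(em, panel = panel, tcfg = tcfg)
  flags <- character(0)

  deb <- gate_debris_free(em, cfg = cfg, scaled = scaled)
  if (deb$trough$unimodal) flags <- c(flags, "debris_unimodal")
  g45 <- gate_cd45(em, deb$gate, cfg = cfg, scaled = scaled)
  if (g45$trough$unimodal) flags <- c(flags, "cd45_unimodal")
  g34 <- gate_cd34(em, g45$gate, cfg = cfg, scaled = scaled)
  if (g34$trough$unimodal) flags <- c(flags, "cd34_rare_positive_fallback")
  sp38 <- split_cd38(em, g34$gate, cfg = cfg, scaled = scaled)
  flags <- c(flags, sp38$flags)

  cal <- tryCatch(
    cd26_cutoff_from_lymphocytes(em, deb$gate, cfg = cfg, scaled = scaled),
    cd26_calibration_error = function(e) e
  )
  gates <- list(debris_free = deb$gate, CD45pos = g45$gate,
                CD34pos = g34$gate, CD38pos = sp38$cd38pos,
                LSC = sp38$lsc)
  thresholds <- c(debris = deb$trough$threshold,
                  cd45 = g45$trough$threshold,
                  cd34 = g34$trough$threshold,
                  cd38 = if (is.null(sp38$trough)) NA_real_
                         else sp38$trough$threshold)
  if (inherits(cal, "cd26_calibration")) {
    flags <- c(flags, cal$flags)
    cls <- classify_cd26(em, sp38$lsc, cal$cutoff, cfg = cfg, scaled = scaled)
    gates$lymphocyte <- cal$lymph_gate
    gates$CD3pos_lymph <- cal$cd3_gate
    gates$LSC_CD26pos <- cls$cd26pos
    gates$LSC_CD26neg <- cls$cd26neg
    thresholds <- c(thresholds, cd26 = cal$cutoff)
    cd26_available <- TRUE
  } else {
    flags <- c(flags, "cd26_calibration_failed")
    thresholds <- c(thresholds, cd26 = NA_real_)
    cd26_available <- FALSE
  }
  if (sp38$lsc$count < cfg$min_lsc_events_warn) {
    flags <- c(flags, "low_lsc_events")
  }
  counts <- c(total = nrow(em$data),
              vapply(gates, function(g) as.numeric(g$count), numeric(1)))
  structure(
    list(gates = gates, thresholds = thresholds, counts = counts,
         flags = unique(flags), cd26_available = cd26_available,
         sample_id = em$sample_id),
    class = "gating_report"
  )
}

#' @export
print.gating_report <- function(x, ...) {
  cat(sprintf("Gating report for '%s' (%d events)\n",
              x$sample_id, x$counts[["total"]]))
  for (g in x$gates) {
    cat(sprintf("  %-14s parent %-12s %8d events\n",
                g$name, g$parent, g$count))
  }
  cat("  thresholds:",
      paste(sprintf("%s=%.3f", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n")
  if (!x$cd26_available) cat("  CD26 quantities UNAVAILABLE\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a gating report as JSON
#'
#' Gate names, parent linkage, counts, thresholds and flags; per-event
#' membership is omitted (export event indices separately if needed).
#'
#' @param report A `gating_report`.
#' @param path Optional path; when given, JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
gating_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "gating_report"))
  obj <- list(
    sample_id = report$sample_id,
    counts = as.list(report$counts),
    thresholds = as.list(report$thresholds),
    gates = lapply(report$gates, function(g) {
      list(name = g$name, parent = g$parent, count = g$count)
    }),
    flags = report$flags,
    cd26_available = report$cd26_available
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
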