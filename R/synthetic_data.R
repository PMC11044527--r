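POPULATIONS <- c(
  "debris",
  "lymphocyte_cd3pos_cd26pos",
  "lymphocyte_cd3pos_cd26neg",
  "lymphocyte_other",
  "granulocyte",
  "monocyte",
  "progenitor_cd34pos_cd38pos",
  "lsc_cd34pos_cd38neg_cd26neg",
  "lsc_cd34pos_cd38neg_cd26pos"
)

#' Simulation configuration for one acquisition
#'
#' Describes a single synthetic peripheral-blood acquisition: how many
#' events, the white-cell concentration used for absolute counts, the
#' clinical group, and the two CD26 targets the population template is
#' solved for. The defaults reproduce a typical chronic-phase CML diagnosis
#' sample: 100,000 events, WBC 278,000/uL, 0.02% CD26+ LSC of CD45+ events
#' and 5.04% CD26+ share of the CD34+/CD38- compartment.
#'
#' @param n_events Number of events to draw (default 100,000).
#' @param wbc_per_ul White-cell concentration in cells/uL.
#' @param group One of `"CML-diagnosis"`, `"CML-followup"`, `"control"`.
#'   Controls carry no CD26+ LSC population: the CD26 target is forced to 0.
#' @param target_pct_cd26_of_cd45 Desired CD26+ LSC percentage of CD45+
#'   events, in \[0, 100\].
#' @param target_pct_cd26_of_lsc Desired CD26+ share of the CD34+/CD38-
#'   compartment, in (0, 100\].
#' @param seed Integer RNG seed; identical seed and config give
#'   bit-identical output.
#' @param cofactor Arcsinh cofactor linking the scaled population template
#'   to raw fluorescence intensities.
#' @param pin_rare If `TRUE` (default) and the CD26 target implies fewer
#'   than 5 expected CD26+ LSC events, the exact event count is pinned
#'   (hypergeometric-style assignment) instead of left to multinomial
#'   noise, so detection at the 0.001% regime is deterministic.
#' @param min_cd26_events Optional hard floor on the number of CD26+ LSC
#'   events placed in a non-control sample (0 disables the floor).
#' @return An object of class `sample_sim_config`.
#' @export
sample_sim_config <- function(n_events = 100000,
                              wbc_per_ul = 278000,
                              group = c("CML-diagnosis", "CML-followup",
                                        "control"),
                              target_pct_cd26_of_cd45 = 0.02,
                              target_pct_cd26_of_lsc = 5.04,
                              seed = 1,
                              cofactor = 150,
                              pin_rare = TRUE,
                              min_cd26_events = 0) {
  group <- match.arg(group)
  n_events <- check_count(n_events, "n_events", min = 1)
  if (!is.numeric(wbc_per_ul) || wbc_per_ul <= 0) {
    stop_cd26("wbc_per_ul must be positive", class = "cd26_parameter_error")
  }
  t45 <- target_pct_cd26_of_cd45
  if (!is.numeric(t45) || t45 < 0 || t45 > 100) {
    stop_cd26("target_pct_cd26_of_cd45 must lie in [0, 100]",
              class = "cd26_parameter_error")
  }
  if (group == "control") t45 <- 0
  tlsc <- target_pct_cd26_of_lsc
  if (!is.numeric(tlsc) || tlsc <= 0 || tlsc > 100) {
    stop_cd26("target_pct_cd26_of_lsc must lie in (0, 100]",
              class = "cd26_parameter_error")
  }
  check_cofactor(cofactor)
  structure(
    list(n_events = n_events, wbc_per_ul = wbc_per_ul, group = group,
         target_pct_cd26_of_cd45 = t45, target_pct_cd26_of_lsc = tlsc,
         seed = as.integer(seed), cofactor = cofactor,
         pin_rare = isTRUE(pin_rare),
         min_cd26_events = check_count(min_cd26_events, "min_cd26_events")),
    class = "sample_sim_config"
  )
}

# Template of population locations/spreads on the gating scale: scatter in
# linear channel units, fluorescence in arcsinh units. Geometry guarantees
# - debris far below cells on FSC,
# - one broad CD45+ mode (CD34+ cells dim relative to lymphocytes),
# - CD3+ lymphocyte CD26 modes >= 3 pooled SD apart (trough exists),
# - CD38 separating progenitors from LSCs by >= 3 pooled SD,
# - CD26+ LSC sharing the lymphocyte CD26+ mode location.
population_template <- function() {
  mk <- PANEL_MARKERS  # FSC SSC CD45 CD34 CD38 CD26 CD3
  loc <- rbind(
    debris                      = c(90, 40, 0.30, 0.30, 0.30, 0.30, 0.30),
    lymphocyte_cd3pos_cd26pos   = c(400, 120, 4.70, 0.35, 1.40, 3.20, 4.30),
    lymphocyte_cd3pos_cd26neg   = c(400, 120, 4.70, 0.35, 1.40, 0.70, 4.30),
    lymphocyte_other            = c(400, 120, 4.70, 0.35, 1.40, 0.70, 0.50),
    granulocyte                 = c(520, 600, 4.30, 0.35, 1.80, 0.80, 0.50),
    monocyte                    = c(480, 300, 4.50, 0.35, 2.50, 1.00, 0.50),
    progenitor_cd34pos_cd38pos  = c(430, 150, 4.00, 3.50, 3.20, 0.50, 0.50),
    lsc_cd34pos_cd38neg_cd26neg = c(430, 150, 4.00, 3.50, 0.80, 0.40, 0.50),
    lsc_cd34pos_cd38neg_cd26pos = c(430, 150, 4.00, 3.50, 0.80, 3.20, 0.50)
  )
  spr <- rbind(
    debris                      = c(80, 30, 0.30, 0.25, 0.30, 0.30, 0.30),
    lymphocyte_cd3pos_cd26pos   = c(50, 30, 0.35, 0.25, 0.45, 0.40, 0.35),
    lymphocyte_cd3pos_cd26neg   = c(50, 30, 0.35, 0.25, 0.45, 0.35, 0.35),
    lymphocyte_other            = c(50, 30, 0.35, 0.25, 0.45, 0.35, 0.30),
    granulocyte                 = c(70, 90, 0.45, 0.25, 0.50, 0.35, 0.30),
    monocyte                    = c(60, 60, 0.40, 0.25, 0.50, 0.40, 0.30),
    progenitor_cd34pos_cd38pos  = c(55, 40, 0.40, 0.35, 0.40, 0.30, 0.30),
    lsc_cd34pos_cd38neg_cd26neg = c(55, 40, 0.40, 0.35, 0.40, 0.28, 0.30),
    lsc_cd34pos_cd38neg_cd26pos = c(55, 40, 0.40, 0.35, 0.40, 0.40, 0.30)
  )
  colnames(loc) <- colnames(spr) <- mk
  list(location = loc, spread = spr)
}

#' Default population mixture for a simulated acquisition
#'
#' Solves the population fractions so that the expected CD26+ LSC
#' percentage of CD45+ events equals the configured target, and the CD26+
#' share of the CD34+/CD38- compartment equals its target. The remaining
#' mass goes to granulocytes (the dominant population in CML blood).
#'
#' @param cfg A [sample_sim_config()].
#' @return List of `population_spec` entries (name, fraction, location,
#'   spread), fractions summing to 1.
#' @export
default_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sample_sim_config"))
  tpl <- population_template()
  base <- c(
    debris = 0.12,
    lymphocyte_cd3pos_cd26pos = 0.03,
    lymphocyte_cd3pos_cd26neg = 0.03,
    lymphocyte_other = 0.04,
    monocyte = 0.04,
    progenitor_cd34pos_cd38pos =
      if (cfg$group == "CML-diagnosis") 0.006 else 0.004
  )
  f_cd45 <- 1 - base[["debris"]]
  f_pos <- cfg$target_pct_cd26_of_cd45 / 100 * f_cd45
  if (f_pos > 0) {
    f_lsc <- f_pos / (cfg$target_pct_cd26_of_lsc / 100)
  } else {
    # CD26-negative stem compartment only (controls / target-zero CML)
    f_lsc <- if (cfg$group == "control") 0.0006 else 0.003
  }
  f_neg <- f_lsc - f_pos
  f_gran <- 1 - sum(base) - f_lsc
  if (f_neg < 0 || f_gran < 0.05) {
    stop_cd26(paste0(
      "CD26 targets jointly infeasible: implied CD34+/CD38- fraction ",
      signif(f_lsc, 4), " leaves granulocyte fraction ", signif(f_gran, 4)),
      class = "cd26_configuration_error")
  }
  fr <- c(base["debris"],
          base["lymphocyte_cd3pos_cd26pos"],
          base["lymphocyte_cd3pos_cd26neg"],
          base["lymphocyte_other"],
          granulocyte = unname(f_gran),
          base["monocyte"],
          base["progenitor_cd34pos_cd38pos"],
          lsc_cd34pos_cd38neg_cd26neg = unname(f_neg),
          lsc_cd34pos_cd38neg_cd26pos = unname(f_pos))
  names(fr) <- POPULATIONS
  stopifnot(abs(sum(fr) - 1) < 1e-9)
  lapply(POPULATIONS, function(p) {
    structure(list(name = p, fraction = unname(fr[[p]]),
                   location = tpl$location[p, ],
                   spread = tpl$spread[p, ]),
              class = "population_spec")
  })
}

sim_channels <- function() {
  data.frame(
    index = 1:7,
    short_name = c("FS", "SS", "FL5", "FL4", "FL6", "FL2", "FL7"),
    marker = c("FSC", "SSC", "CD45 KrO", "CD34 PC7", "CD38 APC750",
               "CD26 PE", "CD3 PB"),
    range = rep(1048576, 7),
    stringsAsFactors = FALSE
  )
}

#' Simulate one acquisition with ground truth
#'
#' Draws per-event population labels multinomially from the configured
#' fractions, then intensities per population from independent normals on
#' the gating scale (scatter linear, fluorescence arcsinh), mapped back to
#' raw intensities through [inverse_asinh_scale()]; scatter is clamped at
#' zero, fluorescence keeps its (compensation-like) negative tail.
#' When the CD26 target implies fewer than 5 expected CD26+ LSC events (or
#' `min_cd26_events` is set), the exact CD26+ LSC event count is pinned by
#' relabeling randomly chosen granulocyte events, making rare-event
#' detection deterministic.
#'
#' @param cfg A [sample_sim_config()].
#' @param populations Population mixture; defaults to
#'   [default_populations()] of `cfg`.
#' @return List with elements `em` (an [event_matrix()]) and `truth` (a
#'   `sim_ground_truth`: per-event `labels`, per-population `counts`, and
#'   realized `pct_cd26_of_cd45`, `pct_cd26_of_lsc`, `abs_cd26_per_ul`).
#' @export
simulate_sample <- function(cfg, populations = default_populations(cfg)) {
  stopifnot(inherits(cfg, "sample_sim_config"))
  frac <- vapply(populations, `[[`, numeric(1), "fraction")
  names(frac) <- vapply(populations, `[[`, character(1), "name")
  if (abs(sum(frac) - 1) > 1e-9) {
    stop_cd26("population fractions must sum to 1",
              class = "cd26_configuration_error")
  }
  n <- cfg$n_events
  pos_name <- "lsc_cd34pos_cd38neg_cd26pos"
  with_seed(cfg$seed, {
    labels <- sample(names(frac), n, replace = TRUE, prob = frac)
    expected_pos <- n * frac[[pos_name]]
    pin <- (cfg$pin_rare && expected_pos > 0 && expected_pos < 5) ||
      (cfg$min_cd26_events > 0 && frac[[pos_name]] > 0)
    if (pin) {
      k <- max(round(expected_pos), cfg$min_cd26_events)
      cur <- which(labels == pos_name)
      if (length(cur) > k) {
        labels[sample(cur, length(cur) - k)] <- "granulocyte"
      } else if (length(cur) < k) {
        pool <- which(labels == "granulocyte")
        labels[sample(pool, k - length(cur))] <- pos_name
      }
    }
    loc <- do.call(rbind, lapply(populations, `[[`, "location"))
    spr <- do.call(rbind, lapply(populations, `[[`, "spread"))
    rownames(loc) <- rownames(spr) <- names(frac)
    idx <- match(labels, names(frac))
    mat <- matrix(0, nrow = n, ncol = length(PANEL_MARKERS),
                  dimnames = list(NULL, PANEL_MARKERS))
    for (m in PANEL_MARKERS) {
      scaled <- stats::rnorm(n, mean = loc[idx, m], sd = spr[idx, m])
      if (m %in% SCATTER_MARKERS) {
        # scatter pulses cannot be negative; fluorescence can (and piling
        # clamped events at zero would fabricate a density mode)
        mat[, m] <- pmax(scaled, 0)
      } else {
        mat[, m] <- inverse_asinh_scale(scaled, cfg$cofactor)
      }
    }
  })
  colnames(mat) <- NULL
  em <- event_matrix(mat, sim_channels(),
                     sample_id = paste0("sim-", cfg$group, "-", cfg$seed))
  truth <- ground_truth_from_labels(labels, cfg$wbc_per_ul)
  list(em = em, truth = truth)
}

ground_truth_from_labels <- function(labels, wbc_per_ul) {
  counts <- vapply(POPULATIONS, function(p) sum(labels == p), integer(1))
  n_cd45 <- sum(counts) - counts[["debris"]]
  n_pos <- counts[["lsc_cd34pos_cd38neg_cd26pos"]]
  n_lsc <- n_pos + counts[["lsc_cd34pos_cd38neg_cd26neg"]]
  pct45 <- if (n_cd45 > 0) 100 * n_pos / n_cd45 else NA_real_
  pctlsc <- if (n_lsc > 0) 100 * n_pos / n_lsc else NA_real_
  structure(
    list(labels = labels, counts = counts,
         n_cd45 = n_cd45, n_lsc = n_lsc, n_cd26pos = n_pos,
         pct_cd26_of_cd45 = pct45, pct_cd26_of_lsc = pctlsc,
         abs_cd26_per_ul = if (is.na(pct45)) NA_real_
                           else wbc_per_ul * pct45 / 100),
    class = "sim_ground_truth"
  )
}

log_uniform <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Simulate a study cohort
#'
#' Emulates a single-center CML study cohort: `n_cml` diagnosis samples with WBC drawn
#' log-uniformly over 42.6-828.3 x10^3/uL and %CD26-of-CD45 log-uniformly
#' over 0.001-1.77 (log-uniform because reported medians sit far below the
#' range midpoints), `n_controls` control samples without a CD26+ LSC
#' population, and `n_followup_pairs` six-month follow-up partners of the
#' first chronic-phase patients with %CD26 drawn log-uniformly over
#' 0.001-0.2 and WBC redrawn in the normal range (4-11 x10^3/uL). Sokal
#' risk is assigned with realistic CML-at-diagnosis proportions (4 low /
#' 31 intermediate / 8 high per 43).
#'
#' @param n_cml Number of CML diagnosis samples.
#' @param n_controls Number of non-CML control samples.
#' @param n_followup_pairs Number of diagnosis samples that also get a
#'   follow-up acquisition (must not exceed `n_cml`).
#' @param seed Master seed; every sample receives its own derived stream.
#' @param n_events Events per acquisition.
#' @param min_cd26_events Hard floor on pinned CD26+ LSC events for CML
#'   samples (0 disables).
#' @param reduction_share Share of follow-up pairs whose %CD26 is forced
#'   not to exceed the diagnosis value (default 1: a true universal
#'   post-treatment reduction).
#' @return List of samples, each a list with `em`, `truth`, `record`.
#' @export
simulate_cohort <- function(n_cml = 43, n_controls = 10,
                            n_followup_pairs = 28, seed = 1,
                            n_events = 100000, min_cd26_events = 0,
                            reduction_share = 1) {
  n_cml <- check_count(n_cml, "n_cml")
  n_controls <- check_count(n_controls, "n_controls")
  n_followup_pairs <- check_count(n_followup_pairs, "n_followup_pairs")
  if (n_followup_pairs > n_cml) {
    stop_cd26("n_followup_pairs must not exceed n_cml",
              class = "cd26_parameter_error")
  }
  params <- with_seed(seed, {
    wbc_dx <- log_uniform(n_cml, 42.6e3, 828.3e3)
    t45_dx <- log_uniform(n_cml, 0.001, 1.77)
    tlsc_dx <- log_uniform(n_cml, pmax(0.05, 5 * t45_dx), 55.94)
    sokal <- if (n_cml > 0) {
      sample(c("low", "intermediate", "high"), n_cml, replace = TRUE,
             prob = c(4, 31, 8) / 43)
    } else character(0)
    # blast-crisis cases (study: 4 of 43) never enter the follow-up series
    phase <- rep("chronic", n_cml)
    n_bc <- round(n_cml * 4 / 43)
    if (n_bc > 0 && n_cml > n_followup_pairs) {
      phase[sample((n_followup_pairs + 1):n_cml,
                   min(n_bc, n_cml - n_followup_pairs))] <- "blast-crisis"
    }
    wbc_fu <- log_uniform(n_followup_pairs, 4e3, 11e3)
    t45_fu <- log_uniform(n_followup_pairs, 0.001, 0.2)
    reduce <- stats::runif(n_followup_pairs) <= reduction_share
    t45_fu[reduce] <- pmin(t45_fu[reduce], t45_dx[seq_len(n_followup_pairs)][reduce])
    tlsc_fu <- log_uniform(n_followup_pairs, pmax(0.05, 5 * t45_fu), 55.94)
    wbc_ctl <- log_uniform(n_controls, 4e3, 11e3)
    list(wbc_dx = wbc_dx, t45_dx = t45_dx, tlsc_dx = tlsc_dx,
         sokal = sokal, phase = phase, wbc_fu = wbc_fu, t45_fu = t45_fu,
         tlsc_fu = tlsc_fu, wbc_ctl = wbc_ctl)
  })
  seeds <- split_seeds(seed, n_cml + n_followup_pairs + n_controls + 1)
  out <- list()
  make <- function(cfg, record) {
    s <- simulate_sample(cfg)
    s$em$sample_id <- record$sample_id
    list(em = s$em, truth = s$truth, record = record,
         targets = list(
           pct_cd26_of_cd45 = cfg$target_pct_cd26_of_cd45,
           pct_cd26_of_lsc = cfg$target_pct_cd26_of_lsc))
  }
  for (i in seq_len(n_cml)) {
    subject <- sprintf("CML%02d", i)
    cfg <- sample_sim_config(
      n_events = n_events, wbc_per_ul = params$wbc_dx[i],
      group = "CML-diagnosis",
      target_pct_cd26_of_cd45 = params$t45_dx[i],
      target_pct_cd26_of_lsc = params$tlsc_dx[i],
      seed = seeds[i], min_cd26_events = min_cd26_events)
    rec <- sample_record(
      sample_id = paste0(subject, "-dx"), group = "CML",
      phase = params$phase[i], sokal = params$sokal[i],
      timepoint = "diagnosis", wbc_per_ul = params$wbc_dx[i],
      subject_id = subject)
    out[[length(out) + 1L]] <- make(cfg, rec)
  }
  for (i in seq_len(n_followup_pairs)) {
    subject <- sprintf("CML%02d", i)
    cfg <- sample_sim_config(
      n_events = n_events, wbc_per_ul = params$wbc_fu[i],
      group = "CML-followup",
      target_pct_cd26_of_cd45 = params$t45_fu[i],
      target_pct_cd26_of_lsc = params$tlsc_fu[i],
      seed = seeds[n_cml + i], min_cd26_events = min_cd26_events)
    rec <- sample_record(
      sample_id = paste0(subject, "-fu"), group = "CML",
      phase = params$phase[i], sokal = params$sokal[i],
      timepoint = "followup-6mo", wbc_per_ul = params$wbc_fu[i],
      subject_id = subject)
    out[[length(out) + 1L]] <- make(cfg, rec)
  }
  for (i in seq_len(n_controls)) {
    subject <- sprintf("CTL%02d", i)
    cfg <- sample_sim_config(
      n_events = n_events, wbc_per_ul = params$wbc_ctl[i],
      group = "control", target_pct_cd26_of_cd45 = 0,
      seed = seeds[n_cml + n_followup_pairs + i])
    rec <- sample_record(
      sample_id = paste0(subject), group = "control",
      phase = "not-applicable", sokal = "not-applicable",
      timepoint = "diagnosis", wbc_per_ul = params$wbc_ctl[i],
      subject_id = subject)
    out[[length(out) + 1L]] <- make(cfg, rec)
  }
  out
}

#' Write a simulated cohort to disk
#'
#' Emits one FCS 3.1 file per sample plus a `manifest.csv` (path and
#' clinical record) and a `ground_truth.csv` (realized per-sample truth),
#' so a cohort run can be reproduced from files alone.
#'
#' @param samples Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    path <- file.path(dir, paste0(s$record$sample_id, ".fcs"))
    write_fcs(s$em, path)
    cbind(data.frame(path = path, stringsAsFactors = FALSE),
          as.data.frame(s$record))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  gt <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$record$sample_id,
               n_cd45 = s$truth$n_cd45, n_lsc = s$truth$n_lsc,
               n_cd26pos = s$truth$n_cd26pos,
               pct_cd26_of_cd45 = s$truth$pct_cd26_of_cd45,
               pct_cd26_of_lsc = s$truth$pct_cd26_of_lsc,
               abs_cd26_per_ul = s$truth$abs_cd26_per_ul,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(manifest)
}
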