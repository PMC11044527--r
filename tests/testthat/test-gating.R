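test_that("density trough matches the analytic mixture minimum", {
  set.seed(2024)
  x <- c(rnorm(5000, -1, 1), rnorm(5000, 2, 1))
  tr <- density_trough(x)
  expect_false(tr$unimodal)
  truth <- mixture_min(0.5, -1, 1, 0.5, 2, 1)  # 0.5 by symmetry
  expect_equal(truth, 0.5, tolerance = 1e-3)
  expect_lt(abs(tr$threshold - truth), 0.15)
})

test_that("density trough agrees with brute-force minimization of the fitted KDE", {
  set.seed(77)
  x <- c(rnorm(5000, -1, 1), rnorm(5000, 2, 1))
  tr <- density_trough(x)
  # independent route: same KDE settings, exhaustive search between the
  # known mode locations
  qs <- quantile(x, c(0.001, 0.999), names = FALSE)
  d <- density(x, bw = "nrd0", n = 512, from = qs[1], to = qs[2])
  inner <- d$x > -0.5 & d$x < 1.5
  brute <- d$x[inner][which.min(d$y[inner])]
  expect_lt(abs(tr$threshold - brute), tr$grid_step + 1e-12)
})

test_that("an unbalanced mixture still yields a trough between the modes", {
  # a 5% component must be far enough out to form a density mode at all
  # (at 3 SD the mixture is analytically unimodal); at 5 SD it does
  set.seed(3)
  x <- c(rnorm(9500, -1, 1), rnorm(500, 4, 1))
  tr <- density_trough(x)
  expect_false(tr$unimodal)
  expect_gt(tr$threshold, -1)
  expect_lt(tr$threshold, 4)
})

test_that("unimodal and degenerate inputs fall back with a flag", {
  set.seed(8)
  x <- rnorm(5000)
  tr <- density_trough(x, fallback_quantile = 0.9)
  expect_true(tr$unimodal)
  expect_equal(tr$threshold, quantile(x, 0.9, names = FALSE))
  const <- density_trough(rep(1, 100))
  expect_true(const$unimodal)
  expect_error(density_trough(rnorm(20)),
               class = "cd26_insufficient_events_error")
})

test_that("debris gate excludes well-separated debris and keeps cells", {
  cfg <- sample_sim_config(n_events = 50000, seed = 21)
  pops <- populations_with_fractions(cfg, list(debris = 0.05))
  # tighten debris so it sits far below cells on FSC
  names(pops) <- vapply(pops, `[[`, character(1), "name")
  pops$debris$location[["FSC"]] <- 60
  pops$debris$spread[["FSC"]] <- 25
  s <- simulate_sample(cfg, unname(pops))
  deb <- gate_debris_free(s$em)
  is_debris <- s$truth$labels == "debris"
  excluded <- sum(is_debris & !deb$gate$member) / sum(is_debris)
  retained <- sum(!is_debris & deb$gate$member) / sum(!is_debris)
  expect_gte(excluded, 0.99)
  expect_gte(retained, 0.99)
})

test_that("debris gate degenerates gracefully without debris", {
  cfg <- sample_sim_config(n_events = 20000, seed = 22)
  pops <- populations_with_fractions(cfg, list(debris = 0))
  s <- simulate_sample(cfg, pops)
  deb <- gate_debris_free(s$em)
  expect_true(deb$trough$unimodal)
  expect_gte(deb$gate$count / 20000, 0.989)
})

test_that("CD45 gate captures the CD45-expressing populations", {
  s <- quick_sample(seed = 23)
  deb <- gate_debris_free(s$em)
  g45 <- gate_cd45(s$em, deb$gate)
  cd45_true <- s$truth$labels != "debris"
  expect_gte(sum(g45$gate$member & cd45_true) / sum(cd45_true), 0.99)
})

test_that("manual overrides replace the density threshold verbatim", {
  s <- quick_sample(seed = 24)
  cfg <- gating_config(manual_overrides = list(cd45 = 2.5))
  deb <- gate_debris_free(s$em, cfg = cfg)
  g45 <- gate_cd45(s$em, deb$gate, cfg = cfg)
  expect_identical(g45$trough$threshold, 2.5)
  sc <- scale_events(s$em)
  expect_identical(g45$gate$member, deb$gate$member & sc[, "CD45"] > 2.5)
})

test_that("a tiny parent population raises an insufficient-events error", {
  s <- quick_sample(seed = 25, n_events = 2000)
  deb <- gate_debris_free(s$em)
  starved <- deb$gate
  starved$member[which(starved$member)[-(1:30)]] <- FALSE
  starved$count <- sum(starved$member)
  expect_error(gate_cd45(s$em, starved),
               class = "cd26_insufficient_events_error")
})

test_that("CD34 gate recovers the rare CD34+ compartment", {
  s <- quick_sample(seed = 26, n_events = 100000)
  deb <- gate_debris_free(s$em)
  g45 <- gate_cd45(s$em, deb$gate)
  g34 <- gate_cd34(s$em, g45$gate)
  truth34 <- sum(s$truth$labels %in% c("progenitor_cd34pos_cd38pos",
                                       "lsc_cd34pos_cd38neg_cd26neg",
                                       "lsc_cd34pos_cd38neg_cd26pos"))
  expect_lt(abs(g34$gate$count - truth34) / truth34, 0.10)
})

test_that("absent CD34+ population falls back to a near-zero gate", {
  cfg <- sample_sim_config(n_events = 20000, seed = 27,
                           group = "control")
  pops <- populations_with_fractions(cfg, list(
    progenitor_cd34pos_cd38pos = 0, lsc_cd34pos_cd38neg_cd26neg = 0))
  s <- simulate_sample(cfg, pops)
  deb <- gate_debris_free(s$em)
  g45 <- gate_cd45(s$em, deb$gate)
  g34 <- gate_cd34(s$em, g45$gate)
  expect_true(g34$trough$unimodal)
  expect_lte(g34$gate$count, 0.002 * g45$gate$count)
})

test_that("CD38 split partitions its parent and separates the compartments", {
  s <- quick_sample(seed = 28, n_events = 100000)
  rep <- run_gating_pipeline(s$em)
  expect_equal(rep$gates$CD38pos$count + rep$gates$LSC$count,
               rep$gates$CD34pos$count)
  lab <- s$truth$labels
  in_lsc_gate <- rep$gates$LSC$member
  is_prog <- lab == "progenitor_cd34pos_cd38pos"
  is_lsc <- lab %in% c("lsc_cd34pos_cd38neg_cd26neg",
                       "lsc_cd34pos_cd38neg_cd26pos")
  in_cd34 <- rep$gates$CD34pos$member
  mis <- (sum(is_prog & in_cd34 & in_lsc_gate) +
            sum(is_lsc & in_cd34 & !in_lsc_gate)) /
    sum((is_prog | is_lsc) & in_cd34)
  expect_lte(mis, 0.01)
})

test_that("a 10-event CD34 parent gets the flagged fallback split", {
  s <- quick_sample(seed = 29, n_events = 2000)
  fake_parent <- gate_result_for_test("CD34pos", "CD45pos",
                                      seq_len(2000) <= 10)
  sp <- split_cd38(s$em, fake_parent)
  expect_identical(sp$flags, "cd38_low_events")
  expect_equal(sp$cd38pos$count + sp$lsc$count, 10)
})

test_that("CD26 cutoff lands at the lymphocyte CD26 trough", {
  s <- quick_sample(seed = 30, n_events = 100000)
  deb <- gate_debris_free(s$em)
  cal <- cd26_cutoff_from_lymphocytes(s$em, deb$gate)
  tpl <- population_template_for_test()
  truth <- mixture_min(0.5,
                       tpl$location["lymphocyte_cd3pos_cd26neg", "CD26"],
                       tpl$spread["lymphocyte_cd3pos_cd26neg", "CD26"],
                       0.5,
                       tpl$location["lymphocyte_cd3pos_cd26pos", "CD26"],
                       tpl$spread["lymphocyte_cd3pos_cd26pos", "CD26"])
  expect_lt(abs(cal$cutoff - truth), 0.15)
  expect_gte(cal$cd3_gate$count, 50)
})

test_that("all-CD26-negative lymphocytes trigger the flagged calibration fallback", {
  cfg <- sample_sim_config(n_events = 20000, seed = 31, group = "control")
  pops <- populations_with_fractions(cfg, list(
    lymphocyte_cd3pos_cd26pos = 0, lymphocyte_cd3pos_cd26neg = 0.06))
  s <- simulate_sample(cfg, pops)
  deb <- gate_debris_free(s$em)
  cal <- cd26_cutoff_from_lymphocytes(s$em, deb$gate)
  expect_true("cd26_calibration_unimodal" %in% cal$flags)
  expect_true(is.finite(cal$cutoff))
})

test_that("CD26 calls are stable under a monotone rescaling of the raw CD26 axis", {
  s <- quick_sample(seed = 32, n_events = 50000)
  r1 <- run_gating_pipeline(s$em)
  # doubling raw CD26 shifts the arcsinh axis nonlinearly but preserves
  # event ranks; the recalibrated cutoff must separate the same events
  em2 <- s$em
  panel <- resolve_panel(s$em)
  em2$data[, panel[["CD26"]]] <- 2 * em2$data[, panel[["CD26"]]]
  r2 <- run_gating_pipeline(em2)
  expect_identical(r1$gates$LSC_CD26pos$member, r2$gates$LSC_CD26pos$member)
  expect_false(isTRUE(all.equal(r1$thresholds[["cd26"]],
                                r2$thresholds[["cd26"]])))
})

test_that("classify_cd26 partitions the LSC gate and finds pinned events", {
  cfg <- sample_sim_config(n_events = 100000, seed = 33,
                           target_pct_cd26_of_cd45 = 0.003,
                           min_cd26_events = 5)
  s <- simulate_sample(cfg)
  expect_identical(s$truth$n_cd26pos, 5L)
  rep <- run_gating_pipeline(s$em)
  expect_identical(rep$counts[["LSC_CD26pos"]], 5)
  expect_equal(rep$counts[["LSC_CD26pos"]] + rep$counts[["LSC_CD26neg"]],
               rep$counts[["LSC"]])
  # empty LSC parent: both children empty
  empty <- gate_result_for_test("LSC", "CD34pos", rep(FALSE, 100000))
  cls <- classify_cd26(s$em, empty, cutoff = 1.9)
  expect_identical(cls$cd26pos$count, 0L)
  expect_identical(cls$cd26neg$count, 0L)
})

test_that("the full pipeline is deterministic, nested and accurate", {
  s <- quick_sample(seed = 34, n_events = 100000)
  r1 <- run_gating_pipeline(s$em)
  r2 <- run_gating_pipeline(s$em)
  expect_identical(gating_report_json(r1), gating_report_json(r2))
  expect_nested_report(r1)
  p_hat <- 100 * r1$counts[["LSC_CD26pos"]] / r1$counts[["CD45pos"]]
  p <- s$truth$pct_cd26_of_cd45 / 100
  se <- 100 * sqrt(p * (1 - p) / s$truth$n_cd45)
  expect_lt(abs(p_hat - s$truth$pct_cd26_of_cd45), 3 * se)
})

test_that("gate membership is invariant under a common positive rescaling", {
  s <- quick_sample(seed = 35)
  r1 <- run_gating_pipeline(s$em)
  em2 <- s$em
  em2$data <- em2$data * 4
  # scatter thresholds are data-driven, fluorescence geometry preserved by
  # scaling the cofactor along with the intensities
  r2 <- run_gating_pipeline(em2, tcfg = transform_config(cofactor = 600))
  for (g in names(r1$gates)) {
    if (g %in% c("debris_free")) next  # linear-scatter gate moves with scale
    expect_identical(r1$gates[[g]]$count, r2$gates[[g]]$count,
                     info = g)
  }
})

test_that("a control sample yields zero CD26+ LSC calls", {
  s <- quick_sample(seed = 36, group = "control", n_events = 100000)
  rep <- run_gating_pipeline(s$em)
  expect_identical(rep$counts[["LSC_CD26pos"]], 0)
  expect_true(rep$cd26_available)
})
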