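# Shared fixtures: all synthetic, generated in code at test time.

# A quick mid-size acquisition (20k events keeps unit tests fast; the
# acceptance tests use the full 100k).
quick_sample <- function(seed = 1, group = "CML-diagnosis",
                         n_events = 20000, ...) {
  simulate_sample(sample_sim_config(n_events = n_events, group = group,
                                    seed = seed, ...))
}

# Small hand-built event matrix for I/O tests.
tiny_em <- function(n = 1000, seed = 42) {
  set.seed(seed)
  mat <- matrix(abs(rnorm(n * 7, mean = 500, sd = 200)), ncol = 7)
  event_matrix(mat, data.frame(
    index = 1:7,
    short_name = c("FS", "SS", "FL5", "FL4", "FL6", "FL2", "FL7"),
    marker = c("FSC", "SSC", "CD45 KrO", "CD34 PC7", "CD38 APC750",
               "CD26 PE", "CD3 PB"),
    range = rep(1048576, 7), stringsAsFactors = FALSE
  ), sample_id = "tiny")
}

# Population list with modified fractions (renormalized over granulocytes).
populations_with_fractions <- function(cfg, fractions) {
  pops <- default_populations(cfg)
  names(pops) <- vapply(pops, `[[`, character(1), "name")
  for (nm in names(fractions)) pops[[nm]]$fraction <- fractions[[nm]]
  tot <- sum(vapply(pops, `[[`, numeric(1), "fraction"))
  pops$granulocyte$fraction <- pops$granulocyte$fraction + (1 - tot)
  unname(pops)
}

population_template_for_test <- function() cd26lsc:::population_template()

gate_result_for_test <- function(name, parent, member) {
  cd26lsc:::gate_result(name, parent, member)
}

# Default records for quantify().
record_for <- function(em, wbc = 278000, group = "CML") {
  sample_record(em$sample_id, group = group,
                phase = if (group == "CML") "chronic" else "not-applicable",
                sokal = if (group == "CML") "intermediate" else
                  "not-applicable",
                timepoint = "diagnosis", wbc_per_ul = wbc)
}

# Assert the nesting chain of a gating report.
expect_nested_report <- function(rep) {
  g <- rep$gates
  chain <- list(
    c("CD45pos", "debris_free"),
    c("CD34pos", "CD45pos"),
    c("CD38pos", "CD34pos"),
    c("LSC", "CD34pos"))
  if (!is.null(g$LSC_CD26pos)) {
    chain <- c(chain, list(c("LSC_CD26pos", "LSC"), c("LSC_CD26neg", "LSC")))
  }
  for (pair in chain) {
    child <- g[[pair[1]]]
    parent <- g[[pair[2]]]
    expect_false(any(child$member & !parent$member),
                 label = paste(pair[1], "nested in", pair[2]))
  }
  expect_equal(g$CD38pos$count + g$LSC$count, g$CD34pos$count)
  if (!is.null(g$LSC_CD26pos)) {
    expect_equal(g$LSC_CD26pos$count + g$LSC_CD26neg$count, g$LSC$count)
  }
  invisible(rep)
}
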