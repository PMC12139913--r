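# Constructed PS / event fixtures with known tallies.

mk_report_fixture <- function() {
  ps <- data.table(
    group_id = "g.p1",
    transcript_id = paste0("t", 1:6),
    ps = c(1, -1, 2, 0, 0, -2),
    significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    direction = c("up", "down", "up", "none", "none", "down"))
  attrs <- data.table(
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g2"),
    transcript_id = paste0("t", 1:6),
    promoter_group = c(1L, 1L, 2L, 1L, 2L, 3L),
    ap = c(0, 0, 1, 0, 0.5, 1),
    ae = c(0, 1, 0, 0, 0, 0))
  event_ps <- data.table(
    event_id = c("e1", "e1", "e1", "e2", "e2", "e3", "e3"),
    gene_id = "g1", scope = "g1.p1",
    class = c("ce", "ce", "ce", "ir", "ir", "alt5", "alt5"),
    side = c("inclusion", "inclusion", "exclusion", "inclusion",
             "inclusion", "inclusion", "inclusion"),
    transcript_id = c("t1", "t2", "t3", "t3", "t4", "t5", "t6"),
    ps = c(1, -1, 2, 2, 0, 0, -2),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    direction = c("up", "down", "up", "up", "none", "none", "down"))
  list(ps = ps, attrs = attrs, event_ps = event_ps)
}

test_that("direction-by-class tallies and binomial p-values", {
  fx <- mk_report_fixture()
  rep <- report_direction_by_class(fx$event_ps)
  ce <- rep[class == "ce"]
  expect_equal(c(ce$up, ce$down, ce$unaffected), c(1L, 1L, 0L))
  expect_equal(ce$p_value, 1)           # 1 up vs 1 down
  ir <- rep[class == "ir"]
  expect_equal(c(ir$up, ir$down, ir$unaffected), c(1L, 0L, 1L))
  a5 <- rep[class == "alt5"]
  expect_equal(c(a5$up, a5$down, a5$unaffected), c(0L, 1L, 1L))
  # exclusion rows are not counted
  expect_equal(sum(rep$up + rep$down + rep$unaffected), 6L)
})

test_that("boundary-position report restricts to varying genes", {
  fx <- mk_report_fixture()
  rep <- report_boundary_position(fx$ps, fx$attrs)
  tss <- rep[boundary == "tss"]
  # both genes vary at the TSS: all 6 transcripts counted
  expect_equal(tss$affected_proximal + tss$affected_distal +
               tss$unaffected_proximal + tss$unaffected_distal, 6L)
  expect_equal(tss$affected_proximal, 2L)   # t1 (ap 0), t2 (ap 0)
  expect_equal(tss$affected_distal, 2L)     # t3 (ap 1), t6 (ap 1)
  # only g1 varies at the TES: 3 transcripts counted
  tes <- rep[boundary == "tes"]
  expect_equal(tes$affected_proximal + tes$affected_distal +
               tes$unaffected_proximal + tes$unaffected_distal, 3L)
  # adjusted p-values are Bonferroni over the two boundaries
  expect_equal(rep$p_adjusted, pmin(1, rep$p_value * 2))
})

test_that("promoter multiplicity report builds the 2x2 and survives degeneracy", {
  fx <- mk_report_fixture()
  rep <- report_promoter_multiplicity(fx$ps, fx$attrs)
  # t1,t2 share g1.p1 (multi); the other four are singletons
  expect_equal(rep$table["affected", "single"], 2L)   # t3, t6
  expect_equal(rep$table["affected", "multi"], 2L)    # t1, t2
  expect_equal(rep$table["unaffected", "single"], 2L) # t4, t5
  expect_equal(rep$table["unaffected", "multi"], 0L)
  expect_equal(rep$chi2$statistic,
               chi2_2x2_yates(rep$table)$statistic)
  # all-multi fixture: degenerate margin yields NULL tests, no error
  attrs2 <- copy(fx$attrs)[, promoter_group := 1L][, gene_id := "g1"]
  rep2 <- report_promoter_multiplicity(fx$ps, attrs2)
  expect_null(rep2$chi2)
  expect_null(rep2$fisher)
})

test_that("class composition report: counts, per-class Fisher, empty classes", {
  fx <- mk_report_fixture()
  expect_warning(rep <- report_class_composition(fx$event_ps),
                 "alt_pro")
  counts <- rep$counts
  expect_equal(counts[class == "ce", affected], 2L)
  expect_equal(counts[class == "ce", unaffected], 0L)
  expect_equal(counts[class == "alt_pro", affected + unaffected], 0L)
  # empty classes carry NA statistics, non-empty ones match fisher_2x2
  expect_true(is.na(counts[class == "alt_pro", p_value]))
  ce_tab <- matrix(c(2L, 0L, 2L, 2L), 2L, byrow = TRUE)
  expect_equal(counts[class == "ce", p_value], fisher_2x2(ce_tab)$p_value)
  # chi-squared runs over the non-empty classes only (3 rows -> df 2)
  expect_equal(rep$chi2$df, 2L)
})

test_that("end-to-end report runs on simulated data", {
  specs <- random_specs(6, seed = 701)
  sim <- generate_genes(specs, seed = 70)
  usage <- generate_usage_truth(sim$groups, p_diff = 0.5, seed = 71)
  cnt <- simulate_counts(usage, seed = 72)
  pr <- build_proportions(cnt$counts, cnt$design, cnt$clusters)
  cfg <- model_config(chains = 2L, burn_in = 300L, draws = 600L)
  fit <- fit_beta_model(pr, cfg)
  calls <- call_differential(fit, cfg = cfg)
  ps <- assign_ps(pr, calls)
  ann <- annotate_transcriptome(sim$genes)
  ep <- propagate_ps_to_events(ps, ann$events,
                               known_transcripts = ann$attributes$transcript_id)
  rep <- suppressWarnings(
    affected_vs_unaffected_report(ps, ep, ann$attributes))
  expect_named(rep, c("direction_by_class", "boundary_position",
                      "promoter_multiplicity", "class_composition"))
  expect_true(nrow(rep$direction_by_class) >= 1L)
  expect_equal(nrow(rep$boundary_position), 2L)
})
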