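# Shared small proportions fixture: direct Beta draws, no count simulation.
mk_props <- function(n_iso, draw_young, draw_aged, seed) {
  set.seed(seed)
  out <- vector("list", n_iso)
  for (k in seq_len(n_iso)) {
    out[[k]] <- data.table(
      gene_id = paste0("g", k), group_id = paste0("g", k, ".p1"),
      transcript_id = paste0("t", k),
      sample = c(paste0("y", 1:3), paste0("a", 1:3)),
      condition = rep(c("young", "aged"), each = 3L),
      proportion = pmin(0.999, pmax(0.001, c(draw_young(3L), draw_aged(3L)))))
  }
  rbindlist(out)
}

test_that("HPD interval equals brute-force shortest-window search", {
  set.seed(99)
  for (k in 1:50) {
    n <- sample(c(20L, 101L, 500L, 4999L), 1L)
    x <- switch(sample(3L, 1L), rnorm(n), rexp(n), c(rnorm(n %/% 2L),
                rnorm(n - n %/% 2L, 8)))
    for (mass in c(0.5, 0.9, 0.95)) {
      expect_equal(hpd_interval(x, mass), oracle_hpd(x, mass))
    }
  }
})

test_that("build_proportions normalizes, clips and filters groups", {
  counts <- data.table(transcript_id = c("t1", "t2", "t3"),
                       y1 = c(90, 10, 0), y2 = c(80, 20, 0),
                       a1 = c(50, 50, 0), a2 = c(40, 60, 0))
  design <- data.frame(sample = c("y1", "y2", "a1", "a2"),
                       condition = c("young", "young", "aged", "aged"))
  clusters <- data.table(transcript_id = c("t1", "t2", "t3"),
                         gene_id = c("g1", "g1", "g2"),
                         promoter_group = c(1L, 1L, 1L))
  expect_message(pr <- build_proportions(counts, design, clusters),
                 "g2")
  # the all-zero group g2 is excluded
  expect_false(any(pr$gene_id == "g2"))
  expect_equal(pr[transcript_id == "t1" & sample == "y1", proportion], 0.9)
  expect_true(all(pr$proportion >= 0.001 & pr$proportion <= 0.999))
  # unknown transcript errors
  counts_bad <- copy(counts)[1, transcript_id := "tX"]
  expect_error(build_proportions(counts_bad, design, clusters), "tX")
})

test_that("posterior mean recovers planted Beta usage levels", {
  cfg <- model_config(chains = 2L, burn_in = 500L, draws = 1500L)
  pr <- mk_props(30, function(n) rbeta(n, 12, 4),   # mean 0.75
                 function(n) rbeta(n, 4, 12), 321)  # mean 0.25
  fit <- fit_beta_model(pr, cfg)
  mu <- fit$units[, .(m = mean(mu_mean)), by = condition]
  expect_lt(abs(mu[condition == "young", m] - 0.75), 0.08)
  expect_lt(abs(mu[condition == "aged", m] - 0.25), 0.08)
  # chains mix: split-Rhat near 1, acceptance in the adapted band
  expect_true(all(fit$units$rhat < 1.1))
  expect_true(all(fit$units$acc_rate > 0.1 & fit$units$acc_rate < 0.6))
  # a clear 0.75 -> 0.25 shift is called significant and down
  calls <- call_differential(fit, cfg = cfg)
  expect_gt(mean(calls$significant & calls$direction == "down"), 0.9)
  expect_true(all(calls[significant == TRUE, hpd_low > 0 | hpd_high < 0]))
})

test_that("significance requires both HPD exclusion and probability criteria", {
  cfg <- model_config(chains = 2L, burn_in = 400L, draws = 1000L)
  pr <- mk_props(20, function(n) rbeta(n, 6, 6), function(n) rbeta(n, 6, 6),
                 555)
  fit <- fit_beta_model(pr, cfg)
  calls <- call_differential(fit, cfg = cfg)
  # decision rule is reproducible from the reported columns
  rule <- (calls$hpd_low > 0 | calls$hpd_high < 0) &
    pmax(calls$p_up, 1 - calls$p_up) > cfg$prob_threshold
  expect_equal(calls$significant, rule)
})

test_that("fits are reproducible for a fixed seed", {
  cfg <- model_config(chains = 2L, burn_in = 200L, draws = 400L)
  pr <- mk_props(5, function(n) rbeta(n, 6, 6), function(n) rbeta(n, 9, 3),
                 777)
  f1 <- fit_beta_model(pr, cfg)
  f2 <- fit_beta_model(pr, cfg)
  expect_identical(f1$mu_draws, f2$mu_draws)
})

test_that("PS assignment and event propagation", {
  pr <- mk_props(4, function(n) rep(0.4, n), function(n) rep(0.8, n), 1)
  cfg <- model_config(chains = 2L, burn_in = 200L, draws = 400L)
  fit <- fit_beta_model(pr, cfg)
  calls <- call_differential(fit, cfg = cfg)
  ps <- assign_ps(pr, calls)
  # PS is the log2 ratio of replicate-mean proportions
  expect_equal(ps$ps, rep(1, 4))
  events <- data.table(
    gene_id = "g1", scope = "g1.p1", class = "ce", chrom = "c",
    start = 1L, end = 2L, including = list(c("t1", "t2")),
    excluding = list("t3"), event_id = "g1.ce.1")
  ep <- propagate_ps_to_events(ps, events)
  expect_equal(nrow(ep), 3L)
  expect_setequal(ep[side == "inclusion", transcript_id], c("t1", "t2"))
  expect_equal(ep[side == "exclusion", transcript_id], "t3")
  # unknown transcript id in an event errors
  events_bad <- copy(events)[, including := list(list(c("t1", "zz")))]
  expect_error(propagate_ps_to_events(ps, events_bad,
                                      known_transcripts = ps$transcript_id),
               "zz")
})
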