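# Hand-built genes, one per event class, on both strands.

mk_tx <- function(id, strand, starts, ends) {
  transcript_model(id, "g", "chrT", strand,
                   data.frame(start = as.integer(starts),
                              end = as.integer(ends)))
}

test_that("alt5 donors are called at the short donor, both strands", {
  # plus: t1 donor at 200, t2 reads through to 210
  t1 <- mk_tx("t1", "+", c(100L, 400L), c(200L, 500L))
  t2 <- mk_tx("t2", "+", c(100L, 400L), c(210L, 500L))
  txs <- list(t1 = t1, t2 = t2)
  ev <- detect_alt5(build_profile(txs), txs)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 200L)
  expect_equal(ev$including[[1L]], "t1")
  expect_equal(ev$excluding[[1L]], "t2")
  # minus: transcription right-to-left; donor variation at exon *starts*
  m1 <- mk_tx("m1", "-", c(100L, 400L), c(200L, 500L))
  m2 <- mk_tx("m2", "-", c(100L, 390L), c(200L, 500L))
  txs <- list(m1 = m1, m2 = m2)
  evm <- detect_alt5(build_profile(txs), txs)
  expect_equal(nrow(evm), 1L)
  expect_equal(evm$start, 400L)
  expect_equal(evm$including[[1L]], "m1")
  # and no alt3 is falsely called for these structures
  expect_equal(nrow(detect_alt3(build_profile(txs), txs)), 0L)
})

test_that("alt3 acceptors are the strand mirror of alt5", {
  t1 <- mk_tx("t1", "+", c(100L, 400L), c(200L, 500L))
  t2 <- mk_tx("t2", "+", c(100L, 390L), c(200L, 500L))
  txs <- list(t1 = t1, t2 = t2)
  ev <- detect_alt3(build_profile(txs), txs)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 400L)
  expect_equal(ev$including[[1L]], "t1")
  expect_equal(ev$excluding[[1L]], "t2")
  expect_equal(nrow(detect_alt5(build_profile(txs), txs)), 0L)
  # mirrored structure on minus strand
  m1 <- mk_tx("m1", "-", c(100L, 400L), c(200L, 500L))
  m2 <- mk_tx("m2", "-", c(100L, 400L), c(210L, 500L))
  txs <- list(m1 = m1, m2 = m2)
  evm <- detect_alt3(build_profile(txs), txs)
  expect_equal(nrow(evm), 1L)
  expect_equal(evm$start, 200L)
})

test_that("donor steps coinciding with alternative ends are suppressed", {
  # t2 simply ends 10 nt later: a TES difference, not an alt5 donor
  t1 <- mk_tx("t1", "+", c(100L, 400L), c(200L, 500L))
  t2 <- mk_tx("t2", "+", c(100L, 400L), c(200L, 510L))
  txs <- list(t1 = t1, t2 = t2)
  ev <- detect_alt5(build_profile(txs), txs,
                    alt_end_positions = c(500, 510), window = 1L)
  expect_equal(nrow(ev), 0L)
})

test_that("cassette exons: interval, carriers, and terminal-exon guard", {
  t1 <- mk_tx("t1", "+", c(100L, 300L, 600L), c(200L, 350L, 700L))
  t2 <- mk_tx("t2", "+", c(100L, 600L), c(200L, 700L))
  txs <- list(t1 = t1, t2 = t2)
  ev <- detect_cassette(build_profile(txs), txs)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end), c(300L, 350L))
  expect_equal(ev$including[[1L]], "t1")
  expect_equal(ev$excluding[[1L]], "t2")
  # same interval but terminal in its only carrier: not a cassette
  t3 <- mk_tx("t3", "+", c(100L, 300L), c(200L, 350L))
  txs2 <- list(t3 = t3, t2 = t2)
  expect_equal(nrow(detect_cassette(build_profile(txs2), txs2)), 0L)
})

test_that("mutually exclusive exons yield two separate ce events", {
  t1 <- mk_tx("t1", "+", c(100L, 300L, 600L), c(200L, 350L, 700L))
  t2 <- mk_tx("t2", "+", c(100L, 400L, 600L), c(200L, 450L, 700L))
  txs <- list(t1 = t1, t2 = t2)
  ev <- detect_cassette(build_profile(txs), txs)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$start, c(300L, 400L))
  expect_equal(ev$end, c(350L, 450L))
})

test_that("retained introns: structural and coverage calls agree", {
  t1 <- mk_tx("t1", "+", c(100L, 300L), c(200L, 400L))
  t2 <- mk_tx("t2", "+", 100L, 400L)          # reads through the intron
  txs <- list(t1 = t1, t2 = t2)
  ev <- detect_retained_introns(build_profile(txs), txs)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end), c(201L, 299L))
  expect_equal(ev$including[[1L]], "t2")
  expect_equal(ev$excluding[[1L]], "t1")
  # an ir structure must not be reported as alt5/alt3
  expect_equal(nrow(detect_alt5(build_profile(txs), txs)), 0L)
  expect_equal(nrow(detect_alt3(build_profile(txs), txs)), 0L)
})

test_that("plain constitutive structures yield no events", {
  t1 <- mk_tx("t1", "+", c(100L, 300L), c(200L, 400L))
  t2 <- mk_tx("t2", "+", c(100L, 300L), c(200L, 400L))
  txs <- list(t1 = t1, t2 = t2)
  prof <- build_profile(txs)
  expect_equal(nrow(detect_alt5(prof, txs)), 0L)
  expect_equal(nrow(detect_alt3(prof, txs)), 0L)
  expect_equal(nrow(detect_cassette(prof, txs)), 0L)
  expect_equal(nrow(detect_retained_introns(prof, txs)), 0L)
})

test_that("detection matches the structural oracle on random genes", {
  sim <- generate_genes(random_specs(40, seed = 303), seed = 31)
  for (g in sim$genes) {
    det <- detected_key(annotate_gene(g)$events)
    ora <- oracle_gene_events(g)
    expect_equal(as.data.frame(det),
                 as.data.frame(ora[, .(class, start, end, inc, exc, scope)]),
                 info = g$gene_id)
  }
})
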