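# Brute-force ORF finder: enumerate every ATG..stop pair in all 3 frames.
oracle_orf <- function(seq, min_len = 30L) {
  n <- nchar(seq)
  best <- NULL
  for (a in seq_len(max(0L, n - 5L))) {
    if (substring(seq, a, a + 2L) != "ATG") next
    p <- a + 3L
    while (p + 2L <= n) {
      if (substring(seq, p, p + 2L) %in% c("TAA", "TAG", "TGA")) {
        len <- p + 2L - a + 1L
        if (is.null(best) || len > best$len ||
            (len == best$len && a < best$start)) {
          best <- list(start = a, end = p + 2L, len = len)
        }
        break
      }
      p <- p + 3L
    }
  }
  if (is.null(best) || best$len < min_len) {
    return(list(cds_start = NA_integer_, cds_end = NA_integer_,
                coding = FALSE))
  }
  list(cds_start = best$start, cds_end = best$end, coding = TRUE)
}

test_that("find_orf matches the exhaustive oracle on random sequences", {
  set.seed(1234)
  for (k in 1:200) {
    n <- sample(30:200, 1L)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    expect_identical(find_orf(s), oracle_orf(s), label = s)
  }
})

test_that("find_orf edge cases", {
  # no stop codon -> non-coding even with a long ATG run
  s <- paste0("ATG", strrep("CCG", 30))
  expect_false(find_orf(s)$coding)
  # below min_len -> non-coding; at min_len -> coding
  s30 <- paste0("ATG", strrep("CCG", 8), "TAA")   # 30 nt including stop
  expect_true(find_orf(s30, min_len = 30L)$coding)
  expect_false(find_orf(s30, min_len = 31L)$coding)
  # 5'-most start wins on equal length
  s2 <- paste0("ATGCCGTAA", "ATGGGGTAA")
  expect_equal(find_orf(s2, min_len = 9L)$cds_start, 1L)
})

test_that("transcript/genome coordinate mapping round-trips on both strands", {
  sim <- generate_genes(random_specs(4, seed = 601), seed = 61)
  for (g in sim$genes) {
    for (tx in g$transcripts) {
      L <- tx_length(tx)
      for (p in unique(c(1L, 2L, L %/% 2L, L - 1L, L))) {
        seg <- map_to_genome(c(p, p), tx)
        expect_equal(seg$start, seg$end)
        expect_equal(map_to_transcript(seg$start, tx), p)
      }
      # whole-transcript projection returns the exon blocks
      segs <- map_to_genome(c(1L, L), tx)
      expect_equal(sum(segs$end - segs$start + 1L), L)
    }
  }
  expect_error(map_to_genome(c(0L, 5L), sim$genes[[1L]]$transcripts[[1L]]),
               "outside")
})

test_that("planted ORFs are recovered and stop location classified", {
  for (strand in c("+", "-")) {
    spec <- synthetic_gene_spec("g1", strand, isoforms_per_promoter = 2,
                                event_classes = "ce")
    sim <- generate_genes(list(spec), seed = 71)
    gene <- sim$genes$g1
    fx <- generate_protein_fixtures(gene, seed = 5)
    carrier <- fx$planted$transcript_id
    rec <- fx$orfs[transcript_id == carrier]
    expect_equal(rec$cds_start, fx$planted$cds_start)
    expect_equal(rec$cds_end, fx$planted$cds_end)
    # no adenine background: every coding call is a planted ORF
    tx <- gene$transcripts[[carrier]]
    expect_equal(classify_stop_location(
      list(cds_start = rec$cds_start, cds_end = rec$cds_end, coding = TRUE),
      tx), "Last")
    # an upstream ORF ending before the terminal exon is NotLast
    genome <- synthesize_genome(gene, seed = 6)
    up <- plant_orf(genome, tx, n_codons = 10L, cds_start = 5L,
                    stop_in_last = FALSE, seed = 7)
    expect_equal(classify_stop_location(
      list(cds_start = up$cds_start, cds_end = up$cds_end, coding = TRUE),
      tx), "NotLast")
  }
})

test_that("event consequences: ORF overlap, domains, start/stop alteration", {
  for (strand in c("+", "-")) {
    spec <- synthetic_gene_spec("g1", strand, isoforms_per_promoter = 3,
                                event_classes = c("ce", "ir"))
    sim <- generate_genes(list(spec), seed = 77)
    gene <- sim$genes$g1
    ann <- annotate_gene(gene)
    ev <- ann$events[class == "ce"][1L]
    carrier <- ev$including[[1L]][1L]
    tx <- gene$transcripts[[carrier]]
    tpos <- min(map_to_transcript(ev$start, tx),
                map_to_transcript(ev$end, tx))
    genome <- synthesize_genome(gene, seed = 5)
    res <- plant_orf(genome, tx, n_codons = 60L,
                     cds_start = max(2L, tpos - 60L),
                     stop_in_last = FALSE, seed = 6)
    ids <- sort(names(gene$transcripts))
    seqs <- vapply(ids, function(id)
      transcript_sequence(gene$transcripts[[id]], res$genome), "")
    orfs <- rbindlist(lapply(ids, function(id) {
      o <- find_orf(seqs[[id]])
      data.table(transcript_id = id, cds_start = o$cds_start,
                 cds_end = o$cds_end, coding = o$coding)
    }))
    dom <- plant_domain(tx, res$cds_start, res$cds_end,
                        cover = c(ev$start, ev$end))
    expect_false(is.null(dom))
    cons <- classify_event_consequences(ann$events, orfs, dom,
                                        list(g1 = gene))
    ce_row <- cons[class == "ce"][1L]
    expect_true(ce_row$overlaps_orf)
    expect_equal(ce_row$domain_overlap, "DomX")
    expect_true(ce_row$alters_domain_start || ce_row$alters_domain_stop)
    # a domain planted away from the event does not overlap it
    dom2 <- plant_domain(tx, res$cds_start, res$cds_end,
                         avoid = c(ev$start, ev$end), domain = "DomY")
    if (!is.null(dom2)) {
      cons2 <- classify_event_consequences(ann$events, orfs, dom2,
                                           list(g1 = gene))
      expect_equal(cons2[class == "ce"][1L, domain_overlap], "")
    }
  }
})

test_that("domtbl and FASTA round trips", {
  d <- data.table(transcript_id = c("t1", "t2"), domain = c("PK", "ZF"),
                  accession = c("PF1.1", "PF2.2"), aa_from = c(3L, 10L),
                  aa_to = c(30L, 45L))
  f <- tempfile()
  write_domtbl(d, f)
  back <- read_domtbl(f)
  expect_equal(back$transcript_id, d$transcript_id)
  expect_equal(back$domain, d$domain)
  expect_equal(back$aa_from, d$aa_from)
  expect_equal(back$aa_to, d$aa_to)
  seqs <- c(t1 = "ACGTACGT", t2 = "GGGCCC")
  ff <- tempfile(fileext = ".fa")
  write_fasta(seqs, ff)
  expect_equal(read_fasta(ff), seqs)
})
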