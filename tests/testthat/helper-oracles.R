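# Independent oracles used by the tests. Everything here is computed from
# first principles (per-base scans, exhaustive enumeration, direct summation)
# without calling the package's own detection/statistics internals.

library(data.table)

# ---- per-base coverage oracle ----------------------------------------------

# Normalized coverage by brute-force base counting: for every base of the
# group span, the fraction of transcripts with an exon containing it.
oracle_coverage <- function(transcripts) {
  lo <- min(vapply(transcripts, function(t) min(t$exons$start), 0))
  hi <- max(vapply(transcripts, function(t) max(t$exons$end), 0))
  pos <- lo:hi
  cov <- numeric(length(pos))
  for (t in transcripts) {
    for (k in seq_len(nrow(t$exons))) {
      idx <- (t$exons$start[k]:t$exons$end[k]) - lo + 1L
      cov[idx] <- cov[idx] + 1
    }
  }
  list(pos = pos, coverage = cov / length(transcripts))
}

# ---- structural event oracle ------------------------------------------------

# Greedy boundary grouping in transcription order, written independently of
# the package's clustering (same +/-window rule).
oracle_group_tss <- function(transcripts, window = 1L) {
  ids <- names(transcripts)
  strand <- transcripts[[1L]]$strand
  tss <- vapply(transcripts, function(t)
    if (t$strand == "+") min(t$exons$start) else max(t$exons$end), 0)
  ord <- if (strand == "+") order(tss, ids) else order(-tss, ids)
  grp <- integer(length(ids)); founders <- numeric(0)
  for (i in ord) {
    hit <- which(abs(founders - tss[i]) <= window)
    if (length(hit)) grp[i] <- hit[1L]
    else { founders <- c(founders, tss[i]); grp[i] <- length(founders) }
  }
  split(ids, grp)
}

# All events of classes alt5/alt3/ce/ir derived purely from transcript
# structures of one scope group (no coverage profile).
oracle_scope_events <- function(transcripts, chrom, strand) {
  ev <- list()
  add <- function(class, s, e, inc, exc) {
    ev[[length(ev) + 1L]] <<- data.table(
      class = class, start = as.integer(s), end = as.integer(e),
      inc = paste(sort(inc), collapse = ","),
      exc = paste(sort(exc), collapse = ","))
  }
  exon_list <- lapply(transcripts, `[[`, "exons")
  intron_of <- function(ex) {
    if (nrow(ex) < 2L) return(ex[0, ])
    data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
  }
  ids <- names(transcripts)

  # donor/acceptor variation: exon boundary p interior to another exon
  for (tid in ids) {
    ex <- exon_list[[tid]]
    if (nrow(ex) < 2L) next
    for (k in seq_len(nrow(ex) - 1L)) {
      p <- ex$end[k]                      # junction start boundary (exon end)
      e1 <- ex$start[k + 1L] - 1L         # intron end
      # witness: another transcript exonic across [p, p+1] whose exon does
      # not read through the whole intron (that would be retention)
      wit <- ids[vapply(ids, function(o) {
        oe <- exon_list[[o]]
        any(oe$start <= p & oe$end >= p + 1L & oe$end <= e1)
      }, NA)]
      if (length(wit)) {
        cls <- if (strand == "+") "alt5" else "alt3"
        inc <- ids[vapply(ids, function(o) any(exon_list[[o]]$end == p), NA)]
        exc <- ids[vapply(ids, function(o)
          any(exon_list[[o]]$start <= p & exon_list[[o]]$end >= p + 1L), NA)]
        add(cls, p, p, inc, exc)
      }
      p2 <- ex$start[k + 1L]              # junction end boundary (exon start)
      s1 <- ex$end[k] + 1L                # intron start
      wit2 <- ids[vapply(ids, function(o) {
        oe <- exon_list[[o]]
        any(oe$start <= p2 - 1L & oe$end >= p2 & oe$start >= s1)
      }, NA)]
      if (length(wit2)) {
        cls <- if (strand == "+") "alt3" else "alt5"
        inc <- ids[vapply(ids, function(o) any(exon_list[[o]]$start == p2),
                          NA)]
        exc <- ids[vapply(ids, function(o)
          any(exon_list[[o]]$start <= p2 - 1L & exon_list[[o]]$end >= p2),
          NA)]
        add(cls, p2, p2, inc, exc)
      }
    }
  }
  # cassette exons: internal exon of one transcript inside an intron of
  # another
  for (tid in ids) {
    ex <- exon_list[[tid]]
    if (nrow(ex) < 3L) next
    for (k in 2:(nrow(ex) - 1L)) {
      s <- ex$start[k]; e <- ex$end[k]
      skip <- ids[vapply(ids, function(o) {
        io <- intron_of(exon_list[[o]])
        nrow(io) > 0L && any(io$start <= s & io$end >= e)
      }, NA)]
      if (length(skip)) {
        inc <- ids[vapply(ids, function(o)
          any(exon_list[[o]]$start <= e & exon_list[[o]]$end >= s), NA)]
        add("ce", s, e, inc, skip)
      }
    }
  }
  # retained introns: intron of one transcript inside a continuous exon of
  # another
  for (tid in ids) {
    io <- intron_of(exon_list[[tid]])
    if (nrow(io) == 0L) next
    for (k in seq_len(nrow(io))) {
      s <- io$start[k]; e <- io$end[k]
      spanners <- ids[vapply(setdiff(ids, tid), function(o)
        any(exon_list[[o]]$start <= s - 1L & exon_list[[o]]$end >= e + 1L),
        NA)]
      if (length(spanners)) {
        inc <- ids[vapply(ids, function(o)
          any(exon_list[[o]]$start <= s & exon_list[[o]]$end >= e), NA)]
        exc <- ids[vapply(ids, function(o) {
          oo <- intron_of(exon_list[[o]])
          nrow(oo) > 0L && any(oo$start <= s & oo$end >= e)
        }, NA)]
        add("ir", s, e, inc, exc)
      }
    }
  }
  if (length(ev) == 0L) {
    return(data.table(class = character(0), start = integer(0),
                      end = integer(0), inc = character(0),
                      exc = character(0)))
  }
  unique(rbindlist(ev))
}

# Full-gene structural oracle over promoter-group scopes (alt5/alt3/ce/ir
# only), comparable with the package's event table.
oracle_gene_events <- function(gene, window = 1L) {
  groups <- oracle_group_tss(gene$transcripts, window)
  if (length(groups) < 2L) groups <- list(`1` = names(gene$transcripts))
  out <- list()
  for (g in names(groups)) {
    e <- oracle_scope_events(gene$transcripts[groups[[g]]], gene$chrom,
                             gene$transcripts[[1L]]$strand)
    if (nrow(e)) {
      e[, scope := paste0(gene$gene_id, ".p", g)]
      out[[length(out) + 1L]] <- e
    }
  }
  if (length(out) == 0L) {
    return(data.table(class = character(0), start = integer(0),
                      end = integer(0), inc = character(0),
                      exc = character(0), scope = character(0)))
  }
  res <- rbindlist(out)
  setorder(res, class, start, end, scope)
  res[]
}

# Package event table reduced to the oracle's comparable shape.
detected_key <- function(events) {
  e <- events[class %in% c("alt5", "alt3", "ce", "ir"),
              .(class, start, end,
                inc = vapply(including, paste, "", collapse = ","),
                exc = vapply(excluding, paste, "", collapse = ","), scope)]
  setorder(e, class, start, end, scope)
  e[]
}

# ---- statistics oracles ------------------------------------------------------

# Exact two-sided binomial p under p0 = 1/2 by direct summation of point
# masses no larger than the observed one.
oracle_binomial_p <- function(k_up, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[k_up + 1L] * (1 + 1e-7)])
}

# Fisher exact two-sided p for a 2x2 table by hypergeometric enumeration.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  support <- max(0L, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  sum(d[d <= dhyper(tab[1L, 1L], m, n, k) * (1 + 1e-7)])
}

# Pearson chi-squared statistic from the definition.
oracle_chi2 <- function(tab, yates = FALSE) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - expected)
  if (yates) dev <- pmax(0, dev - 0.5)
  sum(dev^2 / expected)
}

# ---- HPD oracle --------------------------------------------------------------

# Shortest interval containing ceiling(mass * n) sorted draws, by exhaustive
# window search.
oracle_hpd <- function(x, mass = 0.95) {
  s <- sort(x)
  n <- length(s)
  w <- ceiling(mass * n)
  if (w >= n) return(c(s[1L], s[n]))
  widths <- s[w:n] - s[1:(n - w + 1L)]
  i <- which.min(widths)
  c(s[i], s[i + w - 1L])
}

# ---- shared fixtures ---------------------------------------------------------

# GTF text of a gene set, for whole-structure identity comparisons.
write_gtf_lines_for_test <- function(genes) {
  f <- tempfile(fileext = ".gtf")
  on.exit(unlink(f))
  write_gtf(genes, f)
  readLines(f)
}

# A deterministic random gene spec pool covering all classes and 2-6 isoforms.
random_specs <- function(n, seed) {
  set.seed(seed)
  pool <- c("alt5", "alt3", "ce", "ir", "alt_end")
  lapply(seq_len(n), function(k) {
    synthetic_gene_spec(
      sprintf("g%04d", k),
      strand = sample(c("+", "-"), 1L),
      n_promoters = sample(1:3, 1L),
      isoforms_per_promoter = sample(2:6, 1L),
      event_classes = sample(pool, sample.int(5L, 1L)))
  })
}
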