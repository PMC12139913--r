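# Splice-event detection from the normalized coverage profile.
#
# Six event classes are recognised: alternative promoters (alt_pro),
# alternative 5' donor sites (alt5), alternative 3' acceptor sites (alt3),
# cassette/alternative exons (ce), retained introns (ir) and alternative
# transcription end sites (alt_end). alt_pro and alt_end come from boundary
# clustering; the other four are read off steps, peaks and valleys of the
# coverage profile, with including/excluding transcript sets resolved against
# the transcript structures.

EVENT_CLASSES <- c("alt_pro", "alt5", "alt3", "ce", "ir", "alt_end")

event_row <- function(class, chrom, start, end, including, excluding) {
  data.table(class = class, chrom = chrom, start = as.integer(start),
             end = as.integer(end),
             including = list(sort(including)), excluding = list(sort(excluding)))
}

empty_events <- function() {
  data.table(class = character(0), chrom = character(0), start = integer(0),
             end = integer(0), including = list(), excluding = list())
}

# transcripts with an exon ending / starting exactly at p
txs_exon_end_at <- function(transcripts, p) {
  names(transcripts)[vapply(transcripts, function(t) any(t$exons$end == p),
                            NA)]
}
txs_exon_start_at <- function(transcripts, p) {
  names(transcripts)[vapply(transcripts, function(t) any(t$exons$start == p),
                            NA)]
}
# transcripts with a single exon covering the whole interval [s, e]
txs_exon_covering <- function(transcripts, s, e) {
  names(transcripts)[vapply(transcripts, function(t)
    any(t$exons$start <= s & t$exons$end >= e), NA)]
}
# transcripts with any exonic overlap with [s, e]
txs_exon_overlapping <- function(transcripts, s, e) {
  names(transcripts)[vapply(transcripts, function(t)
    any(t$exons$start <= e & t$exons$end >= s), NA)]
}
# transcripts with an intron containing the whole interval [s, e]
txs_intron_containing <- function(transcripts, s, e) {
  names(transcripts)[vapply(transcripts, function(t) {
    intr <- tx_introns(t)
    nrow(intr) > 0L && any(intr$start <= s & intr$end >= e)
  }, NA)]
}

near_any <- function(pos, positions, window) {
  length(positions) > 0L && any(abs(positions - pos) <= window)
}

#' Detect alternative 5' splice sites (donor variation)
#'
#' Scans the coverage profile in transcription orientation for stepwise drops
#' inside exonic territory: a base whose coverage is lower than the preceding
#' base (5'->3') marks a donor used by a subset of transcripts while others
#' read through. Steps that fall into a valley (ordinary exon/intron borders),
#' and steps coinciding with an alternative transcript end position, are
#' discarded.
#'
#' @param profile A `coverage_profile`.
#' @param transcripts The transcript group the profile was built from.
#' @param alt_end_positions Genomic TES positions to exclude (used when the
#'   gene has more than one end cluster); candidates within `window` nt of any
#'   of these are dropped.
#' @param window Coincidence window in nt (same as the clustering window).
#' @return Event table (class `alt5`); `including` holds transcripts whose
#'   exon ends at the donor coordinate, `excluding` those reading through.
#' @export
detect_alt5 <- function(profile, transcripts, alt_end_positions = numeric(0),
                        window = 1L) {
  runs <- profile$runs
  out <- list()
  nr <- nrow(runs)
  if (nr < 2L) return(empty_events())
  for (i in seq_len(nr - 1L)) {
    v1 <- runs$value[i]; v2 <- runs$value[i + 1L]
    if (profile$strand == "+") {
      # drop moving 5'->3'; lower run must be exonic territory, not a valley
      if (!(v2 < v1) || runs$is_valley[i + 1L]) next
      p <- runs$end[i]                      # donor: last high base
      inc <- txs_exon_end_at(transcripts, p)
      exc <- txs_exon_covering(transcripts, p, p + 1L)
    } else {
      # minus strand: transcription runs right-to-left, a donor drop appears
      # as a rise in genomic orientation
      if (!(v1 < v2) || runs$is_valley[i]) next
      p <- runs$start[i + 1L]               # donor: first high base
      inc <- txs_exon_start_at(transcripts, p)
      exc <- txs_exon_covering(transcripts, p - 1L, p)
    }
    if (near_any(p, alt_end_positions, window)) next
    if (length(inc) == 0L || length(exc) == 0L) next
    out[[length(out) + 1L]] <- event_row("alt5", profile$chrom, p, p, inc, exc)
  }
  if (length(out)) rbindlist(out) else empty_events()
}

#' Detect alternative 3' splice sites (acceptor variation)
#'
#' Mirror image of [detect_alt5()]: stepwise rises inside exonic territory
#' mark an acceptor at which a subset of transcripts begins an exon while
#' others carry extra upstream exonic sequence. Rises out of valleys (ordinary
#' intron/exon borders) are skipped, and candidates coinciding with an
#' alternative promoter (TSS cluster) position are not counted.
#'
#' @inheritParams detect_alt5
#' @param alt_pro_positions Genomic TSS cluster positions to exclude.
#' @return Event table (class `alt3`); `including` holds transcripts whose
#'   exon starts at the acceptor coordinate, `excluding` the read-through set.
#' @export
detect_alt3 <- function(profile, transcripts, alt_pro_positions = numeric(0),
                        window = 1L) {
  runs <- profile$runs
  out <- list()
  nr <- nrow(runs)
  if (nr < 2L) return(empty_events())
  for (i in seq_len(nr - 1L)) {
    v1 <- runs$value[i]; v2 <- runs$value[i + 1L]
    if (profile$strand == "+") {
      # rise moving 5'->3' whose low side is exonic (not a valley)
      if (!(v1 < v2) || runs$is_valley[i]) next
      p <- runs$start[i + 1L]               # acceptor: first high base
      inc <- txs_exon_start_at(transcripts, p)
      exc <- txs_exon_covering(transcripts, p - 1L, p)
    } else {
      if (!(v2 < v1) || runs$is_valley[i + 1L]) next
      p <- runs$end[i]                      # acceptor: last high base
      inc <- txs_exon_end_at(transcripts, p)
      exc <- txs_exon_covering(transcripts, p, p + 1L)
    }
    if (near_any(p, alt_pro_positions, window)) next
    if (length(inc) == 0L || length(exc) == 0L) next
    out[[length(out) + 1L]] <- event_row("alt3", profile$chrom, p, p, inc, exc)
  }
  if (length(out)) rbindlist(out) else empty_events()
}

#' Detect cassette (alternative) exons
#'
#' A cassette exon shows as an internal sub-maximum coverage peak (height
#' below 1) flanked by pronounced valleys on both sides. First and last exons
#' are excluded so that promoter/end variation is not misread as exon
#' skipping; a candidate is kept only if at least one transcript carries the
#' exon internally. Mutually exclusive exons emerge as two separate `ce`
#' events.
#'
#' @inheritParams detect_alt5
#' @param height_tol A peak counts as sub-maximal when its height is below
#'   `1 - height_tol` (float safety, default 1e-6).
#' @param valley_drop Flanking valleys must lie at least this much below the
#'   peak height to count as pronounced (default 0.1 of normalized coverage).
#' @return Event table (class `ce`) with the exon interval; `including` are
#'   transcripts carrying the exon, `excluding` transcripts splicing it out.
#' @export
detect_cassette <- function(profile, transcripts, height_tol = 1e-6,
                            valley_drop = 0.1) {
  runs <- profile$runs
  peaks <- profile$peaks
  out <- list()
  if (nrow(peaks) == 0L) return(empty_events())
  for (k in seq_len(nrow(peaks))) {
    h <- peaks$height[k]
    if (h >= 1 - height_tol) next
    i <- peaks$run[k]
    left <- runs[run < i & is_valley == TRUE]
    right <- runs[run > i & is_valley == TRUE]
    if (nrow(left) == 0L || nrow(right) == 0L) next
    lv <- left[.N]; rv <- right[1L]
    if (!(lv$value < h - valley_drop && rv$value < h - valley_drop)) next
    s <- peaks$start[k]; e <- peaks$end[k]
    inc <- txs_exon_overlapping(transcripts, s, e)
    exc <- txs_intron_containing(transcripts, s, e)
    if (length(inc) == 0L || length(exc) == 0L) next
    # require the exon to be internal in at least one carrier (not a
    # promoter- or end-exon artifact)
    internal <- vapply(transcripts[inc], function(t) {
      ov <- which(t$exons$start <= e & t$exons$end >= s)
      any(ov > 1L & ov < nrow(t$exons))
    }, NA)
    if (!any(internal)) next
    out[[length(out) + 1L]] <- event_row("ce", profile$chrom, s, e, inc, exc)
  }
  if (length(out)) rbindlist(out) else empty_events()
}

#' Detect retained introns
#'
#' Union of two complementary calls: (a) structural -- an intron of one
#' transcript fully contained within a single exon of another transcript; and
#' (b) coverage -- a valley interval of the profile whose coverage is above
#' zero (some transcript is exonic across a normally intronic span).
#'
#' @inheritParams detect_alt5
#' @return Event table (class `ir`) with intron intervals; `including` are
#'   transcripts whose exon spans the intron, `excluding` transcripts that
#'   splice it out.
#' @export
detect_retained_introns <- function(profile, transcripts) {
  cand <- list()
  # structural: introns of one transcript inside a continuous exon of another
  for (tx in transcripts) {
    intr <- tx_introns(tx)
    if (nrow(intr) == 0L) next
    for (k in seq_len(nrow(intr))) {
      s <- intr$start[k]; e <- intr$end[k]
      others <- transcripts[setdiff(names(transcripts), tx$transcript_id)]
      if (length(others) == 0L) next
      spanned <- vapply(others, function(o)
        any(o$exons$start <= s - 1L & o$exons$end >= e + 1L), NA)
      if (any(spanned)) cand[[length(cand) + 1L]] <- c(s, e)
    }
  }
  # coverage: valleys with non-zero mean coverage
  val <- profile$valleys
  if (nrow(val) > 0L) {
    nz <- val[value > 0]
    if (nrow(nz) > 0L) {
      for (k in seq_len(nrow(nz))) {
        cand[[length(cand) + 1L]] <- c(nz$start[k], nz$end[k])
      }
    }
  }
  if (length(cand) == 0L) return(empty_events())
  ivs <- unique(do.call(rbind, cand))
  ivs <- ivs[order(ivs[, 1L], ivs[, 2L]), , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(ivs))) {
    s <- ivs[k, 1L]; e <- ivs[k, 2L]
    inc <- txs_exon_covering(transcripts, s, e)
    exc <- txs_intron_containing(transcripts, s, e)
    if (length(inc) == 0L) inc <- txs_exon_overlapping(transcripts, s, e)
    if (length(inc) == 0L || length(exc) == 0L) next
    out[[length(out) + 1L]] <- event_row("ir", profile$chrom, s, e, inc, exc)
  }
  if (length(out)) rbindlist(out) else empty_events()
}
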