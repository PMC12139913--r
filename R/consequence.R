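# Functional consequence classification: ORFs, stop-codon location, and
# Pfam-domain overlap/start/stop alteration by splicing event.

STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1L]]),
                                     collapse = ""), ""))
}

#' Spliced transcript sequence from a genome
#'
#' @param tx A `transcript_model`.
#' @param genome List with `offset` (genomic coordinate of the first base) and
#'   `bases` (character vector of single bases), as from
#'   [synthesize_genome()].
#' @return Character scalar: exon sequence in transcription orientation
#'   (reverse-complemented for minus-strand transcripts).
#' @export
transcript_sequence <- function(tx, genome) {
  seqs <- apply(tx$exons, 1L, function(iv) {
    paste(genome$bases[(iv[1L]:iv[2L]) - genome$offset + 1L], collapse = "")
  })
  s <- paste(seqs, collapse = "")
  if (tx$strand == "-") unname(revcomp(s)) else s
}

#' Find the open reading frame of a transcript sequence
#'
#' Returns the longest ATG-initiated ORF terminating at an in-frame stop codon
#' across the three forward frames (ties resolved to the 5'-most start). ORF
#' length counts ATG through the stop codon inclusive.
#'
#' @param seq Character scalar (ACGT).
#' @param min_len Minimum ORF length in nt including the stop (default 30);
#'   shorter ORFs flag the transcript non-coding.
#' @return List: `cds_start`, `cds_end` (1-based transcript coordinates,
#'   stop codon included), `coding` (logical). Non-coding: coding = FALSE and
#'   NA coordinates.
#' @export
find_orf <- function(seq, min_len = 30L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- NULL
  if (n >= 6L) {
    codon_at <- substring(seq, seq_len(n - 2L), seq_len(n - 2L) + 2L)
    for (frame in 0:2) {
      pos <- seq.int(1L + frame, n - 2L, by = 3L)
      if (length(pos) == 0L) next
      cods <- codon_at[pos]
      atg <- pos[cods == "ATG"]
      stp <- pos[cods %in% STOP_CODONS]
      if (length(atg) == 0L || length(stp) == 0L) next
      for (a in atg) {
        s <- stp[stp > a]
        if (length(s) == 0L) next
        s <- s[1L]
        len <- s + 2L - a + 1L
        if (is.null(best) || len > best$len ||
            (len == best$len && a < best$start)) {
          best <- list(start = a, end = s + 2L, len = len)
        }
      }
    }
  }
  if (is.null(best) || best$len < min_len) {
    return(list(cds_start = NA_integer_, cds_end = NA_integer_,
                coding = FALSE))
  }
  list(cds_start = best$start, cds_end = best$end, coding = TRUE)
}

# Cumulative exon widths in transcription order.
tx_exon_cumlens <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  w <- ex$end - ex$start + 1L
  list(exons = ex, cum_end = cumsum(w), cum_start = cumsum(w) - w + 1L)
}

#' Project a transcript-coordinate interval onto the genome
#'
#' Strand-aware projection through the exon blocks: returns one genomic
#' segment per exon crossed, in transcription order; segment lengths sum to
#' the interval length.
#'
#' @param interval Integer `c(from, to)` in 1-based transcript coordinates.
#' @param tx A `transcript_model`.
#' @return data.frame with `start`, `end` (genomic, start <= end per segment).
#' @export
map_to_genome <- function(interval, tx) {
  from <- interval[1L]; to <- interval[2L]
  L <- tx_length(tx)
  if (from < 1L || to > L || from > to) {
    stop("interval [", from, ", ", to, "] outside transcript length ", L)
  }
  cl <- tx_exon_cumlens(tx)
  segs <- list()
  for (k in seq_len(nrow(cl$exons))) {
    lo <- max(from, cl$cum_start[k]); hi <- min(to, cl$cum_end[k])
    if (lo > hi) next
    if (tx$strand == "+") {
      gs <- cl$exons$start[k] + (lo - cl$cum_start[k])
      ge <- cl$exons$start[k] + (hi - cl$cum_start[k])
    } else {
      gs <- cl$exons$end[k] - (hi - cl$cum_start[k])
      ge <- cl$exons$end[k] - (lo - cl$cum_start[k])
    }
    segs[[length(segs) + 1L]] <- c(gs, ge)
  }
  out <- do.call(rbind, segs)
  data.frame(start = out[, 1L], end = out[, 2L])
}

#' Map a genomic position to transcript coordinates
#'
#' Inverse of [map_to_genome()] for a single exonic position.
#'
#' @param gpos Genomic position (must fall inside an exon).
#' @param tx A `transcript_model`.
#' @return 1-based transcript coordinate.
#' @export
map_to_transcript <- function(gpos, tx) {
  cl <- tx_exon_cumlens(tx)
  for (k in seq_len(nrow(cl$exons))) {
    if (gpos >= cl$exons$start[k] && gpos <= cl$exons$end[k]) {
      off <- if (tx$strand == "+") gpos - cl$exons$start[k]
             else cl$exons$end[k] - gpos
      return(cl$cum_start[k] + off)
    }
  }
  stop("position ", gpos, " is not exonic in ", tx$transcript_id)
}

#' Classify a stop codon as falling in the last exon or upstream
#'
#' "Last" iff the final base of the stop codon maps into the transcript's
#' terminal exon in transcription orientation (3'-most exon; the first genomic
#' exon for minus-strand transcripts).
#'
#' @param orf Result of [find_orf()].
#' @param tx A `transcript_model`.
#' @return "Last", "NotLast", or NA for non-coding transcripts.
#' @export
classify_stop_location <- function(orf, tx) {
  if (!isTRUE(orf$coding)) return(NA_character_)
  g <- map_to_genome(c(orf$cds_end, orf$cds_end), tx)
  last <- tx_last_exon(tx)
  if (g$start[1L] >= last$start && g$end[1L] <= last$end) "Last" else "NotLast"
}

# Genomic segments of a domain hit (aa coordinates within the CDS).
domain_genomic_segments <- function(aa_from, aa_to, cds_start, tx) {
  nt_from <- cds_start + 3L * (aa_from - 1L)
  nt_to <- cds_start + 3L * aa_to - 1L
  map_to_genome(c(nt_from, nt_to), tx)
}

segments_overlap <- function(segs, s, e) {
  any(segs$start <= e & segs$end >= s)
}

#' Classify functional consequences of splicing events
#'
#' For each event, tests genomic overlap with the ORFs (CDS projections) of
#' the transcripts that carry it, locates stop codons relative to the event
#' span and the terminal exon, and flags Pfam-domain overlap and domain
#' start/stop alteration (event span overlapping the genomic projection of a
#' domain's first/last codon).
#'
#' @param events Event table from [annotate_transcriptome()].
#' @param orfs data.table: transcript_id, cds_start, cds_end, coding (as from
#'   [find_orf()] applied per transcript, or an ingested prediction table).
#' @param domains data.table: transcript_id, domain, aa_from, aa_to (as from
#'   [read_domtbl()]).
#' @param genes Named list of `gene_model` objects covering the events.
#' @return data.table: event_id, class, overlaps_orf, contains_stop,
#'   stop_last_exon, domain_overlap (comma-joined ids), alters_domain_start,
#'   alters_domain_stop.
#' @export
classify_event_consequences <- function(events, orfs, domains, genes) {
  orfs <- as.data.table(orfs)
  domains <- if (is.null(domains)) {
    data.table(transcript_id = character(0), domain = character(0),
               aa_from = integer(0), aa_to = integer(0))
  } else as.data.table(domains)
  all_tx <- list()
  for (g in genes) all_tx[names(g$transcripts)] <- g$transcripts
  out <- list()
  for (k in seq_len(nrow(events))) {
    carriers <- events$including[[k]]
    s <- events$start[k]; e <- events$end[k]
    overlaps_orf <- FALSE; contains_stop <- FALSE
    stop_last <- NA_character_
    dom_hits <- character(0)
    alt_start <- FALSE; alt_stop <- FALSE
    for (tid in carriers) {
      tx <- all_tx[[tid]]
      o <- orfs[transcript_id == tid]
      if (nrow(o) == 0L || !isTRUE(o$coding[1L])) next
      cds_segs <- map_to_genome(c(o$cds_start[1L], o$cds_end[1L]), tx)
      if (segments_overlap(cds_segs, s, e)) overlaps_orf <- TRUE
      stop_segs <- map_to_genome(c(o$cds_end[1L] - 2L, o$cds_end[1L]), tx)
      if (segments_overlap(stop_segs, s, e)) contains_stop <- TRUE
      if (is.na(stop_last)) {
        stop_last <- classify_stop_location(
          list(cds_start = o$cds_start[1L], cds_end = o$cds_end[1L],
               coding = TRUE), tx)
      }
      dh <- domains[transcript_id == tid]
      if (nrow(dh)) {
        for (j in seq_len(nrow(dh))) {
          segs <- domain_genomic_segments(dh$aa_from[j], dh$aa_to[j],
                                          o$cds_start[1L], tx)
          if (segments_overlap(segs, s, e)) {
            dom_hits <- union(dom_hits, dh$domain[j])
            first_cod <- domain_genomic_segments(dh$aa_from[j], dh$aa_from[j],
                                                 o$cds_start[1L], tx)
            last_cod <- domain_genomic_segments(dh$aa_to[j], dh$aa_to[j],
                                                o$cds_start[1L], tx)
            if (segments_overlap(first_cod, s, e)) alt_start <- TRUE
            if (segments_overlap(last_cod, s, e)) alt_stop <- TRUE
          }
        }
      }
    }
    out[[k]] <- data.table(
      event_id = events$event_id[k], class = events$class[k],
      overlaps_orf = overlaps_orf, contains_stop = contains_stop,
      stop_last_exon = stop_last,
      domain_overlap = paste(sort(dom_hits), collapse = ","),
      alters_domain_start = alt_start, alters_domain_stop = alt_stop)
  }
  rbindlist(out)
}

#' Read a domtblout-style domain hit table
#'
#' Whitespace-delimited table in the column layout of hmmsearch --domtblout:
#' target (protein/transcript) name in column 1, query (domain) name in
#' column 4, accession in column 5, envelope coordinates in columns 20-21.
#' Comment lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return data.table: transcript_id, domain, accession, aa_from, aa_to.
#' @export
read_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.table(transcript_id = character(0), domain = character(0),
                      accession = character(0), aa_from = integer(0),
                      aa_to = integer(0)))
  }
  f <- strsplit(trimws(lines), "[ \t]+")
  data.table(
    transcript_id = vapply(f, `[`, "", 1L),
    domain = vapply(f, `[`, "", 4L),
    accession = vapply(f, `[`, "", 5L),
    aa_from = as.integer(vapply(f, `[`, "", 20L)),
    aa_to = as.integer(vapply(f, `[`, "", 21L))
  )
}

#' Write a domtblout-style domain table
#'
#' @param domains data.table: transcript_id, domain, accession, aa_from,
#'   aa_to (and optionally tlen).
#' @param path Output path.
#' @export
write_domtbl <- function(domains, path) {
  d <- as.data.table(domains)
  if (!"tlen" %in% names(d)) d[, tlen := aa_to + 10L]
  lines <- c(
    "# target name accession tlen query name accession qlen E-value score bias # of c-Evalue i-Evalue score bias hmm_from hmm_to ali_from ali_to env_from env_to acc description",
    sprintf(paste("%s - %d %s %s %d 1e-10 50.0 0.1 1 1 1e-10 1e-10 50.0 0.1",
                  "1 %d %d %d %d %d 0.95 -"),
            d$transcript_id, d$tlen, d$domain, d$accession,
            d$aa_to - d$aa_from + 1L, d$aa_to - d$aa_from + 1L,
            d$aa_from, d$aa_to, d$aa_from, d$aa_to))
  writeLines(lines, path)
  invisible(path)
}

#' Write transcript sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(names(seqs), function(nm) c(paste0(">", nm),
                                                     seqs[[nm]])))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file of transcript sequences
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}
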