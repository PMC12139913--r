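# Synthetic genome sequence with plantable ORFs and protein domains.
#
# The background alphabet is {C, G, T}: with no adenine in the background,
# neither start codons (ATG) nor stop codons (TAA/TAG/TGA, all containing A)
# can occur by chance, so the only ORFs present are the planted ones. Codons
# free of A are used for ORF interiors so no premature stop can arise.

# the 27 A-free codons (interior codons; none is a stop, TGG/ATG impossible
# to create accidentally since ATG contains A)
AFREE_CODONS <- as.vector(outer(
  as.vector(outer(c("C", "G", "T"), c("C", "G", "T"), paste0)),
  c("C", "G", "T"), paste0))

#' Synthesize a background genome over a gene span
#'
#' @param gene A `gene_model`; sequence covers its full genomic span.
#' @param seed Integer seed.
#' @param pad Extra bases on each side (default 10).
#' @return List with `offset` (genomic coordinate of the first base), `bases`
#'   (character vector of single bases) and `chrom`.
#' @export
synthesize_genome <- function(gene, seed, pad = 10L) {
  set.seed(seed)
  lo <- min(vapply(gene$transcripts, function(t) min(t$exons$start), 0)) - pad
  hi <- max(vapply(gene$transcripts, function(t) max(t$exons$end), 0)) + pad
  n <- hi - lo + 1L
  list(offset = as.integer(lo), chrom = gene$chrom,
       bases = sample(c("C", "G", "T"), n, replace = TRUE))
}

# Write a transcript-orientation sequence into the genome along a transcript.
# positions: transcript coordinates; chars: bases in transcription orientation.
write_tx_bases <- function(genome, tx, from, chars) {
  n <- length(chars)
  segs <- map_to_genome(c(from, from + n - 1L), tx)
  idx <- unlist(lapply(seq_len(nrow(segs)), function(k) {
    if (tx$strand == "+") segs$start[k]:segs$end[k]
    else segs$end[k]:segs$start[k]
  }))
  if (tx$strand == "-") chars <- chartr("ACGT", "TGCA", chars)
  genome$bases[idx - genome$offset + 1L] <- chars
  genome
}

#' Plant an open reading frame along a transcript
#'
#' Writes `ATG`, `n_codons` A-free interior codons and a `TAA` stop into the
#' genome so that the transcript translates to a single unambiguous ORF.
#'
#' @param genome Genome from [synthesize_genome()].
#' @param tx A `transcript_model` whose exons lie within the genome.
#' @param n_codons Number of interior codons (protein length is
#'   `n_codons + 1` aa counting the initiator Met).
#' @param cds_start Transcript coordinate of the A of ATG (default 11).
#' @param stop_in_last If TRUE (default) the stop codon is placed so its final
#'   base falls in the transcript's terminal exon: `cds_start` is chosen so
#'   that the stop lands `5` nt into the last exon when possible. If FALSE the
#'   caller's `cds_start` is honoured and the stop may fall upstream.
#' @param seed Seed for the interior codon draw.
#' @return List with the updated `genome`, and `cds_start`, `cds_end`
#'   (transcript coordinates, stop included).
#' @export
plant_orf <- function(genome, tx, n_codons = 40L, cds_start = 11L,
                      stop_in_last = TRUE, seed = 1L) {
  set.seed(seed)
  L <- tx_length(tx)
  orf_len <- 3L * (n_codons + 2L)   # ATG + interior + stop
  if (stop_in_last) {
    cl <- tx_exon_cumlens(tx)
    last_start <- cl$cum_start[length(cl$cum_start)]
    # put the stop's final base 5 nt into the last exon when reachable
    target_end <- min(L, last_start + 5L)
    cds_start <- target_end - orf_len + 1L
    if (cds_start < 1L) stop("transcript too short for requested ORF")
  }
  cds_end <- cds_start + orf_len - 1L
  if (cds_end > L) stop("ORF runs past the transcript end")
  chars <- strsplit(paste0(
    "ATG", paste(sample(AFREE_CODONS, n_codons, replace = TRUE),
                 collapse = ""), "TAA"), "")[[1L]]
  genome <- write_tx_bases(genome, tx, cds_start, chars)
  list(genome = genome, cds_start = cds_start, cds_end = cds_end)
}

#' Plan a protein domain within a planted ORF
#'
#' Chooses an amino-acid interval inside the CDS, optionally constrained to
#' cover or avoid a genomic target interval (e.g. a splicing event span).
#'
#' @param tx A `transcript_model`.
#' @param cds_start,cds_end Transcript coordinates of the planted ORF.
#' @param cover Optional genomic interval `c(s, e)` the domain must overlap.
#' @param avoid Optional genomic interval the domain must not overlap.
#' @param width Domain width in aa (default 10).
#' @param domain,accession Identifiers for the emitted hit.
#' @return One-row data.table: transcript_id, domain, accession, aa_from,
#'   aa_to (or NULL if no placement satisfies the constraints).
#' @export
plant_domain <- function(tx, cds_start, cds_end, cover = NULL, avoid = NULL,
                         width = 10L, domain = "DomX",
                         accession = "PF99999.1") {
  n_aa <- (cds_end - cds_start + 1L) %/% 3L - 1L   # exclude the stop
  for (aa_from in seq_len(max(0L, n_aa - width + 1L))) {
    aa_to <- aa_from + width - 1L
    segs <- domain_genomic_segments(aa_from, aa_to, cds_start, tx)
    ok <- TRUE
    if (!is.null(cover) && !segments_overlap(segs, cover[1L], cover[2L])) {
      ok <- FALSE
    }
    if (ok && !is.null(avoid) &&
        segments_overlap(segs, avoid[1L], avoid[2L])) {
      ok <- FALSE
    }
    if (ok) {
      return(data.table(transcript_id = tx$transcript_id, domain = domain,
                        accession = accession, aa_from = aa_from,
                        aa_to = aa_to))
    }
  }
  NULL
}

#' Generate a coding fixture for one gene
#'
#' Builds a background genome and plants one ORF along a single designated
#' transcript (transcripts overlap genomically, so planting along several at
#' once would let later writes corrupt earlier ORFs). Every transcript's
#' spliced sequence is then read back from the shared genome and its ORF
#' recovered with [find_orf()]; the recovered table -- not the plant plan --
#' is the coding truth used downstream.
#'
#' @param gene A `gene_model`.
#' @param seed Integer seed.
#' @param carrier Transcript id to plant the ORF on (default: first id in
#'   sorted order).
#' @param n_codons Interior codons for the planted ORF.
#' @param stop_in_last Passed to [plant_orf()].
#' @return List: `genome`, `sequences` (named character), `orfs` (data.table
#'   transcript_id/cds_start/cds_end/coding for every transcript), `planted`
#'   (carrier id plus the intended transcript coordinates, for verification).
#' @export
generate_protein_fixtures <- function(gene, seed, carrier = NULL,
                                      n_codons = 40L, stop_in_last = TRUE) {
  genome <- synthesize_genome(gene, seed)
  ids <- sort(names(gene$transcripts))
  if (is.null(carrier)) carrier <- ids[1L]
  if (!carrier %in% ids) stop("unknown carrier transcript: ", carrier)
  res <- plant_orf(genome, gene$transcripts[[carrier]], n_codons = n_codons,
                   stop_in_last = stop_in_last, seed = seed + 1L)
  genome <- res$genome
  planted <- data.table(transcript_id = carrier, cds_start = res$cds_start,
                        cds_end = res$cds_end)
  seqs <- vapply(ids, function(id)
    transcript_sequence(gene$transcripts[[id]], genome), "")
  orfs <- rbindlist(lapply(ids, function(id) {
    o <- find_orf(seqs[[id]])
    data.table(transcript_id = id, cds_start = o$cds_start,
               cds_end = o$cds_end, coding = o$coding)
  }))
  list(genome = genome, sequences = seqs, orfs = orfs, planted = planted)
}
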