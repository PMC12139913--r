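#' @import data.table
#' @importFrom stats median quantile rbeta rgamma rmultinom rnorm rpois runif sd var
#' @importFrom utils head tail
NULL

#' Construct a transcript model
#'
#' A transcript model is the unit of all event detection: an ordered set of
#' exons on one strand, with strand-aware transcription start (TSS) and end
#' (TES) coordinates. Coordinates are 1-based and inclusive (GTF convention).
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand "+" or "-".
#' @param exons data.frame with columns `start`, `end` (1-based inclusive).
#'   Exons are sorted in ascending genomic order and must not overlap.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (nrow(exons) == 0L) stop("transcript ", transcript_id, " has no exons")
  if (any(exons$start > exons$end)) {
    stop("transcript ", transcript_id, ": exon start > end")
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("transcript ", transcript_id, ": overlapping exons")
  }
  tss <- if (strand == "+") exons$start[1L] else exons$end[nrow(exons)]
  tes <- if (strand == "+") exons$end[nrow(exons)] else exons$start[1L]
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, tss = tss, tes = tes),
    class = "transcript_model"
  )
}

#' Construct a gene model
#'
#' @param gene_id Identifier.
#' @param transcripts List of `transcript_model` objects, all on the same
#'   chromosome and strand.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcripts) {
  if (length(transcripts) == 0L) stop("gene ", gene_id, " has no transcripts")
  strands <- vapply(transcripts, `[[`, "", "strand")
  chroms <- vapply(transcripts, `[[`, "", "chrom")
  if (length(unique(strands)) != 1L) {
    stop("gene ", gene_id, ": inconsistent strand across transcripts")
  }
  if (length(unique(chroms)) != 1L) {
    stop("gene ", gene_id, ": inconsistent chromosome across transcripts")
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(
    list(gene_id = gene_id, chrom = chroms[1L], strand = strands[1L],
         transcripts = transcripts),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s%s), %d transcripts\n",
              x$gene_id, x$chrom, x$strand, length(x$transcripts)))
  invisible(x)
}

# Introns of a transcript: gaps between consecutive exons (1-based inclusive).
tx_introns <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-n] + 1L, end = ex$start[-1L] - 1L)
}

# Terminal exons in transcription orientation.
tx_first_exon <- function(tx) {
  if (tx$strand == "+") tx$exons[1L, ] else tx$exons[nrow(tx$exons), ]
}
tx_last_exon <- function(tx) {
  if (tx$strand == "+") tx$exons[nrow(tx$exons), ] else tx$exons[1L, ]
}

# Total exonic length.
tx_length <- function(tx) sum(tx$exons$end - tx$exons$start + 1L)

#' Parse transcript models from a GTF file
#'
#' Reads exon features, groups transcripts by `gene_id`, and returns a list of
#' gene models. Exons are re-sorted into ascending genomic order. Transcript
#' rows without any exon feature are dropped with a warning. Transcript-level
#' (feature `transcript`) rows are used only for attribute checking; structure
#' comes from exon rows.
#'
#' @param path Path to a GTF file (1-based inclusive coordinates, `gene_id`
#'   and `transcript_id` attributes on exon rows).
#' @return Named list of `gene_model` objects (by `gene_id`).
#' @export
parse_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  if (length(lineno) == 0L) stop("no feature lines in ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("GTF parse error at line ", lineno[which(nf < 9L)[1L]],
         ": expected 9 tab-separated fields")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  starts <- suppressWarnings(as.integer(m[, 4L]))
  ends <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(starts) | is.na(ends) | starts > ends)
  if (length(bad)) {
    stop("GTF parse error at line ", lineno[bad[1L]],
         ": malformed coordinates '", m[bad[1L], 4L], "'..'", m[bad[1L], 5L], "'")
  }
  attr_field <- m[, 9L]
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", attr_field)
  tid <- sub('.*transcript_id "([^"]+)".*', "\\1", attr_field)
  no_gid <- !grepl('gene_id "', attr_field, fixed = TRUE)
  no_tid <- !grepl('transcript_id "', attr_field, fixed = TRUE)
  is_exon <- grepl("^exon", m[, 3L])
  if (any(no_gid & is_exon)) {
    stop("GTF parse error at line ", lineno[which(no_gid & is_exon)[1L]],
         ": missing mandatory attribute gene_id")
  }
  if (any(no_tid & is_exon)) {
    stop("GTF parse error at line ", lineno[which(no_tid & is_exon)[1L]],
         ": missing mandatory attribute transcript_id")
  }
  ex <- data.table(
    chrom = m[is_exon, 1L], start = starts[is_exon], end = ends[is_exon],
    strand = m[is_exon, 7L], gene_id = gid[is_exon],
    transcript_id = tid[is_exon]
  )
  # transcripts named on transcript rows but having no exon rows are dropped
  is_txrow <- m[, 3L] == "transcript" & !no_tid
  orphan <- setdiff(tid[is_txrow], ex$transcript_id)
  if (length(orphan)) {
    warning("dropping ", length(orphan),
            " transcript(s) without exon features: ",
            paste(head(orphan, 5L), collapse = ", "))
  }
  if (nrow(ex) == 0L) stop("no exon features in ", path)
  genes <- list()
  for (g in unique(ex$gene_id)) {
    sub <- ex[ex$gene_id == g]
    txs <- lapply(split(sub, by = "transcript_id", sorted = TRUE), function(d) {
      transcript_model(d$transcript_id[1L], g, d$chrom[1L], d$strand[1L],
                       data.frame(start = d$start, end = d$end))
    })
    genes[[g]] <- gene_model(g, txs)
  }
  genes[order(names(genes))]
}

# Format one transcript's GTF lines (plain, unannotated).
gtf_tx_lines <- function(tx, source = "splicecraft") {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id,
                   tx$transcript_id)
  tline <- sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                   tx$chrom, source, min(tx$exons$start), max(tx$exons$end),
                   tx$strand, attrs)
  elines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
                    tx$chrom, source, tx$exons$start, tx$exons$end,
                    tx$strand, attrs, seq_len(nrow(tx$exons)))
  c(tline, elines)
}

#' Write gene models to a GTF file
#'
#' Writes 1-based inclusive coordinates with `gene_id`/`transcript_id`
#' attributes; one `transcript` row followed by `exon` rows per transcript.
#' Output order is deterministic: genes as given, transcripts by id.
#'
#' @param genes List of `gene_model` objects.
#' @param path Output path.
#' @export
write_gtf <- function(genes, path) {
  lines <- unlist(lapply(genes, function(g) {
    txs <- g$transcripts[order(names(g$transcripts))]
    unlist(lapply(txs, gtf_tx_lines))
  }))
  writeLines(lines, path)
  invisible(path)
}

# Greedy boundary clustering shared by TSS and TES grouping.
#
# Positions are processed in transcription order (ascending for "+", descending
# for "-"); a position joins the first existing cluster whose FOUNDING
# coordinate lies within `window` nt, otherwise it founds a new cluster.
# Fractional distance is computed over founding coordinates in transcription
# order: 0 for the most upstream cluster, 1 for the most downstream.
cluster_boundaries <- function(ids, pos, strand, window = 1L) {
  ord <- order(if (strand == "+") pos else -pos, ids)
  founders <- numeric(0)
  assign <- integer(length(pos))
  for (k in ord) {
    hit <- which(abs(founders - pos[k]) <= window)
    if (length(hit)) {
      assign[k] <- hit[1L]
    } else {
      founders <- c(founders, pos[k])
      assign[k] <- length(founders)
    }
  }
  nc <- length(founders)
  if (nc == 1L) {
    frac <- 0
  } else {
    rng <- range(founders)
    frac <- (founders - rng[1L]) / diff(rng)
    if (strand == "-") frac <- 1 - frac
  }
  list(
    clusters = data.table(cluster = seq_len(nc), founding = founders,
                          frac = frac,
                          n = as.integer(tabulate(assign, nc))),
    members = data.table(transcript_id = ids, position = pos,
                         cluster = assign)
  )
}

#' Cluster transcription start sites into promoter groups
#'
#' Transcripts whose TSS lies within `window` nt of a cluster's founding
#' coordinate share that promoter group; otherwise a new group is founded.
#' Each cluster carries a fractional position `ap` along the founding TSS
#' range: 0 for the most upstream promoter (in transcription orientation),
#' 1 for the most downstream; 0 if the gene has a single promoter.
#'
#' @param gene A `gene_model`.
#' @param window Clustering window in nt (default 1).
#' @return List with `clusters` (cluster, founding, ap, n) and `members`
#'   (transcript_id, tss, cluster, ap).
#' @export
cluster_tss <- function(gene, window = 1L) {
  ids <- names(gene$transcripts)
  pos <- vapply(gene$transcripts, function(t) as.numeric(t$tss), 0)
  res <- cluster_boundaries(ids, pos, gene$strand, window)
  setnames(res$clusters, "frac", "ap")
  setnames(res$members, "position", "tss")
  res$members[, ap := res$clusters$ap[cluster]]
  res
}

#' Cluster transcription end sites into end groups
#'
#' As [cluster_tss()] but on strand-aware TES coordinates (last exon end on
#' "+", first exon start on "-"). The fractional value `ae` approaches 1 for
#' end sites closer to the gene 3' end; on the minus strand the calculation is
#' inverted because a smaller genomic coordinate lies downstream in
#' transcription.
#'
#' @inheritParams cluster_tss
#' @return List with `clusters` (cluster, founding, ae, n) and `members`
#'   (transcript_id, tes, cluster, ae).
#' @export
cluster_tes <- function(gene, window = 1L) {
  ids <- names(gene$transcripts)
  pos <- vapply(gene$transcripts, function(t) as.numeric(t$tes), 0)
  res <- cluster_boundaries(ids, pos, gene$strand, window)
  setnames(res$clusters, "frac", "ae")
  setnames(res$members, "position", "tes")
  res$members[, ae := res$clusters$ae[cluster]]
  res
}

#' Export promoter/end cluster assignments as a table
#'
#' @param genes List of `gene_model` objects.
#' @param window Clustering window in nt.
#' @return data.table with gene_id, transcript_id, promoter_cluster, ap,
#'   end_cluster, ae.
#' @export
cluster_table <- function(genes, window = 1L) {
  rbindlist(lapply(genes, function(g) {
    pro <- cluster_tss(g, window)$members
    end <- cluster_tes(g, window)$members
    data.table(gene_id = g$gene_id, transcript_id = pro$transcript_id,
               promoter_cluster = pro$cluster, ap = pro$ap,
               end_cluster = end$cluster[match(pro$transcript_id,
                                               end$transcript_id)],
               ae = end$ae[match(pro$transcript_id, end$transcript_id)])
  }))
}
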