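# Gene-level annotation: run all detectors, assemble the event table, the
# per-transcript splicing attributes, and the annotated GTF records.

LABEL_ORDER <- c("alt_pro", "alt5", "alt3", "ce", "ir", "alt_end")

#' Annotate alternative splicing events for one gene
#'
#' Clusters TSS/TES, builds the normalized coverage profile (per promoter
#' group when the gene has two or more promoter clusters and
#' `profile_scope = "promoter"`, per gene otherwise), detects the six event
#' classes, and produces the annotated GTF records: each exon's feature field
#' is replaced by `"exon"` plus the underscore-joined labels of the events
#' overlapping it (fixed order alt_pro, alt5, alt3, ce, ir, alt_end), and each
#' transcript row carries the attribute block `a5, a3, ce, i` (events the
#' transcript includes), the totals `a5t, a3t, cet, it` available in its
#' group, the fractional positions `ap` and `ae`, and its promoter group id.
#'
#' @param gene A `gene_model`.
#' @param window Boundary clustering / coincidence window in nt (default 1).
#' @param profile_scope `"promoter"` (default) to detect events within each
#'   promoter group, `"gene"` to always use one gene-wide profile.
#' @param valley_drop Pronounced-valley threshold for cassette detection.
#' @return List with `events` (data.table: gene_id, scope, class, chrom,
#'   start, end, including, excluding), `attributes` (per-transcript
#'   data.table), `promoters`, `ends` (cluster tables), and `gtf` (character
#'   vector of annotated GTF lines).
#' @export
annotate_gene <- function(gene, window = 1L,
                          profile_scope = c("promoter", "gene"),
                          valley_drop = 0.1) {
  profile_scope <- match.arg(profile_scope)
  pro <- cluster_tss(gene, window)
  end <- cluster_tes(gene, window)
  txs <- gene$transcripts

  # scope units for profile-based detection
  if (profile_scope == "promoter" && nrow(pro$clusters) >= 2L) {
    scopes <- split(pro$members$transcript_id, pro$members$cluster)
    scope_ids <- paste0(gene$gene_id, ".p", names(scopes))
  } else {
    scopes <- list(names(txs))
    scope_ids <- paste0(gene$gene_id, ".p1")
  }

  alt_end_pos <- if (nrow(end$clusters) >= 2L) end$members$tes else numeric(0)
  alt_pro_pos <- if (nrow(pro$clusters) >= 2L) pro$members$tss else numeric(0)

  ev <- list()
  for (si in seq_along(scopes)) {
    group <- txs[scopes[[si]]]
    profile <- build_profile(group)
    e <- rbindlist(list(
      detect_alt5(profile, group, alt_end_pos, window),
      detect_alt3(profile, group, alt_pro_pos, window),
      detect_cassette(profile, group, valley_drop = valley_drop),
      detect_retained_introns(profile, group)
    ))
    if (nrow(e)) {
      e[, scope := scope_ids[si]]
      ev[[length(ev) + 1L]] <- e
    }
  }
  # boundary events are defined gene-wide from the clusters
  for (k in which(pro$clusters$ap > 0)) {
    inc <- pro$members$transcript_id[pro$members$cluster == k]
    exc <- setdiff(names(txs), inc)
    p <- pro$clusters$founding[k]
    e <- event_row("alt_pro", gene$chrom, p, p, inc, exc)
    e[, scope := paste0(gene$gene_id, ".p", k)]
    ev[[length(ev) + 1L]] <- e
  }
  for (k in which(end$clusters$ae > 0)) {
    inc <- end$members$transcript_id[end$members$cluster == k]
    exc <- setdiff(names(txs), inc)
    p <- end$clusters$founding[k]
    e <- event_row("alt_end", gene$chrom, p, p, inc, exc)
    e[, scope := paste0(gene$gene_id, ".e", k)]
    ev[[length(ev) + 1L]] <- e
  }
  events <- if (length(ev)) rbindlist(ev) else {
    e <- empty_events(); e[, scope := character(0)]; e
  }
  if (nrow(events)) {
    events[, gene_id := gene$gene_id]
    setorder(events, class, start, end, scope)
    setcolorder(events, c("gene_id", "scope", "class", "chrom", "start",
                          "end", "including", "excluding"))
    events[, event_id := sprintf("%s.%s.%d", gene_id, class,
                                 seq_len(.N)), by = class]
  } else {
    events[, `:=`(gene_id = character(0), event_id = character(0))]
  }

  attrs <- transcript_attributes(gene, events, pro, end, scopes, scope_ids)
  gtf <- annotated_gtf_lines(gene, events, attrs)
  list(events = events, attributes = attrs, promoters = pro, ends = end,
       gtf = gtf)
}

# Per-transcript splicing attributes: included-event counts, group totals,
# fractional promoter/end positions and promoter group membership.
transcript_attributes <- function(gene, events, pro, end, scopes, scope_ids) {
  tx_scope <- character(0)
  for (si in seq_along(scopes)) tx_scope[scopes[[si]]] <- scope_ids[si]
  ids <- names(gene$transcripts)
  count_for <- function(tid, cls, side = "including") {
    if (nrow(events) == 0L) return(0L)
    sub <- events[class == cls & scope == tx_scope[tid]]
    if (nrow(sub) == 0L) return(0L)
    sum(vapply(sub[[side]], function(v) tid %in% v, NA))
  }
  total_for <- function(tid, cls) {
    if (nrow(events) == 0L) return(0L)
    nrow(events[class == cls & scope == tx_scope[tid]])
  }
  dt <- data.table(
    gene_id = gene$gene_id, transcript_id = ids,
    promoter_group = pro$members$cluster[match(ids, pro$members$transcript_id)],
    ap = pro$members$ap[match(ids, pro$members$transcript_id)],
    ae = end$members$ae[match(ids, end$members$transcript_id)]
  )
  dt[, a5 := vapply(transcript_id, count_for, 0L, "alt5")]
  dt[, a3 := vapply(transcript_id, count_for, 0L, "alt3")]
  dt[, ce := vapply(transcript_id, count_for, 0L, "ce")]
  dt[, i := vapply(transcript_id, count_for, 0L, "ir")]
  dt[, a5t := vapply(transcript_id, total_for, 0L, "alt5")]
  dt[, a3t := vapply(transcript_id, total_for, 0L, "alt3")]
  dt[, cet := vapply(transcript_id, total_for, 0L, "ce")]
  dt[, it := vapply(transcript_id, total_for, 0L, "ir")]
  dt[]
}

# Labels applying to one exon of one transcript.
exon_labels <- function(tx, exon_idx, events, attrs) {
  s <- tx$exons$start[exon_idx]; e <- tx$exons$end[exon_idx]
  tid <- tx$transcript_id
  labs <- character(0)
  arow <- attrs[transcript_id == tid]
  first_ex <- if (tx$strand == "+") 1L else nrow(tx$exons)
  last_ex <- if (tx$strand == "+") nrow(tx$exons) else 1L
  if (arow$ap > 0 && exon_idx == first_ex) labs <- c(labs, "alt_pro")
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      cls <- events$class[k]
      if (!(tid %in% events$including[[k]])) next
      hit <- switch(cls,
        alt5 = if (tx$strand == "+") events$start[k] == e
               else events$start[k] == s,
        alt3 = if (tx$strand == "+") events$start[k] == s
               else events$start[k] == e,
        ce = ,
        ir = events$start[k] <= e && events$end[k] >= s,
        FALSE)
      if (isTRUE(hit)) labs <- c(labs, cls)
    }
  }
  if (arow$ae > 0 && exon_idx == last_ex) labs <- c(labs, "alt_end")
  unique(labs[order(match(labs, LABEL_ORDER))])
}

# Annotated GTF lines for one gene: transcript rows carry the attribute
# block; exon feature fields carry the composite event labels.
annotated_gtf_lines <- function(gene, events, attrs, source = "splicecraft") {
  lines <- character(0)
  for (tid in sort(names(gene$transcripts))) {
    tx <- gene$transcripts[[tid]]
    a <- attrs[transcript_id == tid]
    tattr <- sprintf(
      paste0('gene_id "%s"; transcript_id "%s"; promoter_group "%s"; ',
             'ap "%s"; ae "%s"; a5 "%d"; a3 "%d"; ce "%d"; i "%d"; ',
             'a5t "%d"; a3t "%d"; cet "%d"; it "%d";'),
      gene$gene_id, tid, paste0(gene$gene_id, ".p", a$promoter_group),
      sprintf("%.6g", a$ap), sprintf("%.6g", a$ae),
      a$a5, a$a3, a$ce, a$i, a$a5t, a$a3t, a$cet, a$it)
    lines <- c(lines, sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              gene$chrom, source, min(tx$exons$start),
                              max(tx$exons$end), tx$strand, tattr))
    for (k in seq_len(nrow(tx$exons))) {
      labs <- exon_labels(tx, k, events, attrs)
      feat <- paste(c("exon", labs), collapse = "_")
      lines <- c(lines, sprintf(
        "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; exon_number \"%d\";",
        gene$chrom, source, feat, tx$exons$start[k], tx$exons$end[k],
        tx$strand, gene$gene_id, tid, k))
    }
  }
  lines
}

#' Annotate a set of gene models
#'
#' Runs [annotate_gene()] over every gene and concatenates outputs.
#'
#' @param genes Named list of `gene_model` objects.
#' @inheritParams annotate_gene
#' @return List with `events`, `attributes` (data.tables over all genes) and
#'   `gtf` (annotated GTF lines, genes in input order).
#' @export
annotate_transcriptome <- function(genes, window = 1L,
                                   profile_scope = c("promoter", "gene"),
                                   valley_drop = 0.1) {
  profile_scope <- match.arg(profile_scope)
  res <- lapply(genes, annotate_gene, window = window,
                profile_scope = profile_scope, valley_drop = valley_drop)
  list(
    events = rbindlist(lapply(res, `[[`, "events")),
    attributes = rbindlist(lapply(res, `[[`, "attributes")),
    gtf = unlist(lapply(res, `[[`, "gtf"), use.names = FALSE)
  )
}

#' Write an events table as TSV
#'
#' @param events Event table from [annotate_gene()]/[annotate_transcriptome()].
#' @param path Output path.
#' @export
write_events_tsv <- function(events, path) {
  out <- copy(events)
  out[, including := vapply(including, paste, "", collapse = ",")]
  out[, excluding := vapply(excluding, paste, "", collapse = ",")]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write annotated GTF lines to a file
#'
#' @param annotation Result of [annotate_transcriptome()] or [annotate_gene()].
#' @param path Output path.
#' @export
write_annotated_gtf <- function(annotation, path) {
  writeLines(annotation$gtf, path)
  invisible(path)
}
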