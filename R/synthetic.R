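# Synthetic transcriptome generator.
#
# Builds gene models with planted, ground-truth splicing events, simulates
# replicate abundance tables from a Dirichlet-multinomial noise model over
# within-promoter usage proportions, and plants ORFs/Pfam-like domains into a
# synthetic genome so the consequence classifiers can be validated round-trip.
#
# Construction principle: each promoter group shares a constitutive exon
# backbone; every requested event class occupies its own slot of the backbone
# and exactly one "variant" isoform deviates there, so the truth event set is
# known by construction and must be recovered exactly by the annotator.

SYNTH_CHROM <- "chrSyn1"
INTERNAL_CLASSES <- c("alt5", "alt3", "ce", "ir")
DONOR_SHIFT <- 10L   # nt offset used for alt5/alt3/alt_end variation
TSS_SHIFT <- 37L     # nt spacing between alternative promoter TSSs

#' Specify a synthetic gene
#'
#' @param gene_id Identifier.
#' @param strand "+" or "-".
#' @param n_promoters Number of promoter groups (>= 2 required for alt_pro).
#' @param isoforms_per_promoter Isoforms per promoter group (>= 2 required for
#'   any internal event class or alt_end).
#' @param event_classes Subset of `c("alt_pro","alt5","alt3","ce","ir","alt_end")`.
#' @param exon_length_range,intron_length_range Sampling ranges in nt.
#' @return Object of class `synthetic_gene_spec`.
#' @export
synthetic_gene_spec <- function(gene_id, strand = "+", n_promoters = 1L,
                                isoforms_per_promoter = 2L,
                                event_classes = character(0),
                                exon_length_range = c(80L, 300L),
                                intron_length_range = c(100L, 1000L)) {
  bad <- setdiff(event_classes, EVENT_CLASSES)
  if (length(bad)) stop("unknown event class: ", paste(bad, collapse = ", "))
  if ("alt_pro" %in% event_classes && n_promoters < 2L) {
    stop("alt_pro requires n_promoters >= 2")
  }
  needs2 <- intersect(event_classes, c(INTERNAL_CLASSES, "alt_end"))
  if (length(needs2) && isoforms_per_promoter < 2L) {
    stop(needs2[1L], " requires isoforms_per_promoter >= 2")
  }
  if (n_promoters >= 2L && !("alt_pro" %in% event_classes)) {
    event_classes <- c(event_classes, "alt_pro")
  }
  structure(
    list(gene_id = gene_id, strand = strand,
         n_promoters = as.integer(n_promoters),
         isoforms_per_promoter = as.integer(isoforms_per_promoter),
         event_classes = event_classes,
         exon_length_range = as.integer(exon_length_range),
         intron_length_range = as.integer(intron_length_range)),
    class = "synthetic_gene_spec"
  )
}

# Sample a length uniformly in range (with a floor).
sample_len <- function(range, floor_at = range[1L]) {
  max(floor_at, sample(seq(range[1L], range[2L]), 1L))
}

#' Generate a synthetic gene with ground-truth event labels
#'
#' Builds the gene in transcription space (a shared exon backbone per promoter
#' group, one variant isoform per event slot), maps it to genomic coordinates
#' on `chrSyn1` (mirrored for minus-strand genes), and returns both the gene
#' model and the truth table of events the annotator must recover.
#'
#' @param spec A `synthetic_gene_spec`.
#' @param seed Integer seed; fixed seed fixes every coordinate.
#' @param origin Genomic start coordinate of the gene span.
#' @return List with `gene` (a `gene_model`), `truth` (event table in the
#'   format of [annotate_gene()]'s `events`, without event ids), and `groups`
#'   (data.table transcript_id, promoter_group).
#' @export
generate_gene <- function(spec, seed, origin = 1e6) {
  set.seed(seed)
  strand <- spec$strand
  G <- spec$n_promoters
  m <- spec$isoforms_per_promoter
  slots <- intersect(INTERNAL_CLASSES, spec$event_classes)
  if (length(slots) == 0L) slots <- "const"
  has_alt_end <- "alt_end" %in% spec$event_classes
  exr <- spec$exon_length_range
  inr <- pmax(spec$intron_length_range, 60L)
  d <- DONOR_SHIFT

  # shared backbone in transcription space
  e0 <- sample_len(exr, 40L + TSS_SHIFT * (G - 1L))
  cursor <- e0
  backbone <- list(list(kind = "first", start = 1L, end = e0))
  slot_info <- list()
  for (j in seq_along(slots)) {
    cls <- slots[j]
    ia_s <- cursor + 1L
    ia_e <- cursor + sample_len(inr)
    cursor <- ia_e
    info <- list(class = cls, intron = c(ia_s, ia_e))
    if (cls == "ce") {
      cs <- cursor + 1L; ce_ <- cursor + sample_len(exr)
      cursor <- ce_
      ib_s <- cursor + 1L; ib_e <- cursor + sample_len(inr)
      cursor <- ib_e
      info$cassette <- c(cs, ce_)
      info$intron2 <- c(ib_s, ib_e)
      backbone[[length(backbone) + 1L]] <-
        list(kind = "cassette", start = cs, end = ce_, slot = j)
    }
    as_ <- cursor + 1L; ae_ <- cursor + sample_len(exr)
    cursor <- ae_
    info$anchor <- c(as_, ae_)
    backbone[[length(backbone) + 1L]] <-
      list(kind = "anchor", start = as_, end = ae_, slot = j)
    slot_info[[j]] <- info
  }
  il_s <- cursor + 1L; il_e <- cursor + sample_len(inr)
  cursor <- il_e
  eL_s <- cursor + 1L; eL_e <- cursor + sample_len(exr, 80L)
  backbone[[length(backbone) + 1L]] <-
    list(kind = "last", start = eL_s, end = eL_e)
  L <- eL_e + if (has_alt_end) d else 0L

  variant_of <- function(j) if (m >= 2L) ((j - 1L) %% (m - 1L)) + 2L else NA_integer_
  v_end <- if (has_alt_end) variant_of(length(slots) + 1L) else NA_integer_

  to_gen <- function(pos) {
    if (strand == "+") as.integer(origin + pos - 1L)
    else as.integer(origin + L - pos)
  }
  map_iv <- function(iv) sort(c(to_gen(iv[1L]), to_gen(iv[2L])))

  # build isoform exon sets per promoter group
  txs <- list(); groups <- list()
  tx_ids <- matrix("", nrow = G, ncol = m)
  for (g in seq_len(G)) {
    for (i in seq_len(m)) {
      ex <- do.call(rbind, lapply(backbone, function(b) c(b$start, b$end)))
      keep <- rep(TRUE, nrow(ex))
      kinds <- vapply(backbone, `[[`, "", "kind")
      slot_of <- vapply(backbone, function(b)
        if (is.null(b$slot)) NA_integer_ else b$slot, 0L)
      # promoter shift first, so an ir merge of the first exon keeps the TSS
      ex[kinds == "first", 1L] <- 1L + TSS_SHIFT * (g - 1L)
      for (j in seq_along(slots)) {
        info <- slot_info[[j]]
        if (is.na(variant_of(j)) || i != variant_of(j)) next
        if (info$class == "ce") {
          keep[kinds == "cassette" & slot_of == j] <- FALSE
        } else if (info$class == "ir") {
          # merge the exon preceding the slot intron with the anchor exon
          prev <- which(ex[, 2L] == info$intron[1L] - 1L & keep)
          anch <- which(kinds == "anchor" & slot_of == j)
          ex[anch, 1L] <- ex[prev, 1L]
          keep[prev] <- FALSE
        } else if (info$class == "alt5") {
          prev <- which(ex[, 2L] == info$intron[1L] - 1L & keep)
          ex[prev, 2L] <- ex[prev, 2L] + d
        } else if (info$class == "alt3") {
          anch <- which(kinds == "anchor" & slot_of == j)
          ex[anch, 1L] <- ex[anch, 1L] - d
        }
      }
      if (has_alt_end && !is.na(v_end) && i == v_end) {
        ex[kinds == "last", 2L] <- ex[kinds == "last", 2L] + d
      }
      ex <- ex[keep, , drop = FALSE]
      gex <- t(apply(ex, 1L, function(iv)
        c(to_gen(iv[1L]), to_gen(iv[2L]))))
      gex <- data.frame(start = pmin(gex[, 1L], gex[, 2L]),
                        end = pmax(gex[, 1L], gex[, 2L]))
      tid <- sprintf("%s.p%d.i%d", spec$gene_id, g, i)
      tx_ids[g, i] <- tid
      txs[[tid]] <- transcript_model(tid, spec$gene_id, SYNTH_CHROM,
                                     strand, gex)
      groups[[length(groups) + 1L]] <-
        data.table(transcript_id = tid, promoter_group = g)
    }
  }
  gene <- gene_model(spec$gene_id, txs)

  # truth event table
  tr <- list()
  for (g in seq_len(G)) {
    scope <- sprintf("%s.p%d", spec$gene_id, g)
    members <- tx_ids[g, ]
    for (j in seq_along(slots)) {
      info <- slot_info[[j]]
      if (info$class == "const") next
      v <- members[variant_of(j)]
      rest <- setdiff(members, v)
      e <- switch(info$class,
        ce = {
          iv <- map_iv(info$cassette)
          event_row("ce", SYNTH_CHROM, iv[1L], iv[2L], rest, v)
        },
        ir = {
          iv <- map_iv(info$intron)
          event_row("ir", SYNTH_CHROM, iv[1L], iv[2L], v, rest)
        },
        alt5 = {
          p <- to_gen(info$intron[1L] - 1L)
          event_row("alt5", SYNTH_CHROM, p, p, rest, v)
        },
        alt3 = {
          p <- to_gen(info$anchor[1L])
          event_row("alt3", SYNTH_CHROM, p, p, rest, v)
        })
      e[, scope := scope]
      tr[[length(tr) + 1L]] <- e
    }
  }
  if (has_alt_end) {
    p <- to_gen(eL_e + d)
    inc <- tx_ids[, v_end]
    exc <- setdiff(unlist(tx_ids), inc)
    e <- event_row("alt_end", SYNTH_CHROM, p, p, inc, exc)
    e[, scope := sprintf("%s.e2", spec$gene_id)]
    tr[[length(tr) + 1L]] <- e
  }
  if (G >= 2L) {
    for (g in 2:G) {
      p <- to_gen(1L + TSS_SHIFT * (g - 1L))
      inc <- tx_ids[g, ]
      exc <- setdiff(unlist(tx_ids), inc)
      e <- event_row("alt_pro", SYNTH_CHROM, p, p, inc, exc)
      e[, scope := sprintf("%s.p%d", spec$gene_id, g)]
      tr[[length(tr) + 1L]] <- e
    }
  }
  truth <- if (length(tr)) rbindlist(tr) else {
    e <- empty_events(); e[, scope := character(0)]; e
  }
  if (nrow(truth)) {
    truth[, gene_id := spec$gene_id]
    setorder(truth, class, start, end, scope)
    setcolorder(truth, c("gene_id", "scope", "class", "chrom", "start",
                         "end", "including", "excluding"))
  } else {
    truth[, gene_id := character(0)]
  }
  list(gene = gene, truth = truth, groups = rbindlist(groups))
}

#' Generate a set of synthetic genes on one chromosome
#'
#' Genes are placed non-overlapping on `chrSyn1` with >= 10 kb gaps.
#'
#' @param specs List of `synthetic_gene_spec` objects.
#' @param seed Integer seed (per-gene seeds are derived deterministically).
#' @return List with `genes` (named list of `gene_model`), `truth` (combined
#'   event truth table), `groups` (transcript-to-promoter-group table).
#' @export
generate_genes <- function(specs, seed) {
  origin <- 1e6
  genes <- list(); truths <- list(); groups <- list()
  for (k in seq_along(specs)) {
    res <- generate_gene(specs[[k]], seed = seed + k, origin = origin)
    genes[[res$gene$gene_id]] <- res$gene
    truths[[k]] <- res$truth
    groups[[k]] <- res$groups
    span <- max(vapply(res$gene$transcripts,
                       function(t) max(t$exons$end), 0))
    origin <- span + 10000
  }
  list(genes = genes, truth = rbindlist(truths), groups = rbindlist(groups))
}

#' Simulate a replicate abundance table from usage truth
#'
#' For each sample, within-promoter-group isoform proportions are drawn from a
#' Dirichlet distribution centred on the condition's true usage vector with
#' the given concentration, and integer counts are drawn multinomially from a
#' Poisson group total. This deliberately differs from the Beta inference
#' model (a realistic model mismatch).
#'
#' @param truth data.table with columns gene_id, promoter_group,
#'   transcript_id, mu_young, mu_aged (within-group usage means; each group's
#'   mu must sum to 1 per condition).
#' @param n_reps Replicates per condition (default 3).
#' @param depth Expected group total count (Poisson mean, default 1000).
#' @param dispersion Dirichlet concentration (default 50); larger values pull
#'   sample proportions toward the true usage means.
#' @param seed Integer seed.
#' @param conditions Condition names, denominator (reference) first.
#' @return List with `counts` (data.table: transcript_id + one column per
#'   sample) and `design` (data.table: sample, condition, replicate).
#' @export
simulate_counts <- function(truth, n_reps = 3L, depth = 1000L,
                            dispersion = 50, seed = 1L,
                            conditions = c("young", "aged")) {
  stopifnot(n_reps >= 1L, dispersion > 0)
  truth <- as.data.table(truth)
  mu_cols <- paste0("mu_", conditions)
  if (!all(mu_cols %in% names(truth))) {
    stop("truth must have columns ", paste(mu_cols, collapse = ", "))
  }
  key <- truth[, paste(gene_id, promoter_group)]
  for (grp in unique(key)) {
    for (mc in mu_cols) {
      s <- sum(truth[[mc]][key == grp])
      if (abs(s - 1) > 1e-9) {
        stop("usage means of group ", grp, " sum to ", s, " in ", mc,
             " (must be 1 within 1e-9)")
      }
    }
  }
  set.seed(seed)
  samples <- as.vector(t(outer(conditions, seq_len(n_reps), paste, sep = "_")))
  counts <- truth[, .(gene_id, promoter_group, transcript_id)]
  for (cond in conditions) {
    mu_all <- truth[[paste0("mu_", cond)]]
    for (r in seq_len(n_reps)) {
      col <- paste(cond, r, sep = "_")
      x <- integer(nrow(truth))
      for (grp in unique(key)) {
        idx <- which(key == grp)
        p <- rgamma(length(idx), shape = dispersion * mu_all[idx], rate = 1)
        p <- p / sum(p)
        total <- rpois(1L, depth)
        x[idx] <- as.integer(rmultinom(1L, total, p))
      }
      counts[[col]] <- x
    }
  }
  design <- data.table(
    sample = samples,
    condition = rep(conditions, each = n_reps),
    replicate = rep(seq_len(n_reps), times = length(conditions))
  )
  list(counts = counts[, c("transcript_id", samples), with = FALSE],
       design = design,
       clusters = counts[, .(transcript_id, gene_id, promoter_group)])
}

#' Random usage truth for a synthetic gene set
#'
#' Assigns within-promoter-group usage means per condition: each group draws
#' mu_young from a symmetric Dirichlet; with probability `p_diff` the group is
#' differential and mu_aged is an independent draw, otherwise mu_aged equals
#' mu_young.
#'
#' @param groups data.table transcript_id, gene_id (optional), promoter_group
#'   as returned by [generate_genes()].
#' @param p_diff Probability that a group is differential.
#' @param concentration Dirichlet concentration for the draws.
#' @param seed Integer seed.
#' @return data.table gene_id, promoter_group, transcript_id, mu_young,
#'   mu_aged, true_lfc, differential.
#' @export
generate_usage_truth <- function(groups, p_diff = 0.5, concentration = 3,
                                 seed = 1L) {
  set.seed(seed)
  groups <- as.data.table(groups)
  if (!"gene_id" %in% names(groups)) {
    groups[, gene_id := sub("\\.p[0-9]+\\.i[0-9]+$", "", transcript_id)]
  }
  rdirichlet1 <- function(m) {
    x <- rgamma(m, shape = concentration, rate = 1)
    x / sum(x)
  }
  out <- groups[, {
    m <- .N
    muy <- rdirichlet1(m)
    diff <- runif(1L) < p_diff && m >= 2L
    mua <- if (diff) rdirichlet1(m) else muy
    .(transcript_id = transcript_id, mu_young = muy, mu_aged = mua,
      differential = diff)
  }, by = .(gene_id, promoter_group)]
  out[, true_lfc := log2(mu_aged / mu_young)]
  out[]
}
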