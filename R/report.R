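# Cohort-level reports contrasting transcripts/events affected by
# differential usage against unaffected ones, in the style of an
# aged-vs-young splicing survey: directional binomials per event class,
# proximal/distal boundary enrichment, promoter multiplicity, and event-class
# composition.

#' Directional counts and binomial tests per event class
#'
#' Inclusion-side transcript rows of the event PS table are tallied per event
#' class into up (significant, higher usage in the numerator condition), down
#' (significant, lower) and unaffected. Classes with at least one directional
#' call get an exact two-sided binomial test of up vs down.
#'
#' @param event_ps Output of [propagate_ps_to_events()].
#' @return data.table: class, up, down, unaffected, p_value (NA when both
#'   directional counts are zero).
#' @export
report_direction_by_class <- function(event_ps) {
  ep <- as.data.table(event_ps)[side == "inclusion"]
  out <- ep[, .(
    up = sum(significant & direction == "up"),
    down = sum(significant & direction == "down"),
    unaffected = sum(!significant)
  ), by = class]
  out[, p_value := mapply(function(u, d) {
    if (u + d == 0) NA_real_ else binomial_two_sided(u, d)$p_value
  }, up, down)]
  setorder(out, class)
  out[]
}

#' Proximal vs distal boundary usage among affected transcripts
#'
#' For genes with alternative promoters (TSS) and alternative ends (TES),
#' transcripts are labelled proximal when their fractional boundary position
#' is below 0.5 (closer to the upstream-most boundary in transcription
#' orientation) and distal otherwise, then cross-tabulated against
#' affected/unaffected status. Each boundary gets a Fisher exact test with
#' the sample odds ratio; p-values are Bonferroni-adjusted across the two
#' tests.
#'
#' @param ps Output of [assign_ps()] (one row per transcript).
#' @param attrs Transcript attribute table from [annotate_transcriptome()]
#'   (gene_id, transcript_id, ap, ae).
#' @return data.table: boundary ("tss"/"tes"), affected_proximal,
#'   affected_distal, unaffected_proximal, unaffected_distal, odds_ratio,
#'   p_value, p_adjusted. Boundaries without variation yield NA statistics.
#' @export
report_boundary_position <- function(ps, attrs) {
  ps <- as.data.table(ps)
  attrs <- as.data.table(attrs)
  d <- merge(ps[, .(transcript_id, significant)],
             attrs[, .(gene_id, transcript_id, ap, ae)],
             by = "transcript_id")
  one <- function(frac_col, label) {
    # restrict to genes where the boundary actually varies
    vg <- d[, .(varies = any(get(frac_col) > 0)), by = gene_id][varies ==
                                                                TRUE, gene_id]
    dd <- d[gene_id %in% vg]
    tab <- matrix(c(
      sum(dd$significant & dd[[frac_col]] < 0.5),
      sum(dd$significant & dd[[frac_col]] >= 0.5),
      sum(!dd$significant & dd[[frac_col]] < 0.5),
      sum(!dd$significant & dd[[frac_col]] >= 0.5)), 2L, byrow = TRUE)
    res <- tryCatch(fisher_2x2(tab),
                    error = function(e) list(odds_ratio = NA_real_,
                                             p_value = NA_real_))
    data.table(boundary = label,
               affected_proximal = tab[1L, 1L], affected_distal = tab[1L, 2L],
               unaffected_proximal = tab[2L, 1L],
               unaffected_distal = tab[2L, 2L],
               odds_ratio = res$odds_ratio, p_value = res$p_value)
  }
  out <- rbind(one("ap", "tss"), one("ae", "tes"))
  out[, p_adjusted := bonferroni(p_value, m = 2L)]
  out[]
}

#' Affected status vs promoter multiplicity
#'
#' Cross-tabulates transcripts from single-transcript promoter groups against
#' multi-transcript groups by affected/unaffected status, testing association
#' with both the Yates-corrected chi-squared and Fisher's exact test.
#'
#' @inheritParams report_boundary_position
#' @return List: `table` (2x2 matrix, rows affected/unaffected, columns
#'   single/multi), `chi2` ([chi2_2x2_yates()] result), `fisher`
#'   ([fisher_2x2()] result).
#' @export
report_promoter_multiplicity <- function(ps, attrs) {
  ps <- as.data.table(ps)
  attrs <- as.data.table(attrs)
  a <- copy(attrs)[, group_size := .N, by = .(gene_id, promoter_group)]
  d <- merge(ps[, .(transcript_id, significant)],
             a[, .(transcript_id, group_size)], by = "transcript_id")
  tab <- matrix(c(
    sum(d$significant & d$group_size == 1L),
    sum(d$significant & d$group_size > 1L),
    sum(!d$significant & d$group_size == 1L),
    sum(!d$significant & d$group_size > 1L)), 2L, byrow = TRUE,
    dimnames = list(c("affected", "unaffected"), c("single", "multi")))
  degen <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  list(table = tab,
       chi2 = if (degen) NULL else chi2_2x2_yates(tab),
       fisher = if (degen) NULL else fisher_2x2(tab))
}

#' Event-class composition of affected vs unaffected transcripts
#'
#' Builds the classes x (affected, unaffected) contingency table from the
#' inclusion-side event PS rows, tests overall composition with the Pearson
#' chi-squared (no correction), and tests each class against the pooled rest
#' with Fisher's exact test, Bonferroni-adjusted. Event classes in `classes`
#' that never occur are reported with zero counts but excluded from the
#' chi-squared with a warning.
#'
#' @param event_ps Output of [propagate_ps_to_events()].
#' @param classes Classes to report (default [EVENT_CLASSES]).
#' @return List: `counts` (data.table class/affected/unaffected/odds_ratio/
#'   p_value/p_adjusted), `chi2` ([chi2_rxc()] result over non-empty classes,
#'   or NULL when fewer than two are non-empty).
#' @export
report_class_composition <- function(event_ps, classes = EVENT_CLASSES) {
  ep <- as.data.table(event_ps)[side == "inclusion"]
  counts <- data.table(class = classes)
  counts[, affected := vapply(class, function(cl)
    ep[class == cl, sum(significant)], 0L)]
  counts[, unaffected := vapply(class, function(cl)
    ep[class == cl, sum(!significant)], 0L)]
  nonempty <- counts[affected + unaffected > 0L]
  empty <- setdiff(classes, nonempty$class)
  if (length(empty)) {
    warning("event classes absent from the data, excluded from the ",
            "chi-squared test: ", paste(empty, collapse = ", "))
  }
  chi2 <- NULL
  if (nrow(nonempty) >= 2L &&
      sum(nonempty$affected) > 0L && sum(nonempty$unaffected) > 0L) {
    m <- as.matrix(nonempty[, .(affected, unaffected)])
    rownames(m) <- nonempty$class
    chi2 <- chi2_rxc(m)
  }
  counts[, c("odds_ratio", "p_value") := {
    tot_a <- sum(affected); tot_u <- sum(unaffected)
    or <- rep(NA_real_, .N); pv <- rep(NA_real_, .N)
    for (k in seq_len(.N)) {
      tab <- matrix(c(affected[k], unaffected[k],
                      tot_a - affected[k], tot_u - unaffected[k]),
                    2L, byrow = TRUE)
      res <- tryCatch(fisher_2x2(tab),
                      error = function(e) list(odds_ratio = NA_real_,
                                               p_value = NA_real_))
      or[k] <- res$odds_ratio; pv[k] <- res$p_value
    }
    list(or, pv)
  }]
  counts[, p_adjusted := bonferroni(p_value, m = length(classes))]
  list(counts = counts[], chi2 = chi2)
}

#' Full affected-vs-unaffected report
#'
#' Convenience wrapper running all four cohort analyses.
#'
#' @param ps Output of [assign_ps()].
#' @param event_ps Output of [propagate_ps_to_events()].
#' @param attrs Transcript attribute table from [annotate_transcriptome()].
#' @return List: `direction_by_class`, `boundary_position`,
#'   `promoter_multiplicity`, `class_composition`.
#' @export
affected_vs_unaffected_report <- function(ps, event_ps, attrs) {
  list(
    direction_by_class = report_direction_by_class(event_ps),
    boundary_position = report_boundary_position(ps, attrs),
    promoter_multiplicity = report_promoter_multiplicity(ps, attrs),
    class_composition = report_class_composition(event_ps)
  )
}
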