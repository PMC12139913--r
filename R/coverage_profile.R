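# Normalized exon-coverage profiles.
#
# The profile superimposes all exons of a transcript group onto one coordinate
# axis spanning [first exon start, last exon end]. Coverage at a base is the
# inclusion fraction: (number of group transcripts whose exons contain the
# base) / (group size). Bases exonic in every transcript sit at 1.0; bases
# intronic everywhere sit at 0.

#' Build a normalized exon-coverage profile for a transcript group
#'
#' @param transcripts List of `transcript_model` objects sharing chromosome
#'   and strand (typically one promoter group, or a whole gene).
#' @return An object of class `coverage_profile`: span coordinates, per-base
#'   coverage in \[0,1\], constant-coverage runs with peak/valley flags, peak
#'   table (plateau midpoints, left-biased, with heights) and valley table
#'   (intron intervals with their coverage level). Peaks are maximal plateaus
#'   of local maxima; valleys are maximal plateaus of strict local minima,
#'   already expanded to the full intron span.
#' @export
build_profile <- function(transcripts) {
  if (length(transcripts) == 0L) stop("empty transcript group")
  strands <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(strands) != 1L) stop("mixed strands in transcript group")
  span_start <- min(vapply(transcripts, function(t) min(t$exons$start), 0))
  span_end <- max(vapply(transcripts, function(t) max(t$exons$end), 0))
  L <- as.integer(span_end - span_start + 1L)
  n <- length(transcripts)
  # difference-array accumulation of exon inclusion counts
  diffs <- numeric(L + 1L)
  for (tx in transcripts) {
    s <- tx$exons$start - span_start + 1L
    e <- tx$exons$end - span_start + 1L
    for (k in seq_along(s)) {
      diffs[s[k]] <- diffs[s[k]] + 1
      diffs[e[k] + 1L] <- diffs[e[k] + 1L] - 1
    }
  }
  cov <- cumsum(diffs[seq_len(L)]) / n

  r <- rle(cov)
  nr <- length(r$values)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  prevv <- c(NA_real_, r$values[-nr])
  nextv <- c(r$values[-1L], NA_real_)
  is_valley <- !is.na(prevv) & !is.na(nextv) &
    prevv > r$values & nextv > r$values
  is_peak <- (is.na(prevv) | prevv < r$values) &
    (is.na(nextv) | nextv < r$values)
  runs <- data.table(
    run = seq_len(nr),
    start = span_start + run_start - 1L,
    end = span_start + run_end - 1L,
    value = r$values, is_peak = is_peak, is_valley = is_valley
  )
  peaks <- runs[is_peak == TRUE,
                .(position = start + (end - start) %/% 2L, height = value,
                  start = start, end = end, run = run)]
  valleys <- runs[is_valley == TRUE,
                  .(start = start, end = end, value = value, run = run)]
  structure(
    list(chrom = transcripts[[1L]]$chrom, strand = strands,
         span_start = span_start, span_end = span_end, n = n,
         coverage = cov, runs = runs, peaks = peaks, valleys = valleys),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s:%d-%d (%s), %d transcripts, %d peaks, %d valleys\n",
              x$chrom, x$span_start, x$span_end, x$strand, x$n,
              nrow(x$peaks), nrow(x$valleys)))
  invisible(x)
}

# Coverage at a genomic position (0 outside the span).
profile_cov_at <- function(profile, pos) {
  off <- pos - profile$span_start + 1L
  out <- numeric(length(pos))
  inside <- off >= 1L & off <= length(profile$coverage)
  out[inside] <- profile$coverage[off[inside]]
  out
}
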