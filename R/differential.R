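# Bayesian differential isoform usage.
#
# Within each promoter group, per-sample transcript abundances are converted
# to usage proportions; each isoform's proportions in each condition are
# modelled as draws from a Beta distribution with isoform- and
# condition-specific shape parameters (alpha, beta) under Gamma(shape = 5,
# scale = 1) priors. Posterior sampling uses random-walk Metropolis on
# (log alpha, log beta), vectorised across all isoform-condition units so a
# transcriptome-scale fit is a single chain loop. Differential usage is
# called from the paired posterior of log2(mu_aged / mu_young),
# mu = alpha / (alpha + beta): significant iff the 95% HPD interval excludes
# zero AND the posterior probability of a directional shift exceeds 0.95.

#' Sampler and decision-rule configuration
#'
#' @param prior_shape,prior_scale Gamma prior hyperparameters for both alpha
#'   and beta (defaults 5 and 1).
#' @param chains Number of MCMC chains (default 4).
#' @param burn_in Burn-in iterations per chain, during which the proposal
#'   scale adapts toward 20-40% acceptance (default 2000).
#' @param draws Retained draws per chain (default 5000).
#' @param proposal_sd Initial random-walk proposal SD on the log scale.
#' @param seed RNG seed (default 1337).
#' @param hpd_mass HPD interval mass (default 0.95).
#' @param prob_threshold Posterior directional-probability threshold
#'   (default 0.95, compared strictly).
#' @return List of class `model_config`.
#' @export
model_config <- function(prior_shape = 5, prior_scale = 1, chains = 4L,
                         burn_in = 2000L, draws = 5000L, proposal_sd = 0.5,
                         seed = 1337L, hpd_mass = 0.95,
                         prob_threshold = 0.95) {
  stopifnot(prior_shape > 0, prior_scale > 0, chains >= 1L, burn_in >= 0L,
            draws >= 1L, proposal_sd > 0, hpd_mass > 0, hpd_mass < 1)
  structure(list(prior_shape = prior_shape, prior_scale = prior_scale,
                 chains = as.integer(chains), burn_in = as.integer(burn_in),
                 draws = as.integer(draws), proposal_sd = proposal_sd,
                 seed = as.integer(seed), hpd_mass = hpd_mass,
                 prob_threshold = prob_threshold),
            class = "model_config")
}

#' Convert abundances to within-promoter-group usage proportions
#'
#' Groups transcripts by promoter cluster, drops groups lacking at least one
#' non-zero count in both conditions (logged via `message` and recorded in the
#' `excluded` attribute), converts counts to per-sample proportions of the
#' group total, and clips them into \[0.001, 0.999\].
#'
#' @param counts data.frame/data.table: `transcript_id` plus one numeric
#'   column per sample (counts or TPM).
#' @param design data.frame: `sample`, `condition` (exactly two conditions),
#'   optionally `replicate`.
#' @param clusters data.frame: `transcript_id`, `gene_id`, `promoter_group`
#'   (as from [cluster_table()] or [simulate_counts()]).
#' @param clip Clipping bounds (default `c(0.001, 0.999)`).
#' @return Long data.table (gene_id, group_id, transcript_id, sample,
#'   condition, proportion) with attribute `excluded` listing filtered groups
#'   and the condition that failed.
#' @export
build_proportions <- function(counts, design, clusters,
                              clip = c(0.001, 0.999)) {
  counts <- as.data.table(counts)
  design <- as.data.table(design)
  clusters <- as.data.table(clusters)
  conds <- unique(design$condition)
  if (length(conds) != 2L) stop("design must contain exactly two conditions")
  missing_tx <- setdiff(counts$transcript_id, clusters$transcript_id)
  if (length(missing_tx)) {
    stop("transcripts in abundance table but not in cluster table: ",
         paste(head(missing_tx, 10L), collapse = ", "))
  }
  samples <- design$sample
  long <- melt(counts, id.vars = "transcript_id",
               measure.vars = samples, variable.name = "sample",
               value.name = "count", variable.factor = FALSE)
  long <- merge(long,
                clusters[, .(transcript_id, gene_id, promoter_group)],
                by = "transcript_id")
  long[, condition := design$condition[match(sample, design$sample)]]
  long[, group_id := paste0(gene_id, ".p", promoter_group)]
  # filter: each group needs a non-zero count in both conditions
  gsum <- long[, .(total = sum(count)), by = .(group_id, condition)]
  bad <- gsum[total == 0]
  if (nrow(bad)) {
    message("excluding ", length(unique(bad$group_id)),
            " promoter group(s) lacking expression in: ",
            paste(unique(paste0(bad$group_id, " (", bad$condition, ")")),
                  collapse = ", "))
    long <- long[!group_id %in% bad$group_id]
  }
  long[, group_total := sum(count), by = .(group_id, sample)]
  long[, proportion := ifelse(group_total > 0, count / group_total,
                              1 / .N), by = .(group_id, sample)]
  long[, proportion := pmin(pmax(proportion, clip[1L]), clip[2L])]
  out <- long[, .(gene_id, group_id, transcript_id, sample, condition,
                  proportion)]
  setorder(out, group_id, transcript_id, condition, sample)
  setattr(out, "excluded", bad)
  setattr(out, "conditions", conds)
  out[]
}

# Unnormalised log posterior on (log alpha, log beta), vectorised over units.
# Sx = sum(log x), S1x = sum(log(1-x)), n = observations per unit; includes
# the Jacobian of the log transform.
beta_log_post <- function(la, lb, Sx, S1x, n, shape, scale) {
  a <- exp(la); b <- exp(lb)
  (a - 1) * Sx + (b - 1) * S1x - n * lbeta(a, b) +
    shape * la - a / scale + shape * lb - b / scale
}

#' Fit the Bayesian Beta usage model
#'
#' Fits, for every isoform and condition independently, the posterior over
#' (alpha, beta) given a Beta likelihood of that unit's clipped proportions
#' and Gamma priors, by adaptive random-walk Metropolis on the log scale.
#' Units with zero observations are allowed (prior recovery). A split-R-hat
#' convergence diagnostic on mu = alpha/(alpha+beta) is reported per unit.
#'
#' @param proportions Long table from [build_proportions()] (or any table
#'   with group_id, transcript_id, condition, proportion).
#' @param cfg A [model_config()].
#' @return Object of class `beta_fit`: `units` (data.table with posterior
#'   means of alpha/beta, posterior mean/median mu, acceptance rate, R-hat)
#'   and `mu_draws` (units x total retained draws matrix of usage means).
#' @export
fit_beta_model <- function(proportions, cfg = model_config()) {
  pr <- as.data.table(proportions)
  if (any(pr$proportion <= 0 | pr$proportion >= 1)) {
    stop("proportions must lie strictly in (0, 1); clip them first")
  }
  units <- pr[, .(Sx = sum(log(proportion)),
                  S1x = sum(log1p(-proportion)), n = .N),
              by = .(group_id, transcript_id, condition)]
  setorder(units, group_id, transcript_id, condition)
  nu <- nrow(units)
  shape <- cfg$prior_shape; scale <- cfg$prior_scale
  total <- cfg$chains * cfg$draws
  mu_draws <- matrix(NA_real_, nrow = nu, ncol = total)
  acc_total <- numeric(nu)
  set.seed(cfg$seed)
  for (ch in seq_len(cfg$chains)) {
    # moment-based initialisation, jittered per chain
    mhat <- with(units, ifelse(n > 0, exp(Sx / pmax(n, 1)), 0.5))
    mhat <- pmin(pmax(mhat, 0.05), 0.95)
    k0 <- 10
    la <- log(pmax(mhat * k0, 0.1)) + rnorm(nu, 0, 0.3)
    lb <- log(pmax((1 - mhat) * k0, 0.1)) + rnorm(nu, 0, 0.3)
    lp <- beta_log_post(la, lb, units$Sx, units$S1x, units$n, shape, scale)
    step <- rep(cfg$proposal_sd, nu)
    acc_win <- numeric(nu); win <- 0L
    n_acc <- numeric(nu)
    for (it in seq_len(cfg$burn_in + cfg$draws)) {
      la_p <- la + rnorm(nu) * step
      lb_p <- lb + rnorm(nu) * step
      lp_p <- beta_log_post(la_p, lb_p, units$Sx, units$S1x, units$n,
                            shape, scale)
      acc <- log(runif(nu)) < lp_p - lp
      la[acc] <- la_p[acc]; lb[acc] <- lb_p[acc]; lp[acc] <- lp_p[acc]
      if (it <= cfg$burn_in) {
        acc_win <- acc_win + acc; win <- win + 1L
        if (win == 50L) {
          rate <- acc_win / 50
          step <- pmin(pmax(step * exp(rate - 0.3), 1e-3), 10)
          acc_win[] <- 0; win <- 0L
        }
      } else {
        n_acc <- n_acc + acc
        a <- exp(la)
        mu_draws[, (ch - 1L) * cfg$draws + (it - cfg$burn_in)] <-
          a / (a + exp(lb))
      }
    }
    acc_total <- acc_total + n_acc / cfg$draws
  }
  units[, acc_rate := acc_total / cfg$chains]
  units[, mu_mean := rowMeans(mu_draws)]
  units[, mu_median := apply(mu_draws, 1L, median)]
  units[, rhat := split_rhat(mu_draws, cfg$chains)]
  structure(list(units = units, mu_draws = mu_draws, cfg = cfg),
            class = "beta_fit")
}

# Split-R-hat over the chain layout of the draw matrix.
split_rhat <- function(draws, chains) {
  n <- ncol(draws) / chains
  half <- floor(n / 2)
  if (half < 2) return(rep(NA_real_, nrow(draws)))
  pieces <- list()
  for (ch in seq_len(chains)) {
    off <- (ch - 1L) * n
    pieces[[2 * ch - 1]] <- draws[, off + seq_len(half), drop = FALSE]
    pieces[[2 * ch]] <- draws[, off + half + seq_len(half), drop = FALSE]
  }
  mns <- sapply(pieces, rowMeans)
  vrs <- sapply(pieces, function(p) apply(p, 1L, var))
  m <- length(pieces)
  B <- half * apply(mns, 1L, var)
  W <- rowMeans(vrs)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Shortest (highest posterior density) interval of a sample
#'
#' @param x Numeric draws.
#' @param mass Interval mass (default 0.95).
#' @return Numeric `c(lower, upper)`: the shortest contiguous interval of
#'   sorted draws containing at least `mass` of them.
#' @export
hpd_interval <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  w <- ceiling(mass * n)
  if (w >= n) return(c(x[1L], x[n]))
  i <- which.min(x[seq.int(w, n)] - x[seq_len(n - w + 1L)])
  c(x[i], x[i + w - 1L])
}

#' Call differential isoform usage from paired posteriors
#'
#' Computes per-draw log2 fold changes of usage (numerator vs denominator
#' condition), their posterior median, 95% HPD interval and directional
#' probability, and applies the two-criterion significance rule.
#'
#' @param fit A `beta_fit`.
#' @param numerator,denominator Condition labels; the reported log2FC is
#'   log2(mu_numerator / mu_denominator).
#' @param cfg Optional [model_config()] (defaults to the fit's).
#' @return data.table: group_id, transcript_id, log2fc_median, hpd_low,
#'   hpd_high, p_up, significant, direction.
#' @export
call_differential <- function(fit, numerator = "aged", denominator = "young",
                              cfg = fit$cfg) {
  units <- fit$units
  num <- which(units$condition == numerator)
  den <- which(units$condition == denominator)
  key_num <- units[num, paste(group_id, transcript_id)]
  key_den <- units[den, paste(group_id, transcript_id)]
  common <- intersect(key_num, key_den)
  out <- list()
  for (k in common) {
    i <- num[key_num == k]; j <- den[key_den == k]
    a <- fit$mu_draws[i, ]; b <- fit$mu_draws[j, ]
    if (length(a) != length(b)) {
      warning("unequal draw counts for ", k, "; truncating to shorter chain")
      L <- min(length(a), length(b))
      a <- a[seq_len(L)]; b <- b[seq_len(L)]
    }
    lfc <- log2(a) - log2(b)
    hpd <- hpd_interval(lfc, cfg$hpd_mass)
    p_up <- mean(lfc > 0)
    sig <- (hpd[1L] > 0 || hpd[2L] < 0) &&
      max(p_up, 1 - p_up) > cfg$prob_threshold
    out[[k]] <- data.table(
      group_id = units$group_id[i], transcript_id = units$transcript_id[i],
      log2fc_median = median(lfc), hpd_low = hpd[1L], hpd_high = hpd[2L],
      p_up = p_up, significant = sig,
      direction = ifelse(median(lfc) > 0, "up",
                         ifelse(median(lfc) < 0, "down", "none"))
    )
  }
  res <- rbindlist(out)
  setorder(res, group_id, transcript_id)
  res[]
}

#' Assign percent-spliced (PS) values to transcripts
#'
#' PS is the log2 fold change, between conditions, of an isoform's
#' replicate-mean within-promoter-group usage proportion; the significance
#' flag is inherited from the Bayesian differential call.
#'
#' @param proportions Long table from [build_proportions()].
#' @param calls Output of [call_differential()].
#' @inheritParams call_differential
#' @return data.table: group_id, transcript_id, ps, log2fc_median,
#'   significant, direction.
#' @export
assign_ps <- function(proportions, calls, numerator = "aged",
                      denominator = "young") {
  pr <- as.data.table(proportions)
  means <- dcast(
    pr[, .(m = mean(proportion)), by = .(group_id, transcript_id, condition)],
    group_id + transcript_id ~ condition, value.var = "m")
  means[, ps := log2(get(numerator) / get(denominator))]
  out <- merge(means[, .(group_id, transcript_id, ps)], calls,
               by = c("group_id", "transcript_id"), all.x = TRUE)
  out[is.na(significant), `:=`(significant = FALSE, direction = "none")]
  setorder(out, group_id, transcript_id)
  out[]
}

#' Propagate transcript PS values to splicing events
#'
#' Every event inherits the PS of the transcripts that physically include it
#' (inclusion side) and of the transcripts that exclude it (exclusion side):
#' one row per (event, side, transcript).
#'
#' @param ps Output of [assign_ps()].
#' @param events Event table from [annotate_transcriptome()].
#' @param known_transcripts Character vector of all transcript ids in the
#'   transcriptome; events referencing ids outside it raise an error.
#'   Transcripts absent from `ps` because their group was filtered out are
#'   skipped silently.
#' @return data.table: event_id, gene_id, scope, class, side, transcript_id,
#'   ps, significant, direction.
#' @export
propagate_ps_to_events <- function(ps, events,
                                   known_transcripts = ps$transcript_id) {
  ps <- as.data.table(ps)
  rows <- list()
  for (k in seq_len(nrow(events))) {
    for (side in c("inclusion", "exclusion")) {
      ids <- events[[if (side == "inclusion") "including" else "excluding"]][[k]]
      unknown <- setdiff(ids, known_transcripts)
      if (length(unknown)) {
        stop("event ", events$event_id[k], " references unknown transcript: ",
             paste(unknown, collapse = ", "))
      }
      hit <- ps[transcript_id %in% ids]
      if (nrow(hit) == 0L) next
      rows[[length(rows) + 1L]] <- data.table(
        event_id = events$event_id[k], gene_id = events$gene_id[k],
        scope = events$scope[k], class = events$class[k], side = side,
        transcript_id = hit$transcript_id, ps = hit$ps,
        significant = hit$significant, direction = hit$direction)
    }
  }
  if (length(rows) == 0L) {
    return(data.table(event_id = character(0), gene_id = character(0),
                      scope = character(0), class = character(0),
                      side = character(0), transcript_id = character(0),
                      ps = numeric(0), significant = logical(0),
                      direction = character(0)))
  }
  rbindlist(rows)
}
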