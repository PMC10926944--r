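#' Mean methylation level of a level distribution
#'
#' Expectation of the methylation level L = k/K under the distribution:
#' \eqn{\mathrm{MML} = \sum_k (k/K) p_k \in [0, 1]}.
#'
#' @param p probabilities over levels 0/K .. K/K (length K + 1).
#' @return MML in \[0, 1\].
#' @export
mml <- function(p) {
  .check_level_dist(p)
  K <- length(p) - 1L
  if (K == 0) return(0)
  sum((0:K) / K * p)
}

#' Normalized methylation entropy of a level distribution
#'
#' Shannon entropy of the level distribution in bits, normalized by its
#' maximum: \eqn{\mathrm{NME} = H(p) / \log_2(K + 1) \in [0, 1]}, with
#' \eqn{0 \log 0 := 0}.  0 means a deterministic landscape, 1 a maximally
#' stochastic one.
#'
#' @inheritParams mml
#' @return NME in \[0, 1\].
#' @export
nme <- function(p) {
  .check_level_dist(p)
  K <- length(p) - 1L
  if (K == 0) return(0)
  h <- -sum(ifelse(p > 0, p * log2(p), 0))
  min(1, max(0, h / log2(K + 1)))
}

#' Jensen-Shannon distance between two level distributions
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms:
#' \eqn{\mathrm{JSD}(p, q) = \sqrt{\tfrac12 KL(p \| m) + \tfrac12
#' KL(q \| m)}}, \eqn{m = (p + q)/2}.  A metric on distributions, ranging
#' from 0 (identical) to 1 (disjoint support, maximally discordant).
#' Zero-probability cells contribute 0 to their own KL term; `m` is
#' positive wherever `p` or `q` is.
#'
#' @param p,q probability vectors over the same K + 1 levels.
#' @return JSD in \[0, 1\].
#' @export
jsd <- function(p, q) {
  .check_level_dist(p)
  .check_level_dist(q)
  if (length(p) != length(q))
    stop("level distributions have different K")
  m <- (p + q) / 2
  klp <- sum(p[p > 0] * (log2(p[p > 0]) - log2(m[p > 0])))
  klq <- sum(q[q > 0] * (log2(q[q > 0]) - log2(m[q > 0])))
  d <- sqrt(max(0, (klp + klq) / 2))
  min(1, d)
}

.check_level_dist <- function(p) {
  if (length(p) < 1 || any(!is.finite(p)) || any(p < -1e-12))
    stop("invalid level distribution")
  if (abs(sum(p) - 1) > 1e-6)
    stop("level distribution does not sum to 1")
}

#' Per-subregion MML/NME track of one fitted sample
#'
#' Statistics are computed from the fitted model's exact level
#' distribution, not from the empirical read histogram.  A subregion is
#' scored only if its estimation region was fit and at least
#' `min_sub_reads` fragments have an observed call inside it.
#'
#' @param fit a `landscape_fit` (with assembled fragments attached).
#' @param map the `cpg_map`.
#' @param partition the `region_partition`.
#' @param min_sub_reads minimum supporting fragments per subregion.
#' @return A `landscape_track`: data.frame (`sub_id`, `region_id`, `chrom`,
#'   `start`, `end`, `K`, `n_reads`, `mml`, `nme`) with the per-subregion
#'   level distributions attached as attribute `dists` (list, NULL where
#'   unscored).
#' @export
landscape_track <- function(fit, map, partition, min_sub_reads = 5) {
  assembled <- attr(fit, "assembled")
  if (is.null(assembled))
    stop("fit must carry assembled fragments (use fit_sample)")
  subs <- partition$subs
  regions <- partition$regions
  out <- data.frame(sub_id = subs$sub_id, region_id = subs$region_id,
                    chrom = subs$chrom, start = subs$start, end = subs$end,
                    K = subs$K, n_reads = 0L,
                    mml = NA_real_, nme = NA_real_)
  dists <- vector("list", nrow(subs))
  fit_df <- as.data.frame(fit)
  for (rid in unique(subs$region_id)) {
    frow <- fit_df[fit_df$region_id == rid, ]
    reg <- regions[regions$region_id == rid, ]
    sidx <- which(subs$region_id == rid)
    rr <- assembled[[rid]]
    # per-subregion support: fragments with an observed call inside the sub
    support <- .sub_support(rr, subs[sidx, , drop = FALSE], reg)
    out$n_reads[sidx] <- support
    if (is.na(frow$a)) next
    cov <- .region_covariates(map, reg)
    fl <- ising_fields(list(a = frow$a, b = frow$b, c = frow$c),
                       cov$rho, cov$gaps)
    for (k in seq_along(sidx)) {
      j <- sidx[k]
      if (support[k] < min_sub_reads) next
      subset <- (subs$idx_first[j]:subs$idx_last[j]) - reg$idx_first + 1L
      p <- level_distribution(fl, subset)
      dists[[j]] <- as.numeric(p)
      out$mml[j] <- mml(p)
      out$nme[j] <- nme(p)
    }
  }
  structure(out, dists = dists, class = c("landscape_track", "data.frame"))
}

# fragments covering >= 1 CpG of each subregion (window overlap in CpG
# index space; fragment edges are always observed calls)
.sub_support <- function(rr, subs, reg) {
  if (is.null(rr) || rr$n_frag == 0) return(rep(0L, nrow(subs)))
  s <- rr$starts
  e <- rr$starts + rr$lens - 1L
  vapply(seq_len(nrow(subs)), function(k) {
    lo <- subs$idx_first[k] - reg$idx_first # 0-based within region
    hi <- subs$idx_last[k] - reg$idx_first
    as.integer(sum(rr$counts[e >= lo & s <= hi]))
  }, integer(1))
}

#' Differential track between a test and a reference sample
#'
#' Per analysis subregion: `dmml` = MML(test) - MML(reference), `dnme` =
#' NME(test) - NME(reference), and the Jensen-Shannon distance between the
#' two fitted level distributions.  Subregions unscored in either sample
#' are missing.
#'
#' @param test,reference `landscape_track`s on the same partition.
#' @return A `differential_track`: data.frame (`sub_id`, `chrom`, `start`,
#'   `end`, `K`, `dmml`, `dnme`, `jsd`).
#' @export
differential_track <- function(test, reference) {
  if (!identical(test$sub_id, reference$sub_id))
    stop("tracks were not computed on the same partition")
  dt <- attr(test, "dists")
  dr <- attr(reference, "dists")
  n <- nrow(test)
  out <- data.frame(sub_id = test$sub_id, chrom = test$chrom,
                    start = test$start, end = test$end, K = test$K,
                    dmml = test$mml - reference$mml,
                    dnme = test$nme - reference$nme,
                    jsd = NA_real_)
  for (j in seq_len(n)) {
    if (!is.null(dt[[j]]) && !is.null(dr[[j]]))
      out$jsd[j] <- jsd(dt[[j]], dr[[j]])
  }
  if (!any(is.finite(out$jsd)))
    warning("test and reference have no jointly scored subregion")
  structure(out, class = c("differential_track", "data.frame"))
}

#' Genome-wide paired comparison of two sample tracks
#'
#' Medians and IQRs of MML and NME per sample over the jointly scored
#' subregions, plus a two-sided Wilcoxon signed-rank p-value over the
#' paired per-subregion values.  With all paired differences zero the
#' p-value is reported as 1; with fewer than 10 shared subregions it is
#' undefined (NA) and a message is logged.
#'
#' @param test,reference `landscape_track`s on the same partition.
#' @return data.frame with one row per statistic (`mml`, `nme`): medians
#'   and IQRs per sample, median paired difference, `n`, `p_value`.
#' @export
genome_summary <- function(test, reference) {
  if (!identical(test$sub_id, reference$sub_id))
    stop("tracks were not computed on the same partition")
  rows <- lapply(c("mml", "nme"), function(stat) {
    x <- test[[stat]]
    y <- reference[[stat]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    p <- NA_real_
    if (length(x) < 10) {
      message("genome_summary: only ", length(x),
              " shared subregions for ", stat, "; p undefined")
    } else if (all(x == y)) {
      p <- 1
    } else {
      p <- suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value)
    }
    data.frame(statistic = stat, n = length(x),
               median_test = median(x), iqr_test = stats::IQR(x),
               median_reference = median(y), iqr_reference = stats::IQR(y),
               median_difference = median(x - y), p_value = p)
  })
  do.call(rbind, rows)
}
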