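#' Rank genes by methylation discordance
#'
#' Promoter modes score each gene by the maximum subregion statistic (JSD
#' or dNME) within `window` bp of any of its TSSs; `gene_body_jsd`
#' averages subregion JSD over the gene body, weighted by CpG count.
#' Multiple TSS windows of the same gene symbol are scored as their union.
#' Genes with no scored subregion are reported with NA statistic and rank.
#' Ties are broken by genomic position (chrom, start), never by input
#' order.
#'
#' @param diff a `differential_track`.
#' @param genes gene table: data.frame with `chrom`, `start`, `end`,
#'   `label` (gene name), `strand`, and optionally `tss` (defaults to
#'   `start` on `+`, `end` on `-`); or a `GRanges` with `label`; or a BED
#'   path.
#' @param mode one of `"promoter_jsd"`, `"promoter_dnme"`,
#'   `"gene_body_jsd"`.
#' @param window bp each side of the TSS for promoter modes.
#' @return A `gene_ranking`: data.frame (`gene`, `chrom`, `start`, `end`,
#'   `strand`, `statistic`, `n_subregions`, `rank`, `p_value`, `q_value`)
#'   ordered by rank; unscored genes last with NA rank.
#' @export
rank_genes <- function(diff, genes, mode = c("promoter_jsd",
                                             "promoter_dnme",
                                             "gene_body_jsd"),
                       window = 2000) {
  mode <- match.arg(mode)
  genes <- .as_gene_table(genes)
  if (nrow(genes) == 0) stop("empty gene set")
  scored <- diff[is.finite(diff$jsd), , drop = FALSE]
  stat_col <- if (mode == "promoter_dnme") "dnme" else "jsd"

  sub_gr <- GenomicRanges::GRanges(
    scored$chrom, IRanges::IRanges(scored$start, scored$end))
  if (mode == "gene_body_jsd") {
    win_gr <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start, genes$end))
  } else {
    win_gr <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(pmax(1L, genes$tss - window),
                                    genes$tss + window))
  }
  hits <- GenomicRanges::findOverlaps(win_gr, sub_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  # aggregate per gene symbol (union of its windows)
  stat <- rep(NA_real_, nrow(genes))
  nsub <- integer(nrow(genes))
  sym <- genes$label
  for (g in seq_len(nrow(genes))) {
    rows <- unique(sh[qh %in% which(sym == sym[g])])
    nsub[g] <- length(rows)
    if (!length(rows)) next
    v <- scored[[stat_col]][rows]
    stat[g] <- if (mode == "gene_body_jsd") {
      stats::weighted.mean(v, scored$K[rows])
    } else {
      max(v)
    }
  }
  ord <- order(!is.finite(stat), -stat, genes$chrom, genes$start,
               method = "radix")
  out <- genes[ord, c("chrom", "start", "end", "strand"), drop = FALSE]
  out <- data.frame(gene = genes$label[ord], out, statistic = stat[ord],
                    n_subregions = nsub[ord], stringsAsFactors = FALSE)
  out$rank <- NA_integer_
  out$rank[is.finite(out$statistic)] <- seq_len(sum(is.finite(out$statistic)))
  out$p_value <- NA_real_
  out$q_value <- NA_real_
  rownames(out) <- NULL
  structure(out, mode = mode, window = window,
            class = c("gene_ranking", "data.frame"))
}

.as_gene_table <- function(genes) {
  if (is.character(genes) && length(genes) == 1)
    genes <- read_bed_annotations(genes)
  if (methods::is(genes, "GRanges")) {
    genes <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start = GenomicRanges::start(genes),
      end = GenomicRanges::end(genes),
      label = if (!is.null(genes$label)) genes$label else
        paste0("gene", seq_along(genes)),
      strand = as.character(GenomicRanges::strand(genes)),
      stringsAsFactors = FALSE
    )
    genes$strand[genes$strand == "*"] <- "+"
  }
  if (is.null(genes$tss))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes
}

#' Permutation p-value for between-sample discordance in one region
#'
#' Pools the two samples' read fragments in an estimation region, randomly
#' reassigns sample labels preserving group sizes, refits both groups and
#' recomputes the discordance statistic (JSD between the fitted level
#' distributions over the whole region).  The empirical p-value is
#' (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' Refits default to a coarse 4-point start grid: the same statistic is
#' applied to observed and permuted data, which preserves the validity of
#' the permutation test while keeping hundreds of refits tractable.
#'
#' @param reads_a,reads_b `read_set`s for the two samples.
#' @param map,partition the shared `cpg_map` and `region_partition`.
#' @param region_id estimation region to test.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param min_reads minimum fragments per group; below it the p-value is
#'   NA (flagged).
#' @param start_grid Nelder-Mead start grid for the refits.
#' @return list with `p_value`, `observed`, `null` (numeric vector of null
#'   statistics), `n_a`, `n_b`.
#' @export
permutation_pvalue <- function(reads_a, reads_b, map, partition, region_id,
                               n_perm = 199, seed = 1, min_reads = 10,
                               start_grid = ising_start_grid(c(-4, 4), 0,
                                                             c(0, 8))) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  reg <- partition$regions[partition$regions$region_id == region_id, ]
  if (nrow(reg) != 1) stop("unknown region_id")
  frag_a <- .expand_fragments(assemble_region_reads(reads_a, map,
                                                    partition)[[region_id]])
  frag_b <- .expand_fragments(assemble_region_reads(reads_b, map,
                                                    partition)[[region_id]])
  n_a <- length(frag_a$starts)
  n_b <- length(frag_b$starts)
  if (n_a < min_reads || n_b < min_reads) {
    warning("insufficient reads for permutation test in region ", region_id)
    return(list(p_value = NA_real_, observed = NA_real_, null = numeric(0),
                n_a = n_a, n_b = n_b))
  }
  cov <- .region_covariates(map, reg)
  stat_fun <- function(fa, fb) {
    pa <- fit_parameters(fa, cov$rho, cov$gaps, start_grid = start_grid)
    pb <- fit_parameters(fb, cov$rho, cov$gaps, start_grid = start_grid)
    da <- level_distribution(ising_fields(pa$params, cov$rho, cov$gaps))
    db <- level_distribution(ising_fields(pb$params, cov$rho, cov$gaps))
    jsd(da, db)
  }
  observed <- stat_fun(.compact_fragments(frag_a), .compact_fragments(frag_b))

  pool <- list(starts = c(frag_a$starts, frag_b$starts),
               lens = c(frag_a$lens, frag_b$lens),
               calls = c(frag_a$calls, frag_b$calls)) # calls: list per read
  n_pool <- n_a + n_b
  set.seed(seed)
  null <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    pick <- sample.int(n_pool, n_a)
    null[k] <- stat_fun(.subset_fragments(pool, pick),
                        .subset_fragments(pool,
                                          setdiff(seq_len(n_pool), pick)))
  }
  list(p_value = (1 + sum(null >= observed)) / (1 + n_perm),
       observed = observed, null = null, n_a = n_a, n_b = n_b)
}

# expand multiplicity-collapsed fragments to unit reads for permutation
.expand_fragments <- function(rr) {
  if (is.null(rr) || rr$n_frag == 0)
    return(list(starts = integer(0), lens = integer(0), calls = list()))
  offs <- cumsum(c(0L, rr$lens))
  calls <- lapply(seq_along(rr$starts),
                  function(f) rr$calls[(offs[f] + 1L):offs[f + 1L]])
  rep_idx <- rep(seq_along(rr$starts), times = as.integer(rr$counts))
  list(starts = rr$starts[rep_idx], lens = rr$lens[rep_idx],
       calls = calls[rep_idx])
}

.compact_fragments <- function(fr) {
  list(starts = fr$starts, lens = fr$lens,
       calls = unlist(fr$calls, use.names = FALSE),
       counts = rep(1, length(fr$starts)), n_frag = length(fr$starts))
}

.subset_fragments <- function(pool, idx) {
  list(starts = pool$starts[idx], lens = pool$lens[idx],
       calls = unlist(pool$calls[idx], use.names = FALSE),
       counts = rep(1, length(idx)), n_frag = length(idx))
}

#' Attach permutation significance to a gene ranking
#'
#' Runs [permutation_pvalue()] for the top `top_n` ranked genes (on the
#' estimation region containing each gene's best-scoring subregion) and
#' adjusts across the tested genes by Benjamini-Hochberg.
#'
#' @param ranking a `gene_ranking`.
#' @param diff the `differential_track` the ranking was computed from.
#' @param reads_a,reads_b,map,partition as in [permutation_pvalue()].
#' @param top_n number of top-ranked genes to test.
#' @param n_perm,seed,start_grid passed to [permutation_pvalue()].
#' @return the ranking with `p_value`/`q_value` filled for tested genes.
#' @export
add_gene_significance <- function(ranking, diff, reads_a, reads_b, map,
                                  partition, top_n = 20, n_perm = 199,
                                  seed = 1,
                                  start_grid = ising_start_grid(c(-4, 4), 0,
                                                                c(0, 8))) {
  window <- attr(ranking, "window")
  scored <- diff[is.finite(diff$jsd), , drop = FALSE]
  take <- which(!is.na(ranking$rank) & ranking$rank <= top_n)
  seeds <- {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, length(take))
  }
  for (i in seq_along(take)) {
    g <- take[i]
    tss <- if (ranking$strand[g] == "+") ranking$start[g] else ranking$end[g]
    near <- scored[scored$chrom == ranking$chrom[g] &
                     scored$end >= tss - window &
                     scored$start <= tss + window, , drop = FALSE]
    if (!nrow(near)) next
    best <- near[which.max(near$jsd), ]
    rid <- partition$subs$region_id[partition$subs$sub_id == best$sub_id]
    res <- permutation_pvalue(reads_a, reads_b, map, partition, rid,
                              n_perm = n_perm, seed = seeds[i],
                              start_grid = start_grid)
    ranking$p_value[g] <- res$p_value
  }
  tested <- !is.na(ranking$p_value)
  ranking$q_value[tested] <- p.adjust(ranking$p_value[tested], method = "BH")
  ranking
}

#' Summarize a differential track over annotation classes
#'
#' Each scored subregion is assigned to the annotation label covering its
#' midpoint ("none" if uncovered); per label, the subregion count and the
#' median and IQR of dMML, dNME and JSD are reported.
#'
#' @param diff a `differential_track`.
#' @param annotations a `GRanges` with a `label` column (see
#'   [read_bed_annotations()]), or a data.frame `chrom`, `start`, `end`,
#'   `label` (1-based closed).
#' @return A `feature_summary` data.frame: one row per label.
#' @export
feature_summary <- function(diff, annotations) {
  scored <- diff[is.finite(diff$jsd), , drop = FALSE]
  if (is.data.frame(annotations)) {
    annotations <- GenomicRanges::GRanges(
      annotations$chrom,
      IRanges::IRanges(annotations$start, annotations$end),
      label = annotations$label)
  }
  mid <- as.integer((scored$start + scored$end) %/% 2)
  lab <- rep("none", nrow(scored))
  if (length(annotations)) {
    mid_gr <- GenomicRanges::GRanges(scored$chrom,
                                     IRanges::IRanges(mid, mid))
    hits <- GenomicRanges::findOverlaps(mid_gr, annotations, select = "first")
    hit <- !is.na(hits)
    lab[hit] <- annotations$label[hits[hit]]
  }
  rows <- lapply(split(seq_len(nrow(scored)), lab), function(idx) {
    d <- scored[idx, , drop = FALSE]
    data.frame(label = lab[idx[1]], n = length(idx),
               dmml_median = median(d$dmml), dmml_iqr = stats::IQR(d$dmml),
               dnme_median = median(d$dnme), dnme_iqr = stats::IQR(d$dnme),
               jsd_median = median(d$jsd), jsd_iqr = stats::IQR(d$jsd))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("feature_summary", "data.frame"))
}

#' Meta-profile of a track around anchor points
#'
#' Assigns each scored subregion midpoint to a signed-distance bin from
#' the nearest anchors within `window` bp (strand-aware: for minus-strand
#' anchors downstream distances are positive) and returns per-bin means
#' and counts.
#'
#' @param track a `landscape_track` or `differential_track`.
#' @param value which column of `track` to profile (e.g. `"mml"`, `"nme"`,
#'   `"jsd"`).
#' @param anchors data.frame with `chrom`, `pos` and optionally `strand`
#'   (defaults `+`), e.g. TSS positions; or a gene table with `tss`.
#' @param window half-width (bp) of the profile; must be >= the track's
#'   subregion span.
#' @param n_bins number of distance bins across \[-window, window\].
#' @return data.frame `bin_center`, `mean`, `n`.
#' @export
meta_profile <- function(track, value, anchors, window = 2000, n_bins = 40) {
  if (!is.null(anchors$tss) && is.null(anchors$pos)) anchors$pos <- anchors$tss
  if (is.null(anchors$strand)) anchors$strand <- "+"
  if (nrow(anchors) == 0) stop("anchors must be non-empty")
  sub_span <- median(track$end - track$start + 1)
  if (window < sub_span)
    stop("window is smaller than the subregion span")
  v <- track[[value]]
  ok <- is.finite(v)
  mid <- (track$start + track$end) %/% 2
  breaks <- seq(-window, window, length.out = n_bins + 1)
  acc_sum <- numeric(n_bins)
  acc_n <- integer(n_bins)
  for (i in seq_len(nrow(anchors))) {
    sel <- ok & track$chrom == anchors$chrom[i] &
      abs(mid - anchors$pos[i]) <= window
    if (!any(sel)) next
    d <- mid[sel] - anchors$pos[i]
    if (anchors$strand[i] == "-") d <- -d
    bin <- findInterval(d, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    for (b in unique(bin)) {
      acc_sum[b] <- acc_sum[b] + sum(v[sel][bin == b])
      acc_n[b] <- acc_n[b] + sum(bin == b)
    }
  }
  data.frame(bin_center = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
             mean = ifelse(acc_n > 0, acc_sum / acc_n, NA_real_),
             n = acc_n)
}
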