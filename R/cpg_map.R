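#' Generate a synthetic CpG coordinate map
#'
#' Lays out CpG dinucleotide positions on one or more synthetic chromosomes
#' with two spacing regimes: dense inside CpG islands and sparse in open sea.
#' Shores are the 2 kb flanks of islands and shelves the next 2 kb, following
#' the usual CGI-class nomenclature.  A fraction of islands is relabelled
#' `bivalent_promoter` (islands sitting in bivalent chromatin) and a fraction
#' of the open sea is labelled `heterochromatin`, so downstream profiles can
#' plant feature-specific effects.
#'
#' Positions are 1-based and strand-collapsed (one unit per CpG dinucleotide).
#' Each site carries a local CpG density `rho` — the CpG count within
#' +/- 500 bp divided by 50 (the count at island-typical 20 bp spacing),
#' clamped to \[0, 1\], so islands sit near 1 and open sea near 0.15 — and
#' the gap `gap` to the next site on the chromosome (NA at chromosome
#' ends); these are the covariates of the Ising parameterization.
#'
#' @param n_chrom number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length chromosome length in bp (>= 10000).
#' @param island_fraction fraction of each chromosome covered by islands,
#'   in \[0, 1\].
#' @param seed integer seed; identical inputs and seed give identical maps.
#' @param island_mean_gap,sea_mean_gap mean inter-CpG gap (bp) inside
#'   islands and in open sea; gaps are 2 + geometric, so always >= 2.
#' @param island_length_range island length range (bp), sampled uniformly.
#' @param shore_width,shelf_width widths (bp) of the shore and shelf flanks.
#' @param bivalent_fraction fraction of islands relabelled
#'   `bivalent_promoter`.
#' @param het_fraction fraction of the chromosome covered by 5 kb
#'   heterochromatin blocks (labels only open-sea sites).
#'
#' @return A `cpg_map`: list with `sites` (data.frame `chrom`, `pos`, `rho`,
#'   `gap`, `label`) and `segments` (data.frame `chrom`, `start`, `end`,
#'   `label`, 1-based closed intervals) recording the generating feature
#'   segments.
#' @export
generate_cpg_map <- function(n_chrom = 2, chrom_length = 7e5,
                             island_fraction = 0.06, seed = 1,
                             island_mean_gap = 20, sea_mean_gap = 120,
                             island_length_range = c(600, 1500),
                             shore_width = 2000, shelf_width = 2000,
                             bivalent_fraction = 0.25, het_fraction = 0.1) {
  if (n_chrom < 1) stop("n_chrom must be positive")
  if (chrom_length < 10000) stop("chrom_length must be >= 10000 bp")
  if (island_fraction < 0 || island_fraction > 1)
    stop("island_fraction must lie in [0, 1]")
  if (island_mean_gap < 3 || sea_mean_gap < 3)
    stop("mean gaps must exceed the 2 bp CpG footprint")
  set.seed(seed)

  sites_list <- vector("list", n_chrom)
  segs_list <- vector("list", n_chrom)
  for (ci in seq_len(n_chrom)) {
    chrom <- paste0("chr", ci)
    isl <- .place_islands(chrom_length, island_fraction, island_length_range)
    n_isl <- nrow(isl)
    biv <- rep(FALSE, n_isl)
    if (n_isl > 0 && bivalent_fraction > 0) {
      n_biv <- round(bivalent_fraction * n_isl)
      if (n_biv > 0) biv[sample.int(n_isl, n_biv)] <- TRUE
    }

    pos <- .draw_positions(chrom_length, isl, island_mean_gap, sea_mean_gap)
    if (length(pos) == 0) next

    het <- .place_het_blocks(chrom_length, het_fraction, isl,
                             shore_width + shelf_width)
    lab <- .label_sites(pos, isl, biv, het, shore_width, shelf_width)

    cnt <- .window_counts(pos, 500)
    sites_list[[ci]] <- data.frame(
      chrom = chrom, pos = pos,
      rho = pmin(1, cnt / 50),
      gap = c(diff(pos), NA_integer_),
      label = lab, stringsAsFactors = FALSE
    )
    segs_list[[ci]] <- .feature_segments(chrom, chrom_length, isl, biv, het,
                                         shore_width, shelf_width)
  }
  sites <- do.call(rbind, sites_list)
  if (is.null(sites)) {
    sites <- data.frame(chrom = character(), pos = integer(), rho = numeric(),
                        gap = integer(), label = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(sites) <- NULL
  segments <- do.call(rbind, segs_list)
  rownames(segments) <- NULL
  structure(list(sites = sites, segments = segments,
                 chrom_lengths = setNames(rep(chrom_length, n_chrom),
                                          paste0("chr", seq_len(n_chrom)))),
            class = "cpg_map")
}

#' @export
print.cpg_map <- function(x, ...) {
  cat("CpG map:", nrow(x$sites), "sites on", length(x$chrom_lengths),
      "chromosome(s)\n")
  print(table(x$sites$label))
  invisible(x)
}

# islands placed one per equal-width block at a random offset: non-overlapping
# by construction and roughly uniform along the chromosome
.place_islands <- function(L, frac, len_range) {
  n_isl <- round(frac * L / mean(len_range))
  if (n_isl == 0)
    return(data.frame(start = integer(), end = integer()))
  block <- L / n_isl
  len <- pmin(round(runif(n_isl, len_range[1], len_range[2])),
              floor(block) - 2L)
  off <- floor(runif(n_isl) * (block - len - 1))
  start <- pmax(1L, as.integer(floor((seq_len(n_isl) - 1) * block) + off + 1L))
  data.frame(start = start, end = pmin(as.integer(start + len - 1L), L))
}

.place_het_blocks <- function(L, frac, isl, margin) {
  n_blk <- round(frac * L / 5000)
  if (n_blk == 0) return(data.frame(start = integer(), end = integer()))
  start <- as.integer(sort(floor(runif(n_blk, 1, L - 5000))))
  data.frame(start = start, end = pmin(start + 4999L, L))
}

.draw_positions <- function(L, isl, gap_isl, gap_sea) {
  # decompose [1, L] into alternating sea / island runs, then draw
  # geometric (>= 2 bp) gaps within each run in one batch
  if (nrow(isl)) {
    starts <- c(1L, isl$end + 1L)
    ends <- c(isl$start - 1L, L)
    sea <- data.frame(start = starts, end = ends, island = FALSE)
    sea <- sea[sea$end >= sea$start, , drop = FALSE]
    runs <- rbind(sea, data.frame(start = isl$start, end = isl$end,
                                  island = TRUE))
    runs <- runs[order(runs$start), , drop = FALSE]
  } else {
    runs <- data.frame(start = 1L, end = L, island = FALSE)
  }
  pos <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    span <- runs$end[i] - runs$start[i] + 1L
    mean_gap <- if (runs$island[i]) gap_isl else gap_sea
    n_draw <- max(8L, ceiling(span / mean_gap * 1.6) + 8L)
    gaps <- 2L + rgeom(n_draw, prob = 1 / (mean_gap - 1))
    while (sum(gaps) < span) {
      gaps <- c(gaps, 2L + rgeom(n_draw, prob = 1 / (mean_gap - 1)))
    }
    p <- runs$start[i] - 1L + cumsum(gaps)
    pos[[i]] <- as.integer(p[p <= runs$end[i]])
  }
  unlist(pos)
}

.label_sites <- function(pos, isl, biv, het, shore_w, shelf_w) {
  lab <- rep("open_sea", length(pos))
  if (nrow(isl)) {
    for (tier in c("shelf", "shore")) {
      w <- if (tier == "shore") shore_w else shore_w + shelf_w
      lo <- isl$start - w
      hi <- isl$end + w
      idx <- findInterval(pos, lo)
      hit <- idx > 0 & pos <= hi[pmax(idx, 1)]
      lab[hit] <- tier
    }
    idx <- findInterval(pos, isl$start)
    hit <- idx > 0 & pos <= isl$end[pmax(idx, 1)]
    core <- ifelse(biv[pmax(idx, 1)], "bivalent_promoter", "island")
    lab[hit] <- core[hit]
  }
  # heterochromatin blocks claim open-sea sites only (island hierarchy wins)
  if (nrow(het)) {
    idx <- findInterval(pos, het$start)
    hit <- idx > 0 & pos <= het$end[pmax(idx, 1)] & lab == "open_sea"
    lab[hit] <- "heterochromatin"
  }
  lab
}

.feature_segments <- function(chrom, L, isl, biv, het, shore_w, shelf_w) {
  segs <- list()
  if (nrow(isl)) {
    segs$core <- data.frame(
      chrom = chrom, start = isl$start, end = isl$end,
      label = ifelse(biv, "bivalent_promoter", "island"),
      stringsAsFactors = FALSE
    )
    segs$shore <- data.frame(
      chrom = chrom,
      start = c(pmax(1L, isl$start - shore_w), isl$end + 1L),
      end = c(isl$start - 1L, pmin(L, isl$end + shore_w)),
      label = "shore", stringsAsFactors = FALSE
    )
    segs$shelf <- data.frame(
      chrom = chrom,
      start = c(pmax(1L, isl$start - shore_w - shelf_w), isl$end + shore_w + 1L),
      end = c(isl$start - shore_w - 1L, pmin(L, isl$end + shore_w + shelf_w)),
      label = "shelf", stringsAsFactors = FALSE
    )
  }
  if (nrow(het)) {
    segs$het <- data.frame(chrom = chrom, start = het$start, end = het$end,
                           label = "heterochromatin", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE)
  }
  out <- out[out$end >= out$start, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# CpG count within +/- w bp of each position (self included)
.window_counts <- function(pos, w) {
  hi <- findInterval(pos + w, pos)
  lo <- findInterval(pos - w - 1L, pos)
  hi - lo
}
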