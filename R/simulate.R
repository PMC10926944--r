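#' Simulate bisulfite reads from known Ising parameters
#'
#' Reads are exact draws from each estimation region's Ising distribution
#' restricted to the covered window (forward-filter, backward-sample over
#' the transfer-matrix messages), so empirical pattern frequencies converge
#' to the exact model probabilities.  Each covered site is then
#' independently masked to unobserved (`.`) at `miss_rate`; masked edges are
#' trimmed and fully masked reads dropped.
#'
#' @param map a `cpg_map`.
#' @param partition a `region_partition` of `map`.
#' @param params data.frame with columns `region_id`, `a`, `b`, `c` giving
#'   the true parameters per estimation region.
#' @param depth target mean number of reads covering each CpG (>= 1).
#' @param read_span number of consecutive CpG units covered per read
#'   (truncated to the region's CpG count).
#' @param miss_rate per-site masking probability in \[0, 1).
#' @param seed integer seed.
#' @return list with `reads` (a `read_set`) and `truth` (a
#'   `simulation_truth`: list with `regions` — true parameters per region —
#'   and `subs` — exact model MML and NME per analysis subregion).
#' @export
simulate_reads <- function(map, partition, params, depth = 10, read_span = 8,
                           miss_rate = 0.05, seed = 1) {
  stopifnot(depth >= 1, read_span >= 1, miss_rate >= 0, miss_rate < 1)
  set.seed(seed)
  regions <- partition$regions
  unknown <- setdiff(params$region_id, regions$region_id)
  if (length(unknown))
    warning("parameters for ", length(unknown),
            " region(s) without CpGs skipped")
  params <- params[params$region_id %in% regions$region_id, , drop = FALSE]

  chroms <- character(0); ids <- character(0)
  firsts <- integer(0); strs <- character(0)
  truth_regions <- params
  sub_truth <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    reg <- regions[regions$region_id == params$region_id[i], ]
    cov <- .region_covariates(map, reg)
    fl <- ising_fields(list(a = params$a[i], b = params$b[i],
                            c = params$c[i]), cov$rho, cov$gaps)
    n_sites <- length(cov$rho)
    span <- min(read_span, n_sites)
    n_reads <- ceiling(n_sites * depth / span)
    starts <- if (n_sites == span) rep(1L, n_reads)
              else sample.int(n_sites - span + 1L, n_reads, replace = TRUE)
    flat <- cpp_sample_windows(fl$alpha, fl$beta, starts - 1L,
                               rep(span, n_reads))
    mat <- matrix(flat, nrow = n_reads, ncol = span, byrow = TRUE)
    if (miss_rate > 0)
      mat[runif(length(mat)) < miss_rate] <- -1L
    built <- .build_read_strings(mat, starts)
    keep <- built$keep
    chroms <- c(chroms, rep(reg$chrom, sum(keep)))
    ids <- c(ids, sprintf("r%d_%d", reg$region_id, seq_len(sum(keep))))
    firsts <- c(firsts, reg$idx_first - 1L + built$first[keep])
    strs <- c(strs, built$calls[keep])

    subs <- partition$subs[partition$subs$region_id == reg$region_id, ,
                           drop = FALSE]
    st <- lapply(seq_len(nrow(subs)), function(j) {
      subset <- (subs$idx_first[j]:subs$idx_last[j]) - reg$idx_first + 1L
      p <- level_distribution(fl, subset)
      c(mml = mml(p), nme = nme(p))
    })
    st <- do.call(rbind, st)
    sub_truth[[i]] <- data.frame(sub_id = subs$sub_id,
                                 region_id = reg$region_id,
                                 chrom = subs$chrom, start = subs$start,
                                 end = subs$end, K = subs$K,
                                 mml = st[, "mml"], nme = st[, "nme"])
  }
  reads <- structure(data.frame(chrom = chroms, read_id = ids,
                                first = firsts, calls = strs,
                                stringsAsFactors = FALSE),
                     class = c("read_set", "data.frame"))
  truth <- structure(list(regions = truth_regions,
                          subs = do.call(rbind, sub_truth)),
                     class = "simulation_truth")
  list(reads = reads, truth = truth)
}

# trim masked edges, drop fully masked reads, build call strings
.build_read_strings <- function(mat, starts) {
  n <- nrow(mat)
  first <- integer(n)
  calls <- character(n)
  keep <- logical(n)
  lut <- c("U", "M")
  for (r in seq_len(n)) {
    codes <- mat[r, ]
    obs <- which(codes >= 0)
    if (!length(obs)) next
    codes <- codes[obs[1]:obs[length(obs)]]
    first[r] <- starts[r] + obs[1] - 1L
    calls[r] <- paste(ifelse(codes < 0, ".", lut[codes + 1L]), collapse = "")
    keep[r] <- TRUE
  }
  list(first = first, calls = calls, keep = keep)
}

#' Default generative profiles for the paired normal/tumor simulation
#'
#' Normal tissue: open sea (and heterochromatin) strongly methylated,
#' islands and bivalent promoters strongly unmethylated, high cooperativity
#' `c` (concordant reads, low entropy).  Tumor: field magnitudes shrunk
#' toward 0 (`a_scale`) and cooperativity reduced — global hypomethylation
#' with elevated stochasticity — except bivalent promoters, whose field
#' flips positive (focal hypermethylation).
#'
#' @return list with `normal_a` (named vector per feature class),
#'   `normal_c`, `b`, `tumor_a_scale`, `tumor_c`, `tumor_bivalent_a`.
#' @export
pair_profiles <- function() {
  list(
    normal_a = c(open_sea = 2.5, heterochromatin = 2.5, shelf = 2.0,
                 shore = 1.5, island = -3.0, bivalent_promoter = -3.0,
                 none = 2.5),
    normal_c = 4.0,
    b = 0.0,
    tumor_a_scale = 0.4,
    tumor_c = 1.0,
    tumor_bivalent_a = 2.0
  )
}

#' Simulate a paired normal/tumor read set with planted differences
#'
#' Assigns every estimation region a feature class (majority label of its
#' CpGs), draws normal and tumor parameters from [pair_profiles()], and
#' simulates both read sets.  By construction the tumor exhibits global
#' hypomethylation and elevated methylation entropy with focal
#' hypermethylation at bivalent-promoter regions, the structure used as
#' ground truth for the differential analyses.
#'
#' @param map a `cpg_map` containing at least one region of each feature
#'   class used by the profiles.
#' @param seed integer seed (normal and tumor reads use sub-seeds derived
#'   from it).
#' @param partition optional precomputed `region_partition`.
#' @param est_span,sub_span partition spans (bp) if `partition` is NULL.
#' @param depth,read_span,miss_rate passed to [simulate_reads()].
#' @param profiles profile constants, see [pair_profiles()].
#' @return A `pair_sim`: list with `normal`, `tumor` (read sets), `truth`
#'   (region labels, both parameter sets, exact per-subregion MML/NME per
#'   sample), `partition`, `map`, `profiles` and `config`.
#' @export
make_tumor_normal_pair <- function(map, seed = 1, partition = NULL,
                                   est_span = 3000, sub_span = 150,
                                   depth = 10, read_span = 8,
                                   miss_rate = 0.05,
                                   profiles = pair_profiles()) {
  if (is.null(partition))
    partition <- partition_genome(map, est_span, sub_span)
  lab <- .region_labels(map, partition)
  present <- unique(lab)
  needed <- c("open_sea", "island", "bivalent_promoter")
  if (!all(needed %in% present))
    stop("map must contain at least one region of each class: ",
         paste(setdiff(needed, present), collapse = ", "))

  a_norm <- unname(profiles$normal_a[lab])
  normal_params <- data.frame(region_id = partition$regions$region_id,
                              a = a_norm, b = profiles$b,
                              c = profiles$normal_c)
  a_tum <- a_norm * profiles$tumor_a_scale
  a_tum[lab == "bivalent_promoter"] <- profiles$tumor_bivalent_a
  tumor_params <- data.frame(region_id = partition$regions$region_id,
                             a = a_tum, b = profiles$b,
                             c = profiles$tumor_c)

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2)
  normal <- simulate_reads(map, partition, normal_params, depth = depth,
                           read_span = read_span, miss_rate = miss_rate,
                           seed = sub_seeds[1])
  tumor <- simulate_reads(map, partition, tumor_params, depth = depth,
                          read_span = read_span, miss_rate = miss_rate,
                          seed = sub_seeds[2])

  truth <- list(
    regions = data.frame(region_id = partition$regions$region_id,
                         label = lab,
                         a_normal = a_norm, a_tumor = a_tum,
                         b = profiles$b, c_normal = profiles$normal_c,
                         c_tumor = profiles$tumor_c),
    normal_subs = normal$truth$subs,
    tumor_subs = tumor$truth$subs
  )
  structure(list(normal = normal$reads, tumor = tumor$reads, truth = truth,
                 partition = partition, map = map, profiles = profiles,
                 config = list(seed = seed, sub_seeds = sub_seeds,
                               est_span = partition$est_span,
                               sub_span = partition$sub_span, depth = depth,
                               read_span = read_span,
                               miss_rate = miss_rate)),
            class = "pair_sim")
}

# feature class of a region: island-core classes win whenever the region
# holds a meaningful piece of core (>= min_core CpGs, ~200 bp of island),
# so islands straddling region boundaries keep their profile in both
# halves; otherwise the majority label among the region's CpGs
.region_labels <- function(map, partition, min_core = 10L) {
  regions <- partition$regions
  vapply(seq_len(nrow(regions)), function(i) {
    sites <- map$sites[map$sites$chrom == regions$chrom[i], , drop = FALSE]
    lab <- sites$label[regions$idx_first[i]:regions$idx_last[i]]
    for (core in c("bivalent_promoter", "island")) {
      if (sum(lab == core) >= min_core) return(core)
    }
    tab <- table(lab)
    names(tab)[which.max(tab)]
  }, character(1))
}

#' Fixture map for parameter-recovery simulations
#'
#' A single 20-CpG estimation region with deliberate density contrast: a
#' dense island-like cluster (20 bp gaps) followed by sparse open-sea-like
#' sites (250 bp gaps).  The contrast makes all three Ising parameters
#' identifiable — with uniform spacing `rho_n` is constant and (a, b) are
#' confounded, so recovery claims would be vacuous.
#'
#' @return a `cpg_map` with one chromosome and 20 sites.
#' @export
recovery_region_map <- function() {
  pos <- as.integer(c(seq(1001, by = 20, length.out = 10),
                      seq(1181 + 250, by = 250, length.out = 10)))
  cnt <- vapply(pos, function(p) sum(abs(pos - p) <= 500), integer(1))
  sites <- data.frame(chrom = "chr1", pos = pos, rho = pmin(1, cnt / 50),
                      gap = c(diff(pos), NA), label = "open_sea",
                      stringsAsFactors = FALSE)
  structure(list(sites = sites,
                 segments = data.frame(chrom = character(),
                                       start = integer(), end = integer(),
                                       label = character(),
                                       stringsAsFactors = FALSE),
                 chrom_lengths = c(chr1 = 4200)),
            class = "cpg_map")
}

#' Synthesize a gene table over a simulated genome
#'
#' Places `n_planted` gene TSSs at the centres of bivalent-promoter
#' segments (the planted high-discordance genes) and the remainder at
#' random positions at least `margin` bp away from any bivalent segment.
#' Strands are random; gene bodies extend 5 kb downstream of the TSS.
#'
#' @param map a `cpg_map` with bivalent-promoter segments.
#' @param n_genes total number of genes.
#' @param n_planted number of genes placed on bivalent promoters.
#' @param seed integer seed.
#' @param margin minimum distance (bp) between background TSSs and any
#'   bivalent segment.
#' @param body_length gene-body length (bp).
#' @return data.frame `chrom`, `start`, `end`, `label` (gene name),
#'   `strand`, `tss`, `planted` (1-based closed coordinates).
#' @export
synthesize_genes <- function(map, n_genes = 500, n_planted = 10, seed = 1,
                             margin = 3000, body_length = 5000) {
  set.seed(seed)
  biv <- map$segments[map$segments$label == "bivalent_promoter", ,
                      drop = FALSE]
  if (nrow(biv) < n_planted)
    stop("map has only ", nrow(biv), " bivalent-promoter segments; ",
         n_planted, " planted genes requested")
  pick <- sample.int(nrow(biv), n_planted)
  planted_tss <- as.integer(round((biv$start[pick] + biv$end[pick]) / 2))
  planted_chrom <- biv$chrom[pick]

  chroms <- names(map$chrom_lengths)
  n_bg <- n_genes - n_planted
  bg_chrom <- character(0); bg_tss <- integer(0)
  while (length(bg_tss) < n_bg) {
    ch <- sample(chroms, n_bg, replace = TRUE)
    ts <- as.integer(floor(runif(n_bg, margin + 1,
                                 map$chrom_lengths[ch] - margin)))
    ok <- vapply(seq_along(ch), function(i) {
      b <- biv[biv$chrom == ch[i], , drop = FALSE]
      !any(ts[i] >= b$start - margin & ts[i] <= b$end + margin)
    }, logical(1))
    bg_chrom <- c(bg_chrom, ch[ok])
    bg_tss <- c(bg_tss, ts[ok])
  }
  bg_chrom <- bg_chrom[seq_len(n_bg)]
  bg_tss <- bg_tss[seq_len(n_bg)]

  chrom <- c(planted_chrom, bg_chrom)
  tss <- c(planted_tss, bg_tss)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  start <- ifelse(strand == "+", tss, pmax(1L, tss - body_length))
  end <- ifelse(strand == "+",
                pmin(unname(map$chrom_lengths[chrom]), tss + body_length),
                tss)
  genes <- data.frame(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    label = sprintf("gene%03d", seq_len(n_genes)), strand = strand,
    tss = as.integer(tss),
    planted = c(rep(TRUE, n_planted), rep(FALSE, n_bg)),
    stringsAsFactors = FALSE
  )
  genes[order(genes$chrom, genes$start), , drop = FALSE]
}
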