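#' Partition a CpG map into estimation regions and analysis subregions
#'
#' Estimation regions are fixed-width genomic tiles over which Ising
#' parameters are fit (default 3000 bp); analysis subregions are nested
#' fixed-width tiles over which level distributions and summary statistics
#' are reported (default 150 bp).  Tiles are laid from position 1 of each
#' chromosome; tiles containing no CpG are dropped.  Every CpG belongs to
#' exactly one estimation region and one subregion.
#'
#' @param map a `cpg_map`.
#' @param est_span estimation-region width in bp; must be a multiple of
#'   `sub_span`.
#' @param sub_span analysis-subregion width in bp.
#' @return A `region_partition`: list with data.frames `regions`
#'   (`region_id`, `chrom`, `start`, `end`, `idx_first`, `idx_last`,
#'   `n_cpg`) and `subs` (`sub_id`, `region_id`, `chrom`, `start`, `end`,
#'   `idx_first`, `idx_last`, `K`).  `idx_*` index rows of `map$sites`
#'   within the chromosome (1-based, per-chromosome).
#' @export
partition_genome <- function(map, est_span = 3000, sub_span = 150) {
  stopifnot(inherits(map, "cpg_map"))
  if (est_span %% sub_span != 0)
    stop("est_span must be a multiple of sub_span")
  regions <- list()
  subs <- list()
  for (chrom in unique(map$sites$chrom)) {
    pos <- map$sites$pos[map$sites$chrom == chrom]
    if (is.unsorted(pos, strictly = TRUE))
      stop("CpG map positions must be strictly increasing within a chromosome")
    n_sub <- ceiling(max(pos) / sub_span)
    sub_start <- (seq_len(n_sub) - 1L) * sub_span + 1L
    sub_end <- sub_start + sub_span - 1L
    idx_first <- findInterval(sub_start - 1L, pos) + 1L
    idx_last <- findInterval(sub_end, pos)
    keep <- idx_last >= idx_first
    region_of <- (sub_start[keep] - 1L) %/% est_span + 1L
    subs[[chrom]] <- data.frame(
      chrom = chrom, start = sub_start[keep], end = sub_end[keep],
      idx_first = idx_first[keep], idx_last = idx_last[keep],
      K = idx_last[keep] - idx_first[keep] + 1L,
      region_key = paste0(chrom, ":", region_of),
      stringsAsFactors = FALSE
    )
    reg_start <- (unique(region_of) - 1L) * est_span + 1L
    r_first <- findInterval(reg_start - 1L, pos) + 1L
    r_last <- findInterval(reg_start + est_span - 1L, pos)
    regions[[chrom]] <- data.frame(
      chrom = chrom, start = reg_start, end = reg_start + est_span - 1L,
      idx_first = r_first, idx_last = r_last, n_cpg = r_last - r_first + 1L,
      region_key = paste0(chrom, ":", unique(region_of)),
      stringsAsFactors = FALSE
    )
  }
  regions <- do.call(rbind, regions)
  subs <- do.call(rbind, subs)
  regions$region_id <- seq_len(nrow(regions))
  subs$region_id <- regions$region_id[match(subs$region_key, regions$region_key)]
  subs$sub_id <- seq_len(nrow(subs))
  regions$region_key <- NULL
  subs$region_key <- NULL
  rownames(regions) <- rownames(subs) <- NULL
  structure(list(regions = regions, subs = subs,
                 est_span = est_span, sub_span = sub_span),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("Region partition:", nrow(x$regions), "estimation regions (",
      x$est_span, "bp ) /", nrow(x$subs), "analysis subregions (",
      x$sub_span, "bp )\n")
  invisible(x)
}

#' Read an epiread table
#'
#' The canonical epiread TSV has four tab-separated columns and no header:
#' chromosome, read id, index of the first covered CpG (1-based,
#' per-chromosome), and the call string over consecutive CpG units with
#' alphabet `M` (methylated), `U` (unmethylated), `.` (unobserved).  Call
#' strings must not begin or end with `.`.
#'
#' Malformed rows are dropped with a warning reporting the count; if more
#' than 10% of rows are malformed the file is rejected.
#'
#' @param path path to the TSV.
#' @return A `read_set`: data.frame with columns `chrom`, `read_id`,
#'   `first`, `calls`.
#' @export
read_epireads <- function(path) {
  if (!file.exists(path)) stop("epiread file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty epiread file: ", path)
    return(.empty_read_set())
  }
  raw <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) != 4)
    stop("epiread file must have 4 tab-separated columns")
  first <- suppressWarnings(as.integer(raw[[3]]))
  ok <- !is.na(first) & first >= 1 &
    grepl("^[MU]$|^[MU][MU.]*[MU]$", raw[[4]])
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    if (n_bad > 0.1 * nrow(raw))
      stop(n_bad, " of ", nrow(raw), " epiread rows are malformed (> 10%)")
    warning(n_bad, " malformed epiread row(s) dropped")
  }
  structure(data.frame(chrom = raw[[1]][ok], read_id = raw[[2]][ok],
                       first = first[ok], calls = raw[[4]][ok],
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

.empty_read_set <- function() {
  structure(data.frame(chrom = character(), read_id = character(),
                       first = integer(), calls = character(),
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Write an epiread table
#'
#' @param reads a `read_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epireads <- function(reads, path) {
  write.table(as.data.frame(reads)[c("chrom", "read_id", "first", "calls")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a per-subregion statistic as a bedGraph track
#'
#' Emits one `track type=bedGraph` header line followed by 0-based,
#' half-open intervals with fixed 6-decimal values.  Subregions with missing
#' values are omitted; their count is reported in a message.
#'
#' @param partition a `region_partition` (or any data.frame with `chrom`,
#'   `start`, `end` in 1-based closed coordinates).
#' @param values one numeric value per subregion, in `partition$subs` order.
#' @param path output path.
#' @param name track name for the header line.
#' @return `path`, invisibly.
#' @export
write_track <- function(partition, values, path, name = "methpel") {
  subs <- if (inherits(partition, "region_partition")) partition$subs
          else partition
  if (length(values) != nrow(subs))
    stop("need exactly one value per subregion")
  keep <- is.finite(values)
  if (any(!keep))
    message(sum(!keep), " subregion(s) with missing values omitted from ",
            basename(path))
  lines <- c(
    sprintf("track type=bedGraph name=\"%s\"", name),
    sprintf("%s\t%d\t%d\t%.6f", subs$chrom[keep], subs$start[keep] - 1L,
            subs$end[keep], values[keep])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph track written by [write_track()]
#'
#' @param path bedGraph path.
#' @return data.frame `chrom`, `start`, `end` (1-based closed), `value`.
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  df <- read.table(text = lines, sep = "\t",
                   col.names = c("chrom", "start", "end", "value"),
                   stringsAsFactors = FALSE)
  df$start <- df$start + 1L
  df
}

#' Import BED intervals as an annotation track
#'
#' Thin wrapper over [rtracklayer::import()]; the BED `name` field becomes
#' the annotation label.  Intervals arrive 0-based half-open on disk and are
#' returned as a `GRanges` (1-based closed, the Bioconductor convention).
#'
#' @param path BED file path.
#' @return `GRanges` with a `label` metadata column.
#' @export
read_bed_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  lab <- if (!is.null(gr$name)) gr$name else rep("none", length(gr))
  S4Vectors::mcols(gr)$label <- lab
  gr
}

#' Write feature segments or gene intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` (1-based closed),
#'   `label` (and optionally `strand`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  if (!is.null(df$strand)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", df$chrom, df$start - 1L,
                     df$end, df$label, df$strand)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, df$start - 1L, df$end,
                     df$label)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Serialize and restore a CpG map
#'
#' The site table goes to a BED-like TSV (with header: `chrom`, `pos`,
#' `rho`, `gap`, `label`) and the generating feature segments to a 4-column
#' BED.  `read_cpg_map()` restores both into a `cpg_map`.
#'
#' @param map a `cpg_map`.
#' @param path site-table TSV path.
#' @param segments_path optional BED path for the feature segments.
#' @return `path`, invisibly (writer); a `cpg_map` (reader).
#' @export
write_cpg_map <- function(map, path, segments_path = NULL) {
  write.table(map$sites, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(segments_path)) write_bed(map$segments, segments_path)
  invisible(path)
}

#' @rdname write_cpg_map
#' @param chrom_lengths named lengths per chromosome; defaults to the last
#'   CpG position per chromosome.
#' @export
read_cpg_map <- function(path, segments_path = NULL,
                         chrom_lengths = NULL) {
  sites <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  segments <- if (!is.null(segments_path) && file.exists(segments_path)) {
    gr <- read_bed_annotations(segments_path)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr), label = gr$label,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               label = character(), stringsAsFactors = FALSE)
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(sites$pos, sites$chrom, max)
    chrom_lengths <- setNames(as.integer(chrom_lengths),
                              names(chrom_lengths))
  }
  structure(list(sites = sites, segments = segments,
                 chrom_lengths = chrom_lengths),
            class = "cpg_map")
}

#' Assemble per-region read fragments for fitting
#'
#' Maps each read onto the estimation regions it covers; reads spanning a
#' region boundary are split at the boundary and treated as independent
#' fragments, keeping each region's likelihood self-contained.  Fragment
#' edges are trimmed of unobserved calls and fragments with no observed call
#' are dropped.  Identical fragments are collapsed with multiplicities.
#'
#' @param reads a `read_set`.
#' @param map the `cpg_map` the read indices refer to.
#' @param partition a `region_partition` of `map`.
#' @return list indexed by `region_id`; each element has `starts` (0-based
#'   offset within the region chain), `lens`, `calls` (flat integer codes:
#'   1 = M, 0 = U, -1 = unobserved), `counts` (fragment multiplicities) and
#'   `n_frag` (total informative fragments, multiplicities included).
#' @export
assemble_region_reads <- function(reads, map, partition) {
  regions <- partition$regions
  out <- vector("list", nrow(regions))
  for (chrom in unique(regions$chrom)) {
    reg <- regions[regions$chrom == chrom, , drop = FALSE]
    rr <- reads[reads$chrom == chrom, , drop = FALSE]
    if (nrow(rr) == 0) next
    len <- nchar(rr$calls)
    last <- rr$first + len - 1L
    # region index (within chrom) of each covered CpG endpoint
    r1 <- findInterval(rr$first, reg$idx_first)
    r2 <- findInterval(last, reg$idx_first)
    bad <- r1 < 1 | last > reg$idx_last[nrow(reg)]
    if (any(bad)) {
      warning(sum(bad), " read(s) outside the CpG map bounds dropped")
      rr <- rr[!bad, , drop = FALSE]
      len <- len[!bad]; last <- last[!bad]; r1 <- r1[!bad]; r2 <- r2[!bad]
    }
    for (i in seq_len(nrow(rr))) {
      codes <- .calls_to_codes(rr$calls[i])
      for (rg in r1[i]:r2[i]) {
        lo <- max(rr$first[i], reg$idx_first[rg])
        hi <- min(last[i], reg$idx_last[rg])
        if (hi < lo) next
        frag <- codes[(lo - rr$first[i] + 1L):(hi - rr$first[i] + 1L)]
        obs <- which(frag >= 0)
        if (!length(obs)) next
        frag <- frag[obs[1]:obs[length(obs)]]
        start0 <- lo + obs[1] - 1L - reg$idx_first[rg]
        rid <- reg$region_id[rg]
        key <- paste0(start0, ":", paste(frag, collapse = ""))
        acc <- out[[rid]]
        if (is.null(acc)) acc <- new.env(parent = emptyenv())
        if (is.null(acc[[key]])) acc[[key]] <- list(start0, frag, 0L)
        acc[[key]][[3]] <- acc[[key]][[3]] + 1L
        out[[rid]] <- acc
      }
    }
  }
  lapply(out, function(acc) {
    if (is.null(acc)) {
      return(list(starts = integer(), lens = integer(), calls = integer(),
                  counts = numeric(), n_frag = 0L))
    }
    keys <- sort(ls(acc)) # deterministic fragment order
    items <- lapply(keys, function(k) acc[[k]])
    list(starts = vapply(items, function(x) x[[1]], integer(1)),
         lens = vapply(items, function(x) length(x[[2]]), integer(1)),
         calls = unlist(lapply(items, function(x) x[[2]]), use.names = FALSE),
         counts = vapply(items, function(x) as.numeric(x[[3]]), numeric(1)),
         n_frag = sum(vapply(items, function(x) x[[3]], integer(1))))
  })
}

.calls_to_codes <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  unname(c(M = 1L, U = 0L, "." = -1L)[chars])
}

.codes_to_calls <- function(codes) {
  paste(c("U", "M", ".")[ifelse(codes < 0, 3L, codes + 1L)], collapse = "")
}
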