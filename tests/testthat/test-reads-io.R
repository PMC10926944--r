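test_that("epiread parsing enforces the format and survives round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\tr1\t5\tMU.M", path)
  rs <- read_epireads(path)
  expect_equal(rs$first, 5L)
  expect_equal(rs$calls, "MU.M")
  expect_equal(nchar(rs$calls), 4L) # covers CpGs 5-8, site 7 unobserved

  # empty file: empty set with a warning
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_warning(rs0 <- read_epireads(empty), "empty")
  expect_equal(nrow(rs0), 0L)

  # malformed rows dropped with warning; > 10% malformed is a hard error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(sprintf("chr1\tr%d\t1\tMUM", 1:20), "chr1\trx\t1\tMX."), bad)
  expect_warning(rs1 <- read_epireads(bad), "malformed")
  expect_equal(nrow(rs1), 20L)
  writeLines(c("chr1\tr1\t1\tMUM", "chr1\tr2\t1\t.MU", "chr1\tr3\t1\tZZ"),
             bad)
  expect_error(read_epireads(bad), "malformed")

  # write-read-write round trip is byte-identical on a synthetic set
  map <- tiny_map(seq(101, by = 50, length.out = 40))
  part <- partition_genome(map, est_span = 3000, sub_span = 150)
  sim <- simulate_reads(map, part,
                        data.frame(region_id = 1, a = 0.2, b = 0, c = 1),
                        depth = 125, read_span = 5, miss_rate = 0.1,
                        seed = 2)
  expect_gte(nrow(sim$reads), 1000)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_epireads(sim$reads, f1)
  write_epireads(read_epireads(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("genome partition tiles subregions into estimation regions", {
  # dense map: every 150 bp tile holds a CpG, 3000/150 = 20 slots filled
  map <- tiny_map(seq(10, 5990, by = 50), chrom_length = 6000)
  part <- partition_genome(map, est_span = 3000, sub_span = 150)
  expect_equal(nrow(part$regions), 2L)
  expect_true(all(table(part$subs$region_id) == 20))

  expect_error(partition_genome(map, est_span = 1000, sub_span = 300),
               "multiple")

  # one CpG: one region, one subregion, K = 1
  m1 <- tiny_map(1234)
  p1 <- partition_genome(m1)
  expect_equal(nrow(p1$regions), 1L)
  expect_equal(nrow(p1$subs), 1L)
  expect_equal(p1$subs$K, 1L)

  # partition property: no CpG lost or duplicated on random maps
  for (seed in 1:3) {
    m <- generate_cpg_map(n_chrom = 2, chrom_length = 5e4, seed = seed)
    p <- partition_genome(m)
    for (ch in unique(m$sites$chrom)) {
      subs <- p$subs[p$subs$chrom == ch, ]
      idx <- unlist(mapply(seq, subs$idx_first, subs$idx_last,
                           SIMPLIFY = FALSE))
      expect_equal(sort(idx), seq_len(sum(m$sites$chrom == ch)))
    }
    expect_equal(sum(p$subs$K), nrow(m$sites))
    expect_equal(sum(p$regions$n_cpg), nrow(m$sites))
  }
})

test_that("region assembly conserves calls and splits at boundaries", {
  map <- tiny_map(seq(101, by = 100, length.out = 60))
  part <- partition_genome(map, est_span = 3000, sub_span = 150)
  expect_gt(nrow(part$regions), 1L)
  # long reads guaranteed to straddle estimation-region boundaries
  sim <- simulate_reads(map, part,
                        data.frame(region_id = part$regions$region_id,
                                   a = 0.3, b = 0, c = 0.5),
                        depth = 6, read_span = 12, miss_rate = 0.1,
                        seed = 4)
  asm <- assemble_region_reads(sim$reads, map, part)
  calls_in <- sum(vapply(strsplit(sim$reads$calls, ""), function(x)
    sum(x != "."), integer(1)))
  calls_assigned <- sum(vapply(asm, function(rr) {
    if (rr$n_frag == 0) return(0)
    offs <- cumsum(c(0L, rr$lens))
    sum(vapply(seq_along(rr$starts), function(f)
      rr$counts[f] * sum(rr$calls[(offs[f] + 1L):offs[f + 1L]] >= 0),
      numeric(1)))
  }, numeric(1)))
  expect_equal(calls_assigned, calls_in)
})

test_that("bedGraph tracks use fixed formatting and round-trip", {
  map <- tiny_map(seq(101, by = 100, length.out = 30))
  part <- partition_genome(map, est_span = 3000, sub_span = 150)
  vals <- runif(nrow(part$subs))
  vals[3] <- NaN
  path <- withr::local_tempfile(fileext = ".bedGraph")
  expect_message(write_track(part, vals, path, name = "demo"), "1 subregion")
  lines <- readLines(path)
  expect_match(lines[1], "^track type=bedGraph")
  # fixed 6-decimal, 0-based half-open intervals
  expect_match(lines[2], "^chr1\\t\\d+\\t\\d+\\t0\\.\\d{6}$")
  sub1 <- part$subs[1, ]
  expect_equal(lines[2], sprintf("chr1\t%d\t%d\t%.6f", sub1$start - 1L,
                                 sub1$end, vals[1]))
  back <- read_track(path)
  expect_equal(nrow(back), sum(is.finite(vals)))
  expect_equal(back$value, round(vals[is.finite(vals)], 6),
               tolerance = 1e-6)
  expect_equal(back$start, part$subs$start[is.finite(vals)])

  # all-missing track: header-only file
  expect_message(write_track(part, rep(NaN, nrow(part$subs)), path),
                 "omitted")
  expect_equal(length(readLines(path)), 1L)
})

test_that("BED ingestion yields labelled 1-based GRanges", {
  path <- withr::local_tempfile(fileext = ".bed")
  df <- data.frame(chrom = "chr1", start = c(1001L, 5001L),
                   end = c(2000L, 6000L), label = c("island", "shore"))
  write_bed(df, path)
  gr <- read_bed_annotations(path)
  expect_s4_class(gr, "GRanges")
  expect_equal(GenomicRanges::start(gr), df$start)
  expect_equal(GenomicRanges::end(gr), df$end)
  expect_equal(gr$label, df$label)
})
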