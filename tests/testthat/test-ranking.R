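# hand-built differential track rows for ranking unit tests
fake_diff <- function(jsd_vals, chrom = "chr1", start0 = 1000) {
  n <- length(jsd_vals)
  structure(data.frame(sub_id = seq_len(n), chrom = chrom,
                       start = start0 + (seq_len(n) - 1) * 150,
                       end = start0 + seq_len(n) * 150 - 1,
                       K = 2L, dmml = 0, dnme = jsd_vals / 2,
                       jsd = jsd_vals),
            class = c("differential_track", "data.frame"))
}

test_that("promoter ranking takes the window maximum with positional ties", {
  d <- fake_diff(c(0.1, 0.2, 0.95, 0.2, 0.1, 0.05, 0.05, 0.3))
  genes <- data.frame(chrom = "chr1",
                      start = c(1300, 2050, 50000),
                      end = c(6300, 7050, 55000),
                      label = c("hit", "near", "far"),
                      strand = c("+", "+", "+"))
  rk <- rank_genes(d, genes, mode = "promoter_jsd", window = 500)
  expect_equal(rk$gene[which(rk$rank == 1)], "hit")
  expect_true(is.na(rk$statistic[rk$gene == "far"]))
  expect_true(is.na(rk$rank[rk$gene == "far"]))
  expect_equal(sort(rk$rank[!is.na(rk$rank)]), seq_len(2))

  # all-zero differential: ties resolved by genomic position
  d0 <- fake_diff(rep(0, 8))
  genes2 <- data.frame(chrom = "chr1", start = c(2000, 1200), end = c(2100,
                       1300), label = c("b_gene", "a_gene"),
                       strand = c("+", "+"))
  rk0 <- rank_genes(d0, genes2, mode = "promoter_jsd", window = 500)
  expect_equal(rk0$gene, c("a_gene", "b_gene"))
  expect_true(all(rk0$statistic == 0))

  # invariance to gene-table input order
  rk_shuffled <- rank_genes(d0, genes2[2:1, ], mode = "promoter_jsd",
                            window = 500)
  expect_equal(rk_shuffled$gene, rk0$gene)

  expect_error(rank_genes(d, genes[0, ]), "empty gene set")
})

test_that("planted discordant genes dominate the promoter-JSD ranking", {
  st <- cached_pair_study()
  rk <- rank_genes(st$diff, st$genes, mode = "promoter_jsd", window = 2000)
  planted <- st$genes$label[st$genes$planted]
  expect_equal(sum(planted %in% rk$gene[rk$rank <= 20]), 10L)
  # ranks are a permutation over scored genes
  expect_equal(sort(rk$rank[!is.na(rk$rank)]),
               seq_len(sum(!is.na(rk$rank))))
  # dNME mode runs on the same inputs and ranks the planted genes high
  rk2 <- rank_genes(st$diff, st$genes, mode = "promoter_dnme",
                    window = 2000)
  expect_true(all(!is.na(rk2$statistic[rk2$gene %in% planted])))
})

test_that("BH adjustment matches an independent implementation", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p),
                 tolerance = 1e-12)
  }
})

test_that("permutation test rejects planted differences and bad input", {
  map <- tiny_map(seq(101, by = 40, length.out = 12))
  part <- partition_genome(map, est_span = 600, sub_span = 150)
  strong_a <- simulate_reads(map, part,
                             data.frame(region_id = 1, a = -3, b = 0, c = 4),
                             depth = 10, read_span = 6, miss_rate = 0,
                             seed = 51)
  strong_b <- simulate_reads(map, part,
                             data.frame(region_id = 1, a = 2, b = 0, c = 1),
                             depth = 10, read_span = 6, miss_rate = 0,
                             seed = 52)
  res <- permutation_pvalue(strong_a$reads, strong_b$reads, map, part, 1,
                            n_perm = 199, seed = 9)
  # observed discordance exceeds every null draw
  expect_equal(res$p_value, 1 / 200)
  expect_gt(res$observed, max(res$null))

  expect_error(permutation_pvalue(strong_a$reads, strong_b$reads, map,
                                  part, 1, n_perm = 0), ">= 100")
  few <- strong_a$reads[1:3, ]
  class(few) <- class(strong_a$reads)
  expect_warning(r0 <- permutation_pvalue(few, strong_b$reads, map, part,
                                          1, n_perm = 100, seed = 1),
                 "insufficient")
  expect_true(is.na(r0$p_value))
})

test_that("null permutation p-values are approximately uniform", {
  pv <- cached_null_calibration()
  expect_length(pv, 200)
  # validity: P(p <= alpha) <= alpha + 0.05 across the calibration suite
  for (alpha in c(0.01, 0.05, 0.1, 0.2, 0.5)) {
    expect_lte(mean(pv <= alpha), alpha + 0.05)
  }
  # and not wildly conservative either
  expect_gte(mean(pv < 0.5), 0.25)
})

test_that("feature summary assigns subregions by midpoint label", {
  st <- cached_pair_study()
  # single label covering everything reproduces the genome-wide summary
  whole <- data.frame(chrom = names(st$map$chrom_lengths),
                      start = 1L,
                      end = unname(st$map$chrom_lengths),
                      label = "everything")
  fs <- feature_summary(st$diff, whole)
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$n, sum(is.finite(st$diff$jsd)))
  expect_equal(fs$dmml_median, median(st$diff$dmml[is.finite(st$diff$jsd)]))

  # empty annotation: everything lands under "none"
  fs0 <- feature_summary(st$diff, whole[0, ])
  expect_equal(fs0$label, "none")
  expect_equal(fs0$n, fs$n)

  # planted contrast: islands hypermethylated, open sea hypomethylated
  fs1 <- feature_summary(st$diff, st$map$segments)
  expect_gt(fs1$dmml_median[fs1$label == "island"], 0)
  expect_gt(fs1$dmml_median[fs1$label == "bivalent_promoter"], 0)
  expect_lt(fs1$dmml_median[fs1$label == "none"], 0) # open sea is unlabelled
  expect_gt(fs1$jsd_median[fs1$label == "bivalent_promoter"],
            fs1$jsd_median[fs1$label == "none"])
})

test_that("meta-profiles are strand-aware and exact on constant tracks", {
  st <- cached_pair_study()
  anchors <- data.frame(chrom = "chr1", pos = c(50000, 250000),
                        strand = c("+", "-"))
  # constant track: every populated bin averages to the constant
  const <- st$track_n
  const$mml <- rep(0.42, nrow(const))
  prof <- meta_profile(const, "mml", anchors, window = 2000, n_bins = 10)
  expect_true(all(abs(prof$mean[prof$n > 0] - 0.42) < 1e-12))

  # a subregion downstream of a minus-strand anchor has positive distance
  tr <- fake_diff(1)
  tr$start <- 9000; tr$end <- 9149 # midpoint 9074
  minus <- data.frame(chrom = "chr1", pos = 10000, strand = "-")
  prof_m <- meta_profile(tr, "jsd", minus, window = 2000, n_bins = 4)
  expect_equal(prof_m$n, c(0, 0, 1, 0)) # +500..1000 bin
  plus <- data.frame(chrom = "chr1", pos = 10000, strand = "+")
  prof_p <- meta_profile(tr, "jsd", plus, window = 2000, n_bins = 4)
  expect_equal(prof_p$n, c(0, 1, 0, 0))

  expect_error(meta_profile(st$track_n, "mml", anchors, window = 50),
               "smaller")
  expect_error(meta_profile(st$track_n, "mml", anchors[0, ]), "non-empty")

  # tumor NME sits above normal NME around TSSs
  tss <- st$genes[, c("chrom", "tss", "strand")]
  names(tss)[2] <- "pos"
  pt <- meta_profile(st$track_t, "nme", tss, window = 2000, n_bins = 20)
  pn <- meta_profile(st$track_n, "nme", tss, window = 2000, n_bins = 20)
  ok <- pt$n > 0 & pn$n > 0
  expect_gte(mean(pt$mean[ok] > pn$mean[ok]), 0.8)
})
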