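test_that("map generation is seeded-deterministic and honours structure", {
  m1 <- generate_cpg_map(n_chrom = 1, chrom_length = 5e4, seed = 11)
  m2 <- generate_cpg_map(n_chrom = 1, chrom_length = 5e4, seed = 11)
  expect_identical(m1, m2)

  # no islands requested: no island-class labels anywhere
  m0 <- generate_cpg_map(n_chrom = 1, chrom_length = 5e4,
                         island_fraction = 0, seed = 5)
  expect_false(any(m0$sites$label %in%
                     c("island", "shore", "shelf", "bivalent_promoter")))

  expect_error(generate_cpg_map(chrom_length = 500), ">= 10000")
  expect_error(generate_cpg_map(island_fraction = 1.5), "island_fraction")

  # invariants: strictly increasing positions, gap consistency, rho bounds
  m <- generate_cpg_map(n_chrom = 2, chrom_length = 1e5, seed = 21)
  for (ch in unique(m$sites$chrom)) {
    s <- m$sites[m$sites$chrom == ch, ]
    expect_true(all(diff(s$pos) >= 2))
    expect_equal(s$gap[-nrow(s)], diff(s$pos))
  }
  expect_true(all(m$sites$rho >= 0 & m$sites$rho <= 1))
})

test_that("island spacing is denser than open-sea spacing", {
  # zero-width flanks so the two spacing regimes abut directly
  m <- generate_cpg_map(n_chrom = 1, chrom_length = 1e6,
                        island_fraction = 0.5, seed = 31,
                        shore_width = 0, shelf_width = 0)
  s <- m$sites[m$sites$chrom == "chr1", ]
  gap <- s$gap[-nrow(s)]
  same_run <- s$label[-nrow(s)] == s$label[-1]
  isl <- s$label[-nrow(s)] %in% c("island", "bivalent_promoter") & same_run
  sea <- s$label[-nrow(s)] == "open_sea" & same_run
  expect_lt(mean(gap[isl]), mean(gap[sea]))
})

test_that("simulated reads follow the exact single-site marginals", {
  map1 <- tiny_map(1000)
  part1 <- partition_genome(map1, est_span = 1500, sub_span = 150)
  draw_frac <- function(a, n) {
    sim <- simulate_reads(map1, part1,
                          data.frame(region_id = 1, a = a, b = 0, c = 0),
                          depth = n, read_span = 1, miss_rate = 0,
                          seed = 17)
    mean(sim$reads$calls == "M")
  }
  # overwhelming positive field
  expect_gt(draw_frac(10, 12000), 0.999)
  # symmetric field: 0.5 within 3 standard errors
  n <- 20000
  expect_lt(abs(draw_frac(0, n) - 0.5), 3 * sqrt(0.25 / n))
  # closed-form single-site marginal e/(e + e^-1)
  p1 <- exp(1) / (exp(1) + exp(-1))
  expect_lt(abs(draw_frac(1, n) - p1), 3 * sqrt(p1 * (1 - p1) / n))
})

test_that("pattern frequencies converge to exact Ising probabilities", {
  map <- tiny_map(c(1000, 1060, 1150, 1260))
  part <- partition_genome(map, est_span = 1500, sub_span = 1500)
  pars <- data.frame(region_id = 1, a = 0.4, b = 0, c = 1.2)
  sim <- simulate_reads(map, part, pars, depth = 50000, read_span = 4,
                        miss_rate = 0, seed = 23)
  expect_gte(nrow(sim$reads), 50000)
  emp <- table(factor(sim$reads$calls,
                      levels = apply(expand.grid(rep(list(c("U", "M")), 4)),
                                     1, paste, collapse = "")))
  emp <- as.numeric(emp) / sum(emp)
  fl <- ising_fields(list(a = 0.4, b = 0, c = 1.2), map$sites$rho,
                     diff(map$sites$pos))
  or <- enum_landscape(fl$alpha, fl$beta)
  # both enumerations vary site 1 fastest, so orders align
  expect_lt(sum(abs(emp - exp(or$logp))) / 2, 0.02)
})

test_that("simulation truth equals the exact level-distribution routine", {
  map <- tiny_map(seq(501, by = 80, length.out = 12))
  part <- partition_genome(map, est_span = 1500, sub_span = 300)
  pars <- data.frame(region_id = part$regions$region_id, a = -0.7, b = 0.5,
                     c = 2)
  sim <- simulate_reads(map, part, pars, depth = 2, read_span = 4,
                        miss_rate = 0, seed = 3)
  for (j in seq_len(nrow(sim$truth$subs))) {
    sub <- part$subs[j, ]
    reg <- part$regions[part$regions$region_id == sub$region_id, ]
    idx <- reg$idx_first:reg$idx_last
    fl <- ising_fields(list(a = -0.7, b = 0.5, c = 2),
                       map$sites$rho[idx], diff(map$sites$pos[idx]))
    p <- level_distribution(fl, (sub$idx_first:sub$idx_last) -
                              reg$idx_first + 1L)
    expect_equal(sim$truth$subs$mml[j], mml(p), tolerance = 1e-10)
    expect_equal(sim$truth$subs$nme[j], nme(p), tolerance = 1e-10)
  }
  # seeded determinism of the read draw
  sim2 <- simulate_reads(map, part, pars, depth = 2, read_span = 4,
                         miss_rate = 0, seed = 3)
  expect_identical(sim$reads, sim2$reads)
})

test_that("the planted tumor/normal pair has the designed truth structure", {
  st <- cached_pair_study()
  truth <- st$pair$truth
  lab <- truth$regions$label[match(truth$normal_subs$region_id,
                                   truth$regions$region_id)]
  sea <- lab %in% c("open_sea", "heterochromatin")
  # global hypomethylation over open-sea subregions
  expect_lt(median(truth$tumor_subs$mml[sea]),
            median(truth$normal_subs$mml[sea]))
  # globally elevated methylation entropy
  expect_gt(median(truth$tumor_subs$nme), median(truth$normal_subs$nme))
  # focal hypermethylation at bivalent promoters
  biv <- lab == "bivalent_promoter"
  expect_true(any(biv))
  expect_gt(median(truth$tumor_subs$mml[biv]),
            median(truth$normal_subs$mml[biv]))
})
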