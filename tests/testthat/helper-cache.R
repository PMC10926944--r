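# Expensive seeded runs computed once per test session and shared across
# test files.  Seeds are fixed study conditions, not tunables.

.methpel_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.methpel_cache[[key]])) .methpel_cache[[key]] <- builder()
  .methpel_cache[[key]]
}

# full-scale paired tumor/normal study at the generator defaults
cached_pair_study <- function() {
  cache_get("pair_study", function() {
    map <- generate_cpg_map(seed = 101)
    partition <- partition_genome(map)
    pair <- make_tumor_normal_pair(map, seed = 202, partition = partition)
    fit_n <- fit_sample(pair$normal, map, partition)
    fit_t <- fit_sample(pair$tumor, map, partition)
    track_n <- landscape_track(fit_n, map, partition)
    track_t <- landscape_track(fit_t, map, partition)
    diff <- differential_track(track_t, track_n)
    genes <- synthesize_genes(map, n_genes = 500, n_planted = 10,
                              seed = 303)
    sub_label <- pair$truth$regions$label[
      match(partition$subs$region_id, pair$truth$regions$region_id)]
    list(map = map, partition = partition, pair = pair,
         fit_n = fit_n, fit_t = fit_t,
         track_n = track_n, track_t = track_t, diff = diff,
         genes = genes, sub_label = sub_label)
  })
}

# 50 seeded replicates of 2,000 complete reads on the 20-CpG
# density-contrast region at (a, b, c) = (1, 0, 2)
cached_recovery <- function() {
  cache_get("recovery", function() {
    map <- recovery_region_map()
    partition <- partition_genome(map, est_span = 4500, sub_span = 150)
    truth <- data.frame(region_id = 1, a = 1, b = 0, c = 2)
    est <- t(vapply(1:50, function(s) {
      sim <- simulate_reads(map, partition, truth, depth = 2000,
                            read_span = 20, miss_rate = 0, seed = 7000 + s)
      f <- fit_sample(sim$reads, map, partition)
      c(a = f$a[1], b = f$b[1], c = f$c[1])
    }, numeric(3)))
    list(estimates = est, truth = c(a = 1, b = 0, c = 2))
  })
}

# 200-region null calibration: both samples drawn from the same landscape,
# 199 label permutations each
cached_null_calibration <- function() {
  cache_get("null_calibration", function() {
    map <- tiny_map(seq(101, by = 60, length.out = 8))
    partition <- partition_genome(map, est_span = 600, sub_span = 150)
    truth <- data.frame(region_id = 1, a = 0.5, b = 0, c = 1)
    vapply(1:200, function(s) {
      a <- simulate_reads(map, partition, truth, depth = 8, read_span = 4,
                          miss_rate = 0.05, seed = 40000 + s)
      b <- simulate_reads(map, partition, truth, depth = 8, read_span = 4,
                          miss_rate = 0.05, seed = 80000 + s)
      permutation_pvalue(a$reads, b$reads, map, partition, 1,
                         n_perm = 199, seed = s)$p_value
    }, numeric(1))
  })
}
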