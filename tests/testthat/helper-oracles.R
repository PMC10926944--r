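# Independent oracles: brute-force enumeration over all 2^N methylation
# patterns (log-space), direct-summation JSD, and hand-rolled BH.  These
# never call the transfer-matrix code paths they are used to check.

enum_landscape <- function(alpha, beta) {
  N <- length(alpha)
  pats <- as.matrix(expand.grid(rep(list(0:1), N), KEEP.OUT.ATTRS = FALSE))
  logw <- apply(pats, 1, function(x) {
    s <- 2 * x - 1
    sum(alpha * s) + if (N > 1) sum(beta * s[-N] * s[-1]) else 0
  })
  mx <- max(logw)
  logZ <- mx + log(sum(exp(logw - mx)))
  list(pats = pats, logp = logw - logZ, logZ = logZ)
}

oracle_level_dist <- function(or, subset) {
  k <- rowSums(or$pats[, subset, drop = FALSE])
  vapply(0:length(subset), function(kk) sum(exp(or$logp)[k == kk]),
         numeric(1))
}

# marginal probability of a call string starting at site `first`
oracle_read_marginal <- function(or, first, calls) {
  ch <- strsplit(calls, "", fixed = TRUE)[[1]]
  idx <- first:(first + length(ch) - 1)
  ok <- rep(TRUE, nrow(or$pats))
  for (j in seq_along(ch)) {
    if (ch[j] == "M") ok <- ok & or$pats[, idx[j]] == 1
    if (ch[j] == "U") ok <- ok & or$pats[, idx[j]] == 0
  }
  sum(exp(or$logp)[ok])
}

# direct-summation Jensen-Shannon distance, base-2 logs
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  acc <- 0
  for (k in seq_along(p)) {
    if (p[k] > 0) acc <- acc + 0.5 * p[k] * (log2(p[k]) - log2(m[k]))
    if (q[k] > 0) acc <- acc + 0.5 * q[k] * (log2(q[k]) - log2(m[k]))
  }
  sqrt(acc)
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(1, q)
  out
}

# handmade CpG map from explicit positions (single chromosome)
tiny_map <- function(pos, chrom_length = max(pos) + 500L, label = "open_sea") {
  pos <- as.integer(sort(pos))
  cnt <- vapply(pos, function(p) sum(abs(pos - p) <= 500), integer(1))
  sites <- data.frame(chrom = "chr1", pos = pos, rho = pmin(1, cnt / 50),
                      gap = c(diff(pos), NA), label = label,
                      stringsAsFactors = FALSE)
  structure(list(sites = sites,
                 segments = data.frame(chrom = character(),
                                       start = integer(), end = integer(),
                                       label = character(),
                                       stringsAsFactors = FALSE),
                 chrom_lengths = c(chr1 = as.integer(chrom_length))),
            class = "cpg_map")
}

random_fields <- function(N) {
  list(alpha = runif(N, -6, 6),
       beta = if (N > 1) runif(N - 1, -4, 4) else numeric(0))
}
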