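#' Ising parameters and covariate construction
#'
#' A region's landscape is governed by three parameters: `a` (field
#' intercept), `b` (field coefficient on local CpG density) and `c`
#' (coupling scaled by inverse spacing).  Per-site fields and per-pair
#' couplings are
#' \deqn{\alpha_n = a + b \rho_n, \qquad \beta_n = c / d_n,}
#' where `rho_n` is the local CpG density in \[0, 1\] (see
#' [generate_cpg_map()]) and `d_n` the bp gap between adjacent CpGs, capped
#' at 1000 bp.  Positive `a` favours methylation; positive `c` makes
#' neighbouring sites agree.
#'
#' @param a,b,c numeric parameters; box-constrained to |a|, |b| <= 10 and
#'   |c| <= 20.
#' @return An `ising_params` list.
#' @export
ising_params <- function(a, b = 0, c = 0) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  if (abs(a) > 10 || abs(b) > 10 || abs(c) > 20)
    stop("parameters outside the box |a|,|b| <= 10, |c| <= 20")
  structure(list(a = a, b = b, c = c), class = "ising_params")
}

#' Per-site fields and pair couplings for a set of region sites
#'
#' @param params an `ising_params` (or list with `a`, `b`, `c`).
#' @param rho per-site CpG densities in \[0, 1\].
#' @param gaps bp gaps between adjacent sites (length N - 1); capped at
#'   1000 bp in the coupling.
#' @return list with `alpha` (length N) and `beta` (length N - 1).
#' @export
ising_fields <- function(params, rho, gaps) {
  n <- length(rho)
  stopifnot(length(gaps) == max(n - 1, 0))
  list(alpha = params$a + params$b * rho,
       beta = if (n > 1) params$c / pmin(gaps, 1000) else numeric(0))
}

#' Potential of a methylation pattern
#'
#' \eqn{V(x) = -\sum_n \alpha_n \tilde x_n - \sum_n \beta_n \tilde x_n
#' \tilde x_{n+1}} with \eqn{\tilde x = 2x - 1}.  Lower potential means
#' higher probability: \eqn{P(x) = e^{-V(x)} / Z}.
#'
#' @param fields list with `alpha`, `beta` (see [ising_fields()]).
#' @param pattern binary vector in \{0, 1\}^N.
#' @return the potential (numeric scalar).
#' @export
potential <- function(fields, pattern) {
  s <- 2 * pattern - 1
  if (length(s) != length(fields$alpha))
    stop("pattern length does not match the number of region sites")
  v <- -sum(fields$alpha * s)
  if (length(s) > 1)
    v <- v - sum(fields$beta * s[-length(s)] * s[-1])
  v
}

#' Log partition function of a region chain
#'
#' Computed by 2x2 transfer-matrix products with per-step rescaling
#' (log-space accumulation), O(N) time and overflow-free for any fields.
#'
#' @inheritParams potential
#' @return log Z.
#' @export
log_partition <- function(fields) {
  cpp_log_partition(fields$alpha, fields$beta)
}

#' Log marginal probability of a read's calls
#'
#' Unobserved sites (`.`) inside the covered window and all sites outside
#' it are summed out exactly by forward-backward message passing over the
#' chain.
#'
#' @inheritParams potential
#' @param first 1-based index (within the region chain) of the first
#'   covered site.
#' @param calls call string over consecutive sites, alphabet `M`/`U`/`.`.
#' @return log probability of the observed calls.
#' @export
read_loglikelihood <- function(fields, first, calls) {
  codes <- .calls_to_codes(calls)
  cpp_reads_loglik(fields$alpha, fields$beta, first - 1L, length(codes),
                   codes)[1]
}

#' Exact methylation-level distribution of a subregion
#'
#' P(L = k/K) for the fraction of methylated CpGs among a subset of K sites
#' of the region chain, via transfer-matrix dynamic programming augmented
#' with a methylated-site counter (O(N K) time).  The remaining chain sites
#' are marginalized exactly.
#'
#' @inheritParams potential
#' @param subset 1-based indices (within the region chain) of the
#'   subregion's sites.
#' @return A `level_distribution`: numeric vector of length K + 1 with
#'   probabilities of levels 0/K, ..., K/K (attribute `K`).
#' @export
level_distribution <- function(fields, subset = seq_along(fields$alpha)) {
  if (length(subset) == 0) stop("subregion must contain at least one site")
  p <- cpp_level_distribution(fields$alpha, fields$beta,
                              as.integer(subset) - 1L)
  structure(as.numeric(p), K = length(subset), class = "level_distribution")
}

#' Default multi-start grid for the Nelder-Mead fit
#'
#' @param a_starts,b_starts,c_starts start values per coordinate; the grid
#'   is their Cartesian product (3 x 3 x 3 = 27 starts by default).
#' @return numeric matrix with columns a, b, c.
#' @export
ising_start_grid <- function(a_starts = c(-5, 0, 5), b_starts = c(-5, 0, 5),
                             c_starts = c(-10, 0, 10)) {
  as.matrix(expand.grid(a = a_starts, b = b_starts, c = c_starts,
                        KEEP.OUT.ATTRS = FALSE))
}

#' Fit Ising parameters to one estimation region
#'
#' Maximizes the sum of read log-likelihoods over (a, b, c) within the box
#' |a|, |b| <= 10, |c| <= 20 by Nelder-Mead restarted from a fixed start
#' grid (function tolerance 1e-6); deterministic given the grid, with ties
#' between starts broken by the earliest start.
#'
#' @param region_reads assembled fragments for the region, as one element
#'   of [assemble_region_reads()].
#' @param rho per-site densities for the region chain.
#' @param gaps bp gaps between adjacent region sites (length N - 1).
#' @param start_grid start matrix, see [ising_start_grid()].
#' @param tol relative function tolerance.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param fix_b fix the density coefficient at 0 (useful where `rho` is
#'   nearly constant and (a, b) would ride a likelihood ridge).
#' @return list with `params` (`ising_params`), `logL`, `converged`,
#'   `start_index`, `n_reads`.
#' @export
fit_parameters <- function(region_reads, rho, gaps,
                           start_grid = ising_start_grid(),
                           tol = 1e-6, maxit = 500, fix_b = FALSE) {
  if (region_reads$n_frag == 0) stop("no informative reads in region")
  b_box <- if (fix_b) 0 else 10
  fit <- cpp_fit_ising(as.integer(region_reads$starts),
                       as.integer(region_reads$lens),
                       as.integer(region_reads$calls),
                       as.numeric(region_reads$counts),
                       as.numeric(rho),
                       as.numeric(pmin(gaps, 1000)),
                       start_grid,
                       c(-10, -b_box, -20), c(10, b_box, 20), tol,
                       as.integer(maxit))
  list(params = ising_params(fit$par[1], fit$par[2], fit$par[3]),
       logL = fit$logL, converged = fit$converged,
       start_index = fit$start_index, n_reads = region_reads$n_frag)
}

#' Fit all estimation regions of one sample
#'
#' Regions with fewer than `min_region_reads` informative fragments are not
#' fit and carry NA parameters (excluded downstream).
#'
#' @param reads a `read_set`.
#' @param map the `cpg_map`.
#' @param partition a `region_partition`.
#' @param min_region_reads minimum informative fragments to fit a region.
#' @param start_grid,tol,maxit passed to [fit_parameters()].
#' @param assembled optional precomputed [assemble_region_reads()] output.
#' @return A `landscape_fit`: data.frame (`region_id`, `chrom`, `start`,
#'   `end`, `a`, `b`, `c`, `logL`, `n_reads`, `converged`) with the
#'   assembled fragments attached as attribute `assembled`.
#' @export
fit_sample <- function(reads, map, partition, min_region_reads = 20,
                       start_grid = ising_start_grid(), tol = 1e-6,
                       maxit = 500, assembled = NULL) {
  if (is.null(assembled))
    assembled <- assemble_region_reads(reads, map, partition)
  regions <- partition$regions
  n <- nrow(regions)
  out <- data.frame(region_id = regions$region_id, chrom = regions$chrom,
                    start = regions$start, end = regions$end,
                    a = NA_real_, b = NA_real_, c = NA_real_,
                    logL = NA_real_, n_reads = 0L, converged = FALSE)
  for (i in seq_len(n)) {
    rr <- assembled[[regions$region_id[i]]]
    if (is.null(rr)) next
    out$n_reads[i] <- rr$n_frag
    if (rr$n_frag < min_region_reads) next
    cov <- .region_covariates(map, regions[i, ])
    fit <- fit_parameters(rr, cov$rho, cov$gaps, start_grid = start_grid,
                          tol = tol, maxit = maxit)
    out$a[i] <- fit$params$a
    out$b[i] <- fit$params$b
    out$c[i] <- fit$params$c
    out$logL[i] <- fit$logL
    out$converged[i] <- fit$converged
  }
  structure(out, assembled = assembled, class = c("landscape_fit",
                                                  "data.frame"))
}

#' Write a per-region parameter table
#'
#' @param fit a `landscape_fit`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(fit, path) {
  df <- as.data.frame(fit)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# rho and gaps for the chain of one estimation region (gaps from the
# region's own consecutive positions; density from the genome-wide map)
.region_covariates <- function(map, region_row) {
  sites <- map$sites[map$sites$chrom == region_row$chrom, , drop = FALSE]
  idx <- region_row$idx_first:region_row$idx_last
  pos <- sites$pos[idx]
  list(rho = sites$rho[idx],
       gaps = if (length(pos) > 1) diff(pos) else numeric(0),
       pos = pos)
}
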