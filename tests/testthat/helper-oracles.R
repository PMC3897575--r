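# Independent oracles used across the test files.  These deliberately avoid
# the package's own code paths: regions come straight from the defining tail
# inequalities applied to an enumeration pmf, and Jost's D is re-derived
# from heterozygosities in plain arithmetic.

# Equal-tail acceptance region straight from the definition, by scanning
# every k: k_lo is the largest integer with P(K < k_lo) <= alpha/2, k_hi
# the smallest with P(K > k_hi) <= alpha/2.
oracle_region <- function(pmf, alpha) {
  kmax <- length(pmf) - 1L
  a2 <- alpha / 2 + 1e-12
  k_lo <- 0L
  for (k in 0:kmax) {
    if (sum(pmf[seq_len(k)]) <= a2) k_lo <- k else break
  }
  k_hi <- kmax
  for (k in kmax:0) {
    if (sum(pmf[seq_len(kmax - k) + k + 1L]) <= a2) k_hi <- k else break
  }
  c(k_lo, k_hi)
}

# Accepted candidate rows for one observation, from brute-force pmfs and
# oracle regions, with the same halving relaxation contract.
oracle_accepted <- function(M, N, k_obs, alpha, grid) {
  pmfs <- lapply(seq_len(nrow(grid)), function(i)
    brute_force_pmf(M, N, grid$p[i], grid$P[i])$pmf)
  inside_hull <- vapply(pmfs, function(f)
    sum(f[seq_len(k_obs + 1L)]) > 0 && sum(f[(k_obs + 1L):length(f)]) > 0,
    logical(1))
  if (!any(inside_hull)) {
    return(NULL)  # impossible observation
  }
  a <- alpha
  repeat {
    acc <- vapply(pmfs, function(f) {
      r <- oracle_region(f, a)
      r[1] <= k_obs && k_obs <= r[2]
    }, logical(1))
    if (any(acc)) return(list(accepted = which(acc), effective_alpha = a))
    a <- a / 2
  }
}

# Jost's D re-derived from within/total heterozygosities.
oracle_jost_d <- function(f1, f2) {
  hs <- 1 - (sum(f1 * f1) + sum(f2 * f2)) / 2
  ht <- 1 - sum(((f1 + f2) / 2)^2)
  2 * (ht - hs) / (1 - hs)
}

# Range of Jost's D over a 2-allele-per-population toy box by dense grid
# search on the single free frequency of each population.
oracle_d_range_2allele <- function(lo1, hi1, lo2, hi2, step = 0.001) {
  g1 <- seq(lo1, hi1, by = step)
  g2 <- seq(lo2, hi2, by = step)
  vals <- outer(g1, g2, Vectorize(function(a, b)
    oracle_jost_d(c(a, 1 - a), c(b, 1 - b))))
  range(vals)
}
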