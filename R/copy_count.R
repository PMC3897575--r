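# Exact sampling distribution of the number of copies of one allele in a
# without-replacement sample of N diploid individuals.
#
# With respect to one focal allele the population splits into three genotype
# classes: m2 = MP homozygotes, m1 = 2M(p - P) heterozygous carriers and
# m0 = M(1 - 2p + P) non-carriers.  The sampled class counts (x2, x1, x0)
# follow a multivariate hypergeometric distribution, and the copy count
# K = 2*x2 + x1 has pmf obtained by summing the triple pmf over the feasible
# sampled-homozygote counts x2.
#
# Numerics: when choose(M, N) < 2^53 every term is an exactly representable
# integer and weights are accumulated in exact integer arithmetic (the
# "exact" path, used by the enumeration-oracle comparisons); otherwise terms
# are computed on the log scale via lchoose and exponentiated, which is
# accurate to ~1e-15 relative error because every term is a probability.

.LOG_EXACT_LIMIT <- 53 * log(2)

.class_counts_int <- function(M, a, h) {
  m2 <- h
  m1 <- a - 2L * h
  m0 <- M - a + h
  if (m2 < 0L || m1 < 0L || m0 < 0L) {
    .err(sprintf(paste0("infeasible genotype class counts for M=%d, p=%g, P=%g ",
                        "(homozygotes=%d, heterozygotes=%d, non-carriers=%d)"),
                 M, a / (2 * M), h / M, m2, m1, m0),
         "alleleCI_feasibility_error")
  }
  c(m2, m1, m0)
}

# Validate (M, N, p, P) and return list(M, N, a, h, m) with integer counts.
.resolve_params <- function(M, N, p, P, check_N = TRUE) {
  M <- .check_scalar_count(M, "M", min = 1L)
  if (check_N) {
    N <- .check_scalar_count(N, "N", min = 1L)
    if (N > M) .err("`N` must not exceed `M`", "alleleCI_invalid_argument")
  }
  if (!.is_whole(2 * M * p)) {
    .err("`2 * M * p` must be an integer", "alleleCI_feasibility_error")
  }
  if (!.is_whole(M * P)) {
    .err("`M * P` must be an integer", "alleleCI_feasibility_error")
  }
  a <- as.integer(round(2 * M * p))
  h <- as.integer(round(M * P))
  if (a < 0L || a > 2L * M) .err("`p` must lie in [0, 1]", "alleleCI_feasibility_error")
  list(M = M, N = N, a = a, h = h, m = .class_counts_int(M, a, h))
}

#' Genotype class counts implied by (p, P)
#'
#' @param M Population size.
#' @param p Focal-allele frequency (multiple of 1/(2M)).
#' @param P Focal-allele homozygote frequency (multiple of 1/M).
#' @return Named integer vector `c(m2, m1, m0)`: numbers of individuals with
#'   two, one and zero copies of the focal allele.  Satisfies
#'   `(2*m2 + m1) / (2*M) == p`.
#' @examples
#' genotype_class_counts(1000, 0.5, 0.25)  # 250 500 250
#' @export
genotype_class_counts <- function(M, p, P) {
  pr <- .resolve_params(M, NULL, p, P, check_N = FALSE)
  setNames(pr$m, c("m2", "m1", "m0"))
}

#' Multivariate hypergeometric probability of a sampled genotype triple
#'
#' Probability of drawing exactly `x2` homozygotes, `x1` heterozygous
#' carriers and `x0` non-carriers of the focal allele in a
#' without-replacement sample of `N = x2 + x1 + x0` individuals.
#'
#' @param x2,x1,x0 Sampled genotype class counts (non-negative integers).
#' @inheritParams genotype_class_counts
#' @param N Sample size; must equal `x2 + x1 + x0`.
#' @return A probability; zero when any class count exceeds its population
#'   class size.
#' @examples
#' triple_pmf(0, 2, 0, M = 4, N = 2, p = 0.5, P = 0.25)  # 1/6
#' @export
triple_pmf <- function(x2, x1, x0, M, N, p, P) {
  x2 <- .check_scalar_count(x2, "x2")
  x1 <- .check_scalar_count(x1, "x1")
  x0 <- .check_scalar_count(x0, "x0")
  pr <- .resolve_params(M, N, p, P)
  if (x2 + x1 + x0 != pr$N) {
    .err("`x2 + x1 + x0` must equal `N`", "alleleCI_invalid_argument")
  }
  m <- pr$m
  if (x2 > m[1] || x1 > m[2] || x0 > m[3]) return(0)
  if (lchoose(pr$M, pr$N) < .LOG_EXACT_LIMIT) {
    choose(m[1], x2) * choose(m[2], x1) * choose(m[3], x0) / choose(pr$M, pr$N)
  } else {
    exp(lchoose(m[1], x2) + lchoose(m[2], x1) + lchoose(m[3], x0) -
          lchoose(pr$M, pr$N))
  }
}

#' Feasible range of sampled homozygotes for a given copy count
#'
#' For a sample containing `k` copies of the focal allele, the sampled
#' homozygote count `x2` must satisfy the double inequality obtained by
#' rearranging the six feasibility constraints on the genotype triple
#' (each sampled class non-negative and no larger than its population
#' class): `ceil(max((k - m1)/2, k - N)) <= x2 <= floor(min(m2, k/2,
#' m0 - N + k))`.
#'
#' @param k Copy count in `0..2N`.
#' @inheritParams triple_pmf
#' @return Named integer vector `c(lower, upper)`.  `lower > upper` means no
#'   feasible triple exists and the pmf at `k` is zero.
#' @examples
#' x2_bounds(2, M = 4, N = 2, p = 0.5, P = 0.25)  # c(0, 1)
#' @export
x2_bounds <- function(k, M, N, p, P) {
  k <- .check_scalar_count(k, "k")
  pr <- .resolve_params(M, N, p, P)
  m <- pr$m
  L <- max(0, ceiling((k - m[2]) / 2), k - pr$N)
  U <- min(m[1], floor(k / 2), m[3] - pr$N + k)
  c(lower = as.integer(L), upper = as.integer(U))
}

# Core pmf computation over k = 0..2N.  Enumerates all feasible (x2, x1)
# pairs (x0 = N - x2 - x1) and aggregates weights by k = 2*x2 + x1; this is
# term-for-term the sum over the x2_bounds() range for each k.
# Returns list(pmf, weights, exact); weights are the exact integer
# numerators over choose(M, N) when exact, otherwise NULL.
.pmf_vector <- function(M, N, m2, m1, m0) {
  exact <- lchoose(M, N) < .LOG_EXACT_LIMIT
  x2 <- 0:min(N, m2)
  x1hi <- pmin(N - x2, m1)
  x1lo <- pmax(0L, N - x2 - m0)
  keep <- x1lo <= x1hi
  x2 <- x2[keep]; x1lo <- x1lo[keep]; x1hi <- x1hi[keep]
  if (length(x2) == 0L) {
    .err("no feasible sample exists for these parameters",
         "alleleCI_feasibility_error")
  }
  nx <- x1hi - x1lo + 1L
  x2v <- rep.int(x2, nx)
  x1v <- sequence(nx, from = x1lo, by = 1L)
  x0v <- N - x2v - x1v
  kv <- 2L * x2v + x1v
  pmf <- numeric(2L * N + 1L)
  if (exact) {
    w <- choose(m2, x2v) * choose(m1, x1v) * choose(m0, x0v)
    s <- rowsum(w, kv)
    weights <- numeric(2L * N + 1L)
    weights[as.integer(rownames(s)) + 1L] <- s[, 1L]
    pmf <- weights / choose(M, N)
  } else {
    w <- exp(lchoose(m2, x2v) + lchoose(m1, x1v) + lchoose(m0, x0v) -
               lchoose(M, N))
    s <- rowsum(w, kv)
    pmf[as.integer(rownames(s)) + 1L] <- s[, 1L]
    weights <- NULL
  }
  tot <- sum(pmf)
  if (abs(tot - 1) > 1e-9) {
    .err(sprintf("pmf failed to normalize (sum = %.15g)", tot),
         "alleleCI_internal_error")
  }
  list(pmf = pmf, weights = weights, exact = exact)
}

# Cache of pmf vectors keyed by (M, N, copy count, homozygote count); the
# confidence-interval sweeps reuse the same distributions many times.
.pmf_cache <- new.env(parent = emptyenv())

.cached_pmf <- function(M, N, a, h) {
  key <- paste(M, N, a, h, sep = "_")
  v <- .pmf_cache[[key]]
  if (is.null(v)) {
    if (length(ls(.pmf_cache, sorted = FALSE)) >= 4096L) clear_pmf_cache()
    m <- .class_counts_int(M, a, h)
    v <- .pmf_vector(M, N, m[1], m[2], m[3])$pmf
    assign(key, v, envir = .pmf_cache)
  }
  v
}

#' Empty the internal cache of copy-count distributions
#'
#' The cache is bounded (it clears itself after 4096 entries) so calling
#' this is only needed to release memory eagerly.
#' @return Invisibly, the number of entries removed.
#' @export
clear_pmf_cache <- function() {
  n <- length(ls(.pmf_cache, sorted = FALSE))
  rm(list = ls(.pmf_cache, sorted = FALSE), envir = .pmf_cache)
  invisible(n)
}

#' Exact distribution of the focal-allele copy count in the sample
#'
#' @inheritParams triple_pmf
#' @return An object of class `"copy_count_distribution"`: a list with
#'   `k = 0:(2N)`, `pmf`, `cdf`, the parameters, and `exact` indicating
#'   whether the exact integer path was used (in which case `weights` holds
#'   the integer numerators over `choose(M, N)`).
#' @examples
#' copy_count_pmf(4, 2, 0.5, 0.25)$pmf  # 0 1/3 1/3 1/3 0
#' @export
copy_count_pmf <- function(M, N, p, P) {
  pr <- .resolve_params(M, N, p, P)
  m <- pr$m
  res <- .pmf_vector(pr$M, pr$N, m[1], m[2], m[3])
  assign(paste(pr$M, pr$N, pr$a, pr$h, sep = "_"), res$pmf, envir = .pmf_cache)
  structure(list(M = pr$M, N = pr$N, p = pr$a / (2 * pr$M), P = pr$h / pr$M,
                 k = 0:(2L * pr$N), pmf = res$pmf, cdf = cumsum(res$pmf),
                 weights = res$weights, exact = res$exact),
            class = "copy_count_distribution")
}

#' @export
print.copy_count_distribution <- function(x, ...) {
  cat(sprintf("Copy-count distribution: M = %d, N = %d, p = %g, P = %g\n",
              x$M, x$N, x$p, x$P))
  supp <- range(x$k[x$pmf > 0])
  cat(sprintf("  support [%d, %d], mean p_hat = %g, sd p_hat = %g\n",
              supp[1], supp[2], x$p, sqrt(copy_count_variance(x$M, x$N, x$p, x$P))))
  invisible(x)
}

#' Mean of the sample allele frequency
#'
#' The sample allele frequency is unbiased for any (M, N, P): `E[p_hat] = p`,
#' exactly as when sampling from an infinite diploid population.
#'
#' @inheritParams triple_pmf
#' @return `p`.
#' @export
copy_count_mean <- function(M, N, p, P) {
  pr <- .resolve_params(M, N, p, P)
  pr$a / (2 * pr$M)
}

#' Variance of the sample allele frequency
#'
#' Closed form
#' \deqn{Var(\hat p) = \frac{M - N}{M - 1}\,\frac{p(1 - p) + P - p^2}{2N},}
#' i.e. the infinite-population variance (which depends on the excess
#' homozygosity \eqn{P - p^2}) scaled by the standard finite population
#' correction factor.  At `N = M` (census) the variance is zero; `M = 1` is
#' handled as a zero-variance census.
#'
#' @inheritParams triple_pmf
#' @return The variance of \eqn{\hat p = K/(2N)}.
#' @export
copy_count_variance <- function(M, N, p, P) {
  pr <- .resolve_params(M, N, p, P)
  if (pr$M == 1L) return(0)
  p <- pr$a / (2 * pr$M); P <- pr$h / pr$M
  (pr$M - pr$N) / (pr$M - 1) * (p * (1 - p) + P - p^2) / (2 * pr$N)
}

#' Cumulative distribution function of the copy count
#'
#' @inheritParams triple_pmf
#' @param k Integer in `0..2N`.
#' @return `P(K <= k)`.
#' @export
copy_count_cdf <- function(M, N, p, P, k) {
  k <- .check_scalar_count(k, "k")
  pr <- .resolve_params(M, N, p, P)
  if (k > 2L * pr$N) .err("`k` must lie in 0..2N", "alleleCI_invalid_argument")
  pmf <- .cached_pmf(pr$M, pr$N, pr$a, pr$h)
  sum(pmf[seq_len(k + 1L)])
}

#' Brute-force enumeration oracle for the copy-count distribution
#'
#' Enumerates every N-subset of an explicit M-genotype population and
#' tabulates the focal-allele copy count.  Exactly equals
#' [copy_count_pmf()]; intended as an independent correctness oracle on
#' tiny instances.
#'
#' @inheritParams triple_pmf
#' @return An object of class `"copy_count_distribution"` whose `weights`
#'   element holds the integer subset counts per `k` (out of
#'   `choose(M, N)`).
#' @export
brute_force_pmf <- function(M, N, p, P) {
  pr <- .resolve_params(M, N, p, P)
  if (choose(pr$M, pr$N) > 1e6) {
    .err("instance too large for brute-force enumeration (choose(M, N) > 1e6)",
         "alleleCI_invalid_argument")
  }
  m <- pr$m
  copies <- rep.int(c(2L, 1L, 0L), m)
  ks <- combn(pr$M, pr$N, FUN = function(idx) sum(copies[idx]))
  counts <- tabulate(ks + 1L, nbins = 2L * pr$N + 1L)
  pmf <- counts / choose(pr$M, pr$N)
  structure(list(M = pr$M, N = pr$N, p = pr$a / (2 * pr$M), P = pr$h / pr$M,
                 k = 0:(2L * pr$N), pmf = pmf, cdf = cumsum(pmf),
                 weights = counts, exact = TRUE),
            class = "copy_count_distribution")
}
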