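# Explicit finite populations and without-replacement sampling.  These are
# the empirical oracles for the exact distribution and for interval
# coverage: a population is a static urn of M genotypes, with no
# Wright-Fisher dynamics, mutation or migration.

#' Construct an explicit finite population with given per-allele marginals
#'
#' Builds `M` individual genotypes realizing the requested allele and
#' homozygote frequencies exactly.  Homozygote counts per allele are forced
#' (\eqn{MP_{jj}} individuals); the remaining allele copies are placed in
#' heterozygotes by deterministically pairing the two alleles with the most
#' unplaced copies.  The pairing order cannot affect the copy-count
#' distribution of any single (focal) allele, which depends only on the
#' three focal genotype classes.
#'
#' Scalars may be given for a focal allele: `build_population(M, p, P)` is
#' the two-allele population with allele frequencies `c(p, 1 - p)` and
#' homozygote frequencies `c(P, 1 - 2p + P)`.
#'
#' @param M Population size.
#' @param allele_freqs Allele-frequency vector (or a scalar focal
#'   frequency).
#' @param homozygote_freqs Homozygote-frequency vector (or scalar).
#' @param seed Optional seed; accepted for interface symmetry with
#'   [draw_sample()] but the construction is fully deterministic.
#' @return An object of class `"explicit_population"`: list with the
#'   `genotypes` matrix (`M` rows, two allele indices per row), the
#'   genotype `counts` matrix, and the derived [population_spec()] `spec`.
#' @examples
#' build_population(4, 0.5, 0.25)  # {AA, Aa, Aa, aa}
#' @export
build_population <- function(M, allele_freqs, homozygote_freqs, seed = NULL) {
  if (length(allele_freqs) == 1L) {
    p <- allele_freqs; P <- homozygote_freqs
    allele_freqs <- c(p, 1 - p)
    homozygote_freqs <- c(P, 1 - 2 * p + P)
  }
  spec <- population_spec(M, allele_freqs, homozygote_freqs)
  n <- spec$n_alleles
  counts <- matrix(0L, n, n)
  diag(counts) <- spec$homozygote_counts
  r <- spec$copy_counts - 2L * spec$homozygote_counts  # copies to place in hets
  while (any(r > 0L)) {
    ord <- order(r, decreasing = TRUE)
    i <- ord[1L]; j <- ord[2L]
    if (r[j] <= 0L) {
      .err(paste0("heterozygote copies cannot be paired: allele ", i,
                  " has more unplaced copies than all other alleles combined"),
           "alleleCI_feasibility_error")
    }
    counts[min(i, j), max(i, j)] <- counts[min(i, j), max(i, j)] + 1L
    r[i] <- r[i] - 1L
    r[j] <- r[j] - 1L
  }
  idx <- which(counts > 0L, arr.ind = TRUE)
  genotypes <- cbind(rep.int(idx[, 1L], counts[idx]),
                     rep.int(idx[, 2L], counts[idx]))
  colnames(genotypes) <- c("a1", "a2")
  # round-trip check: derived marginals must equal the request exactly
  a_chk <- tabulate(genotypes, nbins = n)
  h_chk <- tabulate(genotypes[genotypes[, 1L] == genotypes[, 2L], 1L], nbins = n)
  if (!identical(a_chk, spec$copy_counts) ||
      !identical(h_chk, spec$homozygote_counts)) {
    .err("internal error: constructed population does not match its spec",
         "alleleCI_internal_error")
  }
  structure(list(genotypes = genotypes, counts = counts, spec = spec),
            class = "explicit_population")
}

#' @export
print.explicit_population <- function(x, ...) {
  print(x$spec)
  invisible(x)
}

#' Draw one without-replacement sample from an explicit population
#'
#' @param pop An [build_population()] object.
#' @param N Sample size (`N <= M`).
#' @param seed Seed for the draw (mandatory; the generator state is
#'   restored afterwards, so there is no hidden global state).
#' @param focal Focal allele index (default 1).
#' @return A [sample_observation()] with the sampled genotype counts and
#'   the focal-allele copy count `k_obs`.
#' @export
draw_sample <- function(pop, N, seed, focal = 1L) {
  stopifnot(inherits(pop, "explicit_population"))
  M <- pop$spec$M
  N <- .check_scalar_count(N, "N", min = 1L)
  if (N > M) .err("`N` must not exceed `M`", "alleleCI_invalid_argument")
  idx <- withr::with_seed(seed, sample.int(M, N))
  copies <- rowSums(pop$genotypes[idx, , drop = FALSE] == focal)
  sample_observation(N, sum(copies),
                     x2 = sum(copies == 2L), x1 = sum(copies == 1L),
                     x0 = sum(copies == 0L))
}

#' Replicated focal-allele copy counts from repeated sampling
#'
#' Vectorized convenience over [draw_sample()] for Monte-Carlo work: draws
#' `reps` independent without-replacement samples and returns only the
#' copy counts.
#'
#' @inheritParams draw_sample
#' @param reps Number of replicate samples.
#' @return Integer vector of length `reps` with values in `0..2N`.
#' @export
sample_copy_counts <- function(pop, N, reps, seed, focal = 1L) {
  stopifnot(inherits(pop, "explicit_population"))
  M <- pop$spec$M
  N <- .check_scalar_count(N, "N", min = 1L)
  reps <- .check_scalar_count(reps, "reps", min = 1L)
  if (N > M) .err("`N` must not exceed `M`", "alleleCI_invalid_argument")
  copies <- rowSums(pop$genotypes == focal)
  withr::with_seed(seed, vapply(seq_len(reps), function(i)
    sum(copies[sample.int(M, N)]), numeric(1)))
}

#' Monte-Carlo estimate of confidence-interval coverage
#'
#' Builds the population with the given truth, draws `reps` samples,
#' computes the test-inversion CI for each observed copy count under the
#' scenario rule matching the truth, and reports the fraction of replicates
#' whose interval contains the true allele frequency.  Replicates whose
#' interval required alpha relaxation count as covered only if the truth
#' lies in the (relaxed) interval.
#'
#' @param M Population size.
#' @param N Sample size.
#' @param p,P True focal-allele frequency and homozygote frequency; must be
#'   a point of the scenario grid.
#' @param alpha Significance level.
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Seed for the draws.
#' @param scenario Scenario rule under which intervals are computed; the
#'   truth `(p, P)` must satisfy it.
#' @return List with `coverage`, the Monte-Carlo standard error, `reps`,
#'   and the per-copy-count interval table used.
#' @export
empirical_coverage <- function(M, N, p, P, alpha = 0.05, reps = 10000L, seed,
                               scenario = "maxhom") {
  pr <- .resolve_params(M, N, p, P)
  alpha <- .check_alpha(alpha)
  reps <- .check_scalar_count(reps, "reps", min = 1L)
  cand <- .resolve_candidates(pr$M, scenario, NULL)
  if (!any(cand$grid$copies == pr$a & cand$grid$homozygotes == pr$h)) {
    .err("the truth (p, P) is not a point of the scenario grid",
         "alleleCI_invalid_argument")
  }
  pop <- build_population(pr$M, pr$a / (2 * pr$M), pr$h / pr$M)
  ks <- sample_copy_counts(pop, pr$N, reps, seed)
  tab <- table(ks)
  k_vals <- as.integer(names(tab))
  covered_k <- vapply(k_vals, function(k) {
    ci <- ci_known_homozygosity(pr$M, pr$N, k, alpha, grid = cand$grid)
    ci$lower - 1e-12 <= p && p <= ci$upper + 1e-12
  }, logical(1))
  coverage <- sum(as.numeric(tab)[covered_k]) / reps
  list(coverage = coverage,
       se = sqrt(coverage * (1 - coverage) / reps),
       reps = reps,
       per_k = data.frame(k = k_vals, draws = as.numeric(tab),
                          covered = covered_k))
}
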