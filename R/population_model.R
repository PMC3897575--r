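# Domain types and feasibility rules for a finite diploid population.
#
# Frequencies are carried internally as integer counts -- allele-copy counts
# on the 1/(2M) lattice and homozygote counts on the 1/M lattice -- so grid
# construction and feasibility checks never depend on float equality.

#' Specify a finite diploid population by its per-allele marginals
#'
#' A population of `M` diploid individuals is described, per allele j, by its
#' allele frequency \eqn{p_j} (a multiple of 1/(2M)) and its homozygote
#' frequency \eqn{P_{jj}} (a multiple of 1/M).  Only the per-allele marginals
#' are stored; the full genotype table is needed only by
#' [build_population()].
#'
#' @param M Population size (number of diploid individuals, integer >= 1).
#' @param allele_freqs Numeric vector of per-allele population frequencies,
#'   summing to 1; each must lie on the 1/(2M) lattice.
#' @param homozygote_freqs Numeric vector (same length) of per-allele
#'   homozygote frequencies; each must lie on the 1/M lattice and satisfy
#'   \eqn{\max(0, 2p_j - 1) \le P_{jj} \le p_j}.
#' @return An object of class `"population_spec"`: a list with elements
#'   `M`, `n_alleles`, `allele_freqs`, `homozygote_freqs`, and the integer
#'   representations `copy_counts` (\eqn{2Mp_j}) and `homozygote_counts`
#'   (\eqn{MP_{jj}}).
#' @examples
#' population_spec(1000, c(0.5, 0.5), c(0.25, 0.25))
#' @export
population_spec <- function(M, allele_freqs, homozygote_freqs) {
  M <- .check_scalar_count(M, "M", min = 1L)
  if (length(allele_freqs) < 2L) {
    .err("at least two alleles are required", "alleleCI_invalid_argument")
  }
  if (length(allele_freqs) != length(homozygote_freqs)) {
    .err("`allele_freqs` and `homozygote_freqs` must have equal length",
         "alleleCI_invalid_argument")
  }
  a <- 2 * M * allele_freqs
  h <- M * homozygote_freqs
  if (!all(.is_whole(a))) {
    .err("every allele frequency must be a multiple of 1/(2M)",
         "alleleCI_feasibility_error")
  }
  if (!all(.is_whole(h))) {
    .err("every homozygote frequency must be a multiple of 1/M",
         "alleleCI_feasibility_error")
  }
  a <- as.integer(round(a))
  h <- as.integer(round(h))
  if (sum(a) != 2L * M) {
    .err("allele frequencies must sum to exactly 1 (copy counts to 2M)",
         "alleleCI_feasibility_error")
  }
  if (any(h < pmax(0L, a - M)) || any(h > a %/% 2L)) {
    .err(paste0("homozygote frequencies violate the feasibility bound ",
                "max(0, 2p - 1) <= P <= p"),
         "alleleCI_feasibility_error")
  }
  structure(
    list(M = M, n_alleles = length(a),
         allele_freqs = a / (2 * M), homozygote_freqs = h / M,
         copy_counts = a, homozygote_counts = h),
    class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("Finite diploid population: M = %d, %d alleles\n", x$M, x$n_alleles))
  print(data.frame(allele = seq_len(x$n_alleles),
                   p = x$allele_freqs, P_hom = x$homozygote_freqs))
  invisible(x)
}

#' Observed sample of N individuals from a finite population
#'
#' @param N Sample size (integer >= 1).
#' @param k_obs Observed number of copies of the focal allele, in `0..2N`.
#' @param x2,x1,x0 Optional sampled genotype counts (two / one / zero copies
#'   of the focal allele); must satisfy `x2 + x1 + x0 = N` and
#'   `2 * x2 + x1 = k_obs` when supplied.
#' @return An object of class `"sample_observation"` with the observed
#'   sample allele frequency `p_hat = k_obs / (2N)`.
#' @export
sample_observation <- function(N, k_obs, x2 = NULL, x1 = NULL, x0 = NULL) {
  N <- .check_scalar_count(N, "N", min = 1L)
  k_obs <- .check_scalar_count(k_obs, "k_obs")
  if (k_obs > 2L * N) {
    .err("`k_obs` must lie in 0..2N", "alleleCI_invalid_argument")
  }
  if (!is.null(x2)) {
    x2 <- .check_scalar_count(x2, "x2")
    x1 <- .check_scalar_count(x1, "x1")
    x0 <- .check_scalar_count(x0, "x0")
    if (x2 + x1 + x0 != N || 2L * x2 + x1 != k_obs) {
      .err("genotype counts must satisfy x2+x1+x0 = N and 2*x2+x1 = k_obs",
           "alleleCI_invalid_argument")
    }
  }
  structure(list(N = N, k_obs = k_obs, p_hat = k_obs / (2 * N),
                 x2 = x2, x1 = x1, x0 = x0),
            class = "sample_observation")
}

#' Feasible range of the homozygote frequency for a given allele frequency
#'
#' If \eqn{p \le 1/2} every copy of the allele can sit in a heterozygote, so
#' the minimum homozygote frequency is 0; if \eqn{p > 1/2} the copies cannot
#' all be spread across distinct heterozygous individuals and the minimum is
#' \eqn{2p - 1}, attained when every heterozygote carries a copy.  The
#' maximum is always \eqn{p} (all carriers homozygous).
#'
#' @param p Allele frequency; `2 * M * p` must be an integer.
#' @param M Population size.
#' @return Named numeric vector `c(min = max(0, 2p - 1), max = p)`.  The
#'   maximum may need rounding down to the 1/M lattice by callers when
#'   \eqn{Mp} is not an integer.
#' @examples
#' homozygosity_bounds(0.3, 1000)  # c(0, 0.3)
#' homozygosity_bounds(0.7, 1000)  # c(0.4, 0.7)
#' @export
homozygosity_bounds <- function(p, M) {
  M <- .check_scalar_count(M, "M", min = 1L)
  if (length(p) != 1L || !is.numeric(p) || p < 0 || p > 1) {
    .err("`p` must be a single frequency in [0, 1]", "alleleCI_invalid_argument")
  }
  if (!.is_whole(2 * M * p)) {
    .err("`2 * M * p` must be an integer (p on the 1/(2M) lattice)",
         "alleleCI_feasibility_error")
  }
  c(min = max(0, 2 * p - 1), max = p)
}

#' Grid of hypothesizable (allele frequency, homozygote frequency) pairs
#'
#' Builds the set of (p, P) pairs that are feasible for a population of size
#' `M` under one of three archetypal scenarios:
#' \describe{
#'   \item{`"hwe"`}{Hardy-Weinberg equilibrium, \eqn{P = p^2}.  Both
#'     \eqn{2Mp} and \eqn{Mp^2} must be integers (the homozygote count must
#'     be whole), which for `M = 1000` leaves the 11 equally spaced values
#'     \eqn{p \in \{0, 0.1, \ldots, 1\}}; for general `M` the grid may be
#'     irregular.}
#'   \item{`"minhom"`}{minimum homozygosity, \eqn{P = \max(0, 2p - 1)}; all
#'     \eqn{2M + 1} multiples of 1/(2M) are feasible.}
#'   \item{`"maxhom"`}{maximum homozygosity, \eqn{P = p}; the \eqn{M + 1}
#'     multiples of 1/M are feasible.}
#' }
#'
#' @param scenario One of `"hwe"`, `"minhom"`, `"maxhom"` (case-insensitive).
#' @param M Population size.
#' @return A data frame of class `"scenario_grid"` with columns `p`, `P`,
#'   `copies` (\eqn{2Mp}) and `homozygotes` (\eqn{MP}), sorted by `p`.
#' @examples
#' nrow(scenario_grid("hwe", 1000))     # 11
#' nrow(scenario_grid("minhom", 1000))  # 2001
#' nrow(scenario_grid("maxhom", 1000))  # 1001
#' @export
scenario_grid <- function(scenario, M) {
  M <- .check_scalar_count(M, "M", min = 1L)
  scenario <- .normalize_scenario(scenario)
  a <- 0:(2L * M)
  if (scenario == "hwe") {
    h_exact <- a^2 / (4 * M)
    keep <- .is_whole(h_exact, tol = 1e-12)
    a <- a[keep]
    h <- as.integer(round(h_exact[keep]))
  } else if (scenario == "minhom") {
    h <- pmax(0L, a - M)
  } else { # maxhom
    a <- a[a %% 2L == 0L]
    h <- a %/% 2L
  }
  grid <- data.frame(p = a / (2 * M), P = h / M, copies = a, homozygotes = h)
  structure(grid, class = c("scenario_grid", "data.frame"),
            scenario = scenario, M = M)
}

.normalize_scenario <- function(scenario) {
  if (!is.character(scenario) || length(scenario) != 1L) {
    .err("`scenario` must be one of \"hwe\", \"minhom\", \"maxhom\"",
         "alleleCI_invalid_argument")
  }
  s <- tolower(gsub("[^a-z0-9]", "", tolower(scenario)))
  s <- switch(s,
              hwe = "hwe", scenario1 = "hwe",
              minhom = "minhom", minhomozygosity = "minhom", scenario2 = "minhom",
              maxhom = "maxhom", maxhomozygosity = "maxhom", scenario3 = "maxhom",
              NULL)
  if (is.null(s)) {
    .err(sprintf("unknown scenario \"%s\"", scenario), "alleleCI_invalid_argument")
  }
  s
}

# Grid of feasible (p, P) pairs induced by a user-supplied homozygosity rule
# p -> P: lattice values of p whose mapped P lands on the 1/M lattice within
# the feasibility bounds.
.rule_grid <- function(M, rule) {
  a <- 0:(2L * M)
  p <- a / (2 * M)
  P <- vapply(p, rule, numeric(1))
  h <- M * P
  keep <- .is_whole(h) & h >= pmax(0L, a - M) - 1e-9 & h <= a / 2 + 1e-9
  data.frame(p = p[keep], P = round(h[keep]) / M,
             copies = a[keep], homozygotes = as.integer(round(h[keep])))
}

#' Feasible range of the population allele frequency given an observation
#'
#' The population must contain at least the `k_obs` focal-allele copies seen
#' in the sample, and at least the `2N - k_obs` copies of the other alleles,
#' giving \eqn{k/(2M) \le p \le 1 - (2N - k)/(2M)}.
#'
#' @param M Population size.
#' @param N Sample size (`1 <= N <= M`).
#' @param k_obs Observed focal-allele copy count in `0..2N`.
#' @param n_alleles Number of alleles at the locus (>= 2); the bound is the
#'   same for any number of alleles because the non-focal alleles enter only
#'   through their total copy count.
#' @return Named numeric vector `c(min, max)`; both endpoints lie on the
#'   1/(2M) lattice and are attainable.
#' @examples
#' feasible_p_range(1000, 30, 12)  # c(0.006, 0.976)
#' @export
feasible_p_range <- function(M, N, k_obs, n_alleles = 2L) {
  M <- .check_scalar_count(M, "M", min = 1L)
  N <- .check_scalar_count(N, "N", min = 1L)
  k_obs <- .check_scalar_count(k_obs, "k_obs")
  .check_scalar_count(n_alleles, "n_alleles", min = 2L)
  if (N > M) .err("`N` must not exceed `M`", "alleleCI_invalid_argument")
  if (k_obs > 2L * N) .err("`k_obs` must lie in 0..2N", "alleleCI_invalid_argument")
  c(min = k_obs / (2 * M), max = 1 - (2 * N - k_obs) / (2 * M))
}
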