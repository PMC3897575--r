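# Acceptance regions and test-inversion confidence intervals / regions.
#
# The acceptance region of a hypothesized (p, P) is equal-tail: the copy
# counts k with P(K < k_lo) <= alpha/2 and P(K > k_hi) <= alpha/2, with
# non-strict inequalities (ties at exactly alpha/2 widen the region, which
# preserves the coverage guarantee).  A confidence set is every candidate
# (p, P) whose acceptance region contains the observed copy count; the
# reported interval is the hull [min, max] of the accepted allele
# frequencies, with the raw accepted set retained for diagnostics.

#' Equal-tail acceptance region of a hypothesized (p, P)
#'
#' `k_lo` is the largest integer with `P(K < k_lo) <= alpha/2` and `k_hi`
#' the smallest integer with `P(K > k_hi) <= alpha/2`, so that
#' `P(k_lo <= K <= k_hi) >= 1 - alpha`.
#'
#' @inheritParams triple_pmf
#' @param alpha Significance level in (0, 1).
#' @return An object of class `"acceptance_region"`: list with integer
#'   `k_lo`, `k_hi` and the attained `coverage`.
#' @examples
#' acceptance_region(4, 2, 0.5, 0.25, 0.05)  # k_lo = 1, k_hi = 3
#' @export
acceptance_region <- function(M, N, p, P, alpha) {
  alpha <- .check_alpha(alpha)
  pr <- .resolve_params(M, N, p, P)
  pmf <- .cached_pmf(pr$M, pr$N, pr$a, pr$h)
  cdf <- cumsum(pmf)
  lower_tail <- c(0, cdf[-length(cdf)])  # P(K < k), k = 0..2N
  upper_tail <- 1 - cdf                  # P(K > k)
  a2 <- alpha / 2 + .TAIL_TOL
  k_lo <- max(which(lower_tail <= a2)) - 1L
  k_hi <- min(which(upper_tail <= a2)) - 1L
  structure(list(M = pr$M, N = pr$N, p = pr$a / (2 * pr$M), P = pr$h / pr$M,
                 alpha = alpha, k_lo = k_lo, k_hi = k_hi,
                 coverage = cdf[k_hi + 1L] - lower_tail[k_lo + 1L]),
            class = "acceptance_region")
}

#' @export
print.acceptance_region <- function(x, ...) {
  cat(sprintf("Acceptance region for p = %g, P = %g (M = %d, N = %d, alpha = %g):\n",
              x$p, x$P, x$M, x$N, x$alpha))
  cat(sprintf("  k in [%d, %d], coverage %.6f\n", x$k_lo, x$k_hi, x$coverage))
  invisible(x)
}

# P(K <= k) and P(K <= k - 1) for one candidate, via truncated enumeration
# of the (x2, x1) pairs with 2*x2 + x1 <= k.  Used by the large confidence
# region scans where only tail probabilities at k_obs are needed.
.tail_pair <- function(M, N, m2, m1, m0, k) {
  if (k < 0L) return(c(0, 0))
  if (k >= 2L * N) k <- 2L * N
  x2 <- 0:min(N, m2, k %/% 2L)
  x1hi <- pmin(N - x2, m1, k - 2L * x2)
  x1lo <- pmax(0L, N - x2 - m0)
  keep <- x1lo <= x1hi
  x2 <- x2[keep]; x1lo <- x1lo[keep]; x1hi <- x1hi[keep]
  if (length(x2) == 0L) return(c(0, 0))
  nx <- x1hi - x1lo + 1L
  x2v <- rep.int(x2, nx)
  x1v <- sequence(nx, from = x1lo, by = 1L)
  w <- exp(lchoose(m2, x2v) + lchoose(m1, x1v) + lchoose(m0, N - x2v - x1v) -
             lchoose(M, N))
  Fk <- sum(w)
  c(Fk, Fk - sum(w[2L * x2v + x1v == k]))
}

# Membership of k_obs in the acceptance region of a candidate, from its
# tail probabilities: k_obs >= k_lo iff P(K <= k_obs) > alpha/2 and
# k_obs <= k_hi iff P(K > k_obs - 1) > alpha/2 (both with the tie
# tolerance used by acceptance_region()).
.accepts <- function(Fk, Fkm1, alpha) {
  a2 <- alpha / 2 + .TAIL_TOL
  (Fk > a2) & (1 - Fkm1 > a2)
}

# Tail probabilities at k_obs for every row of a candidate grid (columns
# `copies`, `homozygotes`); returns a 2-column matrix (Fk, Fkm1).
.grid_tails <- function(M, N, grid, k_obs) {
  n <- nrow(grid)
  out <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    m <- .class_counts_int(M, grid$copies[i], grid$homozygotes[i])
    out[i, ] <- .tail_pair(M, N, m[1], m[2], m[3], k_obs)
  }
  out
}

# Shared relaxation loop: halve alpha until at least one candidate accepts.
# `tails` is the matrix from .grid_tails().  Errors when k_obs lies outside
# the support hull of every candidate, in which case no amount of
# relaxation can place it inside an acceptance region.  (A copy count with
# zero probability but inside the hull -- e.g. an odd count under an
# all-homozygote hypothesis -- is still accepted by the interval-shaped
# regions; published tables rounded from sample frequencies produce such
# counts routinely.)
.relax_loop <- function(tails, alpha, k_obs) {
  if (!any(tails[, 1L] > 0 & tails[, 2L] < 1)) {
    .err(sprintf(paste0("observed copy count %d lies outside the sampling ",
                        "support of every feasible candidate; the input is ",
                        "inconsistent with the assumed model"), k_obs),
         "alleleCI_impossible_observation")
  }
  a_eff <- alpha
  repeat {
    acc <- .accepts(tails[, 1L], tails[, 2L], a_eff)
    if (any(acc)) return(list(accepted = acc, effective_alpha = a_eff))
    a_eff <- a_eff / 2
    if (a_eff < 1e-300) {
      .err("alpha relaxation failed to terminate", "alleleCI_internal_error")
    }
  }
}

# Resolve the candidate grid for ci_known_homozygosity().
.resolve_candidates <- function(M, scenario, grid) {
  if (!is.null(grid)) {
    if (!all(c("copies", "homozygotes") %in% names(grid))) {
      grid <- .resolve_params_grid(M, grid)
    }
    return(list(grid = grid, label = "custom"))
  }
  if (is.function(scenario)) {
    return(list(grid = .rule_grid(M, scenario), label = "custom rule"))
  }
  s <- .normalize_scenario(scenario)
  list(grid = scenario_grid(s, M), label = s)
}

.resolve_params_grid <- function(M, grid) {
  if (!all(c("p", "P") %in% names(grid))) {
    .err("a candidate grid needs columns `p` and `P`", "alleleCI_invalid_argument")
  }
  a <- 2 * M * grid$p
  h <- M * grid$P
  if (!all(.is_whole(a)) || !all(.is_whole(h))) {
    .err("grid frequencies must lie on the 1/(2M) and 1/M lattices",
         "alleleCI_feasibility_error")
  }
  data.frame(p = grid$p, P = grid$P,
             copies = as.integer(round(a)), homozygotes = as.integer(round(h)))
}

#' Test-inversion confidence interval when homozygosity is a known function
#' of the allele frequency
#'
#' Inverts the exact equal-tail test over every feasible candidate allele
#' frequency, with the homozygote frequency tied to the allele frequency by
#' a scenario rule: Hardy-Weinberg equilibrium (`"hwe"`, \eqn{P = p^2}),
#' minimum homozygosity (`"minhom"`, \eqn{P = \max(0, 2p - 1)}), maximum
#' homozygosity (`"maxhom"`, \eqn{P = p}), or a user-supplied function
#' `p -> P`.  Candidates whose acceptance region contains the observed copy
#' count form the accepted set; the interval is its hull.  If no candidate
#' accepts, `alpha` is halved until at least one does and the final level is
#' reported as `effective_alpha`.
#'
#' @param M Population size.
#' @param N Sample size (`1 <= N <= M`).
#' @param k_obs Observed focal-allele copy count in `0..2N`.
#' @param alpha Nominal significance level (default 0.05).
#' @param scenario Scenario id or a function mapping each feasible `p` to a
#'   homozygote frequency `P`.
#' @param grid Optional pre-built candidate grid (a [scenario_grid()] or a
#'   data frame with columns `p` and `P`); overrides `scenario`.
#' @return An object of class `"allele_ci"`: list with `lower`, `upper`,
#'   `accepted_set` (the accepted allele frequencies, sorted),
#'   `effective_alpha`, the nominal `alpha` and the inputs.  Coverage of the
#'   true `p` is at least `1 - alpha` for every truth consistent with the
#'   scenario rule.
#' @examples
#' ci_known_homozygosity(1000, 30, 30, scenario = "maxhom")
#' @export
ci_known_homozygosity <- function(M, N, k_obs, alpha = 0.05,
                                  scenario = "maxhom", grid = NULL) {
  M <- .check_scalar_count(M, "M", min = 1L)
  N <- .check_scalar_count(N, "N", min = 1L)
  k_obs <- .check_scalar_count(k_obs, "k_obs")
  alpha <- .check_alpha(alpha)
  if (N > M) .err("`N` must not exceed `M`", "alleleCI_invalid_argument")
  if (k_obs > 2L * N) .err("`k_obs` must lie in 0..2N", "alleleCI_invalid_argument")
  cand <- .resolve_candidates(M, scenario, grid)
  tails <- .grid_tails(M, N, cand$grid, k_obs)
  res <- .relax_loop(tails, alpha, k_obs)
  accepted <- sort(cand$grid$p[res$accepted])
  structure(list(lower = accepted[1L], upper = accepted[length(accepted)],
                 accepted_set = accepted,
                 effective_alpha = res$effective_alpha, alpha = alpha,
                 M = M, N = N, k_obs = k_obs, p_hat = k_obs / (2 * N),
                 scenario = cand$label),
            class = "allele_ci")
}

#' @export
print.allele_ci <- function(x, ...) {
  cat(sprintf(">=%g%% CI for the population allele frequency (%s):\n",
              100 * (1 - x$alpha), x$scenario))
  cat(sprintf("  [%g, %g]   (M = %d, N = %d, k_obs = %d, p_hat = %g)\n",
              x$lower, x$upper, x$M, x$N, x$k_obs, x$p_hat))
  if (x$effective_alpha < x$alpha) {
    cat(sprintf("  note: alpha relaxed to %g to obtain a non-empty set\n",
                x$effective_alpha))
  }
  invisible(x)
}

#' Joint confidence region for (p, P) when homozygosity is unknown
#'
#' Scans every feasible allele frequency on the 1/(2M) lattice and, for
#' each, every homozygote frequency on the 1/M lattice within
#' [homozygosity_bounds()]; the region holds the pairs whose acceptance
#' region contains the observed copy count.  Projections of the region give
#' conservative marginal intervals for `p` and for `P`.
#'
#' @inheritParams ci_known_homozygosity
#' @return An object of class `"allele_cr"`: list with `p_interval`,
#'   `P_interval`, the `accepted` data frame of (p, P) pairs,
#'   `effective_alpha` and the inputs.
#' @examples
#' cr_unknown_homozygosity(50, 10, 8)
#' @export
cr_unknown_homozygosity <- function(M, N, k_obs, alpha = 0.05) {
  M <- .check_scalar_count(M, "M", min = 1L)
  N <- .check_scalar_count(N, "N", min = 1L)
  k_obs <- .check_scalar_count(k_obs, "k_obs")
  alpha <- .check_alpha(alpha)
  if (N > M) .err("`N` must not exceed `M`", "alleleCI_invalid_argument")
  if (k_obs > 2L * N) .err("`k_obs` must lie in 0..2N", "alleleCI_invalid_argument")
  a_min <- k_obs
  a_max <- 2L * M - (2L * N - k_obs)
  av <- a_min:a_max
  hlo <- pmax(0L, av - M)
  hhi <- av %/% 2L
  nh <- hhi - hlo + 1L
  grid <- data.frame(copies = rep.int(av, nh),
                     homozygotes = sequence(nh, from = hlo, by = 1L))
  grid$p <- grid$copies / (2 * M)
  grid$P <- grid$homozygotes / M
  tails <- .grid_tails(M, N, grid, k_obs)
  res <- .relax_loop(tails, alpha, k_obs)
  acc <- grid[res$accepted, c("p", "P")]
  acc <- acc[order(acc$p, acc$P), ]
  rownames(acc) <- NULL
  structure(list(p_interval = range(acc$p), P_interval = range(acc$P),
                 accepted = acc, effective_alpha = res$effective_alpha,
                 alpha = alpha, M = M, N = N, k_obs = k_obs),
            class = "allele_cr")
}

#' @export
print.allele_cr <- function(x, ...) {
  cat(sprintf(">=%g%% confidence region for (p, P), M = %d, N = %d, k_obs = %d:\n",
              100 * (1 - x$alpha), x$M, x$N, x$k_obs))
  cat(sprintf("  p in [%g, %g]; P in [%g, %g]; %d accepted pairs\n",
              x$p_interval[1], x$p_interval[2],
              x$P_interval[1], x$P_interval[2], nrow(x$accepted)))
  if (x$effective_alpha < x$alpha) {
    cat(sprintf("  note: alpha relaxed to %g\n", x$effective_alpha))
  }
  invisible(x)
}

#' Relax the significance level until some candidate accepts the observation
#'
#' When the observed copy count falls outside the acceptance region of every
#' candidate at level `alpha`, the level is halved repeatedly until at least
#' one region contains it (the regions grow to the full support as
#' `alpha -> 0`).  Returns the unchanged `alpha` when the accepted set is
#' already non-empty; errors when the observation has zero probability under
#' every candidate.
#'
#' @inheritParams ci_known_homozygosity
#' @param candidates Data frame with columns `p` and `P` (the hypothesized
#'   pairs to test).
#' @return The effective significance level.
#' @export
relax_alpha <- function(M, N, k_obs, alpha, candidates) {
  M <- .check_scalar_count(M, "M", min = 1L)
  N <- .check_scalar_count(N, "N", min = 1L)
  k_obs <- .check_scalar_count(k_obs, "k_obs")
  alpha <- .check_alpha(alpha)
  grid <- .resolve_params_grid(M, candidates)
  tails <- .grid_tails(M, N, grid, k_obs)
  .relax_loop(tails, alpha, k_obs)$effective_alpha
}

#' Clopper-Pearson interval for a binomial proportion (baseline)
#'
#' The exact equal-tail binomial interval, the infinite-population
#' Hardy-Weinberg limit of the test-inversion interval (the copy count then
#' follows a Binomial(2N, p) distribution).
#'
#' @param k_obs Number of successes (allele copies).
#' @param trials Number of trials (`2N` allele copies drawn).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `"allele_ci"` with `lower` and `upper`.
#' @export
clopper_pearson_ci <- function(k_obs, trials, alpha = 0.05) {
  k_obs <- .check_scalar_count(k_obs, "k_obs")
  trials <- .check_scalar_count(trials, "trials", min = 1L)
  alpha <- .check_alpha(alpha)
  if (k_obs > trials) .err("`k_obs` must not exceed `trials`", "alleleCI_invalid_argument")
  lower <- if (k_obs == 0L) 0 else qbeta(alpha / 2, k_obs, trials - k_obs + 1)
  upper <- if (k_obs == trials) 1 else qbeta(1 - alpha / 2, k_obs + 1, trials - k_obs)
  structure(list(lower = lower, upper = upper, accepted_set = NULL,
                 effective_alpha = alpha, alpha = alpha,
                 M = Inf, N = trials / 2, k_obs = k_obs,
                 p_hat = k_obs / trials, scenario = "clopper-pearson"),
            class = "allele_ci")
}

#' Wald-type interval with plug-in variance (baseline)
#'
#' The approximate large-sample interval \eqn{\hat p \pm z_{1-\alpha/2}\hat s}
#' with \eqn{\hat s^2 = (\hat p(1-\hat p) + \hat P - \hat p^2)/(2N)}, the
#' infinite-population variance with sample plug-ins, truncated to [0, 1].
#' Reliable only for large N; degenerates to a zero-length interval at
#' \eqn{\hat p = 0} with no observed homozygotes (a documented pathology of
#' Wald-type intervals).
#'
#' @param k_obs Observed focal-allele copy count.
#' @param N Sample size.
#' @param hom_freq Sample frequency of focal-allele homozygotes,
#'   \eqn{\hat P = x_2/N}.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `"allele_ci"` with `lower` and `upper`.
#' @export
weir_wald_ci <- function(k_obs, N, hom_freq, alpha = 0.05) {
  k_obs <- .check_scalar_count(k_obs, "k_obs")
  N <- .check_scalar_count(N, "N", min = 1L)
  alpha <- .check_alpha(alpha)
  if (k_obs > 2L * N) .err("`k_obs` must lie in 0..2N", "alleleCI_invalid_argument")
  p_hat <- k_obs / (2 * N)
  v <- (p_hat * (1 - p_hat) + hom_freq - p_hat^2) / (2 * N)
  s <- sqrt(max(0, v))
  z <- qnorm(1 - alpha / 2)
  structure(list(lower = max(0, p_hat - z * s), upper = min(1, p_hat + z * s),
                 accepted_set = NULL, effective_alpha = alpha, alpha = alpha,
                 M = Inf, N = N, k_obs = k_obs, p_hat = p_hat,
                 scenario = "wald"),
            class = "allele_ci")
}
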