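# Survey design: maximum CI length over all possible observations, and the
# minimum sample size achieving a target maximum length.

#' Maximum confidence-interval length over all possible observations
#'
#' Computes the test-inversion CI for every observable copy count
#' `k_obs = 0..2N` and returns the maximum length.  A copy count is
#' observable when it has positive probability under at least one candidate
#' in the scenario grid (under maximum homozygosity, for example, odd copy
#' counts can never occur).  Acceptance regions are computed once per grid
#' candidate and reused across all `k_obs`; observable copy counts rejected
#' by every candidate are handled through the alpha-relaxation path of
#' [ci_known_homozygosity()].
#'
#' @inheritParams ci_known_homozygosity
#' @param detail If `TRUE`, also return the per-`k_obs` lengths.
#' @return The maximum CI length (a scalar), or when `detail = TRUE` a list
#'   with `max_length` and a data frame `per_k` of columns `k`, `p_hat`,
#'   `lower`, `upper`, `length`, `possible`, `relaxed`.
#' @examples
#' max_ci_length(1000, 22, "hwe")  # <= 0.2
#' @export
max_ci_length <- function(M, N, scenario, alpha = 0.05, detail = FALSE) {
  M <- .check_scalar_count(M, "M", min = 1L)
  N <- .check_scalar_count(N, "N", min = 1L)
  alpha <- .check_alpha(alpha)
  if (N > M) .err("`N` must not exceed `M`", "alleleCI_invalid_argument")
  cand <- .resolve_candidates(M, scenario, NULL)
  grid <- cand$grid
  nk <- 2L * N + 1L
  possible <- logical(nk)
  n_accept <- integer(nk)
  # hull endpoints tracked as integer copy counts (2 M p): the reported
  # lengths are then exact multiples of 1/(2M), immune to float drift in
  # comparisons against round targets like 0.2
  minc <- rep(Inf, nk)
  maxc <- rep(-Inf, nk)
  a2 <- alpha / 2 + .TAIL_TOL
  for (i in seq_len(nrow(grid))) {
    m <- .class_counts_int(M, grid$copies[i], grid$homozygotes[i])
    pmf <- .pmf_vector(M, N, m[1], m[2], m[3])$pmf
    cdf <- cumsum(pmf)
    lower_tail <- c(0, cdf[-nk])
    k_lo <- max(which(lower_tail <= a2))      # 1-based index of k_lo
    k_hi <- min(which(1 - cdf <= a2))         # 1-based index of k_hi
    idx <- k_lo:k_hi
    n_accept[idx] <- n_accept[idx] + 1L
    a <- grid$copies[i]
    minc[idx] <- pmin(minc[idx], a)
    maxc[idx] <- pmax(maxc[idx], a)
    possible[pmf > 0] <- TRUE
  }
  relaxed <- possible & n_accept == 0L
  for (k1 in which(relaxed)) {  # rare: every candidate rejected this k_obs
    ci <- ci_known_homozygosity(M, N, k1 - 1L, alpha, grid = grid)
    minc[k1] <- round(2 * M * ci$lower)
    maxc[k1] <- round(2 * M * ci$upper)
  }
  lower <- minc / (2 * M)
  upper <- maxc / (2 * M)
  lens <- (maxc - minc) / (2 * M)
  max_length <- max(lens[possible])
  if (!detail) return(max_length)
  per_k <- data.frame(k = 0:(2L * N), p_hat = (0:(2L * N)) / (2 * N),
                      lower = ifelse(possible, lower, NA_real_),
                      upper = ifelse(possible, upper, NA_real_),
                      length = ifelse(possible, lens, NA_real_),
                      possible = possible, relaxed = relaxed)
  list(max_length = max_length, per_k = per_k,
       M = M, N = N, scenario = cand$label, alpha = alpha)
}

#' Minimum sample size achieving a target maximum CI length
#'
#' Scans `N` upward from `start` in increments of `step` until the maximum
#' CI length over all observable copy counts drops to `target_length` or
#' less, then refines downward one individual at a time until the target
#' fails, so the reported `N_min` satisfies
#' `max_ci_length(N_min) <= target_length` and
#' `max_ci_length(N_min - 1) > target_length`.  The refinement checks every
#' `N` downward rather than bisecting because the discreteness of the
#' problem can make the maximum length non-monotone in `N`.
#'
#' @inheritParams max_ci_length
#' @param target_length Required maximum CI length, in (0, 1).
#' @param start,step Coarse-scan origin and increment (defaults 10 and 10).
#' @return An object of class `"min_sample_size"`: list with `N_min`,
#'   `max_length` at `N_min`, `max_length_below` at `N_min - 1` (`NA` when
#'   `N_min == 1`), a `reached_target` flag (`FALSE` only when even a full
#'   census exceeds the target, which cannot happen since a census has
#'   length 0), and the inputs.
#' @examples
#' min_sample_size(1000, "hwe", target_length = 0.2)$N_min  # 22
#' @export
min_sample_size <- function(M, scenario, alpha = 0.05, target_length,
                            start = 10L, step = 10L) {
  M <- .check_scalar_count(M, "M", min = 1L)
  alpha <- .check_alpha(alpha)
  start <- .check_scalar_count(start, "start", min = 1L)
  step <- .check_scalar_count(step, "step", min = 1L)
  if (length(target_length) != 1L || !is.numeric(target_length) ||
      target_length <= 0 || target_length >= 1) {
    .err("`target_length` must be a single number in (0, 1)",
         "alleleCI_invalid_argument")
  }
  Ns <- unique(c(seq(min(start, M), M, by = step), M))
  lens <- setNames(numeric(0), character(0))
  # lengths are exact multiples of 1/(2M); the tolerance only guards the
  # comparison against targets that are not on that lattice
  tol <- 1e-9
  maxlen <- function(N) {
    key <- as.character(N)
    if (is.na(lens[key])) {
      lens[key] <<- max_ci_length(M, N, scenario, alpha)
    }
    lens[[key]]
  }
  N_hit <- NA_integer_
  for (N in Ns) {
    if (maxlen(N) <= target_length + tol) { N_hit <- N; break }
  }
  if (is.na(N_hit)) {
    return(structure(list(N_min = M, max_length = maxlen(M),
                          max_length_below = if (M > 1L) maxlen(M - 1L) else NA_real_,
                          reached_target = FALSE, M = M,
                          scenario = if (is.function(scenario)) "custom rule"
                                     else .normalize_scenario(scenario),
                          alpha = alpha, target_length = target_length),
                     class = "min_sample_size"))
  }
  N_min <- N_hit
  while (N_min > 1L && maxlen(N_min - 1L) <= target_length + tol) {
    N_min <- N_min - 1L
  }
  structure(list(N_min = N_min, max_length = maxlen(N_min),
                 max_length_below = if (N_min > 1L) maxlen(N_min - 1L) else NA_real_,
                 reached_target = TRUE, M = M,
                 scenario = if (is.function(scenario)) "custom rule"
                            else .normalize_scenario(scenario),
                 alpha = alpha, target_length = target_length),
            class = "min_sample_size")
}

#' @export
print.min_sample_size <- function(x, ...) {
  cat(sprintf("Minimum N for max >=%g%% CI length <= %g (M = %d, %s): %d\n",
              100 * (1 - x$alpha), x$target_length, x$M, x$scenario, x$N_min))
  cat(sprintf("  max length at N = %d: %.4f; at N = %d: %s\n",
              x$N_min, x$max_length, x$N_min - 1L,
              ifelse(is.na(x$max_length_below), "NA",
                     sprintf("%.4f", x$max_length_below))))
  invisible(x)
}

#' Maximum CI length across a sweep of population sizes
#'
#' @inheritParams max_ci_length
#' @param M_list Population sizes to sweep (default the grid 100, 250, 500,
#'   750, 1000, 2500, 5000, 7500, 10000).
#' @return Data frame with columns `M` and `max_length`.
#' @export
m_sweep <- function(N, scenario, alpha = 0.05,
                    M_list = c(100, 250, 500, 750, 1000, 2500, 5000, 7500, 10000)) {
  N <- .check_scalar_count(N, "N", min = 1L)
  if (N > min(M_list)) {
    .err("`N` must not exceed the smallest population size in `M_list`",
         "alleleCI_invalid_argument")
  }
  data.frame(M = M_list,
             max_length = vapply(M_list, function(M)
               max_ci_length(M, N, scenario, alpha), numeric(1)))
}
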