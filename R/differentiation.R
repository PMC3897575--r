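# Jost's D between two populations, Bonferroni joint confidence regions
# over several alleles, and the optimized confidence interval for D.

#' Jost's D between two populations
#'
#' For two populations with allele-frequency vectors \eqn{f_1} and
#' \eqn{f_2}, Jost's differentiation measure is
#' \deqn{D = \frac{n}{n-1}\,\frac{H_T - H_S}{1 - H_S}, \qquad n = 2,}
#' where \eqn{H_S = 1 - \tfrac12(\sum_j f_{1j}^2 + \sum_j f_{2j}^2)} is the
#' mean within-population expected heterozygosity and
#' \eqn{H_T = 1 - \sum_j \bar f_j^2} (with \eqn{\bar f_j} the mean frequency
#' across the two populations) is the total expected heterozygosity.
#' `D = 0` for identical allele distributions and `D = 1` for completely
#' disjoint ones.
#'
#' @param freqs1,freqs2 Allele-frequency vectors of equal length; entries
#'   non-negative and summing to 1 (within 1e-6, tolerating published
#'   rounding).
#' @return Jost's D, in [0, 1].
#' @examples
#' jost_d(c(1, 0), c(0, 1))  # 1
#' @export
jost_d <- function(freqs1, freqs2) {
  .check_simplex(freqs1, "freqs1")
  .check_simplex(freqs2, "freqs2")
  if (length(freqs1) != length(freqs2)) {
    .err("frequency vectors must have equal length", "alleleCI_invalid_argument")
  }
  .jost_d_raw(freqs1, freqs2)
}

.jost_d_raw <- function(f1, f2) {
  Hs <- 1 - (sum(f1^2) + sum(f2^2)) / 2
  Ht <- 1 - sum(((f1 + f2) / 2)^2)
  D <- 2 * (Ht - Hs) / (1 - Hs)
  min(1, max(0, D))
}

.check_simplex <- function(f, name, tol = 1e-6) {
  if (!is.numeric(f) || length(f) < 2L || any(!is.finite(f))) {
    .err(sprintf("`%s` must be a numeric vector of >= 2 frequencies", name),
         "alleleCI_invalid_argument")
  }
  if (any(f < -1e-12)) {
    .err(sprintf("`%s` has negative entries", name), "alleleCI_invalid_argument")
  }
  if (abs(sum(f) - 1) > tol) {
    .err(sprintf("`%s` must sum to 1 (got %.8f)", name, sum(f)),
         "alleleCI_invalid_argument")
  }
  invisible(f)
}

#' Bonferroni joint confidence region (box) for several allele frequencies
#'
#' Combines per-allele confidence intervals, each at level
#' `1 - alpha_each`, into a box whose joint coverage of the listed allele
#' frequencies is at least `1 - sum(alpha_each)` by the Bonferroni
#' inequality.  The last allele at the locus is left implied (its frequency
#' is fixed by the listed ones) and receives no interval of its own; its
#' non-negativity enters [d_interval()] only through the sum constraint.
#'
#' @param cis List of per-allele intervals: objects of class `"allele_ci"`
#'   or length-2 numeric vectors `c(lower, upper)` inside [0, 1].  When
#'   `"allele_ci"` objects are given, all must share the same nominal
#'   `alpha`.
#' @param alpha_each Per-allele significance level; required when plain
#'   numeric bounds are supplied, otherwise taken from the intervals.
#' @return An object of class `"joint_box"`: list with vectors `lower`,
#'   `upper`, the per-allele level `alpha_each` and the Bonferroni
#'   `joint_alpha = length(cis) * alpha_each`.
#' @examples
#' cis <- lapply(c(5, 10, 3), function(k)
#'   ci_known_homozygosity(100, 10, k, alpha = 0.05 / 3, scenario = "maxhom"))
#' bonferroni_joint_region(cis)  # joint level >= 95%
#' @export
bonferroni_joint_region <- function(cis, alpha_each = NULL) {
  if (!is.list(cis) || length(cis) < 1L) {
    .err("`cis` must be a non-empty list of intervals", "alleleCI_invalid_argument")
  }
  lower <- numeric(length(cis))
  upper <- numeric(length(cis))
  alphas <- rep(NA_real_, length(cis))
  for (i in seq_along(cis)) {
    ci <- cis[[i]]
    if (inherits(ci, "allele_ci")) {
      lower[i] <- ci$lower; upper[i] <- ci$upper; alphas[i] <- ci$alpha
    } else if (is.numeric(ci) && length(ci) == 2L) {
      lower[i] <- ci[1L]; upper[i] <- ci[2L]
    } else {
      .err("each element of `cis` must be an `allele_ci` or c(lower, upper)",
           "alleleCI_invalid_argument")
    }
  }
  if (any(lower < -1e-12) || any(upper > 1 + 1e-12) || any(lower > upper)) {
    .err("interval bounds must satisfy 0 <= lower <= upper <= 1",
         "alleleCI_invalid_argument")
  }
  known <- alphas[!is.na(alphas)]
  if (length(known) && diff(range(known)) > 1e-12) {
    .err("per-allele intervals have inconsistent significance levels",
         "alleleCI_inconsistent_levels")
  }
  if (is.null(alpha_each)) {
    if (!length(known)) {
      .err("`alpha_each` is required when plain bounds are supplied",
           "alleleCI_invalid_argument")
    }
    alpha_each <- known[1L]
  } else if (length(known) && abs(alpha_each - known[1L]) > 1e-12) {
    .err("`alpha_each` disagrees with the intervals' levels",
         "alleleCI_inconsistent_levels")
  }
  structure(list(lower = pmax(0, lower), upper = pmin(1, upper),
                 alpha_each = alpha_each,
                 joint_alpha = length(cis) * alpha_each),
            class = "joint_box")
}

#' @export
print.joint_box <- function(x, ...) {
  cat(sprintf("Bonferroni joint box, joint level >= %g%%:\n",
              100 * (1 - x$joint_alpha)))
  print(data.frame(allele = seq_along(x$lower), lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Confidence interval for Jost's D from two joint confidence regions
#'
#' Minimizes and maximizes Jost's D over all frequency vectors whose listed
#' allele frequencies lie in the two boxes, subject to the simplex
#' constraints that the listed frequencies of each population sum to at
#' most 1 (the implied final allele takes the remainder).  Because D is
#' non-convex in the frequencies the search combines a multi-start
#' constrained optimizer (Nelder-Mead inside a log-barrier, via
#' [stats::constrOptim()]) started from a fixed-seed Latin-hypercube design
#' over the boxes, with exhaustive evaluation of every feasible box corner.
#'
#' @param box1,box2 [bonferroni_joint_region()] boxes over the same alleles.
#' @param freqs1,freqs2 Optional full observed frequency vectors (listed
#'   alleles plus the implied final allele) used for the point estimate
#'   `D_point`.
#' @param n_starts Number of multi-start points (default 16).
#' @param seed Seed for the Latin-hypercube start design (default 1).
#' @return An object of class `"differentiation_result"`: list with
#'   `D_point` (`NA` when no observed frequencies are supplied), `D_lo`,
#'   `D_hi`, the joint level `1 - (joint_alpha1 + joint_alpha2)` implied by
#'   applying Bonferroni across the two regions, and optimizer diagnostics.
#' @examples
#' b <- bonferroni_joint_region(list(c(0.4, 0.6)), alpha_each = 0.025)
#' d_interval(b, b)
#' @export
d_interval <- function(box1, box2, freqs1 = NULL, freqs2 = NULL,
                       n_starts = 16L, seed = 1L) {
  for (b in list(box1, box2)) {
    if (!inherits(b, "joint_box")) {
      .err("`box1` and `box2` must be `joint_box` objects", "alleleCI_invalid_argument")
    }
  }
  if (length(box1$lower) != length(box2$lower)) {
    .err("boxes must cover the same allele set", "alleleCI_invalid_argument")
  }
  if (sum(box1$lower) > 1 + 1e-9 || sum(box2$lower) > 1 + 1e-9) {
    .err("infeasible box: listed lower bounds exceed the simplex",
         "alleleCI_infeasible_box")
  }
  d1 <- length(box1$lower)
  lower <- c(box1$lower, box2$lower)
  upper <- c(box1$upper, box2$upper)
  pop <- rep(1:2, c(d1, d1))
  obj <- function(theta) {
    f1 <- theta[pop == 1L]; f2 <- theta[pop == 2L]
    .jost_d_raw(c(f1, max(0, 1 - sum(f1))), c(f2, max(0, 1 - sum(f2))))
  }
  free <- upper - lower > 1e-12
  fixed_vals <- (lower + upper) / 2
  eval_at <- function(x_free) {
    theta <- fixed_vals
    theta[free] <- x_free
    obj(theta)
  }
  vals <- numeric(0)
  diagnostics <- list(n_starts = 0L, convergence = integer(0))
  # Every feasible corner of the free coordinates (D is often extremal at a
  # vertex of the box).
  corner_vals <- function() {
    dfree <- sum(free)
    if (dfree == 0L || dfree > 14L) return(numeric(0))
    corners <- as.matrix(expand.grid(lapply(which(free), function(j)
      c(lower[j], upper[j]))))
    ok <- apply(corners, 1L, function(x_free) {
      theta <- fixed_vals; theta[free] <- x_free
      sum(theta[pop == 1L]) <= 1 + 1e-12 && sum(theta[pop == 2L]) <= 1 + 1e-12
    })
    apply(corners[ok, , drop = FALSE], 1L, eval_at)
  }
  vals <- c(vals, corner_vals(), eval_at(fixed_vals[free]))
  dfree <- sum(free)
  if (dfree == 1L) {
    # One free coordinate: the feasible set is an interval; optimize directly.
    j <- which(free)
    g <- pop[j]
    hi_j <- min(upper[j], 1 - sum(fixed_vals[pop == g & !free]))
    if (hi_j >= lower[j]) {
      for (sign in c(1, -1)) {
        op <- optimize(function(x) sign * eval_at(x),
                       interval = c(lower[j], hi_j), tol = 1e-10)
        vals <- c(vals, sign * op$objective)
      }
      vals <- c(vals, eval_at(lower[j]), eval_at(hi_j))
    }
    diagnostics <- list(n_starts = 1L, convergence = 0L)
  } else if (dfree > 1L) {
    # Linear constraints ui %*% x >= ci on the free coordinates: box bounds
    # plus, per population, sum(free coords) <= 1 - sum(fixed coords).
    ui <- rbind(diag(dfree), -diag(dfree))
    ci <- c(lower[free], -upper[free])
    for (g in 1:2) {
      sel <- (pop[free] == g)
      if (any(sel)) {
        ui <- rbind(ui, -as.numeric(sel))
        ci <- c(ci, -(1 - sum(fixed_vals[pop == g & !free])))
      }
    }
    starts <- .box_starts(lower[free], upper[free], pop[free],
                          cap = vapply(1:2, function(g)
                            1 - sum(fixed_vals[pop == g & !free]), numeric(1)),
                          n_starts = n_starts, seed = seed)
    conv <- integer(0)
    for (s in seq_len(nrow(starts))) {
      for (sign in c(1, -1)) {
        fit <- tryCatch(
          constrOptim(starts[s, ], function(x) sign * eval_at(x), grad = NULL,
                      ui = ui, ci = ci - 1e-10,
                      control = list(reltol = 1e-12, maxit = 500L)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          vals <- c(vals, eval_at(fit$par))
          conv <- c(conv, fit$convergence)
        }
      }
    }
    diagnostics <- list(n_starts = nrow(starts), convergence = conv)
  }
  D_point <- if (!is.null(freqs1) && !is.null(freqs2)) {
    jost_d(freqs1, freqs2)
  } else NA_real_
  structure(list(D_point = D_point,
                 D_lo = max(0, min(vals)), D_hi = min(1, max(vals)),
                 joint_alpha = box1$joint_alpha + box2$joint_alpha,
                 diagnostics = diagnostics),
            class = "differentiation_result")
}

# Strictly interior multi-start points: a fixed-seed Latin hypercube over
# the free box, shrunk toward the feasible lower corner until the per-
# population sum constraints hold strictly.
.box_starts <- function(lo, hi, pop_free, cap, n_starts, seed) {
  d <- length(lo)
  u <- withr::with_seed(seed, lhs::randomLHS(max(1L, n_starts), d))
  pts <- sweep(sweep(u, 2L, hi - lo, "*"), 2L, lo, "+")
  pts <- rbind(pts, (lo + hi) / 2)
  eps <- 1e-6 * pmax(1e-3, hi - lo)
  pts <- pmin(pmax(pts, matrix(lo + eps, nrow(pts), d, byrow = TRUE)),
              matrix(hi - eps, nrow(pts), d, byrow = TRUE))
  anchor <- lo + eps
  for (r in seq_len(nrow(pts))) {
    x <- pts[r, ]
    for (it in 1:60) {
      sums <- vapply(1:2, function(g) sum(x[pop_free == g]), numeric(1))
      bad <- sums > cap - 1e-8
      if (!any(bad[is.finite(cap)])) break
      x <- anchor + 0.5 * (x - anchor)
    }
    pts[r, ] <- x
  }
  pts
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(sprintf("Jost's D: point %s, >=%g%% CI [%g, %g]\n",
              ifelse(is.na(x$D_point), "NA", sprintf("%.3f", x$D_point)),
              100 * (1 - x$joint_alpha), x$D_lo, x$D_hi))
  invisible(x)
}
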