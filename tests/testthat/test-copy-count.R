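test_that("genotype class counts partition the population", {
  expect_equal(genotype_class_counts(1000, 0.5, 0.25),
               c(m2 = 250L, m1 = 500L, m0 = 250L))
  expect_equal(genotype_class_counts(4, 0.5, 0.25), c(m2 = 1L, m1 = 2L, m0 = 1L))
  expect_equal(genotype_class_counts(1000, 0.7, 0.4),
               c(m2 = 400L, m1 = 600L, m0 = 0L))
  expect_error(genotype_class_counts(1000, 0.7, 0.2),
               class = "alleleCI_feasibility_error")
})

test_that("the genotype-triple pmf matches direct counting", {
  expect_equal(triple_pmf(0, 2, 0, M = 4, N = 2, p = 0.5, P = 0.25), 1 / 6)
  # census: the full population is the only sample
  expect_equal(triple_pmf(1, 2, 1, M = 4, N = 4, p = 0.5, P = 0.25), 1)
  expect_equal(triple_pmf(0, 2, 2, M = 4, N = 4, p = 0.5, P = 0.25), 0)
  # normalization over all feasible triples
  tot <- 0
  for (x2 in 0:3) for (x1 in 0:(3 - x2)) {
    tot <- tot + triple_pmf(x2, x1, 3 - x2 - x1, M = 6, N = 3, p = 1 / 3, P = 1 / 6)
  }
  expect_equal(tot, 1)
})

test_that("sampled-homozygote bounds delimit exactly the feasible triples", {
  expect_equal(x2_bounds(2, M = 4, N = 2, p = 0.5, P = 0.25),
               c(lower = 0L, upper = 1L))
  # no copies forces x2 = 0 (when enough non-carriers exist for the draw)
  expect_equal(x2_bounds(0, M = 20, N = 2, p = 0.5, P = 0.25),
               c(lower = 0L, upper = 0L))
  # ... and an empty range when they do not: two individuals cannot both
  # be non-carriers if only one non-carrier exists
  b0 <- x2_bounds(0, M = 4, N = 2, p = 0.5, P = 0.25)
  expect_gt(b0[["lower"]], b0[["upper"]])
  # oracle equivalence on all k for small populations: an empty range
  # occurs exactly when no feasible triple exists, and within the range
  # every x2 is feasible
  for (M in c(4L, 6L, 9L, 12L)) {
    grid <- rbind(scenario_grid("minhom", M), scenario_grid("maxhom", M))
    for (N in unique(c(2L, M %/% 2L, M))) {
      for (i in seq_len(nrow(grid))) {
        m <- genotype_class_counts(M, grid$p[i], grid$P[i])
        for (k in 0:(2L * N)) {
          b <- x2_bounds(k, M, N, grid$p[i], grid$P[i])
          feas <- vapply(0:N, function(x2) {
            x1 <- k - 2L * x2
            x0 <- N - x2 - x1
            x1 >= 0 && x0 >= 0 && x2 <= m[1] && x1 <= m[2] && x0 <= m[3]
          }, logical(1))
          if (b["lower"] > b["upper"]) {
            expect_false(any(feas))
          } else {
            expect_equal(which(feas) - 1L, b[["lower"]]:b[["upper"]])
          }
        }
      }
    }
  }
})

test_that("copy-count pmf equals the subset-enumeration oracle exactly", {
  d <- copy_count_pmf(4, 2, 0.5, 0.25)
  expect_equal(d$pmf, c(0, 1, 1, 1, 0) / 3)
  b <- brute_force_pmf(4, 2, 0.5, 0.25)
  expect_identical(d$weights, as.numeric(b$weights))
  # exact integer-weight agreement across all feasible (p, P) at small M
  for (M in c(4L, 6L, 10L)) {
    a <- 0:(2L * M)
    for (ai in a) {
      for (h in max(0L, ai - M):(ai %/% 2L)) {
        for (N in unique(c(1L, M %/% 3L, M %/% 2L, M))) {
          if (N < 1L) next
          dd <- copy_count_pmf(M, N, ai / (2 * M), h / M)
          bb <- brute_force_pmf(M, N, ai / (2 * M), h / M)
          expect_identical(dd$weights, as.numeric(bb$weights))
        }
      }
    }
  }
})

test_that("degenerate parameters give point masses", {
  # census: point mass at 2 M p
  d <- copy_count_pmf(10, 10, 0.3, 0.1)
  expect_equal(d$pmf[7], 1)
  expect_equal(sum(d$pmf), 1)
  # absent allele: point mass at zero
  d0 <- copy_count_pmf(50, 10, 0, 0)
  expect_equal(d0$pmf[1], 1)
})

test_that("mean is p and variance matches the finite-correction closed form", {
  # across all three scenario grids at M = 50
  M <- 50L
  for (sc in c("hwe", "minhom", "maxhom")) {
    g <- scenario_grid(sc, M)
    for (N in c(5L, 25L, 50L)) {
      for (i in seq_len(nrow(g))) {
        d <- copy_count_pmf(M, N, g$p[i], g$P[i])
        phat <- d$k / (2 * N)
        expect_equal(sum(d$pmf * phat), g$p[i], tolerance = 1e-12)
        expect_equal(copy_count_mean(M, N, g$p[i], g$P[i]), g$p[i])
        v_pmf <- sum(d$pmf * (phat - g$p[i])^2)
        expect_equal(v_pmf, copy_count_variance(M, N, g$p[i], g$P[i]),
                     tolerance = 1e-12)
      }
    }
  }
  # census variance is exactly zero
  expect_equal(copy_count_variance(50, 50, 0.3, 0.1), 0)
  # variance increases with P at fixed (M, N, p)
  expect_gte(copy_count_variance(100, 20, 0.4, 0.4),
             copy_count_variance(100, 20, 0.4, 0))
})

test_that("cdf is the running sum of the pmf", {
  expect_equal(copy_count_cdf(4, 2, 0.5, 0.25, 2), 2 / 3)
  d <- copy_count_pmf(50, 10, 0.4, 0.2)
  cdfs <- vapply(0:20, function(k) copy_count_cdf(50, 10, 0.4, 0.2, k), numeric(1))
  expect_equal(cdfs[21], 1)
  expect_false(is.unsorted(cdfs))
  expect_equal(diff(c(0, cdfs)), d$pmf)
})

test_that("the log-scale path agrees with an independent hypergeometric computation", {
  # under maximum homozygosity the copy count is twice a univariate
  # hypergeometric draw of homozygotes; M large enough to force log-scale
  M <- 200L; N <- 50L; p <- 0.3
  d <- copy_count_pmf(M, N, p, p)
  expect_null(d$weights)  # log path used
  expected <- numeric(2L * N + 1L)
  expected[2 * (0:N) + 1L] <- dhyper(0:N, M * p, M - M * p, N)
  expect_equal(d$pmf, expected, tolerance = 1e-12)
})

test_that("the distribution approaches Binomial(2N, p) for large populations at HWE", {
  for (p in c(0.1, 0.5)) {
    d <- copy_count_pmf(1e5, 20, p, p^2)
    tv <- 0.5 * sum(abs(d$pmf - dbinom(0:40, 40, p)))
    expect_lt(tv, 1e-3)
  }
})

test_that("relabelling the focal allele mirrors the distribution", {
  # pmf(k; p, P) = pmf(2N - k; 1 - p, P') with P' the non-carrier frequency
  M <- 30L; N <- 10L
  g <- scenario_grid("minhom", M)
  for (i in seq(1L, nrow(g), by = 7L)) {
    p <- g$p[i]; P <- g$P[i]
    d1 <- copy_count_pmf(M, N, p, P)$pmf
    d2 <- copy_count_pmf(M, N, 1 - p, 1 - 2 * p + P)$pmf
    expect_equal(d1, rev(d2), tolerance = 1e-12)
  }
})

test_that("infeasible or oversized inputs are rejected", {
  expect_error(copy_count_pmf(10, 11, 0.5, 0.25), class = "alleleCI_invalid_argument")
  expect_error(copy_count_pmf(10, 5, 0.33, 0.1), class = "alleleCI_feasibility_error")
  expect_error(brute_force_pmf(100, 50, 0.5, 0.25), class = "alleleCI_invalid_argument")
})
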