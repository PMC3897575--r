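test_that("acceptance regions are equal-tail and minimal", {
  ar <- acceptance_region(4, 2, 0.5, 0.25, 0.05)
  expect_equal(c(ar$k_lo, ar$k_hi), c(1L, 3L))
  # degenerate distribution: region collapses on the point mass
  ar0 <- acceptance_region(50, 10, 0, 0, 0.05)
  expect_equal(c(ar0$k_lo, ar0$k_hi), c(0L, 0L))
  # every maximum-homozygosity grid point at (M = 100, N = 20) has
  # coverage >= 0.95, and shrinking the region from either side violates
  # the defining tail conditions
  g <- scenario_grid("maxhom", 100)
  for (i in seq_len(nrow(g))) {
    d <- copy_count_pmf(100, 20, g$p[i], g$P[i])
    ar <- acceptance_region(100, 20, g$p[i], g$P[i], 0.05)
    expect_gte(ar$coverage, 0.95)
    expect_equal(ar$coverage,
                 sum(d$pmf[(ar$k_lo:ar$k_hi) + 1L]), tolerance = 1e-12)
    expect_gt(sum(d$pmf[seq_len(ar$k_lo + 1L)]), 0.025)       # P(K < k_lo + 1)
    expect_gt(1 - sum(d$pmf[seq_len(ar$k_hi)]), 0.025)        # P(K > k_hi - 1)
  }
})

test_that("acceptance regions match the definition-based oracle on small instances", {
  for (pp in list(c(0.5, 0.25), c(1 / 3, 1 / 6), c(0.75, 0.5))) {
    for (alpha in c(0.01, 0.05, 0.2)) {
      pmf <- brute_force_pmf(12, 5, pp[1], pp[2])$pmf
      r <- oracle_region(pmf, alpha)
      ar <- acceptance_region(12, 5, pp[1], pp[2], alpha)
      expect_equal(c(ar$k_lo, ar$k_hi), r)
    }
  }
})

test_that("test inversion reproduces a brute-force candidate scan", {
  M <- 12L; N <- 4L
  grid <- scenario_grid("maxhom", M)
  for (k_obs in 0:(2L * N)) {
    orc <- oracle_accepted(M, N, k_obs, 0.05, grid)
    if (is.null(orc)) {
      expect_error(ci_known_homozygosity(M, N, k_obs, scenario = "maxhom"),
                   class = "alleleCI_impossible_observation")
    } else {
      ci <- ci_known_homozygosity(M, N, k_obs, scenario = "maxhom")
      expect_equal(ci$accepted_set, sort(grid$p[orc$accepted]))
      expect_equal(ci$effective_alpha, orc$effective_alpha)
      expect_equal(ci$lower, min(ci$accepted_set))
      expect_equal(ci$upper, max(ci$accepted_set))
    }
  }
})

test_that("a census leaves no uncertainty", {
  ci <- ci_known_homozygosity(12, 12, 7, scenario = "minhom")
  expect_equal(ci$lower, 7 / 24)
  expect_equal(ci$upper, 7 / 24)
})

test_that("guaranteed coverage holds exactly for every truth on each scenario grid", {
  for (setting in list(list(M = 100L, N = 20L), list(M = 50L, N = 30L))) {
    M <- setting$M; N <- setting$N
    for (sc in c("hwe", "minhom", "maxhom")) {
      g <- scenario_grid(sc, M)
      # interval per observable copy count (NULL when unobservable)
      cis <- vector("list", 2L * N + 1L)
      for (k in 0:(2L * N)) {
        cis[[k + 1L]] <- tryCatch(
          ci_known_homozygosity(M, N, k, 0.05, grid = g),
          alleleCI_impossible_observation = function(e) NULL)
      }
      for (i in seq_len(nrow(g))) {
        pmf <- copy_count_pmf(M, N, g$p[i], g$P[i])$pmf
        cover <- vapply(0:(2L * N), function(k) {
          ci <- cis[[k + 1L]]
          !is.null(ci) && ci$lower - 1e-12 <= g$p[i] && g$p[i] <= ci$upper + 1e-12
        }, logical(1))
        expect_gte(sum(pmf[cover]), 0.95 - 1e-12)
      }
    }
  }
})

test_that("interval length shrinks (weakly) as alpha grows", {
  for (alpha_pair in list(c(0.01, 0.05), c(0.05, 0.1), c(0.1, 0.2))) {
    ci_narrow <- ci_known_homozygosity(200, 20, 16, alpha_pair[2], scenario = "maxhom")
    ci_wide <- ci_known_homozygosity(200, 20, 16, alpha_pair[1], scenario = "maxhom")
    expect_lte(ci_narrow$upper - ci_narrow$lower, ci_wide$upper - ci_wide$lower)
  }
})

test_that("maximum homozygosity gives intervals at least as long as HWE", {
  M <- 100L; N <- 20L
  for (k_obs in seq(0L, 40L, by = 4L)) {
    len3 <- with(ci_known_homozygosity(M, N, k_obs, scenario = "maxhom"),
                 upper - lower)
    len1 <- with(ci_known_homozygosity(M, N, k_obs, scenario = "hwe"),
                 upper - lower)
    expect_gte(len3 + 1e-12, len1)
  }
})

test_that("the joint (p, P) region matches an exhaustive oracle scan at M = 6", {
  M <- 6L; N <- 3L
  # all lattice pairs
  av <- 0:(2L * M)
  pairs <- do.call(rbind, lapply(av, function(a) {
    h <- max(0L, a - M):(a %/% 2L)
    data.frame(p = a / (2 * M), P = h / M)
  }))
  for (k_obs in 0:(2L * N)) {
    orc <- oracle_accepted(M, N, k_obs, 0.05, pairs)
    if (is.null(orc)) {
      expect_error(cr_unknown_homozygosity(M, N, k_obs),
                   class = "alleleCI_impossible_observation")
    } else {
      cr <- cr_unknown_homozygosity(M, N, k_obs)
      got <- cr$accepted[order(cr$accepted$p, cr$accepted$P), ]
      want <- pairs[orc$accepted, ]
      want <- want[order(want$p, want$P), ]
      expect_equal(got$p, want$p)
      expect_equal(got$P, want$P)
      expect_equal(cr$effective_alpha, orc$effective_alpha)
    }
  }
})

test_that("the unknown-homozygosity region always contains the truth with >= 95% probability", {
  M <- 30L; N <- 10L
  crs <- lapply(0:(2L * N), function(k)
    tryCatch(cr_unknown_homozygosity(M, N, k),
             alleleCI_impossible_observation = function(e) NULL))
  av <- seq(0L, 2L * M, by = 5L)
  for (a in av) {
    for (h in unique(c(max(0L, a - M), a %/% 4L, a %/% 2L))) {
      if (h < max(0L, a - M) || h > a %/% 2L) next
      p <- a / (2 * M); P <- h / M
      pmf <- copy_count_pmf(M, N, p, P)$pmf
      cover <- vapply(0:(2L * N), function(k) {
        cr <- crs[[k + 1L]]
        !is.null(cr) && any(abs(cr$accepted$p - p) < 1e-12 &
                              abs(cr$accepted$P - P) < 1e-12)
      }, logical(1))
      expect_gte(sum(pmf[cover]), 0.95 - 1e-12)
    }
  }
})

test_that("the p-projection of the joint region tracks the maximum-homozygosity interval", {
  cr <- cr_unknown_homozygosity(200, 20, 20)
  ci3 <- ci_known_homozygosity(200, 20, 20, scenario = "maxhom")
  expect_lte(abs(diff(cr$p_interval) - (ci3$upper - ci3$lower)), 0.05)
})

test_that("alpha relaxation halves until some candidate accepts and is idempotent", {
  g <- scenario_grid("hwe", 18)
  # no-op when the accepted set is non-empty
  expect_equal(relax_alpha(18, 7, 5, 0.05, g), 0.05)
  # frozen instance where every candidate rejects k_obs = 1 at 0.05
  ci <- ci_known_homozygosity(18, 7, 1, 0.05, scenario = "hwe")
  expect_equal(ci$effective_alpha, 0.0125)
  expect_equal(ci$accepted_set, 1 / 3)
  expect_equal(relax_alpha(18, 7, 1, 0.05, g), 0.0125)
  # idempotence: relaxing from the effective level returns it unchanged
  expect_equal(relax_alpha(18, 7, 1, 0.0125, g), 0.0125)
  # zero probability under every candidate is an impossible observation
  expect_error(ci_known_homozygosity(8, 4, 1, scenario = "hwe"),
               class = "alleleCI_impossible_observation")
})

test_that("Clopper-Pearson baseline matches stats::binom.test and hits the edges", {
  expect_equal(clopper_pearson_ci(0, 50)$lower, 0)
  expect_equal(clopper_pearson_ci(50, 50)$upper, 1)
  bt <- binom.test(20, 50)$conf.int
  cp <- clopper_pearson_ci(20, 50)
  expect_equal(c(cp$lower, cp$upper), as.numeric(bt), tolerance = 1e-9)
})

test_that("the interval agrees with Clopper-Pearson in the large-population HWE limit", {
  ci <- ci_known_homozygosity(1e5, 25, 20, scenario = "hwe")
  cp <- clopper_pearson_ci(20, 50)
  step <- diff(scenario_grid("hwe", 1e5)$p[1:2])
  expect_lte(abs(ci$lower - cp$lower), step + 1e-12)
  expect_lte(abs(ci$upper - cp$upper), step + 1e-12)
})

test_that("the Wald-type baseline is symmetric, degenerate at the edge, and close for large N", {
  w0 <- weir_wald_ci(0, 100, 0)
  expect_equal(c(w0$lower, w0$upper), c(0, 0))
  w <- weir_wald_ci(120, 200, 0.09)
  expect_equal(w$upper - w$p_hat, w$p_hat - w$lower, tolerance = 1e-12)
  # large-N agreement with the exact interval (maximum homozygosity, whose
  # fine 1/M candidate lattice avoids hull-rounding of the endpoints)
  ci <- ci_known_homozygosity(1e4, 200, 200, scenario = "maxhom")
  ww <- weir_wald_ci(200, 200, 0.5)
  len_exact <- ci$upper - ci$lower
  len_wald <- ww$upper - ww$lower
  expect_lte(abs(len_wald - len_exact) / len_exact, 0.10)
})
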