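---
title: "Exact confidence intervals for allele frequencies in finite diploid populations"
author: "alleleCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact confidence intervals for allele frequencies in finite diploid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleCI)
```

## The model

A diploid population holds `M` individuals. For one focal allele at a locus,
two parameters describe the population: the allele frequency `p` (so the
population carries `2*M*p` copies, necessarily an integer number) and the
homozygote frequency `P` (so `M*P` individuals carry two copies). With
respect to that allele the population partitions into three genotype
classes:

* `m2 = M*P` homozygotes,
* `m1 = 2*M*(p - P)` heterozygous carriers,
* `m0 = M*(1 - 2*p + P)` non-carriers.

`P` is not free: all carriers may be heterozygous only while there are
enough individuals to hold the copies, giving
`max(0, 2*p - 1) <= P <= p` (`homozygosity_bounds()`). Hardy-Weinberg
equilibrium (HWE) is the special case `P = p^2`; the package never assumes
it.

When `N` individuals are drawn without replacement, the sampled class
counts `(x2, x1, x0)` follow a multivariate hypergeometric distribution,
and the sampled copy count `K = 2*x2 + x1` has pmf

```
pr(K = k) = sum over feasible x2 of
            C(m2, x2) C(m1, k - 2*x2) C(m0, N - k + x2) / C(M, N),
```

where the feasible range of `x2` follows from requiring each sampled class
to be non-negative and no larger than its population class
(`x2_bounds()`). The sample frequency `p_hat = K/(2N)` is unbiased for `p`
and has variance

```
Var(p_hat) = (M - N)/(M - 1) * (p(1 - p) + P - p^2) / (2N),
```

i.e. the familiar infinite-population variance (inflated by any excess
homozygosity `P - p^2`) times the finite population correction. Both
moments are verified in the tests against the pmf itself to 1e-12, and the
pmf is verified, term for term, against exhaustive enumeration of every
N-subset of explicit populations with `M <= 12` (`brute_force_pmf()`).

## Intervals by test inversion

For a hypothesized `(p, P)` the equal-tail acceptance region at level
`alpha` is `[k_lo, k_hi]` with `k_lo` the largest integer whose lower tail
`P(K < k_lo)` is at most `alpha/2` and `k_hi` the smallest integer whose
upper tail `P(K > k_hi)` is at most `alpha/2`. The confidence set for an
observed copy count is every candidate whose region contains it; the
reported interval is the hull `[min, max]` of the accepted allele
frequencies. This is the discrete-distribution analogue of the
Clopper-Pearson construction, and coverage is guaranteed to be at least
`1 - alpha` for every truth consistent with the assumed homozygosity rule
-- the package's tests compute the coverage sum exactly for every grid
truth at `M = 100, N = 20` and `M = 50, N = 30`.

Three design points deserve explanation:

* **Ties.** The defining inequalities are non-strict; a tail that equals
  `alpha/2` exactly (to within 1e-12) still counts, which can only widen a
  region and therefore preserves coverage.
* **Empty accepted sets.** A copy count can be rejected by every feasible
  candidate while still being observable. In that case `alpha` is halved
  until at least one candidate accepts (`relax_alpha()`); the level
  actually used is reported as `effective_alpha`. Halving is one concrete
  choice of "decrease until non-empty": it is deterministic, terminates
  (regions grow to the whole support), and is visible to the user. A copy
  count with zero probability under *every* candidate is reported as an
  impossible observation instead -- it signals data inconsistent with the
  assumed model (for example an odd copy count when every carrier is
  homozygous).
* **Hull reporting.** The accepted set need not be contiguous, because the
  cdf is not monotone in `p` across candidate grids. The hull is
  conservative; the raw accepted set is kept on the object for
  diagnostics.

### Candidate grids

Feasibility quantizes everything: `p` lives on the `1/(2M)` lattice and
`P` on the `1/M` lattice. Three scenario rules tie `P` to `p`:

| scenario  | rule                 | candidates for M = 1000 |
|-----------|----------------------|-------------------------|
| `hwe`     | `P = p^2`            | 11 (both `2Mp` and `Mp^2` must be whole; for general `M` this grid can be irregular) |
| `minhom`  | `P = max(0, 2p - 1)` | 2001                    |
| `maxhom`  | `P = p`              | 1001                    |

Endpoints `p = 0` and `p = 1` are kept in every grid; they matter only for
extreme observations and cost nothing. Internally all grids are built from
integer copy counts, so no float-equality comparisons are involved.

When nothing is known about `P`, `cr_unknown_homozygosity()` scans the full
two-dimensional lattice of feasible `(p, P)` pairs and projects the joint
confidence region onto each axis. Because the variance increases with `P`,
the `p`-projection tracks the `maxhom` interval closely (the tests check
the gap at `M = 200, N = 20`; at `M = 1000, N = 30` the two agree exactly,
at roughly 45 s of compute for the full scan). `maxhom` is therefore the
conservative default scenario wherever one must be assumed.

## Sample-size design

`max_ci_length(M, N, scenario)` computes the interval for every observable
copy count `k = 0..2N` and takes the maximum length; acceptance regions
are computed once per candidate and shared across all `k`. Hull endpoints
are carried as integer copy counts so lengths are exact multiples of
`1/(2M)` -- comparisons like "length <= 0.2" must not hinge on binary
rounding of 0.9 - 0.7. `min_sample_size()` scans `N` upward from 10 in
steps of 10 (the result is start-invariant because of the refinement, and
both knobs are exposed), then walks downward one individual at a time
until the target fails, so the reported `N` satisfies the target while
`N - 1` does not. The refinement deliberately re-checks every `N` rather
than bisecting: discreteness can make the maximum length non-monotone in
`N`.

At `M = 1000` and `alpha = 0.05` the package obtains minimum sample sizes
of 22 (`hwe`), 26 (`minhom`) and 94 (`maxhom`) for a maximum length of
0.2, and 50 (`hwe`), 94 (`minhom`) and 285 (`maxhom`) for 0.1. A sample of
30 -- a common rule of thumb -- is therefore adequate only under HWE, and
only for the looser target. One boundary case is worth recording: at
`N = 49`, `hwe`, the candidate `p = 0.4` retains an upper tail of
0.0254 at the central observation `k = 49`, a hair above `alpha/2`, so the
maximum length is still 0.2 there; any construction that would trim that
candidate away sacrifices the coverage guarantee on degenerate
distributions. Minimum sample sizes can be sensitive to tail probabilities
within a few percent of `alpha/2` in exactly this way.

`m_sweep()` repeats the maximum-length computation across population sizes
(default grid 100 to 10,000). Its default sample size in the examples is
`N = 30`, chosen to interrogate the rule of thumb above; `N` is a required,
logged parameter so any other value is equally reproducible. Uncertainty
grows (weakly) with `M` at fixed `N`, but only modestly across two orders
of magnitude.

## Differentiation between two populations

`jost_d()` implements Jost's D for two populations from their
allele-frequency vectors,

```
D = 2 * (H_T - H_S) / (1 - H_S),
```

with `H_S` the mean within-population expected heterozygosity and `H_T`
the expected heterozygosity of the pooled (averaged) frequencies. To
propagate sampling uncertainty into D:

1. compute a per-allele interval for each of the first `n - 1` alleles of
   interest at level `alpha/n_listed` (the last allele is implied by the
   others and gets no interval of its own -- its non-negativity enters only
   through the sum constraint);
2. combine them into a box (`bonferroni_joint_region()`), a joint
   confidence region at level `1 - alpha` by the Bonferroni inequality;
3. minimize and maximize D over the two boxes (`d_interval()`), subject to
   each population's listed frequencies summing to at most 1.

D is non-convex in the frequencies, so the optimizer contract is defined
by agreement with a dense grid search (the tests use a 0.001-step oracle
on toy boxes, tolerance 1e-3). The default search combines
`stats::constrOptim()` (Nelder-Mead within a log-barrier) started from a
fixed-seed Latin-hypercube design (16 starts; `lhs::randomLHS` is the
stratified design generator available here) with exhaustive evaluation of
every feasible box corner, where box-constrained extrema of D usually sit.
One-dimensional problems use `stats::optimize()` directly. Degenerate
(zero-width) box coordinates are pinned rather than optimized.

Published frequency tables are accepted through `read_frequency_table()`,
which converts rounded frequencies back to integer copy counts over `2N`
by round-half-to-even (ties at .5 are not biased upward) and reports the
rounding deltas. The package ships only a synthetic example table; the
checkerspot butterfly table it is shaped after (Palo et al. 1995, CINX1
locus) is under the original publisher's copyright and must be transcribed
by the user (see `inst/extdata/README.txt`).

## The synthetic-population oracle

`build_population()` realizes any feasible marginal specification as an
explicit list of `M` genotypes: homozygote counts are forced, and
remaining copies are paired into heterozygotes by repeatedly joining the
two alleles with the most unplaced copies (a feasible pairing exists
exactly when no allele holds more unplaced copies than all others
combined). The pairing order cannot influence the focal-allele copy-count
distribution, which depends only on the three focal classes -- a property
the tests assert by building the same focal marginals inside different
allele encodings. `draw_sample()` / `sample_copy_counts()` draw uniformly
without replacement under an explicit, mandatory seed (the generator state
is restored afterwards; there is no hidden global state), and
`empirical_coverage()` closes the loop: Monte-Carlo coverage converges to
the exact coverage sum computed from the pmf.

These populations are static urns. They emulate exactly what the
estimator sees -- fixed genotype counts sampled without replacement -- and
nothing else: no mutation, migration, drift, selection, linkage between
loci, or explicit relatedness structure. Passing tests therefore validate
the sampling theory and the interval constructions, not any claim about
how real populations arrived at their genotype frequencies.

## Numerical choices

* Binomial coefficients: when `C(M, N) < 2^53` every pmf term is an exact
  integer ratio and weights are accumulated in exact double-integer
  arithmetic (this is what makes the enumeration-oracle comparisons exact);
  otherwise terms are computed with `lchoose` on the log scale and
  exponentiated, accurate to ~1e-15 since every term is a probability.
  The pmf is required to normalize to within 1e-9 and distributions are
  cached per `(M, N, p, P)` with a bounded cache (`clear_pmf_cache()`).
* Tail ties: non-strict comparisons with an absolute guard of 1e-12.
* Lengths and grids: integer copy counts throughout; reported lengths are
  exact multiples of `1/(2M)`.
* Problem sizes in the test-suite: enumeration oracles run at `M <= 12`;
  exact-coverage sums at `M <= 100, N <= 30`; the joint `(p, P)` scan at
  `M = 200`; the full study-scale sweeps (`M = 1000`, up to `N = 285`)
  run in a few seconds thanks to the per-candidate caching.

## Known limitations

* Intervals are conservative (coverage at least, not exactly, `1 - alpha`);
  shorter constructions exist for discrete families but are out of scope
  here.
* The hull report can include interior `p` values that the test itself
  rejects.
* The Wald-type and Clopper-Pearson baselines are included for comparison
  only; the Wald interval degenerates at boundary observations and the
  Clopper-Pearson interval is valid only in the infinite-population HWE
  limit.
* Multi-locus structure is not modelled; loci are handled independently.
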