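# numeric-integration oracle for the beta-binomial marginal
num_marginal <- function(k, n, alpha, beta) {
  f <- function(v) dbinom(k, n, v) * dbeta(v, alpha, beta)
  integrate(f, 0, 1, rel.tol = 1e-12)$value
}

test_that("beta-binomial marginal matches closed forms and integration", {
  expect_equal(exp(betabin_log_marginal(0, 1, 1, 1)), 0.5)
  # flat prior: every k out of n is equally likely, 1/(n+1)
  for (k in 0:5) expect_equal(exp(betabin_log_marginal(k, 5, 1, 1)), 1 / 6)
  expect_equal(exp(betabin_log_marginal(1, 2, 2, 2)), 0.4)
  for (k in c(0, 1, 3, 7)) for (n in c(7, 20)) for (a in c(0.5, 1, 3)) {
    expect_equal(exp(betabin_log_marginal(k, n, a, 2.5)),
                 num_marginal(k, n, a, 2.5), tolerance = 1e-8)
  }
  expect_error(betabin_log_marginal(5, 3, 1, 1), "k <= n")
  expect_error(betabin_log_marginal(1, 3, -1, 1), "positive")
})

# numeric oracle for the AND-mode joint alternative marginal (shared fraction)
num_and_alt <- function(kf, nf, kr, nr) {
  f <- function(v) dbinom(kf, nf, v) * dbinom(kr, nr, v)
  integrate(f, 0, 1, rel.tol = 1e-12)$value
}

test_that("strand-aware Bayes factors behave per the AND/OR models", {
  # clean sample, clean PON: no alt reads must favour the null
  for (m in c("AND", "OR")) {
    bf <- shearwater_bf(0, 1000, 0, 1000, 0, 10000, 0, 10000, mode = m)
    expect_gt(bf, 1)
  }
  # closed-form AND denominator equals numeric integration
  for (kf in c(0, 2, 5)) for (kr in c(0, 3)) {
    closed <- exp(lchoose(100, kf) + lchoose(80, kr) +
                    lbeta(kf + kr + 1, 180 - kf - kr + 1))
    expect_equal(closed, num_and_alt(kf, 100, kr, 80), tolerance = 1e-8)
  }
  # full-oracle check of the OR Bayes factor: product over strands of
  # null marginal over flat-prior marginal, both by numeric integration
  or_oracle <- function(kf, nf, kr, nr, K, N) {
    num_marginal(kf, nf, K + 1, N - K + 1) /
      num_marginal(kf, nf, 1, 1) *
      num_marginal(kr, nr, K + 1, N - K + 1) /
      num_marginal(kr, nr, 1, 1)
  }
  expect_equal(shearwater_bf(2, 1000, 1, 1000, 2, 20000, 2, 20000, "OR"),
               or_oracle(2, 1000, 1, 1000, 2, 20000), tolerance = 1e-6)
  expect_equal(shearwater_bf(3, 1000, 0, 1000, 2, 20000, 2, 20000, "OR"),
               or_oracle(3, 1000, 0, 1000, 2, 20000), tolerance = 1e-6)
  # OR is uniformly more conservative than AND at low counts: the
  # higher-precision / lower-sensitivity mode
  for (ks in list(c(1, 0), c(2, 0), c(2, 1), c(1, 1))) {
    expect_gt(shearwater_bf(ks[1], 1000, ks[2], 1000, 2, 20000, 2, 20000,
                            "OR"),
              shearwater_bf(ks[1], 1000, ks[2], 1000, 2, 20000, 2, 20000,
                            "AND"))
  }
  # the shared-fraction AND model rewards strand consistency, and both
  # configurations favour the variant at these counts against a clean PON
  bal_and <- shearwater_bf(10, 1000, 10, 1000, 0, 50000, 0, 50000, "AND")
  bias_and <- shearwater_bf(20, 1000, 0, 1000, 0, 50000, 0, 50000, "AND")
  expect_lt(bal_and, bias_and)
  expect_lt(bal_and, 1)
  expect_lt(bias_and, 1)
  # full-oracle check of the AND Bayes factor on one configuration
  null_or <- exp(betabin_log_marginal(3, 50, 0 + 1, 600 - 0 + 1) +
                   betabin_log_marginal(1, 40, 0 + 1, 500 - 0 + 1))
  expect_equal(shearwater_bf(3, 50, 1, 40, 0, 600, 0, 500, "AND"),
               null_or / num_and_alt(3, 50, 1, 40), tolerance = 1e-8)
  # zero depth on both strands carries no evidence
  expect_identical(shearwater_bf(0, 0, 0, 0, 0, 100, 0, 100, "AND"), 1)
  # monotone: more alt reads, smaller BF (fixed depth and PON)
  bfs <- shearwater_bf(0:10, 1000, 0, 1000, 0, 20000, 0, 20000, "AND")
  expect_true(all(diff(bfs) < 0))
})

test_that("posterior transform is the odds identity", {
  expect_identical(bf_to_posterior(1), 0.5)
  expect_identical(bf_to_posterior(0), 0)
  expect_identical(bf_to_posterior(3), 0.75)
  expect_error(bf_to_posterior(-1), "non-negative")
  x <- c(0.01, 0.5, 2, 100)
  expect_true(all(diff(bf_to_posterior(x)) > 0))
})

test_that("the tumor-normal Fisher test matches fisher.test and enumeration", {
  expect_identical(varscan_fisher(0, 100, 0, 100), 1)
  # exhaustive hypergeometric tail for tumor (5,95) vs normal (0,100)
  tail_p <- sum(dhyper(5:100, 5, 195, 100))
  expect_equal(varscan_fisher(5, 95, 0, 100), tail_p, tolerance = 1e-12)
  # reference implementation cross-check over a grid
  for (at in c(0, 1, 4)) for (an in c(0, 2)) {
    ft <- fisher.test(matrix(c(at, 50 - at, an, 80 - an), 2,
                             byrow = TRUE), alternative = "greater")
    expect_equal(varscan_fisher(at, 50 - at, an, 80 - an), ft$p.value,
                 tolerance = 1e-9)
  }
  # one-sidedness: swapping tumor and normal de-significates the table
  expect_lt(varscan_fisher(10, 90, 0, 100), 0.01)
  expect_gt(varscan_fisher(0, 100, 10, 90), 0.99)
  # monotone in the tumor alt count at fixed margins
  ps <- varscan_fisher(0:10, 100 - 0:10, 0, 100)
  expect_true(all(diff(ps) < 0))
  expect_identical(varscan_fisher(0, 0, 0, 0), 1)
})

test_that("TLOD equals its grid-search oracle and responds to alt counts", {
  expect_identical(tlod_score(0, 1000, 1e-3), 0)
  t1 <- tlod_score(10, 1000, 1e-3)
  expect_gt(t1, 0)
  # grid-search oracle over the variant fraction
  grid_tlod <- function(k, n, e) {
    f <- seq(0, 1, by = 1e-5)
    p <- e / 3 + f * (1 - 4 * e / 3)
    ll <- k * log(p) + (n - k) * log1p(-p)
    max(ll) - ll[1]
  }
  expect_equal(t1, grid_tlod(10, 1000, 1e-3) / log(10), tolerance = 1e-6)
  expect_equal(tlod_score(3, 50, 0.01),
               grid_tlod(3, 50, 0.01) / log(10), tolerance = 1e-6)
  # doubling k (below n/2) strictly increases the score
  ks <- c(1, 2, 4, 8, 16, 32)
  ts <- tlod_score(ks, 1000, 1e-3)
  expect_true(all(diff(ts) > 0))
  expect_error(tlod_score(1, 10, 0.9), "0.75")
})

test_that("the error model recovers homogeneous and context-specific rates", {
  set.seed(5)
  n <- 2e5
  y <- rbinom(n, 1, 0.001)
  m <- fit_error_model(data.frame(mismatch = y, ctx = "flat"))
  phat <- predict(m, data.frame(ctx = "flat"))
  se <- sqrt(0.001 * 0.999 / n)
  expect_lt(abs(phat - 0.001), 3 * se)

  # a context at ten times the base rate must be ranked above it
  d <- data.frame(ctx = rep(c("base", "hot"), each = n / 2))
  d$mismatch <- rbinom(n, 1, ifelse(d$ctx == "hot", 0.01, 0.001))
  m2 <- fit_error_model(d)
  pr <- predict(m2, data.frame(ctx = c("base", "hot")))
  expect_gt(pr[2], pr[1])
  expect_lt(abs(pr[2] / pr[1] - 10), 3)

  # single-class input falls back to the floor rate
  m3 <- fit_error_model(data.frame(mismatch = rep(0, 100), ctx = "x"),
                        floor_rate = 1e-6)
  expect_true(m3$fallback)
  expect_identical(predict(m3, data.frame(ctx = "x")), 1e-6)

  # aggregated count weights are honoured
  m4 <- fit_error_model(data.frame(mismatch = c(1, 0), ctx = "x",
                                   weight = c(10, 9990)))
  expect_equal(predict(m4, data.frame(ctx = "x")), 0.001, tolerance = 1e-8)
})

test_that("read-wise LR p-values match their ML oracle and null behaviour", {
  # zero alt reads: tau_hat = 0, p = 1
  expect_identical(dreams_like_pvalue(rep(FALSE, 100), 1e-3), 1)
  expect_identical(dreams_pvalue_counts(0, 100, 1e-3), 1)

  # strong signal: 50 alt of 1000 at eps 1e-3
  p_strong <- dreams_pvalue_counts(50, 1000, 1e-3)
  expect_lt(p_strong, 1e-10)

  # grid-search ML oracle for the count form
  grid_p <- function(k, n, eps) {
    tau <- seq(0, 1, by = 1e-5)
    p <- tau * (1 - 2 * eps) + eps
    ll <- k * log(p) + (n - k) * log1p(-p)
    d <- 2 * (max(ll) - ll[1])
    if (d <= 0) 1 else 0.5 * pchisq(d, 1, lower.tail = FALSE)
  }
  expect_equal(p_strong, grid_p(50, 1000, 1e-3), tolerance = 1e-6)
  expect_equal(dreams_pvalue_counts(3, 500, 2e-3), grid_p(3, 500, 2e-3),
               tolerance = 1e-5)

  # per-read and count implementations agree for constant eps
  is_alt <- c(rep(TRUE, 5), rep(FALSE, 495))
  expect_equal(dreams_like_pvalue(is_alt, 2e-3),
               dreams_pvalue_counts(5, 500, 2e-3), tolerance = 1e-6)

  # alt fraction equal to the error rate: deviance ~ 0, p >= 0.5
  expect_gte(dreams_pvalue_counts(10, 1000, 0.01), 0.5)
  expect_error(dreams_like_pvalue(logical(), 1e-3), "empty")
})

test_that("pileups from consensus observations conserve counts and drop N", {
  p <- tiny_panel(4, ref = c("A", "A", "C", "G"))
  cons <- data.table::data.table(
    site = c(rep(1L, 10), rep(2L, 10), 3L),
    strand = c(rep("+", 10), rep("+", 7), rep("-", 3), "+"),
    base = c(rep("A", 10), rep("A", 7), rep("C", 3), "N"),
    qual = 30)
  pu <- pileup_from_consensus(cons, p)
  expect_identical(pu$A_fwd[1], 10L)
  expect_identical(pu$depth[1], 10)
  expect_identical(pu$A_fwd[2], 7L)
  expect_identical(pu$C_rev[2], 3L)
  expect_identical(pu$depth[2], 10)
  # the N observation contributes to neither counts nor depth
  expect_identical(pu$depth[3], 0)
  expect_error(pileup_from_consensus(
    data.table::data.table(site = 9L, strand = "+", base = "A", qual = 1), p),
    "outside the panel")
})

test_that("candidate enumeration and the calling driver fit together", {
  p <- tiny_panel(4, ref = c("A", "A", "C", "G"))
  pu <- manual_pileup(p, counts = list(C_fwd = c(2L, 0L, 0L, 0L),
                                       T_rev = c(0L, 3L, 0L, 0L)))
  cand <- alt_supported_candidates(pu)
  expect_identical(nrow(cand), 2L)
  expect_identical(cand$alt, c("C", "T"))
  pon <- pon_matrix(list(a = manual_pileup(p), b = manual_pileup(p)))
  s <- call_variants(pu, "shearwater_and", pon = pon)
  expect_identical(nrow(s), 2L)
  expect_true(all(s$kind == "posterior"))
  expect_true(all(s$bf >= 0))
  expect_equal(s$vaf, c(2 / 202, 3 / 203))
  # informed candidates keep zero-support variants at their null values
  inf <- data.table::data.table(site = c(1L, 4L), alt = c("C", "A"))
  s2 <- call_variants(pu, "fisher", normal = manual_pileup(p),
                      candidates = inf)
  expect_identical(nrow(s2), 2L)
  expect_identical(s2$statistic[2], 1)   # k = 0 -> p = 1
  expect_error(call_variants(pu, "fisher", normal = manual_pileup(p),
                             candidates = rbind(inf, inf)), "duplicate")
})

test_that("leave-one-out pooling excludes the scored PON sample", {
  p <- tiny_panel(3, ref = c("A", "C", "G"))
  hot <- manual_pileup(p, counts = list(T_fwd = c(50L, 0L, 0L)))
  clean <- manual_pileup(p)
  pon <- pon_matrix(list(s1 = hot, s2 = clean, s3 = clean))
  pooled_all <- pon_pool(pon)
  pooled_loo <- pon_pool(pon, exclude = "s1")
  expect_identical(pooled_all$T_fwd[1], 50L)
  expect_identical(pooled_loo$T_fwd[1], 0L)
  expect_error(pon_pool(pon, exclude = 1:3), "every PON sample")
})

test_that("a minimal VCF is readable by a standard VCF parser", {
  p <- tiny_panel(4, ref = c("A", "A", "C", "G"))
  pu <- manual_pileup(p, counts = list(C_fwd = c(2L, 0L, 0L, 0L)))
  pon <- pon_matrix(list(a = manual_pileup(p)))
  s <- call_variants(pu, "shearwater_and", pon = pon)
  path <- file.path(withr::local_tempdir(), "calls.vcf")
  write_variants_vcf(s, pu, path)
  vcf <- VariantAnnotation::readVcf(path)
  expect_identical(length(vcf), nrow(s))
  expect_equal(VariantAnnotation::info(vcf)$STAT, s$statistic,
               tolerance = 1e-6)
})
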