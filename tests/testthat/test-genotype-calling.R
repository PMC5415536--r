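test_that("binomial log-likelihood matches the closed form", {
  expect_identical(binom_loglik(10, 10, 1), 0)
  expect_equal(binom_loglik(10, 10, 0.75), 10 * log(0.75), tolerance = 1e-12)
  expect_identical(binom_loglik(3, 10, 0), -Inf)
  expect_identical(binom_loglik(3, 10, 1), -Inf)
  expect_error(binom_loglik(3, 10, 0.3), "0, 0.25, 0.5, 0.75, 1")
  expect_error(binom_loglik(11, 10, 0.5), "k <= n")
})

test_that("caller reproduces the worked single-cell examples", {
  g <- call_genotype(10, 10)
  expect_equal(format(g), "AAAA")
  expect_true(g$complete)
  # LRT against p = 0.75 clears the chi-square(1) critical value
  expect_gt(2 * (0 - 10 * log(0.75)), qchisq(0.95, 1))

  g <- call_genotype(5, 10)
  expect_equal(format(g), "AB00")
  expect_equal(g$best_p, 0.5)
  expect_false(g$complete)
  # 0.25 and 0.75 are not rejected, 0 and 1 are impossible:
  # LRT = 2 (5 ln .5 - 5 ln .25 + 5 ln .5 - 5 ln .75) = 10 ln(4/3) = 2.877
  lrt <- 2 * (dbinom(5, 10, 0.5, log = TRUE) - dbinom(5, 10, 0.25, log = TRUE))
  expect_equal(lrt, 10 * log(4 / 3), tolerance = 1e-12)
  expect_equal(lrt, 2.8768, tolerance = 1e-4)
  expect_lt(lrt, qchisq(0.95, 1))

  g <- call_genotype(0, 2)
  expect_equal(format(g), "BB00")
  expect_equal(g$best_p, 0)
  expect_equal(g$minB, 2L)

  expect_null(call_genotype(1, 1))
  expect_null(call_genotype(0, 0))
  expect_error(call_genotype(3, 2), "k <= n")
})

test_that("caller agrees with the brute-force oracle on a depth sweep", {
  for (n in c(2:12, 20, 33, 47)) {
    for (k in 0:n) {
      got <- call_genotype(k, n)
      want <- oracle_call(k, n)
      expect_equal(got$minA, want$minA, info = sprintf("k=%d n=%d", k, n))
      expect_equal(got$minB, want$minB, info = sprintf("k=%d n=%d", k, n))
      expect_equal(got$best_p, want$best_p, info = sprintf("k=%d n=%d", k, n))
      expect_equal(got$complete, want$complete,
                   info = sprintf("k=%d n=%d", k, n))
    }
  }
})

test_that("allele swap mirrors the call and confidence shrinks with depth", {
  for (n in c(4, 9, 16, 30)) for (k in 0:n) {
    a <- call_genotype(k, n); b <- call_genotype(n - k, n)
    expect_equal(a$minA, b$minB)
    expect_equal(a$minB, b$minA)
  }
  # at fixed k/n, the non-rejected set never grows with n
  for (p_true in c(0, 0.25, 0.5)) {
    unk <- sapply(c(4, 8, 16, 32, 64), function(n)
      call_genotype(round(p_true * n), n)$unknown)
    expect_true(all(diff(unk) <= 0))
  }
})

test_that("matrix caller handles degenerate inputs and recovers truth", {
  # all cells below the two-read minimum: no calls, nothing retained
  rc <- new_read_count_matrix(
    sample = c("s1", "s1", "s2", "s2"), population = c("p1", "p1", "p2", "p2"),
    locus = c("L1", "L2", "L1", "L2"), countA = c(1, 0, 1, 0),
    countB = c(0, 1, 0, 0))
  cs <- call_matrix(rc)
  expect_true(all(is.na(cs$minA)))
  expect_length(cs$retained, 0L)

  # identical complete genotypes everywhere: locus dropped as monomorphic
  rc2 <- new_read_count_matrix(
    sample = rep(c("s1", "s2", "s3"), each = 2),
    population = rep(c("p1", "p1", "p2"), each = 2),
    locus = rep(c("L1", "L2"), 3),
    countA = c(20, 10, 20, 12, 20, 30), countB = c(20, 10, 20, 9, 20, 11))
  cs2 <- call_matrix(rc2)
  expect_false("L1" %in% cs2$retained)  # every sample called AABB
  expect_true("L2" %in% cs2$retained)

  # deep constant coverage: complete calls recover simulated dosages, and
  # the error rate of complete calls shrinks as depth grows
  acc_at <- function(depth, seed) {
    cfg <- toy_config(seed = seed, n_loci = 200, depth_dispersion = Inf,
                      depth_mean = depth)
    sg <- simulate_genotypes(cfg)
    cs <- call_matrix(sg$counts)
    idx <- which(cs$complete)
    mean(cs$minA[idx] == sg$truth$dosage[idx])
  }
  expect_gt(acc_at(100, seed = 11), 0.99)
  expect_gt(acc_at(300, seed = 12), acc_at(30, seed = 12) - 1e-12)
})

test_that("locus retention filters apply the MAF and per-population rules", {
  # L1: scored in only one sample of p2 -> dropped under mode = "all"
  dos <- rbind(s1 = c(1L, 2L), s2 = c(2L, 1L), s3 = c(NA, 3L), s4 = c(NA, 2L))
  colnames(dos) <- c("L1", "L2")
  cs <- make_callset(dos, populations = c("p1", "p1", "p2", "p2"))
  cs$maf <- c(0.3, 0.4)
  out <- filter_loci(cs, min_scored_per_pop = 2)
  expect_equal(out$retained, "L2")
  out_any <- filter_loci(cs, min_scored_per_pop = 2, mode = "any")
  expect_setequal(out_any$retained, c("L1", "L2"))

  # MAF below the cutoff -> dropped
  cs$maf <- c(0.3, 0.005)
  expect_length(filter_loci(cs, min_scored_per_pop = 2)$retained, 0L)
  cs$maf <- c(0.3, 0.01)   # boundary kept (>=)
  expect_equal(filter_loci(cs, min_scored_per_pop = 2)$retained, "L2")
})

test_that("call table export carries one row per non-null call", {
  cfg <- toy_config(seed = 2, n_loci = 30)
  cs <- filter_loci(call_matrix(simulate_genotypes(cfg)$counts))
  tab <- calls_as_table(cs)
  expect_equal(nrow(tab), sum(!is.na(cs$minA)))
  expect_true(all(tab$minA + tab$minB + tab$unknown == 4L))
  expect_true(all(tab$n >= 2))
})
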