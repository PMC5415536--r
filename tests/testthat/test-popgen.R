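test_that("gene diversity matches hand-computed Nei estimator values", {
  # two complete genotypes AAAB and ABBB in one population: 4 A + 4 B copies
  dos <- rbind(s1 = 3L, s2 = 1L)
  colnames(dos) <- "L1"
  cs <- make_callset(dos, populations = c("p1", "p1"))
  he <- gene_diversity(cs)
  expect_equal(unname(he$per_locus["p1", "L1"]), (8 / 7) * 0.5, tolerance = 1e-12)
  expect_equal(he$per_population$He, 0.5714286, tolerance = 1e-6)

  # a single partial call AB00 (nc = 2, p = 0.5): He = 2 * (1 - 0.5) = 1
  cs2 <- make_callset(rbind(s1 = 1L), populations = "p1")
  cs2$minA[] <- 1L; cs2$minB[] <- 1L; cs2$complete[] <- FALSE
  he2 <- gene_diversity(cs2)
  expect_equal(unname(he2$per_locus["p1", 1]), 1.0)

  # monomorphic locus -> He = 0
  cs3 <- make_callset(rbind(s1 = 4L, s2 = 4L), populations = c("p1", "p1"))
  expect_equal(unname(gene_diversity(cs3)$per_locus["p1", 1]), 0)

  # population with no scorable locus -> NA with warning
  dos4 <- rbind(s1 = 2L, s2 = NA)
  cs4 <- make_callset(dos4, populations = c("p1", "p2"))
  expect_warning(he4 <- gene_diversity(cs4), "no scorable")
  expect_true(is.na(he4$per_population$He[he4$per_population$population == "p2"]))
})

test_that("gene diversity and FST agree with brute-force oracles", {
  set.seed(31)
  for (rep in 1:8) {
    npop <- sample(2:3, 1); nper <- sample(2:4, 1); nloc <- sample(1:3, 1)
    dos <- matrix(sample(0:4, npop * nper * nloc, replace = TRUE),
                  npop * nper, nloc)
    rownames(dos) <- paste0("s", seq_len(nrow(dos)))
    colnames(dos) <- paste0("L", seq_len(nloc))
    pops <- rep(paste0("p", seq_len(npop)), each = nper)
    cs <- make_callset(dos, populations = pops)
    cA <- rowsum(dos, pops); cB <- rowsum(4L - dos, pops)
    # skip degenerate draws where FST is undefined
    ok <- tryCatch({fst <- fst_weir_cockerham(cs); TRUE},
                   error = function(e) FALSE)
    if (ok) {
      expect_equal(fst$global, oracle_wc_fst(cA, cB), tolerance = 1e-12)
      expect_true(isSymmetric(fst$pairwise))
      expect_equal(unname(diag(fst$pairwise)), rep(0, npop))
    }
    he <- gene_diversity(cs)
    for (p in seq_len(npop))
      expect_equal(unname(he$per_locus[p, 1]),
                   oracle_he(cA[p, 1], cB[p, 1]), tolerance = 1e-12)
  }
})

test_that("FST hits the fixation and no-differentiation limits", {
  # two populations fixed for alternative alleles
  dos <- rbind(s1 = 4L, s2 = 4L, s3 = 0L, s4 = 0L)
  colnames(dos) <- "L1"
  cs <- make_callset(dos, populations = c("p1", "p1", "p2", "p2"))
  expect_equal(fst_weir_cockerham(cs)$global, 1)

  # identical allele frequencies, equal sizes: estimator at or below zero
  dos2 <- matrix(rep(c(2L, 2L, 2L, 1L, 3L), 2), 5)
  dos2 <- cbind(dos2[, 1]); rownames(dos2) <- paste0("s", 1:5)
  dos2 <- rbind(dos2, dos2); rownames(dos2) <- paste0("s", 1:10)
  colnames(dos2) <- "L1"
  cs2 <- make_callset(dos2, populations = rep(c("p1", "p2"), each = 5))
  expect_lte(fst_weir_cockerham(cs2)$global, 0)

  # population-specific values are means of pairwise rows
  cfg <- toy_config(seed = 17, n_loci = 80)
  cs3 <- filter_loci(call_matrix(simulate_genotypes(cfg)$counts))
  fst3 <- fst_weir_cockerham(cs3)
  i <- 3L
  expect_equal(unname(fst3$popspec[i]), mean(fst3$pairwise[i, -i]))
})

test_that("outlier exclusion is strict at the q threshold", {
  cs <- make_callset(rbind(s1 = c(1L, 2L, 3L), s2 = c(2L, 3L, 0L)),
                     populations = c("p1", "p1"))
  q <- data.frame(locus = c("L1", "L2"), qvalue = c(0.049, 0.05))
  out <- exclude_outlier_loci(cs, q)
  expect_equal(out, "L1")              # 0.05 itself is kept
  expect_length(exclude_outlier_loci(cs, q[0, ]), 0L)
  expect_error(exclude_outlier_loci(cs, data.frame(locus = "L1", qvalue = -0.1)),
               "\\[0, 1\\]")
})

test_that("climatic distances standardize variables before Euclid", {
  cl <- simulate_climate(toy_config(seed = 8))
  d <- climatic_distances(cl)
  expect_equal(unname(diag(d$mat)), rep(0, 8))
  expect_true(isSymmetric(d$mat))
  # permuting variable order leaves the matrix unchanged
  perm <- cl[, c(1:3, sample(4:22))]
  class(perm) <- class(cl)
  expect_equal(climatic_distances(perm)$mat, d$mat)

  # two populations, one variable differing: distance = sqrt(2) * z-gap
  cl2 <- cl[1:2, ]
  for (v in grep("^bio", names(cl2))) cl2[[v]] <- c(1, 1)
  cl2$bio1 <- c(0, 1)
  expect_warning(d2 <- climatic_distances(cl2), "zero-variance")
  # standardized gap between two points is 2/sqrt(2) = sqrt(2)
  expect_equal(d2$mat[1, 2], sqrt(2), tolerance = 1e-12)

  # identical climate rows sit at zero distance
  cl3 <- cl
  cl3[2, grep("^bio", names(cl3))] <- cl3[1, grep("^bio", names(cl3))]
  d3 <- climatic_distances(cl3)
  expect_equal(unname(d3$mat[1, 2]), 0, tolerance = 1e-12)
  # nothing varying at all is an error, not a zero matrix
  cl4 <- cl[c(1, 1), ]; cl4$population <- c("a", "b")
  expect_error(suppressWarnings(climatic_distances(cl4)), "no climate variable")
})

test_that("geographic distances are great circles of radius 6371 km", {
  ct <- data.frame(population = c("a", "b", "c"),
                   longitude = c(0, 180, 0), latitude = c(0, 0, 0))
  d <- geographic_distances(ct)
  expect_equal(d$mat["a", "b"], pi * 6371, tolerance = 1e-6)
  expect_equal(d$mat["a", "c"], 0)
  expect_true(isSymmetric(d$mat))
  ct$latitude[1] <- 95
  expect_error(geographic_distances(ct), "latitude")
})

test_that("Mantel r equals direct Pearson on triangle entries", {
  d1 <- rand_dist(letters[1:4], seed = 3)
  d2 <- rand_dist(letters[1:4], seed = 4)
  m <- mantel(d1, d2, nperm = 199, seed = 5)
  r_direct <- cor(d1$mat[lower.tri(d1$mat)], d2$mat[lower.tri(d2$mat)])
  expect_equal(m$r, r_direct, tolerance = 1e-12)
  expect_true(m$p > 0 && m$p <= 1)

  # perfectly matching matrices
  expect_equal(mantel(d1, d1, nperm = 99, seed = 1)$r, 1, tolerance = 1e-12)

  # constant matrix is rejected
  cm <- new_dist_matrix(matrix(1, 4, 4) - diag(4),
                        labels = letters[1:4])
  expect_error(mantel(d1, cm, nperm = 99, seed = 1), "constant")
  # label mismatch is rejected
  d3 <- rand_dist(letters[5:8], seed = 6)
  expect_error(mantel(d1, d3, nperm = 99, seed = 1), "labels")
})

test_that("partial Mantel matches the residual-correlation computation", {
  d1 <- rand_dist(letters[1:5], seed = 11)
  d2 <- rand_dist(letters[1:5], seed = 12)
  d3 <- rand_dist(letters[1:5], seed = 13)
  pm <- partial_mantel(d1, d2, d3, nperm = 199, seed = 7)
  v1 <- d1$mat[lower.tri(d1$mat)]; v2 <- d2$mat[lower.tri(d2$mat)]
  v3 <- d3$mat[lower.tri(d3$mat)]
  r_resid <- cor(resid(lm(v1 ~ v3)), resid(lm(v2 ~ v3)))
  expect_equal(pm$r, r_resid, tolerance = 1e-10)

  # controlling for d1 itself wipes out the correlation
  pm2 <- partial_mantel(d1, d2, d1, nperm = 99, seed = 8)
  expect_lt(abs(pm2$r), 1e-10)

  # an unrelated conditioning matrix barely changes the plain Mantel r
  set.seed(99)
  big1 <- rand_dist(paste0("x", 1:25), seed = 21)
  big2 <- rand_dist(paste0("x", 1:25), seed = 22)
  big3 <- rand_dist(paste0("x", 1:25), seed = 23)
  plain <- mantel(big1, big2, nperm = 99, seed = 9)$r
  partial <- partial_mantel(big1, big2, big3, nperm = 99, seed = 9)$r
  expect_lt(abs(plain - partial), 0.1)
})

test_that("Mantel statistics agree with an independent implementation", {
  skip_if_not_installed("vegan")
  d1 <- rand_dist(paste0("q", 1:8), seed = 41)
  d2 <- rand_dist(paste0("q", 1:8), seed = 42)
  d3 <- rand_dist(paste0("q", 1:8), seed = 43)
  expect_equal(mantel(d1, d2, nperm = 49, seed = 1)$r,
               unname(vegan::mantel(as.dist(d1), as.dist(d2),
                                    permutations = 49)$statistic),
               tolerance = 1e-10)
  expect_equal(partial_mantel(d1, d2, d3, nperm = 49, seed = 1)$r,
               unname(vegan::mantel.partial(as.dist(d1), as.dist(d2),
                                            as.dist(d3),
                                            permutations = 49)$statistic),
               tolerance = 1e-10)
})
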