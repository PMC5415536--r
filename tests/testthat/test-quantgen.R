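test_that("heritability, evolvability and QST arithmetic follow the formulas", {
  # single draw, gaussian: V_A = 4, V_R = 5 + 1, h2 = 4/10
  vc <- make_vc(cbind(V_F = 1, V_P = 2, V_block = 1, V_err = 5), m = 2)
  expect_equal(heritability(vc)$mean, 0.4)
  # binary adds the logit link variance pi^2/3
  vcb <- make_vc(cbind(V_F = 1, V_block = 1, V_err = 5),
                 link_variance = pi^2 / 3, m = 0.5)
  expect_equal(heritability(vcb)$mean, 4 / (4 + 6 + pi^2 / 3),
               tolerance = 1e-6)
  expect_equal(heritability(vcb)$mean, 0.3010, tolerance = 1e-3)
  # across-treatment models count the family x treatment interaction in V_R
  vct <- make_vc(cbind(V_F = 1, V_block = 1, V_FxT = 2, V_err = 3))
  expect_equal(heritability(vct)$mean, 4 / (4 + 6))

  # evolvability e = 4 V_F / m^2, scale-invariant
  expect_equal(evolvability(vc)$mean, 1.0)
  vc2 <- make_vc(cbind(V_F = 4, V_P = 8, V_block = 4, V_err = 20), m = 4)
  expect_equal(evolvability(vc2)$mean, evolvability(vc)$mean)
  expect_error(evolvability(make_vc(cbind(V_F = 1, V_err = 1), m = 0)),
               "mean is zero")

  # QST = V_P / (2 V_A + V_P)
  expect_equal(qst(make_vc(cbind(V_F = 1, V_P = 8, V_err = 1)))$mean, 0.5)
  expect_equal(qst(make_vc(cbind(V_F = 0, V_P = 0, V_err = 1)))$mean, 0)
  expect_equal(qst(make_vc(cbind(V_F = 1e-12, V_P = 5, V_err = 1)))$mean, 1,
               tolerance = 1e-6)
  expect_error(qst(make_vc(cbind(V_F = 1, V_err = 1))), "population")

  # zero-family-variance draws give h2 = 0
  expect_equal(heritability(make_vc(cbind(V_F = 0, V_err = 2)))$mean, 0)
})

test_that("gaussian sampler recovers simulated variance components", {
  cfg <- toy_config(seed = 71)
  ph <- simulate_phenotypes(cfg)$phenotypes
  vc <- suppressWarnings(fit_halfsib(ph, quick_spec(seed = 71)))
  expect_equal(nrow(vc$draws), 2 * 400)
  expect_true(all(vc$draws >= 0))
  expect_equal(vc$draws[, "V_A"], 4 * vc$draws[, "V_F"])
  # V_F = 1 truth: posterior mean within 30% over this replicate (40 families)
  expect_lt(abs(mean(vc$draws[, "V_F"]) - 1), 0.5)
  expect_lt(abs(mean(vc$draws[, "V_err"]) - 6), 1)
  expect_named(vc$rhat, c("V_P", "V_F", "V_block", "V_err"))
})

test_that("degenerate responses give near-zero variance posteriors", {
  cfg <- toy_config(seed = 5)
  ph <- simulate_phenotypes(cfg)$phenotypes
  ph$biomass <- 3.5
  ph$biomass <- ph$biomass + rnorm(nrow(ph), 0, 1e-6)  # avoid exact ties
  vc <- suppressWarnings(fit_halfsib(ph, quick_spec(seed = 2)))
  # posterior piles up at the weakly-informative prior's noise floor
  expect_lt(mean(vc$draws[, "V_F"]), 1e-3)
  expect_lt(mean(vc$draws[, "V_P"]), 1e-2)
  expect_lt(mean(vc$draws[, "V_err"]), 1e-3)
})

test_that("fits are deterministic given data, spec and seed", {
  cfg <- toy_config(seed = 13)
  ph <- simulate_phenotypes(cfg)$phenotypes
  sp <- quick_spec(seed = 99)
  v1 <- suppressWarnings(fit_halfsib(ph, sp))
  v2 <- suppressWarnings(fit_halfsib(ph, sp))
  expect_identical(v1$draws, v2$draws)
})

test_that("h2 and QST are invariant to affine trait rescaling", {
  cfg <- toy_config(seed = 23)
  ph <- simulate_phenotypes(cfg)$phenotypes
  sp <- quick_spec(seed = 31)
  vc <- suppressWarnings(fit_halfsib(ph, sp))
  ph2 <- ph; ph2$biomass <- 3 * ph2$biomass + 10
  vc2 <- suppressWarnings(fit_halfsib(ph2, sp))
  expect_lt(abs(heritability(vc2)$mean - heritability(vc)$mean), 0.03)
  expect_lt(abs(qst(vc2)$mean - qst(vc)$mean), 0.05)
  # evolvability is invariant to pure scaling only
  ph3 <- ph; ph3$biomass <- 3 * ph3$biomass
  vc3 <- suppressWarnings(fit_halfsib(ph3, sp))
  expect_lt(abs(evolvability(vc3)$mean - evolvability(vc)$mean), 0.01)
})

test_that("binary-logit sampler recovers a simulated family variance", {
  cfg <- toy_config(seed = 37)
  cfg$binary <- list(intercept = 0, lat_slope = 0, V_P = 0.3, V_F = 1)
  ph <- simulate_phenotypes(cfg)$phenotypes
  sp <- halfsib_spec("flowering", family = "binary", fixed = "intercept",
                     random = c("population", "family"), chains = 2L,
                     iter = 3000L, burnin = 1000L, thin = 4L, seed = 37)
  vc <- suppressWarnings(fit_halfsib(ph, sp))
  expect_equal(unique(vc$draws[, "V_err"]), 1)     # fixed, not estimated
  expect_equal(vc$link_variance, pi^2 / 3)
  ci <- quantile(vc$draws[, "V_F"], c(0.025, 0.975))
  expect_true(ci[1] < 1 && 1 < ci[2])
  expect_error(fit_halfsib(ph, halfsib_spec("biomass", family = "binary")),
               "0/1")
})

test_that("model building enforces nesting and level counts", {
  cfg <- toy_config(seed = 3)
  ph <- simulate_phenotypes(cfg)$phenotypes
  bad <- ph
  bad$family[bad$population == "pop02"][1] <- bad$family[1]
  expect_error(suppressWarnings(fit_halfsib(bad, quick_spec(seed = 1))),
               "nested")
  one_pop <- ph[ph$population == "pop01", ]
  expect_error(fit_halfsib(one_pop, quick_spec(seed = 1)),
               "fewer than 2 levels")
  expect_error(halfsib_spec("x", random = "garden"), "unknown random term")
})

test_that("pairwise QST rises along a simulated mean gradient", {
  cfg <- toy_config(seed = 55, n_pop = 3L,
                    latitudes = c(45, 50, 55))
  cfg$traits$biomass <- list(mean = 10, lat_slope = 2, V_P = 0.01, V_F = 1,
                             V_block = 0.2, V_err = 2)
  ph <- simulate_phenotypes(cfg)$phenotypes
  sp <- halfsib_spec("biomass", chains = 1L, iter = 800L, burnin = 300L,
                     thin = 2L, seed = 4)
  m <- suppressWarnings(qst_pairwise(ph, sp))
  expect_true(isSymmetric(m$mat))
  expect_equal(m$kind, "QST")
  # adjacent pairs (5 degrees apart) differentiate less than the extremes
  expect_gt(m$mat["pop01", "pop03"], m$mat["pop01", "pop02"])

  # a population pair with a single family is flagged and left missing
  fam1 <- ph$family[ph$population == "pop02"][1]
  sub <- ph[ph$population == "pop01" |
              (ph$population == "pop02" & ph$family == fam1), ]
  expect_warning(m2 <- qst_pairwise(sub, sp), "fewer than 2 families")
  expect_true(is.na(m2$mat["pop01", "pop02"]))
})

test_that("plasticity QST flags prior-dominated posteriors", {
  cfg <- toy_config(seed = 77)
  ph <- simulate_phenotypes(cfg)$phenotypes   # no interaction variance simulated
  sp <- halfsib_spec("biomass", chains = 1L, iter = 1500L, burnin = 500L,
                     thin = 2L, seed = 6)
  qp <- suppressWarnings(qst_plasticity(ph, sp))
  expect_true(qp$prior_sensitive)

  # strong population x treatment interaction, negligible family x treatment
  cfg2 <- toy_config(seed = 78)
  cfg2$traits$biomass <- list(mean = 10, lat_slope = 0, V_P = 0.5, V_F = 0.5,
                              V_block = 0.2, V_err = 1, V_PxT = 8,
                              V_FxT = 1e-4)
  ph2 <- simulate_phenotypes(cfg2)$phenotypes
  qp2 <- suppressWarnings(qst_plasticity(ph2, sp))
  expect_gt(qp2$mean, 0.7)

  # arithmetic: V_PxT = 8 V_FxT gives 0.5 exactly
  d <- cbind(V_F = 1, V_P = 1, V_FxT = 0.5, V_PxT = 4, V_err = 1)
  q <- d[, "V_PxT"] / (8 * d[, "V_FxT"] + d[, "V_PxT"])
  expect_equal(unname(q), 0.5)

  expect_error(qst_plasticity(ph[ph$treatment == "mild", ], sp),
               "two treatments")
})
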