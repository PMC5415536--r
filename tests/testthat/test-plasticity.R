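test_that("family plasticity CV matches hand computations", {
  ph <- data.frame(
    plant = sprintf("pl%02d", 1:18),
    population = "p1",
    family = rep(c("f1", "f2"), each = 9),
    treatment = rep(rep(c("mild", "frost", "warmfrost"), each = 3), 2),
    block = rep(rep(c("mild_b1", "frost_b1", "warmfrost_b1"), each = 3), 2),
    latitude = 50,
    initial_height = 5, final_height = 7, flowering = 0,
    stringsAsFactors = FALSE)
  ph$growth_rate <- ph$final_height - ph$initial_height
  # f1 treatment means 1, 2, 3 -> mean 2, sd 1, CV = 0.5; f2 flat -> CV 0
  ph$biomass <- c(rep(c(1, 2, 3), each = 3), rep(2, 9))
  ph <- validate_phenotypes(ph)
  fp <- family_plasticity(ph, "biomass")
  expect_equal(fp$cv[fp$family == "f1"], 0.5)
  expect_equal(fp$overall_mean[fp$family == "f1"], 2)
  expect_equal(fp$cv[fp$family == "f2"], 0)

  # positive rescaling leaves CV unchanged
  ph10 <- ph; ph10$biomass <- ph10$biomass * 10
  expect_equal(family_plasticity(ph10, "biomass")$cv, fp$cv)

  # treatment means ignore missing plants
  ph$biomass[1] <- NA
  expect_equal(family_plasticity(ph, "biomass")$cv[1], 0.5)

  # a family seen in one treatment is dropped with a warning
  ph_one <- ph[!(ph$family == "f2" & ph$treatment != "mild"), ]
  expect_warning(fp1 <- family_plasticity(ph_one, "biomass"),
                 "fewer than 2 treatments")
  expect_false("f2" %in% fp1$family)
})

test_that("adaptive plasticity regression recovers signed effects", {
  mk <- function(fitness_fun, seed = 1) {
    set.seed(seed)
    nfam <- 30
    cv <- runif(nfam, 0, 0.6)
    tmean <- rnorm(nfam, 10, 1)
    ph <- do.call(rbind, lapply(seq_len(nfam), function(i) {
      data.frame(plant = paste0("pl", i, "_", 1:3),
                 population = paste0("p", (i - 1) %/% 5 + 1),
                 family = paste0("f", i),
                 treatment = c("mild", "frost", "warmfrost"),
                 block = c("mild_b1", "frost_b1", "warmfrost_b1"),
                 latitude = 50, initial_height = 5, final_height = 7,
                 flowering = 0,
                 biomass = tmean[i] * (1 + cv[i] * c(-1, 0, 1) * sqrt(3 / 2)),
                 stringsAsFactors = FALSE)
    }))
    ph$growth_rate <- 2
    ph$fitness <- rep(fitness_fun(cv, tmean), each = 3)
    validate_phenotypes(ph)
  }
  # fitness = -2 CV + noise: significantly negative (maladaptive) slope
  ph <- mk(function(cv, tm) -2 * cv + rnorm(length(cv), 0, 0.1), seed = 4)
  res <- adaptive_plasticity_test(ph, trait = "biomass",
                                  fitness_trait = "fitness")
  expect_lt(res$slope, 0)
  expect_lt(res$p, 0.01)
  expect_equal(res$df, res$n - 3L)

  # negating fitness flips the slope sign exactly
  ph2 <- ph; ph2$fitness <- -ph2$fitness
  res2 <- adaptive_plasticity_test(ph2, "biomass", "fitness")
  expect_equal(res2$slope, -res$slope, tolerance = 1e-10)

  # constant fitness: slope numerically zero (perfect-fit warning expected)
  ph3 <- ph; ph3$fitness <- 5
  res3 <- suppressWarnings(adaptive_plasticity_test(ph3, "biomass", "fitness"))
  expect_lt(abs(res3$slope), 1e-10)
})

test_that("OLS slope matches the closed-form normal equations", {
  set.seed(8)
  n <- 40
  cv <- runif(n); tm <- rnorm(n); fit <- 1 + 0.5 * cv - 0.2 * tm + rnorm(n)
  X <- cbind(1, cv, tm)
  beta_hat <- solve(t(X) %*% X, t(X) %*% fit)
  co <- coef(lm(fit ~ cv + tm))
  expect_equal(unname(co), as.vector(beta_hat), tolerance = 1e-10)
})

test_that("plasticity slope is well calibrated under the null", {
  set.seed(21)
  nfam <- 25
  pvals <- replicate(300, {
    cv <- runif(nfam); tm <- rnorm(nfam); fit <- rnorm(nfam)
    summary(lm(fit ~ cv + tm))$coefficients["cv", "Pr(>|t|)"]
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
})

test_that("latitudinal correlations use the Pearson t test", {
  lat <- seq(43, 63, length.out = 8)
  expect_equal(latitudinal_correlations(lat, lat)$r, 1)
  set.seed(2)
  vals <- -lat + rnorm(8, 0, 0.3)
  lc <- latitudinal_correlations(vals, lat)
  expect_lt(lc$r, -0.95)
  ct <- cor.test(vals, lat)
  expect_equal(lc$r, unname(ct$estimate))
  expect_equal(lc$p, ct$p.value)
  expect_error(latitudinal_correlations(rep(1, 8), lat), "zero variance")
  expect_error(latitudinal_correlations(vals[1:2], lat[1:2]), "at least 3")
})
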