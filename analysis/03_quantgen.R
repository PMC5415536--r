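#!/usr/bin/env Rscript

# Stage 3 — variance components of the half-sib design per trait: MCMC fits
# with population, family and block as random effects and treatment fixed;
# heritability h2 = VA/(VA+VR) with VA = 4 VF, evolvability e = 4 VF / m^2,
# and QST = VP/(2 VA + VP) with credible intervals from the posterior.
# Also fits per-population models (family + block) for the latitudinal
# pattern of h2, and the pairwise QST matrix for biomass.

library(tetraqst)

ind <- "results/simdata"
outdir <- "results/quantgen"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ph <- read_phenotypes(file.path(ind, "phenotypes.tsv"))
mcmc <- list(chains = 2L, iter = 6000L, burnin = 1000L, thin = 5L)

traits <- c(biomass = "gaussian", initial_height = "gaussian",
            final_height = "gaussian", growth_rate = "gaussian",
            flowering = "binary")
rows <- list()
for (tr in names(traits)) {
  sp <- halfsib_spec(tr, family = traits[[tr]], fixed = "treatment",
                     random = c("population", "family", "block"),
                     chains = mcmc$chains, iter = mcmc$iter,
                     burnin = mcmc$burnin, thin = mcmc$thin,
                     seed = 100L + match(tr, names(traits)))
  vc <- fit_halfsib(ph, sp)
  h2 <- heritability(vc); ev <- evolvability(vc); q <- qst(vc)
  message(sprintf(
    "%-14s h2 = %.3f (%.3f-%.3f)  e = %.4f  QST = %.3f (%.3f-%.3f)%s",
    tr, h2$mean, h2$lower, h2$upper, ev$mean, q$mean, q$lower, q$upper,
    if (vc$converged) "" else "  [Rhat warning]"))
  rows[[tr]] <- data.frame(
    trait = tr, family = traits[[tr]],
    h2_mean = h2$mean, h2_sd = h2$sd, h2_lower = h2$lower,
    h2_upper = h2$upper, e_mean = ev$mean,
    qst_mean = q$mean, qst_lower = q$lower, qst_upper = q$upper,
    converged = vc$converged, stringsAsFactors = FALSE)
}
write_results(do.call(rbind, rows), file.path(outdir, "quantgen.tsv"))

# per-population h2 for the latitudinal correlation (biomass)
pops <- sort(unique(ph$population))
h2_pop <- vapply(pops, function(pp) {
  sp <- halfsib_spec("biomass", fixed = "treatment",
                     random = c("family", "block"),
                     chains = 2L, iter = 3000L, burnin = 800L, thin = 4L,
                     seed = 200L + match(pp, pops))
  heritability(fit_halfsib(ph[ph$population == pp, ], sp))$mean
}, numeric(1))
lat <- tapply(ph$latitude, ph$population, `[`, 1L)[pops]
write_results(data.frame(population = pops, latitude = unname(lat),
                         h2_biomass = unname(h2_pop)),
              file.path(outdir, "h2_per_population.tsv"))

# pairwise QST for biomass (feeds the Mantel tests of stage 5)
sp_pw <- halfsib_spec("biomass", fixed = "treatment",
                      random = c("population", "family", "block"),
                      chains = 1L, iter = 2500L, burnin = 500L, thin = 4L,
                      seed = 300L)
qpw <- qst_pairwise(ph, sp_pw)
write_results(qpw, file.path(outdir, "qst_pairwise_biomass.tsv"))

# plasticity QST with its prior-sensitivity flag
sp_pl <- halfsib_spec("biomass", fixed = "treatment",
                      random = c("population", "family", "block"),
                      chains = 2L, iter = 4000L, burnin = 1000L, thin = 4L,
                      seed = 400L)
qpl <- qst_plasticity(ph, sp_pl)
message(sprintf("plasticity QST (biomass) = %.3f (%.3f-%.3f)%s",
                qpl$mean, qpl$lower, qpl$upper,
                if (qpl$prior_sensitive)
                  "  [prior-sensitive: not interpreted]" else ""))
write_results(data.frame(trait = "biomass", qst_plast_mean = qpl$mean,
                         lower = qpl$lower, upper = qpl$upper,
                         prior_sensitive = qpl$prior_sensitive),
              file.path(outdir, "qst_plasticity.tsv"))
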