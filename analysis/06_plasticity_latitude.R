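#!/usr/bin/env Rscript

# Stage 6 — adaptive-plasticity regressions and latitudinal correlations:
# family-level CV plasticity indices regressed against fitness proxies
# (biomass, flowering probability) with the trait mean as covariate, and
# Pearson correlations of per-population estimates (He, population-specific
# FST, h2) with latitude of origin.

library(tetraqst)

outdir <- "results/plasticity"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ph <- read_phenotypes("results/simdata/phenotypes.tsv")

traits <- c("initial_height", "final_height", "growth_rate")
rows <- list()
for (fitness in c("biomass", "flowering")) {
  for (tr in traits) {
    res <- adaptive_plasticity_test(ph, trait = tr, fitness_trait = fitness)
    message(sprintf("plasticity of %-14s vs %-9s slope %+.4f  t = %+.3f  p = %.3f",
                    tr, fitness, res$slope, res$t, res$p))
    rows[[paste(fitness, tr)]] <- data.frame(
      fitness = fitness, trait = tr, slope = res$slope, t = res$t,
      p = res$p, n_families = res$n, stringsAsFactors = FALSE)
  }
}
write_results(do.call(rbind, rows), file.path(outdir, "plasticity_fitness.tsv"))

# latitudinal patterns of the per-population estimates from earlier stages
he <- utils::read.table("results/popgen/diversity.tsv", sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
fst_tab <- utils::read.table("results/popgen/fst.tsv", sep = "\t",
                             header = TRUE, comment.char = "",
                             stringsAsFactors = FALSE)
h2p <- utils::read.table("results/quantgen/h2_per_population.tsv", sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
pw <- read_dist_matrix("results/popgen/fst_pairwise.tsv")
popspec <- vapply(seq_along(pw$labels),
                  function(i) mean(pw$mat[i, -i]), numeric(1))

lat <- h2p$latitude[match(h2p$population, h2p$population)]
cors <- list(
  He_vs_latitude = latitudinal_correlations(
    he$He[match(h2p$population, he$population)], h2p$latitude),
  popspec_fst_vs_latitude = latitudinal_correlations(
    popspec[match(h2p$population, pw$labels)], h2p$latitude),
  h2_biomass_vs_latitude = latitudinal_correlations(
    h2p$h2_biomass, h2p$latitude))
tab <- do.call(rbind, lapply(names(cors), function(nm)
  data.frame(estimate = nm, r = cors[[nm]]$r, p = cors[[nm]]$p,
             n = cors[[nm]]$n, stringsAsFactors = FALSE)))
write_results(tab, file.path(outdir, "latitudinal_correlations.tsv"))
for (i in seq_len(nrow(tab)))
  message(sprintf("%-26s r = %+.3f  p = %.3f", tab$estimate[i], tab$r[i],
                  tab$p[i]))
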