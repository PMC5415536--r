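#!/usr/bin/env Rscript

# Stage 5 — isolation by distance / climate and the QST-FST covariation:
# great-circle and scaled-climate distances between populations, then
# (partial) Mantel tests of pairwise FST and pairwise QST against them,
# 1000 permutations each.

library(tetraqst)

outdir <- "results/mantel"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cl <- read_climate("results/simdata/climate.tsv")
fst_pw <- read_dist_matrix("results/popgen/fst_pairwise.tsv")
qst_pw <- read_dist_matrix("results/quantgen/qst_pairwise_biomass.tsv")

geo <- geographic_distances(cl)
clim <- climatic_distances(cl)
ord <- match(fst_pw$labels, geo$labels)
geo <- new_dist_matrix(geo$mat[ord, ord], kind = "geographic")
clim <- new_dist_matrix(clim$mat[ord, ord], kind = "climatic")

tests <- list(
  fst_vs_geography = mantel(fst_pw, geo, nperm = 1000L, seed = 801L),
  fst_vs_climate_given_geography =
    partial_mantel(fst_pw, clim, geo, nperm = 1000L, seed = 802L),
  qst_vs_geography = mantel(qst_pw, geo, nperm = 1000L, seed = 803L),
  qst_vs_climate_given_geography =
    partial_mantel(qst_pw, clim, geo, nperm = 1000L, seed = 804L),
  qst_vs_fst = mantel(qst_pw, fst_pw, nperm = 1000L, seed = 805L))

tab <- do.call(rbind, lapply(names(tests), function(nm)
  data.frame(test = nm, r = tests[[nm]]$r, p = tests[[nm]]$p,
             nperm = tests[[nm]]$nperm, stringsAsFactors = FALSE)))
write_results(tab, file.path(outdir, "mantel.tsv"))
for (i in seq_len(nrow(tab)))
  message(sprintf("%-34s r = %+.3f  Mantel p = %.3f",
                  tab$test[i], tab$r[i], tab$p[i]))
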