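#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic study: 8 populations spanning 43.03 to
# 62.94 degrees N, 5 half-sib seed families per population, 15 offspring per
# family under 3 simulated winter treatments; GBS read counts for one
# offspring per family at 500 biallelic loci (Balding-Nichols drift at
# FST 0.09); a per-population climate table. Writes everything under
# results/simdata/ for the later stages.

library(tetraqst)

seed <- 42L
outdir <- "results/simdata"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
message("simulating phenotypes (", cfg$n_pop, " x ", cfg$n_fam_per_pop,
        " x ", cfg$n_off_per_fam, " plants) ...")
ph <- simulate_phenotypes(cfg)
message("simulating read counts at ", cfg$n_loci, " loci, theta = ",
        cfg$theta, " ...")
sg <- simulate_genotypes(cfg)
cl <- simulate_climate(cfg)

write_results(as.data.frame(ph$phenotypes), file.path(outdir, "phenotypes.tsv"))
counts_long <- data.frame(
  sample = rep(sg$counts$samples, times = length(sg$counts$loci)),
  population = rep(unname(sg$counts$populations[sg$counts$samples]),
                   times = length(sg$counts$loci)),
  locus = rep(sg$counts$loci, each = length(sg$counts$samples)),
  countA = as.vector(sg$counts$countsA),
  countB = as.vector(sg$counts$countsB))
write_results(counts_long, file.path(outdir, "read_counts.tsv"))
write_results(as.data.frame(cl), file.path(outdir, "climate.tsv"))

# a small synthetic q-value table: every locus neutral except a handful of
# planted "outliers" (this emulates the outlier-scan output consumed later;
# no outlier scan is run here)
set.seed(seed)
qv <- data.frame(locus = sg$counts$loci,
                 qvalue = runif(length(sg$counts$loci), 0.1, 1))
qv$qvalue[sample.int(nrow(qv), 5L)] <- runif(5L, 0, 0.04)
write_results(qv, file.path(outdir, "qvalues_synthetic.tsv"))

message("wrote ", outdir, ": ",
        nrow(ph$phenotypes), " plants, ",
        length(sg$counts$samples), " genotyped samples, ",
        length(sg$counts$loci), " loci, ",
        sum(qv$qvalue < 0.05), " planted outlier loci")
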