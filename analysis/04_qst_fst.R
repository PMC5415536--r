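#!/usr/bin/env Rscript

# Stage 4 — test each trait's differentiation against the neutral
# expectation: simulate the neutral QSTn distribution from the posterior VA
# draws and the GBS FST (VPn = 2 FST VA/(1-FST) scaled by a chi-square
# sampling factor), subtract it from the QST posterior, and call the
# verdict from the 95% credible interval of the difference.

library(tetraqst)

ind <- "results/simdata"
outdir <- "results/qst_fst"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ph <- read_phenotypes(file.path(ind, "phenotypes.tsv"))

# neutral FST from stage 2's table (global row)
fst_tab <- utils::read.table("results/popgen/fst.tsv", sep = "\t",
                             header = TRUE, comment.char = "",
                             stringsAsFactors = FALSE)
fst_global <- as.numeric(fst_tab$fst[fst_tab$pop1 == "#global"])
npop <- length(unique(ph$population))
message(sprintf("using global FST = %.4f over %d populations",
                fst_global, npop))

traits <- c(biomass = "gaussian", initial_height = "gaussian",
            final_height = "gaussian", growth_rate = "gaussian",
            flowering = "binary")
rows <- list()
for (tr in names(traits)) {
  sp <- halfsib_spec(tr, family = traits[[tr]], fixed = "treatment",
                     random = c("population", "family", "block"),
                     chains = 2L, iter = 6000L, burnin = 1000L, thin = 10L,
                     seed = 500L + match(tr, names(traits)))
  vc <- fit_halfsib(ph, sp)
  q <- qst(vc)$draws
  n_sim <- min(1000L, length(q))
  qn <- simulate_qstn(vc, fst = fst_global, npop = npop, n_sim = n_sim,
                      seed = 600L + match(tr, names(traits)))
  td <- test_divergence(q[seq_len(n_sim)], qn,
                        seed = 700L + match(tr, names(traits)))
  message(sprintf("%-14s QST - QSTn = %+.3f (%+.3f to %+.3f): %s",
                  tr, td$mean_diff, td$lower, td$upper, td$verdict))
  rows[[tr]] <- data.frame(trait = tr, n_sim = td$n_sim,
                           mean_diff = td$mean_diff, lower = td$lower,
                           upper = td$upper, verdict = td$verdict,
                           stringsAsFactors = FALSE)
}
write_results(do.call(rbind, rows), file.path(outdir, "neutrality.tsv"))
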