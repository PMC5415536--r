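#!/usr/bin/env Rscript

# Stage 2 — call tetraploid genotypes from the read counts, apply the locus
# retention filters (polymorphic, MAF >= 0.01, scored in >= 2 samples per
# population), then compute molecular diversity (Nei He) and differentiation
# (Weir-Cockerham FST, global / pairwise / population-specific) with the
# planted outlier loci excluded from the neutral estimate.

library(tetraqst)

ind <- "results/simdata"
outdir <- "results/popgen"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

rc <- read_read_counts(file.path(ind, "read_counts.tsv"))
qv <- read_qvalues(file.path(ind, "qvalues_synthetic.tsv"))

cs <- filter_loci(call_matrix(rc, alpha = 0.05),
                  maf_min = 0.01, min_scored_per_pop = 2L)
message(length(cs$retained), " of ", length(cs$loci), " loci retained; ",
        sum(cs$complete, na.rm = TRUE), " complete calls of ",
        sum(!is.na(cs$minA)))
write_results(calls_as_table(cs), file.path(outdir, "calls.tsv"))

he <- gene_diversity(cs)
write_results(he$per_population, file.path(outdir, "diversity.tsv"))

excl <- exclude_outlier_loci(cs, qv, q_max = 0.05)
fst <- fst_weir_cockerham(cs, exclude = excl)
write_results(fst, file.path(outdir, "fst.tsv"))
write_results(new_dist_matrix(fst$pairwise, kind = "FST"),
              file.path(outdir, "fst_pairwise.tsv"))

message(sprintf("global FST = %.4f over %d loci (%d outliers excluded)",
                fst$global, fst$n_loci_used, length(excl)))
message("He by population: ",
        paste(sprintf("%s %.3f", he$per_population$population,
                      he$per_population$He), collapse = ", "))
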