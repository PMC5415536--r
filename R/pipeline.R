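#' Assemble a full-run configuration
#'
#' One master seed deterministically derives the per-stage seeds (counter
#' scheme: stage k uses `seed * 1000 + k`), so a run is reproducible from a
#' single integer.
#'
#' @param counts A `read_count_matrix`, or `NULL` to skip molecular stages.
#' @param phenotypes A `phenotype_table`.
#' @param qvalues Optional per-locus q-value table (outlier exclusion).
#' @param climate Optional `climate_table`.
#' @param traits Gaussian traits to analyse (default the three height/mass
#'   traits plus derived growth rate).
#' @param binary_trait Binary trait name (default `"flowering"`, `NULL` to
#'   skip).
#' @param alpha,maf_min,min_scored_per_pop Genotype-calling and locus
#'   filters.
#' @param q_max Outlier exclusion threshold.
#' @param nperm Mantel permutations.
#' @param n_sim Neutral QSTn simulations per trait.
#' @param mcmc List of MCMC settings passed to [halfsib_spec()]
#'   (`chains`, `iter`, `burnin`, `thin`).
#' @param seed Master seed.
#' @param outdir Output directory for stage TSVs, or `NULL` to skip writing.
#' @param quiet Suppress stage log lines (written to stderr).
#' @return A `run_config` list.
#' @export
run_config <- function(counts = NULL, phenotypes, qvalues = NULL,
                       climate = NULL,
                       traits = c("biomass", "initial_height",
                                  "final_height", "growth_rate"),
                       binary_trait = "flowering",
                       alpha = 0.05, maf_min = 0.01, min_scored_per_pop = 2L,
                       q_max = 0.05, nperm = 1000L, n_sim = 1000L,
                       mcmc = list(chains = 2L, iter = 13000L,
                                   burnin = 3000L, thin = 10L),
                       seed = 1L, outdir = NULL, quiet = FALSE) {
  structure(list(counts = counts, phenotypes = phenotypes, qvalues = qvalues,
                 climate = climate, traits = traits,
                 binary_trait = binary_trait, alpha = alpha,
                 maf_min = maf_min,
                 min_scored_per_pop = as.integer(min_scored_per_pop),
                 q_max = q_max, nperm = as.integer(nperm),
                 n_sim = as.integer(n_sim), mcmc = mcmc,
                 seed = as.integer(seed), outdir = outdir, quiet = quiet),
            class = "run_config")
}

.stage_seed <- function(cfg, k) cfg$seed * 1000L + as.integer(k)

.log_stage <- function(cfg, stage, msg) {
  if (!isTRUE(cfg$quiet)) message("[", stage, "] ", msg)
}

.stage <- function(cfg, stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Sequences genotype calling and locus filtering, molecular diversity and
#' differentiation, distance/Mantel tests, per-trait variance-component
#' estimation (heritability, evolvability, QST), the QST-FST neutrality
#' test, plasticity-fitness regressions, and latitudinal correlations.
#' Molecular stages are skipped gracefully when no read counts are given;
#' Mantel climate tests are marked skipped without a climate table. Stage
#' outputs are written as TSVs under `cfg$outdir` when set, plus a
#' human-readable `summary.txt`.
#'
#' @param cfg A `run_config`.
#' @return A `run_report` list with elements `calls`, `diversity`, `fst`,
#'   `mantel`, `quantgen` (per-trait table), `neutrality`, `plasticity`,
#'   `latitudinal`, `seeds`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  report <- list(seeds = list(master = cfg$seed))
  ph <- cfg$phenotypes
  pops <- sort(unique(ph$population))
  lat <- tapply(ph$latitude, ph$population, function(x) x[1L])[pops]
  fst_global <- NA_real_
  pairwise_fst <- NULL

  # --- molecular stages ----------------------------------------------------
  if (!is.null(cfg$counts)) {
    cs <- .stage(cfg, "call", {
      .log_stage(cfg, "call", "calling tetraploid genotypes")
      filter_loci(call_matrix(cfg$counts, alpha = cfg$alpha),
                  maf_min = cfg$maf_min,
                  min_scored_per_pop = cfg$min_scored_per_pop)
    })
    report$calls <- cs
    .log_stage(cfg, "call", paste(length(cs$retained), "loci retained"))
    report$diversity <- .stage(cfg, "popgen", gene_diversity(cs))
    excl <- .stage(cfg, "popgen",
                   if (is.null(cfg$qvalues)) character()
                   else exclude_outlier_loci(cs, cfg$qvalues, cfg$q_max))
    report$fst <- .stage(cfg, "popgen", fst_weir_cockerham(cs, exclude = excl))
    fst_global <- report$fst$global
    pairwise_fst <- new_dist_matrix(report$fst$pairwise, kind = "FST")
    .log_stage(cfg, "popgen",
               sprintf("global FST = %.4f (%d outlier loci excluded)",
                       fst_global, length(excl)))
  } else {
    .log_stage(cfg, "call", "no read counts given; molecular stages skipped")
  }

  # --- distances and Mantel tests ------------------------------------------
  mant <- list()
  if (!is.null(cfg$climate) && !is.null(pairwise_fst)) {
    clim_d <- .stage(cfg, "mantel", climatic_distances(cfg$climate))
    geo_d <- .stage(cfg, "mantel", geographic_distances(cfg$climate))
    ord <- match(rownames(pairwise_fst$mat), clim_d$labels)
    clim_d <- new_dist_matrix(clim_d$mat[ord, ord], kind = "climatic")
    geo_d <- new_dist_matrix(geo_d$mat[ord, ord], kind = "geographic")
    mant$fst_geography <- mantel(pairwise_fst, geo_d, nperm = cfg$nperm,
                                 seed = .stage_seed(cfg, 21L))
    mant$fst_climate <- partial_mantel(pairwise_fst, clim_d, geo_d,
                                       nperm = cfg$nperm,
                                       seed = .stage_seed(cfg, 22L))
    report$distances <- list(climate = clim_d, geography = geo_d)
  } else {
    mant$status <- "skipped (climate table or pairwise FST unavailable)"
    .log_stage(cfg, "mantel", mant$status)
  }
  report$mantel <- mant

  # --- quantitative genetics per trait -------------------------------------
  qg_rows <- list(); neut <- list(); qst_pair <- list()
  all_traits <- c(cfg$traits,
                  if (!is.null(cfg$binary_trait)) cfg$binary_trait)
  for (ti in seq_along(all_traits)) {
    tr <- all_traits[ti]
    fam <- if (!is.null(cfg$binary_trait) && tr == cfg$binary_trait)
      "binary" else "gaussian"
    spec <- halfsib_spec(tr, family = fam, fixed = "treatment",
                         random = c("population", "family", "block"),
                         chains = cfg$mcmc$chains, iter = cfg$mcmc$iter,
                         burnin = cfg$mcmc$burnin, thin = cfg$mcmc$thin,
                         seed = .stage_seed(cfg, 30L + ti))
    .log_stage(cfg, "quantgen", paste("fitting", tr, "(", fam, ")"))
    vc <- .stage(cfg, "quantgen", fit_halfsib(ph, spec))
    h2 <- heritability(vc); ev <- evolvability(vc); q <- qst(vc)
    qg_rows[[tr]] <- data.frame(
      trait = tr, family = fam,
      h2_mean = h2$mean, h2_lower = h2$lower, h2_upper = h2$upper,
      e_mean = ev$mean, qst_mean = q$mean, qst_lower = q$lower,
      qst_upper = q$upper, converged = vc$converged,
      stringsAsFactors = FALSE)
    if (!is.na(fst_global)) {
      qstn <- simulate_qstn(vc, fst = fst_global, npop = length(pops),
                            n_sim = cfg$n_sim,
                            seed = .stage_seed(cfg, 50L + ti))
      nd <- min(length(q$draws), cfg$n_sim)
      neut[[tr]] <- test_divergence(q$draws[seq_len(nd)], qstn[seq_len(nd)],
                                    seed = .stage_seed(cfg, 70L + ti))
    }
  }
  report$quantgen <- do.call(rbind, qg_rows)
  report$neutrality <- neut

  # --- per-population heritability for latitudinal patterns ----------------
  .log_stage(cfg, "quantgen", "per-population heritability")
  h2_pop <- vapply(pops, function(pp) {
    sub <- ph[ph$population == pp, , drop = FALSE]
    spec <- halfsib_spec(cfg$traits[1L], family = "gaussian",
                         fixed = "treatment",
                         random = c("family", "block"),
                         chains = cfg$mcmc$chains, iter = cfg$mcmc$iter,
                         burnin = cfg$mcmc$burnin, thin = cfg$mcmc$thin,
                         seed = .stage_seed(cfg, 90L) + match(pp, pops))
    heritability(fit_halfsib(sub, spec))$mean
  }, numeric(1L))

  # --- plasticity-fitness and latitudinal correlations ---------------------
  plast <- list()
  for (tr in cfg$traits) {
    plast[[tr]] <- tryCatch(
      adaptive_plasticity_test(ph, trait = tr, fitness_trait = cfg$traits[1L]),
      error = function(e) NULL)
  }
  report$plasticity <- plast

  latc <- list()
  latc[[paste0("h2_", cfg$traits[1L])]] <-
    latitudinal_correlations(h2_pop, lat)
  if (!is.null(report$diversity)) {
    he <- report$diversity$per_population
    latc$He <- latitudinal_correlations(he$He[match(pops, he$population)], lat)
    latc$popspec_fst <-
      latitudinal_correlations(report$fst$popspec[pops], lat)
  }
  report$latitudinal <- latc
  report$h2_per_population <- data.frame(population = pops, latitude = lat,
                                         h2 = h2_pop, row.names = NULL)

  # --- outputs -------------------------------------------------------------
  if (!is.null(cfg$outdir)) .write_report(report, cfg)
  class(report) <- "run_report"
  report
}

.write_report <- function(report, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  if (!is.null(report$quantgen))
    write_results(report$quantgen, out("quantgen.tsv"))
  if (!is.null(report$diversity))
    write_results(report$diversity$per_population, out("diversity.tsv"))
  if (!is.null(report$fst))
    write_results(report$fst, out("fst.tsv"))
  if (!is.null(report$calls))
    write_results(calls_as_table(report$calls), out("calls.tsv"))
  write_results(report$h2_per_population, out("h2_per_population.tsv"))
  if (length(report$neutrality)) {
    nt <- do.call(rbind, lapply(names(report$neutrality), function(tr) {
      x <- report$neutrality[[tr]]
      data.frame(trait = tr, mean_diff = x$mean_diff, lower = x$lower,
                 upper = x$upper, verdict = x$verdict,
                 stringsAsFactors = FALSE)
    }))
    write_results(nt, out("neutrality.tsv"))
  }
  pl <- Filter(Negate(is.null), report$plasticity)
  if (length(pl)) {
    pt <- do.call(rbind, lapply(pl, function(x)
      data.frame(trait = x$trait, fitness = x$fitness_trait, slope = x$slope,
                 t = x$t, p = x$p, n = x$n, stringsAsFactors = FALSE)))
    write_results(pt, out("plasticity.tsv"))
  }
  con <- file(out("summary.txt"), "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("tetraqst run summary (master seed %d)", cfg$seed)
  if (!is.null(report$fst))
    w("global FST = %.4f over %d loci", report$fst$global,
      report$fst$n_loci_used)
  for (i in seq_len(nrow(report$quantgen))) {
    r <- report$quantgen[i, ]
    w("%s: h2 = %.3f (%.3f-%.3f), e = %.4f, QST = %.3f (%.3f-%.3f)%s",
      r$trait, r$h2_mean, r$h2_lower, r$h2_upper, r$e_mean, r$qst_mean,
      r$qst_lower, r$qst_upper,
      if (r$converged) "" else " [convergence warning]")
    nt <- report$neutrality[[r$trait]]
    if (!is.null(nt))
      w("  QST - QSTn = %.3f (%.3f to %.3f): %s", nt$mean_diff, nt$lower,
        nt$upper, nt$verdict)
  }
  for (nm in names(report$latitudinal)) {
    lc <- report$latitudinal[[nm]]
    w("latitude vs %s: r = %.3f, p = %.4f", nm, lc$r, lc$p)
  }
  invisible(NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat("tetraqst run_report:",
      if (!is.null(x$fst)) sprintf("global FST %.4f;", x$fst$global) else "",
      nrow(x$quantgen), "traits analysed\n")
  invisible(x)
}
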