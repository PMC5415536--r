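#' Family-level plasticity index across winter treatments
#'
#' For each seed family, trait means are taken per treatment (ignoring
#' missing plants), the overall family mean is the unweighted mean of the
#' treatment means (balanced weighting, robust to unequal survival), and the
#' plasticity index is the coefficient of variation of the treatment means:
#' CV = sd(treatment means) / mean(treatment means), with the sample (n - 1)
#' standard deviation. Families observed in fewer than two treatments, or
#' with zero overall mean, are dropped with a warning.
#'
#' @param ph A `phenotype_table`.
#' @param trait Trait column name.
#' @return Data frame (class `family_plasticity`) with columns `family`,
#'   `population`, one `mean_<treatment>` column per treatment,
#'   `overall_mean`, `cv`.
#' @export
family_plasticity <- function(ph, trait) {
  y <- ph[[trait]]
  if (is.null(y)) stop("trait not found: ", trait)
  ok <- !is.na(y)
  agg <- stats::aggregate(y[ok],
                          by = list(family = ph$family[ok],
                                    population = ph$population[ok],
                                    treatment = ph$treatment[ok]),
                          FUN = mean)
  treatments <- sort(unique(agg$treatment))
  fams <- unique(agg[, c("family", "population")])
  rows <- lapply(seq_len(nrow(fams)), function(i) {
    sub <- agg[agg$family == fams$family[i], , drop = FALSE]
    tm <- stats::setNames(sub$x, sub$treatment)[treatments]
    names(tm) <- treatments
    mt <- tm[!is.na(tm)]
    if (length(mt) < 2L) {
      warning("family ", fams$family[i],
              " observed in fewer than 2 treatments; dropped")
      return(NULL)
    }
    om <- mean(mt)
    if (om == 0) {
      warning("family ", fams$family[i], " has zero overall mean; CV undefined, dropped")
      return(NULL)
    }
    out <- data.frame(family = fams$family[i], population = fams$population[i],
                      stringsAsFactors = FALSE)
    for (tr in treatments) out[[paste0("mean_", tr)]] <- unname(tm[tr])
    out$overall_mean <- om
    out$cv <- stats::sd(mt) / om
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("family_plasticity", "data.frame")
  res
}

#' Test for adaptive or maladaptive plasticity
#'
#' Ordinary least squares of family-level fitness on the plasticity index
#' of a trait, with the family trait mean as covariate to separate the
#' fitness effect of plasticity from that of the trait value itself:
#' fitness ~ intercept + CV + trait_mean. A significantly positive CV slope
#' suggests adaptive plasticity, a negative one maladaptive plasticity.
#' For the binary fitness proxy (flowering) the family mean probability is
#' used as the fitness value.
#'
#' @param ph A `phenotype_table`.
#' @param trait Trait whose plasticity is tested.
#' @param fitness_trait Fitness proxy (e.g. `"biomass"` or `"flowering"`).
#' @return An `adaptive_plasticity` list: `fitness_trait`, `trait`, `slope`
#'   (CV coefficient), `t`, `p` (two-sided), `mean_slope` (covariate
#'   coefficient), `n` families, `df` = n - 3.
#' @export
adaptive_plasticity_test <- function(ph, trait, fitness_trait) {
  fp <- family_plasticity(ph, trait)
  fit_means <- family_plasticity(ph, fitness_trait)
  dat <- merge(fp[, c("family", "cv", "overall_mean")],
               fit_means[, c("family", "overall_mean")],
               by = "family", suffixes = c("_trait", "_fitness"))
  names(dat)[names(dat) == "overall_mean_trait"] <- "trait_mean"
  names(dat)[names(dat) == "overall_mean_fitness"] <- "fitness"
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 4L) stop("need at least 4 families with complete records")
  if (abs(stats::cor(dat$cv, dat$trait_mean)) > 1 - 1e-10)
    stop("plasticity index and trait mean are collinear")
  fit <- stats::lm(fitness ~ cv + trait_mean, data = dat)
  sm <- summary(fit)$coefficients
  structure(list(fitness_trait = fitness_trait, trait = trait,
                 slope = sm["cv", "Estimate"], t = sm["cv", "t value"],
                 p = sm["cv", "Pr(>|t|)"],
                 mean_slope = sm["trait_mean", "Estimate"],
                 n = nrow(dat), df = nrow(dat) - 3L),
            class = "adaptive_plasticity")
}

#' @export
print.adaptive_plasticity <- function(x, ...) {
  cat(sprintf(
    "plasticity of %s vs fitness (%s): slope %.4f, t = %.3f, p = %.4f (n = %d)\n",
    x$trait, x$fitness_trait, x$slope, x$t, x$p, x$n))
  invisible(x)
}

#' Pearson correlation of population estimates with latitude
#'
#' @param estimates Numeric vector of per-population values (He, FST, h2, e).
#' @param latitudes Matching latitudes in degrees.
#' @return List with `r` and two-sided `p` (t reference, n - 2 df), `n`.
#' @export
latitudinal_correlations <- function(estimates, latitudes) {
  ok <- !is.na(estimates) & !is.na(latitudes)
  if (sum(ok) < 3L) stop("need at least 3 populations")
  if (stats::sd(estimates[ok]) == 0 || stats::sd(latitudes[ok]) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(estimates[ok], latitudes[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
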