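#' Configuration of the synthetic half-sib common-garden study
#'
#' Defaults reproduce the sampled study design: 8 populations along a
#' latitudinal gradient from 43.03 to 62.94 degrees N, 5 open-pollinated
#' (half-sib) seed families per population, 15 offspring per family (600
#' plants), 3 simulated mid-winter treatments (mild, frost, warmfrost) with
#' 4 blocks nested in each treatment, biallelic SNP loci with
#' Balding-Nichols drift-structured allele frequencies at a target FST of
#' 0.09, and negative-binomial sequencing depths (mean 30). Trait
#' architectures default to the fitted values of the source study's
#' mixed-effects analysis (random-effect standard deviations squared to
#' variances; treatment intercepts and latitude slopes as published); traits
#' whose best model carried no population term default to the drift-coupled
#' neutral among-population variance V_P = 2 theta (4 V_F) / (1 - theta).
#'
#' @param n_pop,n_fam_per_pop,n_off_per_fam Design sizes (8, 5, 15).
#' @param treatments Treatment labels.
#' @param n_blocks_per_treatment Blocks nested in each treatment (4).
#' @param latitudes Population latitudes, strictly increasing, degrees N.
#' @param n_loci Number of simulated SNP loci.
#' @param theta Target FST of the Balding-Nichols frequency model.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model
#'   (mean and size); `depth_dispersion = Inf` gives constant depth
#'   `depth_mean`.
#' @param traits Named list of gaussian trait architectures; each a list
#'   with `mean` (intercept per treatment or scalar), `lat_slope` (scalar or
#'   per treatment), `V_P` (or `NA` for drift-coupled), `V_F`, `V_block`,
#'   `V_err`, and optional `V_PxT`, `V_FxT`.
#' @param binary Architecture of the binary flowering trait: `intercept`,
#'   `lat_slope` (logit scale), `V_P`, `V_F`.
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_pop = 8L, n_fam_per_pop = 5L,
                             n_off_per_fam = 15L,
                             treatments = c("mild", "frost", "warmfrost"),
                             n_blocks_per_treatment = 4L,
                             latitudes = seq(43.03, 62.94, length.out = n_pop),
                             n_loci = 500L, theta = 0.09,
                             depth_mean = 30, depth_dispersion = 5,
                             traits = NULL, binary = NULL, seed = 1L) {
  if (is.unsorted(latitudes, strictly = TRUE))
    stop("latitudes must be strictly increasing")
  if (length(latitudes) != n_pop) stop("need one latitude per population")
  if (theta < 0 || theta >= 1) stop("theta must lie in [0, 1)")
  if (is.null(traits)) {
    traits <- list(
      biomass = list(
        mean = c(mild = 1.17, frost = 0.50, warmfrost = 0.79),
        lat_slope = c(mild = -0.009, frost = -0.002, warmfrost = -0.005),
        V_P = NA_real_,          # drift-coupled
        V_F = 0.07^2, V_block = 0.07^2, V_err = 0.19^2),
      initial_height = list(
        mean = c(mild = 6.63, frost = 6.18, warmfrost = 7.34),
        lat_slope = 0,
        V_P = NA_real_,
        V_F = 0.60^2, V_block = 0, V_err = 1.18^2),
      final_height = list(
        mean = c(mild = 19.90, frost = 15.10, warmfrost = 18.08),
        lat_slope = 0,
        V_P = 1.40^2, V_F = 0.40^2, V_block = 1.70^2, V_err = 3.35^2,
        V_PxT = 0.17^2))
  }
  if (is.null(binary)) {
    binary <- list(intercept = 6.08, lat_slope = -0.14, V_P = 1.24^2,
                   V_F = 0.1)
  }
  structure(list(n_pop = as.integer(n_pop),
                 n_fam_per_pop = as.integer(n_fam_per_pop),
                 n_off_per_fam = as.integer(n_off_per_fam),
                 treatments = treatments,
                 n_blocks_per_treatment = as.integer(n_blocks_per_treatment),
                 latitudes = latitudes, n_loci = as.integer(n_loci),
                 theta = theta, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 traits = traits, binary = binary, seed = as.integer(seed)),
            class = "synthetic_config")
}

# drift-coupled neutral among-population variance
.neutral_vp <- function(theta, v_f) 2 * theta * (4 * v_f) / (1 - theta)

.pop_ids <- function(cfg) sprintf("pop%02d", seq_len(cfg$n_pop))

#' Simulate genotyping-by-sequencing read counts with known truth
#'
#' Per locus an ancestral frequency p0 ~ Uniform(0.05, 0.95) is drawn and
#' population frequencies follow the Balding-Nichols model,
#' p_i ~ Beta(p0 (1 - theta)/theta, (1 - p0)(1 - theta)/theta), so that the
#' expected FST among populations equals theta (theta = 0 copies p0
#' directly). One offspring per seed family is genotyped. Tetraploid dosages
#' are Binomial(4, p_i); read depths are negative-binomial; reads supporting
#' allele A are Binomial(depth, dosage / 4).
#'
#' @param cfg A `synthetic_config`.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return List with `counts` (a `read_count_matrix`), and `truth` (list:
#'   `dosage` samples x loci matrix, `freq` pops x loci matrix, `p0`).
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  pops <- .pop_ids(cfg)
  # one genotyped individual per family
  sample_pop <- rep(pops, each = cfg$n_fam_per_pop)
  samples <- paste0(sample_pop, "_f", rep(seq_len(cfg$n_fam_per_pop), cfg$n_pop))
  ns <- length(samples); nl <- cfg$n_loci
  loci <- sprintf("L%04d", seq_len(nl))
  p0 <- stats::runif(nl, 0.05, 0.95)
  freq <- if (cfg$theta == 0) {
    matrix(p0, cfg$n_pop, nl, byrow = TRUE)
  } else {
    s <- (1 - cfg$theta) / cfg$theta
    matrix(stats::rbeta(cfg$n_pop * nl,
                        rep(p0 * s, each = cfg$n_pop),
                        rep((1 - p0) * s, each = cfg$n_pop)),
           cfg$n_pop, nl)
  }
  dimnames(freq) <- list(pops, loci)
  pf <- freq[match(sample_pop, pops), , drop = FALSE]
  dosage <- matrix(stats::rbinom(ns * nl, 4L, as.vector(pf)), ns, nl,
                   dimnames = list(samples, loci))
  depth <- if (is.finite(cfg$depth_dispersion)) {
    matrix(stats::rnbinom(ns * nl, mu = cfg$depth_mean,
                          size = cfg$depth_dispersion), ns, nl)
  } else {
    # infinite dispersion parameter = constant depth
    matrix(as.integer(round(cfg$depth_mean)), ns, nl)
  }
  k <- matrix(stats::rbinom(ns * nl, as.vector(depth), as.vector(dosage) / 4),
              ns, nl)
  long_sample <- rep(samples, times = nl)
  counts <- new_read_count_matrix(
    sample = long_sample,
    population = rep(sample_pop, times = nl),
    locus = rep(loci, each = ns),
    countA = as.vector(k), countB = as.vector(depth - k))
  list(counts = counts,
       truth = list(dosage = dosage, freq = freq, p0 = p0))
}

#' Simulate the phenotype table of the common-garden experiment
#'
#' Each plant's trait value is the sum of treatment intercept, latitude
#' effects, a population effect ~ N(0, V_P), a family effect ~ N(0, V_F)
#' (so V_A = 4 V_F holds exactly by the half-sib construction), a block
#' effect ~ N(0, V_block), optional interaction effects, and residual noise.
#' `growth_rate` is derived as `final_height - initial_height`. The binary
#' flowering trait is Bernoulli with a logit-linear predictor. Offspring of
#' each family are split evenly over treatments and assigned randomly to
#' blocks within treatment.
#'
#' @param cfg A `synthetic_config`.
#' @param seed Optional seed overriding `cfg$seed`.
#' @param drift_coupled_vp If `TRUE`, every gaussian trait's V_P is forced
#'   to the neutral drift expectation 2 theta (4 V_F)/(1 - theta)
#'   (type-I-error studies); if `FALSE` only traits configured with `V_P =
#'   NA` use it.
#' @param vp_inflation Multiplier applied to the (possibly drift-coupled)
#'   V_P of every gaussian trait (power studies).
#' @return List with `phenotypes` (a `phenotype_table`) and `truth` (per
#'   trait: the variance components used and the realized population/family
#'   effects).
#' @export
simulate_phenotypes <- function(cfg, seed = cfg$seed,
                                drift_coupled_vp = FALSE,
                                vp_inflation = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  pops <- .pop_ids(cfg)
  n_trt <- length(cfg$treatments)
  if (cfg$n_off_per_fam %% n_trt != 0L)
    stop("offspring per family must divide evenly over treatments")
  per_trt <- cfg$n_off_per_fam %/% n_trt
  df <- expand.grid(off = seq_len(per_trt),
                    treatment = cfg$treatments,
                    family = seq_len(cfg$n_fam_per_pop),
                    population = pops,
                    stringsAsFactors = FALSE)
  df$population <- as.character(df$population)
  df$family <- paste0(df$population, "_f", df$family)
  df$latitude <- cfg$latitudes[match(df$population, pops)]
  df$block <- paste0(df$treatment, "_b",
                     sample.int(cfg$n_blocks_per_treatment, nrow(df),
                                replace = TRUE))
  df$plant <- sprintf("pl%04d", seq_len(nrow(df)))
  lat_c <- df$latitude - mean(cfg$latitudes)
  fam_ids <- unique(df$family)
  blk_ids <- unique(df$block)
  truth <- list()
  sim_gaussian <- function(arch) {
    vp <- arch$V_P
    if (drift_coupled_vp || is.na(vp)) vp <- .neutral_vp(cfg$theta, arch$V_F)
    vp <- vp * vp_inflation
    mu <- if (length(arch$mean) > 1L) arch$mean[df$treatment] else arch$mean
    slope <- if (length(arch$lat_slope) > 1L) arch$lat_slope[df$treatment]
             else arch$lat_slope
    pop_eff <- stats::setNames(stats::rnorm(cfg$n_pop, 0, sqrt(vp)), pops)
    fam_eff <- stats::setNames(
      stats::rnorm(length(fam_ids), 0, sqrt(arch$V_F)), fam_ids)
    blk_eff <- stats::setNames(
      stats::rnorm(length(blk_ids), 0, sqrt(arch$V_block)), blk_ids)
    y <- as.numeric(mu) + as.numeric(slope) * lat_c +
      pop_eff[df$population] + fam_eff[df$family] + blk_eff[df$block]
    if (!is.null(arch$V_PxT) && arch$V_PxT > 0) {
      pxt <- interaction(df$population, df$treatment)
      eff <- stats::setNames(stats::rnorm(nlevels(pxt), 0, sqrt(arch$V_PxT)),
                             levels(pxt))
      y <- y + eff[as.character(pxt)]
    }
    if (!is.null(arch$V_FxT) && arch$V_FxT > 0) {
      fxt <- interaction(df$family, df$treatment)
      eff <- stats::setNames(stats::rnorm(nlevels(fxt), 0, sqrt(arch$V_FxT)),
                             levels(fxt))
      y <- y + eff[as.character(fxt)]
    }
    y <- y + stats::rnorm(nrow(df), 0, sqrt(arch$V_err))
    list(y = unname(y),
         components = list(V_P = vp, V_F = arch$V_F,
                           V_block = arch$V_block, V_err = arch$V_err,
                           pop_eff = pop_eff, fam_eff = fam_eff))
  }
  for (tr in names(cfg$traits)) {
    sim <- sim_gaussian(cfg$traits[[tr]])
    df[[tr]] <- sim$y
    truth[[tr]] <- sim$components
  }
  if (!"final_height" %in% names(df) || !"initial_height" %in% names(df))
    stop("trait architectures must include initial_height and final_height")
  df$growth_rate <- df$final_height - df$initial_height
  bb <- cfg$binary
  pop_eff_b <- stats::setNames(stats::rnorm(cfg$n_pop, 0, sqrt(bb$V_P)), pops)
  fam_eff_b <- stats::setNames(stats::rnorm(length(fam_ids), 0, sqrt(bb$V_F)),
                               fam_ids)
  eta <- bb$intercept + bb$lat_slope * df$latitude +
    pop_eff_b[df$population] + fam_eff_b[df$family]
  df$flowering <- stats::rbinom(nrow(df), 1L, stats::plogis(unname(eta)))
  truth$flowering <- list(V_P = bb$V_P, V_F = bb$V_F,
                          pop_eff = pop_eff_b, fam_eff = fam_eff_b)
  cols <- c("plant", "population", "family", "treatment", "block", "latitude",
            names(cfg$traits), "growth_rate", "flowering")
  ph <- validate_phenotypes(df[, cols])
  list(phenotypes = ph, truth = truth)
}

#' Simulate a per-population climate table
#'
#' Nineteen bioclimatic variables generated as latitude-linear trends plus
#' independent noise (synthetic stand-in for a Worldclim extract), with
#' longitudes spread across the gradient.
#'
#' @param cfg A `synthetic_config`.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A `climate_table`.
#' @export
simulate_climate <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed + 101L)
  pops <- .pop_ids(cfg)
  lat <- cfg$latitudes
  slopes <- stats::runif(19L, -1, 1)
  base <- stats::runif(19L, -5, 25)
  m <- sapply(seq_len(19L), function(j)
    base[j] + slopes[j] * (lat - mean(lat)) + stats::rnorm(length(lat), 0, 1))
  colnames(m) <- paste0("bio", seq_len(19L))
  df <- data.frame(population = pops,
                   longitude = seq(5, 25, length.out = cfg$n_pop) +
                     stats::rnorm(cfg$n_pop, 0, 1),
                   latitude = lat, m, stringsAsFactors = FALSE)
  class(df) <- c("climate_table", "data.frame")
  df
}
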