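# Independent brute-force oracles, written deliberately apart from the
# package implementation: explicit loops, explicit probability formulas.

# Brute-force tetraploid genotype caller: enumerate the five dosage
# likelihoods directly from the binomial probability mass and run all four
# likelihood-ratio tests against the chi-square critical value.
oracle_call <- function(k, n, alpha = 0.05) {
  if (n < 2) return(NULL)
  ps <- c(0, 1, 2, 3, 4) / 4
  lik <- sapply(ps, function(p) choose(n, k) * p^k * (1 - p)^(n - k))
  ll <- log(lik)
  best <- which(ll == max(ll))[1L]           # ties: smaller p wins
  crit <- qchisq(1 - alpha, df = 1)
  S <- ps[best]
  for (i in seq_along(ps)) {
    if (i == best) next
    stat <- 2 * (ll[best] - ll[i])           # Inf if lik[i] == 0
    if (is.finite(stat) && stat <= crit) S <- c(S, ps[i])
  }
  minA <- round(4 * min(S))
  minB <- round(4 * (1 - max(S)))
  list(minA = minA, minB = minB, unknown = 4 - minA - minB,
       best_p = ps[best], complete = length(S) == 1L)
}

# Textbook Weir-Cockerham theta on allele copies: explicit per-locus loops
# over populations, then ratio of summed components across loci.
oracle_wc_fst <- function(copiesA, copiesB) {
  stopifnot(is.matrix(copiesA), all(dim(copiesA) == dim(copiesB)))
  num <- den <- 0
  for (l in seq_len(ncol(copiesA))) {
    n_i <- copiesA[, l] + copiesB[, l]
    keep <- n_i >= 2
    if (sum(keep) < 2) next
    n_i <- n_i[keep]
    p_i <- copiesA[keep, l] / n_i
    r <- length(n_i)
    N <- sum(n_i)
    pbar <- sum(n_i * p_i) / N
    MSP <- sum(n_i * (p_i - pbar)^2) / (r - 1)
    MSG <- sum(n_i * p_i * (1 - p_i)) / sum(n_i - 1)
    nc <- (N - sum(n_i^2) / N) / (r - 1)
    a <- (MSP - MSG) / nc
    num <- num + a
    den <- den + a + MSG
  }
  num / den
}

# Nei sample-size-corrected gene diversity from allele copies in one
# population at one locus.
oracle_he <- function(copiesA, copiesB) {
  nc <- copiesA + copiesB
  if (nc < 2) return(NA_real_)
  pA <- copiesA / nc
  nc / (nc - 1) * (1 - pA^2 - (1 - pA)^2)
}

# Build a call_set directly from dosage matrices of complete genotypes
# (rows samples, cols loci), bypassing read counts, for popgen oracles.
make_callset <- function(dosage, populations, retained = colnames(dosage)) {
  samples <- rownames(dosage)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(dosage)))
  loci <- colnames(dosage)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(dosage)))
  dimnames(dosage) <- list(samples, loci)
  minA <- dosage
  minB <- 4L - dosage
  minB[is.na(dosage)] <- NA_integer_
  structure(list(
    samples = samples,
    populations = stats::setNames(populations, samples),
    loci = loci, minA = minA, minB = minB,
    best_p = dosage / 4,
    complete = !is.na(dosage),
    n = matrix(40L, nrow(dosage), ncol(dosage), dimnames = dimnames(dosage)),
    k = 10L * dosage, alpha = 0.05,
    maf = rep(NA_real_, length(loci)),
    polymorphic = rep(TRUE, length(loci)),
    retained = retained), class = "call_set")
}

# Minimal var_components builder for arithmetic checks on fixed draws.
make_vc <- function(draws, link_variance = 0, m = 1) {
  draws <- as.matrix(draws)
  if ("V_F" %in% colnames(draws) && !"V_A" %in% colnames(draws))
    draws <- cbind(draws, V_A = 4 * draws[, "V_F"])
  structure(list(draws = draws, link_variance = link_variance, m = m,
                 rhat = NULL, converged = TRUE, n_obs = NA_integer_,
                 spec = list(trait = "toy", family =
                               if (link_variance > 0) "binary" else "gaussian")),
            class = "var_components")
}

# Shared small synthetic configuration with simple round-number trait
# architectures, used across test files.
toy_config <- function(seed = 1L, n_loci = 120L, theta = 0.09, ...) {
  synthetic_config(
    seed = seed, n_loci = n_loci, theta = theta,
    traits = list(
      biomass = list(mean = 10, lat_slope = 0, V_P = 1, V_F = 1,
                     V_block = 1, V_err = 6),
      initial_height = list(mean = 5, lat_slope = 0, V_P = 0.5, V_F = 0.5,
                            V_block = 0.5, V_err = 2),
      final_height = list(mean = 20, lat_slope = 0, V_P = 2, V_F = 1,
                          V_block = 1, V_err = 8)),
    ...)
}

# fast MCMC settings for tests
quick_spec <- function(trait = "biomass", ...) {
  halfsib_spec(trait, chains = 2L, iter = 1200L, burnin = 400L, thin = 2L, ...)
}

# random small distance matrix on given labels
rand_dist <- function(labels, seed, kind = "toy") {
  set.seed(seed)
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  new_dist_matrix(m + t(m), kind = kind)
}
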