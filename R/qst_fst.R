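#' Simulate the neutral QST distribution (Whitlock-Guillaume)
#'
#' For each of `n_sim` iterations, a V_A value is sampled from the posterior,
#' a neutral among-population variance is simulated as
#' VPn = 2 FST V_A / (1 - FST) * r / (npop - 1) with r drawn from a
#' chi-square distribution with npop - 1 degrees of freedom (the sampling
#' distribution of an among-population variance over npop demes), and the
#' neutral QST is QSTn = VPn / (2 V_A + VPn) using the same (index-paired)
#' posterior V_A draw as the observed within-population variance. With r
#' fixed at its expectation and a degenerate posterior, QSTn = FST exactly.
#'
#' @param vc A `var_components` with a family term (V_A draws).
#' @param fst Neutral molecular differentiation (0 <= fst < 1); negative
#'   values are clamped to 0 with a warning.
#' @param npop Number of populations behind the FST estimate.
#' @param n_sim Number of simulations (default 1000).
#' @param seed Integer seed.
#' @param va How the denominator V_A is taken: `"paired"` (same draw as the
#'   numerator, default) or `"mean"` (posterior mean).
#' @param r_override Optional fixed value(s) replacing the chi-square draw r
#'   (diagnostics; `r_override = npop - 1`, the expectation, reduces QSTn to
#'   FST exactly when the posterior is degenerate).
#' @return Numeric vector of `n_sim` QSTn values, with the sampled V_A
#'   values attached as attribute `"va"`.
#' @export
simulate_qstn <- function(vc, fst, npop, n_sim = 1000L, seed = 1L,
                          va = c("paired", "mean"), r_override = NULL) {
  va <- match.arg(va)
  stopifnot(inherits(vc, "var_components"), npop >= 2L, n_sim >= 1L)
  if (fst >= 1) stop("fst must be < 1")
  if (fst < 0) {
    warning("negative fst clamped to 0")
    fst <- 0
  }
  if (!"V_A" %in% colnames(vc$draws)) stop("posterior V_A draws unavailable")
  set.seed(seed)
  va_draws <- vc$draws[, "V_A"]
  idx <- sample.int(length(va_draws), n_sim, replace = TRUE)
  va_sim <- va_draws[idx]
  r <- if (is.null(r_override)) stats::rchisq(n_sim, df = npop - 1)
       else rep_len(r_override, n_sim)
  vpn <- 2 * fst * va_sim / (1 - fst) * r / (npop - 1)
  va_den <- if (va == "paired") va_sim else rep(mean(va_draws), n_sim)
  qstn <- vpn / (2 * va_den + vpn)
  qstn[vpn == 0 & va_den == 0] <- 0
  attr(qstn, "va") <- va_sim
  qstn
}

#' Test trait differentiation against the neutral expectation
#'
#' Computes the difference between QST posterior draws and simulated neutral
#' QSTn values (paired by index after an independent shuffle of both
#' vectors) and judges it by the 95% credible interval: entirely above zero
#' indicates divergent selection, entirely below homogenizing selection,
#' otherwise the trait is compatible with drift.
#'
#' @param qst_draws Posterior QST draws.
#' @param qstn_draws Simulated neutral QSTn values (same length).
#' @param seed Seed for the pairing shuffle.
#' @return A `neutrality_test`: list with `n_sim`, `diff` draws,
#'   `mean_diff`, `lower`, `upper`, `verdict` in
#'   `c("divergent", "homogenizing", "neutral")`.
#' @export
test_divergence <- function(qst_draws, qstn_draws, seed = 1L) {
  if (length(qst_draws) != length(qstn_draws))
    stop("qst_draws and qstn_draws must have equal length")
  set.seed(seed)
  d <- sample(as.numeric(qst_draws)) - sample(as.numeric(qstn_draws))
  ci <- unname(stats::quantile(d, c(0.025, 0.975)))
  verdict <- if (ci[1L] > 0) "divergent"
             else if (ci[2L] < 0) "homogenizing"
             else "neutral"
  structure(list(n_sim = length(d), diff = d, mean_diff = mean(d),
                 lower = ci[1L], upper = ci[2L], verdict = verdict),
            class = "neutrality_test")
}

#' @export
print.neutrality_test <- function(x, ...) {
  cat(sprintf("QST - QSTn = %.4f (95%% CI %.4f to %.4f) over %d sims: %s\n",
              x$mean_diff, x$lower, x$upper, x$n_sim, x$verdict))
  invisible(x)
}
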