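#' Specify a half-sib variance-component model
#'
#' Describes the mixed model fitted to one trait of the nested half-sib
#' common-garden design: open-pollinated seed families nested in
#' populations, blocks nested in winter treatments. Gaussian traits are
#' fitted by a conjugate Gibbs sampler (normal likelihood, inverse-gamma
#' variance priors); the binary flowering trait by adaptive
#' Metropolis-within-Gibbs on the logit scale with the residual variance
#' fixed at 1 (it is not identifiable in a Bernoulli-logit model).
#'
#' @param trait Trait column name in the phenotype table.
#' @param family `"gaussian"` or `"binary"` (Bernoulli with logit link).
#' @param fixed Fixed terms: `"intercept"` always implied; include
#'   `"treatment"` for across-treatment models.
#' @param random Random terms, a subset of `"population"`, `"family"`,
#'   `"block"`, `"family_treatment"`, `"population_treatment"`.
#' @param chains,iter,burnin,thin MCMC settings; defaults 2 chains of
#'   13000 iterations, 3000 burn-in, thinning 10 (2000 retained draws).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param prior Inverse-gamma prior, list with `shape` and `rate`
#'   (default 0.001 / 0.001, weakly informative).
#' @return A `halfsib_spec` list.
#' @export
halfsib_spec <- function(trait,
                         family = c("gaussian", "binary"),
                         fixed = "treatment",
                         random = c("population", "family", "block"),
                         chains = 2L, iter = 13000L, burnin = 3000L,
                         thin = 10L, seed = 1L,
                         prior = list(shape = 0.001, rate = 0.001)) {
  family <- match.arg(family)
  allowed <- c("population", "family", "block",
               "family_treatment", "population_treatment")
  if (!all(random %in% allowed))
    stop("unknown random term(s): ", paste(setdiff(random, allowed), collapse = ", "))
  stopifnot(iter > burnin, thin >= 1L, chains >= 1L)
  structure(list(trait = trait, family = family,
                 fixed = unique(c("intercept", fixed)),
                 random = random, chains = as.integer(chains),
                 iter = as.integer(iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior = prior),
            class = "halfsib_spec")
}

# build design pieces from a phenotype table for one trait
.build_design <- function(ph, spec) {
  y <- ph[[spec$trait]]
  if (is.null(y)) stop("trait not found: ", spec$trait)
  keep <- !is.na(y)
  ph <- ph[keep, , drop = FALSE]
  y <- y[keep]
  if (spec$family == "binary" && !all(y %in% c(0, 1)))
    stop("binary trait must be coded 0/1")
  # nesting checks
  fam_pops <- tapply(ph$population, ph$family, function(p) length(unique(p)))
  if (any(fam_pops > 1L)) stop("family ids are not nested in populations")
  blk_trt <- tapply(ph$treatment, ph$block, function(t) length(unique(t)))
  if (any(blk_trt > 1L)) stop("block ids are not nested in treatments")
  groups <- list()
  lv <- function(x) as.integer(factor(x))
  if ("population" %in% spec$random) groups$V_P <- lv(ph$population)
  if ("family" %in% spec$random) groups$V_F <- lv(ph$family)
  if ("block" %in% spec$random) groups$V_block <- lv(ph$block)
  if ("family_treatment" %in% spec$random)
    groups$V_FxT <- lv(paste(ph$family, ph$treatment))
  if ("population_treatment" %in% spec$random)
    groups$V_PxT <- lv(paste(ph$population, ph$treatment))
  for (nm in names(groups))
    if (max(groups[[nm]]) < 2L)
      stop("random term ", nm, " has fewer than 2 levels")
  X <- if ("treatment" %in% spec$fixed && length(unique(ph$treatment)) > 1L) {
    stats::model.matrix(~ treatment, data = ph)
  } else {
    matrix(1, nrow(ph), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  list(y = y, X = X, groups = groups, n = length(y))
}

# per-level sums aligned with integer level indices 1..J (rowsum() orders
# groups lexicographically, which misaligns levels >= 10)
.group_sums <- function(x, g, J) {
  tmp <- rowsum(x, g)
  s <- numeric(J)
  s[as.integer(rownames(tmp))] <- tmp[, 1L]
  s
}

# one chain of the conjugate Gibbs sampler for the gaussian model
.gibbs_gaussian <- function(y, X, groups, spec, chain_seed) {
  set.seed(chain_seed)
  n <- length(y); p <- ncol(X)
  a0 <- spec$prior$shape; b0 <- spec$prior$rate
  fac <- names(groups)
  J <- vapply(groups, max, integer(1L))
  nj <- lapply(groups, tabulate)
  XtX <- crossprod(X)
  XtXinv <- chol2inv(chol(XtX))
  beta <- drop(XtXinv %*% crossprod(X, y))
  u <- lapply(J, function(j) numeric(j))
  vy <- stats::var(y); if (vy == 0) vy <- 1e-6
  sig2 <- stats::setNames(rep(vy / (length(fac) + 1), length(fac)), fac)
  sig2e <- vy / 2
  tot_u <- numeric(n)
  keep <- seq.int(spec$burnin + 1L, spec$iter)
  keep <- keep[(keep - spec$burnin) %% spec$thin == 0L]
  out <- matrix(NA_real_, length(keep), length(fac) + 1L,
                dimnames = list(NULL, c(fac, "V_err")))
  row <- 0L
  Ru <- chol(XtXinv)
  for (it in seq_len(spec$iter)) {
    # fixed effects | rest (flat prior)
    r <- y - tot_u
    bhat <- drop(XtXinv %*% crossprod(X, r))
    beta <- bhat + sqrt(sig2e) * drop(t(Ru) %*% stats::rnorm(p))
    xb <- drop(X %*% beta)
    # each random-effect vector | rest
    for (f in fac) {
      g <- groups[[f]]
      tot_u <- tot_u - u[[f]][g]
      rf <- y - xb - tot_u
      s <- .group_sums(rf, g, J[f])
      prec <- nj[[f]] / sig2e + 1 / sig2[f]
      u[[f]] <- stats::rnorm(J[f], (s / sig2e) / prec, sqrt(1 / prec))
      tot_u <- tot_u + u[[f]][g]
      sig2[f] <- 1 / stats::rgamma(1L, a0 + J[f] / 2,
                                   b0 + sum(u[[f]]^2) / 2)
    }
    resid <- y - xb - tot_u
    sig2e <- 1 / stats::rgamma(1L, a0 + n / 2, b0 + sum(resid^2) / 2)
    if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0L) {
      row <- row + 1L
      out[row, ] <- c(sig2, sig2e)
    }
  }
  out
}

# bernoulli-logit log likelihood contributions
.ll_logit <- function(y, eta) y * eta - log1p(exp(eta))

# one chain of adaptive Metropolis-within-Gibbs for the binary-logit model.
# Residual (overdispersion) variance is fixed at 1 and reported as V_err = 1.
.mh_binary <- function(y, X, groups, spec, chain_seed) {
  set.seed(chain_seed)
  n <- length(y); p <- ncol(X)
  a0 <- spec$prior$shape; b0 <- spec$prior$rate
  fac <- names(groups)
  J <- vapply(groups, max, integer(1L))
  beta <- numeric(p)
  beta[1L] <- stats::qlogis(min(max(mean(y), 0.02), 0.98))
  u <- lapply(J, function(j) numeric(j))
  sig2 <- stats::setNames(rep(0.5, length(fac)), fac)
  eta <- drop(X %*% beta)
  step_b <- rep(0.3, p)
  step_u <- stats::setNames(rep(0.5, length(fac)), fac)
  acc_b <- numeric(p); acc_u <- stats::setNames(numeric(length(fac)), fac)
  keep <- seq.int(spec$burnin + 1L, spec$iter)
  keep <- keep[(keep - spec$burnin) %% spec$thin == 0L]
  out <- matrix(NA_real_, length(keep), length(fac) + 1L,
                dimnames = list(NULL, c(fac, "V_err")))
  row <- 0L
  for (it in seq_len(spec$iter)) {
    # fixed effects: scalar random-walk updates
    for (j in seq_len(p)) {
      d <- stats::rnorm(1L, 0, step_b[j])
      eta_new <- eta + X[, j] * d
      dll <- sum(.ll_logit(y, eta_new)) - sum(.ll_logit(y, eta))
      if (log(stats::runif(1L)) < dll) {
        beta[j] <- beta[j] + d; eta <- eta_new; acc_b[j] <- acc_b[j] + 1
      }
    }
    # random effects: all levels of a factor proposed at once
    for (f in fac) {
      g <- groups[[f]]
      d <- stats::rnorm(J[f], 0, step_u[f])
      eta_new <- eta + d[g]
      dll <- .group_sums(.ll_logit(y, eta_new) - .ll_logit(y, eta), g, J[f])
      unew <- u[[f]] + d
      dprior <- (u[[f]]^2 - unew^2) / (2 * sig2[f])
      accept <- log(stats::runif(J[f])) < dll + dprior
      if (any(accept)) {
        dacc <- ifelse(accept, d, 0)
        u[[f]] <- u[[f]] + dacc
        eta <- eta + dacc[g]
      }
      acc_u[f] <- acc_u[f] + mean(accept)
      sig2[f] <- 1 / stats::rgamma(1L, a0 + J[f] / 2, b0 + sum(u[[f]]^2) / 2)
    }
    # adapt proposal scales toward workable acceptance during burn-in
    if (it <= spec$burnin && it %% 50L == 0L) {
      step_b <- step_b * exp((acc_b / 50 - 0.44) * 0.5)
      step_u <- step_u * exp((acc_u / 50 - 0.3) * 0.5)
      acc_b[] <- 0; acc_u[] <- 0
    }
    if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0L) {
      row <- row + 1L
      out[row, ] <- c(sig2, 1)
    }
  }
  out
}

# split-Rhat over a draws-by-chain array (list of equal matrices)
.split_rhat <- function(chains) {
  halves <- list()
  for (m in chains) {
    h <- floor(nrow(m) / 2)
    if (h < 2L) return(stats::setNames(rep(NA_real_, ncol(chains[[1L]])),
                                       colnames(chains[[1L]])))
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE]),
                list(m[seq.int(h + 1L, 2 * h), , drop = FALSE]))
  }
  vapply(colnames(chains[[1L]]), function(cn) {
    xs <- lapply(halves, function(m) m[, cn])
    mns <- vapply(xs, mean, numeric(1L))
    vrs <- vapply(xs, stats::var, numeric(1L))
    nn <- length(xs[[1L]])
    W <- mean(vrs); B <- nn * stats::var(mns)
    if (W == 0) return(1)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }, numeric(1L))
}

#' Fit the half-sib variance-component model by MCMC
#'
#' Draws from the posterior of every random-term variance (and the residual
#' variance for gaussian traits) under the model described by the spec.
#' Gaussian traits use a conjugate Gibbs sampler; binary traits an adaptive
#' Metropolis-within-Gibbs sampler on the logit scale with residual variance
#' fixed at 1. The additive genetic variance is derived per draw from the
#' among-family variance as V_A = 4 V_F (half-sib design). A split-Rhat
#' convergence diagnostic is computed per component; values at or above 1.1
#' raise a warning and set `converged = FALSE`.
#'
#' @param ph A `phenotype_table` (or data frame with the same columns).
#' @param spec A `halfsib_spec`.
#' @return A `var_components`: list with `draws` (matrix, columns the fitted
#'   variance components incl. `V_err` and derived `V_A`), `link_variance`
#'   (0 for gaussian, pi^2/3 for binary-logit), `m` (observed trait mean),
#'   `rhat`, `converged`, `n_obs`, and the `spec`.
#' @export
fit_halfsib <- function(ph, spec) {
  stopifnot(inherits(spec, "halfsib_spec"))
  dsn <- .build_design(ph, spec)
  sampler <- if (spec$family == "gaussian") .gibbs_gaussian else .mh_binary
  chains <- lapply(seq_len(spec$chains), function(c)
    sampler(dsn$y, dsn$X, dsn$groups, spec, chain_seed = spec$seed + c))
  rhat <- if (spec$chains >= 2L) .split_rhat(chains)
          else stats::setNames(rep(NA_real_, ncol(chains[[1L]])),
                               colnames(chains[[1L]]))
  draws <- do.call(rbind, chains)
  if ("V_F" %in% colnames(draws))
    draws <- cbind(draws, V_A = 4 * draws[, "V_F"])
  converged <- !any(rhat >= 1.1, na.rm = TRUE)
  if (!converged)
    warning("split-Rhat >= 1.1 for: ",
            paste(names(rhat)[!is.na(rhat) & rhat >= 1.1], collapse = ", "))
  structure(list(draws = draws,
                 link_variance = if (spec$family == "binary") pi^2 / 3 else 0,
                 m = mean(dsn$y), rhat = rhat, converged = converged,
                 n_obs = dsn$n, spec = spec),
            class = "var_components")
}

#' @export
print.var_components <- function(x, ...) {
  cat("var_components for trait '", x$spec$trait, "' (", x$spec$family,
      "), ", nrow(x$draws), " draws\n", sep = "")
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

.summarize_draws <- function(draws, quantity, extra = list()) {
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  structure(c(list(quantity = quantity, mean = mean(draws),
                   sd = stats::sd(draws), lower = ci[1L], upper = ci[2L],
                   draws = draws), extra),
            class = "quantgen_summary")
}

#' @export
print.quantgen_summary <- function(x, ...) {
  cat(sprintf("%s = %.4f (sd %.4f, 95%% CI %.4f-%.4f)\n",
              x$quantity, x$mean, x$sd, x$lower, x$upper))
  invisible(x)
}

#' Narrow-sense heritability from posterior variance components
#'
#' Per posterior draw, h^2 = V_A / (V_A + V_R) with V_A = 4 V_F and
#' V_R the sum of the residual variance, the block variance, the
#' family-by-treatment interaction variance when the model includes it
#' (across-treatment fits), and for binary traits the logit link variance
#' pi^2/3 on top of the residual fixed at 1.
#'
#' @param vc A `var_components` from [fit_halfsib()].
#' @return A `quantgen_summary` with posterior mean, sd and 95% credible
#'   interval of h^2 (draws attached).
#' @export
heritability <- function(vc) {
  stopifnot(inherits(vc, "var_components"))
  d <- vc$draws
  if (!"V_A" %in% colnames(d)) stop("model has no family term: V_A unavailable")
  vr <- d[, "V_err"] + vc$link_variance
  if ("V_block" %in% colnames(d)) vr <- vr + d[, "V_block"]
  if ("V_FxT" %in% colnames(d)) vr <- vr + d[, "V_FxT"]
  h2 <- d[, "V_A"] / (d[, "V_A"] + vr)
  .summarize_draws(h2, "h2")
}

#' Evolvability (mean-scaled additive genetic variance)
#'
#' Per draw, e = V_A / m^2 = 4 V_F / m^2, with m the observed trait mean.
#' Unitless; invariant to a pure rescaling of the trait.
#'
#' @param vc A `var_components`.
#' @return A `quantgen_summary` for e.
#' @export
evolvability <- function(vc) {
  stopifnot(inherits(vc, "var_components"))
  if (!"V_A" %in% colnames(vc$draws)) stop("model has no family term")
  if (vc$m == 0) stop("trait mean is zero: evolvability undefined")
  .summarize_draws(vc$draws[, "V_A"] / vc$m^2, "evolvability")
}

#' Quantitative genetic differentiation (QST)
#'
#' Per draw, QST = V_P / (2 V_A + V_P), the among-population share of total
#' genetic variance under the diploid-derived definition (used here for the
#' autotetraploid with the caveat that no exact tetraploid equivalent
#' exists). Credible intervals are taken directly from the posterior.
#'
#' @param vc A `var_components` whose model included the population term.
#' @return A `quantgen_summary` for QST.
#' @export
qst <- function(vc) {
  stopifnot(inherits(vc, "var_components"))
  d <- vc$draws
  if (!"V_P" %in% colnames(d)) stop("model has no population term: QST unavailable")
  if (!"V_A" %in% colnames(d)) stop("model has no family term: QST unavailable")
  q <- d[, "V_P"] / (2 * d[, "V_A"] + d[, "V_P"])
  q[d[, "V_P"] == 0 & d[, "V_A"] == 0] <- 0
  .summarize_draws(q, "QST")
}

#' Pairwise QST matrix
#'
#' Refits the half-sib model on every pair of populations and records the
#' posterior-mean QST; pairs in which either population has fewer than two
#' seed families yield a missing entry with a warning.
#'
#' @param ph A `phenotype_table`.
#' @param spec A `halfsib_spec` whose random terms include `population` and
#'   `family`.
#' @return A `dist_matrix` of kind `"QST"`.
#' @export
qst_pairwise <- function(ph, spec) {
  pops <- sort(unique(ph$population))
  np <- length(pops)
  if (np < 2L) stop("need at least two populations")
  m <- matrix(0, np, np, dimnames = list(pops, pops))
  for (i in seq_len(np - 1L)) for (j in seq.int(i + 1L, np)) {
    sub <- ph[ph$population %in% pops[c(i, j)], , drop = FALSE]
    nfam <- tapply(sub$family, sub$population, function(f) length(unique(f)))
    if (any(nfam < 2L)) {
      warning("pair ", pops[i], "-", pops[j],
              ": a population has fewer than 2 families; entry set NA")
      m[i, j] <- m[j, i] <- NA_real_
      next
    }
    sp <- spec
    sp$seed <- spec$seed + i * 1000L + j
    vc <- fit_halfsib(sub, sp)
    m[i, j] <- m[j, i] <- qst(vc)$mean
  }
  new_dist_matrix(m, kind = "QST")
}

#' QST of plasticity from interaction variance components
#'
#' Fits the model with treatment-by-population and treatment-by-family
#' interaction variances and computes, per draw,
#' QST_plast = V_PxT / (2 * 4 * V_FxT + V_PxT). When the interaction
#' variances carry little information the posterior of this ratio reflects
#' the prior and piles up near 0 and 1 (a dumbbell shape); the result then
#' carries `prior_sensitive = TRUE` (flagged when the central 95% interval
#' spans more than 0.9 of the unit range, when both tails hold over 15%
#' of the mass, or when the lower credible bound of V_PxT sits at the noise
#' floor of total variance, i.e. the data cannot tell the numerator from
#' zero).
#'
#' @param ph A `phenotype_table` with at least two treatments.
#' @param spec A `halfsib_spec`; its random terms are extended with the two
#'   interaction terms if absent.
#' @return A `quantgen_summary` with `prior_sensitive` flag and the fitted
#'   `var_components` attached.
#' @export
qst_plasticity <- function(ph, spec) {
  if (length(unique(ph$treatment)) < 2L)
    stop("plasticity QST needs at least two treatments")
  sp <- spec
  sp$random <- unique(c(spec$random, "population", "family", "block",
                        "family_treatment", "population_treatment"))
  vc <- fit_halfsib(ph, sp)
  d <- vc$draws
  q <- d[, "V_PxT"] / (8 * d[, "V_FxT"] + d[, "V_PxT"])
  q[d[, "V_PxT"] == 0 & d[, "V_FxT"] == 0] <- 0
  ci <- stats::quantile(q, c(0.025, 0.975))
  # prior sensitivity: untrustworthy when the posterior spreads over
  # essentially the whole unit interval or piles up at both ends, and
  # meaningless when the data cannot tell the numerator variance from zero
  # (its lower credible bound sits at the noise floor of total variance)
  tot <- rowSums(d[, intersect(c("V_P", "V_A", "V_block", "V_FxT", "V_PxT",
                                 "V_err"), colnames(d)), drop = FALSE])
  dumbbell <- (ci[2L] - ci[1L] > 0.9) ||
    (mean(q < 0.1) > 0.15 && mean(q > 0.9) > 0.15) ||
    stats::quantile(d[, "V_PxT"], 0.025) < 0.01 * stats::median(tot)
  .summarize_draws(q, "QST_plasticity",
                   extra = list(prior_sensitive = unname(dumbbell), vc = vc))
}
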