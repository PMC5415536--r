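#' Dosage frequencies possible in a tetraploid genotype
#'
#' The frequency of allele A in a tetraploid genotype can only be 0, 1/4,
#' 1/2, 3/4, or 1 (zero to four copies).
#' @export
DOSAGE_GRID <- c(0, 0.25, 0.5, 0.75, 1)

#' Binomial log-likelihood of an allele read count at a tetraploid dosage
#'
#' The number of reads k carrying allele A out of n total reads at a locus is
#' modelled as Binomial(n, p), p the within-genotype frequency of allele A.
#' Returns -Inf for observations that are impossible under p (k > 0 at p = 0,
#' k < n at p = 1), which makes those dosages always rejected by the
#' likelihood-ratio test whenever they are not themselves the maximum.
#'
#' @param k Reads supporting allele A (0 <= k <= n).
#' @param n Total reads at the locus.
#' @param p Dosage frequency; must be one of 0, 0.25, 0.5, 0.75, 1.
#' @return Log-likelihood in nats.
#' @export
binom_loglik <- function(k, n, p) {
  if (any(!p %in% DOSAGE_GRID))
    stop("p must be one of 0, 0.25, 0.5, 0.75, 1")
  if (any(k < 0) || any(k > n)) stop("require 0 <= k <= n")
  stats::dbinom(k, n, p, log = TRUE)
}

# vectorised core: for count vectors k, n, return per-cell call fields.
# Used by both call_genotype() and call_matrix() so single-cell and matrix
# paths cannot drift apart.
.call_cells <- function(k, n, alpha = 0.05, df = 1L) {
  stopifnot(length(k) == length(n))
  if (any(k > n)) stop("require k <= n")
  m <- length(k)
  crit <- stats::qchisq(1 - alpha, df = df)
  ll <- vapply(DOSAGE_GRID, function(p) stats::dbinom(k, n, p, log = TRUE),
               numeric(m))
  ll <- matrix(ll, nrow = m)
  # argmax with ties resolved toward the smaller p
  best <- max.col(ll, ties.method = "first")
  llbest <- ll[cbind(seq_len(m), best)]
  lrt <- 2 * (llbest - ll)            # >= 0; Inf where ll = -Inf
  nonrej <- lrt <= crit               # includes the best p itself (lrt = 0)
  # first/last non-rejected column give min(S) and max(S)
  pmin_s <- DOSAGE_GRID[max.col(nonrej, ties.method = "first")]
  pmax_s <- DOSAGE_GRID[max.col(nonrej, ties.method = "last")]
  callable <- n >= 2
  minA <- ifelse(callable, as.integer(round(4 * pmin_s)), NA_integer_)
  minB <- ifelse(callable, as.integer(round(4 * (1 - pmax_s))), NA_integer_)
  best_p <- ifelse(callable, DOSAGE_GRID[best], NA_real_)
  list(minA = minA, minB = minB,
       unknown = 4L - minA - minB,
       best_p = best_p,
       complete = callable & (minA + minB == 4L),
       callable = callable, n = n, k = k)
}

#' Call one tetraploid genotype from allele read counts
#'
#' Maximum-likelihood dosage call with likelihood-ratio-test confidence: the
#' best dosage frequency p maximises the binomial likelihood of k out of n
#' reads; every other dosage is tested against it with the statistic
#' 2(l_best - l_p) against the chi-square critical value at `alpha`.
#' Dosages not rejected form a set S; only allele copies supported by every
#' member of S are claimed: minA = 4 min(S) guaranteed copies of A,
#' minB = 4 (1 - max(S)) of B, the remainder unknown. A singleton S gives a
#' complete genotype (e.g. AAAA); otherwise the call is incomplete (e.g.
#' AB00). Fewer than two reads support no call at all.
#'
#' @param k Reads supporting allele A.
#' @param n Total reads (call requires n >= 2).
#' @param alpha Significance level of the LRT (default 0.05).
#' @param df Degrees of freedom of the chi-square reference (default 1).
#' @return A `tetra_genotype` list (`minA`, `minB`, `unknown`, `best_p`,
#'   `complete`, `n_reads`, `k_reads_A`) or `NULL` when n < 2.
#' @export
call_genotype <- function(k, n, alpha = 0.05, df = 1L) {
  stopifnot(length(k) == 1L, length(n) == 1L, n >= 0)
  if (k > n) stop("require k <= n")
  if (n < 2) return(NULL)
  cc <- .call_cells(k, n, alpha = alpha, df = df)
  structure(list(minA = cc$minA, minB = cc$minB, unknown = cc$unknown,
                 best_p = cc$best_p, complete = cc$complete,
                 n_reads = n, k_reads_A = k),
            class = "tetra_genotype")
}

#' @export
format.tetra_genotype <- function(x, ...) {
  paste0(strrep("A", x$minA), strrep("B", x$minB), strrep("0", x$unknown))
}

#' @export
print.tetra_genotype <- function(x, ...) {
  cat(sprintf("%s (best_p = %.2f, k = %d / n = %d, %s)\n", format(x),
              x$best_p, x$k_reads_A, x$n_reads,
              if (x$complete) "complete" else "incomplete"))
  invisible(x)
}

#' Call tetraploid genotypes for a whole read-count matrix
#'
#' Applies [call_genotype()] to every (sample, locus) cell and computes the
#' per-locus minor allele frequency from the known allele copies of the
#' resulting calls (incomplete genotypes contribute only their guaranteed
#' copies; unknown slots are never imputed). A locus is marked polymorphic
#' when both alleles are observed among known copies and the non-null calls
#' are not all identical; only polymorphic loci enter `retained`.
#'
#' @param rc A `read_count_matrix`.
#' @param alpha LRT significance level.
#' @param df Chi-square degrees of freedom for the LRT.
#' @return A `call_set`: matrices `minA`, `minB`, `best_p`, `complete`, `n`,
#'   `k` (samples x loci; NA where no call), per-locus `maf` and
#'   `polymorphic`, `retained` locus ids, plus the sample/population/locus
#'   bookkeeping of the input.
#' @export
call_matrix <- function(rc, alpha = 0.05, df = 1L) {
  stopifnot(inherits(rc, "read_count_matrix"))
  n <- rc$countsA + rc$countsB
  k <- rc$countsA
  cc <- .call_cells(as.vector(k), as.vector(n), alpha = alpha, df = df)
  dm <- dimnames(rc$countsA)
  shape <- function(v) matrix(v, nrow = length(rc$samples), dimnames = dm)
  minA <- shape(cc$minA); minB <- shape(cc$minB)
  cs <- structure(list(
    samples = rc$samples, populations = rc$populations, loci = rc$loci,
    minA = minA, minB = minB,
    best_p = shape(cc$best_p),
    complete = shape(cc$complete & cc$callable),
    n = shape(ifelse(cc$callable, cc$n, NA_integer_)),
    k = shape(ifelse(cc$callable, cc$k, NA_integer_)),
    alpha = alpha), class = "call_set")
  cs <- .update_locus_stats(cs)
  cs$retained <- cs$loci[cs$polymorphic]
  cs
}

.update_locus_stats <- function(cs) {
  copiesA <- colSums(cs$minA, na.rm = TRUE)
  copiesB <- colSums(cs$minB, na.rm = TRUE)
  tot <- copiesA + copiesB
  maf <- ifelse(tot > 0, pmin(copiesA, copiesB) / tot, NA_real_)
  # identical non-null calls => no variation among genotypes
  all_same <- vapply(seq_along(cs$loci), function(j) {
    a <- cs$minA[, j]; b <- cs$minB[, j]
    ok <- !is.na(a)
    if (!any(ok)) return(TRUE)
    length(unique(paste(a[ok], b[ok]))) == 1L
  }, logical(1L))
  cs$maf <- maf
  cs$polymorphic <- !is.na(maf) & copiesA > 0 & copiesB > 0 & !all_same
  cs
}

#' @export
print.call_set <- function(x, ...) {
  cat("call_set:", length(x$samples), "samples x", length(x$loci), "loci;",
      sum(!is.na(x$minA)), "calls (", sum(x$complete, na.rm = TRUE),
      "complete );", length(x$retained), "retained loci\n")
  invisible(x)
}

#' Apply locus retention filters to a call set
#'
#' Retains loci that are polymorphic, have minor allele frequency at least
#' `maf_min`, and are scored (non-null call) in at least `min_scored_per_pop`
#' samples per population. With `mode = "all"` (default, the stricter
#' reading) the per-population rule must hold in every population; with
#' `mode = "any"` in at least one.
#'
#' @param cs A `call_set`.
#' @param maf_min Minor-allele-frequency cutoff (default 0.01).
#' @param min_scored_per_pop Minimum non-null calls per population (default 2).
#' @param mode `"all"` or `"any"`; see above.
#' @return The call set with `retained` updated.
#' @export
filter_loci <- function(cs, maf_min = 0.01, min_scored_per_pop = 2L,
                        mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cs, "call_set"))
  scored <- !is.na(cs$minA)
  pop <- cs$populations[cs$samples]
  per_pop <- rowsum(scored + 0L, group = pop)   # pops x loci counts
  pop_ok <- if (mode == "all") {
    colSums(per_pop >= min_scored_per_pop) == nrow(per_pop)
  } else {
    colSums(per_pop >= min_scored_per_pop) >= 1L
  }
  keep <- cs$polymorphic & !is.na(cs$maf) & cs$maf >= maf_min & pop_ok
  cs$retained <- cs$loci[keep]
  cs
}

#' Export a call set as a long data frame
#'
#' One row per (sample, locus) with a non-null call: columns `sample`,
#' `population`, `locus`, `minA`, `minB`, `unknown`, `best_p`, `n`, `k`,
#' `complete`, `retained`.
#'
#' @param cs A `call_set`.
#' @return A `data.frame`.
#' @export
calls_as_table <- function(cs) {
  idx <- which(!is.na(cs$minA), arr.ind = TRUE)
  df <- data.frame(
    sample = cs$samples[idx[, 1L]],
    population = unname(cs$populations[cs$samples[idx[, 1L]]]),
    locus = cs$loci[idx[, 2L]],
    minA = cs$minA[idx], minB = cs$minB[idx],
    unknown = 4L - cs$minA[idx] - cs$minB[idx],
    best_p = cs$best_p[idx], n = cs$n[idx], k = cs$k[idx],
    complete = cs$complete[idx],
    retained = cs$loci[idx[, 2L]] %in% cs$retained,
    stringsAsFactors = FALSE)
  df[order(df$locus, df$sample), , drop = FALSE]
}
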