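#' Construct a labelled distance matrix
#'
#' @param m Square symmetric numeric matrix with zero diagonal; dimnames used
#'   as labels if present.
#' @param kind One of "geographic", "climatic", "FST", "QST", or free text.
#' @param labels Optional label vector overriding dimnames.
#' @return A `dist_matrix` (list with `labels`, `mat`, `kind`).
#' @export
new_dist_matrix <- function(m, kind = "unknown", labels = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8) stop("distance matrix must be symmetric")
  structure(list(labels = labels, mat = m, kind = kind), class = "dist_matrix")
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$mat

#' @export
as.dist.dist_matrix <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$mat, diag = diag, upper = upper)

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (", x$kind, "), ", length(x$labels), " labels\n", sep = "")
  print(round(x$mat, 4)); invisible(x)
}

# known allele copies per population at each locus: lists of pops x loci
# matrices (copies of A, copies of B) from the retained loci of a call set
.allele_copies <- function(cs, loci = cs$retained) {
  j <- match(loci, cs$loci)
  pop <- cs$populations[cs$samples]
  a <- rowsum(ifelse(is.na(cs$minA[, j, drop = FALSE]), 0L,
                     cs$minA[, j, drop = FALSE]), group = pop)
  b <- rowsum(ifelse(is.na(cs$minB[, j, drop = FALSE]), 0L,
                     cs$minB[, j, drop = FALSE]), group = pop)
  colnames(a) <- colnames(b) <- loci
  list(A = a, B = b)
}

#' Sample-size-corrected gene diversity per population
#'
#' Nei's unbiased gene diversity computed from the known allele copies of
#' called tetraploid genotypes: with nc known copies at a locus in a
#' population and allele frequencies p_i among them,
#' He = nc/(nc-1) * (1 - sum p_i^2). Loci with fewer than two known copies
#' in a population are skipped for that population; the population value is
#' the unweighted mean across its scorable retained loci.
#'
#' @param cs A `call_set` with retained loci.
#' @return A `diversity_result`: list with `per_population` (data frame
#'   `population`, `He`, `n_loci`) and `per_locus` (pops x loci matrix).
#' @export
gene_diversity <- function(cs) {
  stopifnot(inherits(cs, "call_set"))
  if (length(cs$retained) < 1L) stop("no retained loci")
  ac <- .allele_copies(cs)
  nc <- ac$A + ac$B
  pA <- ifelse(nc > 0, ac$A / nc, NA_real_)
  he <- ifelse(nc >= 2,
               nc / (nc - 1) * (1 - pA^2 - (1 - pA)^2),
               NA_real_)
  pop_he <- rowMeans(he, na.rm = TRUE)
  n_loci <- rowSums(!is.na(he))
  if (any(n_loci == 0L))
    warning("population(s) with no scorable locus: ",
            paste(rownames(he)[n_loci == 0L], collapse = ", "))
  structure(list(
    per_population = data.frame(population = rownames(he),
                                He = ifelse(n_loci > 0, pop_he, NA_real_),
                                n_loci = n_loci, row.names = NULL,
                                stringsAsFactors = FALSE),
    per_locus = he), class = "diversity_result")
}

# Weir-Cockerham variance components on allele copies (one locus, allele A).
# Copies nA, nB per population; returns c(a, b): among- and within-population
# mean squares arranged so that theta = sum(a) / sum(a + b) across loci.
.wc_components <- function(copiesA, copiesB) {
  n_i <- copiesA + copiesB
  use <- n_i >= 2
  if (sum(use) < 2L) return(c(NA_real_, NA_real_))
  n_i <- n_i[use]; p_i <- copiesA[use] / n_i
  r <- length(n_i)
  ntot <- sum(n_i)
  pbar <- sum(n_i * p_i) / ntot
  msp <- sum(n_i * (p_i - pbar)^2) / (r - 1)
  msg <- sum(n_i * p_i * (1 - p_i)) / sum(n_i - 1)
  n_c <- (ntot - sum(n_i^2) / ntot) / (r - 1)
  a <- (msp - msg) / n_c
  c(a, msg)
}

#' Weir-Cockerham FST from tetraploid call sets
#'
#' Moment estimator of FST treating known allele copies as the sampling
#' units (four per complete genotype, fewer for incomplete calls): per locus
#' the among-population (a) and within-population (b) variance components
#' are computed from allele counts, and the multi-locus estimate is the
#' ratio of sums, sum(a) / sum(a + b). Pairwise estimates apply the same
#' estimator restricted to each population pair. The population-specific
#' value reported is the mean of the pairwise estimates involving each
#' population (a documented substitute for a model-based population-specific
#' FST; not equivalent to it). Negative estimates are reported as computed.
#'
#' @param cs A `call_set` with retained loci.
#' @param exclude Locus ids to exclude (e.g. selection outliers).
#' @return A `diff_molecular`: `global`, `pairwise` matrix, `popspec` named
#'   vector, `excluded`, `n_loci_used`.
#' @export
fst_weir_cockerham <- function(cs, exclude = character()) {
  stopifnot(inherits(cs, "call_set"))
  loci <- setdiff(cs$retained, exclude)
  if (length(loci) < 1L) stop("no loci left after exclusion")
  ac <- .allele_copies(cs, loci)
  pops <- rownames(ac$A)
  if (length(pops) < 2L) stop("need at least two populations")
  comp <- vapply(seq_along(loci),
                 function(j) .wc_components(ac$A[, j], ac$B[, j]),
                 numeric(2L))
  ok <- !is.na(comp[1L, ])
  if (!any(ok) || sum(comp[1L, ok] + comp[2L, ok]) == 0)
    stop("FST undefined: no variance components estimable")
  global <- sum(comp[1L, ok]) / sum(comp[1L, ok] + comp[2L, ok])
  np <- length(pops)
  pw <- matrix(0, np, np, dimnames = list(pops, pops))
  for (i in seq_len(np - 1L)) for (j in seq.int(i + 1L, np)) {
    cj <- vapply(seq_along(loci), function(l)
      .wc_components(ac$A[c(i, j), l], ac$B[c(i, j), l]), numeric(2L))
    okj <- !is.na(cj[1L, ])
    pw[i, j] <- pw[j, i] <-
      if (any(okj)) sum(cj[1L, okj]) / sum(cj[1L, okj] + cj[2L, okj]) else NA_real_
  }
  popspec <- vapply(seq_len(np), function(i) mean(pw[i, -i], na.rm = TRUE),
                    numeric(1L))
  names(popspec) <- pops
  structure(list(global = global, pairwise = pw, popspec = popspec,
                 popspec_method = "mean pairwise FST (substitute, not model-based)",
                 excluded = exclude, n_loci_used = sum(ok)),
            class = "diff_molecular")
}

#' @export
print.diff_molecular <- function(x, ...) {
  cat(sprintf("Weir-Cockerham FST: global = %.4f over %d loci (%d excluded)\n",
              x$global, x$n_loci_used, length(x$excluded)))
  invisible(x)
}

#' Select selection-outlier loci to exclude from neutral FST
#'
#' Loci with a false-discovery q-value strictly below `q_max` are treated as
#' putatively under selection. Loci absent from the table are kept.
#'
#' @param cs A `call_set` (only retained loci are considered).
#' @param qvalues Data frame with columns `locus`, `qvalue`.
#' @param q_max Exclusion threshold (default 0.05, strict "lower than").
#' @return Character vector of locus ids to exclude.
#' @export
exclude_outlier_loci <- function(cs, qvalues, q_max = 0.05) {
  if (is.null(qvalues) || nrow(qvalues) == 0L) return(character())
  if (any(qvalues$qvalue < 0 | qvalues$qvalue > 1, na.rm = TRUE))
    stop("q-values must lie in [0, 1]")
  out <- qvalues$locus[!is.na(qvalues$qvalue) & qvalues$qvalue < q_max]
  intersect(cs$retained, out)
}

#' Euclidean climatic distances on standardized bioclimatic variables
#'
#' Each of the 19 bioclimatic variables is standardized to mean 0, sd 1
#' across populations (sample sd, n - 1) before pairwise Euclidean distances
#' are taken; zero-variance variables are dropped with a warning.
#'
#' @param ct A `climate_table` (see [read_climate()]).
#' @return A `dist_matrix` of kind `"climatic"`.
#' @export
climatic_distances <- function(ct) {
  bio <- grep("^bio", names(ct), value = TRUE)
  if (nrow(ct) < 2L) stop("need at least two populations")
  x <- as.matrix(ct[, bio, drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance climate variable(s): ",
            paste(bio[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0L)
    stop("no climate variable varies across populations")
  z <- scale(x)
  m <- as.matrix(stats::dist(z))
  dimnames(m) <- list(ct$population, ct$population)
  new_dist_matrix(m, kind = "climatic")
}

#' Great-circle distances between populations
#'
#' Haversine great-circle distance on a sphere of radius 6371 km.
#'
#' @param ct Data frame with `population`, `longitude`, `latitude` columns.
#' @return A `dist_matrix` of kind `"geographic"` in kilometres.
#' @export
geographic_distances <- function(ct) {
  if (any(ct$latitude < -90 | ct$latitude > 90))
    stop("latitude outside [-90, 90]")
  n <- nrow(ct)
  m <- matrix(0, n, n, dimnames = list(ct$population, ct$population))
  xy <- cbind(ct$longitude, ct$latitude)
  for (i in seq_len(n - 1L)) {
    d <- geosphere::distHaversine(xy[i, , drop = FALSE],
                                  xy[seq.int(i + 1L, n), , drop = FALSE],
                                  r = 6371)
    m[i, seq.int(i + 1L, n)] <- d
    m[seq.int(i + 1L, n), i] <- d
  }
  new_dist_matrix(m, kind = "geographic")
}

.check_mantel_input <- function(...) {
  ds <- list(...)
  labs <- ds[[1L]]$labels
  for (d in ds) {
    if (!identical(d$labels, labs)) stop("distance matrices must share labels and order")
    v <- d$mat[lower.tri(d$mat)]
    if (stats::sd(v) == 0) stop("constant distance matrix: correlation undefined")
  }
  invisible(TRUE)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of off-diagonal entries, with a one-sided permutation
#' p-value from `nperm` simultaneous row/column permutations of the second
#' matrix: p = (#\{r_perm >= r_obs\} + 1) / (nperm + 1).
#'
#' @param d1,d2 `dist_matrix` objects with identical labels and order.
#' @param nperm Number of permutations (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @return List with `r`, `p`, `nperm`.
#' @export
mantel <- function(d1, d2, nperm = 1000L, seed = 1L) {
  .check_mantel_input(d1, d2)
  stopifnot(nperm >= 1L)
  set.seed(seed)
  lt <- lower.tri(d1$mat)
  v1 <- d1$mat[lt]
  r_obs <- stats::cor(v1, d2$mat[lt])
  n <- nrow(d2$mat)
  r_perm <- vapply(seq_len(nperm), function(i) {
    o <- sample.int(n)
    stats::cor(v1, d2$mat[o, o][lt])
  }, numeric(1L))
  list(r = r_obs, p = (sum(r_perm >= r_obs) + 1) / (nperm + 1),
       nperm = nperm)
}

#' Partial Mantel test controlling for a third distance matrix
#'
#' Correlation between `d1` and `d2` after removing the linear effect of
#' `d3` from both (equivalently, the partial correlation of the triangle
#' entries); permutation p-value as in [mantel()].
#'
#' @inheritParams mantel
#' @param d3 Conditioning `dist_matrix`.
#' @return List with `r` (partial correlation), `p`, `nperm`.
#' @export
partial_mantel <- function(d1, d2, d3, nperm = 1000L, seed = 1L) {
  .check_mantel_input(d1, d2, d3)
  stopifnot(nperm >= 1L)
  set.seed(seed)
  lt <- lower.tri(d1$mat)
  v3 <- d3$mat[lt]
  res <- function(v) stats::residuals(stats::lm(v ~ v3))
  v1 <- d1$mat[lt]
  e1 <- res(v1)
  # residuals that are numerically zero (d fully explained by d3) carry no
  # signal: the partial correlation is zero by definition
  eps <- 1e-10 * (stats::sd(v1) + stats::sd(v3))
  pcor <- function(e2) {
    if (stats::sd(e1) <= eps || stats::sd(e2) <= eps) return(0)
    stats::cor(e1, e2)
  }
  r_obs <- pcor(res(d2$mat[lt]))
  n <- nrow(d2$mat)
  r_perm <- vapply(seq_len(nperm), function(i) {
    o <- sample.int(n)
    pcor(res(d2$mat[o, o][lt]))
  }, numeric(1L))
  list(r = r_obs, p = (sum(r_perm >= r_obs) + 1) / (nperm + 1),
       nperm = nperm)
}
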