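#' Read a per-sample, per-locus allele read-count table
#'
#' Reads biallelic read counts from genotyping-by-sequencing output into a
#' validated `read_count_matrix`. Two dialects are supported: the canonical
#' long tab-separated table (columns `sample`, `population`, `locus`,
#' `countA`, `countB`, one row per observed sample-locus cell) and a
#' HapMap-with-depth dialect in which rows are loci, the first column holds
#' locus ids, standard HapMap metadata columns are ignored, and every other
#' column is a sample whose cells contain `"countA|countB"`.
#'
#' Cells absent from a long file are stored as (0, 0) and flagged missing;
#' observed (0, 0) and missing cells are treated identically downstream
#' because neither supports a genotype call (fewer than two reads).
#'
#' @param path Path to a UTF-8, tab-separated file.
#' @param dialect `"tsv-long"` (default) or `"hapmap-depth"`.
#' @param populations Named character vector mapping sample id to population
#'   id; required for the HapMap dialect (which carries no population
#'   column), ignored for the long dialect.
#' @return A `read_count_matrix`: list with `samples`, `populations` (named
#'   character vector, sample to population), `loci`, integer matrices
#'   `countsA` and `countsB` (samples x loci), and a logical `missing`
#'   matrix marking cells absent from the input.
#' @export
read_read_counts <- function(path, dialect = c("tsv-long", "hapmap-depth"),
                             populations = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv-long") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    req <- c("sample", "population", "locus", "countA", "countB")
    if (!all(req %in% names(df)))
      stop("long read-count file must have columns: ", paste(req, collapse = ", "))
    new_read_count_matrix(df$sample, df$population, df$locus,
                          df$countA, df$countB)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            comment.char = "")
    hapmap_meta <- c("alleles", "chrom", "pos", "strand", "assembly#",
                     "center", "protLSID", "assayLSID", "panelLSID", "QCcode")
    loci <- as.character(df[[1L]])
    sample_cols <- setdiff(names(df)[-1L], hapmap_meta)
    if (length(sample_cols) == 0L) stop("no sample columns found in HapMap file")
    if (is.null(populations))
      stop("`populations` (named vector sample -> population) is required for the hapmap-depth dialect")
    parse_depth <- function(x) {
      parts <- strsplit(as.character(x), "|", fixed = TRUE)
      bad <- lengths(parts) != 2L
      if (any(bad)) stop("malformed depth cell (expected 'a|b'): ", x[bad][1L])
      m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2L, byrow = TRUE)
      if (anyNA(m)) stop("non-numeric depth in HapMap cell")
      m
    }
    nl <- length(loci); ns <- length(sample_cols)
    cA <- matrix(0L, ns, nl, dimnames = list(sample_cols, loci))
    cB <- cA
    for (j in seq_along(sample_cols)) {
      m <- parse_depth(df[[sample_cols[j]]])
      cA[j, ] <- as.integer(m[, 1L]); cB[j, ] <- as.integer(m[, 2L])
    }
    long <- data.frame(
      sample = rep(sample_cols, times = nl),
      locus = rep(loci, each = ns),
      countA = as.vector(cA), countB = as.vector(cB),
      stringsAsFactors = FALSE)
    pops <- populations[long$sample]
    if (anyNA(pops)) stop("samples without a population mapping: ",
                          paste(unique(long$sample[is.na(pops)]), collapse = ", "))
    new_read_count_matrix(long$sample, unname(pops), long$locus,
                          long$countA, long$countB)
  }
}

#' Construct a validated read-count matrix from long vectors
#'
#' @param sample,population,locus Character vectors, one entry per observed cell.
#' @param countA,countB Non-negative integer read counts per cell.
#' @return A `read_count_matrix`; see [read_read_counts()].
#' @export
new_read_count_matrix <- function(sample, population, locus, countA, countB) {
  sample <- as.character(sample); population <- as.character(population)
  locus <- as.character(locus)
  countA <- as.numeric(countA); countB <- as.numeric(countB)
  if (any(is.na(countA)) || any(is.na(countB)))
    stop("read counts must be numeric and non-missing")
  if (any(countA < 0) || any(countB < 0)) stop("negative read counts")
  if (any(countA != round(countA)) || any(countB != round(countB)))
    stop("read counts must be integers")
  key <- paste(sample, locus, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (sample, locus) rows: ", gsub("\r", " / ", d))
  }
  pop_per_sample <- tapply(population, sample, function(p) length(unique(p)))
  if (any(pop_per_sample > 1L))
    stop("sample mapped to more than one population: ",
         paste(names(pop_per_sample)[pop_per_sample > 1L], collapse = ", "))
  samples <- unique(sample); loci <- unique(locus)
  pops <- vapply(split(population, sample), `[`, character(1L), 1L)[samples]
  cA <- matrix(0L, length(samples), length(loci), dimnames = list(samples, loci))
  cB <- cA
  miss <- matrix(TRUE, length(samples), length(loci), dimnames = list(samples, loci))
  i <- match(sample, samples); j <- match(locus, loci)
  idx <- cbind(i, j)
  cA[idx] <- as.integer(countA); cB[idx] <- as.integer(countB)
  miss[idx] <- FALSE
  structure(list(samples = samples, populations = pops, loci = loci,
                 countsA = cA, countsB = cB, missing = miss),
            class = "read_count_matrix")
}

#' @export
print.read_count_matrix <- function(x, ...) {
  cat("read_count_matrix:", length(x$samples), "samples x", length(x$loci),
      "loci;", length(unique(x$populations)), "populations;",
      sum(x$missing), "missing cells\n")
  invisible(x)
}

#' Read a plant-level phenotype table
#'
#' Expects a tab-separated file with columns `plant`, `population`, `family`,
#' `treatment`, `block`, `latitude`, and trait columns (`biomass`,
#' `initial_height`, `final_height`, `growth_rate`, `flowering`). Missing
#' trait values are kept as `NA`. `growth_rate` is derived as
#' `final_height - initial_height` when absent from the file, and validated
#' against that identity when present. Nesting is enforced: a seed family id
#' may occur under only one population and a block id under only one
#' treatment.
#'
#' @param path Path to the phenotype TSV.
#' @return A `data.frame` of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("plant", "population", "family", "treatment", "block",
           "latitude", "initial_height", "final_height", "flowering")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("phenotype file lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"growth_rate" %in% names(df))
    df$growth_rate <- df$final_height - df$initial_height
  validate_phenotypes(df)
}

#' Validate a phenotype data frame and stamp the class
#'
#' @param df Data frame with the columns described in [read_phenotypes()].
#' @return The validated `phenotype_table`.
#' @export
validate_phenotypes <- function(df) {
  for (col in c("population", "family", "treatment", "block", "plant"))
    df[[col]] <- as.character(df[[col]])
  fl <- df$flowering[!is.na(df$flowering)]
  if (!all(fl %in% c(0, 1)))
    stop("flowering must be 0/1; found: ",
         paste(unique(fl[!fl %in% c(0, 1)]), collapse = ", "))
  fam_pops <- tapply(df$population, df$family, function(p) length(unique(p)))
  if (any(fam_pops > 1L))
    stop("family id used in more than one population: ",
         paste(names(fam_pops)[fam_pops > 1L], collapse = ", "))
  blk_trt <- tapply(df$treatment, df$block, function(t) length(unique(t)))
  if (any(blk_trt > 1L))
    stop("block id used in more than one treatment: ",
         paste(names(blk_trt)[blk_trt > 1L], collapse = ", "))
  ok <- !is.na(df$final_height) & !is.na(df$initial_height) & !is.na(df$growth_rate)
  # tolerance accommodates fixed-precision round trips through TSV
  if (any(abs(df$growth_rate[ok] - (df$final_height[ok] - df$initial_height[ok])) > 1e-6))
    stop("growth_rate must equal final_height - initial_height")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a per-population climate table
#'
#' One row per population with columns `population`, `longitude`, `latitude`
#' and 19 bioclimatic variables (columns starting with `bio`).
#'
#' @param path Path to the climate TSV.
#' @return A `data.frame` of class `climate_table`.
#' @export
read_climate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("population", "longitude", "latitude")
  if (!all(req %in% names(df)))
    stop("climate file needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$population)) stop("duplicate population rows in climate table")
  bio <- grep("^bio", names(df), value = TRUE)
  if (length(bio) != 19L)
    stop("expected 19 bioclimatic columns (bio1..bio19), found ", length(bio))
  class(df) <- c("climate_table", "data.frame")
  df
}

#' Read a per-locus q-value table
#'
#' @param path TSV with columns `locus` and `qvalue`.
#' @return Data frame with `locus` and `qvalue`.
#' @export
read_qvalues <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("locus", "qvalue") %in% names(df)))
    stop("q-value file needs columns locus, qvalue")
  if (any(df$qvalue < 0 | df$qvalue > 1, na.rm = TRUE))
    stop("q-values must lie in [0, 1]")
  df
}

# fixed float format shared by all writers: enough digits for 1e-6 round trips
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 10))
}

.write_tsv <- function(df, path) {
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot open path for writing: ", path))
  on.exit(close(con))
  num <- vapply(df, is.numeric, logical(1L))
  out <- df
  for (k in which(num)) out[[k]] <- .fmt_num(df[[k]])
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write a pipeline result to a tab-separated file
#'
#' Generic writer used by every stage. Column order is deterministic and
#' floats are written at fixed precision so that write-then-read round-trips
#' agree to 1e-6.
#'
#' @param obj A pipeline result (`data.frame`, `dist_matrix`, or
#'   `diff_molecular`).
#' @param path Output file path.
#' @export
write_results <- function(obj, path) UseMethod("write_results")

#' @export
write_results.data.frame <- function(obj, path) {
  .write_tsv(as.data.frame(obj), path)
}

#' @export
write_results.dist_matrix <- function(obj, path) {
  body <- as.data.frame(lapply(as.data.frame(obj$mat), .fmt_num),
                        check.names = FALSE, stringsAsFactors = FALSE)
  names(body) <- obj$labels
  df <- cbind(data.frame(label = obj$labels, stringsAsFactors = FALSE), body)
  kind_row <- df[1, ]
  kind_row$label <- "_kind_"
  kind_row[1, -1] <- obj$kind
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot open path for writing: ", path))
  on.exit(close(con))
  utils::write.table(rbind(kind_row, df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' @export
write_results.diff_molecular <- function(obj, path) {
  pw <- obj$pairwise
  df <- data.frame(pop1 = rep(rownames(pw), times = ncol(pw)),
                   pop2 = rep(colnames(pw), each = nrow(pw)),
                   fst = as.vector(pw), stringsAsFactors = FALSE)
  df <- df[df$pop1 < df$pop2, , drop = FALSE]
  df <- df[order(df$pop1, df$pop2), , drop = FALSE]
  hdr <- data.frame(pop1 = c("#global", "#popspec_method"),
                    pop2 = c("", ""),
                    fst = c(obj$global, NA), stringsAsFactors = FALSE)
  hdr$pop2[2] <- "mean_pairwise_substitute_for_bayescan"
  .write_tsv(rbind(hdr, df), path)
}

#' Read back a distance matrix written by [write_results()]
#'
#' @param path File produced by `write_results()` on a `dist_matrix`.
#' @return A `dist_matrix`.
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  kind_row <- df$label == "_kind_"
  kind <- if (any(kind_row)) as.character(df[kind_row, 2L]) else "unknown"
  df <- df[!kind_row, , drop = FALSE]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$label
  new_dist_matrix(m, kind = kind)
}
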