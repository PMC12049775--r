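#' Expression matrices
#'
#' An expression matrix in brmtls is a tibble whose first column, `gene`,
#' holds unique gene symbols and whose remaining columns hold one numeric
#' vector per sample. The measurement unit travels with the object as an
#' attribute so that downstream steps can check their preconditions
#' (`"counts"`, `"RPKM"`, `"TPM"` or `"log2"`). Values must be finite and,
#' for every unit except `"log2"`, non-negative.
#'
#' @param x A data frame with a `gene` column and one numeric column per
#'   sample, or a numeric matrix with gene symbols as row names.
#' @param unit Measurement unit, one of `"counts"`, `"RPKM"`, `"TPM"`,
#'   `"log2"`.
#' @return A tibble of class `expr_mat` with a `unit` attribute.
#' @examples
#' m <- as_expr_mat(tibble::tibble(gene = c("A", "B"), s1 = c(1, 2), s2 = c(3, 4)),
#'                  unit = "counts")
#' expr_unit(m)
#' @export
as_expr_mat <- function(x, unit) {
  unit <- match.arg(unit, expr_units())
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix input needs gene symbols as rownames")
    x <- tibble::as_tibble(x, rownames = "gene")
  }
  x <- tibble::as_tibble(x)
  if (!"gene" %in% names(x)) abort("expression input needs a `gene` column")
  x <- dplyr::relocate(x, "gene")
  validate_expr_mat(x, unit)
  structure(x, unit = unit, class = c("expr_mat", class(tibble::tibble())))
}

expr_units <- function() c("counts", "RPKM", "TPM", "log2")

validate_expr_mat <- function(x, unit) {
  genes <- x$gene
  if (anyNA(genes) || any(genes == "")) abort("gene symbols must be non-missing")
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort(paste0("duplicate gene symbols: ", paste(head(dup, 5), collapse = ", ")))
  }
  samp <- setdiff(names(x), "gene")
  if (length(samp) == 0) abort("expression matrix has no sample columns")
  if (anyDuplicated(samp)) abort("duplicate sample IDs")
  vals <- as.matrix(x[samp])
  if (!is.numeric(vals)) abort("sample columns must be numeric")
  if (any(!is.finite(vals))) abort("expression values must be finite")
  if (unit != "log2" && any(vals < 0)) {
    abort(paste0("negative values are not allowed for unit '", unit, "'"))
  }
  invisible(x)
}

#' @rdname as_expr_mat
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit", exact = TRUE)
  if (is.null(u)) abort("not an expression matrix: no unit attribute")
  u
}

#' @rdname as_expr_mat
#' @export
expr_samples <- function(x) setdiff(names(x), "gene")

# genes x samples numeric matrix with rownames
em_matrix <- function(x) {
  m <- as.matrix(x[expr_samples(x)])
  rownames(m) <- x$gene
  m
}

em_rebuild <- function(m, unit) {
  as_expr_mat(tibble::as_tibble(m, rownames = "gene"), unit = unit)
}

check_unit <- function(x, expected, what) {
  u <- expr_unit(x)
  if (!u %in% expected) {
    abort(paste0(what, " expects unit ", paste(expected, collapse = "/"),
                 ", got '", u, "'"))
  }
  invisible(u)
}

#' Read and write expression matrices
#'
#' Delimited-text layout: genes in rows, samples in columns, first column
#' the gene symbol (header `gene`), tab-separated by default. Duplicate gene
#' symbols in a file are an error rather than being silently aggregated,
#' because signature arithmetic requires unique symbols.
#'
#' @param path File path.
#' @param unit Unit of the stored values (see [as_expr_mat()]).
#' @param delim Field delimiter, default tab.
#' @return `read_expr_matrix()` returns an `expr_mat`; `write_expr_matrix()`
#'   returns `path` invisibly.
#' @export
read_expr_matrix <- function(path, unit, delim = "\t") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene"
  as_expr_mat(x, unit = unit)
}

#' @rdname read_expr_matrix
#' @param x An `expr_mat`.
#' @export
write_expr_matrix <- function(x, path, delim = "\t") {
  stopifnot(inherits(x, "expr_mat"))
  readr::write_delim(x, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a gene-length table
#'
#' Two-column delimited file: gene symbol and merged exon-unit length in
#' base pairs. Lengths must be positive.
#'
#' @param path File path.
#' @param delim Field delimiter, default tab.
#' @return A tibble with columns `gene`, `length_bp`.
#' @export
read_gene_lengths <- function(path, delim = "\t") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  names(x)[1:2] <- c("gene", "length_bp")
  validate_gene_lengths(x)
}

validate_gene_lengths <- function(x) {
  x <- tibble::as_tibble(x)
  if (anyDuplicated(x$gene)) abort("duplicate gene symbols in length table")
  if (any(!is.finite(x$length_bp)) || any(x$length_bp <= 0)) {
    abort("gene lengths must be positive")
  }
  x
}

lengths_for <- function(counts, lengths) {
  lengths <- validate_gene_lengths(lengths)
  idx <- match(counts$gene, lengths$gene)
  if (anyNA(idx)) {
    missing <- counts$gene[is.na(idx)]
    abort(paste0("no gene length for: ", paste(head(missing, 5), collapse = ", ")))
  }
  lengths$length_bp[idx]
}

#' RPKM normalization
#'
#' Reads per kilobase of exon model per million mapped reads: each count is
#' divided by the combined exon-unit length of its gene (in kb) and the
#' total number of reads of its sample (in millions, taken as the column
#' sum of the count matrix).
#'
#' @param counts An `expr_mat` with unit `"counts"`.
#' @param lengths A gene-length table (columns `gene`, `length_bp`) covering
#'   every gene in `counts`.
#' @return An `expr_mat` with unit `"RPKM"`.
#' @examples
#' counts <- as_expr_mat(tibble::tibble(gene = "A", s1 = 100), "counts")
#' # a 2 kb gene with 100 of 10 million reads scores 100 / (2 * 10) = 5 RPKM
#' @export
compute_rpkm <- function(counts, lengths) {
  check_unit(counts, "counts", "compute_rpkm()")
  len_kb <- lengths_for(counts, lengths) / 1000
  m <- em_matrix(counts)
  tot_m <- colSums(m) / 1e6
  if (any(tot_m == 0)) {
    abort(paste0("zero total reads in sample(s): ",
                 paste(colnames(m)[tot_m == 0], collapse = ", ")))
  }
  out <- sweep(m / len_kb, 2, tot_m, `/`)
  em_rebuild(out, "RPKM")
}

#' TPM normalization
#'
#' Transcripts per million: counts are first divided by gene length in kb
#' (a per-kb rate), then each sample's rates are rescaled to sum to 10^6,
#' so TPM columns always total one million.
#'
#' @inheritParams compute_rpkm
#' @return An `expr_mat` with unit `"TPM"`.
#' @export
compute_tpm <- function(counts, lengths) {
  check_unit(counts, "counts", "compute_tpm()")
  len_kb <- lengths_for(counts, lengths) / 1000
  m <- em_matrix(counts)
  if (any(colSums(m) == 0)) {
    abort(paste0("zero total reads in sample(s): ",
                 paste(colnames(m)[colSums(m) == 0], collapse = ", ")))
  }
  rate <- m / len_kb
  out <- sweep(rate, 2, colSums(rate), `/`) * 1e6
  em_rebuild(out, "TPM")
}

#' Log2 transform with pseudocount
#'
#' @param x An `expr_mat` with a linear-scale unit (not `"log2"`).
#' @param pseudocount Positive offset added before taking log2; default 1.
#' @return An `expr_mat` with unit `"log2"`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  check_unit(x, c("counts", "RPKM", "TPM"), "log_transform()")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("pseudocount must be a positive number")
  }
  em_rebuild(log2(em_matrix(x) + pseudocount), "log2")
}

#' Per-gene z-scores
#'
#' Centers and scales each gene row to mean 0 and SD 1 across samples.
#' Population SD (divide by n) is the default convention; set
#' `population_sd = FALSE` for the sample SD (divide by n - 1). Constant
#' rows are returned as all zero with a warning.
#'
#' @param x An `expr_mat` with at least two samples.
#' @param population_sd Use the population SD (default `TRUE`).
#' @return A tibble with a `gene` column and one z-scored column per sample.
#' @export
zscore_genes <- function(x, population_sd = TRUE) {
  m <- em_matrix(x)
  n <- ncol(m)
  if (n < 2) abort("z-scoring needs at least two samples")
  mu <- rowMeans(m)
  ctr <- m - mu
  ss <- rowSums(ctr^2)
  sdv <- sqrt(ss / if (population_sd) n else n - 1)
  const <- sdv == 0
  if (any(const)) {
    warn(paste0(sum(const), " constant gene row(s) returned as all-zero"))
    sdv[const] <- 1
  }
  tibble::as_tibble(ctr / sdv, rownames = "gene")
}

# row z-scoring for clustering steps; same constant-row convention, silent
zscore_rows <- function(m, population_sd = TRUE) {
  n <- ncol(m)
  ctr <- m - rowMeans(m)
  sdv <- sqrt(rowSums(ctr^2) / if (population_sd) n else n - 1)
  sdv[sdv == 0] <- 1
  ctr / sdv
}
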