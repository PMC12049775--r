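#' Candidate compendium of TLS-related genes
#'
#' Six published source lists used as the candidate pool for the brain
#' metastasis TLS signature: the 12-chemokine TLS signature, B cell
#' markers, activated dendritic cell / germinal-center light-zone markers,
#' a melanoma-derived TLS signature, TLS hallmark genes, and a T follicular
#' helper (Tfh) signature.
#'
#' @return A named list of six character vectors.
#' @examples
#' lengths(tls_candidates())
#' @export
tls_candidates <- function() {
  list(
    chemokine12 = c("CCL2", "CCL3", "CCL4", "CCL5", "CCL8", "CCL18", "CCL19",
                    "CCL21", "CXCL9", "CXCL10", "CXCL11", "CXCL13"),
    b_cell = c("BANK1", "CD19", "CD22", "CD79A", "CR2", "CR1", "FCRL2",
               "MS4A1", "PAX5", "FCER2", "MZB1"),
    dendritic = c("LAMP3", "CD80", "CD83", "CD86", "CCR7"),
    melanoma_tls = c("CD79B", "RBP5", "EIF1AY", "CETP", "SKAP1", "LAT",
                     "CCR6", "CD1D", "PTGDS"),
    hallmark = c("CCL19", "CCL21", "CXCL13", "CCR7", "CXCR5", "SELL", "LAMP3"),
    tfh = c("CXCL13", "CD200", "FBLN7", "ICOS", "SGPP2", "SH2D1A", "TIGIT",
            "PDCD1")
  )
}

#' Union of the candidate lists with per-gene provenance
#'
#' @param candidates Named list of gene vectors; default [tls_candidates()].
#' @return A tibble sorted by gene with columns `gene`, `sources`
#'   (comma-separated source-list names), `n_sources`.
#' @export
candidate_union <- function(candidates = tls_candidates()) {
  long <- purrr::imap(candidates, \(genes, src) tibble::tibble(gene = genes, source = src)) |>
    purrr::list_rbind()
  long |>
    dplyr::distinct(.data$gene, .data$source) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(sources = paste(.data$source, collapse = ","),
                     n_sources = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$gene)
}

#' Geometric-mean metagene score
#'
#' Per-sample signature score: the geometric mean of the signature genes'
#' expression under a +1 offset, i.e. `exp(mean(log(x + 1)))` over the
#' genes. The offset makes zeros well-defined and is reported without
#' back-subtraction, so the score of an all-zero sample is 1. The score is
#' strictly monotone in every gene's value. Genes absent from the matrix
#' are dropped with a warning; no gene present is an error.
#'
#' @param expr An `expr_mat` on a linear scale (TPM by default in this
#'   pipeline; counts or RPKM are accepted, `log2` is refused).
#' @param genes Character vector of signature genes, or a signature tibble
#'   with a `gene` column (e.g. from [build_signature()]).
#' @param pseudocount Offset added before the log; default 1.
#' @return A tibble with columns `sample`, `score`.
#' @examples
#' m <- as_expr_mat(tibble::tibble(gene = c("A", "B"), s = c(0, 3)), "TPM")
#' metagene_score(m, c("A", "B"))  # geometric mean of 1 and 4 -> 2
#' @export
metagene_score <- function(expr, genes, pseudocount = 1) {
  check_unit(expr, c("counts", "RPKM", "TPM"), "metagene_score()")
  if (is.data.frame(genes)) genes <- genes$gene
  m <- em_matrix(expr)
  present <- intersect(genes, rownames(m))
  if (length(present) == 0) abort("none of the signature genes is present in the matrix")
  absent <- setdiff(genes, present)
  if (length(absent) > 0) {
    warn(paste0("signature genes absent from matrix, dropped: ",
                paste(absent, collapse = ", ")))
  }
  sc <- exp(colMeans(log(m[present, , drop = FALSE] + pseudocount)))
  tibble::tibble(sample = colnames(m), score = unname(sc))
}

#' Build the TLS gene signature by correlation with the 12-chemokine seed
#'
#' Reproduces the construction procedure: the seed score is the
#' geometric-mean metagene score of the 12-chemokine list; every candidate
#' gene is then correlated (Pearson) with the seed score, and genes with
#' low expression across samples (`mean_expr < min_mean_expr`) or a
#' correlation below `min_r` are discarded. The defaults discard only
#' negatively correlated genes (`min_r = 0`) and genes below 1 TPM mean
#' expression; there is no fixed signature size. Remaining genes are
#' ordered by descending correlation.
#'
#' @param expr An `expr_mat` on a linear scale (TPM recommended), at least
#'   3 samples.
#' @param candidates Named list of candidate source lists; must contain a
#'   `chemokine12` element, all of whose genes must be present in `expr`.
#' @param min_mean_expr Expression floor on the per-gene mean; default 1.
#' @param min_r Minimum Pearson correlation with the seed score; default 0.
#' @return A tibble of class `tls_signature` with columns `gene`,
#'   `sources`, `r`, `mean_expr`, ordered by descending `r`.
#' @export
build_signature <- function(expr, candidates = tls_candidates(),
                            min_mean_expr = 1, min_r = 0) {
  check_unit(expr, c("counts", "RPKM", "TPM"), "build_signature()")
  if (!"chemokine12" %in% names(candidates)) {
    abort("candidate list needs a 'chemokine12' element for the seed score")
  }
  m <- em_matrix(expr)
  if (ncol(m) < 3) abort("signature construction needs at least 3 samples")
  seedg <- candidates$chemokine12
  missing_seed <- setdiff(seedg, rownames(m))
  if (length(missing_seed) > 0) {
    abort(paste0("chemokine12 seed genes absent from matrix: ",
                 paste(missing_seed, collapse = ", ")))
  }
  seed <- metagene_score(expr, seedg)$score
  if (sd(seed) == 0) abort("seed score is constant; correlation undefined")

  cand <- candidate_union(candidates)
  cand <- cand[cand$gene %in% rownames(m), , drop = FALSE]
  absent <- setdiff(candidate_union(candidates)$gene, cand$gene)
  if (length(absent) > 0) {
    warn(paste0("candidate genes absent from matrix: ", paste(absent, collapse = ", ")))
  }
  ex <- m[cand$gene, , drop = FALSE]
  mean_expr <- rowMeans(ex)
  sdv <- apply(ex, 1, sd)
  r <- rep(NA_real_, nrow(cand))
  ok <- sdv > 0
  r[ok] <- apply(ex[ok, , drop = FALSE], 1, cor, y = seed)
  if (any(!ok)) {
    warn(paste0("constant candidate gene(s) dropped (correlation undefined): ",
                paste(cand$gene[!ok], collapse = ", ")))
  }
  out <- tibble::tibble(gene = cand$gene, sources = cand$sources,
                        r = r, mean_expr = unname(mean_expr)) |>
    dplyr::filter(!is.na(.data$r), .data$mean_expr >= min_mean_expr,
                  .data$r >= min_r) |>
    dplyr::arrange(dplyr::desc(.data$r))
  class(out) <- c("tls_signature", class(out))
  out
}

#' Read / write a TLS signature table
#'
#' Tab-separated layout `gene, sources, r, mean_expr`; a preset signature
#' (e.g. a published gene list) can be loaded from the same layout, with
#' `r` and `mean_expr` optionally empty.
#'
#' @param x A `tls_signature` tibble.
#' @param path File path.
#' @return `read_signature()` returns a `tls_signature` tibble.
#' @export
write_signature <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene" %in% names(x)) names(x)[1] <- "gene"
  if (anyDuplicated(x$gene)) abort("duplicate genes in signature file")
  class(x) <- c("tls_signature", class(x))
  x
}

#' TLS class assignment by clustering on signature genes
#'
#' Signature-gene rows are z-scored and samples are clustered
#' agglomeratively (Ward linkage on Euclidean distance by default), the
#' tree is cut at `k` clusters, and clusters are relabelled by ascending
#' mean TLS score so that TLS1 is the low-expression and TLSk the
#' high-expression class.
#'
#' @param expr An `expr_mat` on a linear scale (TPM recommended).
#' @param signature A `tls_signature` tibble or character vector of genes.
#' @param k Number of classes; default 3 (TLS1/TLS2/TLS3).
#' @param linkage `"ward"` (default) or `"complete"`.
#' @return A tibble with columns `sample`, `tls_score`, `tls_class`
#'   (ordered factor `TLS1 < ... < TLSk`).
#' @export
assign_tls_classes <- function(expr, signature, k = 3,
                               linkage = c("ward", "complete")) {
  linkage <- match.arg(linkage)
  if (is.data.frame(signature)) signature <- signature$gene
  m <- em_matrix(expr)
  n <- ncol(m)
  if (n < k) abort(paste0("cannot form ", k, " classes from ", n, " samples"))
  genes <- intersect(signature, rownames(m))
  if (length(genes) == 0) abort("no signature gene present in the matrix")
  mz <- zscore_rows(log2(m[genes, , drop = FALSE] + 1))
  hc <- hclust(dist(t(mz), method = "euclidean"),
               method = if (linkage == "ward") "ward.D2" else "complete")
  raw <- cutree(hc, k = k)
  sc <- metagene_score(expr, genes)
  cls <- relabel_by_mean(raw, sc$score, prefix = "TLS")
  tibble::tibble(sample = colnames(m), tls_score = sc$score, tls_class = cls)
}

#' Median split of TLS scores into high and low
#'
#' Samples scoring strictly above the cohort median (standard interpolated
#' median) are `high`; scores at or below the median are `low`. If all
#' scores are equal everything is `low` and a warning is raised.
#'
#' @param scores A tibble with columns `sample` and `score` (e.g. from
#'   [metagene_score()]).
#' @return The input with an added `tls_level` column (factor low < high).
#' @export
median_split <- function(scores) {
  if (nrow(scores) < 2) abort("median split needs at least 2 samples")
  med <- median(scores$score)
  if (all(scores$score == scores$score[1])) {
    warn("all scores equal; every sample assigned to 'low'")
  }
  lvl <- factor(ifelse(scores$score > med, "high", "low"),
                levels = c("low", "high"))
  dplyr::mutate(scores, tls_level = lvl)
}

#' Cytolytic activity score
#'
#' Log-average of GZMA and PRF1 expression:
#' `mean(log2(GZMA + 1), log2(PRF1 + 1))` per sample (default), a proxy for
#' cytotoxic immune activity. The alternative `method = "geom"` returns the
#' geometric mean of the raw values under a 0.01 offset.
#'
#' @param expr An `expr_mat` on a linear scale (TPM recommended); both
#'   GZMA and PRF1 must be present.
#' @param method `"log2mean"` (default) or `"geom"`.
#' @return A tibble with columns `sample`, `cytolytic`.
#' @export
cytolytic_score <- function(expr, method = c("log2mean", "geom")) {
  method <- match.arg(method)
  check_unit(expr, c("counts", "RPKM", "TPM"), "cytolytic_score()")
  m <- em_matrix(expr)
  need <- c("GZMA", "PRF1")
  missing <- setdiff(need, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("cytolytic score needs GZMA and PRF1; absent: ",
                 paste(missing, collapse = ", ")))
  }
  g <- m["GZMA", ]
  p <- m["PRF1", ]
  sc <- switch(method,
    log2mean = (log2(g + 1) + log2(p + 1)) / 2,
    geom = sqrt((g + 0.01) * (p + 0.01))
  )
  tibble::tibble(sample = colnames(m), cytolytic = unname(sc))
}
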