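#' Marker-based cell-population abundance scores
#'
#' MCP-counter-style estimator: the abundance score of a population in a
#' sample is the arithmetic mean of the sample's log2 expression over the
#' population's marker genes. Scores are in arbitrary units and are
#' comparable across samples within a population. Markers absent from the
#' matrix are reported via a message and dropped; a population with no
#' marker present is an error.
#'
#' @param log_expr An `expr_mat` with unit `"log2"` (see [log_transform()]).
#' @param markers Marker table with columns `population`, `gene`,
#'   `compartment`; default [default_markers()].
#' @return A tibble with a `sample` column and one numeric score column per
#'   population.
#' @export
score_populations <- function(log_expr, markers = default_markers()) {
  check_unit(log_expr, "log2", "score_populations()")
  markers <- validate_markers(markers)
  m <- em_matrix(log_expr)
  absent <- setdiff(markers$gene, rownames(m))
  if (length(absent) > 0) {
    inform(paste0("markers absent from matrix: ", paste(absent, collapse = ", ")))
  }
  pops <- unique(markers$population)
  cols <- purrr::map(pops, function(p) {
    genes <- intersect(markers$gene[markers$population == p], rownames(m))
    if (length(genes) == 0) {
      abort(paste0("no marker genes of population '", p, "' present in the matrix"))
    }
    unname(colMeans(m[genes, , drop = FALSE]))
  })
  out <- tibble::tibble(sample = colnames(m))
  out[pops] <- cols
  out
}

#' Immune cell infiltration (ICI) score and tertile groups
#'
#' The ICI score of a sample is the sum of its abundance scores over the
#' immune-flagged populations only; stromal populations (endothelial cells,
#' fibroblasts) are excluded. Samples are assigned to `low`, `intermediate`
#' and `high` infiltration groups by the empirical tertiles of the ICI
#' distribution (linear-interpolation quantiles); a score tied with a
#' tertile boundary goes to the lower group.
#'
#' @param scores Population score table from [score_populations()].
#' @param markers The marker table that produced `scores` (used for the
#'   immune/stromal flags).
#' @return A tibble with columns `sample`, `ici`, `ici_group` (ordered
#'   factor low < intermediate < high).
#' @export
compute_ici <- function(scores, markers = default_markers()) {
  markers <- validate_markers(markers)
  immune <- unique(markers$population[markers$compartment == "immune"])
  immune <- intersect(immune, names(scores))
  if (length(immune) == 0) abort("no immune-flagged population in the score table")
  ici <- rowSums(as.matrix(scores[immune]))
  grp <- tertile_groups(ici)
  tibble::tibble(sample = scores$sample, ici = ici, ici_group = grp)
}

# boundaries at the 1/3 and 2/3 type-7 quantiles, ties to the lower group
tertile_groups <- function(x) {
  q <- quantile(x, c(1, 2) / 3, type = 7, names = FALSE)
  lv <- c("low", "intermediate", "high")
  g <- ifelse(x <= q[1], "low", ifelse(x <= q[2], "intermediate", "high"))
  factor(g, levels = lv, ordered = TRUE)
}

#' Immune-class clustering (IC1..ICk)
#'
#' Population scores are z-scored per population across samples and samples
#' are clustered agglomeratively on Euclidean distance. Ward linkage
#' (`hclust` method `"ward.D2"`) is the default; complete linkage is
#' available via `linkage = "complete"`. The tree is cut at `k` classes,
#' which are then relabelled `IC1..ICk` by ascending mean ICI score so that
#' IC1 is always the least-infiltrated class.
#'
#' @param scores Population score table from [score_populations()].
#' @param markers Marker table used for the ICI ordering.
#' @param k Number of immune classes; default 6.
#' @param linkage `"ward"` (default) or `"complete"`.
#' @return A tibble with columns `sample`, `ic_class` (factor `IC1..ICk`).
#' @export
cluster_immune_classes <- function(scores, markers = default_markers(), k = 6,
                                   linkage = c("ward", "complete")) {
  linkage <- match.arg(linkage)
  n <- nrow(scores)
  if (n < k) abort(paste0("cannot form ", k, " classes from ", n, " samples"))
  pops <- setdiff(names(scores), "sample")
  m <- as.matrix(scores[pops])
  rownames(m) <- scores$sample
  # z-score per population (columns), population SD; constant columns -> 0
  mz <- t(zscore_rows(t(m)))
  hc <- hclust(dist(mz, method = "euclidean"),
               method = if (linkage == "ward") "ward.D2" else "complete")
  raw <- cutree(hc, k = k)
  ici <- compute_ici(scores, markers)$ici
  cls <- relabel_by_mean(raw, ici, prefix = "IC")
  tibble::tibble(sample = scores$sample, ic_class = cls)
}

# relabel cluster ids 1..k by ascending mean of `value`; factor prefix1..prefixk
relabel_by_mean <- function(cluster, value, prefix) {
  k <- length(unique(cluster))
  means <- tapply(value, cluster, mean)
  ord <- names(sort(means))
  new <- match(as.character(cluster), ord)
  factor(paste0(prefix, new), levels = paste0(prefix, seq_len(k)), ordered = TRUE)
}
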