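#' Default immune and stromal marker sets
#'
#' Marker-gene catalogue for the marker-mean abundance estimator: six immune
#' populations (T cells, B lineage, NK cells, monocytic lineage, myeloid
#' dendritic cells, neutrophils) and two stromal populations (endothelial
#' cells, fibroblasts). The lists are deliberately small, canonical
#' lineage markers; the estimator, not this particular catalogue, is the
#' contract, and any user-supplied table with the same columns can replace
#' it.
#'
#' @return A tibble with columns `population`, `gene`, `compartment`
#'   (`"immune"` or `"stromal"`).
#' @examples
#' default_markers() |> dplyr::count(population, compartment)
#' @export
default_markers <- function() {
  sets <- list(
    "T cells"                 = list(c("CD3D", "CD3E", "CD2", "TRAC"), "immune"),
    "B lineage"               = list(c("MS4A1", "CD79A", "CD19", "BANK1"), "immune"),
    "NK cells"                = list(c("NCR1", "KLRD1", "GNLY"), "immune"),
    "Monocytic lineage"       = list(c("CD14", "CSF1R", "CD163"), "immune"),
    "Myeloid dendritic cells" = list(c("CD1C", "FCER1A", "CLEC10A"), "immune"),
    "Neutrophils"             = list(c("FCGR3B", "CSF3R", "S100A12"), "immune"),
    "Endothelial cells"       = list(c("VWF", "PECAM1", "CDH5"), "stromal"),
    "Fibroblasts"             = list(c("COL1A1", "DCN", "PDGFRB"), "stromal")
  )
  purrr::imap(sets, function(s, nm) {
    tibble::tibble(population = nm, gene = s[[1]], compartment = s[[2]])
  }) |>
    purrr::list_rbind()
}

validate_markers <- function(markers) {
  markers <- tibble::as_tibble(markers)
  need <- c("population", "gene", "compartment")
  if (!all(need %in% names(markers))) {
    abort("marker table needs columns population, gene, compartment")
  }
  if (nrow(markers) == 0) abort("marker table is empty")
  if (!all(markers$compartment %in% c("immune", "stromal"))) {
    abort("compartment must be 'immune' or 'stromal'")
  }
  cmp <- dplyr::distinct(markers, .data$population, .data$compartment)
  if (anyDuplicated(cmp$population)) {
    abort("a population cannot be both immune and stromal")
  }
  markers
}
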