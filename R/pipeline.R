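#' Run the full synthetic-cohort analysis pipeline
#'
#' One seed drives the whole chain: simulate a bulk cohort, normalize
#' (TPM, log2), score immune populations and the ICI with tertile groups,
#' cluster immune classes, build and score the TLS signature, assign TLS
#' classes and the median high/low split, compute the cytolytic score,
#' simulate and analyse cell maps for a spatial subset, generate survival
#' outcomes from the planted TLS status, and run the association and
#' survival statistics. When `out_dir` is given, every declared artifact
#' is written as delimited text.
#'
#' @param cfg A [sim_config()]; its `seed` fixes all randomness.
#' @param n_spatial Number of samples (taken from the start of the cohort)
#'   that get simulated cell maps; default 12.
#' @param beta_tls True log hazard ratio for the survival simulation;
#'   default -0.8.
#' @param out_dir Optional directory for TSV/CSV/JSON artifacts.
#' @return A list with elements `bulk`, `tpm`, `scores`, `ici`,
#'   `ic_classes`, `signature`, `tls_scores`, `tls_classes`, `tls_split`,
#'   `cytolytic`, `spatial` (cells, vessels, truth, aggregates, status),
#'   `clinical`, `km`, `cox`, `concordance`.
#' @export
run_brm_pipeline <- function(cfg = sim_config(), n_spatial = 12,
                             beta_tls = -0.8, out_dir = NULL) {
  bulk <- generate_bulk_cohort(cfg)
  tpm <- compute_tpm(bulk$counts, bulk$lengths)
  lg2 <- log_transform(tpm)

  scores <- score_populations(lg2, cfg$markers)
  ici <- compute_ici(scores, cfg$markers)
  ic_classes <- cluster_immune_classes(scores, cfg$markers,
                                       k = min(6, nrow(scores)))

  signature <- build_signature(tpm, cfg$candidates)
  tls_scores <- metagene_score(tpm, signature)
  tls_classes <- assign_tls_classes(tpm, signature, k = 3)
  tls_split <- median_split(tls_scores)
  cyto <- cytolytic_score(tpm)

  truth_samples <- bulk$truth$samples
  spatial_ids <- head(truth_samples$sample, n_spatial)
  planted <- derive_planted(truth_samples[truth_samples$sample %in% spatial_ids, ],
                            seed = cfg$seed + 101L)
  maps <- generate_cell_map(planted, samples = spatial_ids,
                            seed = cfg$seed + 202L)
  spatial <- spatial_tls(maps$cells, maps$vessels)

  clinical <- generate_survival(
    dplyr::left_join(truth_samples,
                     dplyr::select(tls_split, "sample", "tls_level"),
                     by = "sample"),
    beta_tls = beta_tls, seed = cfg$seed + 303L)
  km <- km_logrank(clinical, time, event, tls_level)
  cox <- cox_fit(clinical, covariates = c("tls_level", "age", "sex",
                                          "extracerebral", "treatment"))
  conc <- concordance(tls_classes[tls_classes$sample %in% spatial_ids, ],
                      spatial$status)

  res <- list(bulk = bulk, tpm = tpm, scores = scores, ici = ici,
              ic_classes = ic_classes, signature = signature,
              tls_scores = tls_scores, tls_classes = tls_classes,
              tls_split = tls_split, cytolytic = cyto,
              spatial = c(maps, spatial), clinical = clinical,
              km = km, cox = cox, concordance = conc)
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

# spatial planting from bulk truth: TLS-positive samples get 1-2 clearly
# qualifying perivascular aggregates, TLS-negative samples get either
# nothing or one clearly sub-threshold aggregate
derive_planted <- function(truth_samples, seed = 1L) {
  set.seed(as.integer(seed))
  rows <- purrr::pmap(truth_samples[c("sample", "tls_status")],
                      function(sample, tls_status) {
    if (tls_status) {
      k <- sample(1:2, 1)
      tibble::tibble(sample = sample,
                     n_cells = sample(600:900, k, replace = TRUE),
                     b_frac = runif(k, 0.60, 0.70),
                     n_dc = sample(0:5, k, replace = TRUE),
                     perivascular = TRUE, radius_um = 40)
    } else if (runif(1) < 0.5) {
      tibble::tibble(sample = sample, n_cells = sample(100:300, 1),
                     b_frac = runif(1, 0.3, 0.4), n_dc = 0L,
                     perivascular = TRUE, radius_um = 30)
    } else {
      tibble::tibble(sample = character(), n_cells = integer(),
                     b_frac = double(), n_dc = integer(),
                     perivascular = logical(), radius_um = double())
    }
  })
  purrr::list_rbind(rows)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_expr_matrix(res$bulk$counts, p("expression_counts.tsv"))
  write_expr_matrix(res$tpm, p("expression_tpm.tsv"))
  readr::write_tsv(res$bulk$lengths, p("gene_lengths.tsv"), progress = FALSE)
  readr::write_tsv(res$scores, p("population_scores.tsv"), progress = FALSE)
  readr::write_tsv(res$ici, p("ici_scores.tsv"), progress = FALSE)
  readr::write_tsv(res$ic_classes, p("immune_classes.tsv"), progress = FALSE)
  write_signature(res$signature, p("tls_signature.tsv"))
  readr::write_tsv(
    res$tls_split |>
      dplyr::left_join(dplyr::select(res$tls_classes, "sample", "tls_class"),
                       by = "sample") |>
      dplyr::left_join(res$cytolytic, by = "sample"),
    p("tls_scores.tsv"), progress = FALSE)
  readr::write_csv(res$spatial$cells, p("cell_map.csv"), progress = FALSE)
  readr::write_csv(res$spatial$vessels, p("vessels.csv"), progress = FALSE)
  readr::write_tsv(dplyr::select(res$spatial$aggregates, -"members"),
                   p("aggregates.tsv"), progress = FALSE)
  readr::write_tsv(res$spatial$status, p("spatial_status.tsv"), progress = FALSE)
  readr::write_tsv(res$clinical, p("clinical.tsv"), progress = FALSE)
  readr::write_tsv(tidy(res$cox), p("cox_forest.tsv"), progress = FALSE)
  writeLines(forest_table(res$cox), p("cox_forest.txt"))
  truth <- list(
    samples = res$bulk$truth$samples,
    planted_aggregates = res$spatial$truth$aggregates,
    spatial_status = res$spatial$truth$status
  )
  jsonlite::write_json(truth, p("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
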