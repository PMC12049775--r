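#' Cell phenotype vocabulary for multiplex immunofluorescence maps
#'
#' The fixed phenotype labels a cell map may carry, matching a 7-plex TLS
#' panel: `T` (CD3+), `B` (CD20+), `DC` (Lamp3+ mature dendritic cell),
#' `macrophage` (CD163+), `tumor` (pCK+/MelA+), `endothelial` (vWF+),
#' `other`.
#'
#' @return Character vector of valid phenotype labels.
#' @export
cell_phenotypes <- function() {
  c("T", "B", "DC", "macrophage", "tumor", "endothelial", "other")
}

validate_cell_map <- function(cells) {
  cells <- tibble::as_tibble(cells)
  need <- c("sample", "x_um", "y_um", "phenotype")
  if (!all(need %in% names(cells))) {
    abort("cell map needs columns sample, x_um, y_um, phenotype")
  }
  if (nrow(cells) > 0) {
    if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um))) {
      abort("cell coordinates must be finite")
    }
    bad <- setdiff(unique(cells$phenotype), cell_phenotypes())
    if (length(bad) > 0) {
      abort(paste0("unknown phenotype label(s): ", paste(bad, collapse = ", ")))
    }
  }
  cells
}

#' Read cell maps and vessel coordinates
#'
#' Cell maps are comma-separated with columns `sample,x_um,y_um,phenotype`
#' (coordinates in micrometres); vessel files have columns
#' `sample,x_um,y_um`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_cell_map <- function(path) {
  validate_cell_map(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_cell_map
#' @export
read_vessels <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# ---- density-based clustering ------------------------------------------------

# eps-neighbour lists (self included), chunked to bound memory
eps_neighbours <- function(x, y, eps, block = 512L) {
  n <- length(x)
  nbrs <- vector("list", n)
  eps2 <- eps^2
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    hits <- d2 <= eps2
    nbrs[idx] <- lapply(seq_along(idx), function(i) which(hits[i, ]))
  }
  nbrs
}

# DBSCAN over 2-D points. Core point: >= min_pts neighbours within eps
# (self counted). Clusters are connected core neighbourhoods plus border
# points; noise is labelled 0.
dbscan_xy <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (n == 0) return(integer(0))
  nbrs <- eps_neighbours(x, y, eps)
  core <- lengths(nbrs) >= min_pts
  labels <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cid <- cid + 1L
    queue <- i
    labels[i] <- cid
    head_ptr <- 1L
    while (head_ptr <= length(queue)) {
      p <- queue[head_ptr]
      head_ptr <- head_ptr + 1L
      if (core[p]) {
        new <- nbrs[[p]][labels[nbrs[[p]]] == 0L]
        labels[new] <- cid
        queue <- c(queue, new)
      }
    }
  }
  labels
}

#' Detect lymphoid aggregates in a phenotyped cell map
#'
#' Density-based clustering (DBSCAN semantics) of the T and B lymphocytes
#' of each sample: a core point has at least `min_pts` lymphocytes within
#' `eps_um` (itself included), clusters are connected core neighbourhoods
#' plus border points, and everything else is diffuse background. Each
#' cluster becomes a candidate aggregate. Lamp3+ dendritic cells and
#' macrophages are not clustered themselves; they are counted as belonging
#' to an aggregate when they lie within `eps_um` of any member lymphocyte.
#'
#' @param cells Cell map tibble (`sample`, `x_um`, `y_um`, `phenotype`).
#' @param eps_um Neighbourhood radius in micrometres; default 30.
#' @param min_pts Minimum neighbourhood size for a core point; default 10.
#' @return A tibble with one row per aggregate: `sample`, `aggregate_id`,
#'   `n_cells` (member lymphocytes), `n_B`, `n_T`, `b_fraction`
#'   (`n_B / (n_B + n_T)`), `n_DC`, `n_macrophage`, `centroid_x_um`,
#'   `centroid_y_um`, and `members` (list column of row indices into
#'   `cells`). An empty map yields a zero-row tibble.
#' @export
detect_aggregates <- function(cells, eps_um = 30, min_pts = 10) {
  if (eps_um <= 0) abort("eps_um must be positive")
  if (min_pts < 2) abort("min_pts must be at least 2")
  cells <- validate_cell_map(cells)
  empty <- tibble::tibble(
    sample = character(), aggregate_id = integer(), n_cells = integer(),
    n_B = integer(), n_T = integer(), b_fraction = double(),
    n_DC = integer(), n_macrophage = integer(),
    centroid_x_um = double(), centroid_y_um = double(), members = list()
  )
  if (nrow(cells) == 0) return(empty)
  out <- lapply(split(seq_len(nrow(cells)), cells$sample), function(rows) {
    sub <- cells[rows, ]
    lym <- which(sub$phenotype %in% c("T", "B"))
    if (length(lym) == 0) return(NULL)
    lab <- dbscan_xy(sub$x_um[lym], sub$y_um[lym], eps = eps_um, min_pts = min_pts)
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids) == 0) return(NULL)
    purrr::map(ids, function(id) {
      mem_local <- lym[lab == id]
      xs <- sub$x_um[mem_local]
      ys <- sub$y_um[mem_local]
      phen <- sub$phenotype[mem_local]
      n_b <- sum(phen == "B")
      n_t <- sum(phen == "T")
      # DC / macrophage membership: within eps of any member lymphocyte
      aux <- which(sub$phenotype %in% c("DC", "macrophage"))
      n_dc <- 0L
      n_mac <- 0L
      if (length(aux) > 0) {
        d2 <- outer(sub$x_um[aux], xs, "-")^2 + outer(sub$y_um[aux], ys, "-")^2
        close <- rowSums(d2 <= eps_um^2) > 0
        n_dc <- sum(close & sub$phenotype[aux] == "DC")
        n_mac <- sum(close & sub$phenotype[aux] == "macrophage")
      }
      tibble::tibble(
        sample = sub$sample[1], aggregate_id = id,
        n_cells = length(mem_local), n_B = n_b, n_T = n_t,
        b_fraction = n_b / (n_b + n_t),
        n_DC = n_dc, n_macrophage = n_mac,
        centroid_x_um = mean(xs), centroid_y_um = mean(ys),
        members = list(rows[mem_local])
      )
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(purrr::compact(unname(out)))
  if (nrow(out) == 0) empty else out
}

#' Perivascular test for aggregates
#'
#' An aggregate is perivascular when the distance from its centroid to the
#' nearest vessel point is at most `d_max_um`. Samples with no vessel
#' points yield `FALSE` (infinite distance) with a warning.
#'
#' @param aggregates Aggregate table from [detect_aggregates()].
#' @param vessels Vessel point tibble (`sample`, `x_um`, `y_um`).
#' @param d_max_um Distance threshold in micrometres; default 50.
#' @return `aggregates` with added `vessel_dist_um` and `perivascular`
#'   columns.
#' @export
is_perivascular <- function(aggregates, vessels, d_max_um = 50) {
  if (d_max_um <= 0) abort("d_max_um must be positive")
  vessels <- tibble::as_tibble(vessels)
  if (nrow(aggregates) == 0) {
    return(dplyr::mutate(aggregates, vessel_dist_um = double(), perivascular = logical()))
  }
  dist_um <- purrr::map_dbl(seq_len(nrow(aggregates)), function(i) {
    v <- vessels[vessels$sample == aggregates$sample[i], ]
    if (nrow(v) == 0) return(Inf)
    min(sqrt((v$x_um - aggregates$centroid_x_um[i])^2 +
             (v$y_um - aggregates$centroid_y_um[i])^2))
  })
  if (any(is.infinite(dist_um))) {
    warn(paste0("no vessel points for sample(s): ",
                paste(unique(aggregates$sample[is.infinite(dist_um)]), collapse = ", "),
                "; perivascular set to FALSE"))
  }
  dplyr::mutate(aggregates, vessel_dist_um = dist_um,
                perivascular = dist_um <= d_max_um)
}

#' Classify aggregates with the TLS rules
#'
#' A perivascular aggregate of at least `min_cells` member lymphocytes with
#' a predominance of B cells (B fraction strictly greater than
#' `min_b_frac`) is called `TLS`; if it additionally contains at least one
#' Lamp3+ dendritic cell it is considered more mature and called
#' `intermediate_TLS`. Anything else remains a plain `aggregate`.
#'
#' @param aggregates Aggregate table after [is_perivascular()].
#' @param min_cells Cell floor for a TLS call; default 500.
#' @param min_b_frac B-cell predominance threshold (strict); default 0.5.
#' @param b_frac_denominator `"lymphocytes"` (default, B/(B+T)) or
#'   `"all_members"` (B over lymphocytes plus in-aggregate DC and
#'   macrophages).
#' @return `aggregates` with an added `call` factor
#'   (`TLS`, `intermediate_TLS`, `aggregate`).
#' @export
classify_aggregates <- function(aggregates, min_cells = 500, min_b_frac = 0.5,
                                b_frac_denominator = c("lymphocytes", "all_members")) {
  b_frac_denominator <- match.arg(b_frac_denominator)
  if (!"perivascular" %in% names(aggregates)) {
    abort("run is_perivascular() before classify_aggregates()")
  }
  bf <- switch(b_frac_denominator,
    lymphocytes = aggregates$b_fraction,
    all_members = aggregates$n_B /
      (aggregates$n_cells + aggregates$n_DC + aggregates$n_macrophage)
  )
  tls <- aggregates$perivascular & aggregates$n_cells >= min_cells & bf > min_b_frac
  call <- ifelse(tls & aggregates$n_DC >= 1, "intermediate_TLS",
                 ifelse(tls, "TLS", "aggregate"))
  dplyr::mutate(aggregates,
                call = factor(call, levels = c("TLS", "intermediate_TLS", "aggregate")))
}

#' Per-sample TLS status
#'
#' A sample is TLS-positive when it carries at least one aggregate called
#' `TLS` or `intermediate_TLS`; its TLS score is the count of such calls.
#' Samples with only sub-threshold aggregates or diffuse infiltration (no
#' detected aggregate) are TLS-negative.
#'
#' @param aggregates Classified aggregate table from
#'   [classify_aggregates()].
#' @param samples Optional character vector of all sample IDs, so that
#'   samples without any detected aggregate appear as negative rows.
#' @return A tibble with columns `sample`, `status` (factor
#'   negative/positive), `tls_score`, `n_aggregates`.
#' @export
sample_status <- function(aggregates, samples = NULL) {
  base <- tibble::tibble(sample = unique(c(samples, aggregates$sample)))
  counts <- aggregates |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      tls_score = sum(.data$call %in% c("TLS", "intermediate_TLS")),
      n_aggregates = dplyr::n(), .groups = "drop"
    )
  base |>
    dplyr::left_join(counts, by = "sample") |>
    dplyr::mutate(
      tls_score = dplyr::coalesce(.data$tls_score, 0L),
      n_aggregates = dplyr::coalesce(.data$n_aggregates, 0L),
      status = factor(ifelse(.data$tls_score > 0, "positive", "negative"),
                      levels = c("negative", "positive"))
    ) |>
    dplyr::relocate("sample", "status", "tls_score", "n_aggregates") |>
    dplyr::arrange(.data$sample)
}

#' Spatial TLS pipeline for a cohort of cell maps
#'
#' Convenience wrapper chaining [detect_aggregates()], [is_perivascular()],
#' [classify_aggregates()] and [sample_status()] with one set of
#' parameters.
#'
#' @inheritParams detect_aggregates
#' @inheritParams is_perivascular
#' @inheritParams classify_aggregates
#' @return A list with elements `aggregates` (classified table) and
#'   `status` (per-sample table).
#' @export
spatial_tls <- function(cells, vessels, eps_um = 30, min_pts = 10,
                        d_max_um = 50, min_cells = 500, min_b_frac = 0.5,
                        b_frac_denominator = "lymphocytes") {
  agg <- detect_aggregates(cells, eps_um = eps_um, min_pts = min_pts) |>
    is_perivascular(vessels, d_max_um = d_max_um) |>
    classify_aggregates(min_cells = min_cells, min_b_frac = min_b_frac,
                        b_frac_denominator = b_frac_denominator)
  list(aggregates = agg, status = sample_status(agg, samples = unique(cells$sample)))
}
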