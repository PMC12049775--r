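#' Configuration for the synthetic BrM cohort generator
#'
#' Defines the statistical structure the analysis assumes: a multi-site
#' brain-metastasis cohort with latent immune infiltration ordered by
#' primary site, a TLS-positive subset with coordinated elevation of
#' TLS-related genes, and decoy genes with known behaviour (co-varying,
#' anti-correlated, near-silent) for signature-construction tests.
#'
#' Counts are drawn as Poisson around
#' `exp(baseline + infiltration x marker loading + TLS x log(fold) +
#' library factor + noise)`: marker genes of a population load on that
#' population's latent per-sample level, TLS-positive samples elevate every
#' TLS-related gene (the candidate compendium, GZMA/PRF1 and the planted
#' co-varying genes) by `tls_fold` and depress the anti-correlated decoys
#' by the same fold, library factors are lognormal, and `noise_sd` is an
#' extra lognormal gene-by-sample jitter.
#'
#' @param sites Tibble with columns `site`, `n`, `infiltration` (latent
#'   site mean), `tls_frac` (TLS-positive fraction). The default is a
#'   60-sample five-site cohort with infiltration ordered
#'   lung > melanoma > kidney > colon > breast.
#' @param markers Marker table (see [default_markers()]).
#' @param candidates TLS candidate compendium (see [tls_candidates()]).
#' @param covarying_genes Planted genes that co-vary with TLS status but are
#'   outside the published lists.
#' @param anticorr_genes Planted genes depressed in TLS-positive samples.
#' @param low_expr_genes Planted near-silent decoy genes.
#' @param n_background_genes Unstructured filler genes.
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline log-count
#'   distribution.
#' @param infiltration_sd SD of the latent per-sample population levels
#'   around the site mean.
#' @param marker_loading Log-scale loading of marker genes on their
#'   population's latent level.
#' @param tls_fold Multiplicative elevation of TLS-related genes in
#'   TLS-positive samples; must be >= 1 (1 = null configuration).
#' @param library_size_sd SD of the lognormal per-sample library factor.
#' @param noise_sd SD of the lognormal gene-by-sample jitter.
#' @param seed Integer seed fixing all generator output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sites = NULL,
                       markers = default_markers(),
                       candidates = tls_candidates(),
                       covarying_genes = c("LTB", "POU2AF1", "FDCSP",
                                           "TNFRSF13B", "CD38"),
                       anticorr_genes = c("SOX2", "OLIG2", "GFAP"),
                       low_expr_genes = c("CDX2", "ALB"),
                       n_background_genes = 40,
                       baseline_log_mean = log(50), baseline_log_sd = 1,
                       infiltration_sd = 0.3, marker_loading = 1,
                       tls_fold = 8, library_size_sd = 0.3, noise_sd = 0.1,
                       seed = 1L) {
  if (is.null(sites)) {
    sites <- tibble::tibble(
      site = c("lung", "melanoma", "breast", "kidney", "colon"),
      n = c(20L, 12L, 14L, 7L, 7L),
      infiltration = c(1.5, 1.1, 0.3, 0.8, 0.6),
      tls_frac = c(0.50, 0.35, 0.10, 0.25, 0.15)
    )
  }
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("site", "n", "infiltration", "tls_frac") %in% names(sites)))
  if (any(sites$tls_frac < 0 | sites$tls_frac > 1)) {
    abort("tls_frac must lie in [0, 1]")
  }
  if (tls_fold < 1) abort("tls_fold must be >= 1")
  markers <- validate_markers(markers)
  cfg <- list(
    sites = sites, markers = markers, candidates = candidates,
    covarying_genes = covarying_genes, anticorr_genes = anticorr_genes,
    low_expr_genes = low_expr_genes, n_background_genes = n_background_genes,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    infiltration_sd = infiltration_sd, marker_loading = marker_loading,
    tls_fold = tls_fold, library_size_sd = library_size_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_universe <- function(cfg) {
  bg <- if (cfg$n_background_genes > 0) {
    sprintf("BG%03d", seq_len(cfg$n_background_genes))
  } else character(0)
  unique(c(cfg$markers$gene, candidate_union(cfg$candidates)$gene,
           "GZMA", "PRF1", cfg$covarying_genes, cfg$anticorr_genes,
           cfg$low_expr_genes, bg))
}

# genes elevated by tls_fold in TLS-positive samples
sim_tls_genes <- function(cfg) {
  unique(c(candidate_union(cfg$candidates)$gene, "GZMA", "PRF1",
           cfg$covarying_genes))
}

#' Generate a synthetic bulk expression cohort with ground truth
#'
#' Draws a multi-site cohort per its [sim_config()]: one latent
#' infiltration level per sample and population, a Bernoulli TLS status
#' per sample, Poisson counts around the log-linear expected model, and a
#' deterministic gene-length table. The full ground truth (site, latent
#' levels, TLS status, library factors, expected counts) is returned
#' alongside the data.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `counts` (`expr_mat`, unit counts),
#'   `lengths` (gene-length tibble) and `truth` (list with `samples`,
#'   `infiltration`, `mu`, `tls_genes`, `config`).
#' @export
generate_bulk_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sim_gene_universe(cfg)
  missing_m <- setdiff(cfg$markers$gene, genes)
  if (length(missing_m) > 0) {
    abort(paste0("marker genes missing from gene universe: ",
                 paste(missing_m, collapse = ", ")))
  }
  set.seed(cfg$seed)
  g <- length(genes)
  sites <- cfg$sites
  n <- sum(sites$n)
  sample_site <- rep(sites$site, sites$n)
  sample_id <- sprintf("S%03d", seq_len(n))

  baseline <- rnorm(g, cfg$baseline_log_mean, cfg$baseline_log_sd)
  names(baseline) <- genes
  baseline[cfg$low_expr_genes] <- log(1e-6)  # near-silent decoys

  lengths_bp <- round(runif(g, 500, 5000))
  lengths <- tibble::tibble(gene = genes, length_bp = lengths_bp)

  pops <- unique(cfg$markers$population)
  site_inf <- setNames(sites$infiltration, sites$site)
  infil <- matrix(pmax(0, rnorm(n * length(pops),
                                mean = rep(site_inf[sample_site], length(pops)),
                                sd = cfg$infiltration_sd)),
                  nrow = n, ncol = length(pops),
                  dimnames = list(sample_id, pops))

  site_tf <- setNames(sites$tls_frac, sites$site)
  tls_status <- runif(n) < site_tf[sample_site]
  lib <- exp(rnorm(n, 0, cfg$library_size_sd))

  log_mu <- matrix(baseline, nrow = g, ncol = n,
                   dimnames = list(genes, sample_id))
  for (p in pops) {
    pg <- cfg$markers$gene[cfg$markers$population == p]
    log_mu[pg, ] <- log_mu[pg, ] +
      matrix(cfg$marker_loading * infil[, p], nrow = length(pg), ncol = n,
             byrow = TRUE)
  }
  tg <- intersect(sim_tls_genes(cfg), genes)
  ag <- intersect(cfg$anticorr_genes, genes)
  if (any(tls_status)) {
    log_mu[tg, tls_status] <- log_mu[tg, tls_status] + log(cfg$tls_fold)
    log_mu[ag, tls_status] <- log_mu[ag, tls_status] - log(cfg$tls_fold)
  }
  log_mu <- sweep(log_mu, 2, log(lib), `+`)
  if (cfg$noise_sd > 0) {
    log_mu <- log_mu + matrix(rnorm(g * n, 0, cfg$noise_sd), nrow = g)
  }
  mu <- exp(log_mu)
  counts <- matrix(rpois(g * n, mu), nrow = g, dimnames = dimnames(mu))

  truth <- list(
    samples = tibble::tibble(sample = sample_id, site = sample_site,
                             tls_status = tls_status, library_factor = lib),
    infiltration = tibble::as_tibble(infil, rownames = "sample") |>
      tidyr::pivot_longer(-"sample", names_to = "population",
                          values_to = "level"),
    mu = mu, tls_genes = tg, config = cfg
  )
  list(counts = em_rebuild(counts, "counts"), lengths = lengths, truth = truth)
}

#' Generate phenotyped cell maps with planted lymphoid aggregates
#'
#' Background cells are homogeneous Poisson over a square tissue region
#' with fixed phenotype probabilities; vessels are uniform random points;
#' each planted aggregate places exactly `n_cells` lymphocytes
#' Gaussian-scattered (SD = `radius_um`) around a centre that is adjacent
#' to a vessel (perivascular) or far from all vessels, with exact
#' phenotype counts: `round(b_frac * n_cells)` B cells, the rest T cells,
#' plus exactly `n_dc` Lamp3+ dendritic cells inside the aggregate.
#'
#' @param planted Tibble with one row per planted aggregate: `sample`,
#'   `n_cells`, `b_frac`, `n_dc`, `perivascular` (logical); optional
#'   `radius_um` (default 40).
#' @param samples Character vector of all sample IDs (so samples without
#'   planted aggregates still get background tissue); defaults to the
#'   samples in `planted`.
#' @param extent_um Side of the square tissue region; default 2000.
#' @param background_per_mm2 Background cell intensity; default 200.
#' @param n_vessels Vessel points per sample; default 30.
#' @param seed Integer seed.
#' @return A list with `cells` (tibble `sample,x_um,y_um,phenotype`),
#'   `vessels` (tibble `sample,x_um,y_um`) and `truth` (list with
#'   `aggregates` incl. expected call, and per-sample `status`).
#' @export
generate_cell_map <- function(planted, samples = NULL, extent_um = 2000,
                              background_per_mm2 = 200, n_vessels = 30,
                              seed = 1L) {
  planted <- tibble::as_tibble(planted)
  if (nrow(planted) > 0 && !"radius_um" %in% names(planted)) {
    planted$radius_um <- 40
  }
  if (extent_um <= 0) abort("tissue extent must be positive")
  if (nrow(planted) > 0) {
    if (any(planted$radius_um >= extent_um / 8)) {
      abort("aggregate radius must be small relative to the tissue extent")
    }
    density <- planted$n_cells / (pi * (2 * planted$radius_um)^2)
    if (any(density > 0.1)) {
      abort("requested aggregate cell count exceeds density feasibility")
    }
  }
  samples <- unique(c(samples, planted$sample))
  if (length(samples) == 0) abort("no samples to generate")
  set.seed(as.integer(seed))

  bg_probs <- c(T = 0.30, B = 0.10, DC = 0.02, macrophage = 0.15,
                tumor = 0.35, endothelial = 0.05, other = 0.03)
  cells_all <- list()
  vessels_all <- list()
  truth_rows <- list()
  for (s in samples) {
    vx <- runif(n_vessels, 0, extent_um)
    vy <- runif(n_vessels, 0, extent_um)
    vessels_all[[s]] <- tibble::tibble(sample = s, x_um = vx, y_um = vy)

    n_bg <- rpois(1, background_per_mm2 * (extent_um / 1000)^2)
    parts <- list()
    if (n_bg > 0) {
      parts[[1]] <- tibble::tibble(
        sample = s, x_um = runif(n_bg, 0, extent_um),
        y_um = runif(n_bg, 0, extent_um),
        phenotype = sample(names(bg_probs), n_bg, replace = TRUE,
                           prob = bg_probs)
      )
    }
    pl <- planted[planted$sample == s, , drop = FALSE]
    centers <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(pl))) {
      ctr <- place_center(pl$perivascular[i], vx, vy, extent_um,
                          existing = centers, min_sep = 8 * pl$radius_um[i])
      centers <- rbind(centers, ctr)
      n_c <- pl$n_cells[i]
      n_b <- as.integer(round(pl$b_frac[i] * n_c))
      n_t <- n_c - n_b
      n_dc <- pl$n_dc[i]
      phen <- c(rep("B", n_b), rep("T", n_t), rep("DC", n_dc))
      k <- length(phen)
      parts[[length(parts) + 1]] <- tibble::tibble(
        sample = s,
        x_um = rnorm(k, ctr[1], pl$radius_um[i]),
        y_um = rnorm(k, ctr[2], pl$radius_um[i]),
        phenotype = phen
      )
      qualifies <- pl$perivascular[i] && n_c >= 500 && (n_b / n_c) > 0.5
      truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
        sample = s, center_x_um = ctr[1], center_y_um = ctr[2],
        n_cells = n_c, n_B = n_b, b_fraction = n_b / n_c, n_dc = n_dc,
        perivascular = pl$perivascular[i], radius_um = pl$radius_um[i],
        expected_call = if (!qualifies) "aggregate"
                        else if (n_dc >= 1) "intermediate_TLS" else "TLS"
      )
    }
    cells_all[[s]] <- purrr::list_rbind(parts)
  }
  cells <- purrr::list_rbind(unname(cells_all))
  if (nrow(cells) == 0) {
    cells <- tibble::tibble(sample = character(), x_um = double(),
                            y_um = double(), phenotype = character())
  }
  agg_truth <- purrr::list_rbind(truth_rows)
  if (is.null(agg_truth) || nrow(agg_truth) == 0) {
    agg_truth <- tibble::tibble(sample = character(), center_x_um = double(),
                                center_y_um = double(), n_cells = integer(),
                                n_B = integer(), b_fraction = double(),
                                n_dc = integer(), perivascular = logical(),
                                radius_um = double(), expected_call = character())
  }
  status <- tibble::tibble(sample = samples) |>
    dplyr::left_join(
      agg_truth |>
        dplyr::group_by(.data$sample) |>
        dplyr::summarise(tls_score = sum(.data$expected_call != "aggregate"),
                         .groups = "drop"),
      by = "sample") |>
    dplyr::mutate(tls_score = dplyr::coalesce(.data$tls_score, 0L),
                  status = factor(ifelse(.data$tls_score > 0, "positive",
                                         "negative"),
                                  levels = c("negative", "positive")))
  list(cells = validate_cell_map(cells),
       vessels = purrr::list_rbind(unname(vessels_all)),
       truth = list(aggregates = agg_truth, status = status))
}

# centre for a planted aggregate: near a vessel (<= 20 um) or far from all
# vessels (>= 250 um), and >= min_sep from previously placed centres
place_center <- function(perivascular, vx, vy, extent, existing, min_sep,
                         max_tries = 2000) {
  for (. in seq_len(max_tries)) {
    if (perivascular) {
      j <- sample.int(length(vx), 1)
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 20)
      ctr <- c(vx[j] + rad * cos(ang), vy[j] + rad * sin(ang))
    } else {
      ctr <- runif(2, 0, extent)
      if (min(sqrt((vx - ctr[1])^2 + (vy - ctr[2])^2)) < 250) next
    }
    if (any(ctr < 0 | ctr > extent)) next
    if (nrow(existing) > 0) {
      d <- sqrt((existing[, 1] - ctr[1])^2 + (existing[, 2] - ctr[2])^2)
      if (min(d) < min_sep) next
    }
    return(ctr)
  }
  abort("could not place aggregate centre under the separation constraints")
}

#' Generate survival outcomes for a cohort
#'
#' Exponential event times with hazard
#' `baseline_hazard * exp(beta_tls * tls_high)` (time in months from BrM
#' diagnosis) and independent uniform censoring calibrated to the requested
#' overall censoring fraction. Clinical covariates (age, sex, histological
#' subtype from the primary site, extracerebral metastases, treatment
#' status) are drawn independently except for an optional enrichment of
#' treatment-naive cases among TLS-high samples.
#'
#' @param samples Tibble with a `sample` column and a TLS indicator: either
#'   logical `tls_status`/`tls_high` or a `tls_level` factor with levels
#'   low/high. An optional `site` column feeds the histology covariate.
#' @param beta_tls True log hazard ratio of TLS-high vs low; default -0.8.
#' @param baseline_hazard Events per month in the TLS-low group; default
#'   0.03.
#' @param censoring_rate Target fraction censored, in `[0, 1)`; default 0.2.
#' @param treatment_naive_logodds Log-odds shift of being treatment-naive
#'   for TLS-high samples; default 0 (independence).
#' @param seed Integer seed.
#' @return A tibble with columns `sample`, `time`, `event`, `tls_level`,
#'   `age`, `sex`, `subtype`, `extracerebral`, `treatment`.
#' @export
generate_survival <- function(samples, beta_tls = -0.8, baseline_hazard = 0.03,
                              censoring_rate = 0.2,
                              treatment_naive_logodds = 0, seed = 1L) {
  samples <- tibble::as_tibble(samples)
  if (!is.finite(beta_tls)) abort("beta_tls must be finite")
  if (baseline_hazard <= 0) abort("baseline_hazard must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("censoring_rate must lie in [0, 1)")
  }
  high <- if ("tls_level" %in% names(samples)) {
    samples$tls_level == "high"
  } else if ("tls_status" %in% names(samples)) {
    as.logical(samples$tls_status)
  } else if ("tls_high" %in% names(samples)) {
    as.logical(samples$tls_high)
  } else {
    abort("samples needs a tls_level, tls_status or tls_high column")
  }
  set.seed(as.integer(seed))
  n <- nrow(samples)
  lambda <- baseline_hazard * exp(beta_tls * high)
  t_event <- rexp(n, rate = lambda)
  if (censoring_rate == 0) {
    time <- t_event
    event <- rep(1L, n)
  } else {
    u <- uniroot(function(u) mean((1 - exp(-lambda * u)) / (lambda * u)) -
                   censoring_rate,
                 interval = c(1e-6, 1e7), tol = 1e-9)$root
    cens <- runif(n, 0, u)
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
  }
  p_naive <- stats::plogis(treatment_naive_logodds * high)
  if (treatment_naive_logodds == 0) p_naive <- rep(0.5, n)
  subtype <- if ("site" %in% names(samples)) {
    paste0(samples$site, " carcinoma")
  } else rep("unknown", n)
  tibble::tibble(
    sample = samples$sample,
    time = time, event = event,
    tls_level = factor(ifelse(high, "high", "low"), levels = c("low", "high")),
    age = round(rnorm(n, 62, 11)),
    sex = sample(c("female", "male"), n, replace = TRUE),
    subtype = subtype,
    extracerebral = runif(n) < 0.5,
    treatment = ifelse(runif(n) < p_naive, "naive", "pretreated")
  )
}
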