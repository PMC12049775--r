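# small helpers to build cell maps in code
blob <- function(n, cx, cy, sd, phen, sample = "s1") {
  tibble::tibble(sample = sample, x_um = rnorm(n, cx, sd),
                 y_um = rnorm(n, cy, sd),
                 phenotype = sample(phen, n, replace = TRUE))
}

test_that("aggregate detection matches the connected-components oracle", {
  set.seed(41)
  # one dense blob on sparse background, several geometries
  for (rep in 1:5) {
    cells <- dplyr::bind_rows(
      blob(300, 500, 500, 40, c("B", "T")),
      blob(200, 1500, 300, 35, c("B", "T")),
      tibble::tibble(sample = "s1", x_um = runif(60, 0, 2000),
                     y_um = runif(60, 0, 2000),
                     phenotype = sample(c("B", "T"), 60, replace = TRUE))
    )
    lab_oracle <- oracle_dbscan(cells$x_um, cells$y_um, eps = 30, min_pts = 10)
    agg <- detect_aggregates(cells, eps_um = 30, min_pts = 10)
    lab_pkg <- integer(nrow(cells))
    for (i in seq_len(nrow(agg))) lab_pkg[agg$members[[i]]] <- i
    expect_identical(canon_labels(lab_pkg), canon_labels(lab_oracle))
  }
})

test_that("detection handles blobs, separation, diffuse scatter and empty maps", {
  set.seed(43)
  # 600 lymphocytes in one 40-um blob -> exactly one aggregate of 600
  cells <- blob(600, 1000, 1000, 40, c("B", "T"))
  agg <- detect_aggregates(cells)
  expect_equal(nrow(agg), 1)
  # the aggregate is exactly the oracle's eps-connected cluster; a few
  # sparse Gaussian-tail cells may legitimately stay noise
  lab_o <- oracle_dbscan(cells$x_um, cells$y_um, eps = 30, min_pts = 10)
  expect_equal(agg$n_cells, max(tabulate(lab_o)))
  expect_gte(agg$n_cells, 0.9 * 600)
  expect_equal(agg$n_B + agg$n_T, agg$n_cells)

  # two blobs 1000 um apart -> two aggregates
  two <- dplyr::bind_rows(blob(300, 400, 400, 40, "B"),
                          blob(300, 1400, 400, 40, "T"))
  expect_equal(nrow(detect_aggregates(two)), 2)

  # sparse uniform scatter below core density -> none (diffuse pattern)
  sparse <- tibble::tibble(sample = "s1", x_um = runif(100, 0, 2000),
                           y_um = runif(100, 0, 2000), phenotype = "T")
  expect_equal(nrow(detect_aggregates(sparse)), 0)

  # empty map -> empty aggregate table
  empty <- sparse[0, ]
  expect_equal(nrow(detect_aggregates(empty)), 0)

  # translation and rotation invariance of the partition
  th <- 0.7
  rot <- dplyr::mutate(cells,
                       x2 = cos(th) * x_um - sin(th) * y_um + 5000,
                       y2 = sin(th) * x_um + cos(th) * y_um - 300,
                       x_um = x2, y_um = y2)
  agg_rot <- detect_aggregates(rot[names(cells)])
  expect_equal(nrow(agg_rot), 1)
  expect_setequal(agg_rot$members[[1]], agg$members[[1]])
})

test_that("DC and macrophage membership counts cells within eps of members", {
  set.seed(47)
  cells <- dplyr::bind_rows(
    blob(200, 500, 500, 30, c("B", "T")),
    tibble::tibble(sample = "s1", x_um = c(505, 510, 1900),
                   y_um = c(500, 505, 1900),
                   phenotype = c("DC", "macrophage", "DC"))
  )
  agg <- detect_aggregates(cells)
  expect_equal(agg$n_DC, 1)          # the distant DC is not a member
  expect_equal(agg$n_macrophage, 1)
})

test_that("perivascular test thresholds on centroid-to-vessel distance", {
  agg <- tibble::tibble(sample = "s1", aggregate_id = 1L, n_cells = 600L,
                        n_B = 350L, n_T = 250L, b_fraction = 350 / 600,
                        n_DC = 0L, n_macrophage = 0L,
                        centroid_x_um = 100, centroid_y_um = 100,
                        members = list(1:600))
  on_vessel <- tibble::tibble(sample = "s1", x_um = 100, y_um = 100)
  expect_true(is_perivascular(agg, on_vessel)$perivascular)
  at_51 <- tibble::tibble(sample = "s1", x_um = 151, y_um = 100)
  expect_false(is_perivascular(agg, at_51, d_max_um = 50)$perivascular)
  # random geometry equals a brute-force scan
  set.seed(13)
  vs <- tibble::tibble(sample = "s1", x_um = runif(40, 0, 2000),
                       y_um = runif(40, 0, 2000))
  got <- is_perivascular(agg, vs)$vessel_dist_um
  want <- min(sqrt((vs$x_um - 100)^2 + (vs$y_um - 100)^2))
  expect_equal(got, want, tolerance = 1e-12)
  # no vessels: FALSE with warning
  expect_warning(out <- is_perivascular(agg, vs[0, ]), "vessel")
  expect_false(out$perivascular)
})

test_that("TLS calls follow the rule boundaries", {
  base <- tibble::tibble(sample = "s1", aggregate_id = 1:4,
                         n_cells = c(600L, 600L, 400L, 600L),
                         n_B = c(330L, 330L, 320L, 300L),
                         n_T = c(270L, 270L, 80L, 300L),
                         n_DC = c(0L, 3L, 0L, 0L),
                         n_macrophage = 0L,
                         b_fraction = c(330, 330, 320, 300) /
                           c(600, 600, 400, 600),
                         centroid_x_um = 0, centroid_y_um = 0,
                         members = list(1L, 1L, 1L, 1L),
                         vessel_dist_um = 10, perivascular = TRUE)
  calls <- classify_aggregates(base)$call
  expect_equal(as.character(calls),
               c("TLS",               # 600 cells, 55% B, perivascular
                 "intermediate_TLS",  # same with Lamp3+ DC present
                 "aggregate",         # fails the 500-cell floor
                 "aggregate"))        # exactly 50% B: strict inequality
  # non-perivascular never a TLS
  far <- dplyr::mutate(base[1, ], perivascular = FALSE)
  expect_equal(as.character(classify_aggregates(far)$call), "aggregate")
  # monotonicity: adding B cells to a TLS never demotes it
  more_b <- dplyr::mutate(base[1, ], n_B = n_B + 200L,
                          n_cells = n_cells + 200L,
                          b_fraction = n_B / (n_B + n_T))
  expect_equal(as.character(classify_aggregates(more_b)$call), "TLS")
})

test_that("sample status counts qualifying calls and defaults to negative", {
  agg <- tibble::tibble(sample = c("s1", "s1", "s2", "s3", "s3", "s3"),
                        call = factor(c("TLS", "aggregate", "aggregate",
                                        rep("intermediate_TLS", 3)),
                                      levels = c("TLS", "intermediate_TLS",
                                                 "aggregate")))
  st <- sample_status(agg, samples = c("s1", "s2", "s3", "s4"))
  expect_equal(as.character(st$status),
               c("positive", "negative", "positive", "negative"))
  expect_equal(st$tls_score, c(1L, 0L, 3L, 0L))
  empty <- sample_status(agg[0, ], samples = "s9")
  expect_equal(as.character(empty$status), "negative")
})
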