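test_that("group comparison dispatches MWU / Kruskal-Wallis correctly", {
  # identical distributions: U at its null centre
  d <- tibble::tibble(v = rep(c(1, 2, 3, 4, 5), 2),
                      g = rep(c("a", "b"), each = 5))
  res <- suppressWarnings(group_compare(d, v, g))
  expect_equal(res$method, "Mann-Whitney U")
  expect_equal(res$statistic, 5 * 5 / 2)

  # complete separation, n = (5, 5): exact two-sided p = 2/252
  sep <- tibble::tibble(v = 1:10, g = rep(c("a", "b"), each = 5))
  expect_equal(group_compare(sep, v, g)$p_value, 2 / choose(10, 5),
               tolerance = 1e-12)

  # three identical groups: H = 0
  three <- tibble::tibble(v = rep(c(1, 2, 3), 3),
                          g = rep(c("a", "b", "c"), each = 3))
  res3 <- group_compare(three, v, g)
  expect_equal(res3$method, "Kruskal-Wallis")
  expect_equal(res3$statistic, 0)

  expect_error(group_compare(tibble::tibble(v = 1:3, g = "a"), v, g), "groups")
})

test_that("BH adjustment matches hand computation and the definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(6)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # order-preserving: adjusted values nondecreasing in the raw ordering
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("Pearson correlation matches the covariance formula", {
  d <- tibble::tibble(x = c(1, 2, 4, 7), y = 2 * c(1, 2, 4, 7) + 1)
  expect_equal(pearson_r(d, x, y)$estimate, 1)
  d$y <- -d$x
  expect_equal(pearson_r(d, x, y)$estimate, -1)
  set.seed(8)
  r <- tibble::tibble(x = rnorm(50), y = rnorm(50))
  got <- pearson_r(r, x, y)
  want <- sum((r$x - mean(r$x)) * (r$y - mean(r$y))) /
    sqrt(sum((r$x - mean(r$x))^2) * sum((r$y - mean(r$y))^2))
  expect_equal(got$estimate, want, tolerance = 1e-12)
  expect_error(pearson_r(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               "constant")
})

test_that("concordance counts binary agreement under the class mapping", {
  rna <- tibble::tibble(sample = sprintf("S%02d", 1:20),
                        tls_class = rep(c("TLS1", "TLS2", "TLS3", "TLS3"), 5))
  mif <- tibble::tibble(sample = rna$sample,
                        status = rep(c("negative", "negative", "positive",
                                       "negative"), 5))
  cc <- concordance(rna, mif)
  # 5 of the TLS3/negative rows disagree, 15/20 agree... count explicitly:
  agree <- (rna$tls_class == "TLS3") == (mif$status == "positive")
  expect_equal(cc$concordance, mean(agree))
  expect_equal(cc$n, 20)
  # identical / fully discordant labels
  all_pos <- dplyr::mutate(mif, status = ifelse(rna$tls_class == "TLS3",
                                                "positive", "negative"))
  expect_equal(concordance(rna, all_pos)$concordance, 1)
  flipped <- dplyr::mutate(all_pos, status = ifelse(status == "positive",
                                                    "negative", "positive"))
  expect_equal(concordance(rna, flipped)$concordance, 0)
  # alternative mapping
  cc2 <- concordance(rna, mif, positive_classes = c("TLS2", "TLS3"))
  agree2 <- (rna$tls_class %in% c("TLS2", "TLS3")) == (mif$status == "positive")
  expect_equal(cc2$concordance, mean(agree2))
  expect_error(concordance(rna[1:3, ], mif), "same samples")
})

test_that("KM estimates follow the closed form and log-rank matches the oracle", {
  # one group, no censoring, distinct death times: S = (n - i)/n
  d <- tibble::tibble(time = as.numeric(1:10), event = 1, g = "a")
  km <- km_logrank(d, time, event, g)
  expect_equal(km$curves$estimate, (10 - 1:10) / 10)

  # two identical groups: statistic 0
  d2 <- dplyr::bind_rows(dplyr::mutate(d, g = "a"), dplyr::mutate(d, g = "b"))
  expect_equal(km_logrank(d2, time, event, g)$chisq, 0, tolerance = 1e-12)

  # toy two-group table equals the hand risk-set tabulation
  toy <- tibble::tibble(time = c(1, 3, 4, 6, 8, 9),
                        event = c(1, 1, 0, 1, 1, 1),
                        g = c("a", "b", "a", "b", "a", "b"))
  km_toy <- km_logrank(toy, time, event, g)
  expect_equal(km_toy$chisq, oracle_logrank(toy$time, toy$event, toy$g),
               tolerance = 1e-10)
  # and on random censored data
  set.seed(12)
  rnd <- tibble::tibble(time = round(rexp(40, 0.1), 6),
                        event = rbinom(40, 1, 0.7),
                        g = rep(c("a", "b"), 20))
  expect_equal(km_logrank(rnd, time, event, g)$chisq,
               oracle_logrank(rnd$time, rnd$event, rnd$g), tolerance = 1e-8)
})

test_that("Cox fit maximizes the Breslow partial likelihood", {
  set.seed(14)
  n <- 80
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rnorm(n)
  t <- rexp(n, 0.05 * exp(0.6 * x1 - 0.4 * x2))
  d <- tibble::tibble(time = t, event = 1L, x1 = x1, x2 = x2)
  fit <- cox_fit(d, covariates = c("x1", "x2"))
  beta <- fit$table$estimate
  X <- cbind(x1, x2)
  # the model's reported log partial likelihood equals the oracle at beta
  expect_equal(breslow_loglik(beta, t, rep(1L, n), X),
               fit$loglik[2], tolerance = 1e-6)
  # and beta is a maximum: numeric gradient near zero
  eps <- 1e-5
  for (j in 1:2) {
    up <- beta
    dn <- beta
    up[j] <- up[j] + eps
    dn[j] <- dn[j] - eps
    grad <- (breslow_loglik(up, t, rep(1L, n), X) -
             breslow_loglik(dn, t, rep(1L, n), X)) / (2 * eps)
    expect_lt(abs(grad), 1e-3)
  }

  # binary covariate with identical group survival: beta ~ 0
  same <- tibble::tibble(time = rep(as.numeric(1:20) + 0.1, 2), event = 1L,
                         g = rep(c(0, 1), each = 20))
  expect_lt(abs(cox_fit(same, covariates = "g")$table$estimate), 1e-8)

  # score-test equivalence with log-rank on untied toy data
  set.seed(15)
  toy <- tibble::tibble(time = sort(runif(30, 1, 100)),
                        event = 1L, g = rbinom(30, 1, 0.5))
  sc <- survival::coxph(survival::Surv(time, event) ~ g, data = toy,
                        ties = "breslow")
  expect_lt(abs(sc$score - km_logrank(toy, time, event, g)$chisq), 1e-3)

  expect_error(cox_fit(dplyr::mutate(d, event = 0L), covariates = "x1"),
               "events")
  expect_error(cox_fit(dplyr::mutate(d, x1 = 1), covariates = "x1"),
               "constant")
})

test_that("logistic enrichment equals the 2x2 log odds ratio", {
  tab_data <- function(a, b, c, d) {
    tibble::tibble(
      outcome = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
      pred = c(rep(1, a + b), rep(0, c + d)))
  }
  # (a, b, c, d) = (10, 5, 2, 8): coefficient = ln(10 * 8 / (5 * 2)) = ln 8
  res <- binomial_enrichment(tab_data(10, 5, 2, 8), outcome, pred)
  expect_equal(res$estimate, log(8), tolerance = 1e-6)
  # balanced independent table: coefficient 0
  expect_equal(binomial_enrichment(tab_data(5, 5, 5, 5), outcome, pred)$estimate,
               0, tolerance = 1e-8)
  # swapping outcome labels negates the coefficient
  d <- tab_data(10, 5, 2, 8)
  res_sw <- binomial_enrichment(dplyr::mutate(d, outcome = 1 - outcome),
                                outcome, pred)
  expect_equal(res_sw$estimate, -res$estimate, tolerance = 1e-6)
  # zero cell triggers the Haldane correction with a warning
  expect_warning(hz <- binomial_enrichment(tab_data(10, 0, 2, 8),
                                           outcome, pred), "Haldane")
  expect_true(hz$haldane)
  expect_equal(hz$estimate, log(10.5 * 8.5 / (0.5 * 2.5)), tolerance = 1e-10)
})
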