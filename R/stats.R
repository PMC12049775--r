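#' Compare a quantitative variable across groups
#'
#' Dispatches the two-sided Mann-Whitney U test for two groups and the
#' Kruskal-Wallis test for three or more (the rank-based tests used for
#' score-vs-class comparisons throughout the pipeline). `wilcox.test()`'s
#' default exact/normal-approximation switch applies: the exact
#' distribution for fewer than 50 observations per group and no ties, the
#' normal approximation otherwise.
#'
#' @param data A data frame.
#' @param value Column with the quantitative variable (tidy-eval).
#' @param group Column with the grouping variable (tidy-eval).
#' @return A one-row tibble: `method`, `statistic`, `df` (NA for the U
#'   test), `p_value`, `n_groups`, `group_n` (list column of per-group
#'   sizes).
#' @export
group_compare <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- factor(g[keep])
  g <- droplevels(g)
  sizes <- table(g)
  if (length(sizes) < 2) abort("group comparison needs at least 2 non-empty groups")
  if (any(sizes == 0)) abort("every group must be non-empty")
  if (length(sizes) == 2) {
    ht <- wilcox.test(v[g == levels(g)[1]], v[g == levels(g)[2]],
                      alternative = "two.sided")
    tibble::tibble(method = "Mann-Whitney U", statistic = unname(ht$statistic),
                   df = NA_real_, p_value = ht$p.value,
                   n_groups = 2L, group_n = list(as.integer(sizes)))
  } else {
    ht <- kruskal.test(v, g)
    tibble::tibble(method = "Kruskal-Wallis", statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p_value = ht$p.value,
                   n_groups = length(sizes), group_n = list(as.integer(sizes)))
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement;
#' order-preserving and never below the raw p-value.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be numeric in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Pearson correlation with t-distribution p-value
#'
#' @param data A data frame.
#' @param x,y Numeric columns (tidy-eval).
#' @return A one-row tibble: `estimate`, `statistic`, `p_value`, `n`,
#'   `conf_low`, `conf_high`.
#' @export
pearson_r <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3) abort("Pearson correlation needs at least 3 pairs")
  if (sd(xv) == 0 || sd(yv) == 0) abort("correlation undefined for a constant vector")
  ht <- cor.test(xv, yv, method = "pearson")
  tibble::tibble(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
                 p_value = ht$p.value, n = length(xv),
                 conf_low = ht$conf.int[1], conf_high = ht$conf.int[2])
}

#' Concordance between RNA-based TLS classes and tissue TLS status
#'
#' Collapses the three RNA classes to a binary label (by default only TLS3
#' maps to positive; pass `positive_classes = c("TLS2", "TLS3")` for the
#' alternative) and reports the fraction of samples whose binary RNA label
#' agrees with the multiplex-immunofluorescence status, together with the
#' 2x2 table.
#'
#' @param rna Tibble with columns `sample` and `tls_class`.
#' @param mif Tibble with columns `sample` and `status`
#'   (negative/positive), e.g. from [sample_status()].
#' @param positive_classes RNA classes mapped to positive; default
#'   `"TLS3"`.
#' @return A list of class `tls_concordance`: `concordance`, `n`, `table`
#'   (2x2 contingency table).
#' @export
concordance <- function(rna, mif, positive_classes = "TLS3") {
  if (!setequal(rna$sample, mif$sample)) {
    abort("RNA and mIF tables must cover the same samples")
  }
  joined <- dplyr::inner_join(
    dplyr::select(rna, "sample", "tls_class"),
    dplyr::select(mif, "sample", "status"), by = "sample")
  rna_pos <- joined$tls_class %in% positive_classes
  mif_pos <- joined$status == "positive"
  tab <- table(rna = factor(rna_pos, c(FALSE, TRUE), c("negative", "positive")),
               mif = factor(mif_pos, c(FALSE, TRUE), c("negative", "positive")))
  out <- list(concordance = mean(rna_pos == mif_pos), n = nrow(joined),
              table = tab)
  class(out) <- "tls_concordance"
  out
}

#' @export
print.tls_concordance <- function(x, ...) {
  cat(sprintf("RNA vs mIF TLS concordance: %.3f (n = %d)\n", x$concordance, x$n))
  print(x$table)
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimate per group plus the log-rank chi-square
#' (observed-vs-expected form) comparing the groups.
#'
#' @param data A data frame of survival records.
#' @param time,event,group Columns for follow-up time, event indicator
#'   (0/1) and the grouping variable (tidy-eval).
#' @return A list of class `km_result`: `curves` (tibble `group`, `time`,
#'   `n_risk`, `n_event`, `estimate`, `conf_low`, `conf_high`), `chisq`,
#'   `df`, `p_value`, `n`, `n_events`, `medians` (per-group median
#'   survival), and the underlying `survfit` object as `fit`.
#' @export
km_logrank <- function(data, time, event, group) {
  tv <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  gv <- factor(dplyr::pull(data, {{ group }}))
  if (any(tv <= 0)) abort("survival times must be positive")
  if (sum(ev) == 0) abort("no events: survival comparison is undefined")
  df_ <- data.frame(time = tv, event = as.integer(ev), group = gv)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df_)
  sm <- summary(fit)
  grp_of <- function(strata) sub("^group=", "", as.character(strata))
  grp <- if (is.null(sm$strata)) rep(levels(gv)[1], length(sm$time)) else grp_of(sm$strata)
  curves <- tibble::tibble(
    group = grp, time = sm$time, n_risk = sm$n.risk,
    n_event = sm$n.event, estimate = sm$surv,
    conf_low = sm$lower, conf_high = sm$upper
  )
  med <- summary(fit)$table
  medians <- if (is.matrix(med)) {
    tibble::tibble(group = grp_of(rownames(med)),
                   median = unname(med[, "median"]))
  } else {
    tibble::tibble(group = levels(gv)[1], median = unname(med["median"]))
  }
  if (nlevels(gv) >= 2) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df_)
    chisq <- sd_$chisq
    dfree <- length(sd_$n) - 1
    p <- pchisq(chisq, dfree, lower.tail = FALSE)
  } else {
    chisq <- 0
    dfree <- 0
    p <- NA_real_
  }
  out <- list(curves = curves, chisq = chisq, df = dfree, p_value = p,
              n = nrow(df_), n_events = sum(df_$event), medians = medians,
              fit = fit)
  class(out) <- "km_result"
  out
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("Kaplan-Meier / log-rank: chisq = %.3f on %d df, p = %.4g (n = %d, events = %d)\n",
              x$chisq, x$df, x$p_value, x$n, x$n_events))
  print(x$medians)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.km_result <- function(x, ...) x$curves

#' @exportS3Method generics::glance
glance.km_result <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, p_value = x$p_value,
                 n = x$n, n_events = x$n_events)
}

#' Cox proportional hazards regression
#'
#' Multivariable Cox model maximizing the partial likelihood with Breslow
#' tie handling (Efron available via `ties`), reporting per-covariate log
#' hazard ratio, hazard ratio, 95% confidence interval and Wald p-value —
#' the forest-plot table.
#'
#' @param data A data frame of survival records.
#' @param time,event Column names (strings) for follow-up time and event
#'   indicator.
#' @param covariates Character vector of covariate column names;
#'   categorical covariates are encoded as treatment-contrast dummies.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A list of class `cox_result`: `table` (tibble `term`,
#'   `estimate`, `std_error`, `hr`, `conf_low`, `conf_high`, `p_value`),
#'   `loglik`, `n`, `n_events`, and the `coxph` fit as `model`.
#' @export
cox_fit <- function(data, time = "time", event = "event", covariates,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    abort(paste0("covariates not in data: ", paste(missing_cov, collapse = ", ")))
  }
  n_events <- sum(data[[event]])
  if (n_events < length(covariates)) {
    abort("fewer events than covariates; the model is not identifiable")
  }
  constant <- covariates[purrr::map_lgl(covariates, function(cv) {
    x <- data[[cv]]
    length(unique(x[!is.na(x)])) < 2
  })]
  if (length(constant) > 0) {
    abort(paste0("constant covariate(s): ", paste(constant, collapse = ", ")))
  }
  fml <- as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                           paste(covariates, collapse = " + ")))
  model <- survival::coxph(fml, data = data, ties = ties,
                           control = survival::coxph.control(eps = 1e-9,
                                                             iter.max = 100))
  if (!is.null(model$info) && grepl("did not converge", paste(model$info, collapse = " "))) {
    abort("Cox fit did not converge")
  }
  sm <- summary(model)
  tab <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "coef"],
    std_error = sm$coefficients[, "se(coef)"],
    hr = sm$coefficients[, "exp(coef)"],
    conf_low = sm$conf.int[, "lower .95"],
    conf_high = sm$conf.int[, "upper .95"],
    p_value = sm$coefficients[, "Pr(>|z|)"]
  )
  out <- list(table = tab, loglik = model$loglik, n = sm$n,
              n_events = sm$nevent, model = model)
  class(out) <- "cox_result"
  out
}

#' @export
print.cox_result <- function(x, ...) {
  cat(forest_table(x), sep = "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cox_result <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.cox_result <- function(x, ...) {
  tibble::tibble(loglik = x$loglik[length(x$loglik)], n = x$n,
                 n_events = x$n_events)
}

#' Plain-text forest table for a Cox fit
#'
#' @param x A `cox_result`.
#' @return Character vector of table lines.
#' @export
forest_table <- function(x) {
  stopifnot(inherits(x, "cox_result"))
  hdr <- sprintf("%-24s %8s %18s %10s", "term", "HR", "95% CI", "p")
  rows <- sprintf("%-24s %8.3f [%7.3f, %7.3f] %10.3g",
                  x$table$term, x$table$hr, x$table$conf_low,
                  x$table$conf_high, x$table$p_value)
  c(hdr, strrep("-", nchar(hdr)), rows,
    sprintf("n = %d, events = %d", x$n, x$n_events))
}

#' Logistic enrichment of a binary outcome in a binary predictor
#'
#' Single-covariate binomial logistic regression; the coefficient equals
#' the log odds ratio of the 2x2 table. If a zero cell makes the odds
#' ratio infinite, a Haldane-corrected estimate (0.5 added to every cell)
#' is returned with a warning.
#'
#' @param data A data frame.
#' @param outcome,predictor Binary columns (tidy-eval); logicals, 0/1, or
#'   two-level factors.
#' @return A one-row tibble: `estimate` (log odds ratio), `std_error`,
#'   `p_value`, `odds_ratio`, `haldane` (whether the correction was
#'   applied).
#' @export
binomial_enrichment <- function(data, outcome, predictor) {
  yv <- as_binary(dplyr::pull(data, {{ outcome }}), "outcome")
  xv <- as_binary(dplyr::pull(data, {{ predictor }}), "predictor")
  if (length(unique(yv)) < 2 || length(unique(xv)) < 2) {
    abort("both levels of outcome and predictor must be present")
  }
  tab <- table(xv, yv)  # rows: predictor 0/1; cols: outcome 0/1
  if (any(tab == 0)) {
    warn("zero cell in the 2x2 table; returning Haldane-corrected estimate")
    tc <- tab + 0.5
    est <- log(tc[2, 2] * tc[1, 1] / (tc[2, 1] * tc[1, 2]))
    se <- sqrt(sum(1 / tc))
    p <- 2 * stats::pnorm(abs(est / se), lower.tail = FALSE)
    return(tibble::tibble(estimate = est, std_error = se, p_value = p,
                          odds_ratio = exp(est), haldane = TRUE))
  }
  fit <- glm(yv ~ xv, family = binomial())
  sm <- summary(fit)$coefficients
  tibble::tibble(estimate = sm["xv", "Estimate"],
                 std_error = sm["xv", "Std. Error"],
                 p_value = sm["xv", "Pr(>|z|)"],
                 odds_ratio = exp(sm["xv", "Estimate"]), haldane = FALSE)
}

as_binary <- function(x, what) {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x)) {
    if (nlevels(droplevels(x)) > 2) abort(paste0(what, " must be binary"))
    return(as.integer(droplevels(x)) - 1L)
  }
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) abort(paste0(what, " must be binary (0/1)"))
    return(as.integer(x))
  }
  ux <- sort(unique(x))
  if (length(ux) != 2) abort(paste0(what, " must be binary"))
  as.integer(x == ux[2])
}

#' Read a clinical survival table
#'
#' Tab-separated with at least `sample`, `time` (months, positive) and
#' `event` (0/1); any further columns are kept as covariates.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_clinical <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(x))) {
    abort("clinical table needs columns sample, time, event")
  }
  if (any(x$time <= 0)) abort("survival times must be positive")
  if (!all(x$event %in% c(0, 1))) abort("event must be 0/1")
  x
}
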