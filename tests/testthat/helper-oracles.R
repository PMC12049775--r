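# Independent brute-force oracles used across the suite. Each deliberately
# takes a different route than the implementation it checks.

# element-wise RPKM by explicit loops
oracle_rpkm <- function(counts, len_bp) {
  out <- counts * NA_real_
  for (s in seq_len(ncol(counts))) {
    tot_m <- sum(counts[, s]) / 1e6
    for (g in seq_len(nrow(counts))) {
      out[g, s] <- counts[g, s] / ((len_bp[g] / 1000) * tot_m)
    }
  }
  out
}

oracle_tpm <- function(counts, len_bp) {
  out <- counts * NA_real_
  for (s in seq_len(ncol(counts))) {
    rate <- counts[, s] / (len_bp / 1000)
    out[, s] <- rate / sum(rate) * 1e6
  }
  out
}

# geometric mean of (x + pc) as an explicit product
oracle_geomean <- function(x, pc = 1) prod(x + pc)^(1 / length(x))

# BH step-up from its definition: p_(i) * m / i, cumulative min from the top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# type-7 tertile assignment with explicit interpolation arithmetic,
# ties to the lower group
oracle_tertiles <- function(x) {
  srt <- sort(x)
  n <- length(x)
  qq <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    srt[lo + 1] + (h - lo) * (srt[min(lo + 2, n)] - srt[lo + 1])
  }
  q1 <- qq(1 / 3)
  q2 <- qq(2 / 3)
  ifelse(x <= q1, "low", ifelse(x <= q2, "intermediate", "high"))
}

# DBSCAN via igraph connected components over core-core eps edges;
# border points join an adjacent core's cluster (unique on the maps used)
oracle_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(cbind(x, y)))
  core <- rowSums(d <= eps) >= min_pts
  lab <- integer(n)
  if (any(core)) {
    adj <- d[core, core, drop = FALSE] <= eps
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    lab[core] <- igraph::components(g)$membership
    for (i in which(!core)) {
      near <- which(core & d[i, ] <= eps)
      if (length(near) > 0) lab[i] <- lab[near[1]]
    }
  }
  lab
}

# canonical form of a cluster labelling: relabel by first appearance,
# noise (0) kept as 0, so two labelings can be compared directly
canon_labels <- function(lab) {
  out <- integer(length(lab))
  nxt <- 0L
  seen <- c()
  for (i in seq_along(lab)) {
    if (lab[i] == 0L) next
    key <- as.character(lab[i])
    if (is.na(match(key, names(seen)))) {
      nxt <- nxt + 1L
      seen[key] <- nxt
    }
    out[i] <- seen[key]
  }
  out
}

# Breslow log partial likelihood evaluated from its definition
breslow_loglik <- function(beta, time, event, X) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(eta[dead]) - length(dead) * log(sum(exp(eta[risk])))
  }
  ll
}

# two-group log-rank chi-square by explicit risk-set tabulation
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# small expression fixture: g genes x s samples of Poisson counts
tiny_counts <- function(g = 8, s = 5, lambda = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(g * s, lambda), nrow = g,
              dimnames = list(paste0("G", seq_len(g)), paste0("S", seq_len(s))))
  as_expr_mat(m, unit = "counts")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
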