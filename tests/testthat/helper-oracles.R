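# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation it checks.

# pairwise shared-patient counts by explicit double loop over provider pairs
oracle_shared_counts <- function(visits, provider_ids) {
  pats <- lapply(provider_ids,
                 function(p) unique(visits$patient_id[visits$provider_id == p]))
  names(pats) <- provider_ids
  out <- list()
  for (i in seq_along(provider_ids)) for (j in seq_len(i - 1L)) {
    a <- provider_ids[j]; b <- provider_ids[i]
    out[[length(out) + 1L]] <- data.frame(
      provider_a = min(a, b), provider_b = max(a, b),
      shared = length(intersect(pats[[a]], pats[[b]])),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Newman modularity via the full double-sum over ordered vertex pairs:
# Q = (1/2W) * sum_ij (A_ij - k_i k_j / 2W) [c_i == c_j]
oracle_modularity <- function(graph, partition, weighted = TRUE) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  e <- graph$edges
  w <- if (weighted) e$weight else rep(1, nrow(e))
  for (i in seq_len(nrow(e))) {
    A[e$provider_a[i], e$provider_b[i]] <- A[e$provider_a[i], e$provider_b[i]] + w[i]
    A[e$provider_b[i], e$provider_a[i]] <- A[e$provider_b[i], e$provider_a[i]] + w[i]
  }
  W2 <- sum(A)                       # = 2W
  if (W2 == 0) return(NA_real_)
  k <- rowSums(A)
  cl <- as.character(partition[graph$nodes])
  same <- outer(cl, cl, "==")
  sum((A - outer(k, k) / W2) * same) / W2
}

# all set partitions of a vector (Bell-number enumeration, n <= ~8)
all_partitions <- function(items) {
  if (length(items) == 0) return(list(list()))
  if (length(items) == 1) return(list(list(items)))
  rest <- all_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p; q[[i]] <- c(items[1], q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(items[1]), p)
  }
  out
}

partition_to_membership <- function(p) {
  m <- unlist(lapply(seq_along(p), function(i) {
    stats::setNames(rep(i, length(p[[i]])), p[[i]])
  }))
  m
}

# exhaustive maximum-modularity partition of a small graph
oracle_max_modularity <- function(graph, weighted = TRUE) {
  best <- -Inf; best_p <- NULL
  for (p in all_partitions(graph$nodes)) {
    m <- partition_to_membership(p)
    q <- oracle_modularity(graph, m, weighted = weighted)
    if (!is.na(q) && q > best) { best <- q; best_p <- m }
  }
  list(q = best, membership = best_p)
}

# day-by-day PDC: mark each eligible calendar day covered/uncovered
oracle_pdc <- function(fills, window_start, window_end, diagnosis_date = NULL) {
  ws <- as.Date(window_start)
  if (!is.null(diagnosis_date) && !is.na(diagnosis_date))
    ws <- max(ws, as.Date(diagnosis_date))
  days <- seq(ws, as.Date(window_end), by = "day")
  if (length(days) == 0) return(NA_real_)
  covered <- rep(FALSE, length(days))
  if (!is.null(fills) && nrow(fills) > 0) {
    for (i in seq_len(nrow(fills))) {
      span <- seq(as.Date(fills$fill_date[i]),
                  as.Date(fills$fill_date[i]) + fills$days_supply[i] - 1,
                  by = "day")
      covered[days %in% span] <- TRUE
    }
  }
  mean(covered)
}

# random-intercept binomial-logit marginal log-likelihood by adaptive-free
# numeric integration over each cluster's intercept
oracle_glmm_loglik <- function(y, X, cluster, beta, sigma_b) {
  eta0 <- drop(X %*% beta)
  ll <- 0
  for (g in unique(cluster)) {
    idx <- cluster == g
    f <- function(b) {
      vapply(b, function(bi) {
        p <- plogis(eta0[idx] + bi)
        exp(sum(dbinom(y[idx], 1, p, log = TRUE))) * dnorm(bi, 0, sigma_b)
      }, numeric(1))
    }
    ll <- ll + log(integrate(f, -Inf, Inf, rel.tol = 1e-12)$value)
  }
  ll
}

# small helper: a shared_patient_graph built directly from an edge list
toy_graph <- function(edges, nodes = NULL, threshold = 1) {
  if (is.null(nodes))
    nodes <- sort(unique(c(edges$provider_a, edges$provider_b)))
  g <- list(area_id = "TOY", nodes = nodes, edges = edges,
            threshold = threshold)
  class(g) <- "shared_patient_graph"
  g
}

edge_df <- function(a, b, w = 1) {
  data.frame(provider_a = a, provider_b = b, weight = w,
             stringsAsFactors = FALSE)
}
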