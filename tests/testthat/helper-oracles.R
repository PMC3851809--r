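# Independent brute-force oracles. Everything here enumerates dyads,
# triples and geodesics directly from a 0/1 adjacency matrix -- no igraph,
# no shared code with the package internals -- so metric tests are a true
# dual-route check.

oracle_dyad_census <- function(A) {
  n <- nrow(A)
  m <- a <- nul <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- A[i, j] + A[j, i]
      if (s == 2) m <- m + 1L else if (s == 1) a <- a + 1L else nul <- nul + 1L
    }
  }
  list(mutual = m, asymmetric = a, null = nul)
}

oracle_density <- function(A) {
  n <- nrow(A)
  sum(A) / (n * (n - 1))
}

oracle_degree <- function(A) {
  data.frame(in_degree = as.integer(colSums(A)),
             out_degree = as.integer(rowSums(A)),
             total = as.integer(colSums(A) + rowSums(A)))
}

oracle_isolates <- function(A) {
  which(colSums(A) + rowSums(A) == 0)
}

oracle_reciprocity <- function(A) {
  dc <- oracle_dyad_census(A)
  arcs <- sum(A)
  list(arc_based = if (arcs > 0) 2 * dc$mutual / arcs else NA_real_,
       nonnull = if (dc$mutual + dc$asymmetric > 0) {
         dc$mutual / (dc$mutual + dc$asymmetric)
       } else NA_real_)
}

# Weak components among non-isolates via label propagation.
oracle_excess_components <- function(A) {
  keep <- which(colSums(A) + rowSums(A) > 0)
  if (!length(keep)) return(0L)
  S <- (A[keep, keep, drop = FALSE] + t(A[keep, keep, drop = FALSE])) > 0
  lab <- seq_along(keep)
  repeat {
    changed <- FALSE
    for (i in seq_along(keep)) {
      for (j in seq_along(keep)) {
        if (S[i, j] && lab[j] > lab[i]) { lab[j] <- lab[i]; changed <- TRUE }
        if (S[i, j] && lab[i] > lab[j]) { lab[i] <- lab[j]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  max(0L, length(unique(lab)) - 1L)
}

# All-pairs shortest path lengths by Floyd-Warshall.
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_compactness <- function(A) {
  D <- oracle_distances(A)
  n <- nrow(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_transitivity <- function(A) {
  n <- nrow(A)
  paths <- closed <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k && A[i, j] == 1 && A[j, k] == 1) {
      paths <- paths + 1L
      if (A[i, k] == 1) closed <- closed + 1L
    }
  }
  if (paths == 0) NA_real_ else closed / paths
}

# Geodesic counts via matrix powers: walks of minimal length are exactly
# the shortest paths. sigma[i,j] = number of shortest i->j paths.
oracle_geodesic_counts <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- matrix(0, n, n)
  P <- diag(n)
  maxd <- max(D[is.finite(D) & D > 0], 0)
  for (L in seq_len(max(1, maxd))) {
    P <- P %*% A
    hit <- which(D == L, arr.ind = TRUE)
    sigma[hit] <- P[hit]
    if (L >= maxd) break
  }
  list(D = D, sigma = sigma)
}

# Directed betweenness, scaled by (n-1)(n-2) as in the package convention.
oracle_betweenness_scaled <- function(A) {
  n <- nrow(A)
  gc <- oracle_geodesic_counts(A)
  D <- gc$D; sigma <- gc$sigma
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || i == v || j == v) next
      if (!is.finite(D[i, j])) next
      if (D[i, v] + D[v, j] == D[i, j]) {
        b[v] <- b[v] + sigma[i, v] * sigma[v, j] / sigma[i, j]
      }
    }
  }
  if (n > 2) b / ((n - 1) * (n - 2)) else b * 0
}

oracle_closeness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    r <- length(d)
    if (r == 0) 0 else (r / (n - 1)) * (r / sum(d))
  }, numeric(1))
}

oracle_centralization <- function(A, kind) {
  n <- nrow(A)
  cs <- switch(kind,
    degree = rowSums(A) + colSums(A),
    indegree = colSums(A),
    outdegree = rowSums(A),
    closeness = oracle_closeness(A),
    betweenness = oracle_betweenness_scaled(A))
  spread <- sum(max(cs) - cs)
  if (spread == 0) return(0)
  denom <- switch(kind,
    degree = 2 * (n - 1) * (n - 2),
    indegree = (n - 1)^2,
    outdegree = (n - 1)^2,
    closeness = n - 1,
    betweenness = n - 1)
  if (denom <= 0) return(NA_real_)
  spread / denom
}

# --- fixture builders -------------------------------------------------

# Network from an explicit adjacency matrix; everyone a respondent.
net_from_adjacency <- function(A, wave = "w1", relation = "advice") {
  n <- nrow(A)
  ros <- roster(as.character(seq_len(n)), paste0("P", seq_len(n)))
  idx <- which(A == 1, arr.ind = TRUE)
  arcs <- data.frame(ego = as.character(idx[, 1]),
                     alter = as.character(idx[, 2]),
                     stringsAsFactors = FALSE)
  new_sociometric_network(ros, wave, relation, arcs, ros$member_id)
}

# Random digraph adjacency (Bernoulli arcs, no self-loops).
random_adjacency <- function(n, p) {
  A <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(A) <- 0L
  A
}

# Second, independently coded node-resampling bootstrap for the density
# SE, looping over arcs instead of matrix masking.
oracle_bootstrap_se <- function(net, B, seed) {
  A <- adjacency_matrix(net)
  n <- nrow(A)
  set.seed(seed)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample(n, n, replace = TRUE)
    num <- 0L; den <- 0L
    for (p in seq_len(n)) for (q in seq_len(n)) {
      if (idx[p] != idx[q]) {
        den <- den + 1L
        num <- num + A[idx[p], idx[q]]
      }
    }
    reps[b] <- if (den > 0) num / den else NA_real_
  }
  stats::sd(reps, na.rm = TRUE)
}
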