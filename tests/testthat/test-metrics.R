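# Worked examples use networks whose dyad census pins the metric values
# exactly; structural cases (stars, cycles, paths, complete digraphs)
# check the centralization and distance conventions.

complete_adj <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}

test_that("dyad census partitions all pairs and counts arcs", {
  net <- simulate_dyad_census(n = 11, mutual = 3, asymmetric = 3, seed = 1)
  dc <- dyad_census(net)
  expect_equal(dc, list(mutual = 3L, asymmetric = 3L, null = 49L))
  expect_equal(2 * dc$mutual + dc$asymmetric, nrow(net$arcs))

  empty <- simulate_dyad_census(n = 11, mutual = 0, asymmetric = 0, seed = 1)
  expect_equal(dyad_census(empty), list(mutual = 0L, asymmetric = 0L,
                                        null = 55L))
  expect_equal(dyad_census(net_from_adjacency(complete_adj(3))),
               list(mutual = 3L, asymmetric = 0L, null = 0L))
})

test_that("density matches the published worked examples after rounding", {
  n9 <- simulate_dyad_census(n = 11, mutual = 3, asymmetric = 3, seed = 2)
  expect_equal(density(n9), 9 / 110)
  expect_equal(round_half_up(density(n9)), 0.082)
  n20 <- simulate_dyad_census(n = 11, mutual = 7, asymmetric = 6, seed = 2)
  expect_equal(round_half_up(density(n20)), 0.182)
  expect_equal(density(simulate_dyad_census(11, 0, 0, seed = 1)), 0)
  expect_equal(density(net_from_adjacency(complete_adj(5))), 1)
})

test_that("isolates are exactly the members with no incident ties", {
  d <- pilot_demo()
  expect_equal(isolates(d$networks$advice_week4),
               as.character(c(2, 4, 5, 6)))
  expect_equal(isolates(d$networks$advice_week12),
               as.character(c(2, 4, 5, 6)))
  expect_equal(isolates(net_from_adjacency(complete_adj(4))), character(0))
  empty <- simulate_dyad_census(n = 5, mutual = 0, asymmetric = 0, seed = 1)
  expect_equal(isolates(empty), empty$roster$member_id)
})

test_that("degree table counts in/out per member and sums to 2*arcs", {
  A <- matrix(0L, 3, 3)
  A[1, 2] <- 1L; A[2, 1] <- 1L; A[1, 3] <- 1L  # A<->B plus A->C
  deg <- degree_table(net_from_adjacency(A))
  expect_equal(deg$in_degree, c(1L, 1L, 1L))
  expect_equal(deg$out_degree, c(2L, 1L, 0L))
  expect_equal(deg$total[1], 3L)
  expect_equal(sum(deg$total), 2L * sum(A))

  deg4 <- degree_table(net_from_adjacency(complete_adj(4)))
  expect_true(all(deg4$total == 6L))
})

test_that("non-null reciprocity matches the dyad-census arithmetic", {
  r1 <- reciprocity(simulate_dyad_census(11, 3, 3, seed = 3))
  expect_equal(r1$nonnull, 0.5)
  r2 <- reciprocity(simulate_dyad_census(11, 7, 6, seed = 3))
  expect_equal(round_half_up(r2$nonnull), 0.538)
  r3 <- reciprocity(simulate_dyad_census(11, 1, 4, seed = 3))
  expect_equal(r3$nonnull, 0.2)

  all_mutual <- reciprocity(net_from_adjacency(complete_adj(4)))
  expect_equal(all_mutual, list(arc_based = 1, nonnull = 1))
  empty <- reciprocity(simulate_dyad_census(11, 0, 0, seed = 1))
  expect_true(is.na(empty$arc_based) && is.na(empty$nonnull))
})

test_that("subgroups are weak components among non-isolates", {
  # two separate mutual dyads -> one excess component
  A <- matrix(0L, 6, 6)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L
  cp <- components(net_from_adjacency(A))
  expect_equal(cp$excess, 1L)
  expect_equal(cp$membership, list(c("1", "2"), c("3", "4")))

  # directed chain over all non-isolates -> no excess
  B <- matrix(0L, 4, 4); B[1, 2] <- B[2, 3] <- B[3, 4] <- 1L
  expect_equal(components(net_from_adjacency(B))$excess, 0L)

  # the pre-existing pair in the demo data is a separate week-4 subgroup
  d <- pilot_demo()
  cp4 <- components(d$networks$advice_week4)
  expect_equal(cp4$excess, 1L)
  expect_true(any(vapply(cp4$membership, identical, TRUE, c("7", "8"))))
  expect_equal(components(d$networks$advice_week12)$excess, 0L)
})

test_that("centralization honors the stated conventions on stars and cycles", {
  # mutual star, n = 4: maximal total-degree concentration
  S <- matrix(0L, 4, 4); S[1, 2:4] <- 1L; S[2:4, 1] <- 1L
  expect_equal(centralization(net_from_adjacency(S), "degree"), 1)

  # cycle: all degrees equal
  C <- matrix(0L, 4, 4)
  C[cbind(1:4, c(2, 3, 4, 1))] <- 1L
  for (k in c("degree", "indegree", "outdegree", "closeness", "betweenness")) {
    expect_equal(centralization(net_from_adjacency(C), k), 0, label = k)
  }

  # out-star center->all, n = 4: indegree spread 1 over (n-1)^2 = 9
  O <- matrix(0L, 4, 4); O[1, 2:4] <- 1L
  expect_equal(centralization(net_from_adjacency(O), "indegree"), 1 / 9)
  # and the out-star maximizes closeness centralization
  expect_equal(centralization(net_from_adjacency(O), "closeness"), 1)

  expect_error(centralization(net_from_adjacency(S), "pagerank"))

  comp5 <- net_from_adjacency(complete_adj(5))
  for (k in c("degree", "indegree", "outdegree", "closeness", "betweenness")) {
    expect_equal(centralization(comp5, k), 0, label = k)
  }
})

test_that("transitivity percent closes directed two-paths, excluding i == k", {
  A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 3] <- A[1, 3] <- 1L
  expect_equal(transitivity_percent(net_from_adjacency(A)), 1)
  B <- matrix(0L, 3, 3); B[1, 2] <- B[2, 3] <- 1L
  expect_equal(transitivity_percent(net_from_adjacency(B)), 0)
  # a pure 2-cycle has no qualifying two-paths at all
  M <- matrix(0L, 3, 3); M[1, 2] <- M[2, 1] <- 1L
  expect_true(is.na(transitivity_percent(net_from_adjacency(M))))
  empty <- simulate_dyad_census(n = 4, mutual = 0, asymmetric = 0, seed = 1)
  expect_true(is.na(transitivity_percent(empty)))
  expect_equal(transitivity_percent(net_from_adjacency(complete_adj(5))), 1)
})

test_that("compactness cohesion averages reciprocal geodesic distances", {
  expect_equal(cohesion_compactness(net_from_adjacency(complete_adj(6))), 1)
  empty <- simulate_dyad_census(n = 6, mutual = 0, asymmetric = 0, seed = 1)
  expect_equal(cohesion_compactness(empty), 0)
  # path 1->2->3: pairs (1,2)=1, (2,3)=1, (1,3)=1/2, rest unreachable
  P <- matrix(0L, 3, 3); P[1, 2] <- P[2, 3] <- 1L
  expect_equal(cohesion_compactness(net_from_adjacency(P)), 2.5 / 6)
})

test_that("metrics panel aggregates and the table export rounds half-up", {
  d <- pilot_demo()
  p <- metrics_panel(d$networks$advice_week4)
  expect_equal(p$arc_count, 9)
  expect_equal(p$n, 11)
  expect_equal(p$dyads$mutual, 3)

  empty <- metrics_panel(simulate_dyad_census(11, 0, 0, seed = 1))
  expect_equal(empty$density, 0)
  expect_length(empty$isolate_ids, 11)
  expect_true(is.na(empty$reciprocity_nonnull))

  full <- metrics_panel(net_from_adjacency(complete_adj(5)))
  expect_equal(full$density, 1)
  expect_equal(full$centralization_degree, 0)
  expect_equal(full$transitivity_pct, 1)
  expect_equal(full$cohesion_compactness, 1)

  tab <- export_metrics_table(list(
    metrics_panel(d$networks$advice_week4),
    metrics_panel(d$networks$advice_week12),
    metrics_panel(d$networks$discussion_week4),
    metrics_panel(d$networks$discussion_week12)))
  expect_equal(tab$density, c(0.082, 0.182, 0.027, 0.055))
  expect_equal(tab$reciprocity_nonnull, c(0.5, 0.538, 0, 0.2))
  expect_equal(tab$size, rep(11, 4))
})

test_that("every metric agrees with brute-force enumeration on random digraphs", {
  set.seed(4711)
  n_graphs <- 300
  for (g in seq_len(n_graphs)) {
    n <- sample(2:7, 1)
    A <- random_adjacency(n, p = stats::runif(1, 0.05, 0.9))
    net <- net_from_adjacency(A)
    p <- metrics_panel(net)
    expect_equal(p$dyads, oracle_dyad_census(A))
    expect_equal(p$density, oracle_density(A))
    expect_equal(p$degree_rows[, -1],
                 oracle_degree(A), ignore_attr = TRUE)
    expect_equal(match(p$isolate_ids, net$roster$member_id),
                 oracle_isolates(A), ignore_attr = TRUE)
    rec <- oracle_reciprocity(A)
    expect_equal(p$reciprocity_arc, rec$arc_based)
    expect_equal(p$reciprocity_nonnull, rec$nonnull)
    expect_equal(p$excess_components, oracle_excess_components(A))
    expect_equal(p$transitivity_pct, oracle_transitivity(A))
    expect_equal(p$cohesion_compactness, oracle_compactness(A))
    for (k in c("degree", "indegree", "outdegree", "closeness",
                "betweenness")) {
      expect_equal(centralization(net, k), oracle_centralization(A, k),
                   label = paste("centralization", k, "graph", g))
    }
  }
})

test_that("metrics are permutation-equivariant and monotone in arcs", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    A <- random_adjacency(n, 0.3)
    perm <- sample(n)
    B <- A[perm, perm]
    pa <- metrics_panel(net_from_adjacency(A))
    pb <- metrics_panel(net_from_adjacency(B))
    expect_equal(pa$density, pb$density)
    expect_equal(pa$reciprocity_nonnull, pb$reciprocity_nonnull)
    expect_equal(pa$transitivity_pct, pb$transitivity_pct)
    expect_equal(pa$cohesion_compactness, pb$cohesion_compactness)
    expect_equal(pa$centralization_degree, pb$centralization_degree)
    expect_equal(pa$excess_components, pb$excess_components)

    # adding one absent arc strictly increases density, never decreases
    # compactness
    absent <- which(A == 0L & !diag(TRUE, n), arr.ind = TRUE)
    if (nrow(absent)) {
      pick <- absent[sample(nrow(absent), 1), ]
      A2 <- A; A2[pick[1], pick[2]] <- 1L
      p2 <- metrics_panel(net_from_adjacency(A2))
      expect_gt(p2$density, pa$density)
      expect_gte(p2$cohesion_compactness, pa$cohesion_compactness)
    }
  }

  # symmetric networks: both reciprocity conventions equal 1
  set.seed(100)
  for (rep in 1:10) {
    A <- random_adjacency(6, 0.4)
    S <- ((A + t(A)) > 0) * 1L
    if (sum(S) == 0) next
    r <- reciprocity(net_from_adjacency(S))
    expect_equal(r$arc_based, 1)
    expect_equal(r$nonnull, 1)
  }
})
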