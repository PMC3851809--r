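# Whole-network and individual diagnostics for a sociometric_network.
# All values are kept at full precision internally; rounding happens only
# at presentation (round_half_up, export_metrics_table, report rendering).
# A 0/0 metric is "undefined" and returned as NA_real_, never as 0.

#' Round half away from zero
#'
#' Presentation rounding used in all rendered tables (3 decimals, half-up),
#' as opposed to base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector; NA passes through.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Dyad census (mutual / asymmetric / null)
#'
#' Classifies every unordered node pair: mutual (arcs both ways),
#' asymmetric (one arc), or null (no arc). The census underlies the
#' non-null reciprocity diagnostic.
#'
#' @param net A `sociometric_network`.
#' @return List with integer fields `mutual`, `asymmetric`, `null`;
#'   `mutual + asymmetric + null == n(n-1)/2` and
#'   `arcs == 2*mutual + asymmetric`.
#' @examples
#' net <- simulate_dyad_census(n = 11, mutual = 3, asymmetric = 3, seed = 1)
#' dyad_census(net)  # 3 mutual, 3 asymmetric, 49 null
#' @export
dyad_census <- function(net) {
  A <- adjacency_matrix(net)
  B <- A + t(A)
  up <- upper.tri(B)
  mutual <- sum(B[up] == 2L)
  asymmetric <- sum(B[up] == 1L)
  nulls <- sum(B[up] == 0L)
  list(mutual = mutual, asymmetric = asymmetric, null = nulls)
}

#' Network density
#'
#' Arcs present divided by the `n(n-1)` possible arcs of a digraph with no
#' self-loops. All roster members count in the denominator, including
#' survey non-respondents.
#'
#' Implemented as a method on the `stats::density` generic so the natural
#' `density(net)` call dispatches here.
#'
#' @param x A `sociometric_network`.
#' @param ... Unused.
#' @return Fraction in \[0, 1\].
#' @importFrom stats density
#' @export
density.sociometric_network <- function(x, ...) {
  if (x$n < 2) stop("density is undefined for n < 2")
  nrow(x$arcs) / (x$n * (x$n - 1))
}

#' Isolates
#'
#' Members with neither incoming nor outgoing ties. Isolation is the most
#' actionable individual diagnostic: an unconnected member cannot receive
#' anything through the network.
#'
#' @param net A `sociometric_network`.
#' @return Character vector of member_ids in roster order (possibly empty).
#' @export
isolates <- function(net) {
  deg <- degree_table(net)
  deg$member_id[deg$total == 0L]
}

#' Per-member degree table
#'
#' @param net A `sociometric_network`.
#' @return Data frame in roster order: `member_id`, `in_degree` (times
#'   nominated), `out_degree` (nominations made), `total`. Totals sum to
#'   twice the arc count.
#' @export
degree_table <- function(net) {
  A <- adjacency_matrix(net)
  data.frame(member_id = net$roster$member_id,
             in_degree = as.integer(colSums(A)),
             out_degree = as.integer(rowSums(A)),
             total = as.integer(colSums(A) + rowSums(A)),
             stringsAsFactors = FALSE)
}

#' Reciprocity
#'
#' Two conventions are reported. Arc-based: the fraction of arcs that are
#' returned (`2*mutual / arcs`). Non-null dyad-based (the headline
#' diagnostic): mutual dyads over non-null dyads
#' (`mutual / (mutual + asymmetric)`). Both are `NA` (undefined) when the
#' denominator is zero, e.g. in an empty network.
#'
#' @param net A `sociometric_network`.
#' @return List with `arc_based` and `nonnull` fractions (NA if undefined).
#' @export
reciprocity <- function(net) {
  dc <- dyad_census(net)
  arcs <- 2L * dc$mutual + dc$asymmetric
  list(
    arc_based = if (arcs > 0) 2 * dc$mutual / arcs else NA_real_,
    nonnull = if (dc$mutual + dc$asymmetric > 0) {
      dc$mutual / (dc$mutual + dc$asymmetric)
    } else NA_real_
  )
}

#' Subgroups: weak components among connected members
#'
#' Weakly connected components (direction ignored) computed on the
#' non-isolate members only, so that isolation and splintering are
#' distinct findings. `excess` counts components beyond the first; any
#' value above 0 means the connected part of the group has split into
#' separate subgroups.
#'
#' @param net A `sociometric_network`.
#' @return List: `excess` (integer >= 0) and `membership`, a list of
#'   character vectors of member_ids, one per component, largest first
#'   (ties broken by roster order); empty list if every member is isolated.
#' @export
components <- function(net) {
  iso <- isolates(net)
  keep <- setdiff(net$roster$member_id, iso)
  if (!length(keep)) {
    return(list(excess = 0L, membership = list()))
  }
  g <- igraph::induced_subgraph(as_igraph(net), keep)
  comp <- igraph::components(g, mode = "weak")
  ids <- igraph::V(g)$name
  membership <- split(ids, comp$membership)
  # roster order inside each component; largest component first
  membership <- lapply(membership, function(m) {
    m[order(match(m, net$roster$member_id))]
  })
  o <- order(-vapply(membership, length, 1L),
             vapply(membership, function(m) {
               match(m[1], net$roster$member_id)
             }, 1L))
  membership <- unname(membership[o])
  list(excess = max(0L, comp$no - 1L), membership = membership)
}

# Per-node centrality scores for each supported kind, on the scale used by
# the corresponding centralization denominator.
centrality_scores <- function(net, kind) {
  A <- adjacency_matrix(net)
  n <- net$n
  switch(kind,
    degree = rowSums(A) + colSums(A),
    indegree = colSums(A),
    outdegree = rowSums(A),
    closeness = {
      g <- as_igraph(net)
      D <- igraph::distances(g, mode = "out")
      apply(D, 1, function(d) {
        d <- d[is.finite(d)]
        d <- d[d > 0]
        r <- length(d) # nodes reachable, excluding self
        if (r == 0) 0 else (r / (n - 1)) * (r / sum(d))
      })
    },
    betweenness = {
      g <- as_igraph(net)
      b <- igraph::betweenness(g, directed = TRUE)
      if (n > 2) b / ((n - 1) * (n - 2)) else b * 0
    },
    stop("unknown centralization kind: ", kind)
  )
}

#' Freeman centralization
#'
#' How concentrated the network is on its most central member:
#' `sum(c_max - c_i)` over all members, divided by the theoretical maximum
#' of that sum for a network of the same size, so the result lies in
#' \[0, 1\] (0 = everyone equally central, 1 = a perfect star).
#'
#' Conventions, per kind (the literature admits several; these are fixed
#' here and used consistently):
#' \describe{
#'   \item{degree}{total (in + out) degree; maximum `2(n-1)(n-2)`,
#'     attained by a star of mutual ties.}
#'   \item{indegree, outdegree}{raw in-/out-degree; maximum `(n-1)^2`.}
#'   \item{closeness}{reachability-scaled closeness
#'     `(r/(n-1)) * (r / sum of distances to the r reachable nodes)`,
#'     0 for a node that reaches no one; maximum sum `n-1`, attained by an
#'     out-star.}
#'   \item{betweenness}{directed shortest-path betweenness scaled by
#'     `(n-1)(n-2)`; maximum sum `n-1`.}
#' }
#'
#' @param net A `sociometric_network`.
#' @param kind One of `"degree"`, `"indegree"`, `"outdegree"`,
#'   `"closeness"`, `"betweenness"`.
#' @return Fraction in \[0, 1\]; exactly 0 when all members are equally
#'   central (and for the degenerate n = 2 degree case).
#' @export
centralization <- function(net, kind = c("degree", "indegree", "outdegree",
                                         "closeness", "betweenness")) {
  kind <- match.arg(kind)
  n <- net$n
  cs <- centrality_scores(net, kind)
  spread <- sum(max(cs) - cs)
  if (spread == 0) return(0)
  denom <- switch(kind,
    degree = 2 * (n - 1) * (n - 2),
    indegree = (n - 1)^2,
    outdegree = (n - 1)^2,
    closeness = n - 1,
    betweenness = n - 1
  )
  if (denom <= 0) return(NA_real_)
  spread / denom
}

#' Transitivity percent
#'
#' The fraction of directed two-paths i -> j -> k (i, j, k distinct) that
#' are closed by a direct arc i -> k: the tendency for the contact of a
#' contact to become a contact. Two-paths returning to their origin
#' (i == k) are excluded. Undefined (NA) when the network has no
#' qualifying two-paths.
#'
#' @param net A `sociometric_network`.
#' @return Fraction in \[0, 1\], or NA when undefined.
#' @export
transitivity_percent <- function(net) {
  A <- adjacency_matrix(net)
  P <- A %*% A          # P[i,k] = # two-paths i->j->k (j != i,k as diag(A)=0)
  diag(P) <- 0          # drop i == k
  paths <- sum(P)
  if (paths == 0) return(NA_real_)
  sum(P * A) / paths
}

#' Compactness cohesion
#'
#' Mean of reciprocal geodesic distances over all ordered pairs of
#' distinct roster members, with unreachable pairs contributing 0
#' (1/infinity). Ranges from 0 (no ties at all) to 1 (everyone directly
#' tied to everyone). Unlike average path length it is defined for
#' disconnected networks, which early-stage intervention groups usually
#' are.
#'
#' @param net A `sociometric_network`.
#' @return Fraction in \[0, 1\].
#' @export
cohesion_compactness <- function(net) {
  stopifnot(inherits(net, "sociometric_network"))
  if (net$n < 2) stop("cohesion is undefined for n < 2")
  D <- igraph::distances(as_igraph(net), mode = "out")
  inv <- 1 / D                      # 1/Inf = 0
  diag(inv) <- 0
  sum(inv) / (net$n * (net$n - 1))
}

#' Full diagnostic panel for one network
#'
#' Computes every whole-network and individual diagnostic at once. Values
#' are unrounded; use [export_metrics_table()] or the report renderers for
#' presentation.
#'
#' @param net A `sociometric_network`.
#' @return A `metrics_panel` list: `wave`, `relation`, `n`, `arc_count`,
#'   `density`, `isolate_ids`, `degree_rows`, `dyads`, `reciprocity_arc`,
#'   `reciprocity_nonnull`, `excess_components`, `component_membership`,
#'   `centralization_degree`, `centralization_indegree`,
#'   `centralization_outdegree`, `centralization_closeness`,
#'   `centralization_betweenness`, `transitivity_pct`,
#'   `cohesion_compactness`.
#' @examples
#' net <- simulate_dyad_census(n = 11, mutual = 3, asymmetric = 3, seed = 1)
#' p <- metrics_panel(net)
#' round_half_up(p$density)             # 0.082
#' round_half_up(p$reciprocity_nonnull) # 0.5
#' @export
metrics_panel <- function(net) {
  stopifnot(inherits(net, "sociometric_network"))
  dc <- dyad_census(net)
  rec <- reciprocity(net)
  comp <- components(net)
  structure(list(
    wave = net$wave,
    relation = net$relation,
    n = net$n,
    arc_count = nrow(net$arcs),
    density = density(net),
    isolate_ids = isolates(net),
    degree_rows = degree_table(net),
    dyads = dc,
    reciprocity_arc = rec$arc_based,
    reciprocity_nonnull = rec$nonnull,
    excess_components = comp$excess,
    component_membership = comp$membership,
    centralization_degree = centralization(net, "degree"),
    centralization_indegree = centralization(net, "indegree"),
    centralization_outdegree = centralization(net, "outdegree"),
    centralization_closeness = centralization(net, "closeness"),
    centralization_betweenness = centralization(net, "betweenness"),
    transitivity_pct = transitivity_percent(net),
    cohesion_compactness = cohesion_compactness(net)
  ), class = "metrics_panel")
}

#' @export
print.metrics_panel <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "undefined", round_half_up(v))
  cat(sprintf("Diagnostics (%s, %s): n = %d, arcs = %d\n",
              x$wave, x$relation, x$n, x$arc_count))
  cat(sprintf("  density               %s\n", fmt(x$density)))
  cat(sprintf("  isolates              %s\n",
              if (length(x$isolate_ids)) {
                paste(x$isolate_ids, collapse = ", ")
              } else "none"))
  cat(sprintf("  reciprocity (non-null) %s  (arc-based %s)\n",
              fmt(x$reciprocity_nonnull), fmt(x$reciprocity_arc)))
  cat(sprintf("  excess components     %d\n", x$excess_components))
  cat(sprintf("  centralization (deg)  %s\n", fmt(x$centralization_degree)))
  cat(sprintf("  transitivity percent  %s\n", fmt(x$transitivity_pct)))
  cat(sprintf("  cohesion (compactness) %s\n", fmt(x$cohesion_compactness)))
  invisible(x)
}

#' Export a metrics table for one or more panels
#'
#' One row per (wave, relation), columns in the conventional reporting
#' order: size, density, reciprocity non-nulls, centralization,
#' transitivity percent, cohesion. Values presentation-rounded to 3
#' decimals, half-up; undefined metrics print as NA.
#'
#' @param panels A `metrics_panel` or list of them.
#' @param file Optional CSV output path.
#' @return The table (invisibly if written to file).
#' @export
export_metrics_table <- function(panels, file = NULL) {
  if (inherits(panels, "metrics_panel")) panels <- list(panels)
  tab <- do.call(rbind, lapply(panels, function(p) {
    data.frame(wave = p$wave, relation = p$relation, size = p$n,
               density = round_half_up(p$density),
               reciprocity_nonnull = round_half_up(p$reciprocity_nonnull),
               centralization = round_half_up(p$centralization_degree),
               transitivity_pct = round_half_up(p$transitivity_pct),
               cohesion = round_half_up(p$cohesion_compactness),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(file)) {
    utils::write.table(tab, file, sep = ",", row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
    return(invisible(tab))
  }
  tab
}
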