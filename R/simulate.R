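# Synthetic data generators. The dyad-census generator is EXACT (the
# requested census is always achieved, not merely in expectation) so that
# worked examples built on it are deterministic given a seed.

default_roster <- function(n, group_id = "simulated") {
  names_pool <- c("Ana", "Ben", "Cara", "Dev", "Ema", "Finn", "Gia", "Hugo",
                  "Iris", "Jon", "Kim", "Lev", "Mara", "Nico", "Orla", "Pia",
                  "Quin", "Rosa", "Sam", "Tess", "Uma", "Vik", "Wren", "Xia",
                  "Yara", "Zeno")
  nm <- rep(names_pool, length.out = n)
  if (n > length(names_pool)) {
    nm <- paste0(nm, rep(seq_len(ceiling(n / length(names_pool))),
                         each = length(names_pool))[seq_len(n)])
  }
  roster(as.character(seq_len(n)), nm, group_id = group_id)
}

#' Simulate a network with an exact dyad census
#'
#' Uniformly chooses which unordered pairs are mutual and which are
#' asymmetric (direction uniform at random); all other pairs stay null.
#' The census is exact, so density and non-null reciprocity of the result
#' are fully determined by `(n, mutual, asymmetric)`.
#'
#' @param n Number of members (roster is generated; or pass `roster`).
#' @param mutual Number of mutual dyads.
#' @param asymmetric Number of asymmetric dyads.
#' @param seed Integer seed.
#' @param roster Optional [roster()] overriding `n`.
#' @param wave,relation Labels for the resulting network.
#' @return A `sociometric_network` with all members marked respondents.
#' @examples
#' net <- simulate_dyad_census(n = 11, mutual = 3, asymmetric = 3, seed = 7)
#' density(net) * 110  # 9 arcs
#' @export
simulate_dyad_census <- function(n, mutual, asymmetric, seed,
                                 roster = NULL, wave = "wave1",
                                 relation = "advice") {
  if (is.null(roster)) roster <- default_roster(n)
  stopifnot(inherits(roster, "roster"))
  n <- nrow(roster)
  ndyads <- n * (n - 1) / 2
  if (mutual < 0 || asymmetric < 0 || mutual + asymmetric > ndyads) {
    stop("infeasible dyad census: ", mutual, " mutual + ", asymmetric,
         " asymmetric > ", ndyads, " dyads for n = ", n)
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  arcs <- with_seed(seed, function() {
    chosen <- sample.int(nrow(pairs), mutual + asymmetric)
    mut <- chosen[seq_len(mutual)]
    asym <- chosen[setdiff(seq_len(mutual + asymmetric), seq_len(mutual))]
    flip <- stats::runif(length(asym)) < 0.5
    ids <- roster$member_id
    rbind(
      data.frame(ego = ids[pairs[mut, 1]], alter = ids[pairs[mut, 2]]),
      data.frame(ego = ids[pairs[mut, 2]], alter = ids[pairs[mut, 1]]),
      data.frame(ego = ids[ifelse(flip, pairs[asym, 2], pairs[asym, 1])],
                 alter = ids[ifelse(flip, pairs[asym, 1], pairs[asym, 2])])
    )
  })
  new_sociometric_network(roster, wave, relation, arcs, roster$member_id)
}

#' Simulate two waves of network evolution
#'
#' Wave 1 comes from an exact dyad census; wave 2 keeps each wave-1 arc
#' with probability `retention_prob` and adds each absent arc with
#' probability `formation_prob`, emulating the growth of ties over a group
#' intervention. Respondent patterns are applied per wave: a
#' non-respondent contributes no outgoing arcs at that wave (their
#' incoming arcs are kept -- others can still nominate them).
#'
#' @param n,mutual,asymmetric,seed Wave-1 census (see
#'   [simulate_dyad_census()]).
#' @param retention_prob Probability a wave-1 arc survives to wave 2.
#' @param formation_prob Probability an absent arc forms by wave 2.
#' @param respondents1,respondents2 Optional member_id subsets who
#'   responded at each wave; default everyone.
#' @param roster Optional [roster()] overriding `n`.
#' @param waves Labels for the two waves.
#' @param relation Relation label.
#' @return List of two `sociometric_network`s.
#' @export
simulate_two_waves <- function(n, mutual, asymmetric, seed,
                               retention_prob, formation_prob,
                               respondents1 = NULL, respondents2 = NULL,
                               roster = NULL,
                               waves = c("wave1", "wave2"),
                               relation = "advice") {
  stopifnot(retention_prob >= 0, retention_prob <= 1,
            formation_prob >= 0, formation_prob <= 1)
  if (is.null(roster)) roster <- default_roster(n)
  net1 <- simulate_dyad_census(nrow(roster), mutual, asymmetric, seed,
                               roster = roster, wave = waves[1],
                               relation = relation)
  ids <- roster$member_id
  if (is.null(respondents1)) respondents1 <- ids
  if (is.null(respondents2)) respondents2 <- ids
  A1 <- adjacency_matrix(net1)
  # non-respondents contribute no outgoing arcs
  A1[!(ids %in% respondents1), ] <- 0L
  A2 <- with_seed(seed + 1L, function() {
    U <- matrix(stats::runif(length(A1)), nrow(A1))
    keep <- A1 == 1L & U < retention_prob
    form <- A1 == 0L & U < formation_prob
    out <- (keep | form) * 1L
    diag(out) <- 0L
    out[!(ids %in% respondents2), ] <- 0L
    out
  })
  arcs1 <- which(A1 == 1L, arr.ind = TRUE)
  arcs2 <- which(A2 == 1L, arr.ind = TRUE)
  net1 <- new_sociometric_network(
    roster, waves[1], relation,
    data.frame(ego = ids[arcs1[, 1]], alter = ids[arcs1[, 2]]),
    respondents1)
  net2 <- new_sociometric_network(
    roster, waves[2], relation,
    data.frame(ego = ids[arcs2[, 1]], alter = ids[arcs2[, 2]]),
    respondents2)
  list(net1, net2)
}

#' Simulate a digraph with sender/receiver heterogeneity
#'
#' Bernoulli digraph with node-level random effects: member i nominates
#' member j with probability `plogis(qlogis(density) + a_i + b_j)` where
#' the activity effects `a` and popularity effects `b` are
#' `Normal(0, effects_sd)`. With `effects_sd = 0` this reduces to an
#' Erdos-Renyi digraph; positive values reproduce the row/column
#' dependence (talkative and popular members) typical of real sociometric
#' data, which is exactly the dependence the node-resampling bootstrap is
#' designed to handle -- so this generator is the package's null model for
#' calibration studies of [paired_density_test()].
#'
#' @param n Number of members.
#' @param density Expected tie probability at zero effects (logit
#'   intercept scale).
#' @param effects_sd SD of the activity and popularity effects on the
#'   logit scale.
#' @param seed Integer seed.
#' @param roster Optional [roster()] overriding `n`.
#' @param wave,relation Labels.
#' @return A `sociometric_network` with all members marked respondents.
#' @export
simulate_heterogeneous <- function(n, density = 0.18, effects_sd = 1, seed,
                                   roster = NULL, wave = "wave1",
                                   relation = "advice") {
  stopifnot(density > 0, density < 1, effects_sd >= 0)
  if (is.null(roster)) roster <- default_roster(n)
  n <- nrow(roster)
  A <- with_seed(seed, function() {
    a <- stats::rnorm(n, 0, effects_sd)
    b <- stats::rnorm(n, 0, effects_sd)
    P <- stats::plogis(outer(a, b, "+") + stats::qlogis(density))
    M <- matrix(as.integer(stats::runif(n * n) < P), n, n)
    diag(M) <- 0L
    M
  })
  ids <- roster$member_id
  idx <- which(A == 1L, arr.ind = TRUE)
  new_sociometric_network(
    roster, wave, relation,
    data.frame(ego = ids[idx[, 1]], alter = ids[idx[, 2]]), ids)
}

#' Simulate Perceived Cohesion Scale responses
#'
#' One-factor model with a ceiling: each respondent has a latent cohesion
#' level `~ Normal(latent_mean, latent_sd)`; item j is
#' `round(latent * loading_j + noise)` truncated to the 1-7 Likert range.
#' With a high `latent_mean` this reproduces the ceiling effect typical of
#' socially desirable self-reports in small groups.
#'
#' @param n_respondents Number of respondents.
#' @param loadings Six item loadings in \[0, 1\].
#' @param latent_mean,latent_sd Latent factor distribution.
#' @param noise_sd Item-level noise SD.
#' @param seed Integer seed.
#' @param wave Wave label.
#' @param member_ids Optional ids (default `"1".."n"`).
#' @return A `pcs_responses` data frame.
#' @export
simulate_pcs <- function(n_respondents, loadings = rep(0.85, 6),
                         latent_mean = 5, latent_sd = 1, noise_sd = 0.5,
                         seed, wave = "wave1", member_ids = NULL) {
  stopifnot(length(loadings) == 6, all(loadings >= 0), all(loadings <= 1))
  if (is.null(member_ids)) member_ids <- as.character(seq_len(n_respondents))
  m <- with_seed(seed, function() {
    latent <- stats::rnorm(n_respondents, latent_mean, latent_sd)
    sapply(loadings, function(l) {
      raw <- round(latent * l + stats::rnorm(n_respondents, 0, noise_sd))
      pmin(7, pmax(1, raw))
    })
  })
  m <- matrix(m, nrow = n_respondents)
  df <- data.frame(wave = wave, member_id = member_ids,
                   stringsAsFactors = FALSE)
  for (j in 1:6) df[[paste0("item", j)]] <- m[, j]
  pcs_responses(df)
}

#' Deterministic pilot-shaped demonstration dataset
#'
#' A hand-constructed 11-member group emulating the shape of a small
#' two-wave group intervention study: 8 of 11 members respond at wave 1
#' ("week4") and 7 of 11 at wave 2 ("week12"); four members (ids 2, 4, 5,
#' 6) are isolates at both waves; two members (ids 7, 8) start as a
#' separate pre-existing pair and are integrated into the main cluster by
#' wave 2. Dyad censuses: advice (3 mutual, 3 asymmetric) then (7, 6) --
#' densities 9/110 and 20/110; discussion (0, 3) then (1, 4) -- densities
#' 3/110 and 6/110.
#'
#' @return List: `roster`, `nominations` (record data frame),
#'   `respondents` (per-wave id lists), `networks` (named list
#'   advice/discussion x week4/week12), `pcs` (simulated high-scoring
#'   responses, 8 then 7 respondents, fixed internal seed).
#' @export
pilot_demo <- function() {
  ros <- roster(as.character(1:11),
                c("Tammy", "Brooke", "Carmen", "Dana", "Eve", "Faith",
                  "Michelle", "Natalie", "Imani", "Jada", "Keisha"),
                group_id = "demo")
  arc <- function(wave, relation, ego, alter) {
    data.frame(wave = wave, relation = relation, ego = as.character(ego),
               alter = as.character(alter), stringsAsFactors = FALSE)
  }
  mutual <- function(wave, relation, a, b) {
    rbind(arc(wave, relation, a, b), arc(wave, relation, b, a))
  }
  noms <- rbind(
    # advice, week4: mutual 1-3, 7-8, 9-10; asymmetric 11->1, 3->9, 10->11
    mutual("week4", "advice", 1, 3),
    mutual("week4", "advice", 7, 8),
    mutual("week4", "advice", 9, 10),
    arc("week4", "advice", 11, 1),
    arc("week4", "advice", 3, 9),
    arc("week4", "advice", 10, 11),
    # advice, week12: mutual 1-3, 1-9, 1-10, 1-11, 3-9, 9-10, 7-8;
    # asymmetric 7->1, 8->9, 10->7, 11->3, 10->3, 11->9
    mutual("week12", "advice", 1, 3),
    mutual("week12", "advice", 1, 9),
    mutual("week12", "advice", 1, 10),
    mutual("week12", "advice", 1, 11),
    mutual("week12", "advice", 3, 9),
    mutual("week12", "advice", 9, 10),
    mutual("week12", "advice", 7, 8),
    arc("week12", "advice", 7, 1),
    arc("week12", "advice", 8, 9),
    arc("week12", "advice", 10, 7),
    arc("week12", "advice", 11, 3),
    arc("week12", "advice", 10, 3),
    arc("week12", "advice", 11, 9),
    # discussion, week4: asymmetric 1->3, 9->10, 7->8
    arc("week4", "discussion", 1, 3),
    arc("week4", "discussion", 9, 10),
    arc("week4", "discussion", 7, 8),
    # discussion, week12: mutual 9-10; asymmetric 1->3, 3->9, 11->1, 7->8
    mutual("week12", "discussion", 9, 10),
    arc("week12", "discussion", 1, 3),
    arc("week12", "discussion", 3, 9),
    arc("week12", "discussion", 11, 1),
    arc("week12", "discussion", 7, 8)
  )
  respondents <- list(week4 = as.character(c(1, 2, 3, 7, 8, 9, 10, 11)),
                      week12 = as.character(c(1, 3, 7, 8, 9, 10, 11)))
  networks <- list()
  for (rel in c("advice", "discussion")) {
    for (w in c("week4", "week12")) {
      networks[[paste(rel, w, sep = "_")]] <-
        build_network(noms, ros, w, rel, respondents[[w]])
    }
  }
  # latent means chosen so item means sit near the scale ceiling
  # (latent * loading of about 6.1 then 6.6 on the 1-7 scale), emulating
  # the high-score, limited-variability pattern of self-reported cohesion
  pcs <- rbind(
    simulate_pcs(8, latent_mean = 7.2, latent_sd = 0.8, noise_sd = 0.5,
                 seed = 20260101, wave = "week4",
                 member_ids = respondents$week4),
    simulate_pcs(7, latent_mean = 7.75, latent_sd = 0.7, noise_sd = 0.5,
                 seed = 20260102, wave = "week12",
                 member_ids = respondents$week12)
  )
  list(roster = ros, nominations = noms, respondents = respondents,
       networks = networks, pcs = pcs_responses(pcs, ros))
}

#' Write the demonstration dataset as survey CSV files
#'
#' Emits `roster.csv`, `nominations.csv` and `pcs.csv` in the formats
#' [read_roster()], [read_nominations()] and [read_pcs()] consume.
#'
#' @param dir Output directory (created if needed).
#' @param demo Dataset from [pilot_demo()] (the default) or a list with
#'   the same shape.
#' @return Named character vector of the three file paths.
#' @export
write_demo_csvs <- function(dir, demo = pilot_demo()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(roster = file.path(dir, "roster.csv"),
             nominations = file.path(dir, "nominations.csv"),
             pcs = file.path(dir, "pcs.csv"))
  write_roster(demo$roster, paths["roster"])
  write_nominations(demo$nominations, paths["nominations"])
  write_pcs(demo$pcs, paths["pcs"])
  paths
}
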