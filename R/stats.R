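# Node-resampling bootstrap for density comparisons, and Perceived
# Cohesion Scale psychometrics.
#
# Dyadic observations in one network are not independent (each member
# contributes to n-1 of them), so a classical t-test on tie indicators is
# invalid. The bootstrap here resamples whole NODES with replacement and
# rebuilds the network each node sample induces, which preserves the
# row/column dependence structure. Dyads formed by two copies of the same
# original node have no defined tie value and are excluded from both the
# numerator and the denominator of a replicate's density.

# Run fn() with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, fn) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("a single integer seed is required for reproducibility")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

# Density of the network induced by node sample idx on adjacency A,
# same-node dyads excluded. NA if every off-diagonal pair is excluded.
induced_density <- function(A, idx) {
  S <- A[idx, idx, drop = FALSE]
  keep <- outer(idx, idx, "!=")
  denom <- sum(keep)
  if (denom == 0) return(NA_real_)
  sum(S[keep]) / denom
}

#' Bootstrap standard error of network density
#'
#' Node-resampling bootstrap: each replicate draws n members with
#' replacement and measures the density of the induced network (arcs
#' inherited from the original members at the sampled positions;
#' same-member dyads excluded). The SE is the standard deviation of the
#' replicate densities.
#'
#' @param net A `sociometric_network` with at least 3 members.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed, mandatory for reproducibility.
#' @return The bootstrap standard error (single number).
#' @export
bootstrap_density_se <- function(net, B = 5000, seed) {
  stopifnot(inherits(net, "sociometric_network"))
  if (net$n < 3) stop("node bootstrap needs at least 3 members")
  if (B < 100) stop("B must be at least 100")
  A <- adjacency_matrix(net)
  n <- net$n
  reps <- with_seed(seed, function() {
    vapply(seq_len(B), function(b) {
      induced_density(A, sample.int(n, n, replace = TRUE))
    }, numeric(1))
  })
  stats::sd(reps, na.rm = TRUE)
}

#' Paired bootstrap test for density change between two waves
#'
#' Tests whether network density changed between two measurement waves on
#' the same roster. Each bootstrap replicate draws ONE node sample and
#' applies it to both waves, so the dependence between the waves (same
#' members) is preserved; the replicate statistic is the density
#' difference. t = observed difference / bootstrap SE of the replicate
#' differences, with a two-sided p-value from the standard normal
#' reference. When the bootstrap SE is exactly 0 (e.g. both waves
#' identical), t is 0 if the observed difference is 0 and signed infinity
#' otherwise.
#'
#' @param net1,net2 `sociometric_network`s on the identical roster.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed, mandatory.
#' @return A `bootstrap_density_test` list: `wave_labels`,
#'   `observed_densities`, `observed_diff` (wave 2 minus wave 1),
#'   `bootstrap_se`, `t_value`, `p_two_sided`, `B`, `seed`.
#' @export
paired_density_test <- function(net1, net2, B = 5000, seed) {
  stopifnot(inherits(net1, "sociometric_network"),
            inherits(net2, "sociometric_network"))
  if (!identical(net1$roster$member_id, net2$roster$member_id)) {
    stop("the two waves must share the identical roster")
  }
  if (net1$n < 3) stop("node bootstrap needs at least 3 members")
  if (B < 100) stop("B must be at least 100")
  A1 <- adjacency_matrix(net1)
  A2 <- adjacency_matrix(net2)
  n <- net1$n
  d1 <- density(net1)
  d2 <- density(net2)
  diff_obs <- d2 - d1
  diffs <- with_seed(seed, function() {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      induced_density(A2, idx) - induced_density(A1, idx)
    }, numeric(1))
  })
  se <- stats::sd(diffs, na.rm = TRUE)
  t_value <- if (se > 0) {
    diff_obs / se
  } else if (diff_obs == 0) 0 else sign(diff_obs) * Inf
  p <- 2 * stats::pnorm(-abs(t_value))
  structure(list(wave_labels = c(net1$wave, net2$wave),
                 observed_densities = c(d1, d2), observed_diff = diff_obs,
                 bootstrap_se = se, t_value = t_value, p_two_sided = p,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "bootstrap_density_test")
}

#' @export
print.bootstrap_density_test <- function(x, ...) {
  cat(sprintf(
    "Bootstrap density comparison (%s -> %s)\n", x$wave_labels[1],
    x$wave_labels[2]))
  cat(sprintf("  densities: %.3f -> %.3f (diff %+.3f)\n",
              x$observed_densities[1], x$observed_densities[2],
              x$observed_diff))
  cat(sprintf("  bootstrap SE %.4f (B = %d, seed = %d)\n",
              x$bootstrap_se, x$B, x$seed))
  cat(sprintf("  t = %.2f, two-sided p = %.3f\n", x$t_value, x$p_two_sided))
  invisible(x)
}

#' Serialize a bootstrap density test to JSON
#' @param test A `bootstrap_density_test`.
#' @param file Optional output path.
#' @return JSON string (invisibly if written to file).
#' @export
density_test_json <- function(test, file = NULL) {
  stopifnot(inherits(test, "bootstrap_density_test"))
  js <- jsonlite::toJSON(
    list(waves = test$wave_labels, densities = test$observed_densities,
         diff = test$observed_diff, se = test$bootstrap_se,
         t = test$t_value, p = test$p_two_sided, B = test$B,
         seed = test$seed),
    auto_unbox = FALSE, digits = NA, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(js, file, useBytes = TRUE)
    return(invisible(js))
  }
  js
}

pcs_items <- paste0("item", 1:6)

# Respondent-level subscale and total scores, missing items excluded
# pairwise (a score is NA only if all its items are missing).
pcs_row_scores <- function(responses) {
  m <- as.matrix(as.data.frame(responses)[, pcs_items])
  mode(m) <- "numeric"
  data.frame(wave = as.character(responses$wave),
             member_id = as.character(responses$member_id),
             belonging = rowMeans(m[, 1:3, drop = FALSE], na.rm = TRUE),
             morale = rowMeans(m[, 4:6, drop = FALSE], na.rm = TRUE),
             total = rowMeans(m, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Score the Perceived Cohesion Scale
#'
#' Belonging = mean of items 1-3, morale = mean of items 4-6, total = mean
#' of all six; scored per respondent, then averaged within wave. Missing
#' items are excluded pairwise.
#'
#' @param responses A `pcs_responses` table (see [read_pcs()]).
#' @return Data frame, one row per wave (input order): `wave`, `n_respondents`,
#'   `belonging`, `morale`, `total`.
#' @export
pcs_score <- function(responses) {
  rs <- pcs_row_scores(responses)
  rs <- rs[is.finite(rs$total), , drop = FALSE]
  if (!nrow(rs)) stop("no PCS rows with any answered item")
  waves <- unique(rs$wave)
  out <- do.call(rbind, lapply(waves, function(w) {
    s <- rs[rs$wave == w, ]
    data.frame(wave = w, n_respondents = nrow(s),
               belonging = mean(s$belonging, na.rm = TRUE),
               morale = mean(s$morale, na.rm = TRUE),
               total = mean(s$total), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' PCS reliability and unidimensionality
#'
#' Cronbach's alpha, `(k/(k-1)) * (1 - sum(item variances)/variance(total
#' score))` with k = 6, and the first eigenvalue of the 6 x 6 item
#' correlation matrix (principal-component extraction). A first eigenvalue
#' near 6 with alpha near 1 indicates a single strongly dominant factor;
#' eigenvalues of a correlation matrix always sum to 6.
#'
#' Computed over complete rows pooled across waves.
#'
#' @param responses A `pcs_responses` table.
#' @return List: `alpha`, `first_eigenvalue`, `n_complete`.
#' @export
pcs_reliability <- function(responses) {
  m <- as.matrix(as.data.frame(responses)[, pcs_items])
  mode(m) <- "numeric"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("PCS reliability needs at least 3 complete rows")
  v <- apply(m, 2, stats::var)
  zero <- pcs_items[v == 0]
  if (length(zero)) {
    stop("zero-variance PCS item(s): ", paste(zero, collapse = ", "))
  }
  k <- ncol(m)
  total <- rowSums(m)
  alpha <- (k / (k - 1)) * (1 - sum(v) / stats::var(total))
  ev <- eigen(stats::cor(m), symmetric = TRUE, only.values = TRUE)$values
  list(alpha = alpha, first_eigenvalue = ev[1], n_complete = nrow(m))
}

#' Compare PCS total scores between two waves
#'
#' One-way ANOVA F-test on respondent-level total scores across the two
#' waves, df = (1, n1 + n2 - 2). With two groups, F equals the square of
#' the pooled two-sample t statistic.
#'
#' @param responses A `pcs_responses` table containing both waves.
#' @param waves Character pair of wave labels (case-insensitive); defaults
#'   to the two waves present.
#' @return List: `f_stat`, `df` (length-2), `p`, `means` (per-wave total
#'   means), `n` (per-wave counts).
#' @export
pcs_wave_compare <- function(responses, waves = NULL) {
  rs <- pcs_row_scores(responses)
  rs <- rs[is.finite(rs$total), , drop = FALSE]
  if (is.null(waves)) {
    waves <- unique(rs$wave)
    if (length(waves) != 2) {
      stop("found ", length(waves),
           " wave(s) with scores; pass `waves` to pick two")
    }
  }
  grp <- lapply(waves, function(w) rs$total[label_eq(rs$wave, w)])
  sizes <- lengths(grp)
  if (any(sizes < 2)) {
    stop("each wave needs at least 2 scored respondents; got ",
         paste(sizes, collapse = " and "))
  }
  score <- c(grp[[1]], grp[[2]])
  wave_f <- factor(rep(c(1, 2), sizes))
  fit <- stats::anova(stats::lm(score ~ wave_f))
  list(f_stat = fit$`F value`[1],
       df = c(fit$Df[1], fit$Df[2]),
       p = fit$`Pr(>F)`[1],
       means = stats::setNames(vapply(grp, mean, 0), waves),
       n = stats::setNames(as.integer(sizes), waves))
}
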