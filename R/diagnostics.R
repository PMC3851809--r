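# Threshold evaluation and the action report handed to the group leader.
# Reports are pure functions of their inputs: stable ordering everywhere,
# no randomness, so regeneration is byte-identical.

diag_metrics <- c("isolates", "degree_min", "reciprocity_nonnull",
                  "excess_components", "density", "centralization",
                  "transitivity_pct", "cohesion_compactness")

#' Load a threshold configuration
#'
#' Thresholds are pre-registered before fieldwork so that diagnostic
#' interpretation is standardized and subjective judgement is removed from
#' the feedback loop. The shipped defaults are: no isolates; every member's
#' total degree > 1; non-null reciprocity > 0.50; no excess components;
#' density strictly between 0.15 and 0.50; total-degree centralization
#' < 0.25; transitivity percent > 0.3; compactness cohesion > 0.25.
#'
#' @param file Path to a YAML file with a `metrics:` map (see the shipped
#'   `inst/extdata/thresholds.yaml`); `NULL` loads the defaults.
#' @return A `threshold_config` object: named list of rules, each with
#'   `comparator` (`eq`, `gt`, `lt`, `band`) and bound(s).
#' @export
threshold_config <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "thresholds.yaml", package = "sociodiag",
                        mustWork = TRUE)
  }
  raw <- yaml::read_yaml(file)
  if (is.null(raw$metrics)) stop("threshold config lacks a 'metrics:' map")
  rules <- raw$metrics
  for (m in names(rules)) {
    r <- rules[[m]]
    if (is.null(r$comparator) ||
        !r$comparator %in% c("eq", "gt", "lt", "band")) {
      stop("metric '", m, "': comparator must be eq, gt, lt or band")
    }
    if (r$comparator == "band") {
      if (is.null(r$lower) || is.null(r$upper) || r$lower >= r$upper) {
        stop("metric '", m, "': band needs lower < upper")
      }
    } else if (is.null(r$value)) {
      stop("metric '", m, "': missing 'value'")
    }
  }
  structure(rules, class = "threshold_config")
}

# TRUE = within threshold, FALSE = violation, NA = cannot evaluate
rule_ok <- function(observed, rule) {
  if (is.na(observed)) return(NA)
  switch(rule$comparator,
    eq = observed == rule$value,
    gt = observed > rule$value,
    lt = observed < rule$value,
    band = observed > rule$lower & observed < rule$upper
  )
}

rule_text <- function(rule) {
  switch(rule$comparator,
    eq = paste("should equal", rule$value),
    gt = paste("should be greater than", rule$value),
    lt = paste("should be less than", rule$value),
    band = sprintf("should be greater than %s but less than %s",
                   rule$lower, rule$upper)
  )
}

# Observed value a rule is checked against, given a metrics panel.
observed_value <- function(panel, metric) {
  switch(metric,
    isolates = length(panel$isolate_ids),
    degree_min = min(panel$degree_rows$total),
    reciprocity_nonnull = panel$reciprocity_nonnull,
    excess_components = panel$excess_components,
    density = panel$density,
    centralization = panel$centralization_degree,
    transitivity_pct = panel$transitivity_pct,
    cohesion_compactness = panel$cohesion_compactness,
    stop("no rule mapping for metric: ", metric)
  )
}

#' Evaluate a diagnostics panel against thresholds
#'
#' Produces one finding per configured metric with status `pass`, `flag`,
#' or `cannot_evaluate` (for metrics that are undefined on this network,
#' e.g. reciprocity of an empty network). Node-level targets for flagged
#' metrics come from [identify_targets()].
#'
#' @param panel A [metrics_panel()].
#' @param config A [threshold_config()]; defaults to the shipped rules.
#' @param net The `sociometric_network` the panel came from; required to
#'   attach node-level targets, optional otherwise.
#' @return A `diagnostic_findings` object: list of findings, each with
#'   `metric`, `observed`, `rule`, `status`, `targets`.
#' @export
evaluate_thresholds <- function(panel, config = threshold_config(),
                                net = NULL) {
  stopifnot(inherits(panel, "metrics_panel"),
            inherits(config, "threshold_config"))
  missing_rules <- setdiff(diag_metrics, names(config))
  if (length(missing_rules)) {
    stop("threshold config lacks rule(s) for: ",
         paste(missing_rules, collapse = ", "))
  }
  targets <- if (!is.null(net)) identify_targets(net, panel) else NULL
  findings <- lapply(diag_metrics, function(m) {
    rule <- config[[m]]
    obs <- observed_value(panel, m)
    ok <- rule_ok(obs, rule)
    status <- if (is.na(ok)) "cannot_evaluate" else if (ok) "pass" else "flag"
    tg <- if (!is.null(targets) && status == "flag") {
      metric_targets(m, targets)
    } else list()
    list(metric = m, observed = obs, rule = rule, status = status,
         targets = tg)
  })
  names(findings) <- diag_metrics
  structure(findings, class = "diagnostic_findings",
            wave = panel$wave, relation = panel$relation)
}

# Subset of the target bundle relevant to one metric's teaching methods.
metric_targets <- function(metric, targets) {
  switch(metric,
    isolates = targets[c("isolate_ids", "hub_ids")],
    degree_min = targets[c("low_degree_ids", "hub_ids")],
    reciprocity_nonnull = targets["unreciprocated_dyads"],
    excess_components = targets[c("component_membership", "bridge_pairs")],
    centralization = targets[c("central_id", "central_betweenness_id")],
    list()
  )
}

#' Identify node-level targets for teaching recommendations
#'
#' Finds the specific participants each recommendation should name:
#' isolates, low-degree members (total degree <= 1, excluding isolates),
#' hubs (members with the maximum total degree, ties broken by roster
#' order), all unreciprocated ordered dyads, subgroup memberships with
#' suggested bridge pairs across the two largest components, and the most
#' central member (maximum total degree; the maximum-betweenness member is
#' reported alongside when different).
#'
#' @param net A `sociometric_network`.
#' @param panel Its [metrics_panel()] (recomputed if omitted).
#' @return Named list: `isolate_ids`, `low_degree_ids`, `hub_ids`,
#'   `unreciprocated_dyads` (data frame ego/alter), `component_membership`,
#'   `bridge_pairs` (data frame from/to), `central_id`,
#'   `central_betweenness_id`.
#' @export
identify_targets <- function(net, panel = metrics_panel(net)) {
  stopifnot(inherits(net, "sociometric_network"))
  deg <- panel$degree_rows
  iso <- panel$isolate_ids
  low <- setdiff(deg$member_id[deg$total <= 1L], iso)
  hubs <- deg$member_id[deg$total == max(deg$total) & max(deg$total) > 0L]
  A <- adjacency_matrix(net)
  unrec <- which(A == 1L & t(A) == 0L, arr.ind = TRUE)
  ids <- net$roster$member_id
  unrec_df <- data.frame(ego = ids[unrec[, 1]], alter = ids[unrec[, 2]],
                         stringsAsFactors = FALSE)
  unrec_df <- unrec_df[order(match(unrec_df$ego, ids),
                             match(unrec_df$alter, ids)), , drop = FALSE]
  rownames(unrec_df) <- NULL
  comp <- panel$component_membership
  bridges <- if (length(comp) >= 2) {
    data.frame(from = comp[[1]][1], to = comp[[2]][1],
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0))
  }
  central <- if (max(deg$total) > 0L) hubs[1] else character(0)
  btw <- centrality_scores(net, "betweenness")
  central_btw <- if (length(central) && max(btw) > 0) {
    ids[which.max(btw)]
  } else {
    character(0)
  }
  if (length(central_btw) && identical(central_btw, central)) {
    central_btw <- character(0)
  }
  list(isolate_ids = iso, low_degree_ids = low, hub_ids = hubs,
       unreciprocated_dyads = unrec_df, component_membership = comp,
       bridge_pairs = bridges, central_id = central,
       central_betweenness_id = central_btw)
}

#' Load the teaching-method menu
#'
#' The menu maps each diagnostic to its numbered teaching methods; the
#' texts live in a data file (not code) so wording can be versioned and
#' adapted per study without touching the package.
#'
#' @param file Path to a YAML file; `NULL` loads the shipped menu.
#' @return Named list: metric -> character vector of method templates.
#' @export
teaching_methods <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "teaching_methods.yaml",
                        package = "sociodiag", mustWork = TRUE)
  }
  yaml::read_yaml(file)
}

# Display names in roster order, comma-joined; "" when no ids.
name_list <- function(ids, roster) {
  if (!length(ids)) return("")
  ids <- ids[order(match(ids, roster$member_id))]
  paste(roster$display_name[match(ids, roster$member_id)], collapse = ", ")
}

# Fill a template's {placeholders} from the target bundle. Placeholders
# with no data for this group fall back to a generic phrase so the advice
# is still actionable.
fill_template <- function(template, targets, roster) {
  nm <- function(ids, fallback) {
    s <- name_list(ids, roster)
    if (nzchar(s)) s else fallback
  }
  pairs_text <- function(df, fallback) {
    if (is.null(df) || !nrow(df)) return(fallback)
    paste(sprintf("%s and %s",
                  roster$display_name[match(df[[1]], roster$member_id)],
                  roster$display_name[match(df[[2]], roster$member_id)]),
          collapse = "; ")
  }
  groups_text <- function(comp, fallback) {
    if (!length(comp)) return(fallback)
    paste(vapply(comp, name_list, "", roster = roster), collapse = " | ")
  }
  subs <- c(
    "{isolates}" = nm(targets$isolate_ids, "each isolate"),
    "{hubs}" = nm(targets$hub_ids, "the most connected members"),
    "{low_degree}" = nm(targets$low_degree_ids, "the least connected members"),
    "{unreciprocated}" = pairs_text(targets$unreciprocated_dyads,
                                    "each sender with their non-reciprocating partner"),
    "{bridges}" = pairs_text(targets$bridge_pairs,
                             "one member from each subgroup"),
    "{subgroups}" = groups_text(targets$component_membership,
                                "the observed subgroups"),
    "{central}" = nm(targets$central_id, "the most central member")
  )
  for (k in names(subs)) {
    template <- gsub(k, subs[[k]], template, fixed = TRUE)
  }
  template
}

#' Generate the action report for the group leader
#'
#' The deliverable of the diagnostic cycle: for every flagged metric, the
#' report renders that metric's numbered teaching methods with the
#' relevant participants' display names substituted in, plus the standing
#' instruction to implement at least two recommendations during each
#' subsequent group session. If nothing is flagged, the report instructs
#' the leader not to alter their teaching methods. Output is deterministic:
#' identical inputs give byte-identical reports.
#'
#' @param findings A `diagnostic_findings` from [evaluate_thresholds()].
#' @param targets Node-level targets from [identify_targets()]; when the
#'   findings already carry targets (evaluate_thresholds called with
#'   `net`), this may be omitted.
#' @param roster The group [roster()], for display names.
#' @param methods Teaching-method menu; defaults to the shipped one.
#' @param map_reference Optional path to an exported sociogram to mention.
#' @return An `action_report` object with fields `group_id`, `wave`,
#'   `relation`, `findings`, `recommendations` (data frame: metric,
#'   method_number, text), `leader_instruction`, `map_reference`.
#' @export
generate_action_report <- function(findings, targets = NULL, roster,
                                   methods = teaching_methods(),
                                   map_reference = NULL) {
  stopifnot(inherits(findings, "diagnostic_findings"),
            inherits(roster, "roster"))
  recs <- data.frame(metric = character(0), method_number = integer(0),
                     text = character(0), stringsAsFactors = FALSE)
  for (f in findings) {
    if (f$status != "flag") next
    tg <- if (!is.null(targets)) {
      metric_targets(f$metric, targets)
    } else {
      f$targets
    }
    templates <- methods[[f$metric]]
    if (is.null(templates)) {
      stop("teaching-method menu lacks an entry for metric: ", f$metric)
    }
    for (i in seq_along(templates)) {
      recs <- rbind(recs, data.frame(
        metric = f$metric, method_number = i,
        text = fill_template(templates[[i]], tg, roster),
        stringsAsFactors = FALSE))
    }
  }
  flagged <- any(vapply(findings, function(f) f$status == "flag", TRUE))
  leader_instruction <- if (flagged) {
    paste("Implement at least two of the recommendations above during each",
          "subsequent group session.")
  } else {
    paste("All diagnostics met their pre-registered thresholds:",
          "do not alter your teaching methods.")
  }
  structure(list(group_id = attr(roster, "group_id"),
                 wave = attr(findings, "wave"),
                 relation = attr(findings, "relation"),
                 findings = findings, recommendations = recs,
                 leader_instruction = leader_instruction,
                 map_reference = map_reference),
            class = "action_report")
}

fmt_observed <- function(x) {
  if (is.na(x)) "undefined" else format(round_half_up(x), scientific = FALSE)
}

#' Render an action report
#'
#' @param report An [generate_action_report()] result.
#' @param format `"markdown"` or `"text"`.
#' @return A single character string.
#' @export
render_action_report <- function(report, format = c("markdown", "text")) {
  format <- match.arg(format)
  md <- format == "markdown"
  h <- function(s) if (md) paste0("## ", s) else toupper(s)
  bullet <- function(s) if (md) paste0("- ", s) else paste0("* ", s)
  lines <- c(
    if (md) "# Action report" else "ACTION REPORT",
    "",
    sprintf("Group: %s | Wave: %s | Relation: %s",
            report$group_id, report$wave, report$relation),
    "",
    h("Diagnostic findings"),
    "")
  for (f in report$findings) {
    lines <- c(lines, bullet(sprintf(
      "%s: observed %s (%s) -- %s", f$metric, fmt_observed(f$observed),
      rule_text(f$rule),
      switch(f$status, pass = "within threshold", flag = "FLAGGED",
             cannot_evaluate = "cannot evaluate (metric undefined on this network)"))))
  }
  lines <- c(lines, "", h("Recommendations"), "")
  if (nrow(report$recommendations)) {
    for (i in seq_len(nrow(report$recommendations))) {
      r <- report$recommendations[i, ]
      lines <- c(lines, bullet(sprintf("[%s, method %d] %s", r$metric,
                                       r$method_number, r$text)))
    }
  } else {
    lines <- c(lines, "No changes recommended.")
  }
  lines <- c(lines, "", h("Instruction to the group leader"), "",
             report$leader_instruction)
  if (!is.null(report$map_reference)) {
    lines <- c(lines, "", sprintf("Sociogram: %s", report$map_reference))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.action_report <- function(x, ...) {
  cat(render_action_report(x, "text"))
  invisible(x)
}

#' Serialize findings to JSON
#'
#' Machine-readable companion to the rendered report: one object per
#' metric with the observed value, rule, status and node-level targets.
#'
#' @param findings A `diagnostic_findings`.
#' @param file Optional output path.
#' @return JSON string (invisibly if written to file).
#' @export
findings_json <- function(findings, file = NULL) {
  stopifnot(inherits(findings, "diagnostic_findings"))
  payload <- list(
    wave = attr(findings, "wave"),
    relation = attr(findings, "relation"),
    findings = lapply(unname(findings), function(f) {
      list(metric = f$metric,
           observed = if (is.na(f$observed)) NULL else f$observed,
           rule = f$rule, status = f$status, targets = f$targets)
    })
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                         digits = NA, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(js, file, useBytes = TRUE)
    return(invisible(js))
  }
  js
}
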