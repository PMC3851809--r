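#' Construct a group roster
#'
#' A roster is the complete, ordered list of group members. Its order is
#' stable and defines node indexing in every downstream structure
#' (adjacency matrices, metric tables, exports). Sociometric surveys in
#' small intervention groups are administered against the full roster, so
#' the roster -- not the set of survey respondents -- defines the node set.
#'
#' @param member_id Character vector of unique member identifiers.
#' @param display_name Character vector of display names, same length.
#' @param group_id Single text label for the group.
#' @return A `roster` object: a data frame with columns `member_id` and
#'   `display_name` and a `group_id` attribute.
#' @examples
#' roster(as.character(1:4), c("Ana", "Ben", "Cam", "Dee"))
#' @export
roster <- function(member_id, display_name = member_id, group_id = "group") {
  member_id <- as.character(member_id)
  display_name <- as.character(display_name)
  if (length(member_id) < 2L) {
    stop("a roster needs at least 2 members, got ", length(member_id))
  }
  if (length(display_name) != length(member_id)) {
    stop("display_name must have one entry per member_id")
  }
  dup <- unique(member_id[duplicated(member_id)])
  if (length(dup)) {
    stop("duplicate member_id(s) in roster: ", paste(dup, collapse = ", "))
  }
  out <- data.frame(member_id = member_id, display_name = display_name,
                    stringsAsFactors = FALSE)
  attr(out, "group_id") <- as.character(group_id)[1]
  class(out) <- c("roster", "data.frame")
  out
}

#' @export
print.roster <- function(x, ...) {
  cat(sprintf("Roster '%s': %d members\n", attr(x, "group_id"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read a roster from a delimited file
#'
#' Expects a header with `member_id` and `display_name` columns (extra
#' columns are ignored). File order is preserved and becomes the canonical
#' node order.
#'
#' @param file Path or connection to a delimited text file (UTF-8).
#' @param delim Field delimiter, comma by default.
#' @param group_id Group label attached to the roster.
#' @return A [roster()] object.
#' @export
read_roster <- function(file, delim = ",", group_id = "group") {
  df <- utils::read.table(file, header = TRUE, sep = delim,
                          colClasses = "character", encoding = "UTF-8",
                          strip.white = TRUE)
  if (nrow(df) == 0L) stop("roster file is empty: ", file)
  need <- c("member_id", "display_name")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("roster file lacks column(s): ", paste(miss, collapse = ", "))
  }
  roster(df$member_id, df$display_name, group_id = group_id)
}

#' Write a roster to CSV
#' @param x A [roster()] object.
#' @param file Output path.
#' @param delim Field delimiter.
#' @export
write_roster <- function(x, file, delim = ",") {
  utils::write.table(as.data.frame(x)[, c("member_id", "display_name")],
                     file, sep = delim, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

# Labels (waves, relations) are matched case-insensitively throughout;
# field usage varies ("week four" vs "Week Four" vs "week4").
label_eq <- function(a, b) tolower(trimws(a)) == tolower(trimws(b))

#' Read sociometric nominations
#'
#' Nominations are the rows of a roster-based name-generator survey: at
#' each wave, each respondent (ego) selects the group members (alters)
#' with whom they share the named relation, e.g. seeking advice outside of
#' sessions, or discussing program topics outside of sessions. Exact
#' duplicate rows are collapsed to a single arc with a warning;
#' self-nominations and unknown IDs are data-entry errors and rejected.
#'
#' @param file Path to a delimited file with header columns
#'   `wave, relation, ego, alter`.
#' @param roster A [roster()]; all egos and alters must belong to it.
#' @param delim Field delimiter, comma by default.
#' @return A data frame of validated nomination records with columns
#'   `wave, relation, ego, alter` (character).
#' @export
read_nominations <- function(file, roster, delim = ",") {
  df <- utils::read.table(file, header = TRUE, sep = delim,
                          colClasses = "character", encoding = "UTF-8",
                          strip.white = TRUE)
  need <- c("wave", "relation", "ego", "alter")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("nomination file lacks column(s): ", paste(miss, collapse = ", "))
  }
  validate_nominations(df[, need], roster)
}

#' Validate nomination records against a roster
#'
#' @param records Data frame with columns `wave, relation, ego, alter`.
#' @param roster A [roster()].
#' @return The validated, deduplicated records.
#' @export
validate_nominations <- function(records, roster) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(lapply(records, as.character),
                           stringsAsFactors = FALSE)
  ids <- roster$member_id
  unknown <- setdiff(unique(c(records$ego, records$alter)), ids)
  if (length(unknown)) {
    stop("nomination mentions id(s) not on the roster: ",
         paste(unknown, collapse = ", "))
  }
  self <- records$ego == records$alter
  if (any(self)) {
    stop("self-nomination(s) for id(s): ",
         paste(unique(records$ego[self]), collapse = ", "),
         " (likely data-entry error)")
  }
  key <- paste(tolower(trimws(records$wave)), tolower(trimws(records$relation)),
               records$ego, records$alter, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate nomination row(s) collapsed")
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' Write nominations to CSV
#' @param records Nomination data frame (`wave, relation, ego, alter`).
#' @param file Output path.
#' @param delim Field delimiter.
#' @export
write_nominations <- function(records, file, delim = ",") {
  utils::write.table(records[, c("wave", "relation", "ego", "alter")],
                     file, sep = delim, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' Build a sociometric network for one wave and relation
#'
#' The node set is always the FULL roster: members who did not complete
#' the survey at a wave (non-respondents) contribute no outgoing arcs but
#' remain in the network because they can still be nominated by others,
#' and they stay in every metric denominator. This depresses density and
#' related metrics relative to a respondent-only analysis, deliberately:
#' an unreachable member is a real structural deficit of the group.
#'
#' @param records Nomination records (see [read_nominations()]); rows for
#'   other waves/relations are ignored.
#' @param roster A [roster()].
#' @param wave Wave label (matched case-insensitively).
#' @param relation Relation label (matched case-insensitively).
#' @param respondents Character vector of member_ids who provided survey
#'   data at this wave. Defaults to the egos observed at this wave in
#'   `records` (any relation) -- note that a respondent who nominated
#'   nobody is invisible in an edge list, so pass the true set when known.
#' @return A `sociometric_network` object.
#' @export
build_network <- function(records, roster, wave, relation,
                          respondents = NULL) {
  stopifnot(inherits(roster, "roster"))
  records <- validate_nominations(records, roster)
  in_wave <- label_eq(records$wave, wave)
  if (is.null(respondents)) {
    respondents <- unique(records$ego[in_wave])
  }
  respondents <- as.character(respondents)
  bad_resp <- setdiff(respondents, roster$member_id)
  if (length(bad_resp)) {
    stop("respondent id(s) not on the roster: ",
         paste(bad_resp, collapse = ", "))
  }
  sel <- in_wave & label_eq(records$relation, relation)
  arcs <- records[sel, c("ego", "alter"), drop = FALSE]
  rownames(arcs) <- NULL
  new_sociometric_network(roster, wave, relation, arcs, respondents)
}

#' Low-level sociometric network constructor
#'
#' @param roster A [roster()].
#' @param wave,relation Labels.
#' @param arcs Data frame with character columns `ego`, `alter`; each row
#'   one directed tie. Duplicates collapse.
#' @param respondents Character vector of member_ids with survey data.
#' @return A `sociometric_network`: list with fields `roster`, `wave`,
#'   `relation`, `arcs`, `respondents`, `n`.
#' @export
new_sociometric_network <- function(roster, wave, relation, arcs,
                                    respondents) {
  stopifnot(inherits(roster, "roster"))
  ids <- roster$member_id
  arcs <- data.frame(ego = as.character(arcs$ego),
                     alter = as.character(arcs$alter),
                     stringsAsFactors = FALSE)
  arcs <- unique(arcs)
  respondents <- unique(as.character(respondents))
  if (length(setdiff(respondents, ids))) {
    stop("respondents must be a subset of the roster")
  }
  if (any(arcs$ego == arcs$alter)) stop("self-loops are not allowed")
  unknown <- setdiff(unique(c(arcs$ego, arcs$alter)), ids)
  if (length(unknown)) {
    stop("arc endpoint(s) not on the roster: ", paste(unknown, collapse = ", "))
  }
  stray <- setdiff(unique(arcs$ego), respondents)
  if (length(stray)) {
    stop("arc(s) originate from non-respondent(s): ",
         paste(stray, collapse = ", "),
         " (non-respondents may appear only as alters)")
  }
  # canonical arc order: by ego then alter, in roster order
  o <- order(match(arcs$ego, ids), match(arcs$alter, ids))
  arcs <- arcs[o, , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(roster = roster, wave = as.character(wave)[1],
                 relation = as.character(relation)[1], arcs = arcs,
                 respondents = respondents, n = length(ids)),
            class = "sociometric_network")
}

#' @export
print.sociometric_network <- function(x, ...) {
  cat(sprintf(
    "Sociometric network '%s' (%s, %s): %d nodes, %d arcs, %d respondent(s)\n",
    attr(x$roster, "group_id"), x$wave, x$relation, x$n, nrow(x$arcs),
    length(x$respondents)))
  invisible(x)
}

#' Adjacency matrix of a sociometric network
#'
#' @param net A `sociometric_network`.
#' @return Integer 0/1 matrix in roster order, zero diagonal, dimnames =
#'   member_ids. `A[i, j] == 1` iff i nominated j.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "sociometric_network"))
  ids <- net$roster$member_id
  A <- matrix(0L, net$n, net$n, dimnames = list(ids, ids))
  if (nrow(net$arcs)) {
    A[cbind(match(net$arcs$ego, ids), match(net$arcs$alter, ids))] <- 1L
  }
  A
}

#' Convert a sociometric network to an igraph graph
#'
#' Vertices carry `name` (member_id) and `display_name` attributes;
#' isolates are retained.
#'
#' @param net A `sociometric_network`.
#' @return A directed `igraph` graph on the full roster.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "sociometric_network"))
  vs <- data.frame(name = net$roster$member_id,
                   display_name = net$roster$display_name,
                   respondent = as.integer(net$roster$member_id %in%
                                             net$respondents),
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(net$arcs, directed = TRUE, vertices = vs)
}

#' Read Perceived Cohesion Scale responses
#'
#' The Perceived Cohesion Scale (PCS) is a six-item instrument on a
#' 7-point Likert scale (1 = strongly disagree ... 7 = strongly agree).
#' Items 1-3 form the Sense of Belonging subscale, items 4-6 Feelings of
#' Morale. Missing items are allowed; out-of-range values are rejected
#' with the offending row index.
#'
#' @param file Path to a delimited file with header columns
#'   `wave, member_id, item1..item6`.
#' @param roster A [roster()]; member_ids must belong to it.
#' @param delim Field delimiter.
#' @return A `pcs_responses` data frame: `wave, member_id, item1..item6`.
#' @export
read_pcs <- function(file, roster, delim = ",") {
  df <- utils::read.table(file, header = TRUE, sep = delim,
                          colClasses = "character", encoding = "UTF-8",
                          strip.white = TRUE)
  items <- paste0("item", 1:6)
  miss <- setdiff(c("wave", "member_id", items), names(df))
  if (length(miss)) {
    stop("PCS file lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (it in items) {
    v <- df[[it]]
    v[v == "" | toupper(v) == "NA"] <- NA
    df[[it]] <- suppressWarnings(as.numeric(v))
  }
  pcs_responses(df[, c("wave", "member_id", items)], roster)
}

#' Validate a PCS response table
#' @param df Data frame with `wave, member_id, item1..item6`.
#' @param roster Optional [roster()] to check member_ids against.
#' @return A `pcs_responses` data frame.
#' @export
pcs_responses <- function(df, roster = NULL) {
  items <- paste0("item", 1:6)
  stopifnot(all(c("wave", "member_id", items) %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, items])
  bad <- which(!is.na(vals) & (vals < 1 | vals > 7 | vals != round(vals)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("PCS item value outside 1-7 in row(s): ",
         paste(sort(unique(bad[, 1])), collapse = ", "))
  }
  if (!is.null(roster)) {
    unknown <- setdiff(unique(as.character(df$member_id)), roster$member_id)
    if (length(unknown)) {
      stop("PCS member_id(s) not on the roster: ",
           paste(unknown, collapse = ", "))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("pcs_responses", "data.frame")
  df
}

#' Write PCS responses to CSV
#' @param df A `pcs_responses` data frame.
#' @param file Output path.
#' @param delim Field delimiter.
#' @export
write_pcs <- function(df, file, delim = ",") {
  utils::write.table(as.data.frame(df), file, sep = delim,
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}
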