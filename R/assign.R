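# Mapping ranked hits to the taxonomy: best hit (BH) and next lineage hit
# (NLH) extraction, and paired-end combination.

#' Pair combination policy
#'
#' @param mode `"best"` (keep the mate whose BH has the lower log10 E-value)
#'   or `"concordant"` (keep the better mate only if both mates' BH groups
#'   agree at `level`).
#' @param level Taxonomic level at which concordance is checked.
#' @param allow_single Under `"concordant"`, accept a template where only one
#'   mate has hits (default FALSE: strict reading, such templates are
#'   unassigned).
#' @return A `pair_policy` list.
#' @export
pair_policy <- function(mode = c("best", "concordant"),
                        level = c("lineage", "supergroup"),
                        allow_single = FALSE) {
  structure(list(mode = match.arg(mode), level = match.arg(level),
                 allow_single = isTRUE(allow_single)),
            class = "pair_policy")
}

empty_assignment <- function() {
  data.frame(query_id = character(0), bh_subject = character(0),
             bh_lineage = character(0), bh_supergroup = character(0),
             bh_pident = numeric(0), bh_log10e = numeric(0),
             bh_bitscore = numeric(0),
             nlh_subject = character(0), nlh_lineage = character(0),
             nlh_pident = numeric(0), nlh_log10e = numeric(0),
             n_hits_seen = integer(0), stringsAsFactors = FALSE)
}

#' Extract the best hit and the next lineage hit from a ranked hit list
#'
#' The BH is the rank-1 hit. The NLH is the first subsequent hit whose lineage
#' differs from the BH's; intervening hits that share the BH's lineage are
#' skipped. Returns NULL for an empty hit list.
#'
#' @param hits One hit group (data.frame sorted by rank) as produced by
#'   [parse_m8()] or [builtin_search()].
#' @param tab A `taxonomy_table` resolving every subject's taxon.
#' @param subject_to_taxon Function mapping a subject_id to a taxon_id in
#'   `tab` (default: the part before the first `|`).
#' @return One-row data.frame with columns query_id, bh_subject, bh_lineage,
#'   bh_supergroup, bh_pident, bh_log10e, bh_bitscore, nlh_subject,
#'   nlh_lineage, nlh_pident, nlh_log10e (NA when no NLH exists), and
#'   n_hits_seen; or NULL when `hits` is empty.
#' @export
extract_bh_nlh <- function(hits, tab,
                           subject_to_taxon = function(s) sub("\\|.*$", "", s)) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  taxa <- lookup_taxa(tab, subject_to_taxon(hits$subject_id))
  bh_lin <- taxa$lineage[1L]
  other <- which(taxa$lineage != bh_lin)
  nlh_i <- if (length(other) > 0L) min(other) else NA_integer_
  data.frame(
    query_id = hits$query_id[1L],
    bh_subject = hits$subject_id[1L],
    bh_lineage = bh_lin,
    bh_supergroup = taxa$supergroup[1L],
    bh_pident = hits$pct_identity[1L],
    bh_log10e = hits$log10_evalue[1L],
    bh_bitscore = hits$bit_score[1L],
    nlh_subject = if (is.na(nlh_i)) NA_character_ else hits$subject_id[nlh_i],
    nlh_lineage = if (is.na(nlh_i)) NA_character_ else taxa$lineage[nlh_i],
    nlh_pident = if (is.na(nlh_i)) NA_real_ else hits$pct_identity[nlh_i],
    nlh_log10e = if (is.na(nlh_i)) NA_real_ else hits$log10_evalue[nlh_i],
    n_hits_seen = nrow(hits),
    stringsAsFactors = FALSE)
}

#' Map all hit groups of a sample to BH/NLH assignments
#'
#' @param groups Named list of hit groups (query id -> hits data.frame).
#' @param tab A `taxonomy_table`.
#' @param ... Passed to [extract_bh_nlh()].
#' @return data.frame with one row per query that had hits.
#' @export
map_hits <- function(groups, tab, ...) {
  rows <- lapply(groups, extract_bh_nlh, tab = tab, ...)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty_assignment())
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Combine the forward- and reverse-mate assignments of one read template
#'
#' Under `"best"`, the mate whose BH has the lower log10 E-value wins (ties:
#' higher bit score; a missing mate simply yields the other). Under
#' `"concordant"`, the better mate is returned only when both mates' BH
#' groups agree at `policy$level`; otherwise NULL (unless a single present
#' mate is accepted via `policy$allow_single`).
#'
#' @param fwd,rev One-row assignment data.frames from [extract_bh_nlh()],
#'   or NULL when the mate had no hits.
#' @param policy A [pair_policy()].
#' @return A one-row assignment data.frame, or NULL.
#' @export
combine_pairs <- function(fwd, rev, policy = pair_policy()) {
  better <- function(a, b) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    if (a$bh_log10e < b$bh_log10e) a
    else if (b$bh_log10e < a$bh_log10e) b
    else if (a$bh_bitscore >= b$bh_bitscore) a else b
  }
  if (policy$mode == "best") return(better(fwd, rev))
  # concordant
  if (is.null(fwd) || is.null(rev)) {
    if (policy$allow_single) return(better(fwd, rev))
    return(NULL)
  }
  col <- if (policy$level == "lineage") "bh_lineage" else "bh_supergroup"
  if (identical(fwd[[col]], rev[[col]])) better(fwd, rev) else NULL
}
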