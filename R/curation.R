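# Ortholog set curation: manual exclusions, species deduplication,
# C-terminal fragment removal, length-outlier removal. Every dropped
# record carries a machine-readable reason and the metric that triggered
# the rule; kept records preserve input order.

drop_report <- function(id = character(0), reason = character(0),
                        metric = numeric(0)) {
  data.frame(id = as.character(id), reason = as.character(reason),
             metric = as.numeric(metric), stringsAsFactors = FALSE)
}

#' Remove same-species duplicates
#'
#' One record is kept per species: the longest; ties broken by the
#' lexicographically smallest id. All records must carry a species tag.
#'
#' @param records A [protein_records()] data frame.
#' @return List with `kept` (records, input order) and `dropped` (a drop
#'   report with reason `"duplicate_species"`, metric = length).
#' @export
dedupe_by_species <- function(records) {
  if (anyNA(records$species)) {
    miss <- records$id[is.na(records$species)][1L]
    stop(sprintf("record '%s' has no species tag", miss), call. = FALSE)
  }
  keep_ids <- vapply(split(seq_len(nrow(records)), records$species),
                     function(idx) {
    sub <- records[idx, , drop = FALSE]
    sub <- sub[order(-sub$length, sub$id), , drop = FALSE]
    sub$id[[1L]]
  }, character(1))
  kept <- records[records$id %in% keep_ids, , drop = FALSE]
  drp <- records[!records$id %in% keep_ids, , drop = FALSE]
  list(kept = reset_rows(kept),
       dropped = drop_report(drp$id, rep("duplicate_species", nrow(drp)),
                             drp$length))
}

#' Remove short C-terminal fragments
#'
#' A record is a fragment when its length is below
#' `fragment_min_fraction` of the median length of the input set *and*
#' (when an alignment is available) its first non-gap column lies in the
#' C-terminal half of the alignment columns. Short records that align from
#' the N-terminus are kept: the rule targets C-terminal-only partial
#' sequences. Without an alignment the length criterion is applied alone,
#' with a warning.
#'
#' @param records A [protein_records()] data frame.
#' @param alignment Optional [alignment_matrix()] covering the records.
#' @param fragment_min_fraction Length fraction of the median below which
#'   a record is a fragment candidate, default 0.5.
#' @return List with `kept` and `dropped` (reason
#'   `"c_terminal_fragment"` or, without an alignment,
#'   `"short_fragment"`; metric = length).
#' @export
filter_fragments <- function(records, alignment = NULL,
                             fragment_min_fraction = 0.5) {
  med <- median(records$length)
  short <- records$length < fragment_min_fraction * med
  if (is.null(alignment)) {
    warning("no alignment supplied: dropping fragments on length alone",
            call. = FALSE)
    drop <- short
    reason <- "short_fragment"
  } else {
    miss <- setdiff(records$id, alignment$ids)
    if (length(miss))
      stop(sprintf("no alignment row for record '%s'", miss[1L]),
           call. = FALSE)
    first_col <- vapply(records$id, function(id) {
      regexpr("[^-]", alignment$rows[[id]])[[1L]]
    }, integer(1))
    drop <- short & first_col > alignment$n_columns / 2
    reason <- "c_terminal_fragment"
  }
  list(kept = reset_rows(records[!drop, , drop = FALSE]),
       dropped = drop_report(records$id[drop],
                             rep(reason, sum(drop)),
                             records$length[drop]))
}

#' Remove over-long length outliers
#'
#' Records significantly longer than the rest of the set are dropped:
#' length strictly greater than `length_outlier_ratio` times the median
#' length, the median being computed once over the full input set before
#' any drop. With fewer than 3 records the set is passed through with a
#' warning (no meaningful median).
#'
#' @param records A [protein_records()] data frame.
#' @param length_outlier_ratio Ratio over the median, default 1.5.
#' @return List with `kept` and `dropped` (reason `"length_outlier"`,
#'   metric = length).
#' @export
filter_length_outliers <- function(records, length_outlier_ratio = 1.5) {
  if (nrow(records) < 3L) {
    warning("fewer than 3 records: length-outlier filter skipped",
            call. = FALSE)
    return(list(kept = records, dropped = drop_report()))
  }
  med <- median(records$length)
  drop <- records$length > length_outlier_ratio * med
  list(kept = reset_rows(records[!drop, , drop = FALSE]),
       dropped = drop_report(records$id[drop],
                             rep("length_outlier", sum(drop)),
                             records$length[drop]))
}

#' Curate an ortholog set
#'
#' Applies the curation rules in fixed order: manual exclusion list, then
#' species deduplication, then C-terminal fragment removal, then
#' length-outlier removal. The caller is expected to realign the kept
#' sequences afterwards if a downstream step needs alignment columns that
#' reflect the curated set.
#'
#' @param records A [protein_records()] data frame.
#' @param alignment Optional [alignment_matrix()] (used by the fragment
#'   rule).
#' @param exclude_ids Character vector of ids to exclude outright (e.g.
#'   withdrawn database accessions).
#' @param config An [analysis_config()].
#' @return List with `kept` ([protein_records()], input order) and
#'   `dropped` (drop report: id, reason, metric).
#' @export
curate_orthologs <- function(records, alignment = NULL,
                             exclude_ids = character(0),
                             config = analysis_config()) {
  man <- records$id %in% exclude_ids
  report <- drop_report(records$id[man],
                        rep("manual_exclusion", sum(man)),
                        records$length[man])
  cur <- reset_rows(records[!man, , drop = FALSE])

  st <- dedupe_by_species(cur)
  report <- rbind(report, st$dropped)

  st <- filter_fragments(st$kept, alignment,
                         config$fragment_min_fraction)
  report <- rbind(report, st$dropped)

  st <- filter_length_outliers(st$kept, config$length_outlier_ratio)
  report <- rbind(report, st$dropped)

  list(kept = st$kept, dropped = reset_rows(report))
}

reset_rows <- function(df) {
  rownames(df) <- NULL
  df
}
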