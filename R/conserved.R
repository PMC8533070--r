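# Conserved amyloidogenic region calling on the column profile, the
# amyloid-vs-identity contrast, and back-projection to member sequences.

#' Call conserved amyloidogenic regions
#'
#' Maximal runs of at least `min_run` consecutive unmasked columns whose
#' amyloid fraction is `>=` `conservation_threshold`. Masked
#' (gap-dominated) columns break runs.
#'
#' @param profile A `column_profile` from [build_profile()].
#' @param conservation_threshold Minimum amyloid fraction, default 0.7.
#' @param min_run Minimum run length in columns, default 5.
#' @return A [regions()] data frame labelled `"conserved_amyloid"` on
#'   alignment coordinates (`seq_id` = `"alignment"`); `score` is the mean
#'   amyloid fraction over the run.
#' @export
call_conserved_amyloid_regions <- function(profile,
                                           conservation_threshold = 0.7,
                                           min_run = 5L) {
  ok <- !profile$masked & profile$amyloid_fraction >= conservation_threshold
  runs <- mask_runs(ok)
  runs <- runs[runs$end - runs$start + 1L >= min_run, , drop = FALSE]
  if (!nrow(runs)) return(empty_regions())
  sc <- mapply(function(s, e) mean(profile$amyloid_fraction[s:e]),
               runs$start, runs$end)
  regions("alignment", runs$start, runs$end, "conserved_amyloid", sc)
}

#' Contrast amyloid conservation with sequence identity
#'
#' For each conserved region, computes the mean amyloid fraction and the
#' mean residue identity over its unmasked columns, and their difference.
#' A positive difference means the tendency to aggregate is conserved more
#' strongly than the sequence itself in that region.
#'
#' @param profile A `column_profile`.
#' @param conserved_regions [regions()] on alignment coordinates, as
#'   returned by [call_conserved_amyloid_regions()].
#' @return Data frame with one row per region: `start`, `end` (columns),
#'   `n_columns`, `mean_amyloid_fraction`, `mean_identity`, `difference`.
#' @export
conservation_contrast <- function(profile, conserved_regions) {
  if (!nrow(conserved_regions)) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_columns = integer(0),
                      mean_amyloid_fraction = numeric(0),
                      mean_identity = numeric(0),
                      difference = numeric(0)))
  }
  out <- lapply(seq_len(nrow(conserved_regions)), function(i) {
    cols <- conserved_regions$start[i]:conserved_regions$end[i]
    cols <- cols[!profile$masked[cols]]
    if (!length(cols))
      stop(sprintf("region %d-%d has no unmasked columns",
                   conserved_regions$start[i], conserved_regions$end[i]),
           call. = FALSE)
    ma <- mean(profile$amyloid_fraction[cols])
    mi <- mean(profile$identity[cols])
    data.frame(start = conserved_regions$start[i],
               end = conserved_regions$end[i],
               n_columns = length(cols),
               mean_amyloid_fraction = ma, mean_identity = mi,
               difference = ma - mi)
  })
  do.call(rbind, out)
}

#' Back-project alignment-coordinate regions onto member sequences
#'
#' For every conserved region (alignment columns) and every alignment row,
#' reports the span of residues of that sequence falling inside the
#' region's columns; rows that are all-gap across the region contribute
#' nothing.
#'
#' @param conserved_regions [regions()] on alignment coordinates.
#' @param alignment An [alignment_matrix()].
#' @param label Label for the projected regions, default
#'   `"conserved_amyloid"`.
#' @return A [regions()] data frame in sequence coordinates.
#' @export
backproject_regions <- function(conserved_regions, alignment,
                                label = "conserved_amyloid") {
  if (!nrow(conserved_regions)) return(empty_regions())
  if (any(conserved_regions$end > alignment$n_columns))
    stop("region exceeds alignment width", call. = FALSE)
  out <- list()
  for (id in alignment$ids) {
    inv <- column_to_seq_map(alignment$rows[[id]])
    for (i in seq_len(nrow(conserved_regions))) {
      res <- inv[conserved_regions$start[i]:conserved_regions$end[i]]
      res <- res[!is.na(res)]
      if (!length(res)) next
      out[[length(out) + 1L]] <- regions(
        id, min(res), max(res), label, conserved_regions$score[i])
    }
  }
  if (!length(out)) return(empty_regions())
  reset_rows(do.call(rbind, out))
}
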