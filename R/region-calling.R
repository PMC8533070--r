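# Region calling: score tracks -> disordered segments, arch regions, and
# amyloidogenic regions (arches located in disorder).

mask_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Call disordered segments from a disorder track
#'
#' Maximal runs of consecutive residues whose disorder score is *strictly
#' greater* than the cutoff ("more than 0.3"). There is no minimum segment
#' length.
#'
#' @param track A [score_track()] of kind `"disorder"`.
#' @param cutoff Disorder cutoff, default 0.3; a residue scoring exactly
#'   at the cutoff is not disordered.
#' @return A [regions()] data frame labelled `"disordered"`, sorted and
#'   disjoint; `score` is the maximum track value in each segment.
#' @export
call_disordered_segments <- function(track, cutoff = 0.3) {
  stopifnot(inherits(track, "score_track"), track$kind == "disorder")
  runs <- mask_runs(track$values > cutoff)
  if (!nrow(runs)) return(empty_regions())
  sc <- mapply(function(s, e) max(track$values[s:e]),
               runs$start, runs$end)
  regions(track$seq_id, runs$start, runs$end, "disordered", sc)
}

#' Call arch regions from candidates or a cumulative track
#'
#' With a cumulative [score_track()], arch regions are maximal runs of
#' residues with score `>=` threshold. With an `arch_candidates` data frame
#' (from [scan_arches()]), every candidate whose normalized score is `>=`
#' threshold contributes its full span, and overlapping spans are merged.
#' The comparison is inclusive by convention (the tool threshold 0.575 is
#' itself a qualifying score); pass a marginally larger threshold for a
#' strict rule.
#'
#' @param x An `arch_candidates` data frame or an `arch_cumulative`
#'   [score_track()].
#' @param threshold Arch score threshold, default 0.575.
#' @return A [regions()] data frame labelled `"arch"`: disjoint, sorted,
#'   each carrying the maximum contributing score.
#' @export
call_arch_regions <- function(x, threshold = 0.575) {
  if (inherits(x, "score_track")) {
    stopifnot(x$kind == "arch_cumulative")
    runs <- mask_runs(x$values >= threshold)
    if (!nrow(runs)) return(empty_regions())
    sc <- mapply(function(s, e) max(x$values[s:e]), runs$start, runs$end)
    return(regions(x$seq_id, runs$start, runs$end, "arch", sc))
  }
  stopifnot(inherits(x, "arch_candidates") || is.data.frame(x))
  keep <- x[x$norm_score >= threshold, , drop = FALSE]
  if (!nrow(keep)) return(empty_regions())
  if (length(unique(keep$seq_id)) > 1L)
    stop("candidates mix several sequences", call. = FALSE)
  merged <- merge_intervals(keep$start, keep$end, keep$norm_score)
  regions(keep$seq_id[[1L]], merged$start, merged$end, "arch",
          merged$score)
}

# Merge possibly-overlapping intervals; score of a merged interval is the
# maximum score among the members it absorbed.
merge_intervals <- function(start, end, score = rep(NA_real_, length(start))) {
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  ms <- IRanges::start(ir)
  me <- IRanges::end(ir)
  msc <- vapply(seq_along(ms), function(i) {
    inside <- start >= ms[i] & end <= me[i]
    if (any(inside)) max(score[inside], na.rm = FALSE) else NA_real_
  }, numeric(1))
  data.frame(start = ms, end = me, score = msc)
}

#' Call amyloidogenic regions
#'
#' An arch region is amyloidogenic when it lies in an unstructured part of
#' the protein: it is retained iff the fraction of its residues falling
#' inside any disordered segment is at least `overlap_fraction`. Retained
#' regions are returned with their original bounds (not clipped to the
#' disorder), merged if overlapping. With `overlap_fraction` near 0 the
#' rule approaches "any overlap"; at 1 it is full containment.
#'
#' @param arch_regions [regions()] labelled `"arch"` for one sequence.
#' @param disordered [regions()] labelled `"disordered"` for the same
#'   sequence.
#' @param overlap_fraction Required residue-overlap fraction in (0, 1],
#'   default 0.5.
#' @return A [regions()] data frame labelled `"amyloidogenic"`.
#' @export
call_amyloidogenic_regions <- function(arch_regions, disordered,
                                       overlap_fraction = 0.5) {
  ids <- unique(c(arch_regions$seq_id, disordered$seq_id))
  if (length(ids) > 1L)
    stop("arch and disordered regions mix several sequences", call. = FALSE)
  if (!nrow(arch_regions) || !nrow(disordered)) return(empty_regions())
  n <- max(arch_regions$end, disordered$end)
  dis_mask <- region_mask(disordered, n)
  frac <- vapply(seq_len(nrow(arch_regions)), function(i) {
    idx <- arch_regions$start[i]:arch_regions$end[i]
    sum(dis_mask[idx]) / length(idx)
  }, numeric(1))
  keep <- arch_regions[frac >= overlap_fraction, , drop = FALSE]
  if (!nrow(keep)) return(empty_regions())
  merged <- merge_intervals(keep$start, keep$end, keep$score)
  regions(keep$seq_id[[1L]], merged$start, merged$end, "amyloidogenic",
          merged$score)
}

#' Is a protein a potential amyloid?
#'
#' A protein is a potential amyloid iff it has at least one amyloidogenic
#' region (one above-threshold arch located in disorder).
#'
#' @param amyloidogenic_regions [regions()] for one sequence.
#' @return `TRUE` iff the region set is non-empty.
#' @export
is_potential_amyloid <- function(amyloidogenic_regions) {
  nrow(amyloidogenic_regions) > 0L
}

#' Region calls for one sequence's tracks
#'
#' Convenience wrapper running the three calling steps on one sequence.
#'
#' @param arch_track `arch_cumulative` [score_track()].
#' @param dis_track `disorder` [score_track()].
#' @param config An [analysis_config()].
#' @return List with elements `disordered`, `arch`, `amyloidogenic`
#'   (region data frames) and `is_potential_amyloid`.
#' @export
call_regions <- function(arch_track, dis_track,
                         config = analysis_config()) {
  dis <- call_disordered_segments(dis_track, config$disorder_cutoff)
  arch <- call_arch_regions(arch_track, config$arch_threshold)
  amy <- call_amyloidogenic_regions(arch, dis, config$overlap_fraction)
  list(disordered = dis, arch = arch, amyloidogenic = amy,
       is_potential_amyloid = is_potential_amyloid(amy))
}
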