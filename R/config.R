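#' Analysis configuration
#'
#' Bundles every tunable threshold of the region-calling, curation,
#' projection and conserved-region stages. Defaults follow the published
#' predictor conventions where those exist (arch score threshold 0.575;
#' disorder cutoff 0.3, applied strictly: a residue is disordered only when
#' its score is *more than* the cutoff) and declared package conventions
#' elsewhere.
#'
#' @param arch_threshold Minimum normalized beta-arch score for a region to
#'   count as an arch region. Comparison is `>=` (see
#'   [call_arch_regions()]). Default 0.575.
#' @param disorder_cutoff Disorder score above which (strictly) a residue is
#'   considered unstructured. Default 0.3.
#' @param overlap_fraction Minimum fraction of an arch region's residues
#'   that must lie inside disordered segments for the region to be called
#'   amyloidogenic. In (0, 1]; 0.5 is a neutral majority rule; values near 0
#'   approximate "any overlap", 1 requires full containment. Default 0.5.
#' @param gap_mask_fraction Alignment columns with gap fraction strictly
#'   greater than this are masked out of column statistics. Default 0.5.
#' @param conservation_threshold Minimum per-column amyloid fraction for a
#'   column to qualify as conserved-amyloidogenic. Default 0.7.
#' @param min_conserved_run Minimum number of consecutive qualifying columns
#'   for a conserved region. Default 5.
#' @param length_outlier_ratio Sequences longer than this multiple of the
#'   median length are dropped as over-long outliers. Default 1.5.
#' @param fragment_min_fraction Sequences shorter than this fraction of the
#'   median length are fragment candidates. Default 0.5.
#'
#' @return An object of class `analysis_config` (a validated named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$arch_threshold
#' @export
analysis_config <- function(arch_threshold = 0.575,
                            disorder_cutoff = 0.3,
                            overlap_fraction = 0.5,
                            gap_mask_fraction = 0.5,
                            conservation_threshold = 0.7,
                            min_conserved_run = 5L,
                            length_outlier_ratio = 1.5,
                            fragment_min_fraction = 0.5) {
  stop_unless <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  in01 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= 0 && x <= 1
  frac01 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x > 0 && x <= 1

  stop_unless(in01(arch_threshold), "arch_threshold must be in [0, 1]")
  stop_unless(in01(disorder_cutoff), "disorder_cutoff must be in [0, 1]")
  stop_unless(in01(conservation_threshold),
              "conservation_threshold must be in [0, 1]")
  stop_unless(frac01(overlap_fraction), "overlap_fraction must be in (0, 1]")
  stop_unless(frac01(gap_mask_fraction),
              "gap_mask_fraction must be in (0, 1]")
  stop_unless(frac01(fragment_min_fraction),
              "fragment_min_fraction must be in (0, 1]")
  stop_unless(is.numeric(length_outlier_ratio) &&
                length(length_outlier_ratio) == 1L &&
                length_outlier_ratio > 0,
              "length_outlier_ratio must be a positive number")
  min_conserved_run <- as.integer(min_conserved_run)
  stop_unless(length(min_conserved_run) == 1L && !is.na(min_conserved_run) &&
                min_conserved_run >= 1L,
              "min_conserved_run must be a positive integer")

  structure(
    list(arch_threshold = arch_threshold,
         disorder_cutoff = disorder_cutoff,
         overlap_fraction = overlap_fraction,
         gap_mask_fraction = gap_mask_fraction,
         conservation_threshold = conservation_threshold,
         min_conserved_run = min_conserved_run,
         length_outlier_ratio = length_outlier_ratio,
         fragment_min_fraction = fragment_min_fraction),
    class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
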