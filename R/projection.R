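# Gap-aware projection of per-sequence region calls onto alignment
# columns, and the per-column conservation profile.

#' Map residue indices to alignment columns
#'
#' @param row A gapped row string from a validated [alignment_matrix()].
#' @return Integer vector `m` with `m[r]` = alignment column of residue
#'   `r`; strictly increasing over `1..(ungapped length)`. Its inverse is
#'   defined on non-gap columns only (see [column_to_seq_map()]).
#' @examples
#' seq_to_column_map("A-CD")  # 1, 3, 4
#' @export
seq_to_column_map <- function(row) {
  which(strsplit(row, "")[[1L]] != "-")
}

#' Map alignment columns back to residue indices
#'
#' @param row A gapped row string.
#' @return Integer vector over columns: residue index at each non-gap
#'   column, `NA` at gap columns.
#' @export
column_to_seq_map <- function(row) {
  chars <- strsplit(row, "")[[1L]]
  out <- rep(NA_integer_, length(chars))
  nongap <- chars != "-"
  out[nongap] <- seq_len(sum(nongap))
  out
}

alignment_char_matrix <- function(alignment) {
  if (!length(alignment$ids))
    return(matrix(character(0), nrow = 0, ncol = alignment$n_columns))
  matrix(unlist(strsplit(alignment$rows, ""), use.names = FALSE),
         nrow = length(alignment$ids), ncol = alignment$n_columns,
         byrow = TRUE, dimnames = list(alignment$ids, NULL))
}

#' Per-column fraction of sequences inside an amyloidogenic region
#'
#' For each alignment column, the fraction of sequences in which the
#' residue at that column is included in an amyloidogenic region. The
#' denominator counts only the rows with a residue (non-gap) at the
#' column; an all-gap column gets fraction 0.
#'
#' @param alignment An [alignment_matrix()].
#' @param amyloid_regions A [regions()] data frame of amyloidogenic calls
#'   (sequence coordinates); every `seq_id` must have an alignment row.
#'   Rows with no regions still count in denominators.
#' @return Numeric vector of length `n_columns`.
#' @export
column_amyloid_fraction <- function(alignment, amyloid_regions) {
  unknown <- setdiff(unique(amyloid_regions$seq_id), alignment$ids)
  if (length(unknown))
    stop(sprintf("region for unknown alignment row '%s'", unknown[1L]),
         call. = FALSE)
  M <- alignment_char_matrix(alignment)
  nongap <- M != "-"
  amy <- matrix(FALSE, nrow = nrow(M), ncol = ncol(M))
  for (i in seq_along(alignment$ids)) {
    id <- alignment$ids[[i]]
    reg <- amyloid_regions[amyloid_regions$seq_id == id, , drop = FALSE]
    if (!nrow(reg)) next
    map <- which(nongap[i, ])
    mask <- region_mask(reg, length(map))
    amy[i, map[mask]] <- TRUE
  }
  den <- colSums(nongap)
  num <- colSums(amy)
  ifelse(den == 0L, 0, num / den)
}

#' Per-column sequence identity
#'
#' Identity of a column is the frequency of its modal residue among the
#' non-gap residues; an all-gap column gets 0.
#'
#' @param alignment An [alignment_matrix()].
#' @return Numeric vector of length `n_columns`.
#' @export
column_identity <- function(alignment) {
  M <- alignment_char_matrix(alignment)
  if (ncol(M) == 0L) return(numeric(0))
  den <- colSums(M != "-")
  letters_used <- setdiff(unique(as.vector(M)), "-")
  modal <- rep(0L, ncol(M))
  for (a in letters_used) modal <- pmax(modal, colSums(M == a))
  ifelse(den == 0L, 0, modal / den)
}

#' Build the per-column conservation profile
#'
#' Assembles, for every alignment column: the amyloid fraction
#' ([column_amyloid_fraction()]), the gap fraction (gaps over all rows),
#' the residue identity ([column_identity()]), the number of non-gap
#' residues, and a gap mask (`gap_fraction > gap_mask_fraction`) that
#' excludes gap-dominated columns from downstream statistics.
#'
#' @param alignment An [alignment_matrix()].
#' @param amyloid_regions A [regions()] data frame of amyloidogenic calls.
#' @param config An [analysis_config()].
#' @return A data frame of class `column_profile` with columns `column`,
#'   `amyloid_fraction`, `gap_fraction`, `identity`, `n_residues`,
#'   `masked`, plus attributes `n_sequences` and `config`.
#' @export
build_profile <- function(alignment, amyloid_regions,
                          config = analysis_config()) {
  M <- alignment_char_matrix(alignment)
  nrows <- length(alignment$ids)
  gap_fraction <- if (nrows) colSums(M == "-") / nrows else
    rep(1, alignment$n_columns)
  out <- data.frame(
    column = seq_len(alignment$n_columns),
    amyloid_fraction = column_amyloid_fraction(alignment, amyloid_regions),
    gap_fraction = gap_fraction,
    identity = column_identity(alignment),
    n_residues = if (nrows) as.integer(colSums(M != "-")) else integer(0),
    stringsAsFactors = FALSE)
  out$masked <- out$gap_fraction > config$gap_mask_fraction
  attr(out, "n_sequences") <- nrows
  attr(out, "config") <- config
  class(out) <- c("column_profile", "data.frame")
  out
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf(
    "Column profile: %d columns over %d sequences (%d masked)\n",
    nrow(x), attr(x, "n_sequences"), sum(x$masked)))
  um <- x[!x$masked, , drop = FALSE]
  if (nrow(um)) {
    cat(sprintf("  unmasked columns: mean amyloid fraction %.3f, mean identity %.3f\n",
                mean(um$amyloid_fraction), mean(um$identity)))
  }
  invisible(x)
}

#' @export
summary.column_profile <- function(object, ...) {
  cfg <- attr(object, "config")
  reg <- call_conserved_amyloid_regions(object,
                                        cfg$conservation_threshold,
                                        cfg$min_conserved_run)
  print(object)
  if (nrow(reg)) {
    cat(sprintf("  %d conserved amyloidogenic region(s):\n", nrow(reg)))
    con <- conservation_contrast(object, reg)
    for (i in seq_len(nrow(con))) {
      cat(sprintf(
        "    columns %d-%d: amyloid %.3f vs identity %.3f (diff %+.3f)\n",
        con$start[i], con$end[i], con$mean_amyloid_fraction[i],
        con$mean_identity[i], con$difference[i]))
    }
  } else {
    cat("  no conserved amyloidogenic regions at current thresholds\n")
  }
  invisible(object)
}

#' Plot a conservation profile as a two-track heatmap
#'
#' Mirrors the usual family-conservation figure layout: one strip for
#' per-column sequence identity and one for the amyloid fraction; masked
#' (gap-dominated) columns are blanked.
#'
#' @param x A `column_profile`.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.column_profile <- function(x, ...) {
  vals <- rbind(identity = x$identity,
                amyloid_fraction = x$amyloid_fraction)
  vals[, x$masked] <- NA_real_
  op <- par(mar = c(4, 8, 2, 1))
  on.exit(par(op))
  image(x = x$column, y = 1:2, z = t(vals[2:1, , drop = FALSE]),
        zlim = c(0, 1), col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "alignment column", ylab = "", yaxt = "n",
        main = "Conservation profile")
  axis(2, at = 1:2, labels = c("amyloid fraction", "identity"),
       las = 1, tick = FALSE)
  box()
  invisible(x)
}
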