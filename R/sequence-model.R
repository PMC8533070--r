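# Core domain containers and standard-format readers/writers.
# Coordinates: 1-based inclusive on ungapped sequences; gap character "-".

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET21 <- c(AA_ALPHABET20, "X")
REGION_LABELS <- c("arch", "disordered", "amyloidogenic",
                   "conserved_amyloid", "annotation")

#' Construct a set of protein records
#'
#' A protein record set is the package's container for ungapped protein
#' sequences: a data frame with columns `id`, `species`, `sequence` and
#' `length`. Sequences may use the 20 amino-acid letters plus `X`; ids must
#' be unique and non-empty.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param sequence Character vector of ungapped protein sequences.
#' @param species Character vector of species tags (`NA` allowed unless a
#'   downstream step needs them).
#' @return A `protein_records` data frame.
#' @examples
#' protein_records(c("P1", "P2"), c("MFGQ", "QQNN"),
#'                 c("Homo_sapiens", "Mus_musculus"))
#' @export
protein_records <- function(id, sequence, species = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  species <- rep_len(as.character(species), length(id))
  if (length(sequence) != length(id))
    stop("id and sequence must have equal length", call. = FALSE)
  if (any(!nzchar(id)) || anyNA(id))
    stop("sequence ids must be non-empty", call. = FALSE)
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1L]
    stop(sprintf("duplicate sequence id: '%s'", dup), call. = FALSE)
  }
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop(sprintf(
      "invalid character in sequence '%s' at position %d ('%s')",
      id[i], bad[i], substr(sequence[i], bad[i], bad[i])), call. = FALSE)
  }
  out <- data.frame(id = id, species = species, sequence = sequence,
                    length = nchar(sequence), stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Headers are parsed as `>id [...] species=<tag> [...]`; alternatively a
#' two-column tab-separated sidecar file (`id<TAB>species`) can supply the
#' species tags, which takes precedence over header tokens.
#'
#' @param path Path to a FASTA file of ungapped protein sequences.
#' @param require_species Error if any record ends up without a species tag.
#' @param species_file Optional path to a two-column TSV mapping id to
#'   species.
#' @return A [protein_records()] data frame, in file order.
#' @export
read_fasta <- function(path, require_species = FALSE, species_file = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  # read as raw strings so the package's own alphabet validation (with
  # residue positions in error messages) applies
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) {
    return(protein_records(character(0), character(0), character(0)))
  }
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  species <- extract_header_token(headers, "species")
  if (!is.null(species_file)) {
    map <- read.delim(species_file, header = FALSE, sep = "\t",
                      col.names = c("id", "species"),
                      colClasses = "character")
    hit <- match(ids, map$id)
    species[!is.na(hit)] <- map$species[hit[!is.na(hit)]]
  }
  if (require_species && anyNA(species)) {
    miss <- ids[is.na(species)][1L]
    stop(sprintf("no species resolvable for record '%s'", miss),
         call. = FALSE)
  }
  protein_records(ids, as.character(aa), species)
}

extract_header_token <- function(headers, key) {
  pat <- paste0(key, "=([^\\s]+)")
  m <- regmatches(headers, regexpr(pat, headers, perl = TRUE))
  out <- rep(NA_character_, length(headers))
  has <- grepl(pat, headers, perl = TRUE)
  out[has] <- sub(paste0(".*", key, "="), "", m)
  out
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Construct an alignment matrix
#'
#' @param rows Named character vector: gapped row strings, names are
#'   sequence ids. All rows must have identical length.
#' @return An object of class `alignment_matrix` with elements `ids`,
#'   `rows` (named character) and `n_columns`.
#' @examples
#' alignment_matrix(c(P1 = "A-CD", P2 = "ABCD"))
#' @export
alignment_matrix <- function(rows) {
  ids <- names(rows)
  rows <- setNames(toupper(as.character(rows)), ids)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("alignment rows must be named by sequence id", call. = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate alignment row id: '%s'",
                 ids[duplicated(ids)][1L]), call. = FALSE)
  w <- nchar(rows)
  if (length(unique(w)) > 1L)
    stop(sprintf("ragged alignment: row lengths %s",
                 paste(unique(w), collapse = ", ")), call. = FALSE)
  structure(list(ids = ids, rows = rows,
                 n_columns = if (length(w)) w[[1L]] else 0L,
                 gap_char = "-"),
            class = "alignment_matrix")
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("Alignment: %d rows x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

#' Subset an alignment to a set of row ids
#'
#' @param alignment An [alignment_matrix()].
#' @param ids Sequence ids to keep (order of `ids` is preserved).
#' @return An `alignment_matrix` over the requested rows. Columns are kept
#'   as-is (columns that become all-gap stay in place and are handled by
#'   gap masking downstream).
#' @export
subset_alignment <- function(alignment, ids) {
  miss <- setdiff(ids, alignment$ids)
  if (length(miss))
    stop(sprintf("no alignment row for id '%s'", miss[1L]), call. = FALSE)
  alignment_matrix(alignment$rows[ids])
}

#' Read a multiple alignment from an aligned FASTA file
#'
#' Every row id (first header token) must match a record id, and every row
#' with gaps removed must equal that record's sequence exactly.
#'
#' @param path Path to an aligned FASTA file.
#' @param records A [protein_records()] set the rows must be consistent
#'   with.
#' @return An [alignment_matrix()].
#' @export
read_alignment <- function(path, records) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  aa <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  rows <- setNames(toupper(as.character(aa)), ids)
  aln <- alignment_matrix(rows)
  check_alignment_records(aln, records)
  aln
}

check_alignment_records <- function(alignment, records) {
  unknown <- setdiff(alignment$ids, records$id)
  if (length(unknown))
    stop(sprintf("alignment row '%s' matches no sequence record",
                 unknown[1L]), call. = FALSE)
  for (id in alignment$ids) {
    got <- degap(alignment$rows[[id]])
    want <- records$sequence[records$id == id]
    if (!identical(got, want)) {
      a <- strsplit(got, "")[[1L]]
      b <- strsplit(want, "")[[1L]]
      n <- min(length(a), length(b))
      diff <- which(a[seq_len(n)] != b[seq_len(n)])
      at <- if (length(diff)) diff[1L] else n + 1L
      stop(sprintf(
        "alignment row '%s' disagrees with its sequence at residue %d",
        id, at), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Construct a per-residue score track
#'
#' @param seq_id Sequence the track belongs to.
#' @param kind Either `"arch_cumulative"` (beta-arch cumulative score) or
#'   `"disorder"`.
#' @param values Numeric vector in `[0, 1]`, one value per residue.
#' @param provenance Free-text origin tag: `"external"` for tracks read from
#'   predictor output, `"standin_simplified"` for the bundled scorers,
#'   `"synthetic"` for simulated tracks.
#' @return An object of class `score_track`.
#' @export
score_track <- function(seq_id, kind = c("arch_cumulative", "disorder"),
                        values, provenance = "external") {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0 | values > 1)) {
    bad <- which(is.na(values) | values < 0 | values > 1)[1L]
    stop(sprintf("score out of [0, 1] for '%s' at position %d",
                 seq_id, bad), call. = FALSE)
  }
  structure(list(seq_id = as.character(seq_id), kind = kind,
                 values = values, provenance = provenance),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track %s> %s, %d residues, range [%.3f, %.3f] (%s)\n",
              x$kind, x$seq_id, length(x$values),
              min(x$values), max(x$values), x$provenance))
  invisible(x)
}

#' Read per-residue score tracks from a tab-separated table
#'
#' The generic carrier for external predictor output: a TSV with header
#' columns `seq_id`, `position` (1-based) and `score`. Positions must cover
#' `1..length` contiguously for each sequence, and scores must already be in
#' `[0, 1]` (out-of-range values are rejected, not clipped).
#'
#' @param path Path to the TSV file.
#' @param kind Track kind, `"arch_cumulative"` or `"disorder"`.
#' @param records Optional [protein_records()]; when given, track lengths
#'   are checked against sequence lengths and ids must be known.
#' @return Named list of [score_track()] objects, one per `seq_id`, in
#'   first-appearance order.
#' @export
read_score_table <- function(path, kind = c("arch_cumulative", "disorder"),
                             records = NULL) {
  kind <- match.arg(kind)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "numeric"))
  need <- c("seq_id", "position", "score")
  if (!all(need %in% names(tab)))
    stop("score table must have columns seq_id, position, score",
         call. = FALSE)
  out <- list()
  for (id in unique(tab$seq_id)) {
    sub <- tab[tab$seq_id == id, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    n <- max(sub$position)
    missing <- setdiff(seq_len(n), sub$position)
    if (length(missing))
      stop(sprintf("missing position %d for sequence '%s'",
                   missing[1L], id), call. = FALSE)
    if (anyDuplicated(sub$position))
      stop(sprintf("duplicated position for sequence '%s'", id),
           call. = FALSE)
    if (!is.null(records)) {
      if (!id %in% records$id)
        stop(sprintf("score table references unknown sequence '%s'", id),
             call. = FALSE)
      want <- records$length[records$id == id]
      if (n != want)
        stop(sprintf(
          "track for '%s' has %d positions but the sequence has %d residues",
          id, n, want), call. = FALSE)
    }
    out[[id]] <- score_track(id, kind, sub$score, provenance = "external")
  }
  out
}

#' Write score tracks to the 3-column TSV carrier format
#'
#' @param tracks Named list of [score_track()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(seq_id = tr$seq_id, position = seq_along(tr$values),
               score = tr$values, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(tab)) {
    tab <- data.frame(seq_id = character(0), position = integer(0),
                      score = numeric(0))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a region table
#'
#' Regions are 1-based inclusive intervals on ungapped sequences (or, for
#' conserved-region calls, on alignment columns with `seq_id`
#' `"alignment"`).
#'
#' @param seq_id Character vector of sequence ids.
#' @param start,end Integer vectors, `1 <= start <= end`.
#' @param label One of `"arch"`, `"disordered"`, `"amyloidogenic"`,
#'   `"conserved_amyloid"`, `"annotation"` (recycled).
#' @param score Optional numeric score (recycled; `NA` allowed).
#' @return A data frame with columns `seq_id`, `start`, `end`, `label`,
#'   `score`.
#' @examples
#' regions("P1", 146, 213, "amyloidogenic", 0.9)
#' @export
regions <- function(seq_id = character(0), start = integer(0),
                    end = integer(0), label = "annotation",
                    score = NA_real_) {
  n <- length(start)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(end) != n)
    stop("start and end must have equal length", call. = FALSE)
  if (length(seq_id) != n) {
    if (length(seq_id) == 1L && n > 0L) seq_id <- rep(seq_id, n) else
      if (n > 0L || length(seq_id) > 0L)
        stop("seq_id must match start/end length", call. = FALSE)
  }
  label <- rep_len(as.character(label), n)
  score <- rep_len(as.numeric(score), n)
  if (n > 0) {
    if (!all(label %in% REGION_LABELS))
      stop(sprintf("unknown region label '%s'",
                   setdiff(label, REGION_LABELS)[1L]), call. = FALSE)
    if (any(start < 1L) || any(end < start))
      stop("regions require 1 <= start <= end", call. = FALSE)
  }
  data.frame(seq_id = as.character(seq_id), start = start, end = end,
             label = label, score = score, stringsAsFactors = FALSE)
}

empty_regions <- function() regions()

#' Write regions as BED
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention (`start - 1`, `end`). The BED score column is the
#' region score scaled by 1000 and truncated to `[0, 1000]` (`NA` scores
#' become 0).
#'
#' @param reg A [regions()] data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_regions_bed()] for the inverse.
#' @export
write_regions_bed <- function(reg, path) {
  if (nrow(reg) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  sc <- ifelse(is.na(reg$score), 0, reg$score)
  sc <- as.integer(pmin(pmax(round(sc * 1000), 0), 1000))
  bed <- data.frame(chrom = reg$seq_id, start = reg$start - 1L,
                    end = reg$end, name = reg$label, score = sc)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read regions from a BED file written by [write_regions_bed()]
#'
#' @param path Path to a 5-column BED file.
#' @return A [regions()] data frame (scores divided back by 1000).
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0L) return(empty_regions())
  bed <- read.delim(path, header = FALSE, sep = "\t",
                    col.names = c("chrom", "start", "end", "name", "score"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "numeric"))
  regions(bed$chrom, bed$start + 1L, bed$end, bed$name, bed$score / 1000)
}

# Rasterize regions for one sequence into a per-residue logical mask.
region_mask <- function(reg, length) {
  mask <- logical(length)
  if (nrow(reg)) {
    if (any(reg$end > length))
      stop("region exceeds sequence length", call. = FALSE)
    for (i in seq_len(nrow(reg))) mask[reg$start[i]:reg$end[i]] <- TRUE
  }
  mask
}
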