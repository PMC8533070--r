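# Simplified stand-in scorers. These exist so the pipeline runs end-to-end
# with no external predictor binaries; they are labelled
# "standin_simplified" in track provenance and make no claim to reproduce
# the external tools whose output the package can also read.

#' Read a 21-letter propensity scale
#'
#' Scales are two-column (letter, value) tab-separated text files with
#' `#` comment lines; exactly the 20 amino acids plus `X` must be present
#' and all values finite.
#'
#' @param path Path to the scale file.
#' @param note Provenance note stored with the scale.
#' @return Named numeric vector of length 21 with a `provenance` attribute.
#' @export
read_propensity_scale <- function(path, note = path) {
  tab <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                    col.names = c("letter", "value"),
                    colClasses = c("character", "numeric"))
  scale <- setNames(tab$value, toupper(tab$letter))
  if (!setequal(names(scale), AA_ALPHABET21) ||
      length(scale) != 21L || !all(is.finite(scale)))
    stop("scale must give one finite value for each of the 20 amino acids plus X",
         call. = FALSE)
  scale <- scale[AA_ALPHABET21]
  attr(scale, "provenance") <- note
  scale
}

#' @rdname read_propensity_scale
#' @export
default_arch_scale <- function() {
  read_propensity_scale(
    system.file("extdata", "arch_propensity_scale.tsv",
                package = "amylofam"),
    note = "synthetic stand-in beta-aggregation scale (bundled)")
}

#' @rdname read_propensity_scale
#' @export
default_disorder_scale <- function() {
  read_propensity_scale(
    system.file("extdata", "disorder_propensity_scale.tsv",
                package = "amylofam"),
    note = "synthetic stand-in disorder scale (bundled)")
}

#' Enumerate and score candidate beta-arches (simplified stand-in)
#'
#' A beta-arch is modelled as strand1-loop-strand2 with contiguous parts.
#' All placements with strand lengths in `strand_len` and loop lengths in
#' `loop_len` are enumerated. The raw score of a candidate is the mean
#' scale value over both strand windows minus a proline penalty of 0.5 per
#' proline in a strand; the normalized score is
#' `plogis((raw - mu) / s)`. With the bundled scale and default `mu`, `s`,
#' poly-Q/poly-N strands score above 0.575 and poly-P/poly-E strands stay
#' below 0.2 (the stand-in's calibration contract).
#'
#' @param record A single-row [protein_records()] data frame, or a plain
#'   sequence string.
#' @param scale A 21-letter propensity scale ([default_arch_scale()]).
#' @param strand_len Length-2 integer vector: min and max strand length.
#' @param loop_len Length-2 integer vector: min and max loop length.
#' @param mu,s Location and scale of the logistic normalization.
#' @param seq_id Sequence id when `record` is a plain string.
#' @return Data frame of class `arch_candidates`, sorted by decreasing
#'   `norm_score` (ties by start, then total span length), with columns
#'   `seq_id`, `start`, `end`, `strand1_len`, `loop_len`, `strand2_len`,
#'   `raw_score`, `norm_score`. Sequences too short for any placement give
#'   zero rows.
#' @examples
#' head(scan_arches(strrep("Q", 30)))
#' @export
scan_arches <- function(record, scale = default_arch_scale(),
                        strand_len = c(4L, 9L), loop_len = c(1L, 15L),
                        mu = 0.5, s = 0.1, seq_id = NULL) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    seq <- record$sequence
    seq_id <- record$id
  } else {
    seq <- as.character(record)
    if (is.null(seq_id)) seq_id <- "seq"
  }
  chars <- strsplit(toupper(seq), "")[[1L]]
  L <- length(chars)
  v <- unname(scale[chars])
  if (anyNA(v)) stop("sequence contains letters missing from the scale",
                     call. = FALSE)
  cs <- c(0, cumsum(v))
  cp <- c(0, cumsum(chars == "P"))
  win_sum <- function(st, len) cs[st + len] - cs[st]
  win_pro <- function(st, len) cp[st + len] - cp[st]

  acc <- vector("list", 0L)
  for (a in strand_len[1L]:strand_len[2L]) {
    for (l in loop_len[1L]:loop_len[2L]) {
      for (b in strand_len[1L]:strand_len[2L]) {
        span <- a + l + b
        if (span > L) next
        st <- seq_len(L - span + 1L)
        raw <- (win_sum(st, a) + win_sum(st + a + l, b)) / (a + b) -
          0.5 * (win_pro(st, a) + win_pro(st + a + l, b))
        acc[[length(acc) + 1L]] <- data.frame(
          start = st, end = st + span - 1L, strand1_len = a,
          loop_len = l, strand2_len = b, raw_score = raw)
      }
    }
  }
  if (!length(acc)) {
    out <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand1_len = integer(0),
                      loop_len = integer(0), strand2_len = integer(0),
                      raw_score = numeric(0), norm_score = numeric(0))
  } else {
    out <- do.call(rbind, acc)
    out$norm_score <- plogis((out$raw_score - mu) / s)
    out <- cbind(seq_id = seq_id, out)
    out <- out[order(-out$norm_score, out$start, out$end - out$start), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("arch_candidates", "data.frame")
  out
}

#' Per-residue cumulative arch score track
#'
#' Reduces scored arch candidates to one value per residue: the maximum
#' normalized score over all candidates whose full strand1..strand2 span
#' covers the residue, 0 where no candidate covers. Maximum (rather than a
#' sum) preserves "at least one arch" semantics.
#'
#' @param candidates An `arch_candidates` data frame from [scan_arches()].
#' @param length Sequence length.
#' @param seq_id Sequence id (defaults to the candidates' id).
#' @return A [score_track()] of kind `"arch_cumulative"` with provenance
#'   `"standin_simplified"`.
#' @export
cumulative_track <- function(candidates, length, seq_id = NULL) {
  if (is.null(seq_id)) {
    seq_id <- if (nrow(candidates)) candidates$seq_id[[1L]] else "seq"
  }
  vals <- numeric(length)
  if (nrow(candidates)) {
    if (any(candidates$start < 1L) || any(candidates$end > length))
      stop("arch candidate out of sequence bounds", call. = FALSE)
    # collapse to the best score per distinct (start, end) span first
    key <- paste(candidates$start, candidates$end)
    best <- tapply(candidates$norm_score, key, max)
    se <- do.call(rbind, strsplit(names(best), " "))
    st <- as.integer(se[, 1L]); en <- as.integer(se[, 2L])
    for (i in seq_along(best)) {
      idx <- st[i]:en[i]
      vals[idx] <- pmax(vals[idx], best[[i]])
    }
  }
  score_track(seq_id, "arch_cumulative", vals,
              provenance = "standin_simplified")
}

#' Per-residue disorder score track (simplified stand-in)
#'
#' The value at residue `i` is the mean disorder-scale value over a window
#' centred at `i` (truncated at the termini), min-max rescaled to `[0, 1]`
#' within the sequence; a sequence whose windowed means are constant gets
#' 0.5 everywhere. The disorder cutoff (default 0.3) then applies on the
#' rescaled track.
#'
#' @param record A single-row [protein_records()] data frame or a plain
#'   sequence string.
#' @param scale A 21-letter disorder scale ([default_disorder_scale()]).
#' @param window Odd window width, >= 1.
#' @param seq_id Sequence id when `record` is a plain string.
#' @return A [score_track()] of kind `"disorder"` with provenance
#'   `"standin_simplified"`.
#' @export
disorder_track <- function(record, scale = default_disorder_scale(),
                           window = 21L, seq_id = NULL) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    seq <- record$sequence
    seq_id <- record$id
  } else {
    seq <- as.character(record)
    if (is.null(seq_id)) seq_id <- "seq"
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1", call. = FALSE)
  chars <- strsplit(toupper(seq), "")[[1L]]
  L <- length(chars)
  v <- unname(scale[chars])
  if (anyNA(v)) stop("sequence contains letters missing from the scale",
                     call. = FALSE)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  m <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  rng <- range(m)
  vals <- if (diff(rng) < .Machine$double.eps^0.5) {
    rep(0.5, L)
  } else {
    (m - rng[1L]) / diff(rng)
  }
  score_track(seq_id, "disorder", vals, provenance = "standin_simplified")
}
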