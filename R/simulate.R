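# Synthetic ortholog-family generator with full ground truth. Families
# emulate a mostly-disordered barrier-nucleoporin-like protein: a
# disorder-biased background with interspersed FG dipeptides, implanted
# aggregation-prone (Q/N/hydrophobic-rich) motifs, and a star phylogeny of
# descendants carrying substitutions and indels (indels never inside
# motifs, so truth regions stay contiguous). Species duplicates, a
# C-terminal fragment and an over-long outlier are appended so the
# curation rules have known positives.

BG_LETTERS <- c("G", "S", "Q", "N", "E", "K", "P", "A", "T", "D", "R")
BG_WEIGHTS <- c(0.14, 0.14, 0.10, 0.08, 0.10, 0.10, 0.08, 0.07, 0.07,
                0.06, 0.06)
MOTIF_LETTERS <- c("Q", "N", "I", "V", "F", "Y", "L", "M")
MOTIF_WEIGHTS <- c(0.28, 0.28, 0.10, 0.10, 0.08, 0.08, 0.04, 0.04)

#' Specification of a synthetic ortholog family
#'
#' Defaults define the package's reference study conditions: 20 species,
#' 600-residue ancestor, two implanted amyloidogenic motifs (at 150 for 60
#' residues, echoing a main amyloidogenic region in the mid-N-terminal
#' part of the protein, and at 320 for 40), 30% background / 10%
#' within-motif per-site substitution, 2% per-site indel rate outside
#' motifs, plus two same-species duplicates, one C-terminal fragment and
#' one over-long outlier for the curation rules to find.
#'
#' @param n_species Number of primary descendant species.
#' @param seq_length Ancestor length in residues.
#' @param motifs List of `c(position, length)` pairs, non-overlapping and
#'   within the sequence.
#' @param p_sub_background Per-site substitution probability outside
#'   motifs.
#' @param p_sub_motif Per-site substitution probability inside motifs
#'   (substitutions stay within the aggregation-prone residue class).
#' @param p_indel Per-site probability (outside motifs) of starting an
#'   indel event.
#' @param max_indel_len Maximum indel length; lengths are uniform on
#'   `1..max_indel_len`.
#' @param duplicate_species Number of same-species duplicate records to
#'   append.
#' @param fragment_count Number of C-terminal fragment records to append.
#' @param outlier_count Number of over-long outlier records to append.
#' @param seed Integer seed; all randomness flows through it.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_species = 20L, seq_length = 600L,
                        motifs = list(c(150L, 60L), c(320L, 40L)),
                        p_sub_background = 0.3, p_sub_motif = 0.1,
                        p_indel = 0.02, max_indel_len = 5L,
                        duplicate_species = 2L, fragment_count = 1L,
                        outlier_count = 1L, seed = 1L) {
  spec <- list(n_species = as.integer(n_species),
               seq_length = as.integer(seq_length),
               motifs = lapply(motifs, as.integer),
               p_sub_background = p_sub_background,
               p_sub_motif = p_sub_motif,
               p_indel = p_indel,
               max_indel_len = as.integer(max_indel_len),
               duplicate_species = as.integer(duplicate_species),
               fragment_count = as.integer(fragment_count),
               outlier_count = as.integer(outlier_count),
               seed = as.integer(seed))
  probs <- c(spec$p_sub_background, spec$p_sub_motif, spec$p_indel)
  if (any(probs < 0 | probs > 1))
    stop("substitution and indel probabilities must be in [0, 1]",
         call. = FALSE)
  if (spec$n_species < 1L || spec$seq_length < 1L)
    stop("n_species and seq_length must be positive", call. = FALSE)
  iv <- t(vapply(spec$motifs, function(m) c(m[1L], m[1L] + m[2L] - 1L),
                 integer(2)))
  if (any(iv[, 1L] < 1L) || any(iv[, 2L] > spec$seq_length))
    stop("motifs must lie within [1, seq_length]", call. = FALSE)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
    stop("motifs overlap", call. = FALSE)
  structure(spec, class = "family_spec")
}

motif_intervals <- function(spec) {
  t(vapply(spec$motifs, function(m) c(m[1L], m[1L] + m[2L] - 1L),
           integer(2)))
}

motif_site_mask <- function(spec) {
  mask <- logical(spec$seq_length)
  iv <- motif_intervals(spec)
  for (i in seq_len(nrow(iv))) mask[iv[i, 1L]:iv[i, 2L]] <- TRUE
  mask
}

# One mutated descendant of the ancestor: substituted characters plus an
# indel history in ancestral coordinates (deletions marked per position,
# insertions keyed by the slot after an ancestral position).
mutate_descendant <- function(anc, spec, motif_mask) {
  L <- spec$seq_length
  chars <- anc
  bg_idx <- which(!motif_mask)
  sub_bg <- bg_idx[runif(length(bg_idx)) < spec$p_sub_background]
  if (length(sub_bg))
    chars[sub_bg] <- sample(BG_LETTERS, length(sub_bg), replace = TRUE,
                            prob = BG_WEIGHTS)
  mo_idx <- which(motif_mask)
  sub_mo <- mo_idx[runif(length(mo_idx)) < spec$p_sub_motif]
  if (length(sub_mo))
    chars[sub_mo] <- sample(MOTIF_LETTERS, length(sub_mo), replace = TRUE,
                            prob = MOTIF_WEIGHTS)

  deleted <- logical(L)
  ins <- list()
  log <- list()
  ev <- bg_idx[runif(length(bg_idx)) < spec$p_indel]
  for (p in ev) {
    len <- sample.int(spec$max_indel_len, 1L)
    if (runif(1) < 0.5) {
      rng <- p:min(p + len - 1L, L)
      rng <- rng[!motif_mask[rng]]
      deleted[rng] <- TRUE
      log[[length(log) + 1L]] <- data.frame(
        type = "del", anc_pos = p, length = length(rng))
    } else {
      str <- paste(sample(BG_LETTERS, len, replace = TRUE,
                          prob = BG_WEIGHTS), collapse = "")
      key <- as.character(p)
      ins[[key]] <- paste0(if (is.null(ins[[key]])) "" else ins[[key]],
                           str)
      log[[length(log) + 1L]] <- data.frame(
        type = "ins", anc_pos = p, length = len)
    }
  }
  list(chars = chars, deleted = deleted, ins = ins,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(type = character(0), anc_pos = integer(0),
                    length = integer(0)))
}

ins_len_at <- function(desc, p) {
  s <- desc$ins[[as.character(p)]]
  if (is.null(s)) 0L else nchar(s)
}

#' Simulate an ortholog family with ground truth
#'
#' Generates a disorder-biased ancestor with implanted aggregation-prone
#' motifs, independent descendants under the spec's substitution and indel
#' rates (star phylogeny), and the appended curation targets: same-species
#' duplicates (trimmed C-terminally so the primary is always the longest),
#' C-terminal fragments (the last third of a fresh descendant, aligning
#' only in the C-terminal columns), and over-long outliers (a fresh
#' descendant carrying an internal isoform-like insertion of one ancestor
#' length, about twice the family median length). The true alignment is
#' built from the recorded residue homology to ancestral coordinates; the
#' output is fully reproducible from the spec's seed.
#'
#' @param spec A [family_spec()].
#' @return List with elements `records` ([protein_records()]),
#'   `alignment` ([alignment_matrix()]) and `truth`, a list of class
#'   `family_truth` with: `regions` (true amyloidogenic regions per
#'   sequence), `column_homology` (ancestral position per alignment
#'   column, `NA` for insert columns), `conserved_columns` (logical, true
#'   motif columns), `injected_drops` (data frame of the appended
#'   curation-target ids and their kinds), `indel_log`, `motifs`, `seed`.
#' @examples
#' fam <- simulate_family(family_spec(n_species = 4, seq_length = 200,
#'                                    motifs = list(c(60L, 30L)),
#'                                    duplicate_species = 1, seed = 7))
#' fam$records$id
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  L <- spec$seq_length
  motif_mask <- motif_site_mask(spec)
  iv <- motif_intervals(spec)

  anc <- sample(BG_LETTERS, L, replace = TRUE, prob = BG_WEIGHTS)
  fg_at <- seq(10L, L - 1L, by = 25L)
  fg_at <- fg_at[!motif_mask[fg_at] & !motif_mask[fg_at + 1L]]
  anc[fg_at] <- "F"
  anc[fg_at + 1L] <- "G"
  for (i in seq_len(nrow(iv))) {
    idx <- iv[i, 1L]:iv[i, 2L]
    anc[idx] <- sample(MOTIF_LETTERS, length(idx), replace = TRUE,
                       prob = MOTIF_WEIGHTS)
  }

  if (spec$duplicate_species > spec$n_species)
    stop("more duplicates requested than species", call. = FALSE)
  dup_trim <- 80L
  frag_cut <- (2L * L) %/% 3L + 1L
  out_slot <- max(1L, min(50L, iv[1L, 1L] - 1L))
  if (spec$fragment_count > 0L && nrow(iv) && max(iv[, 2L]) >= frag_cut)
    stop("motifs extend into the fragment cut region", call. = FALSE)
  if (spec$duplicate_species > 0L && nrow(iv) &&
      max(iv[, 2L]) > L - dup_trim)
    stop("motifs extend into the duplicate trim region", call. = FALSE)

  members <- list()
  add_member <- function(id, species, keep_min, keep_max, desc,
                         kind = "primary") {
    members[[length(members) + 1L]] <<- c(
      desc, list(id = id, species = species, keep_min = keep_min,
                 keep_max = keep_max, kind = kind))
  }
  for (i in seq_len(spec$n_species)) {
    add_member(sprintf("ortho%02d", i), sprintf("sp%02d", i), 1L, L,
               mutate_descendant(anc, spec, motif_mask))
  }
  for (d in seq_len(spec$duplicate_species)) {
    add_member(sprintf("ortho%02d_dup", d), sprintf("sp%02d", d),
               1L, L - dup_trim,
               mutate_descendant(anc, spec, motif_mask),
               kind = "duplicate_species")
  }
  for (f in seq_len(spec$fragment_count)) {
    add_member(sprintf("frag%d", f), sprintf("frag_sp%d", f),
               frag_cut, L,
               mutate_descendant(anc, spec, motif_mask),
               kind = "c_terminal_fragment")
  }
  for (o in seq_len(spec$outlier_count)) {
    desc <- mutate_descendant(anc, spec, motif_mask)
    key <- as.character(out_slot)
    ext <- paste(sample(BG_LETTERS, L, replace = TRUE, prob = BG_WEIGHTS),
                 collapse = "")
    desc$ins[[key]] <- paste0(ext,
                              if (is.null(desc$ins[[key]])) "" else
                                desc$ins[[key]])
    desc$log <- rbind(desc$log,
                      data.frame(type = "ins", anc_pos = out_slot,
                                 length = L))
    add_member(sprintf("long%d", o), sprintf("long_sp%d", o), 1L, L,
               desc, kind = "length_outlier")
  }

  # column layout: one match column per ancestral position, followed by
  # max-insertion-length padding columns for the slot after that position
  ins_width <- integer(L)
  for (m in members) {
    slots <- as.integer(names(m$ins))
    slots <- slots[slots >= m$keep_min & slots <= m$keep_max]
    for (p in slots)
      ins_width[p] <- max(ins_width[p], ins_len_at(m, p))
  }
  homology <- unlist(lapply(seq_len(L), function(p) {
    c(p, rep(NA_integer_, ins_width[p]))
  }))
  n_columns <- length(homology)

  rows <- character(length(members))
  for (k in seq_along(members)) {
    m <- members[[k]]
    pieces <- character(2L * L)
    for (p in seq_len(L)) {
      keepp <- p >= m$keep_min && p <= m$keep_max
      pieces[2L * p - 1L] <- if (keepp && !m$deleted[p]) m$chars[p] else "-"
      if (ins_width[p] > 0L) {
        s <- if (keepp) m$ins[[as.character(p)]] else NULL
        if (is.null(s)) s <- ""
        pieces[2L * p] <- paste0(s, strrep("-", ins_width[p] - nchar(s)))
      }
    }
    rows[k] <- paste(pieces, collapse = "")
  }
  ids <- vapply(members, `[[`, character(1), "id")
  names(rows) <- ids
  alignment <- alignment_matrix(rows)
  stopifnot(alignment$n_columns == n_columns)

  records <- protein_records(
    ids, degap(rows), vapply(members, `[[`, character(1), "species"))

  # truth regions: each motif shifted by the member's indel history
  treg <- list()
  for (m in members) {
    for (i in seq_len(nrow(iv))) {
      ms <- iv[i, 1L]; me <- iv[i, 2L]
      if (ms < m$keep_min || me > m$keep_max) next
      before <- if (ms > m$keep_min) {
        rng <- m$keep_min:(ms - 1L)
        sum(!m$deleted[rng]) +
          sum(vapply(rng, function(p) ins_len_at(m, p), integer(1)))
      } else 0L
      treg[[length(treg) + 1L]] <- regions(
        m$id, before + 1L, before + (me - ms) + 1L, "amyloidogenic")
    }
  }
  truth_regions <- if (length(treg)) reset_rows(do.call(rbind, treg)) else
    empty_regions()

  conserved_columns <- !is.na(homology) & motif_mask[
    ifelse(is.na(homology), 1L, homology)]
  conserved_columns[is.na(homology)] <- FALSE

  logs <- lapply(members, function(m) {
    if (nrow(m$log)) cbind(seq_id = m$id, m$log) else NULL
  })
  logs <- logs[!vapply(logs, is.null, logical(1))]
  indel_log <- if (length(logs)) reset_rows(do.call(rbind, logs)) else
    data.frame(seq_id = character(0), type = character(0),
               anc_pos = integer(0), length = integer(0))

  injected <- data.frame(
    id = ids,
    kind = vapply(members, `[[`, character(1), "kind"),
    stringsAsFactors = FALSE)
  injected <- injected[injected$kind != "primary", , drop = FALSE]

  truth <- structure(
    list(regions = truth_regions, column_homology = homology,
         conserved_columns = conserved_columns,
         injected_drops = reset_rows(injected),
         indel_log = indel_log, motifs = iv, seed = spec$seed),
    class = "family_truth")

  list(records = records, alignment = alignment, truth = truth)
}

#' Simulate predictor score tracks from ground truth
#'
#' Stands in for external predictor output on a simulated family: the
#' arch cumulative track is 0.8 inside true amyloidogenic regions and 0.3
#' outside; the disorder track is 0.6 everywhere except an ordered stub
#' (the first 50 residues of each sequence) at 0.2. Gaussian noise of the
#' given standard deviation is added and values are clipped to `[0, 1]`.
#'
#' @param records A [protein_records()] data frame.
#' @param truth A `family_truth` from [simulate_family()].
#' @param noise_sd Noise standard deviation, default 0.1.
#' @param seed Integer seed.
#' @param stub_length Length of the ordered N-terminal stub, default 50.
#' @return List with named lists `arch` and `disorder` of [score_track()]
#'   objects (provenance `"synthetic"`).
#' @export
simulate_tracks <- function(records, truth, noise_sd = 0.1, seed = 1L,
                            stub_length = 50L) {
  stopifnot(inherits(truth, "family_truth"))
  set.seed(as.integer(seed))
  arch <- list()
  disorder <- list()
  clip <- function(x) pmin(pmax(x, 0), 1)
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    n <- records$length[i]
    reg <- truth$regions[truth$regions$seq_id == id, , drop = FALSE]
    mask <- region_mask(reg, n)
    a <- ifelse(mask, 0.8, 0.3)
    d <- rep(0.6, n)
    d[seq_len(min(stub_length, n))] <- 0.2
    if (noise_sd > 0) {
      a <- a + rnorm(n, sd = noise_sd)
      d <- d + rnorm(n, sd = noise_sd)
    }
    arch[[id]] <- score_track(id, "arch_cumulative", clip(a),
                              provenance = "synthetic")
    disorder[[id]] <- score_track(id, "disorder", clip(d),
                                  provenance = "synthetic")
  }
  list(arch = arch, disorder = disorder)
}

#' Write a family's ground truth to plain-text files
#'
#' @param truth A `family_truth`.
#' @param regions_path Output TSV for true regions (`seq_id`, `start`,
#'   `end`).
#' @param columns_path Output TSV for column truth (`column`,
#'   `is_conserved`).
#' @return Invisibly, the two paths.
#' @export
write_truth <- function(truth, regions_path, columns_path) {
  write.table(truth$regions[, c("seq_id", "start", "end")], regions_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(column = seq_along(truth$conserved_columns),
                         is_conserved = truth$conserved_columns),
              columns_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(regions_path, columns_path))
}
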