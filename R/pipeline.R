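# End-to-end driver: simulate or load inputs, score, call regions, curate,
# project, call conserved regions, and write a reproducible output tree.

#' Write protein records to FASTA
#'
#' Headers are `>id species=<tag>` (the `species=` token is omitted for
#' records without a tag).
#'
#' @param records A [protein_records()] data frame.
#' @param path Output path.
#' @param gapped Optional named character vector of gapped rows to write
#'   instead of the ungapped sequences (for aligned FASTA).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, gapped = NULL) {
  seqs <- if (is.null(gapped)) setNames(records$sequence, records$id) else
    gapped
  hdr <- names(seqs)
  sp <- records$species[match(names(seqs), records$id)]
  hdr <- ifelse(is.na(sp), hdr, paste0(hdr, " species=", sp))
  x <- Biostrings::AAStringSet(setNames(unname(seqs), hdr))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Run the full amyloid-conservation pipeline
#'
#' Either simulates a synthetic family (`synthetic = TRUE`) or consumes
#' user inputs (records + alignment, with optional external score
#' tracks), then: scores every sequence (external tracks if given,
#' otherwise the simplified stand-in scorers), calls disordered, arch and
#' amyloidogenic regions, curates the ortholog set, builds the per-column
#' conservation profile over the curated rows, calls conserved
#' amyloidogenic regions, and writes all results plus a run manifest to
#' `out_dir`.
#'
#' Output files: `summary.tsv` (per protein: number of amyloidogenic
#' regions, potential-amyloid flag), `amyloid_regions.bed`,
#' `drop_report.tsv`, `column_profile.tsv`, `conserved_regions.tsv`,
#' `conserved_backprojected.bed`, `arch_scores.tsv`,
#' `disorder_scores.tsv`, `manifest.txt`; for synthetic runs also
#' `sequences.fasta`, `alignment.fasta`, `truth_regions.tsv`,
#' `truth_columns.tsv`; optionally `heatmap.png`.
#'
#' @param out_dir Output directory (created if missing).
#' @param records A [protein_records()] data frame (ignored when
#'   `synthetic`).
#' @param alignment An [alignment_matrix()] (ignored when `synthetic`).
#' @param arch_tracks,disorder_tracks Optional named lists of external
#'   [score_track()]s (e.g. from [read_score_table()]); when absent the
#'   bundled stand-in scorers are used.
#' @param exclude_ids Character vector of manually excluded ids.
#' @param config An [analysis_config()].
#' @param synthetic Simulate the inputs instead of consuming them.
#' @param spec A [family_spec()] for synthetic runs; its `seed` is
#'   overridden by `seed`.
#' @param noise_sd Track noise for synthetic runs.
#' @param seed Integer seed for every source of randomness in the run.
#' @param heatmap Also write `heatmap.png` of the conservation profile.
#' @return Invisibly, a list with the in-memory results: `records`,
#'   `alignment`, `calls`, `curation`, `profile`, `conserved`,
#'   `contrast`, `truth` (synthetic only) and `out_dir`.
#' @export
run_pipeline <- function(out_dir,
                         records = NULL, alignment = NULL,
                         arch_tracks = NULL, disorder_tracks = NULL,
                         exclude_ids = character(0),
                         config = analysis_config(),
                         synthetic = FALSE, spec = family_spec(),
                         noise_sd = 0.1, seed = 1L,
                         heatmap = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (synthetic) {
    spec$seed <- as.integer(seed)
    fam <- simulate_family(spec)
    records <- fam$records
    alignment <- fam$alignment
    truth <- fam$truth
    tr <- simulate_tracks(records, truth, noise_sd = noise_sd,
                          seed = seed + 1L)
    arch_tracks <- tr$arch
    disorder_tracks <- tr$disorder
    provenance <- "synthetic"
    write_fasta(records, file.path(out_dir, "sequences.fasta"))
    write_fasta(records, file.path(out_dir, "alignment.fasta"),
                gapped = alignment$rows)
    write_truth(truth, file.path(out_dir, "truth_regions.tsv"),
                file.path(out_dir, "truth_columns.tsv"))
  } else {
    if (is.null(records))
      stop("stage input: records are required for a non-synthetic run",
           call. = FALSE)
    if (is.null(alignment))
      stop("stage input: an alignment is required (projection and the fragment rule need it)",
           call. = FALSE)
    check_alignment_records(alignment, records)
    provenance <- if (is.null(arch_tracks) && is.null(disorder_tracks))
      "standin_simplified" else "external"
  }

  # stage: scoring (fill whatever tracks were not supplied)
  if (is.null(arch_tracks)) {
    arch_tracks <- lapply(seq_len(nrow(records)), function(i) {
      cand <- scan_arches(records[i, , drop = FALSE])
      cumulative_track(cand, records$length[i], seq_id = records$id[i])
    })
    names(arch_tracks) <- records$id
  }
  if (is.null(disorder_tracks)) {
    disorder_tracks <- lapply(seq_len(nrow(records)), function(i) {
      disorder_track(records[i, , drop = FALSE])
    })
    names(disorder_tracks) <- records$id
  }
  miss <- setdiff(records$id, names(arch_tracks))
  if (length(miss))
    stop(sprintf("stage scoring: no arch track for '%s'", miss[1L]),
         call. = FALSE)
  miss <- setdiff(records$id, names(disorder_tracks))
  if (length(miss))
    stop(sprintf("stage scoring: no disorder track for '%s'", miss[1L]),
         call. = FALSE)
  write_score_table(arch_tracks[records$id],
                    file.path(out_dir, "arch_scores.tsv"))
  write_score_table(disorder_tracks[records$id],
                    file.path(out_dir, "disorder_scores.tsv"))

  # stage: per-sequence region calling
  calls <- lapply(records$id, function(id) {
    call_regions(arch_tracks[[id]], disorder_tracks[[id]], config)
  })
  names(calls) <- records$id
  amy <- do.call(rbind, c(lapply(calls, `[[`, "amyloidogenic"),
                          list(make.row.names = FALSE)))
  if (is.null(amy)) amy <- empty_regions()
  summary_tab <- data.frame(
    seq_id = records$id,
    n_amyloidogenic_regions = vapply(calls, function(cl)
      nrow(cl$amyloidogenic), integer(1)),
    is_potential_amyloid = vapply(calls, `[[`, logical(1),
                                  "is_potential_amyloid"))
  write.table(summary_tab, file.path(out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_regions_bed(amy, file.path(out_dir, "amyloid_regions.bed"))

  # stage: curation
  cur <- curate_orthologs(records, alignment, exclude_ids, config)
  write.table(cur$dropped, file.path(out_dir, "drop_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # stage: projection over the curated rows
  kept_aln <- subset_alignment(alignment, cur$kept$id)
  kept_amy <- amy[amy$seq_id %in% cur$kept$id, , drop = FALSE]
  profile <- build_profile(kept_aln, kept_amy, config)
  write.table(as.data.frame(profile),
              file.path(out_dir, "column_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # stage: conserved regions and contrast
  conserved <- call_conserved_amyloid_regions(
    profile, config$conservation_threshold, config$min_conserved_run)
  contrast <- conservation_contrast(profile, conserved)
  write.table(contrast, file.path(out_dir, "conserved_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_regions_bed(backproject_regions(conserved, kept_aln),
                    file.path(out_dir, "conserved_backprojected.bed"))

  write_manifest(file.path(out_dir, "manifest.txt"), config, seed,
                 provenance, synthetic, spec, noise_sd,
                 n_input = nrow(records), n_kept = nrow(cur$kept))
  if (heatmap) {
    png(file.path(out_dir, "heatmap.png"), width = 1200, height = 400)
    plot(profile)
    dev.off()
  }

  invisible(list(records = records, alignment = alignment,
                 calls = calls, amyloidogenic = amy, curation = cur,
                 profile = profile, conserved = conserved,
                 contrast = contrast, truth = truth, out_dir = out_dir))
}

write_manifest <- function(path, config, seed, provenance, synthetic,
                           spec, noise_sd, n_input, n_kept) {
  lines <- c(
    "# amylofam run manifest",
    paste0("tool_version=", as.character(packageVersion("amylofam"))),
    paste0("seed=", seed),
    paste0("scorer_provenance=", provenance),
    paste0("n_input_sequences=", n_input),
    paste0("n_kept_sequences=", n_kept),
    "[analysis_config]",
    "# arch_threshold / disorder_cutoff are predictor defaults (0.575; strictly > 0.3);",
    "# the remaining thresholds are package conventions",
    vapply(names(unclass(config)), function(nm)
      paste0(nm, "=", format(config[[nm]])), character(1)))
  if (synthetic) {
    sp <- unclass(spec)
    sp$motifs <- paste(vapply(sp$motifs, function(m)
      paste(m, collapse = ":"), character(1)), collapse = ",")
    lines <- c(lines, "[family_spec]",
               vapply(names(sp), function(nm)
                 paste0(nm, "=", format(sp[[nm]])), character(1)),
               paste0("noise_sd=", format(noise_sd)))
  }
  writeLines(lines, path)
  invisible(path)
}
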