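# Synthetic family generator: determinism, zero-mutation limit, truth
# consistency through the alignment, and simulated track levels.

small_spec <- function(...) {
  family_spec(n_species = 5L, seq_length = 200L,
              motifs = list(c(50L, 30L), c(90L, 20L)), seed = 101L, ...)
}

test_that("family_spec validates motifs and probabilities", {
  expect_error(family_spec(motifs = list(c(150L, 60L), c(180L, 40L))),
               "overlap")
  expect_error(family_spec(motifs = list(c(590L, 60L))), "within")
  expect_error(family_spec(p_sub_background = 1.2), "probabilities")
})

test_that("zero-mutation limit reproduces the ancestor with no gaps", {
  spec <- family_spec(n_species = 4L, seq_length = 150L,
                      motifs = list(c(50L, 30L)),
                      p_sub_background = 0, p_sub_motif = 0, p_indel = 0,
                      duplicate_species = 0L, fragment_count = 0L,
                      outlier_count = 0L, seed = 5L)
  fam <- simulate_family(spec)
  expect_equal(length(unique(fam$records$sequence)), 1L)
  expect_equal(fam$alignment$n_columns, 150L)
  expect_false(any(grepl("-", fam$alignment$rows, fixed = TRUE)))
  expect_equal(fam$truth$regions$start, rep(50L, 4))
  expect_equal(fam$truth$regions$end, rep(79L, 4))
  expect_equal(which(fam$truth$conserved_columns), 50:79)
})

test_that("simulation is byte-identical for a fixed seed", {
  a <- simulate_family(small_spec())
  b <- simulate_family(small_spec())
  expect_identical(a$records, b$records)
  expect_identical(a$alignment$rows, b$alignment$rows)
  expect_identical(a$truth, b$truth)
  ta <- simulate_tracks(a$records, a$truth, seed = 7L)
  tb <- simulate_tracks(b$records, b$truth, seed = 7L)
  expect_identical(lapply(ta$arch, `[[`, "values"),
                   lapply(tb$arch, `[[`, "values"))
  # and a different seed moves the noise
  tc <- simulate_tracks(a$records, a$truth, seed = 8L)
  expect_false(identical(ta$arch[[1]]$values, tc$arch[[1]]$values))
})

test_that("alignment rows degap to the record sequences", {
  fam <- simulate_family(small_spec())
  for (id in fam$records$id) {
    expect_identical(gsub("-", "", fam$alignment$rows[[id]], fixed = TRUE),
                     fam$records$sequence[fam$records$id == id])
  }
})

test_that("truth regions project onto exactly the motif homology columns", {
  fam <- simulate_family(family_spec(seed = 31L))
  iv <- fam$truth$motifs
  hom <- fam$truth$column_homology
  for (i in seq_len(nrow(fam$truth$regions))) {
    tr <- fam$truth$regions[i, ]
    row <- fam$alignment$rows[[tr$seq_id]]
    cols <- seq_to_column_map(row)[tr$start:tr$end]
    anc <- hom[cols]
    # the region's residues sit on consecutive ancestral motif positions
    expect_false(anyNA(anc))
    expect_equal(anc, anc[1]:(anc[1] + length(anc) - 1L))
    hit <- which(iv[, 1L] == anc[1])
    expect_length(hit, 1L)
    expect_equal(anc[length(anc)], iv[hit, 2L])
  }
  # every primary record carries every motif
  primaries <- setdiff(fam$records$id, fam$truth$injected_drops$id)
  tab <- table(fam$truth$regions$seq_id[
    fam$truth$regions$seq_id %in% primaries])
  expect_true(all(tab == nrow(iv)))
})

test_that("injected duplicates, fragments and outliers have the stated shapes", {
  fam <- simulate_family(family_spec(seed = 13L))
  rec <- fam$records
  inj <- fam$truth$injected_drops
  med <- median(rec$length)
  frag <- rec[rec$id %in% inj$id[inj$kind == "c_terminal_fragment"], ]
  expect_true(all(frag$length < 0.5 * med))
  outl <- rec[rec$id %in% inj$id[inj$kind == "length_outlier"], ]
  expect_true(all(outl$length > 1.5 * med))
  for (d in inj$id[inj$kind == "duplicate_species"]) {
    sp <- rec$species[rec$id == d]
    main_len <- max(rec$length[rec$species == sp & rec$id != d])
    expect_lt(rec$length[rec$id == d], main_len)
  }
})

test_that("simulated tracks hit the stated levels and separate regions", {
  fam <- simulate_family(small_spec())
  tr0 <- simulate_tracks(fam$records, fam$truth, noise_sd = 0, seed = 1L)
  id <- fam$records$id[1]
  n <- fam$records$length[1]
  reg <- fam$truth$regions[fam$truth$regions$seq_id == id, ]
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(reg))) mask[reg$start[i]:reg$end[i]] <- TRUE
  expect_equal(tr0$arch[[id]]$values, ifelse(mask, 0.8, 0.3))
  expect_equal(tr0$disorder[[id]]$values[1:50], rep(0.2, 50))
  expect_equal(unique(tr0$disorder[[id]]$values[51:n]), 0.6)
  # the ordered stub is never called disordered in the noiseless limit
  dis <- call_disordered_segments(tr0$disorder[[id]], 0.3)
  expect_true(all(dis$start > 50L))

  trn <- simulate_tracks(fam$records, fam$truth, noise_sd = 0.1, seed = 2L)
  sep <- vapply(fam$records$id, function(id) {
    n <- fam$records$length[fam$records$id == id]
    reg <- fam$truth$regions[fam$truth$regions$seq_id == id, ]
    if (!nrow(reg)) return(NA_real_)
    mask <- rep(FALSE, n)
    for (i in seq_len(nrow(reg))) mask[reg$start[i]:reg$end[i]] <- TRUE
    mean(trn$arch[[id]]$values[mask]) - mean(trn$arch[[id]]$values[!mask])
  }, numeric(1))
  expect_true(all(sep[!is.na(sep)] > 0))
})

test_that("truth files are written as plain TSV", {
  fam <- simulate_family(small_spec())
  rp <- tempfile(fileext = ".tsv")
  cp <- tempfile(fileext = ".tsv")
  write_truth(fam$truth, rp, cp)
  reg <- read.delim(rp)
  expect_equal(names(reg), c("seq_id", "start", "end"))
  cols <- read.delim(cp)
  expect_equal(nrow(cols), fam$alignment$n_columns)
  expect_equal(sum(cols$is_conserved),
               sum(fam$truth$conserved_columns))
})
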