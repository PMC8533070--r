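# Ortholog curation rules: species dedup, C-terminal fragments, length
# outliers; partition, order-preservation and idempotence properties.

recs <- function(ids, lens, species = ids) {
  protein_records(ids, vapply(lens, function(n) strrep("A", n),
                              character(1)), species)
}

test_that("dedupe_by_species keeps the longest record, ties by smallest id", {
  r <- recs(c("h1", "h2", "m1"), c(500, 480, 300),
            c("Homo_sapiens", "Homo_sapiens", "Mus_musculus"))
  st <- dedupe_by_species(r)
  expect_equal(st$kept$id, c("h1", "m1"))
  expect_equal(st$dropped$id, "h2")
  expect_equal(st$dropped$reason, "duplicate_species")

  # tie on length: lexicographically smallest id wins
  tie <- recs(c("B", "A"), c(100, 100), c("sp", "sp"))
  expect_equal(dedupe_by_species(tie)$kept$id, "A")

  uniq <- recs(c("x", "y"), c(10, 20), c("s1", "s2"))
  st2 <- dedupe_by_species(uniq)
  expect_equal(st2$kept$id, c("x", "y"))
  expect_equal(nrow(st2$dropped), 0L)

  nosp <- protein_records("p", "AAAA", NA)
  expect_error(dedupe_by_species(nosp), "p")
})

test_that("filter_fragments drops short C-terminal-only records", {
  r <- recs(c("a", "b", "c", "d"), c(600, 590, 580, 200))
  # fragment aligns only to the last third of the columns
  rows <- c(a = strrep("A", 600), b = paste0(strrep("A", 590), strrep("-", 10)),
            c = paste0(strrep("A", 580), strrep("-", 20)),
            d = paste0(strrep("-", 400), strrep("A", 200)))
  aln <- alignment_matrix(rows)
  st <- filter_fragments(r, aln, 0.5)
  expect_equal(st$dropped$id, "d")
  expect_equal(st$dropped$reason, "c_terminal_fragment")
  expect_equal(st$kept$id, c("a", "b", "c"))

  # a short N-terminal fragment is kept: the rule targets C-terminal-only
  rows2 <- rows
  rows2["d"] <- paste0(strrep("A", 200), strrep("-", 400))
  st2 <- filter_fragments(r, alignment_matrix(rows2), 0.5)
  expect_equal(nrow(st2$dropped), 0L)

  # nothing below half median -> identity
  r3 <- recs(c("a", "b", "c"), c(600, 590, 580))
  st3 <- filter_fragments(r3, alignment_matrix(rows[1:3]), 0.5)
  expect_equal(st3$kept$id, r3$id)

  # without an alignment, length rule alone plus a warning
  expect_warning(st4 <- filter_fragments(r, NULL, 0.5), "length alone")
  expect_equal(st4$dropped$id, "d")
  expect_equal(st4$dropped$reason, "short_fragment")
})

test_that("filter_length_outliers drops records above ratio x median", {
  r <- recs(c("a", "b", "c", "d"), c(500, 510, 520, 900))
  st <- filter_length_outliers(r, 1.5)  # median 515, bound 772.5
  expect_equal(st$dropped$id, "d")
  expect_equal(st$dropped$reason, "length_outlier")

  same <- recs(c("a", "b", "c"), c(500, 500, 500))
  expect_equal(nrow(filter_length_outliers(same, 1.5)$dropped), 0L)
  expect_equal(nrow(filter_length_outliers(r, Inf)$dropped), 0L)

  few <- recs(c("a", "b"), c(10, 1000))
  expect_warning(st2 <- filter_length_outliers(few, 1.5), "fewer than 3")
  expect_equal(st2$kept$id, c("a", "b"))
})

test_that("median for the outlier rule is computed once, before any drop", {
  # two outliers: with a once-computed median both go; a re-computed
  # median after dropping the larger would spare the smaller
  r <- recs(c("a", "b", "c", "d", "e"), c(500, 500, 500, 800, 1600))
  st <- filter_length_outliers(r, 1.5)
  expect_setequal(st$dropped$id, c("d", "e"))
})

test_that("curation partitions the input, preserves order, is idempotent", {
  r <- recs(c("k1", "k2", "dup", "frag", "long", "k3"),
            c(600, 610, 550, 200, 1400, 590),
            c("s1", "s2", "s2", "s4", "s5", "s6"))
  width <- 1400
  pad <- function(seq, lead = 0) {
    paste0(strrep("-", lead), seq, strrep("-", width - lead - nchar(seq)))
  }
  rows <- c(k1 = pad(r$sequence[1]), k2 = pad(r$sequence[2]),
            dup = pad(r$sequence[3]), frag = pad(r$sequence[4], 1100),
            long = pad(r$sequence[5]), k3 = pad(r$sequence[6]))
  aln <- alignment_matrix(rows)

  cur <- curate_orthologs(r, aln, exclude_ids = character(0))
  expect_equal(cur$kept$id, c("k1", "k2", "k3"))
  expect_setequal(cur$dropped$id, c("dup", "frag", "long"))
  expect_setequal(c(cur$kept$id, cur$dropped$id), r$id)
  expect_equal(sort(unique(cur$dropped$reason)),
               c("c_terminal_fragment", "duplicate_species",
                 "length_outlier"))

  # idempotence: curating the kept set changes nothing
  again <- curate_orthologs(cur$kept, aln)
  expect_equal(again$kept, cur$kept)
  expect_equal(nrow(again$dropped), 0L)

  # manual exclusions are applied first and reported
  cur2 <- curate_orthologs(r, aln, exclude_ids = "k1")
  expect_false("k1" %in% cur2$kept$id)
  expect_equal(cur2$dropped$reason[cur2$dropped$id == "k1"],
               "manual_exclusion")
})

test_that("individual filters are idempotent", {
  r <- recs(c("a", "b", "c", "d"), c(500, 510, 520, 900),
            c("s", "s", "t", "u"))
  d1 <- dedupe_by_species(r)
  expect_equal(dedupe_by_species(d1$kept)$kept, d1$kept)
  o1 <- filter_length_outliers(r, 1.5)
  expect_equal(filter_length_outliers(o1$kept, 1.5)$kept, o1$kept)
})
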