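# Brute-force oracles, kept deliberately independent of the package
# implementation (explicit per-residue loops, no interval libraries).

oracle_runs <- function(mask) {
  out <- list()
  i <- 1L
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L])
}

oracle_mask <- function(reg, n) {
  mask <- rep(FALSE, n)
  if (nrow(reg)) {
    for (i in seq_len(nrow(reg))) {
      for (p in reg$start[i]:reg$end[i]) mask[p] <- TRUE
    }
  }
  mask
}

# arch regions kept iff residue-overlap fraction with the disorder mask
# reaches `frac`; kept regions merged by rasterize-and-rescan
oracle_amyloid <- function(arch_runs, dis_mask, frac) {
  n <- length(dis_mask)
  keep_mask <- rep(FALSE, n)
  if (nrow(arch_runs)) {
    for (i in seq_len(nrow(arch_runs))) {
      idx <- arch_runs$start[i]:arch_runs$end[i]
      ov <- 0L
      for (p in idx) if (p <= n && dis_mask[p]) ov <- ov + 1L
      if (ov / length(idx) >= frac) keep_mask[idx] <- TRUE
    }
  }
  oracle_runs(keep_mask)
}

oracle_column_fraction <- function(aln, reg) {
  n <- aln$n_columns
  num <- integer(n)
  den <- integer(n)
  for (id in aln$ids) {
    chars <- strsplit(aln$rows[[id]], "")[[1L]]
    rr <- reg[reg$seq_id == id, , drop = FALSE]
    mask <- oracle_mask(rr, sum(chars != "-"))
    r <- 0L
    for (cc in seq_len(n)) {
      if (chars[cc] != "-") {
        r <- r + 1L
        den[cc] <- den[cc] + 1L
        if (mask[r]) num[cc] <- num[cc] + 1L
      }
    }
  }
  ifelse(den == 0L, 0, num / den)
}

# random instance generators --------------------------------------------

rand_track <- function(len, kind = "disorder") {
  score_track("S1", kind, runif(len))
}

rand_alignment <- function(n_rows, n_cols, p_gap = 0.25) {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  rows <- character(n_rows)
  for (i in seq_len(n_rows)) {
    chars <- ifelse(runif(n_cols) < p_gap, "-",
                    sample(letters20, n_cols, replace = TRUE))
    if (all(chars == "-")) chars[sample.int(n_cols, 1L)] <- "A"
    rows[i] <- paste(chars, collapse = "")
  }
  names(rows) <- sprintf("R%02d", seq_len(n_rows))
  alignment_matrix(rows)
}

rand_regions_for_alignment <- function(aln, max_regions = 3L) {
  out <- list()
  for (id in aln$ids) {
    len <- nchar(gsub("-", "", aln$rows[[id]], fixed = TRUE))
    k <- sample.int(max_regions + 1L, 1L) - 1L
    for (j in seq_len(k)) {
      s <- sample.int(len, 1L)
      e <- min(len, s + sample.int(30L, 1L) - 1L)
      out[[length(out) + 1L]] <- regions(id, s, e, "amyloidogenic")
    }
  }
  if (!length(out)) return(regions())
  do.call(rbind, out)
}

region_column_mask <- function(reg, n_columns) {
  mask <- rep(FALSE, n_columns)
  if (nrow(reg)) {
    for (i in seq_len(nrow(reg))) mask[reg$start[i]:reg$end[i]] <- TRUE
  }
  mask
}
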