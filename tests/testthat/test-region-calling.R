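# Region calling: threshold semantics, interval algebra, and equivalence
# with per-residue boolean oracles.

test_that("call_disordered_segments finds maximal strict-> runs", {
  tr <- score_track("S1", "disorder", c(0.1, 0.4, 0.5, 0.2, 0.35))
  seg <- call_disordered_segments(tr, 0.3)
  expect_equal(seg$start, c(2L, 5L))
  expect_equal(seg$end, c(3L, 5L))
  expect_equal(seg$label, rep("disordered", 2))

  # a score exactly at the cutoff is NOT disordered ("more than")
  tr2 <- score_track("S1", "disorder", c(0.3, 0.3, 0.3))
  expect_equal(nrow(call_disordered_segments(tr2, 0.3)), 0L)

  tr3 <- score_track("S1", "disorder", c(0.1, 0.2, 0.05))
  expect_equal(nrow(call_disordered_segments(tr3, 0.3)), 0L)
})

test_that("call_arch_regions merges candidate spans and scans tracks", {
  cand <- data.frame(seq_id = "S1", start = c(5L, 15L), end = c(20L, 28L),
                     norm_score = c(0.6, 0.8))
  class(cand) <- c("arch_candidates", "data.frame")
  reg <- call_arch_regions(cand, 0.575)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start, reg$end), c(5L, 28L))
  expect_equal(reg$score, 0.8)

  # a track value exactly at the threshold IS an arch region (>=)
  tr <- score_track("S1", "arch_cumulative", c(0.6, 0.6, 0.5))
  reg2 <- call_arch_regions(tr, 0.575)
  expect_equal(c(reg2$start, reg2$end), c(1L, 2L))
  tr575 <- score_track("S1", "arch_cumulative", c(0.575, 0.1))
  expect_equal(nrow(call_arch_regions(tr575, 0.575)), 1L)

  none <- cand[cand$norm_score > 0.9, , drop = FALSE]
  expect_equal(nrow(call_arch_regions(none, 0.575)), 0L)
})

test_that("call_amyloidogenic_regions applies the overlap-fraction rule", {
  arch <- regions("S1", 10L, 30L, "arch", 0.7)
  dis_wide <- regions("S1", 5L, 40L, "disordered")
  kept <- call_amyloidogenic_regions(arch, dis_wide, 0.5)
  expect_equal(c(kept$start, kept$end), c(10L, 30L))  # not clipped
  expect_equal(kept$label, "amyloidogenic")

  # overlap 6/21 = 0.286 < 0.5 -> dropped
  dis_part <- regions("S1", 25L, 60L, "disordered")
  expect_equal(nrow(call_amyloidogenic_regions(arch, dis_part, 0.5)), 0L)
  # ... but kept under an any-overlap rule, and dropped under containment
  expect_equal(nrow(call_amyloidogenic_regions(arch, dis_part, 1e-9)), 1L)
  expect_equal(nrow(call_amyloidogenic_regions(arch, dis_wide, 1)), 1L)
  expect_equal(nrow(call_amyloidogenic_regions(arch, dis_part, 1)), 0L)

  expect_equal(nrow(call_amyloidogenic_regions(arch, regions(), 0.5)), 0L)
  expect_error(call_amyloidogenic_regions(
    arch, regions("OTHER", 1L, 5L, "disordered"), 0.5), "several")
})

test_that("is_potential_amyloid is non-emptiness of the amyloid set", {
  expect_false(is_potential_amyloid(regions()))
  expect_true(is_potential_amyloid(regions("S1", 1L, 5L, "amyloidogenic")))
  five <- regions(rep("S1", 5), seq(1, 401, 100), seq(20, 420, 100),
                  "amyloidogenic")
  expect_true(is_potential_amyloid(five))
})

test_that("track-based calls match the per-residue boolean oracle", {
  set.seed(21)
  for (rep in 1:30) {
    L <- sample(10:150, 1)
    dis <- score_track("S1", "disorder", runif(L))
    arch <- score_track("S1", "arch_cumulative", runif(L))
    cutoff <- runif(1, 0.2, 0.8)
    thr <- runif(1, 0.2, 0.8)
    frac <- runif(1, 0.1, 1)

    dseg <- call_disordered_segments(dis, cutoff)
    want_d <- oracle_runs(dis$values > cutoff)
    expect_equal(dseg$start, want_d$start)
    expect_equal(dseg$end, want_d$end)

    aseg <- call_arch_regions(arch, thr)
    want_a <- oracle_runs(arch$values >= thr)
    expect_equal(aseg$start, want_a$start)
    expect_equal(aseg$end, want_a$end)

    amy <- call_amyloidogenic_regions(aseg, dseg, frac)
    if (nrow(aseg) && nrow(dseg)) {
      want_m <- oracle_amyloid(want_a, dis$values > cutoff, frac)
      expect_equal(amy$start, want_m$start)
      expect_equal(amy$end, want_m$end)
    } else {
      expect_equal(nrow(amy), 0L)
    }
  }
})

test_that("all called region sets are sorted and pairwise disjoint", {
  set.seed(31)
  for (rep in 1:20) {
    L <- sample(20:150, 1)
    cl <- call_regions(
      score_track("S1", "arch_cumulative", runif(L)),
      score_track("S1", "disorder", runif(L)))
    for (reg in cl[c("disordered", "arch", "amyloidogenic")]) {
      if (nrow(reg) < 2L) next
      expect_true(all(diff(reg$start) > 0))
      expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
    }
  }
})

test_that("raising thresholds never enlarges called sets", {
  set.seed(41)
  for (rep in 1:20) {
    L <- sample(20:120, 1)
    dis <- score_track("S1", "disorder", runif(L))
    arch <- score_track("S1", "arch_cumulative", runif(L))
    cuts <- sort(runif(2, 0.2, 0.8))
    lo_d <- region_column_mask(call_disordered_segments(dis, cuts[1]), L)
    hi_d <- region_column_mask(call_disordered_segments(dis, cuts[2]), L)
    expect_true(all(!hi_d | lo_d))
    lo_a <- region_column_mask(call_arch_regions(arch, cuts[1]), L)
    hi_a <- region_column_mask(call_arch_regions(arch, cuts[2]), L)
    expect_true(all(!hi_a | lo_a))
  }
})
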