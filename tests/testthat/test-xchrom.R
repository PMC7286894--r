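block <- list(contig = "X", start = 5e5, end = 2.5e6)

sim_block <- function(seed, asg = NULL, noise = 0, n_sites = 1500) {
  cfg <- sim_config(n_sites = n_sites, seed = seed)
  s <- simulate_populations(cfg)
  spec <- c(block, list(assignments = asg, noise = noise))
  simulate_x_mosaic(s$gt, s$truth, spec, seed = seed + 1)
}

test_that("reference-relative coding is 0 on matches and 1 on mismatches", {
  h1 <- rbind(c(0L, 1L), c(1L, 0L)); h2 <- h1
  gt <- make_gt(h1, h2, pos = c(100L, 200L), contig = "X",
                sex = c("F", "F"))
  M <- encode_reference_relative(gt, list(contig = "X", start = 1, end = 300))
  expect_equal(unname(M["s01.a", ]), c(0L, 1L))
  expect_equal(unname(M["s02.a", ]), c(1L, 0L))
  # flipped reference alleles invert the coding
  M2 <- encode_reference_relative(gt, list(contig = "X", start = 1, end = 300),
                                  ref_alleles = c(1L, 1L))
  expect_equal(unname(M2["s01.a", ]), c(1L, 0L))
  expect_error(encode_reference_relative(
    gt, list(contig = "X", start = 1, end = 300),
    ref_alleles = c(0L, NA)), "reference allele")
})

test_that("males contribute one haplotype, females two", {
  h1 <- matrix(0L, 2, 2); h2 <- matrix(1L, 2, 2)
  gt <- make_gt(h1, h2, pos = c(100L, 200L), contig = "X",
                sex = c("M", "F"))
  gt$h2[, 1] <- gt$h1[, 1]
  M <- encode_reference_relative(gt, list(contig = "X", start = 1, end = 300))
  expect_equal(rownames(M), c("s01.a", "s02.a", "s02.b"))
})

test_that("unphased heterozygotes cannot be encoded", {
  gt <- make_gt(rbind(c(0L, 0L)), rbind(c(1L, 0L)),
                pos = 100L, contig = "X",
                phased = matrix(c(FALSE, TRUE), 1, 2))
  expect_error(encode_reference_relative(
    gt, list(contig = "X", start = 1, end = 200)), "phase required")
})

test_that("clean datasets classify into pure backgrounds with no recombinants", {
  res <- sim_block(21)
  M <- encode_reference_relative(res$gt, block)
  calls <- call_major_haplotypes(
    M, anchors_n = c(group_samples(res$gt, "Europe"),
                     group_samples(res$gt, "wild")),
    anchors_s = group_samples(res$gt, "CnSouth"))
  expect_true(all(calls$calls$class %in% c("N", "S")))
  truth_lab <- res$truth$x_haplotypes$labels
  got <- calls$calls$class[match(truth_lab$sample, calls$calls$sample)]
  expect_equal(got, truth_lab$class)
  # group pattern: S only among the southern anchor samples
  s_samples <- calls$calls$sample[calls$calls$class == "S"]
  expect_true(all(grepl("^CnSouth", s_samples)))
})

test_that("planted single-switch mosaics are called recombinant with one breakpoint", {
  asg <- data.frame(sample = paste0(c("CnSouth_", "CnNorth_"),
                                    rep(sprintf("%02d", 1:5), each = 2)),
                    stringsAsFactors = FALSE)
  # default background by group, one recombinant
  cfg <- sim_config(n_sites = 1500, seed = 33)
  s <- simulate_populations(cfg)
  asg <- data.frame(sample = s$gt$samples$sample,
                    class = ifelse(grepl("^CnSouth", s$gt$samples$sample),
                                   "S", "N"),
                    breakpoints = NA_character_, stringsAsFactors = FALSE)
  asg$class[asg$sample == "CnNorth_02"] <- "recombinant"
  asg$breakpoints[asg$sample == "CnNorth_02"] <- "1400000"
  res <- simulate_x_mosaic(s$gt, s$truth, c(block, list(assignments = asg)),
                           seed = 5)
  M <- encode_reference_relative(res$gt, block)
  calls <- call_major_haplotypes(
    M, anchors_n = group_samples(res$gt, "Europe"),
    anchors_s = group_samples(res$gt, "CnSouth"))
  rec <- calls$calls[calls$calls$sample == "CnNorth_02", ]
  expect_true(all(rec$class == "recombinant-1"))
  bp <- calls$breakpoints[calls$breakpoints$sample == "CnNorth_02", ][1, ]
  expect_lt(bp$left_pos, 1400000)
  expect_gt(bp$right_pos, 1400000)
})

test_that("ambiguous rows with no clean mosaic stay unclassified", {
  consN <- rep(0L, 40); consS <- rep(1L, 40)
  M <- rbind(alt = as.integer(rep(c(0, 1), 20)))
  attr(M, "positions") <- seq(1000, by = 1000, length.out = 40)
  attr(M, "sample") <- "alt"
  rownames(M) <- "alt.a"
  anchors <- rbind(N = consN, S = consS)
  Mfull <- rbind(M, N.a = consN, S.a = consS)
  attr(Mfull, "positions") <- attr(M, "positions")
  attr(Mfull, "sample") <- c("alt", "N", "S")
  calls <- call_major_haplotypes(Mfull, anchors_n = "N", anchors_s = "S")
  expect_equal(calls$calls$class[calls$calls$sample == "alt"], "unclassified")
})

test_that("breakpoints are bounded by informative markers only", {
  pos <- seq(10, 80, by = 10)
  consN <- rep(0L, 8)
  consS <- c(1L, 0L, rep(1L, 6))      # marker 2 uninformative
  row <- c(0L, 1L, 0L, 0L, 1L, 1L, 1L, 1L)   # N on 1,3,4; S on 5..8
  iv <- localize_breakpoints(row, consN, consS, pos)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$left_pos, 40)
  expect_equal(iv$right_pos, 50)
  # an uninformative marker can never bound an interval: shift it to the
  # boundary and the interval must skip over it
  consS2 <- c(1L, 1L, 1L, 1L, 0L, 1L, 1L, 1L)  # marker 5 uninformative
  row2 <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  iv2 <- localize_breakpoints(row2, consN, consS2, pos)
  expect_equal(iv2$left_pos, 40)
  expect_equal(iv2$right_pos, 60)     # skips the uninformative marker at 50
  expect_equal(iv$left_bg, "N"); expect_equal(iv$right_bg, "S")
})

test_that("breakpoint interval: 000|111 switching between 30 and 40", {
  pos <- c(10, 20, 30, 40, 50, 60)
  consN <- rep(0L, 6); consS <- rep(1L, 6)
  row <- c(0L, 0L, 0L, 1L, 1L, 1L)
  iv <- localize_breakpoints(row, consN, consS, pos)
  expect_equal(c(iv$left_pos, iv$right_pos), c(30, 40))
})

test_that("sparser markers can only widen the localized interval", {
  pos <- seq(100, by = 100, length.out = 60)
  consN <- rep(0L, 60); consS <- rep(1L, 60)
  row <- c(rep(0L, 30), rep(1L, 30))
  iv_all <- localize_breakpoints(row, consN, consS, pos)
  keep <- seq(1, 60, by = 3)
  iv_sub <- localize_breakpoints(row[keep], consN[keep], consS[keep],
                                 pos[keep])
  expect_lte(iv_sub$left_pos, iv_all$left_pos)
  expect_gte(iv_sub$right_pos, iv_all$right_pos)
})

test_that("interval aggregation unions overlaps and measures the core", {
  bp <- data.frame(left_pos = c(30, 25, 80), right_pos = c(40, 38, 95))
  agg <- aggregate_recomb_intervals(bp)
  expect_equal(nrow(agg$groups), 2)
  expect_equal(c(agg$groups$start[1], agg$groups$end[1]), c(25, 40))
  expect_equal(c(agg$core$start, agg$core$end), c(40, 80))
  # the printed-coordinate case: ends of the two observed intervals
  bp2 <- data.frame(left_pos = c(46219219, 56819762),
                    right_pos = c(46419569, 57752631))
  agg2 <- aggregate_recomb_intervals(bp2)
  expect_equal(agg2$core$mb, 10.40)
  expect_equal(agg2$core$bp, 56819762 - 46419569)
  # no recombinants: empty result
  empty <- aggregate_recomb_intervals(NULL)
  expect_equal(nrow(empty$groups), 0)
  expect_null(empty$core)
})

test_that("round trip on simulated mosaics recovers labels and breakpoints", {
  cfg <- sim_config(n_sites = 1800, seed = 55)
  s <- simulate_populations(cfg)
  asg <- data.frame(sample = s$gt$samples$sample,
                    class = ifelse(grepl("^CnSouth", s$gt$samples$sample),
                                   "S", "N"),
                    breakpoints = NA_character_, stringsAsFactors = FALSE)
  recs <- c("CnNorth_01", "CnNorth_03")
  true_bp <- c(900000, 1700000)
  asg$class[asg$sample %in% recs] <- "recombinant"
  asg$breakpoints[asg$sample == recs[1]] <- as.character(true_bp[1])
  asg$breakpoints[asg$sample == recs[2]] <- as.character(true_bp[2])
  res <- simulate_x_mosaic(s$gt, s$truth, c(block, list(assignments = asg)),
                           seed = 5)
  M <- encode_reference_relative(res$gt, block)
  calls <- call_major_haplotypes(
    M, anchors_n = c(group_samples(res$gt, "Europe"),
                     group_samples(res$gt, "wild")),
    anchors_s = group_samples(res$gt, "CnSouth"))
  truth_lab <- res$truth$x_haplotypes$labels
  for (i in seq_len(nrow(truth_lab))) {
    cl <- calls$calls$class[calls$calls$sample == truth_lab$sample[i]][1]
    want <- switch(truth_lab$class[i], recombinant = "recombinant-1",
                   truth_lab$class[i])
    expect_equal(cl, want)
  }
  for (k in 1:2) {
    bp <- calls$breakpoints[calls$breakpoints$sample == recs[k], ][1, ]
    expect_true(bp$left_pos < true_bp[k] && bp$right_pos > true_bp[k])
  }
})
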