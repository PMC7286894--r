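test_that("theta_pi matches hand-computed and all-pairs values", {
  # 2 haplotypes differing at 2 of 1000 bp
  H <- cbind(c(0L, 0L), c(1L, 1L))
  expect_equal(theta_pi(H, 1000), 2.0)
  # monomorphic window
  expect_equal(theta_pi(cbind(c(1L, 1L), c(1L, 1L)), 1000), 0)
  # n = 4, one site at p = 0.5, 1 Kb: 2 * 0.25 * 4/3
  H4 <- matrix(c(1L, 1L, 0L, 0L), 1, 4)
  expect_equal(theta_pi(H4, 1000), 2 * 0.25 * 4 / 3, tolerance = 1e-12)
  expect_equal(theta_pi(H4, 1000), theta_pi_pairs_oracle(H4, 1000))
})

test_that("theta_pi frequency form equals the all-pairs oracle on random windows", {
  for (seed in 1:5) {
    H <- withr::with_seed(seed, matrix(rbinom(8 * 20, 1, 0.4), 20, 8))
    expect_equal(theta_pi(H, 2500), theta_pi_pairs_oracle(H, 2500),
                 tolerance = 1e-12)
  }
})

test_that("theta_w follows the harmonic-number scaling", {
  H2 <- cbind(c(0L, 0L, 0L), c(1L, 1L, 1L))           # n=2, S=3
  expect_equal(theta_w(H2, 1000), 3.0)
  H4 <- matrix(c(1L, 0L, 0L, 0L), 3, 4, byrow = FALSE)
  H4 <- rbind(c(1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L), c(0L, 1L, 0L, 1L))
  expect_equal(theta_w(H4, 1000), 3 / (1 + 1/2 + 1/3), tolerance = 1e-12)
  expect_equal(theta_w(matrix(1L, 5, 4), 1000), 0)    # S = 0
})

test_that("theta estimators agree genome-wide under neutrality", {
  cfg <- sim_config(n_per_group = c(A = 10, B = 10), divergence_F = 0,
                    contig_lengths = c(chr1 = 5e6), n_sites = 10000,
                    spectrum = "neutral", indel_fraction = 0, seed = 21)
  s <- simulate_populations(cfg)
  H <- haplotype_matrix(s$gt)   # 40 haplotypes
  tp <- theta_pi(H, 5e6)
  tw <- theta_w(H, 5e6)
  expect_lt(abs(tp - tw) / tw, 0.10)
})

test_that("hudson_fst hits its closed-form limits", {
  HA <- matrix(0L, 5, 6); HB <- matrix(1L, 5, 6)
  expect_equal(hudson_fst(HA, HB), 1.0)
  # same frequencies, large n: near zero
  H <- withr::with_seed(2, matrix(rbinom(200 * 80, 1, 0.3), 200, 80))
  expect_lt(abs(hudson_fst(H[, 1:40], H[, 41:80])), 0.03)
  # p = 0.8 vs 0.2 infinite-n limit 1 - 0.32/0.68; estimator converges
  lim <- 1 - 0.32 / 0.68
  fst_n <- function(n, seed) {
    HA <- withr::with_seed(seed, matrix(rbinom(400 * n, 1, 0.8), 400, n))
    HB <- withr::with_seed(seed + 1, matrix(rbinom(400 * n, 1, 0.2), 400, n))
    hudson_fst(HA, HB)
  }
  expect_lt(abs(fst_n(400, 7) - lim), abs(fst_n(8, 7) - lim) + 0.02)
  expect_lt(abs(fst_n(400, 7) - lim), 0.02)
})

test_that("fst is undefined when pi_between is zero", {
  H <- matrix(1L, 4, 8)
  expect_warning(v <- hudson_fst(H[, 1:4], H[, 5:8]), "undefined")
  expect_true(is.na(v))
})

test_that("hom/het ratios count correctly and flag zero-het samples", {
  h1 <- matrix(0L, 40, 2); h2 <- matrix(0L, 40, 2)
  h1[1:30, 1] <- 1L; h2[1:30, 1] <- 1L      # 30 hom-alt
  h2[31:40, 1] <- 1L                        # 10 het
  h2[1:10, 2] <- 1L                         # sample 2: 10 het only
  gt <- make_gt(h1, h2)
  hh <- hom_het_ratio(gt)
  expect_equal(hh$hom_het_ratio[1], 3.0)
  expect_equal(hh$hom_het_ratio[2], 0.0)
  h2b <- matrix(0L, 4, 1); h1b <- h2b; h1b[1, 1] <- 1L; h2b[1, 1] <- 1L
  expect_warning(hh2 <- hom_het_ratio(make_gt(h1b, h2b)), "zero het")
  expect_equal(hh2$hom_het_ratio[1], Inf)
})

test_that("coding effects follow the genetic code on both strands", {
  seq <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("T", 30), "ATGCTTAAACCCGGG", strrep("T", 30))))
  feats <- data.frame(contig = "chr1", start = c(31, 31), end = c(45, 45),
                      strand = "+", type = c("gene", "CDS"),
                      gene_id = "g1", phase = c(NA, 0L))
  # ATG -> ATA: M -> I
  expect_equal(classify_coding_effect("chr1", 33, "G", "A", seq, feats),
               "nonsynonymous")
  # CTT -> CTC: L -> L
  expect_equal(classify_coding_effect("chr1", 36, "T", "C", seq, feats),
               "synonymous")
  # AAA -> TAA would be a stop on the forward frame
  expect_equal(classify_coding_effect("chr1", 37, "A", "T", seq, feats),
               "stop_gain")
  # 4 bp insertion in CDS
  expect_equal(classify_coding_effect("chr1", 33, "G", "GACGT", seq, feats),
               "frameshift")
  # 3 bp in-frame deletion
  expect_equal(classify_coding_effect("chr1", 33, "GCTT", "G", seq, feats),
               "nonframeshift")
})

test_that("minus-strand codons are reverse complemented", {
  # genomic CAT on minus strand reads ATG (start); mutate genomic C>T
  # so codon becomes ATA (M -> I)
  seq <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("G", 30), "CATGGG", strrep("G", 30))))
  feats <- data.frame(contig = "chr1", start = c(31, 31), end = c(36, 36),
                      strand = "-", type = c("gene", "CDS"),
                      gene_id = "g1", phase = c(NA, 0L))
  expect_equal(classify_coding_effect("chr1", 31, "C", "T", seq, feats),
               "nonsynonymous")
  # genomic G>A at codon third position: CAT -> ATG stays... use wobble:
  # CCC on minus strand = GGG (Gly); genomic G>A at its first genomic base
  # changes the codon third position: GGG -> GGT? verify synonymous via
  # position 34..36 (GGG -> reverse complement CCC)
  expect_equal(classify_coding_effect("chr1", 34, "G", "A", seq, feats),
               "synonymous")
})

test_that("non-coding zones are labeled by distance to genes", {
  seq <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 5000)))
  feats <- data.frame(contig = "chr1", start = c(8000, 8500),
                      end = c(9500, 9100), strand = "+",
                      type = c("gene", "CDS"), gene_id = "g1",
                      phase = c(NA, 0L))
  expect_equal(classify_coding_effect("chr1", 8100, "A", "C", seq, feats),
               "intronic")
  expect_equal(classify_coding_effect("chr1", 5000, "A", "C", seq, feats),
               "updownstream_5kb")
  expect_equal(classify_coding_effect("chr1", 100, "A", "C", seq, feats),
               "intergenic")
})

test_that("annotation with zero genes leaves all variants intergenic", {
  ann <- emit_genome_annotation(c(chr1 = 5e4), genes_per_mb = 0, seed = 2)
  expect_equal(nrow(ann$features), 0)
  lab <- classify_coding_effect("chr1", c(10, 2000), c("A", "A"),
                                c("C", "C"), ann$reference, ann$features)
  expect_equal(lab, c("intergenic", "intergenic"))
})

test_that("NS/S ratio reproduces count arithmetic", {
  labs <- c(rep("nonsynonymous", 44), rep("synonymous", 50))
  expect_equal(ns_s_ratio(labs), 0.88)
  expect_equal(ns_s_ratio(c(nonsynonymous = 46618, synonymous = 53028)), 0.88)
  expect_equal(ns_s_ratio(rep("synonymous", 3)), 0)
  expect_equal(ns_s_ratio(c(rep("nonsynonymous", 5), rep("synonymous", 5))), 1)
  expect_warning(v <- ns_s_ratio(rep("nonsynonymous", 2)), "synonymous")
  expect_true(is.na(v))
})

test_that("windowed scan reports per-window statistics with bounds", {
  cfg <- sim_config(n_per_group = c(A = 8, B = 8), divergence_F = 0.1,
                    contig_lengths = c(chr1 = 1e6), n_sites = 500, seed = 5)
  s <- simulate_populations(cfg)
  div <- windowed_diversity(s$gt, 1e5, groups = c("A", "B"))
  expect_equal(nrow(div), 10)
  expect_true(all(div$theta_pi_kb >= 0))
  expect_true(all(div$theta_w_kb >= 0))
  expect_true(all(div$fst <= 1, na.rm = TRUE))
  expect_true(all(div$end - div$start <= 1e5 - 1))
})
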