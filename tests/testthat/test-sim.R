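test_that("fixed seed gives byte-identical VCF output", {
  cfg <- sim_config(n_sites = 300, seed = 11)
  s1 <- simulate_populations(cfg)
  s2 <- simulate_populations(cfg)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(s1$gt, f1); write_vcf(s2$gt, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_populations(sim_config(n_sites = 300, seed = 12))
  expect_false(identical(s1$gt$h1, s3$gt$h1))
})

test_that("zero drift removes group structure; drift orders F_ST", {
  cfg0 <- sim_config(n_per_group = c(A = 15, B = 15), divergence_F = 0,
                     contig_lengths = c(chr1 = 1e6), n_sites = 800, seed = 3)
  s0 <- simulate_populations(cfg0)
  fr <- group_frequencies(s0$gt)
  expect_lt(mean(abs(fr[, "A"] - fr[, "B"])), 0.12)  # binomial noise only
  H0 <- haplotype_matrix(s0$gt)
  grp <- rep(s0$gt$samples$group, each = 2)
  fst0 <- hudson_fst(H0[, grp == "A"], H0[, grp == "B"])
  expect_lt(abs(fst0), 0.05)

  fst_at <- function(F, seed) {
    cfg <- sim_config(n_per_group = c(A = 15, B = 15), divergence_F = F,
                      contig_lengths = c(chr1 = 1e6), n_sites = 800,
                      seed = seed)
    s <- simulate_populations(cfg)
    H <- haplotype_matrix(s$gt)
    g <- rep(s$gt$samples$group, each = 2)
    hudson_fst(H[, g == "A"], H[, g == "B"])
  }
  expect_gt(fst_at(0.2, 5), fst_at(0.02, 5))
})

test_that("empirical group frequencies recover the truth", {
  cfg <- sim_config(n_per_group = c(A = 50, B = 50), divergence_F = 0.1,
                    contig_lengths = c(chr1 = 1e6), n_sites = 1000, seed = 8)
  s <- simulate_populations(cfg)
  emp <- group_frequencies(s$gt)
  q <- s$truth$site_freqs
  n_chrom <- 100
  se <- sqrt(q * (1 - q) / n_chrom)
  within3 <- abs(emp - q) <= 3 * se + 1e-12
  expect_gte(mean(within3), 0.99)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_per_group = c(A = 5)), "groups")
  expect_error(sim_config(divergence_F = 1.2), "divergence_F")
  expect_error(sim_config(n_sites = 0), "n_sites")
  expect_error(sim_config(n_per_group = c(5, 5)), "named")
  expect_error(
    sim_config(introgression_spec = data.frame(
      donor = "Europe", recipient = "CnSouth_01", contig = "chr1",
      start = 1, end = 9e9)),
    "introgression_spec")
})

test_that("planted tracts copy the donor genotype exactly", {
  isp <- data.frame(donor = "Europe", recipient = "CnSouth_01",
                    contig = "chr1", start = 1e6, end = 3e6)
  cfg <- sim_config(n_sites = 1000, seed = 4, introgression_spec = isp)
  s <- simulate_populations(cfg)
  tr <- s$truth$tracts
  expect_equal(nrow(tr), 1)
  vi <- s$gt$variants$contig == "chr1" & s$gt$variants$pos >= 1e6 &
    s$gt$variants$pos <= 3e6
  ri <- match("CnSouth_01", s$gt$samples$sample)
  di <- match(tr$donor_sample, s$gt$samples$sample)
  expect_true(all(s$gt$h1[vi, ri] == s$gt$h1[vi, di]))
  expect_true(all(s$gt$h2[vi, ri] == s$gt$h2[vi, di]))
  g <- geno_dosage(s$gt)
  expect_equal(pairwise_sharing(g[vi, ri], g[vi, di]), 1.0)
})

test_that("zero-site tracts change nothing but are logged", {
  cfg <- sim_config(n_sites = 200, seed = 4)
  s <- simulate_populations(cfg)
  gap <- data.frame(donor = "Europe", recipient = "CnSouth_01",
                    contig = "chr1", start = 2, end = 3)  # no site inside
  res <- plant_introgression_tracts(s$gt, s$truth, gap, seed = 1)
  expect_equal(res$gt$h1, s$gt$h1)
  expect_equal(nrow(res$truth$tracts), 1)
})

test_that("overlapping tracts for one recipient are rejected", {
  cfg <- sim_config(n_sites = 200, seed = 4)
  s <- simulate_populations(cfg)
  bad <- data.frame(donor = "Europe", recipient = "CnSouth_01",
                    contig = "chr1", start = c(1e5, 2e5), end = c(3e5, 4e5))
  expect_error(plant_introgression_tracts(s$gt, s$truth, bad), "overlapping")
})

test_that("x mosaic without recombinants yields exactly two block haplotypes", {
  cfg <- sim_config(n_sites = 1500, seed = 6)
  s <- simulate_populations(cfg)
  spec <- list(contig = "X", start = 5e5, end = 2.5e6, assignments = NULL)
  res <- simulate_x_mosaic(s$gt, s$truth, spec, seed = 2)
  vi <- res$gt$variants$contig == "X" & res$gt$variants$pos >= 5e5 &
    res$gt$variants$pos <= 2.5e6
  H <- haplotype_matrix(subset_gt(res$gt, variants = which(vi)))
  expect_equal(length(unique(apply(H, 2, paste, collapse = ""))), 2)
})

test_that("two-breakpoint mosaics alternate backgrounds across segments", {
  cfg <- sim_config(n_sites = 1500, seed = 6)
  s <- simulate_populations(cfg)
  asg <- data.frame(sample = s$gt$samples$sample, class = "N",
                    breakpoints = NA_character_, stringsAsFactors = FALSE)
  asg$class[asg$sample == "CnNorth_01"] <- "recombinant"
  asg$breakpoints[asg$sample == "CnNorth_01"] <- "1000000,2000000"
  spec <- list(contig = "X", start = 5e5, end = 2.5e6, assignments = asg)
  res <- simulate_x_mosaic(s$gt, s$truth, spec, seed = 2)
  xh <- res$truth$x_haplotypes
  vi <- which(res$gt$variants$contig == "X" &
                res$gt$variants$pos >= 5e5 & res$gt$variants$pos <= 2.5e6)
  hap <- res$gt$h1[vi, match("CnNorth_01", res$gt$samples$sample)]
  pos <- res$gt$variants$pos[vi]
  seg1 <- pos < 1e6; seg2 <- pos > 1e6 & pos < 2e6; seg3 <- pos > 2e6
  expect_true(all(hap[seg1] == xh$bgN[seg1]))
  expect_true(all(hap[seg2] == xh$bgS[seg2]))
  expect_true(all(hap[seg3] == xh$bgN[seg3]))
})

test_that("breakpoints outside the block are rejected", {
  cfg <- sim_config(n_sites = 300, seed = 6)
  s <- simulate_populations(cfg)
  asg <- data.frame(sample = "CnNorth_01", class = "recombinant",
                    breakpoints = "2900000", stringsAsFactors = FALSE)
  spec <- list(contig = "X", start = 5e5, end = 2.5e6, assignments = asg)
  expect_error(simulate_x_mosaic(s$gt, s$truth, spec), "breakpoint")
})

test_that("linked-haplotype process decays r2 near its design length", {
  pos <- sort(withr::with_seed(9, sample(1:2e6, 250)))
  s_rate <- log(2) / (4 * 10000)           # designed half-distance 10 Kb
  H <- simulate_ld_haplotypes(60, pos, switch_rate = s_rate, seed = 2)
  dec <- ld_decay(H, pos, max_distance = 2e5)
  expect_gt(dec$half_decay_bp, 5000)
  expect_lt(dec$half_decay_bp, 20000)
})

test_that("male X genotypes are haploid coded as homozygous", {
  cfg <- sim_config(n_sites = 600, seed = 13)
  s <- simulate_populations(cfg)
  males <- s$gt$samples$sex == "M"
  xi <- s$gt$variants$contig == "X"
  expect_true(all(s$gt$h1[xi, males] == s$gt$h2[xi, males]))
  expect_gt(sum(s$gt$h1[xi, !males] != s$gt$h2[xi, !males]), 0)
})
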