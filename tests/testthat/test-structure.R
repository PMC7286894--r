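test_that("p-distance counts shared alleles per pair", {
  # identical samples
  h1 <- matrix(c(0L, 1L), 2, 2); h2 <- matrix(c(1L, 1L), 2, 2)
  expect_equal(unname(p_distance_matrix(make_gt(h1, h2))[1, 2]), 0)
  # opposite homozygotes at every site
  gA <- matrix(0L, 5, 1); gB <- matrix(2L, 5, 1)
  D <- p_distance_matrix(cbind(s1 = gA[, 1], s2 = gB[, 1]))
  expect_equal(unname(D[1, 2]), 1)
  # het vs hom-ref at 1 of 10 sites
  g <- cbind(s1 = rep(0L, 10), s2 = c(1L, rep(0L, 9)))
  expect_equal(unname(p_distance_matrix(g)[1, 2]), 0.05)
})

test_that("pairs with no comparable sites raise a named error", {
  g <- cbind(a = c(1L, NA), b = c(NA, 1L))
  expect_error(p_distance_matrix(g), "a / b")
})

test_that("nj solves the three-point equations exactly for 3 taxa", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  pd <- cophenetic(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(pd), unname(D), tolerance = 1e-8)
})

test_that("nj recovers the AB|CD split from the additive 4-taxon matrix", {
  lbl <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(lbl, lbl))
  tr <- neighbor_joining(D)
  # the split AB|CD must be present: prune to quartet topology via ape
  expect_equal(ape::dist.topo(
    tr, ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))), 0,
    ignore_attr = TRUE)
  # and path lengths reproduce the additive matrix
  expect_equal(unname(cophenetic(tr)[lbl, lbl]), unname(D), tolerance = 1e-8)
})

test_that("nj recovers random additive trees and matches ape's nj", {
  for (seed in 1:20) {
    n <- sample(5:8, 1)
    ref <- random_additive_tree(n, seed)
    tr <- neighbor_joining(ref$D)
    expect_equal(ape::dist.topo(tr, ref$tree), 0, ignore_attr = TRUE)
    cross <- ape::nj(ref$D)
    expect_equal(ape::dist.topo(tr, cross), 0, ignore_attr = TRUE)
  }
})

test_that("nj on an ultrametric matrix matches single-linkage clusters", {
  withr::with_seed(4, {
    tr0 <- ape::rcoal(6)
    D <- cophenetic(tr0)
  })
  tr <- neighbor_joining(D)
  expect_equal(ape::dist.topo(tr, ape::unroot(tr0)), 0, ignore_attr = TRUE)
  hc <- hclust(as.dist(D), method = "single")
  # single-linkage on an ultrametric matrix recovers the same nested groups:
  # compare rooted splits at k = 2
  k2 <- cutree(hc, 2)
  grp1 <- names(k2)[k2 == 1]
  # the same bipartition must exist in the nj tree
  parts <- ape::prop.part(tr0)
  labs <- attr(parts, "labels")
  part_sets <- lapply(parts, function(p) sort(labs[p]))
  expect_true(any(vapply(part_sets, function(s)
    setequal(s, grp1) || setequal(s, setdiff(labs, grp1)), logical(1))))
})

test_that("nj rejects non-symmetric matrices and clamps negative branches", {
  D <- matrix(runif(16), 4); diag(D) <- 0
  expect_error(neighbor_joining(D), "symmetric")
  # a matrix known to produce a negative NJ branch
  lbl <- letters[1:4]
  Dn <- matrix(c(0, 2, 2, 2,
                 2, 0, 3.9, 0.1,
                 2, 3.9, 0, 3.9,
                 2, 0.1, 3.9, 0), 4, dimnames = list(lbl, lbl))
  tr <- neighbor_joining(Dn)
  expect_true(all(tr$edge.length >= 0))
})

test_that("pca separates diverged groups and orders eigenvalues", {
  cfg <- sim_config(n_per_group = c(A = 10, B = 10), divergence_F = 0.3,
                    contig_lengths = c(chr1 = 1e6), n_sites = 600, seed = 2)
  s <- simulate_populations(cfg)
  p <- pca_genotypes(s$gt)
  expect_true(all(diff(p$eigenvalues) <= 1e-8))
  expect_true(all(p$eigenvalues >= 0))
  pc1 <- p$coordinates[, 1]
  a <- pc1[s$gt$samples$group == "A"]; b <- pc1[s$gt$samples$group == "B"]
  expect_true(max(a) < min(b) || max(b) < min(a))   # sign-invariant
})

test_that("duplicated samples get identical coordinates; order is immaterial", {
  g <- withr::with_seed(3, matrix(rbinom(200 * 6, 2, 0.4), 200, 6))
  colnames(g) <- paste0("s", 1:6)
  g <- cbind(g, s7 = g[, 3])
  p <- pca_genotypes(g)
  expect_equal(p$coordinates["s3", 1:3], p$coordinates["s7", 1:3],
               tolerance = 1e-6)
  perm <- sample(ncol(g))
  p2 <- pca_genotypes(g[, perm])
  for (k in 1:3) {
    v1 <- p$coordinates[colnames(g)[perm], k]
    v2 <- p2$coordinates[, k]
    expect_true(isTRUE(all.equal(v1, v2, tolerance = 1e-6)) ||
                  isTRUE(all.equal(v1, -v2, tolerance = 1e-6)))
  }
})

test_that("monomorphic-only input is rejected", {
  g <- matrix(2L, 50, 4)
  expect_error(pca_genotypes(g), "monomorphic")
})

test_that("K=1 admixture is the closed-form frequency fit", {
  g <- withr::with_seed(5, matrix(rbinom(100 * 8, 2, 0.3), 100, 8))
  fit <- admixture_em(g, K = 1)
  expect_true(all(fit$Q == 1))
  expect_equal(as.vector(fit$F), colMeans(t(g)) / 2)
})

test_that("admixture EM log-likelihood never decreases", {
  cfg <- sim_config(n_per_group = c(A = 8, B = 8), divergence_F = 0.3,
                    contig_lengths = c(chr1 = 1e6), n_sites = 300, seed = 7)
  s <- simulate_populations(cfg)
  fit <- admixture_em(s$gt, K = 2, seed = 3, max_iter = 300, n_restarts = 2)
  expect_true(all(diff(fit$loglik) > -1e-6))
  expect_equal(unname(rowSums(fit$Q)), rep(1, n_samples(s$gt)),
               tolerance = 1e-8)
  expect_true(all(fit$F >= 0 & fit$F <= 1))
})

test_that("admixture recovers pure and 50/50 ancestries", {
  cfg <- sim_config(n_per_group = c(A = 10, B = 10), divergence_F = 0.3,
                    contig_lengths = c(chr1 = 1e6), n_sites = 700, seed = 9)
  s <- simulate_populations(cfg)
  # plant an admixed individual: h1 from A frequencies, h2 from B
  q <- s$truth$site_freqs
  mix_h1 <- withr::with_seed(31, rbinom(nrow(q), 1, q[, "A"]))
  mix_h2 <- withr::with_seed(32, rbinom(nrow(q), 1, q[, "B"]))
  gt <- s$gt
  gt$h1 <- cbind(gt$h1, admx = mix_h1)
  gt$h2 <- cbind(gt$h2, admx = mix_h2)
  gt$phased <- cbind(gt$phased, admx = TRUE)
  gt$samples <- rbind(gt$samples,
                      data.frame(sample = "admx", group = "admixed",
                                 sex = "F", size_class = NA))
  fit <- admixture_em(gt, K = 2, seed = 11, max_iter = 1000)
  Q <- align_components(fit$Q, ifelse(gt$samples$group == "admixed", "A",
                                      gt$samples$group))
  pure <- gt$samples$group %in% c("A", "B")
  err_pure <- max(abs(Q[pure, "A"] - ifelse(
    gt$samples$group[pure] == "A", 1, 0)))
  expect_lte(err_pure, 0.05)
  expect_lt(abs(Q["admx", "A"] - 0.5), 0.10)
})

test_that("K above the sample count warns", {
  g <- matrix(rbinom(40, 2, 0.5), 10, 4)
  expect_warning(admixture_em(g, K = 6, seed = 1, max_iter = 20,
                              n_restarts = 1), "exceeds")
})
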