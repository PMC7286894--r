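# Synthetic multi-population genotype data with planted ground truth.
#
# Group allele frequencies follow a Balding-Nichols model: for ancestral
# frequency p and drift coefficient F, the group frequency is
# Beta(p(1-F)/F, (1-p)(1-F)/F), so E[q] = p and Var[q] = F p(1-p).  Sites
# are unlinked; linked haplotypes for LD work come from the separate
# copy-with-mutation process in simulate_ld_haplotypes().

#' Simulation configuration
#'
#' Defaults emulate a 31-animal resequencing design: two diverged Chinese
#' domestic subpopulations (CnSouth n=11, CnNorth n=9), a European domestic
#' group (n=5) and wild boars (n=6), with drift coefficients calibrated so
#' the expected Hudson F_ST between CnSouth and CnNorth is about 0.06 and
#' between the European and wild groups about 0.08 (E[F_ST] ~ (F_A+F_B)/2
#' under Balding-Nichols).
#'
#' @param n_per_group named integer vector: samples per group label.
#' @param n_sites total variant sites across contigs.
#' @param contig_lengths named numeric vector of contig lengths in bp; a
#'   contig named `"X"` is treated as the X chromosome (males carry one
#'   haplotype, coded as homozygous).
#' @param divergence_F named numeric vector in `[0,1)`: Balding-Nichols
#'   drift per group (recycled if length 1).
#' @param spectrum ancestral-frequency spectrum: `"uniform"` on (0,1)
#'   (default), or `"neutral"` with density proportional to 1/p on
#'   `(spectrum_min, 1)` — the standing neutral site-frequency spectrum,
#'   under which theta-pi and Watterson's theta agree in expectation.
#' @param spectrum_min lower truncation of the neutral spectrum.
#' @param indel_fraction fraction of sites simulated as short indels.
#' @param prop_female proportion of females per group (deterministic
#'   assignment: the first `round(prop_female*n)` samples of each group).
#' @param introgression_spec data.frame(`donor`, `recipient`, `contig`,
#'   `start`, `end`) of tracts to plant, or `NULL`.
#' @param x_block_spec list describing the X LD block
#'   (see [simulate_x_mosaic()]), or `NULL`.
#' @param size_effect_spec data.frame(`site`, `high_group`, `hi`, `lo`) of
#'   size-differentiated sites to plant, or `NULL`.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_group = c(CnSouth = 11, CnNorth = 9,
                                       Europe = 5, wild = 6),
                       n_sites = 4000,
                       contig_lengths = c(chr1 = 5e6, X = 3e6),
                       divergence_F = c(CnSouth = 0.06, CnNorth = 0.06,
                                        Europe = 0.10, wild = 0.06),
                       spectrum = c("uniform", "neutral"),
                       spectrum_min = 0.0025,
                       indel_fraction = 0.05,
                       prop_female = 0.25,
                       introgression_spec = NULL,
                       x_block_spec = NULL,
                       size_effect_spec = NULL,
                       seed = 1L) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == ""))
    stop_cfg("n_per_group must be a named vector of group sizes")
  if (length(n_per_group) < 2) stop_cfg("n_per_group: need >= 2 groups")
  if (any(n_per_group < 1)) stop_cfg("n_per_group: counts must be >= 1")
  if (n_sites < 1) stop_cfg("n_sites must be >= 1")
  if (length(divergence_F) == 1)
    divergence_F <- setNames(rep(divergence_F, length(n_per_group)),
                             names(n_per_group))
  if (!all(names(n_per_group) %in% names(divergence_F)))
    stop_cfg("divergence_F: missing value for some group")
  if (any(divergence_F < 0 | divergence_F >= 1))
    stop_cfg("divergence_F must lie in [0, 1)")
  if (is.null(names(contig_lengths))) stop_cfg("contig_lengths must be named")
  if (!is.null(introgression_spec)) {
    isp <- as.data.frame(introgression_spec)
    bad <- !(isp$contig %in% names(contig_lengths)) |
      isp$start < 1 | isp$end > contig_lengths[isp$contig]
    if (any(bad)) stop_cfg("introgression_spec: tract outside contig bounds")
  }
  spectrum <- match.arg(spectrum)
  structure(list(n_per_group = n_per_group, n_sites = as.integer(n_sites),
                 contig_lengths = contig_lengths,
                 divergence_F = divergence_F,
                 spectrum = spectrum, spectrum_min = spectrum_min,
                 indel_fraction = indel_fraction,
                 prop_female = prop_female,
                 introgression_spec = introgression_spec,
                 x_block_spec = x_block_spec,
                 size_effect_spec = size_effect_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate diverged populations
#'
#' Draws per-site ancestral frequencies uniformly on (0,1), group
#' frequencies from the Balding-Nichols beta, and phased diploid haplotypes
#' independently per site given the group frequency.  Returns the genotype
#' table plus a `sim_truth` record of everything planted.  When
#' `introgression_spec`, `x_block_spec` or `size_effect_spec` are present in
#' the config they are applied here (in that order: size effects, X block,
#' tracts).
#'
#' @param config a [sim_config()].
#' @param reference optional `DNAStringSet` (as from
#'   [emit_genome_annotation()]); when given, SNP ref alleles are read from
#'   the sequence so the VCF is consistent with the FASTA.
#' @return list with `gt` (genotype_table) and `truth` (sim_truth).
#' @export
simulate_populations <- function(config, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_populations_impl(config, reference))
}

.simulate_populations_impl <- function(config, reference) {
  groups <- names(config$n_per_group)
  samples <- .sim_sample_sheet(config)
  ns <- nrow(samples)

  # site placement proportional to contig length
  cl <- config$contig_lengths
  n_per_contig <- setNames(pmax(1L, round(config$n_sites * cl / sum(cl))),
                           names(cl))
  # adjust to hit n_sites exactly
  while (sum(n_per_contig) != config$n_sites) {
    i <- which.max(n_per_contig)
    n_per_contig[i] <- n_per_contig[i] + sign(config$n_sites - sum(n_per_contig))
  }
  contig <- rep(names(cl), n_per_contig)
  pos <- unlist(lapply(names(cl), function(cn)
    sort(sample.int(cl[[cn]] - 10L, n_per_contig[[cn]]))), use.names = FALSE)
  nv <- length(pos)

  p_anc <- if (identical(config$spectrum, "neutral"))
    exp(runif(nv, log(config$spectrum_min), 0)) else runif(nv)
  qs <- sapply(groups, function(g) {
    F <- config$divergence_F[[g]]
    if (F <= 0) p_anc else {
      a <- p_anc * (1 - F) / F
      b <- (1 - p_anc) * (1 - F) / F
      rbeta(nv, a, b)
    }
  })
  qs <- matrix(qs, nrow = nv, dimnames = list(NULL, groups))

  truth_effects <- NULL
  if (!is.null(config$size_effect_spec)) {
    se <- as.data.frame(config$size_effect_spec)
    if (is.null(se$hi)) se$hi <- 0.95
    if (is.null(se$lo)) se$lo <- 0.05
    for (i in seq_len(nrow(se))) {
      s <- se$site[i]
      if (s < 1 || s > nv) stop_cfg("size_effect_spec: site index out of range")
      qs[s, ] <- se$lo[i]
      qs[s, se$high_group[i]] <- se$hi[i]
    }
  }
  if (any(qs < 0 | qs > 1)) stop_cfg("internal: frequency outside [0,1]")

  q_sample <- qs[, samples$group, drop = FALSE]
  h1 <- matrix(rbinom(nv * ns, 1L, q_sample), nv, ns)
  h2 <- matrix(rbinom(nv * ns, 1L, q_sample), nv, ns)

  # alleles
  bases <- c("A", "C", "G", "T")
  is_indel <- runif(nv) < config$indel_fraction
  ref <- sample(bases, nv, replace = TRUE)
  if (!is.null(reference)) {
    for (cn in intersect(names(reference), unique(contig))) {
      idx <- which(contig == cn)
      ref[idx] <- strsplit(as.character(
        Biostrings::subseq(reference[[cn]], 1, cl[[cn]])), "")[[1]][pos[idx]]
    }
  }
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ins_len <- sample(1:20, nv, replace = TRUE)
  ext <- vapply(ins_len, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  ins <- runif(nv) < 0.5
  ref[is_indel & ins] <- ref[is_indel & ins]
  alt[is_indel & ins] <- paste0(ref[is_indel & ins], ext[is_indel & ins])
  ref[is_indel & !ins] <- paste0(ref[is_indel & !ins], ext[is_indel & !ins])
  alt[is_indel & !ins] <- substr(ref[is_indel & !ins], 1, 1)

  variants <- data.frame(
    contig = contig, pos = pos,
    id = sprintf("%s_%d", contig, pos),
    ref = unname(ref), alt = unname(alt),
    class = ifelse(is_indel, "indel", "SNP"),
    stringsAsFactors = FALSE)

  gt <- genotype_table(variants, h1, h2, NULL, samples, cl)
  gt <- .apply_male_x(gt)

  truth <- structure(list(
    tracts = data.frame(sample = character(), contig = character(),
                        start = numeric(), end = numeric(),
                        donor_group = character(), donor_sample = character(),
                        stringsAsFactors = FALSE),
    x_haplotypes = NULL, site_freqs = qs,
    effects = truth_effects,
    size_effect_spec = config$size_effect_spec), class = "sim_truth")

  if (!is.null(config$x_block_spec)) {
    res <- simulate_x_mosaic(gt, truth, config$x_block_spec,
                             seed = sub_seed(config$seed, 2L))
    gt <- res$gt; truth <- res$truth
  }
  if (!is.null(config$introgression_spec)) {
    res <- plant_introgression_tracts(gt, truth, config$introgression_spec,
                                      seed = sub_seed(config$seed, 3L))
    gt <- res$gt; truth <- res$truth
  }
  list(gt = gt, truth = truth)
}

.sim_sample_sheet <- function(config) {
  groups <- names(config$n_per_group)
  samples <- do.call(rbind, lapply(groups, function(g) {
    n <- config$n_per_group[[g]]
    nf <- round(config$prop_female * n)
    data.frame(sample = sprintf("%s_%02d", g, seq_len(n)), group = g,
               sex = c(rep("F", nf), rep("M", n - nf)),
               size_class = NA_character_, stringsAsFactors = FALSE)
  }))
  # body-size split: first 7 CnSouth small, first 7 of CnNorth+Europe large
  small <- grep("^CnSouth", samples$sample, value = TRUE)
  large <- c(grep("^CnNorth", samples$sample, value = TRUE),
             grep("^Europe", samples$sample, value = TRUE))
  samples$size_class[samples$sample %in% head(small, 7)] <- "small"
  samples$size_class[samples$sample %in% head(large, 7)] <- "large"
  samples
}

# males carry a single X haplotype, coded as homozygous
.apply_male_x <- function(gt) {
  xi <- gt$variants$contig == "X"
  if (!any(xi)) return(gt)
  males <- gt$samples$sex == "M" & !is.na(gt$samples$sex)
  gt$h2[xi, males] <- gt$h1[xi, males]
  gt
}

#' Plant introgression tracts
#'
#' Emulates introgression of a haplotype that segregates widely in the
#' donor group, the situation in which haplotype-sharing scans have power:
#' inside each tract (i) the donor group is made to share a common
#' haplotype — every donor-group haplotype is replaced by the shared one
#' with probability `donor_ibd`, mimicking an identity-by-descent region in
#' a low-diversity donor population — and (ii) the recipient's genotype is
#' replaced by a copy of a randomly chosen donor individual's genotype
#' (both haplotypes), so recipient-vs-donor allele sharing is exactly 1 at
#' every tract site.  The tract is logged in the truth record.  Overlapping
#' tracts for the same recipient raise an error.
#'
#' @param gt a `genotype_table`.
#' @param truth a `sim_truth`.
#' @param spec data.frame(`donor` group, `recipient` sample, `contig`,
#'   `start`, `end`).
#' @param seed integer seed for the donor choice.
#' @param donor_ibd probability that a donor-group haplotype carries the
#'   shared tract haplotype (default 1: the tract haplotype is fixed in the
#'   donor group; 0 disables donor homogenization).
#' @return list with updated `gt` and `truth`.
#' @export
plant_introgression_tracts <- function(gt, truth, spec, seed = 1L,
                                       donor_ibd = 1) {
  spec <- as.data.frame(spec)
  for (r in unique(spec$recipient)) {
    rows <- spec[spec$recipient == r, , drop = FALSE]
    if (nrow(rows) > 1) {
      o <- order(rows$contig, rows$start)
      rows <- rows[o, ]
      same <- rows$contig[-nrow(rows)] == rows$contig[-1]
      if (any(same & rows$end[-nrow(rows)] >= rows$start[-1]))
        stop_cfg("overlapping tracts for recipient '", r, "'")
    }
  }
  with_seed(seed, {
    for (i in seq_len(nrow(spec))) {
      donors <- group_samples(gt, spec$donor[i])
      donors <- setdiff(donors, spec$recipient[i])
      donor <- sample(donors, 1)
      di <- match(donor, gt$samples$sample)
      ri <- match(spec$recipient[i], gt$samples$sample)
      if (is.na(ri)) stop_cfg("unknown recipient '", spec$recipient[i], "'")
      vi <- gt$variants$contig == spec$contig[i] &
        gt$variants$pos >= spec$start[i] & gt$variants$pos <= spec$end[i]
      if (donor_ibd > 0 && any(vi)) {
        shared <- gt$h1[vi, di]
        for (ds in match(donors, gt$samples$sample)) {
          if (runif(1) < donor_ibd) gt$h1[vi, ds] <- shared
          if (runif(1) < donor_ibd) gt$h2[vi, ds] <- shared
        }
      }
      gt$h1[vi, ri] <- gt$h1[vi, di]
      gt$h2[vi, ri] <- gt$h2[vi, di]
      truth$tracts <- rbind(truth$tracts, data.frame(
        sample = spec$recipient[i], contig = spec$contig[i],
        start = spec$start[i], end = spec$end[i],
        donor_group = spec$donor[i], donor_sample = donor,
        stringsAsFactors = FALSE))
    }
  })
  list(gt = gt, truth = truth)
}

#' Simulate an X-chromosome haplotype-mosaic block
#'
#' Inside the declared block two ancestral backgrounds are defined: N (the
#' reference-allele vector) and S (the opposite allele at a fraction
#' `informative_frac` of block markers).  Each sample is assigned pure-N,
#' pure-S, or a mosaic switching backgrounds at given breakpoints; the block
#' is written homozygous for the assigned haplotype (strong-LD block with no
#' within-individual recombination).  Truth stores the label, breakpoints
#' and background vectors.
#'
#' @param gt a `genotype_table`.
#' @param truth a `sim_truth`.
#' @param spec list with `contig`, `start`, `end`, optional
#'   `informative_frac` (default 0.9), optional `noise` (per-marker flip
#'   probability, default 0), and `assignments`: data.frame(`sample`,
#'   `class` in N/S/recombinant, `breakpoints` comma-separated bp for
#'   recombinants).  Samples not listed get a default by group: CnSouth and
#'   southern wild -> S; Europe and other wild -> N; CnNorth -> N.
#' @param seed integer seed (background construction and noise).
#' @return list with updated `gt` and `truth`.
#' @export
simulate_x_mosaic <- function(gt, truth, spec, seed = 1L) {
  contig <- spec$contig %||% "X"
  vi <- which(gt$variants$contig == contig &
                gt$variants$pos >= spec$start & gt$variants$pos <= spec$end)
  if (!length(vi)) stop_cfg("x_block_spec: no markers inside block")
  pos <- gt$variants$pos[vi]
  infra <- spec$informative_frac %||% 0.9
  noise <- spec$noise %||% 0

  asg <- spec$assignments
  if (is.null(asg)) {
    cls <- ifelse(grepl("^CnSouth", gt$samples$sample), "S", "N")
    asg <- data.frame(sample = gt$samples$sample, class = cls,
                      breakpoints = NA_character_, stringsAsFactors = FALSE)
  }
  asg <- as.data.frame(asg)
  if (is.null(asg$breakpoints)) asg$breakpoints <- NA_character_

  with_seed(seed, {
    bgN <- integer(length(vi))                    # reference-like
    inf <- runif(length(vi)) < infra
    bgS <- ifelse(inf, 1L, 0L)
    calls <- vector("list", nrow(asg))
    for (i in seq_len(nrow(asg))) {
      si <- match(asg$sample[i], gt$samples$sample)
      if (is.na(si)) stop_cfg("x_block_spec: unknown sample '", asg$sample[i], "'")
      bps <- if (is.na(asg$breakpoints[i]) || asg$breakpoints[i] == "")
        numeric() else as.numeric(strsplit(asg$breakpoints[i], ",")[[1]])
      if (length(bps) && (any(bps <= spec$start) || any(bps >= spec$end)))
        stop_cfg("x_block_spec: breakpoint outside block for '",
                 asg$sample[i], "'")
      cls <- asg$class[i]
      if (cls == "recombinant" && !length(bps))
        stop_cfg("recombinant assignment needs breakpoints")
      seg <- findInterval(pos, sort(bps))          # 0..k segments
      use_s <- switch(cls,
                      N = rep(FALSE, length(vi)),
                      S = rep(TRUE, length(vi)),
                      recombinant = {
                        sb <- if (!is.null(asg$start_bg)) asg$start_bg[i] else "N"
                        if (is.na(sb) || !nzchar(sb)) sb <- "N"
                        if (sb == "N") (seg %% 2) == 1 else (seg %% 2) == 0
                      },
                      stop_cfg("unknown x class '", cls, "'"))
      hap <- ifelse(use_s, bgS, bgN)
      if (noise > 0) {
        flip <- runif(length(hap)) < noise
        hap[flip] <- 1L - hap[flip]
      }
      gt$h1[vi, si] <- hap
      gt$h2[vi, si] <- hap
      calls[[i]] <- data.frame(
        sample = asg$sample[i], class = cls,
        breakpoints = if (length(bps)) paste(sort(bps), collapse = ",") else "",
        stringsAsFactors = FALSE)
    }
    truth$x_haplotypes <- list(
      contig = contig, start = spec$start, end = spec$end,
      marker_pos = pos, bgN = bgN, bgS = bgS,
      labels = do.call(rbind, calls))
  })
  list(gt = gt, truth = truth)
}

#' Simulate linked haplotypes by template switching
#'
#' A copy-with-mutation process used for LD work: two complementary founder
#' haplotypes segregate at frequency 1/2, and each simulated haplotype
#' follows a hidden template chain that switches founder between adjacent
#' sites with probability `(1 - (1-2s)^d)/2` for inter-site distance `d` bp
#' and per-bp switch rate `s`.  Pairwise r^2 then decays as
#' `(1-2s)^(2d)` in expectation, i.e. halves at about `ln(2)/(4s)` bp.
#'
#' @param n_hap number of haplotypes.
#' @param positions sorted site positions (bp).
#' @param switch_rate per-bp template switch rate `s`.
#' @param mutation_prob independent per-site flip probability.
#' @param seed integer seed.
#' @return 0/1 matrix, sites x haplotypes.
#' @export
simulate_ld_haplotypes <- function(n_hap, positions, switch_rate = 1.7e-5,
                                   mutation_prob = 0.01, seed = 1L) {
  if (is.unsorted(positions)) stop_cfg("positions must be sorted")
  m <- length(positions)
  with_seed(seed, {
    founderA <- rbinom(m, 1L, 0.5)
    d <- diff(positions)
    p_switch <- (1 - (1 - 2 * switch_rate)^d) / 2
    H <- matrix(0L, m, n_hap)
    for (h in seq_len(n_hap)) {
      state <- rbinom(1, 1L, 0.5)
      states <- integer(m); states[1] <- state
      sw <- runif(m - 1) < p_switch
      for (j in seq_len(m - 1)) {
        if (sw[j]) state <- 1L - state
        states[j + 1] <- state
      }
      hap <- ifelse(states == 1L, founderA, 1L - founderA)
      if (mutation_prob > 0) {
        flip <- runif(m) < mutation_prob
        hap[flip] <- 1L - hap[flip]
      }
      H[, h] <- hap
    }
    H
  })
}

#' Simulate a structural-variant presence/absence table
#'
#' Null SVs get a common presence probability; planted SVs are present in
#' (nearly) all samples of `high_group` and absent elsewhere.
#'
#' @param samples sample metadata data.frame (`sample`, `group`).
#' @param n_null number of null SVs.
#' @param planted data.frame(`high_group`) rows for group-exclusive SVs,
#'   or `NULL`.
#' @param contig,contig_length placement coordinates.
#' @param base_prob presence probability of null SVs.
#' @param seed integer seed.
#' @return list with `sv` (data.frame sv_id, contig, start, end, type,
#'   planted) and `presence` (0/1 matrix, SV x samples).
#' @export
simulate_sv_table <- function(samples, n_null = 100, planted = NULL,
                              contig = "chr1", contig_length = 5e6,
                              base_prob = 0.4, seed = 1L) {
  npl <- if (is.null(planted)) 0L else nrow(planted)
  n <- n_null + npl
  with_seed(seed, {
    pres <- matrix(rbinom(n_null * nrow(samples), 1L, base_prob),
                   n_null, nrow(samples))
    if (npl > 0) {
      pl <- t(sapply(seq_len(npl), function(i)
        as.integer(samples$group == planted$high_group[i])))
      pres <- rbind(pres, pl)
    }
    colnames(pres) <- samples$sample
    start <- sort(sample.int(contig_length - 1000L, n))
    len <- sample(46:2000, n, replace = TRUE)
    sv <- data.frame(sv_id = sprintf("sv%03d", seq_len(n)),
                     contig = contig, start = start, end = start + len,
                     type = sample(c("DEL", "CTX"), n, replace = TRUE),
                     planted = c(rep(FALSE, n_null), rep(TRUE, npl)),
                     stringsAsFactors = FALSE)
    list(sv = sv, presence = pres)
  })
}

#' Write simulation truth tables
#'
#' @param truth a `sim_truth`.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "tracts.tsv")
  write.table(truth$tracts, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(truth$x_haplotypes)) {
    p <- file.path(dir, "x_haplotypes.tsv")
    write.table(truth$x_haplotypes$labels, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
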