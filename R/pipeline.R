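# End-to-end orchestration over the simulated study design: simulate ->
# annotate -> diversity/differentiation -> structure -> LD -> X haplotypes
# -> introgression -> differential scans, with all artifacts and a
# machine-readable JSON summary under one output directory.

#' Pipeline configuration
#'
#' Thresholds default to the values the analyses are defined with: 100 Kb
#' sharing windows with >= 10 SNPs and >= 3 comparisons per group, sharing
#' ratio < 0.8, high-sharing fraction >= 0.90, near-fixation 0.80/0.20,
#' coverage filter >= 5 genotyped samples per group, top-100 SVs at FDR
#' P < 0.01, Gabriel thresholds 0.70/0.98/0.90 with the 95% informative-
#' pair rule, 5 Kb LD-decay bins, 3 Kb marker thinning.
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param out_dir output directory.
#' @param window_bp diversity/sharing window width.
#' @param admixture_K K values for the admixture sweep.
#' @param thresholds named list overriding scan thresholds.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = tempfile("run"),
                            window_bp = 1e5, admixture_K = 2:3,
                            thresholds = list(), seed = 1L) {
  defaults <- list(ratio_threshold = 0.8, high_sharing = 0.90,
                   min_snps = 10, min_comparisons = 3,
                   near_fix_hi = 0.80, near_fix_lo = 0.20,
                   min_per_group = 5, sv_k = 100, sv_alpha = 0.01,
                   thin_gap = 3000, decay_bin = 5000)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown))
    stop_cfg("unknown threshold key(s): ", paste(unknown, collapse = ", "))
  defaults[names(thresholds)] <- thresholds
  structure(list(sim = sim, out_dir = out_dir, window_bp = window_bp,
                 admixture_K = admixture_K, thresholds = defaults,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a simulated dataset and writes: the VCF, FASTA,
#' GFF3, metadata and truth tables; windowed diversity TSV; newick tree,
#' PCA coordinates and Q matrices; LD decay curve and Gabriel blocks on the
#' X block; X-haplotype calls and recombination intervals (BED); flagged
#' introgression windows and merged segments; differential-scan hits; and
#' `summary.json` with every headline statistic.  Fully deterministic for
#' a fixed config.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly; artifacts under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("pigpopgen %s | seed=%d", as.character(utils::packageVersion("pigpopgen")),
       config$seed)
  for (nm in names(th)) logf("threshold %s=%s", nm, format(th[[nm]]))

  # --- simulate
  ann <- emit_genome_annotation(config$sim$contig_lengths,
                                seed = sub_seed(config$seed, 11L),
                                dir = config$out_dir)
  sim <- simulate_populations(config$sim, reference = ann$reference)
  gt <- sim$gt; truth <- sim$truth
  write_vcf(gt, file.path(config$out_dir, "variants.vcf"))
  write_sample_metadata(gt$samples, file.path(config$out_dir, "samples.tsv"))
  write_truth(truth, file.path(config$out_dir, "truth"))
  logf("simulated %d variants x %d samples", n_variants(gt), n_samples(gt))

  # --- effects + diversity
  gt$variants$effect <- classify_coding_effect(
    gt$variants$contig, gt$variants$pos, gt$variants$ref, gt$variants$alt,
    ann$reference, ann$features)
  snp_eff <- gt$variants$effect[gt$variants$class == "SNP"]
  omega <- suppressWarnings(ns_s_ratio(snp_eff))
  div <- windowed_diversity(gt, config$window_bp,
                            groups = c("CnSouth", "CnNorth"))
  write.table(div, file.path(config$out_dir, "diversity_windows.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hh <- hom_het_ratio(subset_gt(gt, variants = which(gt$variants$class == "SNP")))
  write.table(hh, file.path(config$out_dir, "hom_het.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- structure
  D <- p_distance_matrix(gt)
  tree <- neighbor_joining(D)
  ape::write.tree(tree, file.path(config$out_dir, "nj_tree.nwk"))
  pca <- pca_genotypes(gt, n_pc = 3)
  write.table(data.frame(sample = rownames(pca$coordinates),
                         pca$coordinates),
              file.path(config$out_dir, "pca_coordinates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  adm <- lapply(config$admixture_K, function(K)
    admixture_em(gt, K, seed = sub_seed(config$seed, 20L + K),
                 max_iter = 2000, n_restarts = 3))
  for (fit in adm)
    write.table(data.frame(sample = rownames(fit$Q), fit$Q),
                file.path(config$out_dir, sprintf("admixture_Q_K%d.tsv",
                                                  fit$K)),
                sep = "\t", quote = FALSE, row.names = FALSE)

  # --- LD on the X block (or first contig when no block declared)
  xb <- config$sim$x_block_spec
  ld_summary <- NULL
  xhap_summary <- NULL
  if (!is.null(xb)) {
    block <- list(contig = xb$contig %||% "X", start = xb$start, end = xb$end)
    vi <- which(gt$variants$contig == block$contig & gt$variants$class == "SNP" &
                  gt$variants$pos >= block$start & gt$variants$pos <= block$end)
    Hx <- haplotype_matrix(subset_gt(gt, variants = vi))
    posx <- gt$variants$pos[vi]
    thin <- thin_markers(posx, th$thin_gap)
    blocks <- gabriel_blocks(Hx[thin, , drop = FALSE], posx[thin])
    if (nrow(blocks))
      write_bed(data.frame(contig = block$contig, start = blocks$start,
                           end = blocks$end,
                           name = sprintf("ldblock%d", seq_len(nrow(blocks)))),
                file.path(config$out_dir, "ld_blocks.bed"))
    main_block <- if (nrow(blocks)) {
      len <- segment_length(blocks$start[1], blocks$end[1])
      list(start = blocks$start[1], end = blocks$end[1],
           bp = len$bp, mb = len$mb)
    } else NULL
    ld_summary <- list(n_block_markers = length(vi),
                       n_thinned = length(thin),
                       n_gabriel_blocks = nrow(blocks),
                       main_block = main_block)

    # X haplotype mosaic classification against the planted anchors
    M <- encode_reference_relative(gt, block)
    anchors_s <- group_samples(gt, "CnSouth")
    anchors_n <- c(group_samples(gt, "Europe"), group_samples(gt, "wild"))
    calls <- call_major_haplotypes(M, anchors_n, anchors_s)
    write.table(calls$calls, file.path(config$out_dir, "x_haplotype_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    agg <- aggregate_recomb_intervals(calls$breakpoints)
    if (nrow(agg$groups))
      write_bed(data.frame(contig = block$contig, start = agg$groups$start,
                           end = agg$groups$end,
                           name = sprintf("recomb_interval_%d",
                                          agg$groups$group)),
                file.path(config$out_dir, "recomb_intervals.bed"))
    xhap_summary <- list(
      class_counts = as.list(table(calls$calls$class)),
      n_recomb_interval_groups = nrow(agg$groups),
      conserved_core = agg$core)
  }

  # --- introgression
  scan <- sharing_ratio_scan(gt, c("CnSouth", "Europe"),
                             window_bp = config$window_bp,
                             min_snps = th$min_snps,
                             min_comparisons = th$min_comparisons,
                             ratio_threshold = th$ratio_threshold,
                             contigs = "chr1")
  segs <- merge_flagged_windows(scan)
  write.table(scan, file.path(config$out_dir, "sharing_windows.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(segs))
    write_bed(data.frame(contig = segs$contig, start = segs$start,
                         end = segs$end,
                         name = paste0(segs$sample, "_from_",
                                       segs$other_group)),
              file.path(config$out_dir, "introgression_segments.bed"))

  # --- differential
  snps <- which(gt$variants$class == "SNP")
  nf <- near_fixation_scan(gt, "large", "small", th$near_fix_hi,
                           th$near_fix_lo, by = "size_class")
  write.table(nf, file.path(config$out_dir, "near_fixation_hits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  indels <- which(gt$variants$class == "indel")
  kept <- intersect(indels, coverage_filter(gt, c("large", "small"),
                                            th$min_per_group,
                                            by = "size_class"))
  indel_hits <- if (length(kept))
    chisq_scan(gt, "large", "small", "bonferroni", by = "size_class",
               variants = kept) else NULL
  sv <- simulate_sv_table(gt$samples, n_null = 100,
                          planted = data.frame(high_group = rep("CnNorth", 5)),
                          seed = sub_seed(config$seed, 31L))
  rownames(sv$presence) <- sv$sv$sv_id
  top_sv <- top_k_sv(sv$presence, gt$samples$group, "CnNorth", "CnSouth",
                     k = th$sv_k, alpha = th$sv_alpha)
  write.table(top_sv, file.path(config$out_dir, "top_svs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = config$seed,
    n_variants = n_variants(gt), n_samples = n_samples(gt),
    ns_s_ratio = omega,
    mean_theta_pi_kb = mean(div$theta_pi_kb),
    mean_theta_w_kb = mean(div$theta_w_kb),
    mean_fst_cnsouth_cnnorth = mean(div$fst, na.rm = TRUE),
    hom_het_range = range(hh$hom_het_ratio[is.finite(hh$hom_het_ratio)]),
    pca_eigenvalues = pca$eigenvalues[1:3],
    admixture_loglik = lapply(adm, function(f)
      list(K = f$K, loglik = tail(f$loglik, 1))),
    ld = ld_summary, x_haplotypes = xhap_summary,
    introgression = list(n_windows = nrow(scan),
                         n_flagged = sum(scan$introgressed),
                         n_segments = nrow(segs)),
    differential = list(n_near_fixation = nrow(nf),
                        n_indels_tested = length(kept),
                        n_indel_hits = if (is.null(indel_hits)) 0L else
                          sum(indel_hits$p_adj < 0.05, na.rm = TRUE),
                        n_top_svs = nrow(top_sv)))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  logf("pipeline complete")
  invisible(summary)
}
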