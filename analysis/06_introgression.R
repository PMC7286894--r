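#!/usr/bin/env Rscript
# Stage 6: haplotype-sharing introgression scan.
#
# 100 Kb windows, >= 10 SNPs, >= 3 comparisons per group; a window is
# flagged when the pig shares less with its own group than with the other
# (R = S_own / S_cross < 0.8).  High-sharing regions (>= 90% identically
# shared SNPs vs the best other-group pig) are reported separately, and a
# window likelihood-ratio test assigns the favored ancestry of the
# recipient inside the recovered segments.

suppressMessages(library(pigpopgen))

sim <- "results/sim"; out <- "results/introgression"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gt <- read_vcf(file.path(sim, "variants.vcf"),
               metadata = file.path(sim, "samples.tsv"))
truth <- read.delim(file.path(sim, "truth", "tracts.tsv"))

sc <- sharing_ratio_scan(gt, c("CnSouth", "Europe"), contigs = "chr1")
write.table(sc, file.path(out, "sharing_windows.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
segs <- merge_flagged_windows(sc)
write_bed(data.frame(contig = segs$contig, start = segs$start,
                     end = segs$end,
                     name = paste0(segs$sample, "_from_", segs$other_group)),
          file.path(out, "introgression_segments.bed"))

cat(sprintf("windows scanned: %d, flagged: %d, merged segments: %d\n",
            nrow(sc), sum(sc$introgressed), nrow(segs)))
for (r in seq_len(nrow(truth))) {
  s <- segs[segs$sample == truth$sample[r], , drop = FALSE]
  cov <- if (nrow(s)) sum(pmin(s$end, truth$end[r]) -
                            pmax(s$start, truth$start[r]) + 1) else 0
  cat(sprintf("planted tract %s:%d-%d (%s): %.0f%% covered by flagged segments\n",
              truth$sample[r], truth$start[r], truth$end[r],
              truth$donor_group[r],
              100 * cov / (truth$end[r] - truth$start[r])))
}

hs <- high_sharing_regions(gt, c("CnSouth", "Europe"), contigs = "chr1")
write.table(hs$windows, file.path(out, "high_sharing_windows.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("high-sharing (>=90%% shared SNPs) windows: %d\n",
            sum(hs$windows$flagged)))

# ancestry LRT inside each recovered segment
fr <- group_frequencies(gt, c("CnSouth", "Europe"))
g <- geno_dosage(gt)
n_cs <- length(group_samples(gt, "CnSouth"))
n_eu <- length(group_samples(gt, "Europe"))
for (r in seq_len(nrow(segs))) {
  vi <- gt$variants$contig == segs$contig[r] & gt$variants$class == "SNP" &
    gt$variants$pos >= segs$start[r] & gt$variants$pos <= segs$end[r]
  focal <- match(segs$sample[r], gt$samples$sample)
  lrt <- window_lrt(g[vi, focal], fr[vi, "CnSouth"], fr[vi, "Europe"],
                    n_cs, n_eu)
  cat(sprintf("segment %s:%d-%d (%s): Lambda = %.1f, favored ancestry: %s\n",
              segs$contig[r], segs$start[r], segs$end[r], segs$sample[r],
              lrt$lambda,
              ifelse(lrt$favored == "A", "CnSouth", "Europe")))
}
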