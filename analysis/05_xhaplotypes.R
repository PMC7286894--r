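#!/usr/bin/env Rscript
# Stage 5: X-chromosome haplotype structure.
#
# Encodes the block haplotypes relative to the reference, calls the two
# major backgrounds (S anchored on CnSouth, N on Europe + wild) and the
# recombinant mosaics, localizes recombination intervals, and measures the
# conserved core between the aggregated interval groups.

suppressMessages(library(pigpopgen))

sim <- "results/sim"; out <- "results/xhap"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gt <- read_vcf(file.path(sim, "variants.vcf"),
               metadata = file.path(sim, "samples.tsv"))
block <- jsonlite::read_json(file.path(sim, "x_block.json"),
                             simplifyVector = TRUE)

M <- encode_reference_relative(gt, block)
calls <- call_major_haplotypes(
  M,
  anchors_n = c(group_samples(gt, "Europe"), group_samples(gt, "wild")),
  anchors_s = group_samples(gt, "CnSouth"))

write.table(calls$calls, file.path(out, "haplotype_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("haplotype classes:\n")
print(table(sample_class = calls$calls$class))

truth <- read.delim(file.path(sim, "truth", "x_haplotypes.tsv"))
per_sample <- calls$calls[!duplicated(calls$calls$sample), ]
got <- sub("-[0-9]+$", "", per_sample$class[match(truth$sample,
                                                  per_sample$sample)])
cat(sprintf("label agreement with truth: %.0f%%\n",
            100 * mean(got == truth$class)))

if (nrow(calls$breakpoints)) {
  write_bed(data.frame(contig = block$contig,
                       start = calls$breakpoints$left_pos,
                       end = calls$breakpoints$right_pos,
                       name = calls$breakpoints$hap),
            file.path(out, "breakpoint_intervals.bed"))
  agg <- aggregate_recomb_intervals(calls$breakpoints)
  write.table(agg$groups, file.path(out, "recomb_interval_groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in seq_len(nrow(agg$groups)))
    cat(sprintf("recombination interval %d: maximal range %d-%d (%d intervals)\n",
                g, agg$groups$start[g], agg$groups$end[g],
                agg$groups$n_intervals[g]))
  if (!is.null(agg$core))
    cat(sprintf("conserved core: %d-%d (%.2f Mb)\n",
                agg$core$start, agg$core$end, agg$core$mb))
}
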