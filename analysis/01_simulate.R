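#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates the sampling design of a 31-animal resequencing panel: CnSouth
# (n=11), CnNorth (n=9), European domestic (n=5) and wild boars (n=6), with
# drift calibrated to the observed F_ST scale (CnSouth/CnNorth ~0.06,
# Europe/wild ~0.08).  Planted ground truth: two Europe->CnSouth
# introgression tracts on chr1, an X LD block carrying the two ancestral
# backgrounds (with two CnNorth recombinant mosaics), and four size-
# differentiated near-fixed sites.  All downstream stages read only the
# files written here.

suppressMessages(library(pigpopgen))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260924L

block <- list(contig = "X", start = 5e5, end = 2.5e6)
recombinants <- data.frame(
  sample = c("CnNorth_01", "CnNorth_03"),
  breakpoints = c("900000", "1700000"))

cfg <- sim_config(
  n_sites = 6000,
  seed = seed,
  introgression_spec = data.frame(
    donor = "Europe", recipient = c("CnSouth_01", "CnSouth_02"),
    contig = "chr1", start = c(1.0e6, 3.5e6), end = c(3.0e6, 4.5e6)),
  x_block_spec = c(block, list(assignments = NULL)),
  size_effect_spec = data.frame(site = c(101, 202, 303, 404),
                                high_group = "CnNorth",
                                hi = 0.95, lo = 0.03))

# assignments: group defaults (CnSouth -> S, others -> N) plus two mosaics
s0 <- simulate_populations(sim_config(n_sites = 10, seed = seed))
asg <- data.frame(sample = s0$gt$samples$sample,
                  class = ifelse(grepl("^CnSouth", s0$gt$samples$sample),
                                 "S", "N"),
                  breakpoints = NA_character_, stringsAsFactors = FALSE)
asg$class[asg$sample %in% recombinants$sample] <- "recombinant"
asg$breakpoints[match(recombinants$sample, asg$sample)] <-
  recombinants$breakpoints
cfg$x_block_spec$assignments <- asg

ann <- emit_genome_annotation(cfg$contig_lengths, genes_per_mb = 40,
                              cds_length = 600, seed = seed, dir = out)
sim <- simulate_populations(cfg, reference = ann$reference)

write_vcf(sim$gt, file.path(out, "variants.vcf"))
write_sample_metadata(sim$gt$samples, file.path(out, "samples.tsv"))
write_truth(sim$truth, file.path(out, "truth"))
jsonlite::write_json(block, file.path(out, "x_block.json"),
                     auto_unbox = TRUE)

cat(sprintf("simulated %d variants x %d samples -> %s\n",
            n_variants(sim$gt), n_samples(sim$gt), out))
cat(sprintf("planted: %d introgression tracts, %d recombinant X mosaics, %d size-contrast sites\n",
            nrow(sim$truth$tracts),
            sum(sim$truth$x_haplotypes$labels$class == "recombinant"),
            nrow(cfg$size_effect_spec)))
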