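#!/usr/bin/env Rscript
# Build the study-shaped synthetic MA experiment.
#
# Emulates the real design on a toy genome: 3 chromosomes, 80 control and
# 90 treated sequenced lines (two per dish), 50 transfers with ~1,009 and
# 865 measured total divisions, arm-specific substitution spectra and
# indel/SSR structure taken from the observed mutation tables, and the QC
# artifacts the study reported (3 + 1 cross-contaminated dishes, 4 + 3
# lines under 30x). Truth rates are scaled so the expected mutation
# counts on the toy genome match the real totals (62/114 BPS, 34/23
# indels over the kept lines).
#
# Writes results/data/ (FASTA, GFF3, per-line VCFs, metadata, truth).

suppressPackageStartupMessages(library(mamut))

seed <- 101L
out <- "results/data"

ref <- generate_genome(genome_spec(
  n_chromosomes = 3L, chrom_length = 30000L, gc_content = 0.36,
  n_genes = 36L, mean_cds_length = 900L, intron_probability = 0.3,
  ssr_density = 2, seed = seed))
n_sites <- sum(nchar(ref$sequences))
cat(sprintf("toy genome: %d chromosomes, %d bp, %d genes, %d SSR tracts\n",
            length(ref$sequences), n_sites, nrow(ref$genes),
            nrow(ref$ssr_tracts)))

truth <- list(
  control = truth_rates(
    bps_rate = 62 / (73 * 1009 * n_sites),
    indel_rate = 34 / (73 * 1009 * n_sites),
    spectrum_weights = c(11, 18, 5, 5, 5, 18),
    insertion_fraction = 30 / 34, ssr_bias = 1.0),
  treatment = truth_rates(
    bps_rate = 114 / (86 * 865 * n_sites),
    indel_rate = 23 / (86 * 865 * n_sites),
    spectrum_weights = c(21, 27, 5, 11, 5, 45),
    insertion_fraction = 19 / 23, ssr_bias = 15 / 23))

design <- experiment_design()  # 80/90 lines, 2 per dish, 1009/865 divisions
sim <- simulate_ma_lines(ref, truth, design, seed = seed)
sim <- inject_artifacts(sim, ref, n_shared_pairs = 3, n_low_depth = 4,
                        seed = seed + 1L, group = "control")
sim <- inject_artifacts(sim, ref, n_shared_pairs = 1, n_low_depth = 3,
                        seed = seed + 2L, group = "treatment")

write_experiment(sim, ref, out)
cat(sprintf("simulated %d mutations across %d lines -> %s\n",
            nrow(sim$mutations), nrow(sim$metadata), out))
cat(sprintf("planted artifacts: contaminated dishes [%s], %d low-depth lines\n",
            paste(sim$truth$shared_pairs, collapse = ", "),
            length(sim$truth$low_depth_lines)))
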