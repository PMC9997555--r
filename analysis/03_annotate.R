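#!/usr/bin/env Rscript
# Site inventory and mutation classification. Builds the genome-wide
# denominators (analyzable sites per region, fractional syn/nonsyn sites,
# four-fold degenerate sites, 64 trinucleotide context counts), detects
# SSR tracts, and classifies every QC-passing mutation.
#
# Reads results/data/ and results/qc/, writes results/annotate/.

suppressPackageStartupMessages(library(mamut))

ref <- read_reference("results/data/reference.fasta",
                      "results/data/genes.gff3")
inv <- build_site_inventory(ref)
tracts <- detect_ssrs_genome(ref, min_copies = 3, min_tract_bp = 5,
                             max_motif = 6)
kept <- read_metadata("results/qc/metadata_kept.tsv")
mut <- utils::read.delim("results/qc/mutations_kept.tsv",
                         stringsAsFactors = FALSE)
ann <- classify_mutations(mut, ref, inv, tracts = tracts, flank_bp = 1)
ann <- merge(ann, kept[, c("line_id", "group")], by = "line_id",
             sort = FALSE)

dir.create("results/annotate", recursive = TRUE, showWarnings = FALSE)
write.table(ann, "results/annotate/annotations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tracts, "results/annotate/ssr_tracts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(
  analyzable_sites_total = inv$analyzable_sites_total,
  sites_by_region = as.list(inv$sites_by_region),
  syn_sites = inv$syn_sites, nonsyn_sites = inv$nonsyn_sites,
  fourfold_sites = inv$fourfold_sites,
  context_counts = as.list(inv$context_counts)),
  "results/annotate/inventory.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("inventory: %d analyzable sites (CDS %d / intron %d / intergenic %d)\n",
            inv$analyzable_sites_total, inv$sites_by_region[["CDS"]],
            inv$sites_by_region[["intron"]],
            inv$sites_by_region[["intergenic"]]))
cat(sprintf("  %.1f non-synonymous and %.1f synonymous sites; %d four-fold sites\n",
            inv$nonsyn_sites, inv$syn_sites, inv$fourfold_sites))
cat(sprintf("  %d SSR tracts detected\n", nrow(tracts)))
print(table(ann$group, ann$kind))
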