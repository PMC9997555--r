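#!/usr/bin/env Rscript
# Rate and spectrum estimation with the study's statistics: per-site and
# per-genome BPS rates with exact Poisson CIs, indel rates, four-fold and
# region rates, spectrum tables with Ts/Tv and ins/del ratios, NS/S
# goodness of fit against site availability, between-arm rate-ratio and
# 2x2 comparisons, the 64-cell context matrix, and the per-gene
# enrichment scan.
#
# Reads results/data/, results/qc/, results/annotate/; writes
# results/rates/.

suppressPackageStartupMessages(library(mamut))

ref <- read_reference("results/data/reference.fasta",
                      "results/data/genes.gff3")
inv <- build_site_inventory(ref)
kept <- read_metadata("results/qc/metadata_kept.tsv")
ann <- utils::read.delim("results/annotate/annotations.tsv",
                         stringsAsFactors = FALSE)
dir.create("results/rates", recursive = TRUE, showWarnings = FALSE)

groups <- sort(unique(kept$group))
rates <- list(); spectra <- list()
for (g in groups) {
  lg <- kept[kept$group == g, ]
  ag <- ann[ann$group == g, ]
  bps <- ag[ag$kind == "BPS", ]
  rates[[g]] <- list(
    bps_site = mutation_rate(nrow(bps), lg, per = "site"),
    bps_genome = mutation_rate(nrow(bps), lg, per = "genome"),
    indel_site = mutation_rate(sum(ag$kind != "BPS"), lg, per = "site"),
    fourfold = mutation_rate(sum(bps$at_fourfold_site), lg, per = "site",
                             category_sites = inv$fourfold_sites))
  spectra[[g]] <- spectrum_table(ag)

  cat(sprintf("\n== %s (%d lines) ==\n", g, nrow(lg)))
  cat("  BPS per site per division:   "); print(rates[[g]]$bps_site)
  cat("  BPS per genome per division: "); print(rates[[g]]$bps_genome)
  cat("  indels per site per division:"); print(rates[[g]]$indel_site)
  cat("  four-fold degenerate sites:  "); print(rates[[g]]$fourfold)
  cat(sprintf("  Ts/Tv %.2f | ins/del %.2f\n",
              spectra[[g]]$ts_tv_ratio, spectra[[g]]$ins_del_ratio))
  ns <- sum(bps$coding_effect == "non-synonymous", na.rm = TRUE)
  s <- sum(bps$coding_effect == "synonymous", na.rm = TRUE)
  gof <- gof_test_ns_s(ns, s, inv$nonsyn_sites, inv$syn_sites)
  cat(sprintf("  NS/S %d/%d vs site ratio: chi2=%.2f, P=%.2f (drift dominates if large P)\n",
              ns, s, gof$chi2, gof$p))
  idx <- ag$kind != "BPS"
  cat(sprintf("  indels in SSRs: %.1f%%\n",
              100 * mean(ag$in_ssr[idx], na.rm = TRUE)))
  write.table(as.data.frame(spectra[[g]]),
              sprintf("results/rates/spectrum_%s.tsv", g), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(context_rate_matrix(ag, inv, lg),
              sprintf("results/rates/context_matrix_%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gene_enrichment_scan(ag, ref$genes, rates[[g]]$bps_site, lg),
              sprintf("results/rates/enrichment_%s.tsv", g), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

if (length(groups) == 2) {
  g1 <- groups[1]; g2 <- groups[2]
  cat(sprintf("\n== %s vs %s ==\n", g2, g1))
  for (cat_name in c("bps_site", "fourfold", "indel_site")) {
    r1 <- rates[[g1]][[cat_name]]; r2 <- rates[[g2]][[cat_name]]
    t <- rate_ratio_test(r1$m, r1$exposure, r2$m, r2$exposure)
    cat(sprintf("  %s: ratio %.2fx, chi2=%.2f, P=%.3f\n",
                cat_name, t$ratio, t$chi2, t$p))
  }
  s1 <- spectra[[g1]]; s2 <- spectra[[g2]]
  tt <- count_comparison_test(s1$ts_count, s1$tv_count,
                              s2$ts_count, s2$tv_count)
  cat(sprintf("  Ts/Tv heterogeneity: chi2=%.2f, P=%.2f\n", tt$chi2, tt$p))
}

rate_tab <- do.call(rbind, lapply(groups, function(g) {
  do.call(rbind, lapply(names(rates[[g]]), function(cat) {
    e <- rates[[g]][[cat]]
    data.frame(group = g, category = cat, m = e$m, exposure = e$exposure,
               per = e$per, rate = e$rate, ci_low = e$ci_low,
               ci_high = e$ci_high, stringsAsFactors = FALSE)
  }))
}))
write.table(rate_tab, "results/rates/rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwrote results/rates/\n")
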