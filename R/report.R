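# Pipeline orchestration: configuration, the qc -> annotate -> rates run,
# and publication-style output tables (TSV for humans, JSON at full
# precision for machines).

#' Pipeline configuration
#'
#' @param fasta,gff3 Reference genome and gene models.
#' @param vcf_dir Directory of per-line VCFs named `<line_id>.vcf`.
#' @param metadata Line metadata TSV.
#' @param out_dir Output directory.
#' @param min_depth Depth floor for [depth_filter()] (default 30).
#' @param ci_level Confidence level for Poisson CIs.
#' @param ssr_min_copies,ssr_min_tract_bp,ssr_max_motif SSR detection
#'   parameters.
#' @param flank_bp Indel-to-tract flank tolerance.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, gff3, vcf_dir, metadata, out_dir,
                            min_depth = 30, ci_level = 0.95,
                            ssr_min_copies = 3L, ssr_min_tract_bp = 5L,
                            ssr_max_motif = 6L, flank_bp = 1L, seed = 1L) {
  for (p in c(fasta, gff3, vcf_dir, metadata)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  stopifnot(min_depth >= 0, ci_level > 0, ci_level < 1, ssr_min_copies >= 1,
            ssr_min_tract_bp >= 1, ssr_max_motif >= 1, flank_bp >= 0)
  structure(list(fasta = fasta, gff3 = gff3, vcf_dir = vcf_dir,
                 metadata = metadata, out_dir = out_dir,
                 min_depth = min_depth, ci_level = ci_level,
                 ssr_min_copies = as.integer(ssr_min_copies),
                 ssr_min_tract_bp = as.integer(ssr_min_tract_bp),
                 ssr_max_motif = as.integer(ssr_max_motif),
                 flank_bp = as.integer(flank_bp), seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

rate_row <- function(group, category, est) {
  data.frame(group = group, category = category, m = est$m,
             exposure = est$exposure, per = est$per, rate = est$rate,
             ci_low = est$ci_low, ci_high = est$ci_high,
             stringsAsFactors = FALSE)
}

#' Run the full MA analysis pipeline
#'
#' Executes line QC (contamination filter, then depth filter), builds the
#' site inventory and SSR tract set, classifies every mutation, and
#' produces per-group rate estimates with exact Poisson CIs, spectrum
#' tables, region and four-fold rates, the 64-cell context-rate matrix,
#' the gene-enrichment scan, and between-group chi-square comparisons.
#' All tables are written as TSV with a machine-readable `report.json`
#' (full precision) and a QC log naming every removed line.
#'
#' @param config A [pipeline_config()].
#' @return The report bundle (named list of all tables), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("mamut pipeline; seed=%d; ci_level=%g; min_depth=%g",
                         config$seed, config$ci_level, config$min_depth))

  stage <- "input"
  res <- tryCatch({
    ref <- read_reference(config$fasta, config$gff3)
    md <- read_metadata(config$metadata)
    mutations <- read_vcf_dir(config$vcf_dir, line_ids = md$line_id)

    stage <- "qc"
    qc <- qc_lines(mutations, md, min_depth = config$min_depth)
    for (i in seq_len(nrow(qc$report))) {
      log_lines <- c(log_lines, sprintf(
        "removed line %s (dish %s): rule=%s%s", qc$report$line_id[i],
        qc$report$dish_id[i], qc$report$rule[i],
        if (!is.na(qc$report$shared_site[i])) {
          paste0(" shared_site=", qc$report$shared_site[i])
        } else ""))
    }
    log_lines <- c(log_lines, sprintf("kept %d of %d lines",
                                      nrow(qc$kept), nrow(md)))

    stage <- "annotate"
    inv <- build_site_inventory(ref)
    if (is.null(md$analyzable_sites)) {
      qc$kept$analyzable_sites <- inv$analyzable_sites_total
    }
    tracts <- detect_ssrs_genome(ref, min_copies = config$ssr_min_copies,
                                 min_tract_bp = config$ssr_min_tract_bp,
                                 max_motif = config$ssr_max_motif)
    ann <- classify_mutations(qc$mutations, ref, inv, tracts = tracts,
                              flank_bp = config$flank_bp)
    ann <- merge(ann, qc$kept[, c("line_id", "group")], by = "line_id",
                 sort = FALSE)

    stage <- "rates"
    groups <- sort(unique(qc$kept$group))
    lvl <- config$ci_level
    rates <- list(); spectra <- list(); ctx <- list(); enrich <- list()
    gof <- list()
    for (g in groups) {
      lg <- qc$kept[qc$kept$group == g, , drop = FALSE]
      ag <- ann[ann$group == g, , drop = FALSE]
      bps <- ag[ag$kind == "BPS", , drop = FALSE]
      ind <- ag[ag$kind != "BPS", , drop = FALSE]
      rates[[g]] <- list(
        bps_genome = mutation_rate(nrow(bps), lg, per = "genome",
                                   level = lvl),
        bps_site = mutation_rate(nrow(bps), lg, per = "site", level = lvl),
        indel_site = mutation_rate(nrow(ind), lg, per = "site",
                                   level = lvl),
        fourfold = mutation_rate(sum(bps$at_fourfold_site), lg,
                                 per = "site",
                                 category_sites = inv$fourfold_sites,
                                 level = lvl),
        CDS = mutation_rate(sum(bps$region == "CDS"), lg, per = "site",
                            category_sites = inv$sites_by_region[["CDS"]],
                            level = lvl),
        intron = mutation_rate(sum(bps$region == "intron"), lg,
                               per = "site",
                               category_sites =
                                 inv$sites_by_region[["intron"]],
                               level = lvl),
        intergenic = mutation_rate(sum(bps$region == "intergenic"), lg,
                                   per = "site",
                                   category_sites =
                                     inv$sites_by_region[["intergenic"]],
                                   level = lvl))
      spectra[[g]] <- spectrum_table(ag)
      ctx[[g]] <- context_rate_matrix(ag, inv, lg)
      enrich[[g]] <- gene_enrichment_scan(ag, ref$genes,
                                          rates[[g]]$bps_site, lg)
      gof[[g]] <- gof_test_ns_s(
        sum(bps$coding_effect == "non-synonymous", na.rm = TRUE),
        sum(bps$coding_effect == "synonymous", na.rm = TRUE),
        inv$nonsyn_sites, inv$syn_sites)
    }

    comparisons <- NULL
    if (length(groups) == 2) {
      g1 <- groups[1]; g2 <- groups[2]
      s1 <- spectra[[g1]]; s2 <- spectra[[g2]]
      cmp_row <- function(name, t) {
        data.frame(comparison = name, chi2 = t$chi2, df = t$df, p = t$p,
                   ratio = t$ratio %||% NA_real_, stringsAsFactors = FALSE)
      }
      rr <- function(cat) {
        rate_ratio_test(rates[[g1]][[cat]]$m, rates[[g1]][[cat]]$exposure,
                        rates[[g2]][[cat]]$m, rates[[g2]][[cat]]$exposure)
      }
      in_ssr1 <- sum(ann$group == g1 & ann$kind != "BPS" & ann$in_ssr %in%
                       TRUE)
      out_ssr1 <- sum(ann$group == g1 & ann$kind != "BPS" &
                        ann$in_ssr %in% FALSE)
      in_ssr2 <- sum(ann$group == g2 & ann$kind != "BPS" & ann$in_ssr %in%
                       TRUE)
      out_ssr2 <- sum(ann$group == g2 & ann$kind != "BPS" &
                        ann$in_ssr %in% FALSE)
      comparisons <- rbind(
        cmp_row("ts_tv", count_comparison_test(
          s1$ts_count, s1$tv_count, s2$ts_count, s2$tv_count)),
        cmp_row("ins_del", count_comparison_test(
          s1$insertions, s1$deletions, s2$insertions, s2$deletions)),
        cmp_row("indel_ssr", count_comparison_test(
          in_ssr1, out_ssr1, in_ssr2, out_ssr2)),
        cmp_row("bps_genome_rate", rr("bps_genome")),
        cmp_row("fourfold_rate", rr("fourfold")),
        cmp_row("CDS_rate", rr("CDS")),
        cmp_row("intron_rate", rr("intron")),
        cmp_row("intergenic_rate", rr("intergenic")))
    }

    stage <- "write"
    design <- summarize_experiment(qc$kept)
    rate_tab <- do.call(rbind, lapply(groups, function(g) {
      do.call(rbind, lapply(names(rates[[g]]), function(cat) {
        rate_row(g, cat, rates[[g]][[cat]])
      }))
    }))
    write_tsv(rate_tab, file.path(config$out_dir, "rates.tsv"))
    write_tsv(ann, file.path(config$out_dir, "annotations.tsv"))
    write_tsv(design, file.path(config$out_dir, "design_summary.tsv"))
    write_tsv(qc$report, file.path(config$out_dir, "qc_removals.tsv"))
    if (!is.null(comparisons)) {
      write_tsv(comparisons, file.path(config$out_dir, "comparisons.tsv"))
    }
    for (g in groups) {
      write_tsv(as.data.frame(spectra[[g]]),
                file.path(config$out_dir, sprintf("spectrum_%s.tsv", g)))
      write_tsv(ctx[[g]],
                file.path(config$out_dir,
                          sprintf("context_matrix_%s.tsv", g)))
      write_tsv(enrich[[g]],
                file.path(config$out_dir, sprintf("enrichment_%s.tsv", g)))
    }
    writeLines(log_lines, file.path(config$out_dir, "qc_log.txt"))

    inv_json <- list(analyzable_sites_total = inv$analyzable_sites_total,
                     sites_by_region = as.list(inv$sites_by_region),
                     syn_sites = inv$syn_sites,
                     nonsyn_sites = inv$nonsyn_sites,
                     fourfold_sites = inv$fourfold_sites,
                     context_counts = as.list(inv$context_counts))
    jsonlite::write_json(inv_json,
                         file.path(config$out_dir, "inventory.json"),
                         auto_unbox = TRUE, digits = NA)
    bundle <- list(qc = qc["report"], kept_lines = qc$kept$line_id,
                   inventory = inv_json, rates = rate_tab,
                   spectra = lapply(spectra, unclass),
                   gof_ns_s = gof, comparisons = comparisons,
                   design = design, seed = config$seed)
    jsonlite::write_json(bundle, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    list(ref = ref, inventory = inv, qc = qc, annotations = ann,
         rates = rates, spectra = spectra, context = ctx,
         enrichment = enrich, gof_ns_s = gof, comparisons = comparisons,
         design = design, tracts = tracts)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Summarize the experimental design per group
#'
#' Lines, transfers, divisions per transfer, total divisions, and the
#' harmonic-mean effective population size per arm. A group mixing several
#' divisions-per-transfer values triggers a warning and reports the range.
#'
#' @param metadata Line metadata.
#' @return Data.frame, one row per group.
#' @export
summarize_experiment <- function(metadata) {
  out <- lapply(split(metadata, metadata$group), function(d) {
    dpt <- unique(d$divisions_per_transfer)
    if (length(dpt) > 1) {
      warning("group ", d$group[1], " mixes divisions_per_transfer values; ",
              "reporting per-line Ne range")
    }
    data.frame(group = d$group[1], n_lines = nrow(d),
               transfers = mean(d$transfers),
               divisions_per_transfer = mean(d$divisions_per_transfer),
               total_divisions = mean(d$total_divisions),
               Ne = mean(effective_population_size(d$divisions_per_transfer)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
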