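# Genome-wide denominators and per-mutation classification.
#
# The site inventory provides every denominator used by the rate
# estimators: analyzable sites per region, Nei-Gojobori-style fractional
# synonymous/non-synonymous site counts, four-fold degenerate sites, and
# the 64 trinucleotide context counts. Classification assigns each called
# variant its region, coding effect, strand-collapsed spectrum class,
# transition/transversion status, reference-strand context, and (for
# indels) SSR overlap.

#' Build the genome-wide site inventory
#'
#' Counts analyzable (non-N) sites per region with priority
#' CDS > intron > intergenic; overlapping gene models are resolved by
#' assigning each position to the gene with the longest total CDS. Per
#' coding position the synonymous site fraction is the number of the three
#' alternative bases preserving the amino acid divided by 3; four-fold
#' degenerate sites are third-codon positions where all four bases encode
#' the same amino acid. Trinucleotide contexts are counted on the reference
#' strand over interior positions (64 cells, windows containing N skipped).
#'
#' @param ref A `reference_bundle`.
#' @return An object of class `site_inventory`.
#' @export
build_site_inventory <- function(ref) {
  stopifnot(inherits(ref, "reference_bundle"))
  chroms <- names(ref$sequences)
  lens <- nchar(ref$sequences)
  chars <- lapply(ref$sequences, function(s) strsplit(s, "")[[1]])
  n_count <- sum(vapply(chars, function(v) sum(v == "N"), numeric(1)))
  total <- sum(lens) - n_count

  tabs <- codon_tables()
  # per-chromosome maps: assigned gene index, 1-based coding coordinate
  gene_at <- lapply(lens, function(L) integer(L))
  coding_pos_at <- lapply(lens, function(L) integer(L))
  names(gene_at) <- names(coding_pos_at) <- chroms

  genes <- ref$genes
  cds <- ref$cds
  spliced <- character(0)
  syn_sites <- 0; nonsyn_sites <- 0
  fourfold <- lapply(lens, function(L) integer(0))
  names(fourfold) <- chroms
  cds_assigned <- 0L
  if (nrow(genes)) {
    ord <- order(-genes$cds_length)  # longest transcript wins overlaps
    spliced <- setNames(character(nrow(genes)), genes$gene_id)
    for (g in ord) {
      gid <- genes$gene_id[g]
      ci <- genes$chromosome[g]
      strand <- genes$strand[g]
      ivs <- cds[cds$gene_id == gid, , drop = FALSE]
      ivs <- ivs[order(ivs$start), , drop = FALSE]
      gpos <- unlist(Map(seq.int, ivs$start, ivs$end), use.names = FALSE)
      if (strand == "-") gpos <- rev(gpos)
      bases <- chars[[ci]][if (strand == "-") rev(gpos) else gpos]
      coding <- if (strand == "-") {
        revcomp(paste(bases, collapse = ""))
      } else paste(bases, collapse = "")
      clen <- nchar(coding)
      if (clen %% 3 != 0) {
        stop("CDS length of ", gid, " is not a multiple of 3")
      }
      codons <- substring(coding, seq(1, clen, 3), seq(3, clen, 3))
      if (any(bad <- grepl("N", codons))) {
        codons[bad] <- NA
      }
      aa <- ifelse(is.na(codons), NA, unname(tabs$code[codons]))
      if (any(aa[-length(aa)] == "*", na.rm = TRUE)) {
        stop("internal stop codon in gene ", gid)
      }
      spliced[gid] <- coding
      free <- gene_at[[ci]][gpos] == 0L
      gene_at[[ci]][gpos[free]] <- g
      coding_pos_at[[ci]][gpos[free]] <- seq_len(clen)[free]
      # site counts only over positions assigned to this gene, N excluded
      cpos <- seq_len(clen)[free]
      cod_idx <- (cpos - 1L) %/% 3L + 1L
      within <- (cpos - 1L) %% 3L + 1L
      ok <- !is.na(codons[cod_idx])
      sf <- tabs$syn_frac[cbind(match(codons[cod_idx[ok]],
                                      rownames(tabs$syn_frac)),
                                within[ok])]
      syn_sites <- syn_sites + sum(sf)
      nonsyn_sites <- nonsyn_sites + sum(1 - sf)
      cds_assigned <- cds_assigned + sum(ok)
      ff <- ok & within == 3L & tabs$fourfold[codons[cod_idx]]
      ff[is.na(ff)] <- FALSE
      fourfold[[ci]] <- c(fourfold[[ci]], gpos[free][ff])
    }
  }

  # intron positions: gaps between a gene's CDS intervals, minus positions
  # already claimed as CDS by another gene
  intron_sites <- 0L
  intron_at <- lapply(lens, function(L) logical(L))
  names(intron_at) <- chroms
  if (nrow(genes)) {
    for (g in seq_len(nrow(genes))) {
      gid <- genes$gene_id[g]
      ci <- genes$chromosome[g]
      ivs <- cds[cds$gene_id == gid, , drop = FALSE]
      ivs <- ivs[order(ivs$start), , drop = FALSE]
      if (nrow(ivs) < 2) next
      for (r in seq_len(nrow(ivs) - 1L)) {
        gap <- seq.int(ivs$end[r] + 1L, ivs$start[r + 1L] - 1L)
        gap <- gap[gene_at[[ci]][gap] == 0L & chars[[ci]][gap] != "N"]
        intron_at[[ci]][gap] <- TRUE
      }
    }
    intron_sites <- sum(vapply(intron_at, sum, numeric(1)))
  }
  cds_sites <- cds_assigned
  intergenic_sites <- total - cds_sites - intron_sites

  ctx <- colSums(Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(ref$sequences)))
  ctx <- ctx[context_keys()]

  inv <- structure(list(
    analyzable_sites_total = total,
    sites_by_region = c(CDS = cds_sites, intron = intron_sites,
                        intergenic = intergenic_sites),
    syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
    fourfold_sites = sum(lengths(fourfold)),
    context_counts = ctx,
    gene_at = gene_at, coding_pos_at = coding_pos_at,
    intron_at = intron_at, fourfold_pos = fourfold,
    spliced_cds = spliced, genes = genes),
    class = "site_inventory")
  stopifnot(abs(inv$syn_sites + inv$nonsyn_sites - cds_sites) < 1e-6)
  inv
}

#' Classify called mutations against the reference
#'
#' Vectorized over a mutation table. Each record gets its region
#' (CDS/intron/intergenic), coding effect for CDS substitutions (decided by
#' translating the mutated vs original codon of the assigned gene model),
#' four-fold-site flag, strand-collapsed spectrum class,
#' transition/transversion status, reference-strand trinucleotide context,
#' owning gene, and - for indels, when `tracts` is supplied - SSR overlap.
#'
#' @param mutations Data.frame with line_id, chromosome, position, ref, alt
#'   (kind derived if absent).
#' @param ref A `reference_bundle`.
#' @param inv The matching [build_site_inventory()] result.
#' @param tracts Optional SSR tract table from [detect_ssrs()] /
#'   `ref$ssr_tracts` for indel flagging.
#' @param flank_bp Flank tolerance passed to [indel_in_ssr()].
#' @return The input with annotation columns appended (class
#'   `mutation_annotations`).
#' @export
classify_mutations <- function(mutations, ref, inv, tracts = NULL,
                               flank_bp = 1L) {
  stopifnot(inherits(ref, "reference_bundle"),
            inherits(inv, "site_inventory"))
  mut <- mutations
  if (is.null(mut$kind)) mut$kind <- variant_kind(mut$ref, mut$alt)
  n <- nrow(mut)
  out <- cbind(mut, data.frame(
    region = rep(NA_character_, n), gene_id = rep(NA_character_, n),
    coding_effect = rep(NA_character_, n),
    at_fourfold_site = rep(FALSE, n),
    spectrum_class = rep(NA_character_, n), ts_tv = rep(NA_character_, n),
    context = rep(NA_character_, n), in_ssr = rep(NA, n),
    stringsAsFactors = FALSE))
  if (!n) return(structure(out, class = c("mutation_annotations",
                                          "data.frame")))
  tabs <- codon_tables()
  for (i in seq_len(n)) {
    ci <- mut$chromosome[i]
    pos <- mut$position[i]
    seq_i <- ref$sequences[[ci]]
    if (is.null(seq_i)) stop("unknown chromosome ", ci)
    L <- nchar(seq_i)
    ref_here <- substr(seq_i, pos, pos + nchar(mut$ref[i]) - 1L)
    if (ref_here != mut$ref[i]) {
      stop("reference-allele mismatch at ", ci, ":", pos, " (VCF says ",
           mut$ref[i], ", reference has ", ref_here,
           "); wrong reference build?")
    }
    g <- inv$gene_at[[ci]][pos]
    region <- if (g > 0L) "CDS" else if (inv$intron_at[[ci]][pos]) {
      "intron"
    } else "intergenic"
    out$region[i] <- region
    if (g > 0L) out$gene_id[i] <- inv$genes$gene_id[g]

    if (mut$kind[i] == "BPS") {
      out$spectrum_class[i] <- spectrum_class(mut$ref[i], mut$alt[i])
      out$ts_tv[i] <- if (is_transition(out$spectrum_class[i])) {
        "transition"
      } else "transversion"
      if (pos > 1L && pos < L) {
        ctx <- substr(seq_i, pos - 1L, pos + 1L)
        if (!grepl("N", ctx)) out$context[i] <- ctx
      }
      out$at_fourfold_site[i] <- pos %in% inv$fourfold_pos[[ci]]
      if (region == "CDS") {
        gid <- inv$genes$gene_id[g]
        strand <- inv$genes$strand[g]
        cpos <- inv$coding_pos_at[[ci]][pos]
        coding <- inv$spliced_cds[[gid]]
        cod_idx <- (cpos - 1L) %/% 3L
        within <- (cpos - 1L) %% 3L + 1L
        codon <- substr(coding, cod_idx * 3L + 1L, cod_idx * 3L + 3L)
        alt_c <- if (strand == "-") COMPLEMENT[[mut$alt[i]]] else mut$alt[i]
        mutated <- codon
        substr(mutated, within, within) <- alt_c
        out$coding_effect[i] <-
          if (tabs$code[[codon]] == tabs$code[[mutated]]) {
            "synonymous"
          } else "non-synonymous"
      }
    } else if (!is.null(tracts)) {
      out$in_ssr[i] <- indel_in_ssr(mut[i, , drop = FALSE], tracts,
                                    flank_bp = flank_bp)
    }
  }
  structure(out, class = c("mutation_annotations", "data.frame"))
}

#' Classify a single mutation record
#' @inheritParams classify_mutations
#' @param rec One-row mutation data.frame (or list coercible to one).
#' @return A one-row `mutation_annotations` data.frame.
#' @export
classify_mutation <- function(rec, ref, inv, tracts = NULL, flank_bp = 1L) {
  if (!is.data.frame(rec)) rec <- as.data.frame(rec, stringsAsFactors = FALSE)
  classify_mutations(rec, ref, inv, tracts = tracts, flank_bp = flank_bp)
}
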