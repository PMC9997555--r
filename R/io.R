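# Reading and writing the on-disk interchange formats: FASTA + GFF3 for the
# reference, one VCF v4.2 per MA line, TSV for metadata and truth.

#' Write a simulated experiment (plus its reference) to a directory
#'
#' Produces `reference.fasta`, `genes.gff3`, `ssr_truth.tsv`,
#' `metadata.tsv`, `truth.tsv`, and `vcf/<line_id>.vcf`.
#'
#' @param sim An `ma_experiment`.
#' @param ref The matching `reference_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, ref, dir) {
  stopifnot(inherits(sim, "ma_experiment"), inherits(ref, "reference_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reference(ref, file.path(dir, "reference.fasta"),
                  file.path(dir, "genes.gff3"))
  utils::write.table(ref$ssr_tracts, file.path(dir, "ssr_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$planted, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vdir <- file.path(dir, "vcf")
  dir.create(vdir, showWarnings = FALSE)
  for (ln in sim$metadata$line_id) {
    write_line_vcf(sim$mutations[sim$mutations$line_id == ln, , drop = FALSE],
                   ln, file.path(vdir, paste0(ln, ".vcf")))
  }
  invisible(dir)
}

#' Write the reference bundle as FASTA + GFF3
#' @param ref A `reference_bundle`.
#' @param fasta,gff3 Output paths.
#' @return `invisible(NULL)`.
#' @export
write_reference <- function(ref, fasta, gff3) {
  seqs <- Biostrings::DNAStringSet(ref$sequences)
  Biostrings::writeXStringSet(seqs, fasta)
  gr <- GenomicRanges::GRanges()
  if (nrow(ref$genes)) {
    gene_gr <- GenomicRanges::GRanges(
      ref$genes$chromosome,
      IRanges::IRanges(ref$genes$start, ref$genes$end),
      strand = ref$genes$strand, type = "gene",
      ID = ref$genes$gene_id, Parent = NA_character_,
      phase = NA_integer_)
    cds <- ref$cds
    # GFF3 phase: bases to skip before the first complete codon, in coding
    # (5'->3') order along each gene
    phase <- integer(nrow(cds))
    for (gid in unique(cds$gene_id)) {
      ix <- which(cds$gene_id == gid)
      ix <- ix[order(cds$start[ix],
                     decreasing = cds$strand[ix[1]] == "-")]
      lens <- cds$end[ix] - cds$start[ix] + 1L
      prior <- c(0L, cumsum(lens)[-length(lens)])
      phase[ix] <- (3L - prior %% 3L) %% 3L
    }
    cds_gr <- GenomicRanges::GRanges(
      cds$chromosome,
      IRanges::IRanges(cds$start, cds$end),
      strand = cds$strand, type = "CDS",
      ID = paste0(cds$gene_id, ".cds", cds$exon_rank),
      Parent = cds$gene_id, phase = phase)
    gr <- c(gene_gr, cds_gr)
  }
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(NULL)
}

# minimal VCF v4.2 emitter: header + 8 fixed columns, no samples
write_line_vcf <- function(mut, line_id, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=mamut simulate (line ", line_id, ")"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(mut)) {
    o <- order(mut$chromosome, mut$position)
    mut <- mut[o, , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                    mut$chromosome, mut$position, mut$ref, mut$alt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a reference genome (FASTA) and gene models (GFF3)
#'
#' CDS features are attached to genes via their `Parent` attribute (or, if
#' absent, their own `ID` prefix).
#'
#' @param fasta,gff3 Input paths; `gff3` may be `NULL` for a gene-free
#'   reference.
#' @return A `reference_bundle`.
#' @export
read_reference <- function(fasta, gff3 = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  sequences <- toupper(as.character(seqs))
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  genes <- data.frame(gene_id = character(), chromosome = character(),
                      strand = character(), start = integer(),
                      end = integer(), cds_length = integer(),
                      stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = character(), chromosome = character(),
                    strand = character(), start = integer(), end = integer(),
                    exon_rank = integer(), stringsAsFactors = FALSE)
  if (!is.null(gff3) && file.exists(gff3)) {
    gr <- rtracklayer::import(gff3)
    is_cds <- !is.na(gr$type) & gr$type == "CDS"
    if (any(is_cds)) {
      cg <- gr[is_cds]
      parent <- vapply(as.list(cg$Parent), function(p) {
        if (length(p)) as.character(p[[1]]) else NA_character_
      }, character(1))
      ord <- order(parent, GenomicRanges::start(cg))
      cg <- cg[ord]; parent <- parent[ord]
      cds <- data.frame(
        gene_id = parent,
        chromosome = as.character(GenomicRanges::seqnames(cg)),
        strand = as.character(GenomicRanges::strand(cg)),
        start = GenomicRanges::start(cg), end = GenomicRanges::end(cg),
        exon_rank = stats::ave(seq_along(parent), parent, FUN = seq_along),
        stringsAsFactors = FALSE)
      agg <- do.call(rbind, lapply(split(cds, cds$gene_id), function(d) {
        data.frame(gene_id = d$gene_id[1], chromosome = d$chromosome[1],
                   strand = d$strand[1], start = min(d$start),
                   end = max(d$end),
                   cds_length = sum(d$end - d$start + 1L),
                   stringsAsFactors = FALSE)
      }))
      genes <- agg[order(agg$chromosome, agg$start), , drop = FALSE]
      rownames(genes) <- NULL
    }
  }
  structure(list(sequences = sequences, genes = genes, cds = cds,
                 ssr_tracts = NULL, spec = NULL),
            class = "reference_bundle")
}

#' Read per-line VCFs from a directory
#'
#' Expects one uncompressed VCF per MA line named `<line_id>.vcf`; only the
#' fixed columns are used. Multi-allelic records are rejected.
#'
#' @param vcf_dir Directory of per-line VCFs.
#' @param line_ids Optional subset of line ids to read.
#' @return A mutation data.frame (line_id, chromosome, position, ref, alt,
#'   kind).
#' @export
read_vcf_dir <- function(vcf_dir, line_ids = NULL) {
  files <- list.files(vcf_dir, pattern = "\\.vcf$", full.names = TRUE)
  ids <- sub("\\.vcf$", "", basename(files))
  if (!is.null(line_ids)) {
    keep <- ids %in% line_ids
    files <- files[keep]; ids <- ids[keep]
  }
  out <- lapply(seq_along(files), function(i) {
    v <- vcfR::read.vcfR(files[i], verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx))) {  # single record collapses to a named vector
      fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
    }
    if (is.null(fx) || nrow(fx) == 0) return(NULL)
    fx <- as.data.frame(fx, stringsAsFactors = FALSE)
    if (any(grepl(",", fx$ALT, fixed = TRUE))) {
      stop("multi-allelic record in ", files[i])
    }
    data.frame(line_id = ids[i], chromosome = fx$CHROM,
               position = as.integer(fx$POS), ref = fx$REF, alt = fx$ALT,
               kind = variant_kind(fx$REF, fx$ALT),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(empty_mutations())))
  rownames(res) <- NULL
  res
}

#' Read the line-metadata table
#' @param path TSV with columns line_id, group, dish_id, transfers,
#'   divisions_per_transfer, total_divisions, mean_depth, analyzable_sites.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line_id", "group", "dish_id", "mean_depth")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(md$total_divisions)) {
    md$total_divisions <- md$transfers * md$divisions_per_transfer
  }
  md
}
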