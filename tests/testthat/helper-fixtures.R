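# Fixtures built in code: hand-crafted references with known gene models,
# shared toy genomes, and a study-shaped simulated experiment (built once
# per session and memoized).

.fixture_env <- new.env(parent = emptyenv())

# reference bundle assembled by hand from explicit sequences + CDS rows
make_ref <- function(sequences, cds = NULL, tracts = NULL) {
  if (is.null(cds)) {
    cds <- data.frame(gene_id = character(), chromosome = character(),
                      strand = character(), start = integer(),
                      end = integer(), exon_rank = integer(),
                      stringsAsFactors = FALSE)
  }
  genes <- if (nrow(cds)) {
    do.call(rbind, lapply(split(cds, cds$gene_id), function(d) {
      data.frame(gene_id = d$gene_id[1], chromosome = d$chromosome[1],
                 strand = d$strand[1], start = min(d$start),
                 end = max(d$end), cds_length = sum(d$end - d$start + 1L),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = character(), chromosome = character(),
               strand = character(), start = integer(), end = integer(),
               cds_length = integer(), stringsAsFactors = FALSE)
  }
  rownames(genes) <- NULL
  structure(list(sequences = sequences, genes = genes, cds = cds,
                 ssr_tracts = tracts, spec = NULL),
            class = "reference_bundle")
}

# one plus-strand gene ATG TTT AAA GGG TAA at positions 6..20 of chr1
tiny_plus_ref <- function() {
  seqs <- c(chr1 = paste0("ACGTC", "ATGTTTAAAGGGTAA", "TCCGATCGAT"))
  cds <- data.frame(gene_id = "g1", chromosome = "chr1", strand = "+",
                    start = 6L, end = 20L, exon_rank = 1L,
                    stringsAsFactors = FALSE)
  make_ref(seqs, cds)
}

# the same gene on the minus strand: revcomp("ATGTTTAAAGGGTAA")
tiny_minus_ref <- function() {
  seqs <- c(chr1 = paste0("ACGTC", "TTACCCTTTAAACAT", "TCCGATCGAT"))
  cds <- data.frame(gene_id = "g1", chromosome = "chr1", strand = "-",
                    start = 6L, end = 20L, exon_rank = 1L,
                    stringsAsFactors = FALSE)
  make_ref(seqs, cds)
}

random_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# shared small generated genome for simulator-driven tests
toy_genome <- function() {
  if (is.null(.fixture_env$toy)) {
    .fixture_env$toy <- generate_genome(
      genome_spec(n_chromosomes = 1L, chrom_length = 20000L,
                  gc_content = 0.4, n_genes = 10L, mean_cds_length = 600L,
                  intron_probability = 0.3, ssr_density = 3, seed = 11L))
  }
  .fixture_env$toy
}

toy_inventory <- function() {
  if (is.null(.fixture_env$toy_inv)) {
    .fixture_env$toy_inv <- build_site_inventory(toy_genome())
  }
  .fixture_env$toy_inv
}

# study-shaped synthetic experiment: 3 chromosomes, 80 control + 90
# treated sequenced lines, 3 + 1 contaminated dishes, 4 + 3 low-depth
# lines, arm-specific spectra scaled so expected mutation counts match
# the real experiment's totals on the toy genome size
study_experiment <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  ref <- generate_genome(
    genome_spec(n_chromosomes = 3L, chrom_length = 30000L,
                gc_content = 0.36, n_genes = 36L, mean_cds_length = 900L,
                intron_probability = 0.3, ssr_density = 2, seed = 101L))
  n_sites <- sum(nchar(ref$sequences))
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
  design <- experiment_design()  # study defaults: 80/90 lines, 1009/865
  sim <- simulate_ma_lines(ref, truth, design, seed = 101L)
  sim <- inject_artifacts(sim, ref, n_shared_pairs = 3, n_low_depth = 4,
                          seed = 102L, group = "control")
  sim <- inject_artifacts(sim, ref, n_shared_pairs = 1, n_low_depth = 3,
                          seed = 103L, group = "treatment")
  .fixture_env$study <- list(ref = ref, sim = sim, truth = truth,
                             design = design)
  .fixture_env$study
}

# brute-force coding-effect oracle: mutate the genome, re-extract and
# translate the whole spliced CDS, compare protein sequences
oracle_coding_effect <- function(ref, gene_id, chrom, pos, alt) {
  cds <- ref$cds[ref$cds$gene_id == gene_id, , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  strand <- cds$strand[1]
  splice <- function(seqs) {
    parts <- substring(seqs[[chrom]], cds$start, cds$end)
    s <- paste(parts, collapse = "")
    if (strand == "-") {
      s <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }
  before <- splice(ref$sequences)
  mutated <- ref$sequences
  substr(mutated[[chrom]], pos, pos) <- alt
  after <- splice(mutated)
  if (before == after) "synonymous" else "non-synonymous"
}

# brute-force SSR enumerator: tests every (start, motif-length) pair
oracle_ssrs <- function(seq, min_copies = 3L, min_tract_bp = 5L,
                        max_motif = 6L) {
  n <- nchar(seq)
  v <- strsplit(seq, "")[[1]]
  period_of <- function(s) {
    L <- nchar(s)
    for (k in seq_len(L - 1)) {
      if (L %% k == 0 && s == strrep(substr(s, 1, k), L / k)) return(k)
    }
    L
  }
  cand <- list()
  for (start in seq_len(n)) {
    for (k in seq_len(max_motif)) {
      if (start + k - 1L > n) next
      motif <- substr(seq, start, start + k - 1L)
      if (grepl("N", motif) || period_of(motif) < k) next
      # maximal to the left?
      if (start > 1L && start + k - 1L <= n && v[start - 1L] == v[start + k - 1L]) next
      end <- start + k - 1L
      while (end < n && v[end + 1L] == v[end + 1L - k]) end <- end + 1L
      tract_len <- end - start + 1L
      copies <- tract_len %/% k
      if (copies < min_copies || tract_len < min_tract_bp) next
      cand[[length(cand) + 1L]] <- data.frame(
        chromosome = NA_character_, start = start, end = end,
        motif = motif, n_copies = copies, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) {
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), motif = character(),
                      n_copies = integer(), stringsAsFactors = FALSE))
  }
  cand <- unique(do.call(rbind, cand))
  # same published resolution rule: longest tract, then shortest motif
  len <- cand$end - cand$start + 1L
  ord <- order(-len, nchar(cand$motif), cand$start)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(occ_s <= cand$end[i] & occ_e >= cand$start[i])) {
      keep[i] <- TRUE
      occ_s <- c(occ_s, cand$start[i]); occ_e <- c(occ_e, cand$end[i])
    }
  }
  res <- cand[keep, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# minimal annotation table from class/kind counts (Table-1-style input)
ann_from_counts <- function(class_counts, insertions = 0L, deletions = 0L) {
  classes <- rep(names(class_counts), class_counts)
  data.frame(
    kind = c(rep("BPS", length(classes)), rep("insertion", insertions),
             rep("deletion", deletions)),
    spectrum_class = c(classes, rep(NA_character_, insertions + deletions)),
    stringsAsFactors = FALSE)
}
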