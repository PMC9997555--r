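# Synthetic MA experiments: toy genomes with gene models and microsatellite
# tracts, then per-line mutation lists drawn from known truth rates.

#' Specification of a toy reference genome
#'
#' Describes a small multi-chromosome genome with protein-coding genes
#' (optionally intron-containing), a target GC content, and planted
#' simple-sequence-repeat (SSR) tracts in intergenic space.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (>= 1000).
#' @param gc_content Target GC fraction, strictly between 0 and 1.
#' @param n_genes Total number of genes across the genome.
#' @param mean_cds_length Mean total CDS length in bp; realized lengths are
#'   multiples of 3 and include the start and stop codons.
#' @param intron_probability Probability that a gene carries one intron.
#' @param ssr_density Planted SSR tracts per 10 kb of sequence.
#' @param seed Integer seed; the same spec yields byte-identical output.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 2L, chrom_length = 50000L,
                        gc_content = 0.36, n_genes = 40L,
                        mean_cds_length = 900L, intron_probability = 0.3,
                        ssr_density = 2, seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length >= 1000,
            gc_content > 0, gc_content < 1,
            n_genes >= 0, mean_cds_length >= 9,
            intron_probability >= 0, intron_probability <= 1,
            ssr_density >= 0)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 gc_content = gc_content,
                 n_genes = as.integer(n_genes),
                 mean_cds_length = as.integer(mean_cds_length),
                 intron_probability = intron_probability,
                 ssr_density = ssr_density,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' True mutational parameters for a simulated MA experiment
#'
#' @param bps_rate Base-substitution rate per site per cell division.
#' @param indel_rate Small-indel rate per site per cell division.
#' @param spectrum_weights Nonnegative weights over the six strand-collapsed
#'   substitution classes (order of [SPECTRUM_CLASSES]); normalized
#'   internally.
#' @param context_multipliers Positive rate multipliers for the 64
#'   trinucleotide contexts, named by `context_keys()` order; default flat.
#' @param insertion_fraction Fraction of indels that are insertions.
#' @param ssr_bias Probability that an indel is placed inside a planted SSR
#'   tract.
#' @return An object of class `truth_rates`.
#' @export
truth_rates <- function(bps_rate = 1e-8, indel_rate = 2e-9,
                        spectrum_weights = rep(1, 6),
                        context_multipliers = rep(1, 64),
                        insertion_fraction = 0.8, ssr_bias = 0.9) {
  stopifnot(bps_rate >= 0, indel_rate >= 0,
            length(spectrum_weights) == 6, all(spectrum_weights >= 0),
            sum(spectrum_weights) > 0,
            length(context_multipliers) == 64, all(context_multipliers > 0),
            insertion_fraction >= 0, insertion_fraction <= 1,
            ssr_bias >= 0, ssr_bias <= 1)
  spectrum_weights <- spectrum_weights / sum(spectrum_weights)
  names(spectrum_weights) <- SPECTRUM_CLASSES
  names(context_multipliers) <- context_keys()
  structure(list(bps_rate = bps_rate, indel_rate = indel_rate,
                 spectrum_weights = spectrum_weights,
                 context_multipliers = context_multipliers,
                 insertion_fraction = insertion_fraction,
                 ssr_bias = ssr_bias),
            class = "truth_rates")
}

#' Design of a two-arm MA experiment
#'
#' Defaults mirror a fission-yeast MA design: two lines per Petri dish,
#' 50 transfers, roughly 20 (control) and 17 (treatment) cell divisions per
#' transfer, with measured total divisions of ~1,009 and 865.
#'
#' @param n_lines_control,n_lines_treatment Sequenced lines per arm.
#' @param transfers Number of single-colony transfers.
#' @param divisions_per_transfer_control,divisions_per_transfer_treatment
#'   Cell divisions per transfer (T).
#' @param lines_per_dish MA lines sharing one dish (>= 1).
#' @param total_divisions_control,total_divisions_treatment Optional measured
#'   totals overriding `transfers * divisions_per_transfer`.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_lines_control = 80L, n_lines_treatment = 90L,
                              transfers = 50L,
                              divisions_per_transfer_control = 20L,
                              divisions_per_transfer_treatment = 17L,
                              lines_per_dish = 2L,
                              total_divisions_control = 1009L,
                              total_divisions_treatment = 865L) {
  stopifnot(n_lines_control >= 0, n_lines_treatment >= 0, transfers >= 1,
            divisions_per_transfer_control >= 1,
            divisions_per_transfer_treatment >= 1,
            lines_per_dish >= 1)
  structure(list(
    n_lines_control = as.integer(n_lines_control),
    n_lines_treatment = as.integer(n_lines_treatment),
    transfers = as.integer(transfers),
    divisions_per_transfer_control = as.integer(divisions_per_transfer_control),
    divisions_per_transfer_treatment =
      as.integer(divisions_per_transfer_treatment),
    lines_per_dish = as.integer(lines_per_dish),
    total_divisions_control = total_divisions_control %||%
      (transfers * divisions_per_transfer_control),
    total_divisions_treatment = total_divisions_treatment %||%
      (transfers * divisions_per_transfer_treatment)),
    class = "experiment_design")
}

random_sense_codons <- function(n) {
  code <- codon_tables()$code
  sense <- names(code)[code != "*"]
  sample(sense, n, replace = TRUE)
}

#' Generate a toy reference genome with gene models and SSR tracts
#'
#' Chromosome background sequence is drawn base-by-base at the requested GC
#' content. Genes are placed without overlap; every CDS starts with ATG,
#' ends with a stop codon, and contains no internal stop on its coding
#' strand (minus-strand genes are written as the reverse complement).
#' SSR tracts are planted in intergenic space and recorded as truth.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `reference_bundle`: `sequences` (named
#'   uppercase character vector), `genes` (one row per gene), `cds` (one row
#'   per CDS interval, 1-based inclusive), `ssr_tracts` (planted truth).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  p <- c(A = (1 - spec$gc_content) / 2, C = spec$gc_content / 2,
         G = spec$gc_content / 2, T = (1 - spec$gc_content) / 2)
  chrom_names <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  seqs <- vapply(chrom_names, function(cn) {
    paste(sample(BASES, spec$chrom_length, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))

  # assign genes round-robin to chromosomes
  gene_chrom <- rep(seq_len(spec$n_chromosomes), length.out = spec$n_genes)
  genes <- list(); cds <- list()
  if (spec$n_genes > 0) {
    # realized CDS lengths: multiples of 3, at least 5 codons
    n_codons <- pmax(5L, as.integer(round(
      stats::rnorm(spec$n_genes, spec$mean_cds_length / 3,
                   spec$mean_cds_length / 12))))
    has_intron <- stats::runif(spec$n_genes) < spec$intron_probability
    intron_len <- ifelse(has_intron, sample(40:120, spec$n_genes,
                                            replace = TRUE), 0L)
    gi <- 0L
    for (ci in seq_len(spec$n_chromosomes)) {
      idx <- which(gene_chrom == ci)
      if (!length(idx)) next
      footprints <- 3L * n_codons[idx] + intron_len[idx]
      min_gap <- 30L
      slack <- spec$chrom_length - sum(footprints) -
        min_gap * (length(idx) + 1L)
      if (slack < 0) {
        stop("genes do not fit: chromosome ", chrom_names[ci], " needs ",
             sum(footprints) + min_gap * (length(idx) + 1L),
             " bp but has ", spec$chrom_length)
      }
      extra <- as.vector(stats::rmultinom(1, slack,
                                          rep(1, length(idx) + 1L)))
      pos <- 1L
      for (k in seq_along(idx)) {
        g <- idx[k]
        pos <- pos + min_gap + extra[k]
        gi <- gi + 1L
        gene_id <- sprintf("gene%03d", gi)
        strand <- sample(c("+", "-"), 1)
        coding <- paste(c("ATG", random_sense_codons(n_codons[g] - 2L),
                          sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
        clen <- nchar(coding)
        if (intron_len[g] > 0) {
          # split CDS into two exons at a codon-internal point
          cut <- 3L * sample(seq_len(n_codons[g] - 1L), 1)
          ex1 <- c(pos, pos + cut - 1L)
          ex2 <- c(pos + cut + intron_len[g],
                   pos + clen + intron_len[g] - 1L)
          ivs <- rbind(ex1, ex2)
        } else {
          ivs <- rbind(c(pos, pos + clen - 1L))
        }
        # genomic-forward sequence of the CDS intervals
        genomic <- if (strand == "+") coding else revcomp(coding)
        off <- 0L
        for (r in seq_len(nrow(ivs))) {
          w <- ivs[r, 2] - ivs[r, 1] + 1L
          substr(seqs[ci], ivs[r, 1], ivs[r, 2]) <-
            substr(genomic, off + 1L, off + w)
          off <- off + w
          cds[[length(cds) + 1L]] <- data.frame(
            gene_id = gene_id, chromosome = chrom_names[ci],
            strand = strand, start = ivs[r, 1], end = ivs[r, 2],
            exon_rank = r, stringsAsFactors = FALSE)
        }
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gene_id, chromosome = chrom_names[ci], strand = strand,
          start = ivs[1, 1], end = ivs[nrow(ivs), 2],
          cds_length = clen, stringsAsFactors = FALSE)
        pos <- ivs[nrow(ivs), 2] + 1L
      }
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), chromosome = character(),
               strand = character(), start = integer(), end = integer(),
               cds_length = integer(), stringsAsFactors = FALSE)
  cds <- if (length(cds)) do.call(rbind, cds) else
    data.frame(gene_id = character(), chromosome = character(),
               strand = character(), start = integer(), end = integer(),
               exon_rank = integer(), stringsAsFactors = FALSE)
  rownames(genes) <- NULL; rownames(cds) <- NULL

  # plant SSR tracts in intergenic space, never overlapping genes or each
  # other
  tracts <- list()
  n_tracts <- as.integer(round(spec$ssr_density * spec$chrom_length / 1e4))
  if (n_tracts > 0) {
    for (ci in seq_len(spec$n_chromosomes)) {
      occupied <- genes[genes$chromosome == chrom_names[ci], c("start", "end")]
      placed <- 0L; tries <- 0L
      while (placed < n_tracts && tries < 200L * n_tracts) {
        tries <- tries + 1L
        mlen <- sample(1:3, 1)
        ncop <- switch(mlen, sample(6:12, 1), sample(4:8, 1), sample(3:6, 1))
        motif <- paste(sample(BASES, mlen, replace = TRUE), collapse = "")
        # primitive motif only (e.g. "AA" is really a mononucleotide run)
        if (mlen > 1 && min_period(motif) < mlen) next
        tlen <- mlen * ncop
        start <- sample.int(spec$chrom_length - tlen - 2L, 1) + 1L
        end <- start + tlen - 1L
        hit <- any(occupied$start <= end + 1L & occupied$end >= start - 1L)
        if (hit) next
        # avoid accidental extension by matching flanks
        tract_seq <- strrep(motif, ncop)
        substr(seqs[ci], start, end) <- tract_seq
        occupied <- rbind(occupied, data.frame(start = start - 1L,
                                               end = end + 1L))
        tracts[[length(tracts) + 1L]] <- data.frame(
          chromosome = chrom_names[ci], start = start, end = end,
          motif = motif, n_copies = ncop, stringsAsFactors = FALSE)
        placed <- placed + 1L
      }
    }
  }
  tracts <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(chromosome = character(), start = integer(), end = integer(),
               motif = character(), n_copies = integer(),
               stringsAsFactors = FALSE)
  rownames(tracts) <- NULL

  structure(list(sequences = seqs, genes = genes, cds = cds,
                 ssr_tracts = tracts, spec = spec),
            class = "reference_bundle")
}

# minimal period of a string (primitivity check for SSR motifs)
min_period <- function(s) {
  n <- nchar(s)
  for (k in seq_len(n - 1)) {
    if (n %% k == 0 && s == strrep(substr(s, 1, k), n / k)) return(k)
  }
  n
}

group_truth <- function(truth, group) {
  if (inherits(truth, "truth_rates")) return(truth)
  stopifnot(is.list(truth), all(c("control", "treatment") %in% names(truth)))
  truth[[group]]
}

#' Simulate mutation accumulation across MA lines
#'
#' Each line accumulates `Poisson(sites x rate x divisions)` base
#' substitutions and indels. Substitution positions are sampled with
#' probability proportional to the trinucleotide-context multiplier of the
#' site; the alternate allele is drawn from the six-class spectrum weights
#' restricted to the classes compatible with the reference base. Indels are
#' placed inside planted SSR tracts with probability `ssr_bias`, have
#' lengths uniform on 1-3 bp, and are emitted VCF-style with a left anchor
#' base. Per-line random streams are derived from the master seed by stable
#' indexing.
#'
#' @param ref A [generate_genome()] reference bundle.
#' @param truth A [truth_rates()] object, or `list(control =, treatment =)`
#'   for arm-specific truth.
#' @param design An [experiment_design()].
#' @param seed Master integer seed.
#' @return An object of class `ma_experiment` with elements `mutations`
#'   (line_id, chromosome, position, ref, alt, kind), `metadata` (one row
#'   per line), and `truth` (planted-mutation table plus the inputs).
#' @export
simulate_ma_lines <- function(ref, truth, design, seed = 1L) {
  stopifnot(inherits(ref, "reference_bundle"),
            inherits(design, "experiment_design"))
  n_sites <- sum(nchar(ref$sequences))
  if (n_sites == 0) stop("zero analyzable sites in reference")

  chroms <- names(ref$sequences)
  lens <- nchar(ref$sequences)
  # flat position index over the genome and per-position context weights
  chars <- lapply(ref$sequences, function(s) strsplit(s, "")[[1]])
  keys <- context_keys()

  site_weight <- function(mult) {
    unlist(lapply(chars, function(v) {
      L <- length(v)
      w <- rep(1, L)
      if (L >= 3) {
        ctx <- paste0(v[1:(L - 2)], v[2:(L - 1)], v[3:L])
        w[2:(L - 1)] <- mult[ctx]
      }
      w
    }), use.names = FALSE)
  }
  chrom_of <- rep.int(seq_along(chroms), lens)
  pos_of <- unlist(lapply(lens, seq_len), use.names = FALSE)

  in_tract <- function(ci, pos) {
    tr <- ref$ssr_tracts
    any(tr$chromosome == chroms[ci] & tr$start <= pos & tr$end >= pos)
  }

  groups <- c(rep("control", design$n_lines_control),
              rep("treatment", design$n_lines_treatment))
  prefix <- c(control = "C", treatment = "T")
  idx_in_group <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  line_ids <- sprintf("%s%03d", prefix[groups], idx_in_group)
  dish_ids <- sprintf("%sD%03d", prefix[groups],
                      ceiling(idx_in_group / design$lines_per_dish))
  totals <- c(control = design$total_divisions_control,
              treatment = design$total_divisions_treatment)
  dpt <- c(control = design$divisions_per_transfer_control,
           treatment = design$divisions_per_transfer_treatment)

  weights <- list()
  muts <- vector("list", length(line_ids))
  depth <- numeric(length(line_ids))
  for (i in seq_along(line_ids)) {
    g <- groups[i]
    tr <- group_truth(truth, g)
    if (is.null(weights[[g]])) {
      weights[[g]] <- site_weight(tr$context_multipliers)
    }
    set.seed(derive_seed(seed, i))
    T_i <- totals[[g]]
    n_bps <- stats::rpois(1, n_sites * tr$bps_rate * T_i)
    n_ind <- stats::rpois(1, n_sites * tr$indel_rate * T_i)
    depth[i] <- max(30.1, stats::rnorm(1, 49.44, 13.44))

    used <- integer(0)
    rows <- list()
    if (n_bps > 0) {
      sel <- sample.int(n_sites, n_bps, prob = weights[[g]])
      used <- sel
      for (s in sel) {
        ci <- chrom_of[s]; pos <- pos_of[s]
        rb <- chars[[ci]][pos]
        cls_opts <- if (rb %in% c("A", "T")) {
          SPECTRUM_CLASSES[c(1, 3, 4)]
        } else SPECTRUM_CLASSES[c(2, 5, 6)]
        w <- tr$spectrum_weights[cls_opts]
        if (sum(w) == 0) w <- rep(1, 3)
        cls <- sample(cls_opts, 1, prob = w)
        alt <- alt_for_class(rb, cls)
        rows[[length(rows) + 1L]] <- data.frame(
          line_id = line_ids[i], chromosome = chroms[ci], position = pos,
          ref = rb, alt = alt, kind = "BPS", in_ssr_truth = NA,
          stringsAsFactors = FALSE)
      }
    }
    if (n_ind > 0) {
      n_tr <- nrow(ref$ssr_tracts)
      if (tr$ssr_bias > 0 && n_tr == 0) {
        stop("ssr_bias > 0 but the reference has no planted SSR tracts")
      }
      for (k in seq_len(n_ind)) {
        in_ssr <- stats::runif(1) < tr$ssr_bias
        repeat {
          if (in_ssr) {
            t_row <- ref$ssr_tracts[sample.int(n_tr, 1), ]
            ci <- match(t_row$chromosome, chroms)
            pos <- sample(t_row$start:t_row$end, 1)
          } else {
            s <- sample.int(n_sites, 1)
            ci <- chrom_of[s]; pos <- pos_of[s]
            if (in_tract(ci, pos)) next
          }
          if (pos >= 2 && pos <= lens[ci] - 4L &&
              !((flat <- cumsum(c(0, lens))[ci] + pos) %in% used)) break
        }
        used <- c(used, flat)
        ilen <- sample(1:3, 1)
        anchor <- chars[[ci]][pos]
        if (stats::runif(1) < tr$insertion_fraction) {
          ins <- paste(sample(BASES, ilen, replace = TRUE), collapse = "")
          refa <- anchor; alta <- paste0(anchor, ins); kind <- "insertion"
        } else {
          refa <- paste(chars[[ci]][pos:(pos + ilen)], collapse = "")
          alta <- anchor; kind <- "deletion"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          line_id = line_ids[i], chromosome = chroms[ci], position = pos,
          ref = refa, alt = alta, kind = kind, in_ssr_truth = in_ssr,
          stringsAsFactors = FALSE)
      }
    }
    muts[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  mutations <- do.call(rbind, c(muts, list(empty_mutations(TRUE))))
  rownames(mutations) <- NULL

  metadata <- data.frame(
    line_id = line_ids, group = groups, dish_id = dish_ids,
    transfers = design$transfers,
    divisions_per_transfer = unname(dpt[groups]),
    total_divisions = unname(totals[groups]),
    mean_depth = round(depth, 2),
    analyzable_sites = n_sites, stringsAsFactors = FALSE)

  structure(list(mutations = mutations[, names(empty_mutations())],
                 metadata = metadata,
                 truth = list(planted = mutations, rates = truth,
                              design = design)),
            class = "ma_experiment")
}

empty_mutations <- function(with_truth = FALSE) {
  d <- data.frame(line_id = character(), chromosome = character(),
                  position = integer(), ref = character(), alt = character(),
                  kind = character(), stringsAsFactors = FALSE)
  if (with_truth) d$in_ssr_truth <- logical()
  d
}

# alternate base realizing a strand-collapsed class at a given reference base
alt_for_class <- function(ref, cls) {
  hits <- names(.SPECTRUM_MAP)[.SPECTRUM_MAP == cls]
  hit <- hits[startsWith(hits, ref)]
  if (!length(hit)) stop("class ", cls, " impossible at reference ", ref)
  sub(".*>", "", hit)
}

#' Inject QC-triggering artifacts into a simulated experiment
#'
#' Plants one identical mutation into both lines of `n_shared_pairs`
#' dish-mate pairs (mimicking cross-contamination) and forces
#' `n_low_depth` lines below the 30x depth floor. Low-depth lines are drawn
#' from lines outside the contaminated dishes so the two filters remove
#' disjoint sets. All modifications are recorded in the truth table.
#'
#' @param sim An [simulate_ma_lines()] result.
#' @param ref The [generate_genome()] bundle the experiment was simulated
#'   from (needed to plant shared mutations with the true reference base).
#' @param n_shared_pairs Number of dish pairs to contaminate.
#' @param n_low_depth Number of lines to push below 30x.
#' @param seed Integer seed.
#' @param group Optional arm (`"control"` or `"treatment"`) to restrict the
#'   injection to; default both.
#' @return The modified `ma_experiment`.
#' @export
inject_artifacts <- function(sim, ref, n_shared_pairs, n_low_depth,
                             seed = 1L, group = NULL) {
  stopifnot(inherits(sim, "ma_experiment"),
            inherits(ref, "reference_bundle"))
  md <- sim$metadata
  sel <- if (is.null(group)) rep(TRUE, nrow(md)) else md$group == group
  set.seed(derive_seed(seed, 999983L))

  dishes <- split(md$line_id[sel], md$dish_id[sel])
  pairs <- dishes[vapply(dishes, length, integer(1)) == 2L]
  if (n_shared_pairs > length(pairs)) {
    stop("n_shared_pairs (", n_shared_pairs, ") exceeds available dish pairs (",
         length(pairs), ")")
  }
  chosen <- if (n_shared_pairs > 0) {
    sample(names(pairs), n_shared_pairs)
  } else character(0)

  chrom1 <- names(ref$sequences)[1]
  len1 <- nchar(ref$sequences[[1]])
  for (d in chosen) {
    ln <- pairs[[d]]
    # one identical planted substitution in both dish mates
    key <- paste(sim$mutations$chromosome, sim$mutations$position)
    repeat {
      pos <- sample.int(len1 - 2L, 1) + 1L
      if (!(paste(chrom1, pos) %in% key)) break
    }
    rb <- substr(ref$sequences[[1]], pos, pos)
    alt <- sample(setdiff(BASES, rb), 1)
    add <- data.frame(line_id = ln, chromosome = chrom1, position = pos,
                      ref = rb, alt = alt, kind = "BPS",
                      stringsAsFactors = FALSE)
    sim$mutations <- rbind(sim$mutations, add)
    addt <- add; addt$in_ssr_truth <- NA
    sim$truth$planted <- rbind(sim$truth$planted, addt)
  }
  sim$truth$shared_pairs <- c(sim$truth$shared_pairs, chosen)

  pool <- md$line_id[sel & !(md$dish_id %in% chosen)]
  if (n_low_depth > length(pool)) {
    stop("n_low_depth exceeds lines available outside contaminated dishes")
  }
  low <- if (n_low_depth > 0) sample(pool, n_low_depth) else character(0)
  sim$metadata$mean_depth[md$line_id %in% low] <-
    round(stats::runif(length(low), 15, 29), 2)
  sim$truth$low_depth_lines <- c(sim$truth$low_depth_lines, low)
  sim
}
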