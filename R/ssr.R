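# Simple-sequence-repeat (microsatellite) detection and indel overlap.
#
# Convention (MISA-like, scaled for toy genomes): motifs of 1-6 bp,
# tracts of >= 3 copies and >= 5 bp by default, maximal and
# non-extendable; overlapping calls with different motifs are resolved to
# the longest tract, ties to the shortest motif.

#' Detect simple-sequence-repeat tracts in a nucleotide sequence
#'
#' Scans for maximal tandem repetitions of primitive motifs of length 1 to
#' `max_motif`. A tract may carry a partial trailing copy; `n_copies` is
#' the number of complete copies. Overlapping candidates are resolved
#' greedily: longest tract first, ties broken by shorter motif, then by
#' position.
#'
#' @param seq Uppercase nucleotide string.
#' @param min_copies Minimum complete motif copies per tract.
#' @param min_tract_bp Minimum tract length in bp.
#' @param max_motif Maximum motif length (1-6).
#' @param chromosome Optional chromosome label carried into the output.
#' @return Data.frame with chromosome, start, end (1-based inclusive),
#'   motif, n_copies.
#' @export
detect_ssrs <- function(seq, min_copies = 3L, min_tract_bp = 5L,
                        max_motif = 6L, chromosome = NA_character_) {
  stopifnot(max_motif >= 1, max_motif <= 6)
  n <- nchar(seq)
  empty <- data.frame(chromosome = character(), start = integer(),
                      end = integer(), motif = character(),
                      n_copies = integer(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  v <- strsplit(seq, "")[[1]]
  cand <- list()
  for (k in seq_len(min(max_motif, n - 1L))) {
    eq <- v[seq_len(n - k)] == v[(k + 1L):n]
    r <- rle(eq)
    ends_rel <- cumsum(r$lengths)
    starts_rel <- ends_rel - r$lengths + 1L
    hit <- which(r$values)
    for (h in hit) {
      start <- starts_rel[h]
      tract_len <- r$lengths[h] + k
      end <- start + tract_len - 1L
      copies <- tract_len %/% k
      if (copies < min_copies || tract_len < min_tract_bp) next
      motif <- substr(seq, start, start + k - 1L)
      if (grepl("N", motif)) next
      if (min_period(motif) < k) next  # non-primitive: found at shorter k
      cand[[length(cand) + 1L]] <- data.frame(
        chromosome = chromosome, start = start, end = end, motif = motif,
        n_copies = copies, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  resolve_tract_overlaps(cand)
}

# greedy overlap resolution: longest tract, then shortest motif, then start
resolve_tract_overlaps <- function(cand) {
  len <- cand$end - cand$start + 1L
  ord <- order(-len, nchar(cand$motif), cand$start)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  occ_start <- integer(0); occ_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(occ_start <= cand$end[i] & occ_end >= cand$start[i])) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, cand$start[i])
      occ_end <- c(occ_end, cand$end[i])
    }
  }
  res <- cand[keep, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect SSR tracts on every chromosome of a reference bundle
#' @inheritParams detect_ssrs
#' @param ref A `reference_bundle`.
#' @return Combined tract table across chromosomes.
#' @export
detect_ssrs_genome <- function(ref, min_copies = 3L, min_tract_bp = 5L,
                               max_motif = 6L) {
  res <- lapply(names(ref$sequences), function(cn) {
    detect_ssrs(ref$sequences[[cn]], min_copies = min_copies,
                min_tract_bp = min_tract_bp, max_motif = max_motif,
                chromosome = cn)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Does an indel fall in (or next to) an SSR tract?
#'
#' True iff the indel's anchor position, widened by `flank_bp` on each
#' side, intersects any tract on the same chromosome. The default flank of
#' 1 counts an indel immediately adjacent to a tract as repeat-associated
#' (slippage events are anchored one base left of the tract in VCF
#' left-aligned representation).
#'
#' @param rec One-row mutation data.frame of kind insertion or deletion.
#' @param tracts Tract table from [detect_ssrs()].
#' @param flank_bp Nonnegative flank in bp.
#' @return Logical flag.
#' @export
indel_in_ssr <- function(rec, tracts, flank_bp = 1L) {
  if (!is.data.frame(rec)) rec <- as.data.frame(rec, stringsAsFactors = FALSE)
  stopifnot(nrow(rec) == 1, flank_bp >= 0)
  kind <- rec$kind %||% variant_kind(rec$ref, rec$alt)
  if (kind == "BPS") stop("indel_in_ssr is defined for indels, got a BPS")
  if (is.null(tracts) || nrow(tracts) == 0) return(FALSE)
  lo <- rec$position - flank_bp
  hi <- rec$position + flank_bp
  any(tracts$chromosome == rec$chromosome &
        tracts$start <= hi & tracts$end >= lo)
}
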