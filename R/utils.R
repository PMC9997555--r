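# Shared lookup tables and small helpers.

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Six strand-collapsed base-substitution classes
#'
#' Substitutions are reported on the A:T / G:C pair so that, e.g., a
#' reference-strand C>A and a G>T both belong to G:C->T:A.
#' @keywords internal
SPECTRUM_CLASSES <- c(
  "A:T->G:C", "G:C->A:T",              # transitions
  "A:T->T:A", "A:T->C:G", "G:C->C:G", "G:C->T:A"  # transversions
)

TRANSITION_CLASSES <- SPECTRUM_CLASSES[1:2]

# (ref, alt) -> strand-collapsed class
.SPECTRUM_MAP <- c(
  "A>G" = "A:T->G:C", "T>C" = "A:T->G:C",
  "G>A" = "G:C->A:T", "C>T" = "G:C->A:T",
  "A>T" = "A:T->T:A", "T>A" = "A:T->T:A",
  "A>C" = "A:T->C:G", "T>G" = "A:T->C:G",
  "G>C" = "G:C->C:G", "C>G" = "G:C->C:G",
  "G>T" = "G:C->T:A", "C>A" = "G:C->T:A"
)

#' All 64 trinucleotide context keys (5' base, focal base, 3' base)
#' @keywords internal
context_keys <- function() {
  g <- expand.grid(p3 = BASES, focal = BASES, p5 = BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p5, g$focal, g$p3))
}

#' Strand-collapsed class of a single-base substitution
#'
#' @param ref,alt Single reference and alternate bases.
#' @return Character vector of classes from the six-class spectrum.
#' @examples
#' spectrum_class("G", "A")  # "G:C->A:T"
#' @export
spectrum_class <- function(ref, alt) {
  cls <- unname(.SPECTRUM_MAP[paste0(ref, ">", alt)])
  if (anyNA(cls)) {
    bad <- which(is.na(cls))[1]
    stop("not a base substitution: ", ref[bad], ">", alt[bad])
  }
  cls
}

is_transition <- function(cls) cls %in% TRANSITION_CLASSES

# Codon tables derived from the standard genetic code, built once per session.
.mamut_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.mamut_env$codons)) return(.mamut_env$codons)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  # syn_frac[codon, pos]: of the 3 alternative bases at pos, the fraction
  # whose codon encodes the same amino acid (Nei-Gojobori style site count).
  syn_frac <- matrix(0, nrow = length(codons), ncol = 3,
                     dimnames = list(codons, NULL))
  for (cod in codons) {
    aa <- gc[[cod]]
    for (pos in 1:3) {
      alts <- setdiff(BASES, substr(cod, pos, pos))
      mut <- vapply(alts, function(b) {
        x <- cod
        substr(x, pos, pos) <- b
        gc[[x]]
      }, character(1))
      syn_frac[cod, pos] <- sum(mut == aa) / 3
    }
  }
  fourfold <- syn_frac[, 3] == 1  # third position fully degenerate
  .mamut_env$codons <- list(code = gc, syn_frac = syn_frac,
                            fourfold = fourfold)
  .mamut_env$codons
}

translate_codon <- function(codon) {
  codon_tables()$code[[codon]]
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(unname(COMPLEMENT[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Derive a per-unit child seed from a master seed
#'
#' Stable indexing: the i-th stream does not change when more units are
#' added, so adding MA lines leaves earlier lines' draws untouched.
#' @keywords internal
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# variant kind from REF/ALT lengths
variant_kind <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  kind <- rep(NA_character_, length(ref))
  kind[nr == 1 & na == 1] <- "BPS"
  kind[na > nr] <- "insertion"
  kind[nr > na] <- "deletion"
  if (any(bad <- nr == na & nr > 1)) {
    stop("multi-nucleotide substitutions are not supported (record ",
         which(bad)[1], ": ", ref[which(bad)[1]], ">", alt[which(bad)[1]], ")")
  }
  kind
}
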