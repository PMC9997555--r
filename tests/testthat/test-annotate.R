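# Site inventory and mutation classification against hand-checked and
# brute-force oracles.

test_that("fractional synonymous sites follow codon-table enumeration", {
  # gene ATG TTT AAA GGG TAA: per-position syn fractions enumerated by
  # hand against the standard code:
  #   ATG: 0,0,0; TTT: 0,0,1/3; AAA: 0,0,1/3; GGG: 1/3,0,1 (GGA/GGC/GGT
  #   all Gly; GGG pos1: AGG Arg, CGG Arg, TGG Trp -> wait, enumerate:
  #   pos1 alternatives AGG/CGG/TGG -> Arg,Arg,Trp -> 0/3? no: Gly vs
  #   Arg/Arg/Trp, none synonymous -> 0); stop TAA excluded? no: TAA is
  #   part of the CDS and counted (TGA/TAG stops are synonymous to it).
  inv <- build_site_inventory(tiny_plus_ref())
  # recompute expected by direct enumeration
  code <- Biostrings::GENETIC_CODE
  expected_syn <- 0
  coding <- "ATGTTTAAAGGGTAA"
  for (ci in seq_len(nchar(coding) / 3)) {
    cod <- substr(coding, 3 * ci - 2, 3 * ci)
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- b
        if (code[[alt]] == code[[cod]]) expected_syn <- expected_syn + 1 / 3
      }
    }
  }
  expect_equal(inv$syn_sites, expected_syn, tolerance = 1e-12)
  expect_equal(inv$syn_sites + inv$nonsyn_sites, 15, tolerance = 1e-9)
  # GGG third position is four-fold degenerate; it is the only one here
  # (TTT, AAA third positions are two-fold; TAA's is not four-fold)
  expect_identical(inv$fourfold_sites, 1L)
})

test_that("minus-strand genes give the same site counts as plus-strand", {
  inv_p <- build_site_inventory(tiny_plus_ref())
  inv_m <- build_site_inventory(tiny_minus_ref())
  expect_equal(inv_p$syn_sites, inv_m$syn_sites, tolerance = 1e-12)
  expect_identical(inv_p$fourfold_sites, inv_m$fourfold_sites)
})

test_that("context counts cover exactly the interior positions", {
  set.seed(21)
  ref <- make_ref(c(chr1 = random_seq(500), chr2 = random_seq(300)))
  inv <- build_site_inventory(ref)
  expect_equal(sum(inv$context_counts),
               inv$analyzable_sites_total - 2 * 2)
})

test_that("fractional site conservation holds on a generated genome", {
  inv <- toy_inventory()
  expect_equal(inv$syn_sites + inv$nonsyn_sites,
               unname(inv$sites_by_region[["CDS"]]),
               tolerance = 1e-9 * inv$sites_by_region[["CDS"]] / 1e6 + 1e-9)
  expect_identical(sum(unname(inv$sites_by_region)),
                   inv$analyzable_sites_total)
  expect_lte(inv$fourfold_sites, inv$sites_by_region[["CDS"]] / 3)
})

test_that("classification matches hand-derived cases", {
  ref <- tiny_plus_ref()
  inv <- build_site_inventory(ref)
  # G>A anywhere: G:C->A:T transition (position 17 = GGG codon pos 3)
  a <- classify_mutation(list(line_id = "L1", chromosome = "chr1",
                              position = 17L, ref = "G", alt = "A"),
                         ref, inv)
  expect_identical(a$spectrum_class, "G:C->A:T")
  expect_identical(a$ts_tv, "transition")
  expect_identical(a$region, "CDS")
  expect_identical(a$coding_effect, "synonymous")  # GGG -> GGA, still Gly
  expect_true(a$at_fourfold_site)
  # A>C: A:T->C:G transversion; AAA -> ACA is non-synonymous
  b <- classify_mutation(list(line_id = "L1", chromosome = "chr1",
                              position = 13L, ref = "A", alt = "C"),
                         ref, inv)
  expect_identical(b$spectrum_class, "A:T->C:G")
  expect_identical(b$ts_tv, "transversion")
  expect_identical(b$coding_effect, "non-synonymous")
  expect_false(b$at_fourfold_site)
  # intergenic position: no coding effect, context read off the genome
  d <- classify_mutation(list(line_id = "L1", chromosome = "chr1",
                              position = 2L, ref = "C", alt = "T"),
                         ref, inv)
  expect_identical(d$region, "intergenic")
  expect_identical(d$coding_effect, NA_character_)
  expect_identical(d$context, "ACG")
  # ref mismatch signals a wrong reference build
  expect_error(classify_mutation(list(line_id = "L1", chromosome = "chr1",
                                      position = 2L, ref = "G", alt = "T"),
                                 ref, inv),
               "mismatch")
})

test_that("multi-nucleotide substitutions are rejected", {
  ref <- tiny_plus_ref()
  inv <- build_site_inventory(ref)
  expect_error(classify_mutation(list(line_id = "L1", chromosome = "chr1",
                                      position = 2L, ref = "CG",
                                      alt = "TA"),
                                 ref, inv),
               "multi-nucleotide")
})

test_that("CDS substitutions agree with the whole-gene translation oracle", {
  ref <- toy_genome()
  inv <- toy_inventory()
  set.seed(31)
  cds <- ref$cds
  checked <- 0
  for (rep in 1:120) {
    r <- cds[sample.int(nrow(cds), 1), ]
    pos <- sample(r$start:r$end, 1)
    base <- substr(ref$sequences[[r$chromosome]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    a <- classify_mutation(list(line_id = "L", chromosome = r$chromosome,
                                position = pos, ref = base, alt = alt),
                           ref, inv)
    expect_identical(a$coding_effect,
                     oracle_coding_effect(ref, r$gene_id, r$chromosome,
                                          pos, alt))
    checked <- checked + 1
  }
  expect_identical(checked, 120)
})

test_that("spectrum class is invariant under strand flip of the genome", {
  ref <- toy_genome()
  inv <- toy_inventory()
  flipped_seqs <- vapply(ref$sequences, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  flipped <- make_ref(flipped_seqs)
  inv_f <- build_site_inventory(flipped)
  L <- nchar(ref$sequences[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(41)
  for (rep in 1:40) {
    pos <- sample.int(L, 1)
    base <- substr(ref$sequences[[1]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    a <- classify_mutation(list(line_id = "L", chromosome = "chr1",
                                position = pos, ref = base, alt = alt),
                           ref, inv)
    b <- classify_mutation(list(line_id = "L", chromosome = "chr1",
                                position = L - pos + 1L,
                                ref = unname(comp[base]),
                                alt = unname(comp[alt])),
                           flipped, inv_f)
    expect_identical(a$spectrum_class, b$spectrum_class)
    expect_identical(a$ts_tv, b$ts_tv)
  }
})

test_that("four-fold sites all have synonymous fraction 1 at codon pos 3", {
  ref <- toy_genome()
  inv <- toy_inventory()
  # every recorded four-fold position, when mutated to any base, must be
  # synonymous by the translation oracle
  set.seed(51)
  positions <- inv$fourfold_pos[["chr1"]]
  take <- sample(positions, min(15, length(positions)))
  for (pos in take) {
    g <- inv$gene_at[["chr1"]][pos]
    gid <- inv$genes$gene_id[g]
    base <- substr(ref$sequences[["chr1"]], pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), base)) {
      expect_identical(oracle_coding_effect(ref, gid, "chr1", pos, alt),
                       "synonymous")
    }
  }
})
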