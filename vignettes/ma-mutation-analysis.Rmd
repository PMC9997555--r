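---
title: "Estimating mutation rates and spectra from mutation-accumulation lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutation rates and spectra from mutation-accumulation lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment this package analyzes

In a mutation-accumulation (MA) experiment, many replicate lines are founded
from a single ancestral colony and repeatedly passed through single-colony
(effectively single-cell) bottlenecks. The bottlenecking makes genetic drift
overwhelm selection, so even deleterious mutations fix within a line at
nearly the rate at which they arise. After dozens of transfers each line is
whole-genome sequenced, variants are called against the ancestor's
reference, and the per-site mutation rate is estimated as

$$\mu = \frac{m}{\sum_{i=1}^{n} N_i \, T_i},$$

where $m$ is the total number of mutations over the $n$ lines that pass
quality control, $N_i$ is the number of analyzable sites in line $i$, and
$T_i$ its total number of cell divisions. `mamut` implements everything
downstream of variant calling for a two-arm (control vs treatment) MA
design: line QC, classification of each variant, rate estimation with exact
Poisson confidence intervals, spectrum and context tables, and the
comparisons between arms. A synthetic-data module simulates the entire
experiment with known truth so that every stage can be tested for parameter
recovery.

## Line quality control

Two filters are applied, in this order:

1. **Cross-contamination.** When two MA lines grow on the same Petri dish,
   a mutation shared by both dish mates (identical chromosome, position,
   REF and ALT) is taken as evidence of cross-contamination, and the line
   whose identifier carries an even trailing number is removed. We parse
   "even-numbered" as the trailing integer of the line id; the rule is
   deterministic and a dish pair sharing several mutations still loses only
   that one line. More than two lines per dish is a configuration error
   because the rule is defined for pairs. Requiring identical alleles (not
   just identical positions) is deliberate: two lines hitting the same site
   with different alternate bases is parallel mutation, not contamination.
2. **Depth floor.** Lines with mean coverage below 30x are removed; below
   that depth, heterozygous-looking artifacts and missed calls distort $m$.

Both filters partition their input (kept plus removed equals input) and are
idempotent. Mutations of removed lines are excluded from all downstream
counts *and* exposures, so a removed line contributes neither numerator nor
denominator.

## Classification against the reference

`build_site_inventory()` computes every denominator once per reference:

* **Regions.** Each position is CDS, intron, or intergenic, with priority
  CDS > intron > intergenic. When gene models overlap, the gene with the
  longest total CDS claims the position ("longest transcript wins") — a
  deterministic rule chosen because no convention is universal.
* **Synonymous/non-synonymous site fractions.** Per coding position, the
  synonymous fraction is the number of the three alternative bases that
  preserve the amino acid, divided by 3 (the Nei–Gojobori counting style).
  These fractional sites sum exactly to the CDS site total, which the
  inventory asserts.
* **Four-fold degenerate sites** are third-codon positions at which all
  four bases encode the same amino acid; substitutions there are
  synonymous by construction, making them the cleanest read-out of the
  underlying rate.
* **Trinucleotide contexts.** The 64 contexts (5' base, focal base, 3'
  base) are counted on the reference strand over interior positions;
  chromosome-terminal bases have no context and are excluded, so the
  context counts sum to $N - 2 \times$ (number of chromosomes) on an
  N-free genome.

`classify_mutations()` then assigns each variant its region, coding effect
(by translating the mutated versus original codon in the owning gene's
frame, complementing the alternate base for minus-strand genes), four-fold
flag, strand-collapsed substitution class, transition/transversion status,
and reference-strand context. The six substitution classes collapse
strands (a reference C>A and a G>T are both G:C→T:A) because mutation
mechanisms act on base pairs; contexts are *not* collapsed, matching the
4×16 heat-map layout the field uses. Substitutions creating a stop codon
count as non-synonymous (the standard convention). Records with equal
REF/ALT lengths above 1 are rejected: multi-nucleotide substitutions need
haplotype-aware handling that a per-site pipeline should refuse rather than
approximate.

## Simple-sequence repeats

Slippage makes microsatellites indel hotspots, so each indel is flagged by
SSR overlap. No universal SSR definition exists; we adopt a MISA-like
convention scaled to small genomes: primitive motifs of 1–6 bp, tracts of
at least 3 complete copies and 5 bp, maximal and non-extendable, with
overlapping calls resolved to the longest tract (ties to the shortest
motif). All thresholds are arguments. An indel counts as repeat-associated
when its anchor position, widened by a 1 bp flank, touches a tract — the
flank is needed because VCF left-alignment anchors a slippage indel one
base to the left of the tract it modifies. The detector is tested against
an exhaustive enumerator that tries every (start, motif-length) pair.

## Rates, intervals, and tests

* **Exact Poisson (Garwood) intervals.** Counts are small (tens), so
  normal approximations are poor. The CI on a count $m$ is
  $[\tfrac{1}{2}\chi^2_{\alpha/2}(2m),\ \tfrac{1}{2}\chi^2_{1-\alpha/2}(2m+2)]$,
  with a lower bound of 0 at $m = 0$; dividing by the exposure gives the
  CI on the rate. This choice reproduces the published genome-rate
  interval from its count, which is how we anchored it.
* **Chi-square flavor.** All 1-df comparisons use the Yates continuity
  correction, clamped to zero when $|O - E| < 0.5$: the NS/S goodness of
  fit against site availability, the 2×2 heterogeneity tests, and the
  conditional rate-ratio test (given $m_1 + m_2$, the split is binomial
  with probability proportional to exposures). The corrected statistics
  reproduce the published values from their printed counts where
  uncorrected Pearson does not, which fixed the convention.
* **Enrichment scan.** Under neutrality a gene's substitution count is
  Poisson with mean CDS length × rate × divisions; the upper-tail
  probability is Benjamini–Hochberg adjusted and genes with $q < 0.05$
  are flagged. This is a selection *screen*, not an estimator; the null
  calibration test checks that the flag rate stays within the BH level on
  neutral simulations.
* **Auxiliary statistics.** Divisions per transfer from colony CFU counts
  ($T = \log_2 N$); harmonic-mean effective population size
  $N_e = (T+1)/\sum_{i=0}^{T} 2^{-i}$ of one bottleneck-expansion cycle;
  the moment dispersion $\alpha = (V - \mu)/\mu^2$ of per-gene read
  counts (0 under Poisson noise; note the moment estimator carries a
  small negative finite-replicate skew of order $1/(\text{replicates}
  \times \mu)$, far below biologically meaningful overdispersion); and
  efficiency of plating (treated CFU / control CFU) for survival curves.

## What the simulator emulates — and what it does not

`generate_genome()` builds a small multi-chromosome genome at a target GC
content with non-overlapping genes (ATG start, stop end, no internal stop,
optional single intron) and planted SSR tracts in intergenic space.
`simulate_ma_lines()` draws each line's mutation count as Poisson(sites ×
rate × divisions), samples substitution positions with probability
proportional to per-context multipliers, draws alternate alleles from the
six-class spectrum weights compatible with the reference base, and places
indels (1–3 bp, uniform — the length distribution is otherwise
unconstrained by published MA data) into SSR tracts with a configurable
bias. `inject_artifacts()` plants the two QC triggers: identical shared
mutations in dish-mate pairs and sub-30x depth assignments.

Deliberate simplifications: each line is a single sampled genotype
(bottlenecking justifies ignoring within-line ancestry); positions mutate
at most once per line (rates are far below one per site); there is no
read-level error model because the pipeline starts at called variants; and
simulated depths are draws from a normal shaped like typical MA coverage
(mean ≈ 49, SD ≈ 13), truncated at the QC floor so that only injected
lines fail it. Consequently, passing tests demonstrate correct arithmetic
and calibrated inference given correct variant calls — they say nothing
about alignment or calling artifacts in real data.

Seeding: one master seed; each line's stream is derived by stable
indexing, so enlarging an experiment leaves earlier lines' draws
untouched, and identical inputs give byte-identical outputs.

## Study-shaped defaults and problem sizes

The default `experiment_design()` mirrors a fission-yeast MA study: 80
control and 90 treated sequenced lines, two lines per dish, 50 transfers,
~20 and 17 divisions per transfer with measured totals of 1,009 and 865.
The `analysis/` scripts simulate that design on a 3-chromosome, 90 kb toy
genome, with truth rates scaled so expected mutation counts match the real
experiment's totals (62/114 substitutions, 34/23 indels over kept lines)
and spectrum weights, insertion fractions, and SSR biases taken from the
observed mutation tables. The artifact injection (3 + 1 contaminated
dishes, 4 + 3 low-depth lines) reproduces the study's QC accounting
(80−3−4 = 73 and 90−1−3 = 86 kept). Low-depth lines are drawn outside the
contaminated dishes so the two filters remove disjoint sets, matching that
arithmetic.

Test problem sizes are chosen so the full suite runs in well under a
minute: 9–90 kb genomes, 10–20 lines and 50 replicate experiments for the
coverage, recovery, and null-calibration properties. These sizes keep
Monte-Carlo noise within the stated tolerances (e.g. binomial noise on 50
trials is why 95% CI coverage is asserted at ≥ 90%).

## Known limitations

* Gene models are single-transcript; alternative splicing is out of scope.
* Multi-allelic VCF records and multi-nucleotide substitutions are
  rejected, not decomposed.
* The SSR definition is a convention; tract calls (and hence the
  repeat-associated indel fraction) depend on its thresholds, which is why
  they are exposed as arguments and reported alongside results.
* The enrichment scan assumes a uniform rate across genes; regional rate
  variation would inflate it, so flagged genes are candidates, not calls.
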