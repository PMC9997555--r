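# Estimators and statistics: division and effective-population-size
# calculators, mutation rates with exact Poisson (Garwood) confidence
# intervals, spectrum and context-rate tables, Yates-corrected chi-square
# comparisons, the per-gene enrichment scan, the moment dispersion
# statistic, and efficiency of plating.

#' Cell divisions per transfer from a colony's cell count
#'
#' Assuming exponential growth within a colony founded by a single cell,
#' the number of divisions between transfers is `log2(N)`.
#'
#' @param cells Cell count at transfer (>= 1).
#' @return Divisions (possibly fractional).
#' @export
divisions_from_cfu <- function(cells) {
  if (any(cells < 1)) stop("cell count must be >= 1")
  log2(cells)
}

#' Effective population size of a single-cell-bottlenecked expansion
#'
#' Harmonic-mean Ne over one growth cycle of T doublings:
#' `Ne = (T + 1) / sum_{i=0..T} 2^(-i)`.
#'
#' @param T Integer divisions per transfer (>= 0).
#' @return Ne in cells.
#' @examples
#' effective_population_size(20)  # ~10.5
#' @export
effective_population_size <- function(T) {
  if (any(T < 0)) stop("divisions per transfer must be >= 0")
  vapply(T, function(t) (t + 1) / sum(2^(-(0:t))), numeric(1))
}

#' Exact (Garwood) Poisson confidence interval on a count
#'
#' `low = qchisq(alpha/2, 2m)/2` (0 when `m = 0`) and
#' `high = qchisq(1 - alpha/2, 2m + 2)/2`.
#'
#' @param m Observed count (nonnegative integer).
#' @param level Confidence level in (0, 1).
#' @return Numeric vector `c(low, high)` in count units.
#' @export
poisson_ci <- function(m, level = 0.95) {
  stopifnot(m >= 0)
  if (level <= 0 || level >= 1) stop("confidence level must be in (0, 1)")
  alpha <- 1 - level
  low <- if (m == 0) 0 else stats::qchisq(alpha / 2, 2 * m) / 2
  high <- stats::qchisq(1 - alpha / 2, 2 * m + 2) / 2
  c(low = low, high = high)
}

#' Mutation-rate estimate with exact Poisson CI
#'
#' The point estimate is `m / exposure` where the exposure is summed over
#' QC-passing lines: `sum(sites x total_divisions)` for a per-site rate or
#' `sum(total_divisions)` for a per-genome rate. The CI is the Garwood
#' interval on `m` scaled by the same exposure.
#'
#' @param m Total mutation count across lines.
#' @param lines QC-filtered line metadata (total_divisions, and
#'   analyzable_sites for per-site rates).
#' @param per `"site"` or `"genome"`.
#' @param category_sites Optional per-line (or scalar) analyzable-site
#'   count for the category (e.g. four-fold sites); defaults to
#'   `lines$analyzable_sites`.
#' @param level Confidence level.
#' @return An object of class `rate_estimate`.
#' @export
mutation_rate <- function(m, lines, per = c("site", "genome"),
                          category_sites = NULL, level = 0.95) {
  per <- match.arg(per)
  stopifnot(m >= 0, "total_divisions" %in% names(lines))
  exposure <- if (per == "genome") {
    sum(lines$total_divisions)
  } else {
    sites <- category_sites %||% lines$analyzable_sites
    if (length(sites) == 1L) sites <- rep(sites, nrow(lines))
    sum(sites * lines$total_divisions)
  }
  if (!isTRUE(exposure > 0)) stop("zero exposure: no lines or no sites")
  ci <- poisson_ci(m, level)
  structure(list(m = m, exposure = exposure, per = per,
                 rate = m / exposure, ci_low = ci[["low"]] / exposure,
                 ci_high = ci[["high"]] / exposure, level = level),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%d mutations / %.4g %s-divisions: rate %.3g (%d%% CI %.3g-%.3g)\n",
              x$m, x$exposure, x$per, x$rate, round(100 * x$level),
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Mutation spectrum table
#'
#' Tabulates base substitutions into the six strand-collapsed classes,
#' transitions vs transversions with their ratio, insertion and deletion
#' counts with their ratio, and within-block proportions.
#'
#' @param annotations A `mutation_annotations` table.
#' @return An object of class `spectrum_table`.
#' @export
spectrum_table <- function(annotations) {
  bps <- annotations[annotations$kind == "BPS", , drop = FALSE]
  counts <- table(factor(bps$spectrum_class, levels = SPECTRUM_CLASSES))
  counts <- stats::setNames(as.integer(counts), SPECTRUM_CLASSES)
  ts <- sum(counts[TRANSITION_CLASSES])
  tv <- sum(counts[setdiff(SPECTRUM_CLASSES, TRANSITION_CLASSES)])
  ins <- sum(annotations$kind == "insertion")
  del <- sum(annotations$kind == "deletion")
  prop <- rep(NA_real_, 6); names(prop) <- SPECTRUM_CLASSES
  if (ts > 0) prop[TRANSITION_CLASSES] <- counts[TRANSITION_CLASSES] / ts
  tv_cl <- setdiff(SPECTRUM_CLASSES, TRANSITION_CLASSES)
  if (tv > 0) prop[tv_cl] <- counts[tv_cl] / tv
  structure(list(counts = counts, proportions = prop,
                 ts_count = ts, tv_count = tv,
                 ts_tv_ratio = if (tv > 0) ts / tv else NA_real_,
                 insertions = ins, deletions = del,
                 ins_del_ratio = if (del > 0) ins / del else NA_real_),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("Base substitutions:", x$ts_count + x$tv_count,
      sprintf("(Ts/Tv %.2f)\n", x$ts_tv_ratio))
  for (cl in SPECTRUM_CLASSES) {
    cat(sprintf("  %-9s %3d  (%.2f of %s)\n", cl, x$counts[[cl]],
                x$proportions[[cl]],
                if (is_transition(cl)) "Ts" else "Tv"))
  }
  cat(sprintf("Indels: %d insertions, %d deletions (ins/del %.2f)\n",
              x$insertions, x$deletions, x$ins_del_ratio))
  invisible(x)
}

#' As a Table-1-style data.frame (Count / Proportion per category)
#' @param x A `spectrum_table`.
#' @param ... Unused.
#' @return A data.frame.
#' @export
as.data.frame.spectrum_table <- function(x, ...) {
  data.frame(
    category = c("Transitions", TRANSITION_CLASSES, "Transversions",
                 setdiff(SPECTRUM_CLASSES, TRANSITION_CLASSES),
                 "Insertions", "Deletions"),
    count = c(x$ts_count, x$counts[TRANSITION_CLASSES], x$tv_count,
              x$counts[setdiff(SPECTRUM_CLASSES, TRANSITION_CLASSES)],
              x$insertions, x$deletions),
    proportion = c(NA, x$proportions[TRANSITION_CLASSES], NA,
                   x$proportions[setdiff(SPECTRUM_CLASSES,
                                         TRANSITION_CLASSES)],
                   if (x$insertions + x$deletions > 0) {
                     c(x$insertions, x$deletions) /
                       (x$insertions + x$deletions)
                   } else c(NA, NA)),
    stringsAsFactors = FALSE)
}

# Yates-corrected 1-df goodness of fit on two cells with given expectation
yates_gof2 <- function(obs, expected) {
  dev <- pmax(abs(obs - expected) - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Goodness-of-fit test of the NS/S split against site availability
#'
#' Tests whether observed non-synonymous and synonymous substitution
#' counts follow the genomic ratio of non-synonymous to synonymous sites
#' (a departure signals selection during MA). Yates-corrected 1-df
#' chi-square.
#'
#' @param nonsyn_obs,syn_obs Observed substitution counts.
#' @param nonsyn_sites,syn_sites Genomic site counts (may be fractional).
#' @return List with chi2, df, p (p is `NA` when no observations).
#' @export
gof_test_ns_s <- function(nonsyn_obs, syn_obs, nonsyn_sites, syn_sites) {
  stopifnot(nonsyn_obs >= 0, syn_obs >= 0, nonsyn_sites > 0, syn_sites > 0)
  n <- nonsyn_obs + syn_obs
  if (n == 0) return(list(chi2 = NA_real_, df = 1L, p = NA_real_))
  p_ns <- nonsyn_sites / (nonsyn_sites + syn_sites)
  yates_gof2(c(nonsyn_obs, syn_obs), n * c(p_ns, 1 - p_ns))
}

#' Yates-corrected chi-square on a 2x2 count table
#'
#' @param a,b,c,d Counts, rows = groups: `[[a, b], [c, d]]`.
#' @return List with chi2, df, p (`NA` on a zero margin).
#' @export
count_comparison_test <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  list(chi2 = unname(ct$statistic), df = 1L, p = unname(ct$p.value))
}

#' Compare two mutation rates by a conditional chi-square
#'
#' Conditions on the total count `m1 + m2`: under equal rates the split is
#' binomial with probability proportional to the exposures. Tested by a
#' Yates-corrected 1-df chi-square of the observed split against that
#' expectation.
#'
#' @param m1,m2 Counts in the two groups.
#' @param e1,e2 Exposures (site-divisions or genome-divisions).
#' @return List with chi2, df, p, and `ratio` = (m2/e2)/(m1/e1).
#' @export
rate_ratio_test <- function(m1, e1, m2, e2) {
  stopifnot(e1 > 0, e2 > 0, m1 >= 0, m2 >= 0)
  ratio <- if (m1 > 0) (m2 / e2) / (m1 / e1) else NA_real_
  n <- m1 + m2
  if (n == 0) return(list(chi2 = NA_real_, df = 1L, p = NA_real_,
                          ratio = ratio))
  p1 <- e1 / (e1 + e2)
  res <- yates_gof2(c(m1, m2), n * c(p1, 1 - p1))
  c(res, list(ratio = ratio))
}

#' Context-dependent mutation-rate matrix (64 trinucleotide cells)
#'
#' Each cell holds the substitution count at that reference-strand context
#' and the rate `count / (context_sites x total divisions)`, reported in
#' units of 1e-10 per site per cell division. Cells with zero context
#' sites carry `NA` rates.
#'
#' @param annotations Classified mutations (BPS rows are used; records at
#'   chromosome-terminal positions have no context and are excluded).
#' @param inventory The [build_site_inventory()] result.
#' @param lines QC-filtered line metadata.
#' @return Data.frame with five_prime, focal, three_prime, count, sites,
#'   exposure, rate_1e10.
#' @export
context_rate_matrix <- function(annotations, inventory, lines) {
  keys <- context_keys()
  bps <- annotations[annotations$kind == "BPS" & !is.na(annotations$context),
                     , drop = FALSE]
  counts <- table(factor(bps$context, levels = keys))
  sites <- inventory$context_counts[keys]
  divisions <- sum(lines$total_divisions)
  exposure <- sites * divisions
  rate <- ifelse(sites > 0, as.integer(counts) / exposure, NA_real_)
  data.frame(five_prime = substr(keys, 1, 1), focal = substr(keys, 2, 2),
             three_prime = substr(keys, 3, 3),
             count = as.integer(counts), sites = as.integer(sites),
             exposure = as.numeric(exposure), rate_1e10 = rate * 1e10,
             stringsAsFactors = FALSE)
}

#' Per-gene mutation-enrichment scan
#'
#' Under neutrality each gene's substitution count is Poisson with mean
#' `CDS length x genome rate x total divisions`. The upper-tail
#' probability P(X >= observed) is computed per gene and
#' Benjamini-Hochberg adjusted; genes with `q < alpha` are flagged as
#' enriched (candidate targets of positive selection).
#'
#' @param annotations Classified mutations (CDS substitutions are counted
#'   via their `gene_id`).
#' @param genes Gene table with gene_id and cds_length.
#' @param genome_rate A per-site [mutation_rate()] estimate.
#' @param lines QC-filtered line metadata.
#' @param alpha BH threshold (default 0.05).
#' @return Data.frame with gene_id, cds_length, observed, expected, p,
#'   bh_q, enriched.
#' @export
gene_enrichment_scan <- function(annotations, genes, genome_rate, lines,
                                 alpha = 0.05) {
  stopifnot(inherits(genome_rate, "rate_estimate"))
  divisions <- sum(lines$total_divisions)
  bps <- annotations[annotations$kind == "BPS" &
                       !is.na(annotations$gene_id), , drop = FALSE]
  obs <- table(factor(bps$gene_id, levels = genes$gene_id))
  lambda <- genes$cds_length * genome_rate$rate * divisions
  observed <- as.integer(obs)
  p <- stats::ppois(observed - 1L, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = genes$gene_id, cds_length = genes$cds_length,
             observed = observed, expected = lambda, p = p, bh_q = q,
             enriched = q < alpha, stringsAsFactors = FALSE)
}

#' Moment dispersion of per-gene read counts
#'
#' For each gene, `alpha = (V - mu) / mu^2` with the sample mean `mu` and
#' sample variance `V` (denominator n-1) across replicates; 0 under
#' Poisson noise, positive when overdispersed. Genes with `mu = 0` get
#' `NA`.
#'
#' @param counts Numeric matrix, genes x replicates (>= 2 columns).
#' @return Data.frame with gene, mean, variance, alpha.
#' @export
gene_dispersion <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("dispersion needs >= 2 replicates")
  mu <- rowMeans(counts)
  V <- apply(counts, 1, stats::var)
  alpha <- ifelse(mu > 0, (V - mu) / mu^2, NA_real_)
  data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
             mean = mu, variance = V, alpha = alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Efficiency of plating
#'
#' Colony-forming units of a treated culture divided by the control CFU.
#'
#' @param cfu_treated,cfu_control Colony counts; control must be positive.
#' @return EOP fraction in `[0, Inf)`.
#' @export
efficiency_of_plating <- function(cfu_treated, cfu_control) {
  if (any(cfu_control <= 0)) stop("control CFU must be positive")
  cfu_treated / cfu_control
}
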