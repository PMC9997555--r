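# Estimators and statistics: closed forms, independent oracles, and
# parameter recovery on simulated data.

test_that("division counts follow log2 of colony size", {
  expect_equal(divisions_from_cfu(1048576), 20)
  expect_equal(divisions_from_cfu(131072), 17)
  expect_equal(divisions_from_cfu(1), 0)
  expect_error(divisions_from_cfu(0), ">= 1")
})

test_that("harmonic-mean Ne reproduces hand-computed values", {
  expect_equal(round(effective_population_size(20), 2), 10.50)
  expect_equal(round(effective_population_size(17), 2), 9.00)
  expect_equal(effective_population_size(0), 1.0)
  # direct oracle: (T+1)/sum(2^-i)
  for (T in c(1, 5, 12)) {
    expect_equal(effective_population_size(T),
                 (T + 1) / sum(2^-(0:T)))
  }
  expect_error(effective_population_size(-1), ">= 0")
})

test_that("Garwood interval matches closed forms and is well-ordered", {
  ci0 <- poisson_ci(0)
  expect_equal(unname(ci0["low"]), 0)
  expect_equal(unname(ci0["high"]), -log(0.025), tolerance = 1e-9)
  ci62 <- poisson_ci(62)
  expect_equal(unname(ci62["low"] / 62), 0.767, tolerance = 1e-3)
  expect_equal(unname(ci62["high"] / 62), 1.282, tolerance = 1e-3)
  expect_error(poisson_ci(5, level = 1.2), "level")
  # width monotone increasing in m; relative width decreasing
  cis <- vapply(0:40, poisson_ci, numeric(2))
  widths <- cis[2, ] - cis[1, ]
  expect_true(all(diff(widths) > 0))
  rel <- widths[-1] / (1:40)
  expect_true(all(diff(rel) < 0))
})

test_that("Garwood interval attains nominal coverage on Poisson draws", {
  set.seed(71)
  draws <- stats::rpois(2000, 5)
  covered <- vapply(draws, function(m) {
    ci <- poisson_ci(m)
    ci["low"] <= 5 && 5 <= ci["high"]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("rate estimates scale counts by the summed exposure", {
  lines <- data.frame(total_divisions = rep(1009, 73),
                      analyzable_sites = 1.23e7)
  r <- mutation_rate(62, lines, per = "genome")
  expect_equal(r$exposure, 73 * 1009)
  expect_equal(signif(r$rate, 2), 0.84e-3)
  rs <- mutation_rate(62, lines, per = "site")
  expect_equal(rs$exposure, 73 * 1009 * 1.23e7)
  r0 <- mutation_rate(0, lines, per = "genome")
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_low, 0)
  expect_equal(r0$ci_high, -log(0.025) / (73 * 1009), tolerance = 1e-9)
  expect_error(mutation_rate(1, lines[0, ], per = "genome"), "exposure")
})

test_that("spectrum table reproduces hand-tabulated ratios", {
  ann <- ann_from_counts(c("A:T->G:C" = 11, "G:C->A:T" = 18,
                           "A:T->T:A" = 5, "A:T->C:G" = 5,
                           "G:C->C:G" = 5, "G:C->T:A" = 18),
                         insertions = 30, deletions = 4)
  st <- spectrum_table(ann)
  expect_identical(st$ts_count, 29L)
  expect_identical(st$tv_count, 33L)
  expect_equal(round(st$ts_tv_ratio, 2), 0.88)
  expect_equal(st$ins_del_ratio, 7.5)
  expect_equal(unname(st$proportions[["G:C->A:T"]]), 18 / 29)
  expect_equal(sum(st$proportions[c("A:T->G:C", "G:C->A:T")]), 1)
  expect_equal(sum(st$proportions[c("A:T->T:A", "A:T->C:G", "G:C->C:G",
                                    "G:C->T:A")]), 1)
  # invariant to input order
  st2 <- spectrum_table(ann[rev(seq_len(nrow(ann))), ])
  expect_identical(st2$counts, st$counts)
  # empty input: zero table, undefined ratios
  st0 <- spectrum_table(ann[0, ])
  expect_true(all(st0$counts == 0))
  expect_true(is.na(st0$ts_tv_ratio))
  expect_true(is.na(st0$ins_del_ratio))
})

test_that("Yates goodness of fit matches prop.test and clamps at zero", {
  g <- gof_test_ns_s(26, 6, 6074090, 1641376)
  p0 <- 6074090 / (6074090 + 1641376)
  pt <- stats::prop.test(26, 32, p = p0, correct = TRUE)
  expect_equal(g$chi2, unname(pt$statistic), tolerance = 1e-9)
  expect_equal(g$p, pt$p.value, tolerance = 1e-9)
  # observation at expectation: correction clamps the statistic to 0
  g0 <- gof_test_ns_s(75, 25, 3, 1)
  expect_equal(g0$chi2, 0)
  expect_true(is.na(gof_test_ns_s(0, 0, 3, 1)$p))
})

test_that("2x2 comparison equals an independent Yates implementation", {
  yates22 <- function(a, b, c, d) {  # textbook formula, not chisq.test
    n <- a + b + c + d
    num <- (max(abs(a * d - b * c) - n / 2, 0))^2 * n
    den <- (a + b) * (c + d) * (a + c) * (b + d)
    num / den
  }
  set.seed(81)
  for (rep in 1:100) {
    x <- sample(1:50, 4, replace = TRUE)
    got <- count_comparison_test(x[1], x[2], x[3], x[4])
    expect_equal(got$chi2, yates22(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-9)
  }
  expect_equal(count_comparison_test(10, 10, 10, 10)$chi2, 0)
  expect_true(is.na(count_comparison_test(0, 0, 5, 5)$chi2))
})

test_that("rate-ratio test agrees with the exact binomial split", {
  r <- rate_ratio_test(4, 73657, 14, 74390)
  bt <- stats::binom.test(4, 18, p = 73657 / (73657 + 74390))
  expect_lt(abs(r$p - bt$p.value), 0.02)
  expect_equal(r$ratio, (14 / 74390) / (4 / 73657))
  # equal rates give a null statistic; ratio is scale-invariant
  eq <- rate_ratio_test(10, 1000, 20, 2000)
  expect_equal(eq$chi2, 0)
  expect_equal(rate_ratio_test(4, 2 * 73657, 14, 2 * 74390)$ratio, r$ratio)
  expect_true(is.na(rate_ratio_test(0, 10, 0, 10)$p))
})

test_that("context matrix conserves counts and flags empty cells", {
  ref <- toy_genome()
  inv <- toy_inventory()
  sim <- simulate_ma_lines(
    ref, truth_rates(bps_rate = 1e-7, indel_rate = 0, ssr_bias = 0),
    experiment_design(n_lines_control = 10, n_lines_treatment = 0),
    seed = 19)
  ann <- classify_mutations(sim$mutations, ref, inv)
  cm <- context_rate_matrix(ann, inv, sim$metadata)
  interior <- sum(ann$kind == "BPS" & !is.na(ann$context))
  expect_equal(sum(cm$count), interior)
  expect_true(all(is.na(cm$rate_1e10[cm$sites == 0])))
  expect_true(all(cm$rate_1e10[cm$sites > 0 & cm$count == 0] == 0))
  # no mutations at all: all defined rates are zero
  cm0 <- context_rate_matrix(ann[0, ], inv, sim$metadata)
  expect_true(all(cm0$rate_1e10[cm0$sites > 0] == 0))
})

test_that("context multipliers push the targeted cells above the median", {
  ref <- toy_genome()
  inv <- toy_inventory()
  mult <- rep(1, 64)
  names(mult) <- mamut:::context_keys()
  target <- grepl("^C.C$", names(mult))  # 5'-C[N]C-3'
  mult[target] <- 20
  hits <- 0
  n_runs <- 20
  for (k in seq_len(n_runs)) {
    sim <- simulate_ma_lines(
      ref, truth_rates(bps_rate = 2e-7, indel_rate = 0, ssr_bias = 0,
                       context_multipliers = mult),
      experiment_design(n_lines_control = 8, n_lines_treatment = 0),
      seed = 100 + k)
    ann <- classify_mutations(sim$mutations, ref, inv)
    cm <- context_rate_matrix(ann, inv, sim$metadata)
    key <- paste0(cm$five_prime, cm$focal, cm$three_prime)
    elevated <- cm$rate_1e10[key == "CAC"]
    med <- stats::median(cm$rate_1e10, na.rm = TRUE)
    if (isTRUE(elevated > med)) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("enrichment p-values equal direct Poisson summation", {
  ref <- toy_genome()
  inv <- toy_inventory()
  lines <- data.frame(total_divisions = rep(1000, 5),
                      analyzable_sites = inv$analyzable_sites_total)
  rate <- mutation_rate(25, lines, per = "site")
  pos <- ref$cds$start[1] + 1L
  base <- substr(ref$sequences[[ref$cds$chromosome[1]]], pos, pos)
  ann <- classify_mutations(
    data.frame(line_id = "C001", chromosome = ref$cds$chromosome[1],
               position = pos, ref = base,
               alt = setdiff(c("A", "C", "G", "T"), base)[1],
               stringsAsFactors = FALSE),
    ref, inv)
  sc <- gene_enrichment_scan(ann, ref$genes, rate, lines)
  # direct summation oracle: P(X >= obs) = 1 - sum_{k < obs} dpois
  for (i in seq_len(nrow(sc))) {
    lam <- sc$expected[i]
    obs <- sc$observed[i]
    oracle <- if (obs == 0) 1 else {
      1 - sum(exp(-lam) * lam^(0:(obs - 1)) / factorial(0:(obs - 1)))
    }
    expect_equal(sc$p[i], oracle, tolerance = 1e-9)
  }
  expect_true(all(sc$p[sc$observed == 0] == 1))
})

test_that("moment dispersion matches hand arithmetic and Poisson null", {
  d <- gene_dispersion(matrix(c(10, 10, 10), nrow = 1))
  expect_equal(d$alpha, -0.10)
  d2 <- gene_dispersion(matrix(c(4, 16), nrow = 1))
  expect_equal(d2$mean, 10)
  expect_equal(d2$variance, 72)
  expect_equal(d2$alpha, 0.62)
  expect_true(is.na(gene_dispersion(matrix(c(0, 0), nrow = 1))$alpha))
  expect_error(gene_dispersion(matrix(1:3, ncol = 1)), "replicates")
  # Poisson counts: V = mu, so the median alpha is near zero
  set.seed(91)
  cnt <- matrix(stats::rpois(1000 * 6, 50), nrow = 1000)
  alphas <- gene_dispersion(cnt)$alpha
  # near zero on the scale of real overdispersion (alpha ~ 0.1-1); the
  # moment estimator carries a small finite-replicate skew of order
  # 1/(replicates x mean), which this bound comfortably contains
  expect_lt(abs(stats::median(alphas)), 0.01)
  expect_lt(abs(mean(alphas)), 0.01)
})

test_that("efficiency of plating is the treated/control CFU ratio", {
  expect_equal(efficiency_of_plating(500, 500), 1.0)
  expect_equal(efficiency_of_plating(0, 500), 0.0)
  expect_equal(efficiency_of_plating(c(450, 300, 20), 500),
               c(0.9, 0.6, 0.04))
  expect_error(efficiency_of_plating(10, 0), "positive")
})

test_that("rate estimator recovers planted truth with covering CIs", {
  ref <- generate_genome(genome_spec(n_chromosomes = 1,
                                     chrom_length = 20000, n_genes = 0,
                                     ssr_density = 0, seed = 23))
  truth_rate <- 1e-7
  n_runs <- 50
  est <- numeric(n_runs)
  covered <- logical(n_runs)
  for (k in seq_len(n_runs)) {
    sim <- simulate_ma_lines(
      ref, truth_rates(bps_rate = truth_rate, indel_rate = 0,
                       ssr_bias = 0),
      experiment_design(n_lines_control = 20, n_lines_treatment = 0,
                        total_divisions_control = 1000),
      seed = 3000 + k)
    m <- sum(sim$mutations$kind == "BPS")
    r <- mutation_rate(m, sim$metadata, per = "site")
    est[k] <- r$rate
    covered[k] <- r$ci_low <= truth_rate && truth_rate <= r$ci_high
  }
  expect_gte(mean(covered), 0.90)
  se <- stats::sd(est) / sqrt(n_runs)
  expect_lt(abs(mean(est) - truth_rate), 3 * se)
})
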