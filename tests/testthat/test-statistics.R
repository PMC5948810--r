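# Build a classification table directly from class counts; the statistics
# layer only reads clone_class / excluded / sample / individual columns.
class_table <- function(counts, sample = "s1", individual = NA_character_) {
  cls <- rep(names(counts), counts)
  data.frame(clone_id = sprintf("c%03d", seq_along(cls)), sample = sample,
             individual = individual, clone_class = cls,
             motif1_units = NA_integer_,
             excluded = cls %in% c("INTRA_ALLELIC", "AMBIGUOUS"),
             stringsAsFactors = FALSE)
}

test_that("HR frequencies follow the exclusion rule arithmetic", {
  f <- estimate_frequencies(class_table(c(PD = 42, MD = 43, CO_I = 31,
                                          CO_II = 21, CO_I_II = 9)))
  expect_equal(f$n_retained, 146)
  expect_equal(f$hr_fraction, 61 / 146)
  expect_equal(f$hr_pct, 41.78)
  expect_equal(f$pct_CO_I, 21.23)
  expect_equal(f$pct_CO_I_II, 6.16)
  expect_equal(f$pct_parental, 58.22)
  # no HR
  f0 <- estimate_frequencies(class_table(c(PD = 5, MD = 5)))
  expect_equal(f0$hr_fraction, 0)
  # artifacts excluded from numerator and denominator
  f1 <- estimate_frequencies(class_table(c(PD = 8, MD = 8, CO_I = 4,
                                           INTRA_ALLELIC = 5)))
  expect_equal(f1$hr_fraction, 4 / 20)
  expect_equal(f1$n_excluded, 5)
  # zero retained clones
  fz <- estimate_frequencies(class_table(c(INTRA_ALLELIC = 3)))
  expect_true(fz$flagged)
  expect_true(is.na(fz$hr_fraction))
})

test_that("adding intra-allelic clones never changes the HR fraction", {
  set.seed(202)
  for (i in 1:25) {
    counts <- c(PD = sample(0:30, 1), MD = sample(0:30, 1),
                CO_I = sample(0:20, 1), CO_II = sample(0:10, 1),
                CO_I_II = sample(0:5, 1))
    if (sum(counts) == 0) counts["PD"] <- 1
    base <- estimate_frequencies(class_table(counts))
    spiked <- estimate_frequencies(
      class_table(c(counts, INTRA_ALLELIC = sample(1:20, 1))))
    expect_equal(spiked$hr_fraction, base$hr_fraction)
  }
})

test_that("samples are kept separate, never pooled", {
  tab <- rbind(class_table(c(PD = 5, CO_I = 5), sample = "a"),
               class_table(c(PD = 10), sample = "b"))
  f <- estimate_frequencies(tab)
  expect_equal(nrow(f), 2)
  expect_equal(f$hr_fraction[f$sample == "a"], 0.5)
  expect_equal(f$hr_fraction[f$sample == "b"], 0)
})

test_that("the confidence interval is the Wilson score interval", {
  f <- estimate_frequencies(class_table(c(PD = 20, CO_I = 10)))
  ref <- stats::prop.test(10, 30, correct = FALSE)$conf.int
  expect_equal(f$hr_ci_lo, round(100 * ref[1], 2))
  expect_equal(f$hr_ci_hi, round(100 * ref[2], 2))
})

test_that("half-tetrad genotypes follow the observed haplotype patterns", {
  gf <- genotype_gynogenote(class_table(c(PD = 5)))
  expect_equal(gf$genotype, "HOM_GF")
  gm <- genotype_gynogenote(class_table(c(MD = 4)))
  expect_equal(gm$genotype, "HOM_GM")
  het <- genotype_gynogenote(class_table(c(MD = 3, CO_I = 2)))
  expect_equal(het$genotype, "HET")
  expect_setequal(het$patterns, c("grandmaternal", "crossover"))
  # one informative clone: withheld
  single <- genotype_gynogenote(class_table(c(PD = 1)))
  expect_equal(single$genotype, "withheld")
  # artifact clones do not contribute patterns
  art <- genotype_gynogenote(class_table(c(PD = 3, INTRA_ALLELIC = 4)))
  expect_equal(art$genotype, "HOM_GF")
})

test_that("meiotic HR frequency is the heterozygote proportion", {
  g <- data.frame(individual_id = sprintf("g%d", 1:9),
                  genotype = c(rep("HET", 2), rep("HOM_GF", 4), rep("HOM_GM", 3)))
  m <- meiotic_hr_frequency(g)
  expect_equal(m$het_pct, 22.22)
  expect_equal(m$hom_pct, 77.78)
  expect_equal(m$n_genotyped, 9)
  allhom <- meiotic_hr_frequency(data.frame(individual_id = "a", genotype = "HOM_GF"))
  expect_equal(allhom$het_fraction, 0)
  most <- meiotic_hr_frequency(
    data.frame(individual_id = sprintf("g%d", 1:9),
               genotype = c(rep("HET", 7), rep("HOM_GF", 2))))
  expect_equal(most$het_pct, 77.78)
  expect_error(meiotic_hr_frequency(data.frame(individual_id = character(),
                                               genotype = character())))
  # withheld individuals drop out of the denominator
  gw <- rbind(g, data.frame(individual_id = "g10", genotype = "withheld"))
  expect_equal(meiotic_hr_frequency(gw)$n_genotyped, 9)
})

test_that("novel repeat lengths are flagged against parental and control spectra", {
  locus <- test_locus()
  none <- detect_novel_lengths(c(84, 36, 84), locus)
  expect_length(none$novel, 0)
  flags <- detect_novel_lengths(c(84, 36, 33, 90), locus,
                                control_units = c(84, 36, 33))
  expect_equal(flags$novel, c(33, 90))
  expect_equal(flags$test_unique, 90)
  empty <- detect_novel_lengths(integer(0), locus)
  expect_length(empty$novel, 0)
  withna <- detect_novel_lengths(c(84, NA, 40), locus)
  expect_equal(withna$novel, 40)
})

test_that("simulated cohorts recover the meiotic crossover probability", {
  locus <- test_locus()
  for (q in c(0, 0.25, 1)) {
    coh <- simulate_gynogenote_cohort(q, 400, 4, locus, p_zero,
                                      seed = 1000 + round(100 * q))
    cls <- classify_clones(coh$clones, locus)
    gen <- genotype_gynogenote_cohort(cls)
    est <- meiotic_hr_frequency(gen)
    se <- sqrt(q * (1 - q) / 400)
    expect_lte(abs(est$het_fraction - q), max(3 * se, 1e-9))
  }
})
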