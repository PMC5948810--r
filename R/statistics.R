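# Aggregation of clone classifications into HR frequencies (with artifact
# exclusion), half-tetrad genotypes of gynogenetic diploids, and motif-length
# instability flags. Intra-allelic (PCR template-switch artifact) and
# ambiguous clones are excluded from both numerator and denominator of every
# HR proportion and reported separately.

#' Per-sample clone-class counts and HR frequencies
#'
#' @param classifications data frame from [classify_clones()].
#' @param by grouping column (default \code{"sample"}); samples are never
#'   pooled implicitly.
#' @param conf confidence level of the Wilson score interval.
#' @return a data frame with one row per sample: per-class counts
#'   (\code{n_PD} ... \code{n_AMBIGUOUS}), \code{n_retained} (parental +
#'   crossover clones), \code{n_excluded}, \code{hr_fraction} =
#'   (CO_I + CO_II + CO_I_II) / n_retained with \code{hr_pct} and Wilson
#'   CI bounds (\code{hr_ci_lo}, \code{hr_ci_hi}, as percentages), plus
#'   per-class percentages of retained clones (\code{pct_PD}, ...,
#'   \code{pct_parental}). Samples with zero retained clones get NA
#'   fractions and \code{flagged = TRUE}.
#' @export
estimate_frequencies <- function(classifications, by = "sample", conf = 0.95) {
  stopifnot(by %in% names(classifications))
  groups <- unique(classifications[[by]])
  out <- lapply(groups, function(g) {
    cls <- classifications$clone_class[classifications[[by]] == g]
    counts <- vapply(CLONE_CLASSES, function(k) sum(cls == k), 1L)
    retained <- sum(counts[c("PD", "MD", HR_CLASSES)])
    excluded <- sum(counts[c("INTRA_ALLELIC", "AMBIGUOUS")])
    n_hr <- sum(counts[HR_CLASSES])
    row <- as.data.frame(as.list(stats::setNames(counts, paste0("n_", CLONE_CLASSES))))
    row <- cbind(data.frame(sample = g, stringsAsFactors = FALSE), row)
    names(row)[1] <- by
    row$n_retained <- retained
    row$n_excluded <- excluded
    if (retained > 0) {
      ci <- wilson_ci(n_hr, retained, conf)
      row$hr_fraction <- n_hr / retained
      row$hr_pct <- round(100 * n_hr / retained, 2)
      row$hr_ci_lo <- round(100 * ci[1], 2)
      row$hr_ci_hi <- round(100 * ci[2], 2)
      for (k in c("PD", "MD", HR_CLASSES))
        row[[paste0("pct_", k)]] <- round(100 * counts[[k]] / retained, 2)
      row$pct_parental <- round(100 * (counts[["PD"]] + counts[["MD"]]) / retained, 2)
      row$flagged <- FALSE
    } else {
      row$hr_fraction <- NA_real_
      row$hr_pct <- row$hr_ci_lo <- row$hr_ci_hi <- NA_real_
      for (k in c("PD", "MD", HR_CLASSES)) row[[paste0("pct_", k)]] <- NA_real_
      row$pct_parental <- NA_real_
      row$flagged <- TRUE
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Half-tetrad genotype of one gynogenetic diploid individual
#'
#' Both alleles of a meio-gynogenetic diploid derive from a single egg
#' haplotype pair, so the haplotype patterns observed among an individual's
#' clones reveal whether a meiotic crossover occurred: a homozygote shows a
#' single pattern identical to one grandparent, a heterozygote shows two or
#' more distinct patterns (typically one grandparental and one crossover
#' haplotype). Artifact and ambiguous clones are ignored.
#'
#' @param classifications data frame from [classify_clones()] for one
#'   individual's clones.
#' @param min_clones minimum informative clones required to call a genotype
#'   (default 2); below it the genotype is withheld.
#' @return a list with \code{genotype} (\code{HOM_GF}, \code{HOM_GM},
#'   \code{HET} or \code{withheld}), \code{patterns} (distinct haplotype
#'   patterns observed: \code{grandpaternal}, \code{grandmaternal},
#'   \code{crossover}) and \code{n_informative}.
#' @export
genotype_gynogenote <- function(classifications, min_clones = 2) {
  keep <- !classifications$excluded
  cls <- classifications$clone_class[keep]
  pattern <- ifelse(cls == "PD", "grandpaternal",
                    ifelse(cls == "MD", "grandmaternal", "crossover"))
  pats <- unique(pattern)
  n <- length(pattern)
  if (n < min_clones)
    return(list(genotype = "withheld", patterns = pats, n_informative = n))
  genotype <- if (length(pats) >= 2) {
    "HET"
  } else if (pats == "grandpaternal") {
    "HOM_GF"
  } else if (pats == "grandmaternal") {
    "HOM_GM"
  } else {
    # a single, purely recombinant pattern still evidences meiotic exchange
    "HET"
  }
  list(genotype = genotype, patterns = pats, n_informative = n)
}

#' Genotype every individual of a gynogenetic cohort
#'
#' @param classifications data frame from [classify_clones()] with an
#'   \code{individual} column.
#' @param min_clones see [genotype_gynogenote()].
#' @return a data frame: individual_id, genotype, patterns (comma-joined),
#'   n_informative.
#' @export
genotype_gynogenote_cohort <- function(classifications, min_clones = 2) {
  stopifnot("individual" %in% names(classifications))
  inds <- unique(classifications$individual)
  res <- do.call(rbind, lapply(inds, function(id) {
    g <- genotype_gynogenote(
      classifications[classifications$individual == id, , drop = FALSE],
      min_clones = min_clones)
    data.frame(individual_id = id, genotype = g$genotype,
               patterns = paste(g$patterns, collapse = ","),
               n_informative = g$n_informative, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Meiotic HR frequency from gynogenote genotypes
#'
#' The proportion of heterozygous individuals among genotyped gynogenetic
#' diploids directly estimates the frequency of meiotic HR at the locus.
#' Withheld individuals are excluded.
#'
#' @param genotypes data frame from [genotype_gynogenote_cohort()].
#' @param conf confidence level of the Wilson score interval.
#' @return a list: \code{n_genotyped}, \code{n_het}, \code{het_fraction},
#'   \code{het_pct}, \code{hom_pct}, \code{ci_lo}, \code{ci_hi} (percent).
#' @export
meiotic_hr_frequency <- function(genotypes, conf = 0.95) {
  g <- genotypes$genotype[genotypes$genotype != "withheld"]
  if (length(g) == 0) stop("no genotyped individuals")
  n_het <- sum(g == "HET")
  ci <- wilson_ci(n_het, length(g), conf)
  list(n_genotyped = length(g), n_het = n_het,
       het_fraction = n_het / length(g),
       het_pct = round(100 * n_het / length(g), 2),
       hom_pct = round(100 * (1 - n_het / length(g)), 2),
       ci_lo = round(100 * ci[1], 2), ci_hi = round(100 * ci[2], 2))
}

#' Flag repeat lengths absent from both parental alleles
#'
#' Flags every observed motif-1 unit count that matches neither parental
#' count (novel lengths, the signature of repeat instability), and
#' optionally contrasts a test sample against a control sample, reporting
#' lengths unique to the test sample.
#'
#' @param units integer vector of observed motif-1 unit counts for the test
#'   sample (NA entries are dropped).
#' @param locus a validated \code{locus_reference}.
#' @param control_units optional unit counts from a control sample (e.g. a
#'   mixed-parental-genome PCR control).
#' @return a list: \code{novel} (sorted novel unit counts), \code{spectrum}
#'   (table of all observed counts), and, when a control is given,
#'   \code{test_unique} (novel counts absent from the control spectrum).
#' @export
detect_novel_lengths <- function(units, locus, control_units = NULL) {
  units <- units[!is.na(units)]
  parental <- c(locus$motifs$paternal_units[1], locus$motifs$maternal_units[1])
  novel <- sort(unique(units[!units %in% parental]))
  out <- list(novel = novel,
              spectrum = table(factor(units, levels = sort(unique(units)))))
  if (!is.null(control_units)) {
    control_units <- control_units[!is.na(control_units)]
    out$test_unique <- sort(setdiff(novel, control_units))
  }
  out
}
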