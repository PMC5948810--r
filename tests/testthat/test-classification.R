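seg_calls <- function(locus, up, mid, m23, down) {
  # build a call vector by segment: upstream_of_motif1, between_motif1_and_
  # motif2, between_motif2_and_motif3, downstream_of_motif3
  seg <- locus$markers$segment
  out <- character(length(seg))
  out[seg == "upstream_of_motif1"] <- up
  out[seg == "between_motif1_and_motif2"] <- mid
  out[seg == "between_motif2_and_motif3"] <- m23
  out[seg == "downstream_of_motif3"] <- down
  out
}

test_that("canonical linkage patterns map to the clone taxonomy", {
  locus <- test_locus()
  cls <- function(calls, units) {
    classify_clone(make_calls(calls, locus), make_repeats(units, locus), locus)
  }
  expect_equal(cls(seg_calls(locus, "P", "P", "P", "P"), 84)$clone_class, "PD")
  expect_equal(cls(seg_calls(locus, "M", "M", "M", "M"), 36)$clone_class, "MD")
  co1 <- cls(seg_calls(locus, "P", "M", "M", "M"), 36)
  expect_equal(co1$clone_class, "CO_I")
  m1 <- c(locus$motifs$pat_start[1], locus$motifs$pat_end[1])
  iv <- co1$breakpoint_intervals[[1]]
  expect_true(iv[1] <= m1[1] && m1[2] <= iv[2])
  # crossover II: switch within the motif2..motif3 marker block
  calls <- seg_calls(locus, "P", "P", "P", "M")
  calls[locus$markers$element_id == "snpE"] <- "M"
  co2 <- cls(calls, 84)
  expect_equal(co2$clone_class, "CO_II")
  iv <- co2$breakpoint_intervals[[1]]
  expect_true(locus$co2_region[1] <= iv[1] && iv[2] <= locus$co2_region[2])
  # co-occurring crossovers: P flanks, M middle
  co12 <- cls(seg_calls(locus, "P", "M", c("M", "P", "P"), "P"), 36)
  expect_equal(co12$clone_class, "CO_I_II")
  expect_equal(co12$n_switches, 2)
  # uniparental markers with a novel repeat length: PCR artifact
  intra <- cls(seg_calls(locus, "M", "M", "M", "M"), 30)
  expect_equal(intra$clone_class, "INTRA_ALLELIC")
  expect_true(intra$excluded)
})

test_that("off-region switches and noisy call sets are ambiguous, not forced", {
  locus <- test_locus()
  cls <- function(calls, units) {
    classify_clone(make_calls(calls, locus), make_repeats(units, locus), locus)
  }
  # single switch between the two SNPs downstream of motif 1: no motif there
  calls <- seg_calls(locus, "P", c("P", "M", "M"), "M", "M")
  expect_equal(cls(calls, 84)$clone_class, "AMBIGUOUS")
  # single switch spanning motif 2 only
  calls <- seg_calls(locus, "P", "P", "M", "M")
  expect_equal(cls(calls, 84)$clone_class, "AMBIGUOUS")
  # more than a third of markers unusable
  calls <- seg_calls(locus, "P", "P", "P", "P")
  calls[1:4] <- "missing"
  expect_equal(cls(calls, 84)$clone_class, "AMBIGUOUS")
  # three switches cannot be explained by the two-crossover taxonomy
  calls <- seg_calls(locus, "P", "M", c("P", "P", "M"), "M")
  calls[locus$markers$element_id == "snpC"] <- "P"
  res <- cls(calls, 84)
  expect_equal(res$clone_class, "AMBIGUOUS")
  # uniparental markers with the other parent's exact count is irreducible
  expect_equal(cls(seg_calls(locus, "P", "P", "P", "P"), 36)$clone_class,
               "AMBIGUOUS")
})

test_that("classification requires calls matching the locus marker set", {
  locus <- test_locus()
  calls <- make_calls(seg_calls(locus, "P", "P", "P", "P"), locus)[-1, ]
  expect_error(classify_clone(calls, make_repeats(84, locus), locus),
               class = "gtrecomb_input_mismatch_error")
})

test_that("DSB origin follows the motif-1 repair template", {
  locus <- test_locus()
  co1 <- function(units) {
    classify_clone(make_calls(seg_calls(locus, "P", "M", "M", "M"), locus),
                   make_repeats(units, locus), locus)
  }
  expect_equal(infer_dsb_origin(co1(36), locus),
               list(origin = "dsb_paternal", basis = "units_equal_maternal"))
  expect_equal(infer_dsb_origin(co1(84), locus),
               list(origin = "dsb_maternal", basis = "units_equal_paternal"))
  expect_equal(infer_dsb_origin(co1(60), locus)$origin, "indeterminate")
  expect_equal(infer_dsb_origin(co1(60), locus)$basis, "expanded")
  expect_equal(infer_dsb_origin(co1(20), locus)$basis, "contracted")
  expect_equal(infer_dsb_origin(co1(NA), locus)$basis, "missing")
  pd <- classify_clone(make_calls(seg_calls(locus, "P", "P", "P", "P"), locus),
                       make_repeats(84, locus), locus)
  expect_error(infer_dsb_origin(pd, locus), class = "gtrecomb_contract_error")
})

test_that("classifier recovers simulation truth exactly on error-free clones", {
  locus <- test_locus()
  comp <- c(PD = 20, MD = 20, CO_I = 30, CO_II = 20, CO_I_II = 20,
            INTRA_ALLELIC = 20)
  set <- simulate_clone_set(comp, locus, p_zero, seed = 41)
  cls <- classify_clones(set$clones, locus)
  truth <- set$truth[match(cls$clone_id, set$truth$clone_id), ]
  expect_identical(cls$clone_class, truth$true_class)
  # DSB origin matches the simulated break-bearing homolog
  co1 <- cls$clone_class == "CO_I"
  expect_identical(cls$dsb_origin[co1],
                   paste0("dsb_", truth$dsb_parent[co1]))
  # reported breakpoint intervals contain the true breakpoints
  for (i in which(cls$n_switches > 0)) {
    ivs <- lapply(strsplit(cls$breakpoints[i], ";")[[1]],
                  function(s) as.integer(strsplit(s, "-")[[1]]))
    bps <- as.integer(strsplit(truth$breakpoints[i], ";")[[1]])
    expect_equal(length(ivs), length(bps))
    for (j in seq_along(bps)) {
      expect_true(ivs[[j]][1] <= bps[j] && bps[j] <= ivs[[j]][2],
                  info = sprintf("clone %s bp %d", cls$clone_id[i], j))
    }
  }
})

test_that("classifier agrees with the brute-force minimal-switch oracle", {
  locus <- test_locus()
  set.seed(17)
  states <- c("P", "M", "ambiguous", "missing")
  for (case in 1:400) {
    calls <- sample(states, nrow(locus$markers), replace = TRUE,
                    prob = c(0.4, 0.4, 0.1, 0.1))
    units <- sample(c(84L, 36L, 30L, 90L, NA), 1)
    got <- classify_clone(make_calls(calls, locus),
                          make_repeats(units, locus), locus)$clone_class
    want <- oracle_classify(calls, units, locus)
    expect_identical(got, want,
                     info = paste(paste(calls, collapse = ","), units))
  }
})

test_that("reciprocal crossover products mirror each other", {
  locus <- test_locus()
  set.seed(23)
  for (dsb in c("paternal", "maternal")) {
    a <- simulate_clone("CO_I", locus, p_zero, dsb_parent = dsb,
                        flank_parent = "paternal")
    b <- simulate_clone("CO_I", locus, p_zero, dsb_parent = dsb,
                        flank_parent = "maternal")
    ca <- call_markers(a$seq, locus)
    cb <- call_markers(b$seq, locus)
    expect_true(all((ca$call == "P") == (cb$call == "M")))
    ra <- classify_clone(ca, measure_repeats(a$seq, locus), locus)
    rb <- classify_clone(cb, measure_repeats(b$seq, locus), locus)
    expect_equal(ra$clone_class, "CO_I")
    expect_equal(rb$clone_class, "CO_I")
    expect_identical(ra$breakpoint_intervals, rb$breakpoint_intervals)
  }
})

test_that("co-occurring crossover intervals sit in their candidate regions", {
  locus <- test_locus()
  set <- simulate_clone_set(c(CO_I_II = 40), locus, p_zero, seed = 77)
  cls <- classify_clones(set$clones, locus)
  expect_true(all(cls$clone_class == "CO_I_II"))
  m1 <- c(locus$motifs$pat_start[1], locus$motifs$pat_end[1])
  for (bp in cls$breakpoints) {
    ivs <- lapply(strsplit(bp, ";")[[1]],
                  function(s) as.integer(strsplit(s, "-")[[1]]))
    expect_true(ivs[[1]][1] <= m1[1] && m1[2] <= ivs[[1]][2])
    expect_true(locus$co2_region[1] <= ivs[[2]][1] &&
                  ivs[[2]][2] <= locus$co2_region[2])
  }
})

test_that("repeat-length spectra report parental-count fractions", {
  locus <- test_locus()
  comp <- rbind(
    data.frame(class = "CO_I", n = 81, dsb_parent = "paternal",
               motif1_units = NA),
    data.frame(class = "CO_I", n = 17, dsb_parent = "maternal",
               motif1_units = NA),
    data.frame(class = "CO_I", n = 1, dsb_parent = NA,
               motif1_units = rep(c(30, 33, 39, 45, 60, 78, 90, 96), each = 5)))
  set <- simulate_clone_set(comp, locus, p_zero, seed = 13, sample_id = "somatic")
  cls <- classify_clones(set$clones, locus)
  dist <- summarize_repeat_distribution(cls, locus, by = "sample")
  expect_equal(dist$summary$n, 138)
  expect_equal(round(100 * dist$summary$frac_paternal_count, 2), 12.32)
  expect_equal(round(100 * dist$summary$frac_maternal_count, 2), 58.70)
  expect_equal(dist$summary$frac_maternal_count +
                 dist$summary$frac_paternal_count +
                 dist$summary$frac_other, 1)
  expect_true(all(abs(tapply(dist$histogram$fraction, dist$histogram$group, sum) - 1) < 1e-9))
  # degenerate inputs
  empty <- summarize_repeat_distribution(cls[0, ], locus)
  expect_equal(nrow(empty$histogram), 0)
  allmat <- summarize_repeat_distribution(
    cls[cls$motif1_units == 36, , drop = FALSE], locus)
  expect_equal(nrow(allmat$histogram), 1)
  expect_equal(allmat$histogram$fraction, 1)
})
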