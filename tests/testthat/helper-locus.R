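# Shared fixtures: the default emulated locus (memoized; building it
# validates anchors exhaustively, so do it once) and error-free artifact
# parameters for ground-truth closure tests.

test_locus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_locus_spec(default_locus_spec())
    cache
  }
})

p_zero <- artifact_params(slippage_prob = 0, template_switch_prob = 0,
                          seq_error_rate = 0)

# Independent tract reconstruction from the specification fields alone
# (unit string repetition + interruption substitution + optional reverse
# complement), used as the oracle for rendered motif tracts.
oracle_tract <- function(spec, motif_id, parent) {
  el <- Find(function(e) identical(e$id, motif_id), spec$elements)
  units <- if (parent == "paternal") el$paternal_units else el$maternal_units
  chars <- rep(strsplit(el$unit, "")[[1]], units)
  for (it in el$interruptions[[parent]]) {
    chars[(it$unit - 1) * nchar(el$unit) + it$pos] <- it$base
  }
  s <- paste(chars, collapse = "")
  if (identical(el$orientation, "reverse")) {
    s <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  s
}

# Build a marker-call data frame directly (bypassing sequence analysis) for
# classifier unit tests: `calls` is a character vector over the locus
# markers with values P/M/ambiguous/missing.
make_calls <- function(calls, locus) {
  data.frame(marker_id = locus$markers$element_id, call = calls,
             observed_allele = NA_character_,
             anchor_left_found = calls != "missing",
             anchor_right_found = calls != "missing",
             stringsAsFactors = FALSE)
}

make_repeats <- function(motif1_units, locus) {
  pu <- locus$motifs$paternal_units[1]
  mu <- locus$motifs$maternal_units[1]
  matches <- if (is.na(motif1_units)) "missing"
  else if (motif1_units == pu) "paternal_count"
  else if (motif1_units == mu) "maternal_count"
  else "other"
  data.frame(motif_id = "motif1", observed_units = motif1_units,
             matches = matches,
             delta_vs_nearest_parent = NA_integer_, stringsAsFactors = FALSE)
}

# Brute-force minimal-switch oracle: enumerate every parental mosaic with
# 0, 1 or 2 switches over the usable calls, keep those consistent with the
# observations, and map the minimal-switch explanation to a clone class
# using the candidate-region definitions recomputed here from the locus
# coordinate table.
oracle_classify <- function(calls, motif1_units, locus) {
  mk <- locus$markers
  n <- length(calls)
  usable <- which(calls %in% c("P", "M"))
  if ((n - length(usable)) > ceiling(n / 3) || length(usable) == 0)
    return("AMBIGUOUS")
  obs <- calls[usable]
  m <- length(usable)
  best <- NULL
  for (k in 0:2) {
    if (!is.null(best)) break
    gap_sets <- if (k == 0) list(integer(0)) else
      utils::combn(seq_len(m - 1), k, simplify = FALSE)
    if (m - 1 < k) gap_sets <- list()
    for (first in c("P", "M")) {
      for (gaps in gap_sets) {
        blocks <- findInterval(seq_len(m), c(0.5, gaps + 0.5))
        mosaic <- ifelse(blocks %% 2 == 1, first, setdiff(c("P", "M"), first))
        if (all(mosaic == obs)) best <- list(k = k, gaps = gaps, first = first)
      }
    }
  }
  if (is.null(best)) return("AMBIGUOUS")
  pu <- locus$motifs$paternal_units[1]
  mu <- locus$motifs$maternal_units[1]
  m1 <- c(locus$motifs$pat_start[1], locus$motifs$pat_end[1])
  co2 <- locus$co2_region
  iv_of <- function(g) c(mk$pat_end[usable[g]], mk$pat_start[usable[g + 1]])
  is_co1 <- function(iv) iv[1] <= m1[1] && m1[2] <= iv[2]
  is_co2 <- function(iv) co2[1] <= iv[1] && iv[2] <= co2[2]
  if (best$k == 0) {
    parent <- best$first
    if (!is.na(motif1_units) && motif1_units != pu && motif1_units != mu)
      return("INTRA_ALLELIC")
    own <- if (parent == "P") pu else mu
    if (is.na(motif1_units) || motif1_units == own)
      return(if (parent == "P") "PD" else "MD")
    return("AMBIGUOUS")
  }
  if (best$k == 1) {
    iv <- iv_of(best$gaps[1])
    if (is_co1(iv)) return("CO_I")
    if (is_co2(iv)) return("CO_II")
    return("AMBIGUOUS")
  }
  iv1 <- iv_of(best$gaps[1]); iv2 <- iv_of(best$gaps[2])
  if (is_co1(iv1) && is_co2(iv2)) return("CO_I_II")
  "AMBIGUOUS"
}
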