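# Anchor-based extraction of diagnostic markers and repeat tracts from cloned
# amplicon sequences. Extraction is a three-step search per anchor: exact
# k-mer match, approximate match (<= 2 mismatches), then coordinates mapped
# through a global alignment to the closer parental reference. This keeps
# calls local: a mutation that destroys one anchor affects only the markers
# that depend on it.

#' Globally align a clone to a parental reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties (via
#' \code{\link[Biostrings]{pairwiseAlignment}}), wrapped with a coordinate map
#' so that any interval on the reference can be projected onto the clone.
#'
#' @param clone_seq,parent_seq nucleotide strings (A/C/G/T/N).
#' @return an object of class \code{parent_alignment} with elements
#'   \code{score}, \code{pid} (percent identity), \code{edits} (edit count
#'   over aligned columns) and \code{map_interval(start, end)} projecting a
#'   0-based half-open reference interval to clone coordinates (NA if the
#'   interval falls in a deletion).
#' @export
align_to_parent <- function(clone_seq, parent_seq) {
  check_dna <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
      stop(sprintf("%s must be a non-empty nucleotide string", what))
    if (grepl("[^ACGTNacgtn]", x))
      stop(sprintf("%s contains characters outside A/C/G/T/N", what))
  }
  check_dna(clone_seq, "clone_seq")
  check_dna(parent_seq, "parent_seq")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(clone_seq)),
    Biostrings::DNAString(toupper(parent_seq)),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 1)
  qg <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sg <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  q_nongap <- qg != "-"
  s_nongap <- sg != "-"
  qpos <- cumsum(q_nongap)                # clone position at each column
  # ref_to_clone[i]: 0-based clone offset aligned to 0-based ref offset i-1
  ref_to_clone <- rep(NA_integer_, sum(s_nongap))
  ref_to_clone[cumsum(s_nongap)[s_nongap & q_nongap]] <-
    qpos[s_nongap & q_nongap] - 1L
  n_edit <- sum(!q_nongap | !s_nongap | qg != sg)
  # identity over all alignment columns, so truncations and long gaps count
  ident <- 100 * (length(qg) - n_edit) / length(qg)
  map_interval <- function(start, end) {
    # 0-based half-open; projects interval ends through the alignment
    if (start < 0 || end > length(ref_to_clone) || start > end)
      return(c(NA_integer_, NA_integer_))
    if (start == end) {
      p <- if (start < length(ref_to_clone)) ref_to_clone[start + 1L] else NA_integer_
      return(c(p, p))
    }
    left <- ref_to_clone[(start + 1L):end]
    left <- left[!is.na(left)]
    if (length(left) == 0) return(c(NA_integer_, NA_integer_))
    c(left[1], left[length(left)] + 1L)
  }
  structure(list(
    score = Biostrings::score(al),
    pid = ident,
    edits = n_edit,
    map_interval = map_interval
  ), class = "parent_alignment")
}

# Exact then approximate search for an anchor k-mer; returns the 0-based
# start or NA. Requires a unique hit at each level.
find_anchor <- function(clone_seq, anchor, max_mismatch = 2L) {
  m <- gregexpr(anchor, clone_seq, fixed = TRUE)[[1]]
  if (m[1] != -1L && length(m) == 1L) return(as.integer(m[1]) - 1L)
  if (m[1] != -1L) return(NA_integer_)  # non-unique exact hit
  hits <- Biostrings::matchPattern(anchor, Biostrings::DNAString(clone_seq),
                                   max.mismatch = max_mismatch)
  if (length(hits) == 1L) return(Biostrings::start(hits)[1] - 1L)
  NA_integer_
}

# Decide whether a clone is reverse-complemented relative to the locus by
# voting with exact anchor hits on both strands. A handful of well-spread
# anchors decides the common case; the full panel breaks near-ties.
orient_clone <- function(clone_seq, locus) {
  anchors <- c(locus$elements$anchor_left, locus$elements$anchor_right)
  probe <- anchors[unique(round(seq(1, length(anchors), length.out = 5)))]
  fwd <- sum(vapply(probe, function(a) count_fixed(a, clone_seq) == 1L, TRUE))
  if (fwd >= 4L) return(clone_seq)
  fwd_all <- sum(vapply(anchors, function(a) count_fixed(a, clone_seq) == 1L, TRUE))
  if (fwd_all > length(anchors) / 2) return(clone_seq)
  rc <- revcomp(clone_seq)
  rev_all <- sum(vapply(anchors, function(a) count_fixed(a, rc) == 1L, TRUE))
  if (rev_all > fwd_all) rc else clone_seq
}

# Resolve both anchors of each requested element, using alignment fallback
# lazily (both parental alignments computed at most once per clone).
resolve_anchors <- function(clone_seq, locus, element_ids) {
  tab <- locus$elements
  k <- locus$anchor_k
  rows <- match(element_ids, tab$element_id)
  res <- lapply(rows, function(i) {
    list(left = find_anchor(clone_seq, tab$anchor_left[i]),
         right = find_anchor(clone_seq, tab$anchor_right[i]))
  })
  names(res) <- element_ids
  unresolved <- vapply(res, function(r) is.na(r$left) || is.na(r$right), TRUE)
  if (any(unresolved)) {
    alp <- tryCatch(align_to_parent(clone_seq, locus$paternal_seq), error = function(e) NULL)
    alm <- tryCatch(align_to_parent(clone_seq, locus$maternal_seq), error = function(e) NULL)
    use_pat <- !is.null(alp) && (is.null(alm) || alp$score >= alm$score)
    al <- if (use_pat) alp else alm
    if (!is.null(al) && al$pid >= 50) {
      for (j in which(unresolved)) {
        i <- rows[j]
        s <- if (use_pat) tab$pat_start[i] else tab$mat_start[i]
        e <- if (use_pat) tab$pat_end[i] else tab$mat_end[i]
        if (is.na(res[[j]]$left)) {
          iv <- al$map_interval(s - k, s)
          if (!any(is.na(iv)) && iv[2] - iv[1] == k) res[[j]]$left <- iv[1]
        }
        if (is.na(res[[j]]$right)) {
          iv <- al$map_interval(e, e + k)
          if (!any(is.na(iv)) && iv[2] - iv[1] == k) res[[j]]$right <- iv[1]
        }
      }
    }
  }
  res
}

# Allele comparison rules: SNP alleles must match exactly; indel alleles may
# carry one substitution provided the length matches (sequencing error must
# not flip an indel call).
allele_matches <- function(observed, allele, kind) {
  if (nchar(observed) != nchar(allele)) return(FALSE)
  if (kind == "snp" || nchar(allele) <= 1L) return(observed == allele)
  if (observed == allele) return(TRUE)
  sum(strsplit(observed, "")[[1]] != strsplit(allele, "")[[1]]) <= 1L
}

#' Call parental origin of every diagnostic marker in a clone
#'
#' Locates each marker's conserved anchors in the clone, extracts the
#' enclosed allele and compares it with the two parental alleles.
#'
#' @param clone_seq a nucleotide string (one cloned amplicon).
#' @param locus a validated \code{locus_reference}.
#' @return a data frame with one row per marker, in locus (5'->3') order:
#'   \code{marker_id}, \code{call} (\code{P}, \code{M}, \code{ambiguous} or
#'   \code{missing}), \code{observed_allele}, \code{anchor_left_found},
#'   \code{anchor_right_found}.
#' @export
call_markers <- function(clone_seq, locus) {
  stopifnot(inherits(locus, "locus_reference"))
  analyze_clone(orient_clone(toupper(clone_seq), locus), locus)$calls
}

# One pass over an already-oriented clone: resolve all marker and motif
# anchors together (sharing the alignment fallback), then derive marker
# calls and repeat measurements.
analyze_clone <- function(clone_seq, locus) {
  mk <- locus$markers
  mo <- locus$motifs
  k <- locus$anchor_k
  anch <- resolve_anchors(clone_seq, locus, c(mk$element_id, mo$element_id))
  nm <- nrow(mk)
  call <- rep("missing", nm)
  observed <- rep(NA_character_, nm)
  l_found <- r_found <- logical(nm)
  max_allele <- pmax(nchar(mk$pat_allele), nchar(mk$mat_allele))
  for (i in seq_len(nm)) {
    a <- anch[[i]]
    l_found[i] <- !is.na(a$left)
    r_found[i] <- !is.na(a$right)
    if (is.na(a$left) || is.na(a$right)) next
    lo <- a$left + k          # 0-based start of enclosed allele
    hi <- a$right             # 0-based end (exclusive)
    if (hi < lo || hi - lo > max_allele[i] + 10L) next  # implausible layout
    obs <- substr(clone_seq, lo + 1L, hi)
    p_ok <- allele_matches(obs, mk$pat_allele[i], mk$kind[i])
    m_ok <- allele_matches(obs, mk$mat_allele[i], mk$kind[i])
    observed[i] <- obs
    call[i] <- if (p_ok && !m_ok) "P" else if (m_ok && !p_ok) "M" else "ambiguous"
  }
  calls <- quick_df(list(marker_id = mk$element_id, call = call,
                         observed_allele = observed,
                         anchor_left_found = l_found,
                         anchor_right_found = r_found))
  nmo <- nrow(mo)
  units <- rep(NA_integer_, nmo)
  for (j in seq_len(nmo)) {
    a <- anch[[nm + j]]
    if (is.na(a$left) || is.na(a$right) || a$right < a$left + k) next
    # unit count from tract length: a trailing odd nucleotide is not counted,
    # and interrupting substitutions / strand do not change the count
    units[j] <- (a$right - (a$left + k)) %/% nchar(mo$unit[j])
  }
  matches <- ifelse(is.na(units), "missing",
                    ifelse(units == mo$paternal_units, "paternal_count",
                           ifelse(units == mo$maternal_units, "maternal_count", "other")))
  nearest <- ifelse(abs(units - mo$paternal_units) <= abs(units - mo$maternal_units),
                    mo$paternal_units, mo$maternal_units)
  reps <- quick_df(list(motif_id = mo$element_id,
                        observed_units = units,
                        matches = matches,
                        delta_vs_nearest_parent = as.integer(units - nearest)))
  list(calls = calls, repeats = reps)
}

# Unit count from resolved anchors, single-motif variant.
measurement_from_anchors <- function(clone_seq, mo, a, k) {
  if (is.na(a$left) || is.na(a$right) || a$right < a$left + k) {
    return(data.frame(motif_id = mo$element_id, observed_units = NA_integer_,
                      matches = "missing", delta_vs_nearest_parent = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  len <- a$right - (a$left + k)
  units <- len %/% nchar(mo$unit)   # a trailing odd nucleotide is not counted
  matches <- if (units == mo$paternal_units) "paternal_count"
  else if (units == mo$maternal_units) "maternal_count"
  else "other"
  nearest <- if (abs(units - mo$paternal_units) <= abs(units - mo$maternal_units))
    mo$paternal_units else mo$maternal_units
  data.frame(motif_id = mo$element_id, observed_units = as.integer(units),
             matches = matches,
             delta_vs_nearest_parent = as.integer(units - nearest),
             stringsAsFactors = FALSE)
}

#' Measure a repeat tract's unit count in a clone
#'
#' Counts whole repeat units between the motif's conserved anchors.
#' Reverse-oriented motifs are measured on the reverse complement of the
#' enclosed substring, so the count is strand-symmetric. Length-preserving
#' interrupting substitutions do not change the count (units are derived from
#' tract length, which interruptions preserve).
#'
#' @param clone_seq a nucleotide string.
#' @param motif_id id of the motif to measure (e.g. \code{"motif1"}).
#' @param locus a validated \code{locus_reference}.
#' @return a one-row data frame: \code{motif_id}, \code{observed_units}
#'   (NA if an anchor could not be located), \code{matches}
#'   (\code{paternal_count}, \code{maternal_count} or \code{other}),
#'   \code{delta_vs_nearest_parent}.
#' @export
measure_repeat <- function(clone_seq, motif_id, locus) {
  stopifnot(inherits(locus, "locus_reference"))
  mo <- locus$motifs[locus$motifs$element_id == motif_id, ]
  if (nrow(mo) != 1L) stop(sprintf("unknown motif id: %s", motif_id))
  clone_seq <- orient_clone(toupper(clone_seq), locus)
  a <- resolve_anchors(clone_seq, locus, motif_id)[[1]]
  measurement_from_anchors(clone_seq, mo, a, locus$anchor_k)
}

#' Measure all repeat motifs of the locus in a clone
#'
#' @inheritParams measure_repeat
#' @return a data frame with one row per motif (see [measure_repeat()]).
#' @export
measure_repeats <- function(clone_seq, locus) {
  stopifnot(inherits(locus, "locus_reference"))
  analyze_clone(orient_clone(toupper(clone_seq), locus), locus)$repeats
}
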