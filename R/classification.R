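# Clone taxonomy: parental (PD/MD), crossover around motif 1 (CO_I),
# crossover between motifs 2 and 3 (CO_II), short-segment exchange from
# co-occurring crossovers (CO_I_II), intra-allelic PCR artifact
# (INTRA_ALLELIC) and AMBIGUOUS. Classification is by minimal-switch
# parsimony over the ordered parental-origin calls, with breakpoint
# intervals reported in the anchor frame (paternal-reference coordinates
# of the conserved anchors).

CLONE_CLASSES <- c("PD", "MD", "CO_I", "CO_II", "CO_I_II",
                   "INTRA_ALLELIC", "AMBIGUOUS")
HR_CLASSES <- c("CO_I", "CO_II", "CO_I_II")

# region containment in the anchor frame; intervals are 0-based half-open
contains_interval <- function(outer, inner) {
  outer[1] <= inner[1] && inner[2] <= outer[2]
}

#' Classify one clone from its marker calls and repeat measurements
#'
#' Counts parental-origin switches over the usable (non-missing,
#' non-ambiguous) marker calls, in 5'->3' order. Zero switches give a
#' parental clone (PD or MD) unless the motif-1 unit count matches neither
#' parent, in which case the clone is an intra-allelic PCR artifact. One
#' switch is a crossover-I clone when the switch interval contains motif 1,
#' a crossover-II clone when it lies between motifs 2 and 3, and AMBIGUOUS
#' anywhere else. Two switches returning to the flanking parent are the
#' co-occurring crossover class when the first interval is a crossover-I
#' site and the second a crossover-II site. More than two switches, or more
#' than a third of markers unusable, is AMBIGUOUS. Breakpoint intervals are
#' the open gaps between the last marker before and the first marker after
#' each switch.
#'
#' @param calls marker-call data frame from [call_markers()] (one row per
#'   locus marker, locus order).
#' @param repeats repeat-measurement data frame from [measure_repeats()].
#' @param locus a validated \code{locus_reference}.
#' @return an object of class \code{clone_classification}: a list with
#'   \code{clone_class}, \code{n_switches}, \code{breakpoint_intervals}
#'   (list of length-2 vectors, anchor frame), \code{motif1_measurement},
#'   \code{excluded} (TRUE for artifact/ambiguous clones, which are kept in
#'   outputs but left out of HR statistics) and the input \code{calls}.
#' @export
classify_clone <- function(calls, repeats, locus) {
  stopifnot(inherits(locus, "locus_reference"))
  mk <- locus$markers
  if (!identical(calls$marker_id, mk$element_id))
    stop(errorCondition("marker calls do not match the locus marker set",
                        class = c("gtrecomb_input_mismatch_error", "gtrecomb_error")))
  m1 <- repeats[repeats$motif_id == "motif1", , drop = FALSE]
  if (nrow(m1) == 0)
    m1 <- data.frame(motif_id = "motif1", observed_units = NA_integer_,
                     matches = "missing", delta_vs_nearest_parent = NA_integer_,
                     stringsAsFactors = FALSE)

  res <- function(clone_class, n_switches = 0L, intervals = list()) {
    structure(list(clone_class = clone_class,
                   n_switches = n_switches,
                   breakpoint_intervals = intervals,
                   motif1_measurement = m1,
                   excluded = clone_class %in% c("INTRA_ALLELIC", "AMBIGUOUS"),
                   calls = calls),
              class = "clone_classification")
  }

  n <- nrow(calls)
  usable <- calls$call %in% c("P", "M")
  if (sum(!usable) > ceiling(n / 3) || sum(usable) == 0L)
    return(res("AMBIGUOUS"))

  idx <- which(usable)
  orig <- calls$call[idx]
  runs <- rle(orig)
  n_sw <- length(runs$values) - 1L

  # anchor-frame gap between the usable markers flanking each switch
  switch_intervals <- function() {
    ends <- cumsum(runs$lengths)
    lapply(seq_len(n_sw), function(s) {
      left <- idx[ends[s]]
      right <- idx[ends[s] + 1L]
      c(mk$pat_end[left], mk$pat_start[right])
    })
  }

  motif1_iv <- c(locus$motifs$pat_start[1], locus$motifs$pat_end[1])
  co2_region <- locus$co2_region

  if (n_sw == 0L) {
    parent <- runs$values[1]
    if (m1$matches == "other") return(res("INTRA_ALLELIC"))
    own <- if (parent == "P") "paternal_count" else "maternal_count"
    if (m1$matches %in% c(own, "missing")) {
      return(res(if (parent == "P") "PD" else "MD"))
    }
    # uniparental markers but the other parent's exact repeat count: neither
    # a clean parental clone nor the artifact signature
    return(res("AMBIGUOUS"))
  }

  if (n_sw == 1L) {
    iv <- switch_intervals()
    if (contains_interval(iv[[1]], motif1_iv)) return(res("CO_I", 1L, iv))
    if (contains_interval(co2_region, iv[[1]])) return(res("CO_II", 1L, iv))
    return(res("AMBIGUOUS", 1L, iv))
  }

  if (n_sw == 2L) {
    iv <- switch_intervals()
    # with two switches the run pattern is necessarily flank-X/middle-Y/flank-X
    if (contains_interval(iv[[1]], motif1_iv) &&
        contains_interval(co2_region, iv[[2]]))
      return(res("CO_I_II", 2L, iv))
    return(res("AMBIGUOUS", 2L, iv))
  }

  res("AMBIGUOUS", n_sw, switch_intervals())
}

#' @export
print.clone_classification <- function(x, ...) {
  ivs <- vapply(x$breakpoint_intervals, function(iv)
    sprintf("[%d,%d)", iv[1], iv[2]), "")
  cat(sprintf("<clone_classification> %s  switches: %d  motif1: %s units (%s)%s\n",
              x$clone_class, x$n_switches,
              ifelse(is.na(x$motif1_measurement$observed_units), "NA",
                     x$motif1_measurement$observed_units),
              x$motif1_measurement$matches,
              if (length(ivs)) paste0("  breakpoints: ", paste(ivs, collapse = " ")) else ""))
  invisible(x)
}

#' Infer which homolog carried the double-strand break in a crossover-I clone
#'
#' In a crossover-I clone the repeat tract of motif 1 reports the repair
#' template: a clone carrying the maternal unit count implies a break on the
#' paternal homolog repaired from the maternal chromosome, and vice versa.
#' Counts matching neither parent leave the origin indeterminate.
#'
#' @param classification a \code{clone_classification} with
#'   \code{clone_class == "CO_I"}.
#' @param locus a validated \code{locus_reference}.
#' @return a list with \code{origin} (\code{dsb_paternal},
#'   \code{dsb_maternal} or \code{indeterminate}) and \code{basis}
#'   (\code{units_equal_maternal}, \code{units_equal_paternal},
#'   \code{contracted}, \code{expanded} or \code{missing}).
#' @export
infer_dsb_origin <- function(classification, locus) {
  stopifnot(inherits(classification, "clone_classification"))
  if (classification$clone_class != "CO_I")
    stop(errorCondition("DSB origin is inferred for crossover-I clones only",
                        class = c("gtrecomb_contract_error", "gtrecomb_error")))
  units <- classification$motif1_measurement$observed_units
  pu <- locus$motifs$paternal_units[1]
  mu <- locus$motifs$maternal_units[1]
  if (is.na(units))
    return(list(origin = "indeterminate", basis = "missing"))
  if (units == mu) return(list(origin = "dsb_paternal", basis = "units_equal_maternal"))
  if (units == pu) return(list(origin = "dsb_maternal", basis = "units_equal_paternal"))
  if (units < min(pu, mu))
    return(list(origin = "indeterminate", basis = "contracted"))
  list(origin = "indeterminate", basis = "expanded")
}

#' Classify a set of clones end to end
#'
#' Runs marker calling, repeat measurement, classification and (for
#' crossover-I clones) DSB-origin inference on every clone, returning one
#' tabular row per clone.
#'
#' @param clones a named character vector or
#'   \code{\link[Biostrings]{DNAStringSet}} of clone sequences. Names may
#'   carry \code{key=value} metadata after the clone id (e.g.
#'   \code{"cl0001 sample=embryo_4d individual=i1"}).
#' @param locus a validated \code{locus_reference}.
#' @param metadata optional data frame with columns \code{clone_id} and any
#'   of \code{sample}, \code{individual}; overrides header metadata.
#' @param detail if TRUE, also return the per-clone marker-call and
#'   repeat-measurement tables.
#' @return a data frame with columns clone_id, sample, individual,
#'   clone_class, n_switches, breakpoints (anchor-frame intervals as
#'   \code{"start-end"}, ;-separated), motif1_units, motif1_matches,
#'   dsb_origin, dsb_basis, excluded. With \code{detail = TRUE}, a list
#'   \code{(classifications, marker_calls, repeats)}.
#' @export
classify_clones <- function(clones, locus, metadata = NULL, detail = FALSE) {
  if (inherits(clones, "DNAStringSet")) {
    seqs <- as.character(clones)
  } else {
    seqs <- clones
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("clone%04d", seq_along(seqs))
  meta <- parse_clone_headers(names(seqs))
  if (!is.null(metadata)) {
    i <- match(meta$clone_id, metadata$clone_id)
    for (col in intersect(c("sample", "individual"), names(metadata))) {
      hit <- !is.na(i)
      meta[[col]][hit] <- metadata[[col]][i[hit]]
    }
  }
  n <- length(seqs)
  clone_class <- character(n)
  n_switches <- rep(NA_integer_, n)
  breakpoints <- character(n)
  motif1_units <- rep(NA_integer_, n)
  motif1_matches <- rep("missing", n)
  dsb_origin <- rep(NA_character_, n)
  dsb_basis <- rep(NA_character_, n)
  excluded <- logical(n)
  all_calls <- if (detail) vector("list", n)
  all_reps <- if (detail) vector("list", n)
  for (j in seq_len(n)) {
    s <- toupper(seqs[[j]])
    if (nchar(s) == 0L || grepl("[^ACGTN]", s)) {
      warning(sprintf("clone %s: empty or non-ACGTN sequence; classified AMBIGUOUS",
                      meta$clone_id[j]))
      clone_class[j] <- "AMBIGUOUS"
      excluded[j] <- TRUE
      next
    }
    s <- orient_clone(s, locus)
    an <- analyze_clone(s, locus)
    cl <- classify_clone(an$calls, an$repeats, locus)
    clone_class[j] <- cl$clone_class
    n_switches[j] <- cl$n_switches
    breakpoints[j] <- paste(vapply(cl$breakpoint_intervals, function(iv)
      sprintf("%d-%d", iv[1], iv[2]), ""), collapse = ";")
    motif1_units[j] <- cl$motif1_measurement$observed_units
    motif1_matches[j] <- cl$motif1_measurement$matches
    excluded[j] <- cl$excluded
    if (cl$clone_class == "CO_I") {
      dsb <- infer_dsb_origin(cl, locus)
      dsb_origin[j] <- dsb$origin
      dsb_basis[j] <- dsb$basis
    }
    if (detail) {
      all_calls[[j]] <- an$calls
      all_reps[[j]] <- an$repeats
    }
  }
  classifications <- cbind(meta, quick_df(list(
    clone_class = clone_class, n_switches = n_switches,
    breakpoints = breakpoints, motif1_units = motif1_units,
    motif1_matches = motif1_matches, dsb_origin = dsb_origin,
    dsb_basis = dsb_basis, excluded = excluded)))
  if (!detail) return(classifications)
  bind_with_id <- function(lst) {
    keep <- !vapply(lst, is.null, TRUE)
    if (!any(keep)) return(NULL)
    per <- nrow(lst[which(keep)[1]][[1]])
    cbind(data.frame(clone_id = rep(meta$clone_id[keep], each = per),
                     stringsAsFactors = FALSE),
          do.call(rbind, lst[keep]))
  }
  list(classifications = classifications,
       marker_calls = bind_with_id(all_calls),
       repeats = bind_with_id(all_reps))
}

# ">id key=value ..." header convention used by the simulator and CLI
parse_clone_headers <- function(headers) {
  parts <- strsplit(headers, "\\s+")
  get_kv <- function(p, key) {
    hit <- grep(paste0("^", key, "="), p, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
  }
  data.frame(
    clone_id = vapply(parts, function(p) p[1], ""),
    sample = vapply(parts, get_kv, "", key = "sample"),
    individual = vapply(parts, get_kv, "", key = "individual"),
    stringsAsFactors = FALSE
  )
}

#' Distribution of motif-1 unit counts among HR clones
#'
#' Tabulates the motif-1 repeat length observed in homologous-recombination
#' clones (crossover classes), optionally split by sample origin, and reports
#' the fraction of clones at the maternal count, at the paternal count and
#' elsewhere. Fractions are over clones with a non-missing measurement and
#' sum to one.
#'
#' @param classifications data frame from [classify_clones()].
#' @param locus a validated \code{locus_reference}.
#' @param by optional column of \code{classifications} to split by
#'   (e.g. \code{"sample"}); \code{NULL} pools all clones.
#' @return a list with \code{histogram} (group, observed_units, n, fraction)
#'   and \code{summary} (group, n, frac_maternal_count, frac_paternal_count,
#'   frac_other).
#' @export
summarize_repeat_distribution <- function(classifications, locus, by = NULL) {
  hr <- classifications[classifications$clone_class %in% HR_CLASSES &
                          !is.na(classifications$motif1_units), , drop = FALSE]
  group <- if (is.null(by)) rep("all", nrow(hr)) else hr[[by]]
  if (nrow(hr) == 0) {
    return(list(histogram = data.frame(group = character(), observed_units = integer(),
                                       n = integer(), fraction = numeric()),
                summary = data.frame(group = character(), n = integer(),
                                     frac_maternal_count = numeric(),
                                     frac_paternal_count = numeric(),
                                     frac_other = numeric())))
  }
  pu <- locus$motifs$paternal_units[1]
  mu <- locus$motifs$maternal_units[1]
  hist <- as.data.frame(table(group = group, observed_units = hr$motif1_units),
                        stringsAsFactors = FALSE)
  names(hist)[3] <- "n"
  hist <- hist[hist$n > 0, ]
  hist$observed_units <- as.integer(hist$observed_units)
  tot <- tapply(hist$n, hist$group, sum)
  hist$fraction <- hist$n / as.vector(tot[hist$group])
  hist <- hist[order(hist$group, hist$observed_units), , drop = FALSE]
  summ <- do.call(rbind, lapply(sort(unique(group)), function(g) {
    u <- hr$motif1_units[group == g]
    data.frame(group = g, n = length(u),
               frac_maternal_count = mean(u == mu),
               frac_paternal_count = mean(u == pu),
               frac_other = mean(u != mu & u != pu),
               stringsAsFactors = FALSE)
  }))
  rownames(hist) <- rownames(summ) <- NULL
  list(histogram = hist, summary = summ)
}
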