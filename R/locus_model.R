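#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

locus_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gtrecomb_error")))
}

#' Default two-parent locus specification
#'
#' Builds the specification of a heterozygous ~2.6 kb promoter locus carrying
#' three GT-dinucleotide microsatellite motifs and the diagnostic markers that
#' distinguish the two parental haplotypes: a 39-bp indel upstream of motif 1,
#' two SNPs and a 3-bp indel between motifs 1 and 2, three diversified markers
#' between motifs 2 and 3, and one marker downstream of motif 3. Motif 1 is
#' long and imperfect (one interrupting substitution per parent) with unequal
#' parental unit counts; motif 2 is reverse-oriented on the reference strand;
#' motif 3 is short. Conserved spacer sequences are generated deterministically
#' from \code{seed}, so the default locus is identical across sessions.
#'
#' @param seed integer seed for the conserved spacer sequences (fixed default
#'   so that the emulated locus is reproducible).
#' @param motif1_paternal_units,motif1_maternal_units GT unit counts of motif 1
#'   (defaults 84 and 36, i.e. tracts of about 168 nt and 72 nt).
#' @param motif2_units,motif3_units unit counts of the two short downstream
#'   motifs (equal in both parents).
#' @param ins39_parent which parent carries the 39-bp insertion allele.
#' @param ins3_parent which parent carries the 3-bp insertion allele.
#' @param anchor_k length in nt of the conserved anchor k-mers flanking each
#'   marker and motif.
#' @return a locus specification list consumable by [load_locus_spec()].
#' @export
default_locus_spec <- function(seed = 20180511,
                               motif1_paternal_units = 84,
                               motif1_maternal_units = 36,
                               motif2_units = 12,
                               motif3_units = 10,
                               ins39_parent = c("paternal", "maternal"),
                               ins3_parent = c("maternal", "paternal"),
                               anchor_k = 20) {
  ins39_parent <- match.arg(ins39_parent)
  ins3_parent <- match.arg(ins3_parent)
  with_seed(seed, {
    spacer_len <- c(300, 300, 150, 100, 100, 250, 200, 180, 160, 150, 250, 200)
    spacers <- lapply(spacer_len, random_dna)
    ins39 <- random_dna(39)
    ins3 <- random_dna(3)
    ins5 <- random_dna(5)

    indel_alleles <- function(ins, carrier) {
      if (carrier == "paternal") list(paternal = ins, maternal = "")
      else list(paternal = "", maternal = ins)
    }
    a39 <- indel_alleles(ins39, ins39_parent)
    a3 <- indel_alleles(ins3, ins3_parent)

    marker <- function(id, kind, segment, paternal, maternal) {
      list(id = id, type = "marker", kind = kind, segment = segment,
           paternal = paternal, maternal = maternal)
    }
    motif <- function(id, unit, orientation, pat_units, mat_units,
                      interruptions = list()) {
      list(id = id, type = "motif", unit = unit, orientation = orientation,
           paternal_units = pat_units, maternal_units = mat_units,
           interruptions = interruptions)
    }
    spacer <- function(id, seq) list(id = id, type = "spacer", seq = seq)

    list(
      locus_id = "gt3_promoter_emulation",
      anchor_k = anchor_k,
      elements = list(
        spacer("sp01", spacers[[1]]),
        marker("ind39", "indel", "upstream_of_motif1", a39$paternal, a39$maternal),
        spacer("sp02", spacers[[2]]),
        motif("motif1", "GT", "forward",
              motif1_paternal_units, motif1_maternal_units,
              interruptions = list(
                paternal = list(list(unit = 42, pos = 2, base = "A")),
                maternal = list(list(unit = 18, pos = 2, base = "A")))),
        spacer("sp03", spacers[[3]]),
        marker("snpA", "snp", "between_motif1_and_motif2", "A", "G"),
        spacer("sp04", spacers[[4]]),
        marker("snpB", "snp", "between_motif1_and_motif2", "C", "T"),
        spacer("sp05", spacers[[5]]),
        marker("ind3", "indel", "between_motif1_and_motif2", a3$paternal, a3$maternal),
        spacer("sp06", spacers[[6]]),
        motif("motif2", "GT", "reverse", motif2_units, motif2_units),
        spacer("sp07", spacers[[7]]),
        marker("snpC", "snp", "between_motif2_and_motif3", "G", "A"),
        spacer("sp08", spacers[[8]]),
        marker("ind5", "indel", "between_motif2_and_motif3", ins5, ""),
        spacer("sp09", spacers[[9]]),
        marker("snpE", "snp", "between_motif2_and_motif3", "T", "C"),
        spacer("sp10", spacers[[10]]),
        motif("motif3", "GT", "forward", motif3_units, motif3_units),
        spacer("sp11", spacers[[11]]),
        marker("snpF", "snp", "downstream_of_motif3", "A", "C"),
        spacer("sp12", spacers[[12]])
      )
    )
  })
}

# Render one motif tract for one parent, on the reference strand.
render_tract <- function(el, parent) {
  units <- if (parent == "paternal") el$paternal_units else el$maternal_units
  tract <- strrep(el$unit, units)
  ints <- el$interruptions[[parent]]
  if (!is.null(ints)) {
    chars <- strsplit(tract, "")[[1]]
    for (it in ints) {
      idx <- (it$unit - 1L) * nchar(el$unit) + it$pos
      if (idx >= 1 && idx <= length(chars)) chars[idx] <- it$base
    }
    tract <- paste(chars, collapse = "")
  }
  if (identical(el$orientation, "reverse")) tract <- revcomp(tract)
  tract
}

element_allele <- function(el, parent) {
  switch(el$type,
    spacer = el$seq,
    marker = if (parent == "paternal") el$paternal else el$maternal,
    motif = render_tract(el, parent))
}

count_fixed <- function(pattern, subject) {
  if (nchar(pattern) == 0) return(0L)
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Load and validate a locus specification
#'
#' Renders both parental haplotype sequences from a locus specification,
#' derives per-element coordinate tables (0-based, half-open) and conserved
#' anchor k-mers, and validates the layout: alleles must differ at every
#' marker, anchors must occur exactly once in each parental sequence, every
#' marker and motif must be bracketed by conserved spacers at least one anchor
#' long, and each of the four segments used for crossover typing (upstream of
#' motif 1, motif 1 to motif 2, motif 2 to motif 3, downstream of motif 3)
#' must carry at least one marker.
#'
#' Breakpoint intervals reported downstream are expressed in the anchor frame:
#' coordinates on the rendered paternal sequence, whose conserved anchors are
#' shared with the maternal sequence, so indel length differences between the
#' parents do not shift interval semantics.
#'
#' @param spec a specification list as produced by [default_locus_spec()] or
#'   [read_locus_spec()], or a path to a YAML file containing one.
#' @return an object of class \code{locus_reference}.
#' @export
load_locus_spec <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) spec <- read_locus_spec(spec)
  stopifnot(is.list(spec), !is.null(spec$elements))
  k <- spec$anchor_k %||% 20L
  els <- spec$elements
  types <- vapply(els, function(e) e$type, "")
  ids <- vapply(els, function(e) e$id, "")
  if (anyDuplicated(ids))
    locus_error("duplicate element ids in locus spec", "gtrecomb_layout_error")

  for (i in seq_along(els)) {
    el <- els[[i]]
    if (el$type == "spacer") next
    if (el$type == "marker") {
      if (identical(el$paternal, el$maternal))
        locus_error(sprintf("marker %s: paternal and maternal alleles identical", el$id),
                    "gtrecomb_layout_error")
      if (el$kind == "snp" && (nchar(el$paternal) != 1L || nchar(el$maternal) != 1L))
        locus_error(sprintf("marker %s: snp alleles must have length 1", el$id),
                    "gtrecomb_layout_error")
    }
    if (el$type == "motif") {
      if (el$paternal_units < 1L || el$maternal_units < 1L)
        locus_error(sprintf("motif %s: unit counts must be >= 1", el$id),
                    "gtrecomb_layout_error")
      if (nchar(el$unit) != 2L)
        locus_error(sprintf("motif %s: unit must be a dinucleotide", el$id),
                    "gtrecomb_layout_error")
    }
    # every marker/motif needs conserved flanks long enough to host anchors
    left_ok <- i > 1L && types[i - 1L] == "spacer" && nchar(els[[i - 1L]]$seq) >= k
    right_ok <- i < length(els) && types[i + 1L] == "spacer" && nchar(els[[i + 1L]]$seq) >= k
    if (!left_ok || !right_ok)
      locus_error(sprintf("element %s lacks a conserved flank of >= %d nt", el$id, k),
                  "gtrecomb_layout_error")
  }

  n_motifs <- sum(types == "motif")
  if (n_motifs != 3L)
    locus_error("locus must define exactly three repeat motifs", "gtrecomb_layout_error")

  render_one <- function(parent) {
    pieces <- vapply(els, element_allele, "", parent = parent)
    seq <- paste(pieces, collapse = "")
    start <- cumsum(c(0L, nchar(pieces)[-length(pieces)]))
    data.frame(element_id = ids, type = types,
               start = start, end = start + nchar(pieces),
               allele = pieces, stringsAsFactors = FALSE, row.names = NULL)
  }
  pat <- render_one("paternal")
  mat <- render_one("maternal")
  paternal_seq <- paste(pat$allele, collapse = "")
  maternal_seq <- paste(mat$allele, collapse = "")

  keep <- types != "spacer"
  tab <- data.frame(
    element_id = ids[keep], type = types[keep],
    kind = vapply(els[keep], function(e) e$kind %||% NA_character_, ""),
    segment = vapply(els[keep], function(e) e$segment %||% NA_character_, ""),
    unit = vapply(els[keep], function(e) e$unit %||% NA_character_, ""),
    orientation = vapply(els[keep], function(e) e$orientation %||% NA_character_, ""),
    paternal_units = vapply(els[keep], function(e) as.integer(e$paternal_units %||% NA), 1L),
    maternal_units = vapply(els[keep], function(e) as.integer(e$maternal_units %||% NA), 1L),
    pat_start = pat$start[keep], pat_end = pat$end[keep],
    mat_start = mat$start[keep], mat_end = mat$end[keep],
    pat_allele = pat$allele[keep], mat_allele = mat$allele[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  # anchors: conserved k-mers immediately flanking each element, read off the
  # paternal rendering and verified identical in the maternal one
  tab$anchor_left <- substring(paternal_seq, tab$pat_start - k + 1L, tab$pat_start)
  tab$anchor_right <- substring(paternal_seq, tab$pat_end + 1L, tab$pat_end + k)
  mat_left <- substring(maternal_seq, tab$mat_start - k + 1L, tab$mat_start)
  mat_right <- substring(maternal_seq, tab$mat_end + 1L, tab$mat_end + k)
  if (!all(tab$anchor_left == mat_left) || !all(tab$anchor_right == mat_right))
    locus_error("flanking anchors are not conserved between parents",
                "gtrecomb_anchor_error")
  for (a in unique(c(tab$anchor_left, tab$anchor_right))) {
    if (count_fixed(a, paternal_seq) != 1L || count_fixed(a, maternal_seq) != 1L)
      locus_error(sprintf("anchor %s does not occur exactly once per parental sequence", a),
                  "gtrecomb_anchor_error")
  }

  segs <- c("upstream_of_motif1", "between_motif1_and_motif2",
            "between_motif2_and_motif3", "downstream_of_motif3")
  mk <- tab[tab$type == "marker", ]
  missing_segs <- setdiff(segs, mk$segment)
  if (length(missing_segs) > 0)
    locus_error(paste("no marker in segment(s):", paste(missing_segs, collapse = ", ")),
                "gtrecomb_insufficient_markers_error")

  # intervals must be strictly increasing and non-overlapping (paternal frame)
  if (any(diff(as.vector(rbind(tab$pat_start, tab$pat_end))) < 0))
    locus_error("element intervals overlap or are out of order", "gtrecomb_layout_error")

  mo <- tab[tab$type == "motif", ]
  up_mk <- mk[mk$segment == "upstream_of_motif1", ]
  mid_mk <- mk[mk$segment == "between_motif1_and_motif2", ]
  co1_region <- c(max(up_mk$pat_end), min(mid_mk$pat_start))
  co2_region <- c(mo$pat_end[2], mo$pat_start[3])

  structure(list(
    locus_id = spec$locus_id %||% "locus",
    anchor_k = k,
    spec = spec,
    paternal_seq = paternal_seq,
    maternal_seq = maternal_seq,
    elements = tab,
    markers = mk,
    motifs = mo,
    co1_region = co1_region,
    co2_region = co2_region,
    # per-piece renderings cached for the simulator's hot path
    piece_ids = ids,
    piece_pat = pat$allele,
    piece_mat = mat$allele
  ), class = "locus_reference")
}

#' @export
print.locus_reference <- function(x, ...) {
  cat(sprintf("<locus_reference> %s\n", x$locus_id))
  cat(sprintf("  paternal: %d nt   maternal: %d nt   anchor k-mer: %d nt\n",
              nchar(x$paternal_seq), nchar(x$maternal_seq), x$anchor_k))
  cat(sprintf("  markers: %d   motifs: %d (motif1 %d/%d units)\n",
              nrow(x$markers), nrow(x$motifs),
              x$motifs$paternal_units[1], x$motifs$maternal_units[1]))
  cat(sprintf("  crossover-I region: [%d,%d)   crossover-II region: [%d,%d)\n",
              x$co1_region[1], x$co1_region[2], x$co2_region[1], x$co2_region[2]))
  invisible(x)
}

#' Render parental reference sequences and the coordinate table
#'
#' @param locus a validated \code{locus_reference}.
#' @return a list with \code{sequences}, a named
#'   \code{\link[Biostrings]{DNAStringSet}} of the paternal and maternal
#'   haplotypes, and \code{coordinates}, a long-format table (element_id,
#'   parent, start, end, allele; 0-based half-open).
#' @export
render_parental_sequences <- function(locus) {
  stopifnot(inherits(locus, "locus_reference"))
  seqs <- Biostrings::DNAStringSet(c(paternal = locus$paternal_seq,
                                     maternal = locus$maternal_seq))
  tab <- locus$elements
  coords <- rbind(
    data.frame(element_id = tab$element_id, parent = "paternal",
               start = tab$pat_start, end = tab$pat_end,
               allele = tab$pat_allele, stringsAsFactors = FALSE),
    data.frame(element_id = tab$element_id, parent = "maternal",
               start = tab$mat_start, end = tab$mat_end,
               allele = tab$mat_allele, stringsAsFactors = FALSE)
  )
  list(sequences = seqs, coordinates = coords)
}

#' Write / read a locus specification as YAML
#'
#' @param spec a locus specification list.
#' @param path file path.
#' @return \code{read_locus_spec} returns the specification list;
#'   \code{write_locus_spec} returns \code{path} invisibly.
#' @export
write_locus_spec <- function(spec, path) {
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' @rdname write_locus_spec
#' @export
read_locus_spec <- function(path) {
  yaml::read_yaml(path)
}

#' Write the parental references as FASTA and the coordinate table as TSV
#'
#' @param locus a validated \code{locus_reference}.
#' @param fasta_path,coords_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_locus_reference <- function(locus, fasta_path, coords_path) {
  r <- render_parental_sequences(locus)
  Biostrings::writeXStringSet(r$sequences, fasta_path)
  utils::write.table(r$coordinates, coords_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_path, coordinates = coords_path))
}
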