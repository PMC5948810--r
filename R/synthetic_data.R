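# Ground-truth clone simulator. The generator inverts the classifier's class
# definitions: crossover clones switch parental haplotype at breakpoints
# placed uniformly within the candidate regions, crossover-I clones carry the
# repair template's motif-1 tract, and intra-allelic artifact clones carry a
# uniparental marker pattern with a contracted/expanded tract, emulating PCR
# template switching. Sequencing errors are applied last.

#' PCR / sequencing artifact parameters for the clone simulator
#'
#' @param slippage_prob per-clone probability that the amplified motif-1
#'   tract contracts or expands by replication slippage.
#' @param template_switch_prob per-clone probability of a PCR template-switch
#'   chimera. Template switching within a homogeneous repeat tract re-anneals
#'   the nascent strand at a shifted register, so its observable product is a
#'   repeat-length change with the clone's marker pattern unchanged.
#' @param seq_error_rate per-base substitution probability.
#' @param slippage_geom_p success parameter of the geometric distribution of
#'   slippage step sizes (in units, |k| >= 1; sign symmetric).
#' @return a list of class \code{artifact_params}.
#' @export
artifact_params <- function(slippage_prob = 0.15,
                            template_switch_prob = 0.1,
                            seq_error_rate = 0.001,
                            slippage_geom_p = 0.5) {
  probs <- c(slippage_prob, template_switch_prob, seq_error_rate)
  if (any(probs < 0 | probs > 1))
    stop("artifact probabilities must lie in [0, 1]")
  stopifnot(slippage_geom_p > 0, slippage_geom_p <= 1)
  structure(list(slippage_prob = slippage_prob,
                 template_switch_prob = template_switch_prob,
                 seq_error_rate = seq_error_rate,
                 slippage_geom_p = slippage_geom_p),
            class = "artifact_params")
}

# signed slippage step: |k| ~ 1 + geometric, sign symmetric
slippage_step <- function(params) {
  (1L + stats::rgeom(1L, params$slippage_geom_p)) * sample(c(-1L, 1L), 1L)
}

# Render a motif tract with an arbitrary unit count. When the count equals a
# parental count the parent's interruption pattern is reproduced exactly;
# otherwise a perfect tract is emitted.
render_tract_units <- function(el, units) {
  if (units == el$paternal_units) return(render_tract(el, "paternal"))
  if (units == el$maternal_units) return(render_tract(el, "maternal"))
  tract <- strrep(el$unit, units)
  if (identical(el$orientation, "reverse")) tract <- revcomp(tract)
  tract
}

# Build a clone sequence from per-element parental origins (named vector over
# non-spacer element ids) and a motif-1 unit count. Uses the per-piece
# renderings cached on the locus.
render_clone <- function(locus, origins, m1_units) {
  pieces <- locus$piece_pat
  maternal_ids <- names(origins)[origins == "maternal"]
  sel <- locus$piece_ids %in% maternal_ids
  pieces[sel] <- locus$piece_mat[sel]
  i1 <- which(locus$piece_ids == "motif1")
  m1_spec <- Find(function(el) identical(el$id, "motif1"), locus$spec$elements)
  pieces[i1] <- render_tract_units(m1_spec, m1_units)
  paste(pieces, collapse = "")
}

apply_seq_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

other_parent <- function(p) if (p == "paternal") "maternal" else "paternal"

#' Simulate one cloned amplicon with known truth
#'
#' @param true_class one of \code{PD}, \code{MD}, \code{CO_I}, \code{CO_II},
#'   \code{CO_I_II}, \code{INTRA_ALLELIC}.
#' @param locus a validated \code{locus_reference}.
#' @param params an \code{\link{artifact_params}} object.
#' @param dsb_parent for \code{CO_I}: which homolog carried the double-strand
#'   break (\code{"paternal"} or \code{"maternal"}); the emitted motif-1
#'   tract carries the other (template) parent's unit count. Default samples
#'   paternal with probability \code{dsb_paternal_prob}.
#' @param motif1_units optional override of the emitted motif-1 unit count
#'   (used to construct repeat-length spectra with known composition).
#' @param flank_parent parent of the upstream flank for crossover and
#'   intra-allelic clones (default: random).
#' @param dsb_paternal_prob probability that a simulated crossover-I break
#'   sits on the paternal (long-tract) homolog.
#' @param clone_id identifier recorded in the truth record.
#' @return a list with \code{seq} (nucleotide string) and \code{truth}
#'   (one-row data frame: clone_id, true_class, flank_parent, dsb_parent,
#'   true_motif1_units, breakpoints, slippage, template_switch).
#' @export
simulate_clone <- function(true_class, locus, params = artifact_params(),
                           dsb_parent = NULL, motif1_units = NULL,
                           flank_parent = NULL, dsb_paternal_prob = 0.8,
                           clone_id = "clone1") {
  stopifnot(inherits(locus, "locus_reference"))
  if (!true_class %in% c("PD", "MD", "CO_I", "CO_II", "CO_I_II", "INTRA_ALLELIC"))
    stop(sprintf("unknown clone class: %s", true_class))
  tab <- locus$elements
  ids <- tab$element_id
  pu <- locus$motifs$paternal_units[1]
  mu <- locus$motifs$maternal_units[1]
  m1_iv <- c(locus$motifs$pat_start[1], locus$motifs$pat_end[1])
  mid_markers <- which(tab$type == "marker" & tab$segment == "between_motif2_and_motif3")
  i_motif1 <- which(ids == "motif1")

  origins <- stats::setNames(rep("paternal", length(ids)), ids)
  breakpoints <- integer(0)
  dsb <- "none"
  m1_units <- pu

  unit_boundary_in <- function(iv) {
    # a repeat-unit / inter-marker boundary drawn uniformly inside the region
    b <- seq(iv[1], iv[2], by = 2L)
    b[sample.int(length(b), 1L)]
  }
  co2_gap <- function() {
    g <- sample.int(length(mid_markers) - 1L, 1L)
    list(last_left = mid_markers[g],
         iv = c(tab$pat_end[mid_markers[g]], tab$pat_start[mid_markers[g] + 1L]))
  }

  up <- flank_parent %||% sample(c("paternal", "maternal"), 1L)

  if (true_class == "PD") {
    origins[] <- "paternal"; m1_units <- pu
  } else if (true_class == "MD") {
    origins[] <- "maternal"; m1_units <- mu
  } else if (true_class == "CO_I") {
    dsb <- dsb_parent %||%
      (if (stats::runif(1) < dsb_paternal_prob) "paternal" else "maternal")
    template <- other_parent(dsb)
    origins[seq_len(i_motif1 - 1L)] <- up
    origins[i_motif1:length(ids)] <- other_parent(up)
    m1_units <- if (template == "paternal") pu else mu
    breakpoints <- unit_boundary_in(m1_iv)
  } else if (true_class == "CO_II") {
    gap <- co2_gap()
    origins[seq_len(gap$last_left)] <- up
    origins[(gap$last_left + 1L):length(ids)] <- other_parent(up)
    m1_units <- if (up == "paternal") pu else mu
    breakpoints <- sample(seq.int(gap$iv[1], gap$iv[2]), 1L)
  } else if (true_class == "CO_I_II") {
    gap <- co2_gap()
    mid <- other_parent(up)
    origins[] <- up
    origins[i_motif1:gap$last_left] <- mid
    m1_units <- if (mid == "paternal") pu else mu
    breakpoints <- c(unit_boundary_in(m1_iv),
                     sample(seq.int(gap$iv[1], gap$iv[2]), 1L))
  } else if (true_class == "INTRA_ALLELIC") {
    origins[] <- up
    base <- if (up == "paternal") pu else mu
    repeat {
      u <- base + slippage_step(params)
      if (u >= 1L && u != pu && u != mu) break
    }
    m1_units <- u
  }

  if (!is.null(motif1_units)) m1_units <- as.integer(motif1_units)

  slip <- FALSE; tswitch <- FALSE
  if (true_class != "INTRA_ALLELIC") {
    if (stats::runif(1) < params$slippage_prob) {
      slip <- TRUE
      m1_units <- max(1L, m1_units + slippage_step(params))
    }
    if (stats::runif(1) < params$template_switch_prob) {
      tswitch <- TRUE
      m1_units <- max(1L, m1_units + slippage_step(params))
    }
  }

  seq <- render_clone(locus, origins, m1_units)
  seq <- apply_seq_errors(seq, params$seq_error_rate)

  list(seq = seq,
       truth = quick_df(list(
         clone_id = clone_id, true_class = true_class,
         flank_parent = if (true_class %in% c("PD", "MD")) true_class else up,
         dsb_parent = dsb,
         true_motif1_units = as.integer(m1_units),
         breakpoints = paste(breakpoints, collapse = ";"),
         slippage = slip, template_switch = tswitch)))
}

#' Simulate a clone set with a known class composition
#'
#' @param composition either a named integer vector of per-class counts
#'   (e.g. \code{c(PD = 42, MD = 43, CO_I = 31)}) or a data frame with
#'   columns \code{class}, \code{n} and optionally \code{dsb_parent} and
#'   \code{motif1_units} for fine control of crossover-I repeat spectra.
#' @param locus a validated \code{locus_reference}.
#' @param params an \code{\link{artifact_params}} object.
#' @param seed integer seed; fixed seeds give byte-identical output.
#' @param sample_id sample tag recorded in headers and truth.
#' @param dsb_paternal_prob see [simulate_clone()].
#' @return a list with \code{clones} (named character vector; names are FASTA
#'   headers \code{"<id> sample=<sample_id>"}) and \code{truth} (data frame).
#' @export
simulate_clone_set <- function(composition, locus, params = artifact_params(),
                               seed = NULL, sample_id = "sample1",
                               dsb_paternal_prob = 0.8) {
  if (is.data.frame(composition)) {
    spec_tab <- composition
    stopifnot(all(c("class", "n") %in% names(spec_tab)))
  } else {
    spec_tab <- data.frame(class = names(composition) %||% character(0),
                           n = as.integer(composition),
                           stringsAsFactors = FALSE)
  }
  if (any(spec_tab$n < 0)) stop("negative clone counts in composition")
  if (nrow(spec_tab) == 0 || sum(spec_tab$n) == 0) {
    return(list(clones = stats::setNames(character(0), character(0)),
                truth = data.frame(clone_id = character(), sample = character(),
                                   true_class = character(), flank_parent = character(),
                                   dsb_parent = character(), true_motif1_units = integer(),
                                   breakpoints = character(), slippage = logical(),
                                   template_switch = logical(), stringsAsFactors = FALSE)))
  }
  with_seed(seed, {
    rows <- spec_tab[rep(seq_len(nrow(spec_tab)), spec_tab$n), , drop = FALSE]
    rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
    sims <- lapply(seq_len(nrow(rows)), function(i) {
      simulate_clone(rows$class[i], locus, params,
                     dsb_parent = if ("dsb_parent" %in% names(rows) &&
                                      !is.na(rows$dsb_parent[i])) rows$dsb_parent[i] else NULL,
                     motif1_units = if ("motif1_units" %in% names(rows) &&
                                        !is.na(rows$motif1_units[i])) rows$motif1_units[i] else NULL,
                     dsb_paternal_prob = dsb_paternal_prob,
                     clone_id = sprintf("cl%05d", i))
    })
    clones <- vapply(sims, function(s) s$seq, "")
    col <- function(name, proto) vapply(sims, function(s) s$truth[[name]], proto)
    truth <- quick_df(list(
      clone_id = col("clone_id", ""), sample = rep(sample_id, length(sims)),
      true_class = col("true_class", ""), flank_parent = col("flank_parent", ""),
      dsb_parent = col("dsb_parent", ""),
      true_motif1_units = col("true_motif1_units", 1L),
      breakpoints = col("breakpoints", ""),
      slippage = col("slippage", TRUE), template_switch = col("template_switch", TRUE)))
    names(clones) <- sprintf("%s sample=%s", truth$clone_id, sample_id)
    list(clones = clones, truth = truth)
  })
}

#' Simulate an embryo division series with accumulating HR
#'
#' A sampled allele lineage after \code{d} divisions is recombinant with
#' probability \eqn{1 - (1 - p)^d}, so the expected HR fraction is
#' nondecreasing in the division count. Recombinant lineages are emitted as
#' crossover-I clones; non-recombinant lineages as parental clones (paternal
#' or maternal with equal odds).
#'
#' @param per_division_hr_prob probability \code{p} of an HR event per
#'   division per lineage.
#' @param division_counts increasing vector of division numbers to sample.
#' @param clones_per_sample number of clones sequenced per time point.
#' @param locus,params,seed,dsb_paternal_prob as in [simulate_clone_set()].
#' @return a list with \code{samples} (one clone-set list per division count,
#'   sample ids \code{"d<divisions>"}) and \code{truth} (combined data frame
#'   with a \code{divisions} column).
#' @export
simulate_embryo_series <- function(per_division_hr_prob, division_counts,
                                   clones_per_sample, locus,
                                   params = artifact_params(), seed = NULL,
                                   dsb_paternal_prob = 0.8) {
  p <- per_division_hr_prob
  if (p < 0 || p > 1) stop("per_division_hr_prob must lie in [0, 1]")
  stopifnot(all(diff(division_counts) > 0))
  with_seed(seed, {
    samples <- lapply(seq_along(division_counts), function(i) {
      d <- division_counts[i]
      p_rec <- 1 - (1 - p)^d
      n_rec <- stats::rbinom(1L, clones_per_sample, p_rec)
      n_par <- clones_per_sample - n_rec
      n_pd <- stats::rbinom(1L, n_par, 0.5)
      set <- simulate_clone_set(
        c(PD = n_pd, MD = n_par - n_pd, CO_I = n_rec), locus, params,
        seed = child_seed(seed, i), sample_id = sprintf("d%d", d),
        dsb_paternal_prob = dsb_paternal_prob)
      set$truth$divisions <- d
      set
    })
    list(samples = samples,
         truth = do.call(rbind, lapply(samples, function(s) s$truth)))
  })
}

#' Simulate a gynogenetic diploid cohort for half-tetrad analysis
#'
#' Each meio-gynogenetic individual carries two allele copies duplicated
#' from one egg haplotype. With probability \code{meiotic_co_prob} the
#' individual is heterozygous, carrying one grandparental haplotype and one
#' crossover haplotype; otherwise it is homozygous for the grandpaternal or
#' grandmaternal haplotype with equal odds. Heterozygous individuals always
#' show both haplotypes among their sequenced clones.
#'
#' @param meiotic_co_prob probability \code{q} that an individual reveals a
#'   meiotic crossover (ignored when \code{composition} is given).
#' @param n_individuals cohort size (ignored when \code{composition} is given).
#' @param clones_per_individual clones sequenced per individual (>= 2).
#' @param locus,params,seed,dsb_paternal_prob as in [simulate_clone_set()].
#' @param composition optional named counts fixing the cohort genotypes,
#'   e.g. \code{c(HET = 2, HOM_GF = 4, HOM_GM = 3)}.
#' @return a list with \code{clones} (named character vector; headers carry
#'   \code{sample=gyno individual=<id>}), \code{truth} (per-clone data frame)
#'   and \code{genotypes} (per-individual truth: individual_id, genotype).
#' @export
simulate_gynogenote_cohort <- function(meiotic_co_prob = NULL,
                                       n_individuals = NULL,
                                       clones_per_individual = 10,
                                       locus, params = artifact_params(),
                                       seed = NULL, dsb_paternal_prob = 0.8,
                                       composition = NULL) {
  stopifnot(clones_per_individual >= 2)
  if (is.null(composition)) {
    q <- meiotic_co_prob
    if (is.null(q) || q < 0 || q > 1)
      stop("meiotic_co_prob must lie in [0, 1]")
    stopifnot(n_individuals >= 1)
  }
  with_seed(seed, {
    genotypes <- if (!is.null(composition)) {
      g <- rep(names(composition), composition)
      g[sample.int(length(g))]
    } else {
      ifelse(stats::runif(n_individuals) < q, "HET",
             ifelse(stats::runif(n_individuals) < 0.5, "HOM_GF", "HOM_GM"))
    }
    all_clones <- character(0)
    all_truth <- list()
    for (i in seq_along(genotypes)) {
      ind <- sprintf("g%03d", i)
      g <- genotypes[i]
      if (g == "HET") {
        grandparent <- sample(c("PD", "MD"), 1L)
        dsb <- if (stats::runif(1) < dsb_paternal_prob) "paternal" else "maternal"
        up <- sample(c("paternal", "maternal"), 1L)
        pick <- stats::runif(clones_per_individual) < 0.5
        if (all(pick) || all(!pick)) pick[1] <- !pick[1]  # both alleles observed
        haps <- ifelse(pick, "CO_I", grandparent)
      } else {
        haps <- rep(if (g == "HOM_GF") "PD" else "MD", clones_per_individual)
      }
      sims <- lapply(seq_along(haps), function(j) {
        simulate_clone(haps[j], locus, params,
                       dsb_parent = if (haps[j] == "CO_I") dsb else NULL,
                       flank_parent = if (haps[j] == "CO_I") up else NULL,
                       dsb_paternal_prob = dsb_paternal_prob,
                       clone_id = sprintf("%s_cl%03d", ind, j))
      })
      clones <- vapply(sims, function(s) s$seq, "")
      truth <- do.call(rbind, lapply(sims, function(s) s$truth))
      truth$individual <- ind
      truth$true_genotype <- g
      names(clones) <- sprintf("%s sample=gyno individual=%s", truth$clone_id, ind)
      all_clones <- c(all_clones, clones)
      all_truth[[i]] <- truth
    }
    list(clones = all_clones,
         truth = do.call(rbind, all_truth),
         genotypes = data.frame(individual_id = sprintf("g%03d", seq_along(genotypes)),
                                genotype = genotypes, stringsAsFactors = FALSE))
  })
}
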