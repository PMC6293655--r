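# Synthetic genomes with assembly gaps, and truly-null gap-avoiding track
# pairs: the study's data-generating machinery. Defaults emulate the
# human-reference situation the study targets: tens of equal-length
# chromosomes, a configurable fraction of bases in long gap runs (7.6%
# hg19-like, 5% hg38-like), and tracks of many equal-length elements
# placed uniformly in the gap complement.

#' Specification of a simulated gapped genome
#'
#' @param n_chromosomes number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chromosome_length single length in bp applied to every
#'   chromosome, or a vector of per-chromosome lengths.
#' @param gap_fraction fraction of bases inside gap runs, in `[0, 1)`.
#' @param gap_length_law distribution of individual gap run lengths:
#'   `list(law = "fixed")` (default; each chromosome carries
#'   `n_gaps_per_chromosome` equal gap runs totalling
#'   `gap_fraction * length`), `list(law = "uniform", min =, max =)` or
#'   `list(law = "lognormal", meanlog =, sdlog =)`. Stochastic laws are
#'   rescaled so the per-chromosome gap total hits its target.
#' @param n_gaps_per_chromosome number of gap runs per chromosome.
#' @param seed integer seed making the simulated genome reproducible.
#' @return an object of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(n_chromosomes = 22,
                            chromosome_length = 1e7,
                            gap_fraction = 0.076,
                            gap_length_law = list(law = "fixed"),
                            n_gaps_per_chromosome = 10,
                            seed = NULL) {
  stopifnot(n_chromosomes >= 1, gap_fraction >= 0, gap_fraction < 1,
            n_gaps_per_chromosome >= 1)
  lens <- if (length(chromosome_length) == 1) {
    rep(chromosome_length, n_chromosomes)
  } else {
    stopifnot(length(chromosome_length) == n_chromosomes)
    chromosome_length
  }
  stopifnot(all(lens > 0))
  structure(
    list(n_chromosomes = n_chromosomes, chromosome_lengths = as.numeric(lens),
         gap_fraction = gap_fraction, gap_length_law = gap_length_law,
         n_gaps_per_chromosome = n_gaps_per_chromosome, seed = seed),
    class = "genome_sim_spec"
  )
}

sample_gap_lengths <- function(law, n, target) {
  lens <- switch(law$law,
    fixed = {
      base <- floor(target / n)
      out <- rep(base, n)
      out[1] <- out[1] + (target - base * n)
      out
    },
    uniform = runif(n, law$min, law$max),
    lognormal = rlnorm(n, law$meanlog, law$sdlog),
    stop("unknown gap_length_law: ", law$law)
  )
  if (law$law != "fixed") {
    lens <- lens * (target / sum(lens))
    lens <- pmax(1, round(lens))
    # absorb rounding drift in the largest run
    i <- which.max(lens)
    lens[i] <- max(1, lens[i] + (target - sum(lens)))
  }
  lens[lens >= 1]
}

#' Simulate a gapped genome
#'
#' Builds a multi-chromosome genome and a disjoint gap set whose total
#' length is within 1% of `gap_fraction` times the genome length
#' (exact up to rounding for the default fixed law). Gap runs are placed
#' uniformly and disjointly within each chromosome by the same spacing
#' construction used for track elements. Deterministic given the spec seed.
#'
#' @param spec a [genome_sim_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return `list(genome =, gaps =)` where `gaps` is a canonical
#'   `interval_set`.
#' @export
#' @examples
#' sim <- simulate_genome(genome_sim_spec(2, 1e5, 0.05, seed = 1))
#' total_bp(sim$gaps) / sim$genome$total
simulate_genome <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  lens <- spec$chromosome_lengths
  names(lens) <- paste0("chr", seq_along(lens))
  g <- genome(lens)
  if (spec$gap_fraction == 0) {
    return(list(genome = g, gaps = empty_interval_set("gaps")))
  }
  gaps <- with_seed_(seed, {
    pieces <- vector("list", length(lens))
    for (i in seq_along(lens)) {
      target <- round(spec$gap_fraction * lens[i])
      gl <- sample_gap_lengths(spec$gap_length_law,
                               spec$n_gaps_per_chromosome, target)
      if (sum(gl) > lens[i]) {
        stop("infeasible genome spec: sampled gap lengths exceed chromosome ", i)
      }
      pl <- place_lengths(gl, run_start = 0, run_len = lens[i])
      pieces[[i]] <- data.frame(chrom = names(lens)[i],
                                start = pl$start, end = pl$end,
                                stringsAsFactors = FALSE)
    }
    interval_set(do.call(rbind, pieces), label = "gaps", genome = g)
  })
  list(genome = g, gaps = gaps)
}

#' Specification of a simulated track
#'
#' @param n_elements number of genomic elements (intervals).
#' @param segment_length_law element length distribution:
#'   `list(law = "fixed", length =)` (default for study presets),
#'   `list(law = "empirical", lengths =)` (the exact length multiset of a
#'   template track), or `list(law = "lognormal", meanlog =, sdlog =)`.
#' @param avoid_gaps should elements avoid the gap set (the defining
#'   property of real sequencing-derived tracks)?
#' @param preserve_arm_distribution optional named vector of element counts
#'   per chromosomal arm (see [shuffle_track()]'s `arm_counts`).
#' @param seed integer seed.
#' @return an object of class `track_sim_spec`.
#' @export
track_sim_spec <- function(n_elements,
                           segment_length_law = list(law = "fixed", length = 1000),
                           avoid_gaps = TRUE,
                           preserve_arm_distribution = NULL,
                           seed = NULL) {
  stopifnot(n_elements >= 0)
  structure(
    list(n_elements = as.integer(n_elements),
         segment_length_law = segment_length_law,
         avoid_gaps = isTRUE(avoid_gaps),
         preserve_arm_distribution = preserve_arm_distribution,
         seed = seed),
    class = "track_sim_spec"
  )
}

sample_segment_lengths <- function(law, n) {
  switch(law$law,
    fixed = rep(as.numeric(law$length), n),
    empirical = {
      if (length(law$lengths) == n) as.numeric(law$lengths)
      else as.numeric(sample(law$lengths, n, replace = TRUE))
    },
    lognormal = pmax(1, round(rlnorm(n, law$meanlog, law$sdlog))),
    stop("unknown segment_length_law: ", law$law)
  )
}

#' Simulate a single synthetic track
#'
#' Draws element lengths from the spec's length law and places them
#' uniformly (non-overlapping) in the accessible space — the gap
#' complement when `avoid_gaps` is set, the whole genome otherwise.
#'
#' @param spec a [track_sim_spec()].
#' @param genome a [genome()].
#' @param gaps the gap `interval_set` (used only when `spec$avoid_gaps`).
#' @param seed overrides `spec$seed` when given.
#' @param label track label.
#' @return an `interval_set`.
#' @export
simulate_track <- function(spec, genome, gaps = NULL, seed = spec$seed,
                           label = "synthetic") {
  stopifnot(inherits(spec, "track_sim_spec"))
  use_gaps <- if (spec$avoid_gaps) gaps else NULL
  with_seed_(seed, {
    lens <- sample_segment_lengths(spec$segment_length_law, spec$n_elements)
    if (is.null(spec$preserve_arm_distribution)) {
      space <- accessible_space(genome, use_gaps)
      sample_uniform_placement(lens, space, label = label)
    } else {
      place_stratified(lens, genome, use_gaps,
                       spec$preserve_arm_distribution, label = label)
    }
  })
}

#' Simulate a truly-null pair of tracks
#'
#' Draws two tracks from independent random streams so that, by
#' construction, they share no association beyond whatever placement
#' constraints their specs impose (in the study design: their shared
#' avoidance of assembly gaps). H0 of the colocalization test is therefore
#' true for every simulated pair.
#'
#' @param spec_a,spec_b [track_sim_spec()]s for the two tracks.
#' @param genome a [genome()].
#' @param gaps the gap `interval_set`.
#' @param seed integer seed; the two tracks use sub-seeds derived with
#'   [derive_seed()].
#' @return `list(a =, b =)` of `interval_set`s labelled `"A"` and `"B"`.
#' @export
simulate_null_pair <- function(spec_a, spec_b, genome, gaps, seed = NULL) {
  sa <- if (is.null(seed)) NULL else derive_seed(seed, 1)
  sb <- if (is.null(seed)) NULL else derive_seed(seed, 2)
  list(a = simulate_track(spec_a, genome, gaps, seed = sa, label = "A"),
       b = simulate_track(spec_b, genome, gaps, seed = sb, label = "B"))
}
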