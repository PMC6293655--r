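# Independent oracles and fixture builders used across the suite.
# All oracles work by brute force (per-base bitmaps, full enumeration) and
# share no code with the implementation they check.

toy_genome <- function(...) genome(c(...))

# Per-base occupancy bitmap of an interval set on a small genome.
bitmap_of <- function(x, g) {
  v <- logical(g$total)
  if (nrow(x) == 0) return(v)
  off <- g$offsets[x$chrom]
  for (i in seq_len(nrow(x))) {
    v[(off[i] + x$start[i] + 1):(off[i] + x$end[i])] <- TRUE
  }
  v
}

# Random raw intervals (possibly overlapping) on a genome; returned as a
# plain data.frame so callers control canonicalization.
random_raw_intervals <- function(g, n, max_len = 50) {
  ci <- sample(seq_along(g$names), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  len <- pmin(len, g$lengths[ci])
  start <- floor(runif(n) * (g$lengths[ci] - len + 1))
  data.frame(chrom = g$names[ci], start = start, end = start + len,
             stringsAsFactors = FALSE)
}

random_iset <- function(g, n, max_len = 50, label = "rand") {
  interval_set(random_raw_intervals(g, n, max_len), label = label, genome = g)
}

# Canonical key of a placement draw (single-chromosome toys).
placement_key <- function(x) {
  paste(sprintf("%.0f-%.0f", x$start, x$end), collapse = ";")
}

# Full enumeration of all arrangements (sets of non-overlapping intervals
# with the given length multiset, each inside one run). Runs are given as
# list(start =, len =) in a shared linear coordinate space. Returns the
# arrangements as a character vector of canonical keys.
enumerate_arrangements <- function(lengths, runs) {
  seen <- new.env(parent = emptyenv())
  rec <- function(ps, pe, remaining) {
    if (length(remaining) == 0) {
      o <- order(ps)
      key <- paste(sprintf("%.0f-%.0f", ps[o], pe[o]), collapse = ";")
      assign(key, TRUE, envir = seen)
      return(invisible())
    }
    l <- remaining[1]
    for (j in seq_along(runs$start)) {
      if (runs$len[j] < l) next
      for (off in 0:(runs$len[j] - l)) {
        s <- runs$start[j] + off
        e <- s + l
        if (all(e <= ps | s >= pe)) rec(c(ps, s), c(pe, e), remaining[-1])
      }
    }
  }
  rec(numeric(0), numeric(0), lengths)
  ls(seen)
}

# Accessible runs of a single-chromosome genome with a gap set, as the
# linear run list enumerate_arrangements() expects.
runs_of <- function(g, gaps = NULL) {
  acc <- if (is.null(gaps) || nrow(gaps) == 0) {
    data.frame(start = 0, end = unname(g$lengths[1]))
  } else {
    cmp <- complement(gaps, g)
    data.frame(start = cmp$start, end = cmp$end)
  }
  list(start = acc$start, len = acc$end - acc$start)
}

# Overlap of one enumerated arrangement (by key) with a reference set of
# linear intervals, counted per base.
key_overlap <- function(key, ref_start, ref_end) {
  iv <- do.call(rbind, lapply(strsplit(key, ";")[[1]], function(s) {
    as.numeric(strsplit(s, "-")[[1]])
  }))
  tot <- 0
  for (i in seq_len(nrow(iv))) {
    tot <- tot + sum(pmax(0, pmin(iv[i, 2], ref_end) - pmax(iv[i, 1], ref_start)))
  }
  tot
}

# Small study config on a toy genome, used by the pipeline tests.
toy_study_config <- function(n_pairs = 10, n_chrom = 4, chrom_len = 1e6,
                             gap_fraction = 0.15, n_elements = 5000,
                             segment_length = 100, mc_samples = 99,
                             modes = c("whole_genome", "exclude_gaps"),
                             seed = 1) {
  study_config(
    genome_spec = genome_sim_spec(n_chrom, chrom_len, gap_fraction),
    n_pairs = n_pairs,
    track_spec_a = track_sim_spec(
      n_elements, list(law = "fixed", length = segment_length)),
    modes = modes, mc_samples = mc_samples, seed = seed
  )
}
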