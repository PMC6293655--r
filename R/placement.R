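# Constrained uniform placement of non-overlapping elements.
#
# An "arrangement" is a set of non-overlapping intervals, one per element
# length, each lying entirely inside one accessible run (an element cannot
# span an N-stretch). Within a run, non-overlapping starts for the
# committed elements are drawn by the order-statistics (stars-and-bars)
# construction in the compressed coordinate space, which is exactly uniform
# over the feasible configurations of that run. Across runs, the element
# allocation is drawn:
#   * exactly, by a counting DP over per-run packing counts
#     C(R - k*l + k, k), when all lengths are equal and the DP is small
#     enough (J * (k+1)^2 <= exact_max_ops); this covers every
#     enumeration-scale problem, so small-genome draws are exactly uniform
#     over all feasible arrangements; or
#   * by i.i.d. capacity-weighted assignment (weight R_j - l + 1 per run)
#     with a bounded feasibility retry, used at study scale. This is exact
#     for unit-length elements and asymptotically equivalent otherwise;
#     every feasible arrangement keeps positive probability.

PLACE_EXACT_MAX_OPS <- 1e6

# Build a placer: a closure that, on each call, draws one arrangement of
# `lengths` into the linearized runs (consuming the current RNG stream)
# and returns sorted absolute start/end vectors. Building once amortizes
# the exact-allocation DP across the shuffles of a Monte Carlo test.
make_placer <- function(lengths, run_start, run_len,
                        exact_max_ops = PLACE_EXACT_MAX_OPS) {
  k <- length(lengths)
  if (k == 0) {
    return(function() list(start = numeric(0), end = numeric(0)))
  }
  if (any(lengths < 1) || any(lengths != floor(lengths))) {
    stop("element lengths must be positive integers")
  }
  if (sum(lengths) > sum(run_len)) {
    stop("infeasible packing: total element length exceeds the accessible space")
  }
  J <- length(run_len)
  equal <- all(lengths == lengths[1])
  finish <- function(lens, assign) {
    res <- cpp_place_in_runs(run_start, run_len, lens, assign)
    if (!isTRUE(res$ok)) stop("infeasible packing")
    list(start = res$start, end = res$end)
  }
  if (J == 1) {
    if (sum(lengths) > run_len[1]) stop("infeasible packing")
    assign1 <- rep(1L, k)
    return(function() {
      lens <- if (equal || k == 1) lengths else sample(lengths)
      finish(lens, assign1)
    })
  }
  if (equal && J * (k + 1)^2 <= exact_max_ops) {
    G <- exact_alloc_dp(k, lengths[1], run_len)
    return(function() {
      cnt <- exact_alloc_sample(k, lengths[1], run_len, G)
      finish(lengths, rep.int(seq_len(J), cnt))
    })
  }
  function() {
    lens <- if (equal) lengths else sample(lengths)
    finish(lens, assign_capacity_weighted(lens, run_len))
  }
}

# One-shot convenience wrapper around make_placer().
place_lengths <- function(lengths, run_start, run_len,
                          exact_max_ops = PLACE_EXACT_MAX_OPS) {
  make_placer(lengths, run_start, run_len, exact_max_ops)()
}

# i.i.d. capacity-weighted run assignment with bounded feasibility retry.
assign_capacity_weighted <- function(lengths, run_len, max_retry = 100L) {
  k <- length(lengths)
  J <- length(run_len)
  uls <- unique(lengths)
  cumw <- lapply(uls, function(l) {
    w <- pmax(run_len - l + 1, 0)
    if (all(w == 0)) {
      stop("infeasible packing: an element is longer than every accessible run")
    }
    cumsum(w)
  })
  names(cumw) <- as.character(uls)
  for (try in seq_len(max_retry)) {
    assign <- integer(k)
    for (l in uls) {
      idx <- which(lengths == l)
      assign[idx] <- cpp_assign_runs(length(idx), cumw[[as.character(l)]])
    }
    committed <- numeric(J)
    s <- rowsum(lengths, assign)
    committed[as.integer(rownames(s))] <- s[, 1]
    if (all(committed <= run_len)) return(assign)
  }
  stop("infeasible packing: could not allocate elements to accessible runs after ",
       max_retry, " attempts")
}

# Exact uniform allocation of k equal-length elements over runs:
# P(k_1..k_J) proportional to prod_j C(R_j - k_j*l + k_j, k_j).
# The backward counting DP (log space) is built once; each draw then
# samples the per-run counts from the DP's conditional distributions.
alloc_lcount <- function(R, a, l) {
  free <- R - a * l
  ifelse(free >= 0, lchoose(free + a, a), -Inf)
}

# G[j, t+1] = log number of arrangements of t elements in runs j..J
exact_alloc_dp <- function(k, l, run_len) {
  J <- length(run_len)
  G <- matrix(-Inf, nrow = J, ncol = k + 1)
  G[J, ] <- alloc_lcount(run_len[J], 0:k, l)
  if (J > 1) {
    for (j in (J - 1):1) {
      lj <- alloc_lcount(run_len[j], 0:k, l)
      for (t in 0:k) {
        G[j, t + 1] <- logsumexp(lj[1:(t + 1)] + G[j + 1, (t:0) + 1])
      }
    }
  }
  if (!is.finite(G[1, k + 1])) stop("infeasible packing")
  G
}

exact_alloc_sample <- function(k, l, run_len, G) {
  J <- length(run_len)
  cnt <- integer(J)
  t <- k
  for (j in seq_len(J - 1)) {
    if (t == 0) break
    lp <- alloc_lcount(run_len[j], 0:t, l) + G[j + 1, (t:0) + 1]
    p <- exp(lp - max(lp))
    a <- sample.int(t + 1, 1, prob = p) - 1L
    cnt[j] <- a
    t <- t - a
  }
  cnt[J] <- t
  cnt
}

#' Uniformly place elements into an accessible space
#'
#' Draws a set of non-overlapping intervals with exactly the given length
#' multiset, uniformly over the feasible arrangements inside the accessible
#' runs of `space` (elements never intersect a gap and never span two
#' accessible runs). This is the placement law shared by the synthetic
#' track generator and the Monte Carlo null models.
#'
#' @param lengths integer vector (multiset) of element lengths in bp.
#' @param space an [accessible_space()].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param label label for the returned set.
#' @return an `interval_set` with `length(lengths)` intervals (bookended
#'   placements are kept unmerged so the length multiset is conserved).
#' @export
#' @examples
#' g <- genome(c(chr1 = 100))
#' sp <- accessible_space(g)
#' sample_uniform_placement(c(5, 5, 10), sp, seed = 1)
sample_uniform_placement <- function(lengths, space, seed = NULL,
                                     label = "placed") {
  stopifnot(inherits(space, "accessible_space"))
  lengths <- as.numeric(lengths)
  if (length(lengths) && sum(lengths) > space$total_bp) {
    stop("infeasible packing: total element length exceeds the accessible space")
  }
  res <- with_seed_(seed, place_lengths(lengths, space$run_start, space$run_len))
  delinearize(res$start, res$end, space$genome, label = label, merge = FALSE)
}

#' Shuffle a track under a placement null model
#'
#' Resamples the positions of a track while preserving its element count
#' and exact segment-length multiset: the placement universe is the whole
#' genome when `gaps` is `NULL`, or the genome minus `gaps` otherwise. When
#' `arm_counts` is given, placement is stratified so that each chromosomal
#' arm receives the specified number of elements.
#'
#' @param track an `interval_set`.
#' @param genome a [genome()].
#' @param gaps optional `interval_set` of regions the shuffled elements
#'   must avoid.
#' @param seed optional integer seed.
#' @param arm_counts optional named integer vector of element counts per
#'   arm. Arms are named `"<chrom>:p"` / `"<chrom>:q"`; for a single-
#'   chromosome genome plain `"p"` / `"q"` are accepted. Counts must sum to
#'   the number of elements.
#' @return an `interval_set` with the same length multiset as `track`.
#' @export
shuffle_track <- function(track, genome, gaps = NULL, seed = NULL,
                          arm_counts = NULL) {
  stopifnot(inherits(track, "interval_set"), inherits(genome, "genome"))
  lengths <- segment_lengths(track)
  label <- paste0(track_label(track), "_shuffled")
  if (is.null(arm_counts)) {
    space <- accessible_space(genome, gaps)
    return(sample_uniform_placement(lengths, space, seed = seed, label = label))
  }
  place_stratified(lengths, genome, gaps, arm_counts, seed = seed, label = label)
}

# Split accessible runs at arm boundaries; returns list of per-arm run
# tables keyed by "<chrom>:p"/"<chrom>:q" (chromosomes without an arm split
# form a single stratum named after the chromosome).
arm_runs <- function(genome, gaps = NULL) {
  space <- accessible_space(genome, gaps)
  regions <- space$regions
  out <- list()
  for (i in seq_along(genome$names)) {
    cn <- genome$names[i]
    sub <- regions[regions$chrom == cn, , drop = FALSE]
    if (nrow(sub) == 0) next
    off <- genome$offsets[[cn]]
    if (!is.null(genome$arm_split) && cn %in% names(genome$arm_split)) {
      sp <- genome$arm_split[[cn]]
      p <- data.frame(start = pmin(sub$start, sp), end = pmin(sub$end, sp))
      p <- p[p$start < p$end, , drop = FALSE]
      q <- data.frame(start = pmax(sub$start, sp), end = pmax(sub$end, sp))
      q <- q[q$start < q$end, , drop = FALSE]
      if (nrow(p)) out[[paste0(cn, ":p")]] <-
          list(start = off + p$start, len = p$end - p$start)
      if (nrow(q)) out[[paste0(cn, ":q")]] <-
          list(start = off + q$start, len = q$end - q$start)
    } else {
      out[[cn]] <- list(start = off + sub$start, len = sub$end - sub$start)
    }
  }
  out
}

place_stratified <- function(lengths, genome, gaps, arm_counts, seed = NULL,
                             label = "placed") {
  runs <- arm_runs(genome, gaps)
  nm <- names(arm_counts)
  if (is.null(nm)) stop("arm_counts must be named")
  if (length(genome$names) == 1 && all(nm %in% c("p", "q"))) {
    nm <- paste0(genome$names[1], ":", nm)
  }
  missing <- setdiff(nm, names(runs))
  if (length(missing)) {
    stop("arm_counts name(s) not matching any accessible arm: ",
         paste(missing, collapse = ", "))
  }
  if (sum(arm_counts) != length(lengths)) {
    stop("arm_counts must sum to the number of elements")
  }
  res <- with_seed_(seed, {
    perm <- if (length(lengths) > 1) sample(lengths) else lengths
    starts <- numeric(0); ends <- numeric(0)
    pos <- 0
    for (i in seq_along(nm)) {
      c_i <- arm_counts[[i]]
      if (c_i == 0) next
      li <- perm[(pos + 1):(pos + c_i)]
      pos <- pos + c_i
      r <- runs[[nm[i]]]
      pl <- place_lengths(li, r$start, r$len)
      starts <- c(starts, pl$start)
      ends <- c(ends, pl$end)
    }
    o <- order(starts)
    list(start = starts[o], end = ends[o])
  })
  delinearize(res$start, res$end, genome, label = label, merge = FALSE)
}
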