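# Descriptive statistics of how a collection of tracks intersects a gap
# set. All relative values are dimensionless fractions in [0, 1]: overlap
# bp divided by the size of the gap (or gap portion) being considered.

# Partition one gap of width w into (start, middle, end) portion widths.
# The default "thirds" rule assigns floor(w/3) to each flank and the
# remainder to the middle, the simplest rule consistent with overlap being
# concentrated at the beginning and end portions of gaps. A custom rule may
# be supplied as function(width) -> c(start, middle, end).
portion_widths <- function(w, portioning = "thirds") {
  if (is.function(portioning)) {
    out <- t(vapply(w, portioning, numeric(3)))
  } else if (identical(portioning, "thirds")) {
    s <- floor(w / 3)
    out <- cbind(s, w - 2 * s, s)
  } else {
    stop("unknown portioning rule")
  }
  if (any(rowSums(out) != w) || any(out < 0)) {
    stop("portioning rule must split each gap exactly into three non-negative parts")
  }
  out
}

#' Profile the intersection of a track collection with a gap set
#'
#' For each (gap, track) pair the overlap is counted relative to the gap
#' size, and separately relative to the sizes of the start, middle and end
#' portions of the gap, to show where across gaps the overlap sits. Means
#' are unweighted over all (gap, track) pairs. The overlap hotspot is the
#' gap with the largest track-averaged relative overlap.
#'
#' @param tracks a list of `interval_set`s (a single set is accepted).
#' @param gaps a non-empty `interval_set` of gaps.
#' @param portioning `"thirds"` (default) or a `function(width)` returning
#'   the three portion widths `c(start, middle, end)`.
#' @return an object of class `gap_overlap_profile`: a list with the
#'   collection-level means (`mean_relative_gap_overlap`,
#'   `mean_relative_start_overlap`, `mean_relative_middle_overlap`,
#'   `mean_relative_end_overlap`, `mean_interval_length_relative`), the
#'   `hotspot` (gap row + value), and `per_track_table`. Note that
#'   `mean_interval_length_relative` — mean interval length divided by the
#'   track's total covered bp — is a nonstandard collection descriptor kept
#'   for report compatibility.
#' @export
profile_gap_overlap <- function(tracks, gaps, portioning = "thirds") {
  if (inherits(tracks, "interval_set")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1,
            all(vapply(tracks, inherits, logical(1), "interval_set")))
  if (!inherits(gaps, "interval_set") || nrow(gaps) == 0) {
    stop("gap set must be a non-empty interval_set (profile undefined)")
  }
  w <- gaps$end - gaps$start
  pw <- portion_widths(w, portioning)
  starts <- data.frame(chrom = gaps$chrom, start = gaps$start,
                       end = gaps$start + pw[, 1])
  mids <- data.frame(chrom = gaps$chrom, start = gaps$start + pw[, 1],
                     end = gaps$start + pw[, 1] + pw[, 2])
  ends <- data.frame(chrom = gaps$chrom, start = gaps$end - pw[, 3],
                     end = gaps$end)
  nt <- length(tracks)
  ng <- nrow(gaps)
  rel <- matrix(0, ng, nt)       # per (gap, track) relative overlap
  rel_s <- matrix(NA_real_, ng, nt)
  rel_m <- matrix(NA_real_, ng, nt)
  rel_e <- matrix(NA_real_, ng, nt)
  for (t in seq_len(nt)) {
    tr <- tracks[[t]]
    rel[, t] <- overlap_by_interval(tr, gaps) / w
    ok_s <- pw[, 1] > 0
    if (any(ok_s)) {
      rel_s[ok_s, t] <- overlap_by_interval(tr, starts[ok_s, ]) / pw[ok_s, 1]
      rel_e[ok_s, t] <- overlap_by_interval(tr, ends[ok_s, ]) / pw[ok_s, 3]
    }
    ok_m <- pw[, 2] > 0
    if (any(ok_m)) {
      rel_m[ok_m, t] <- overlap_by_interval(tr, mids[ok_m, ]) / pw[ok_m, 2]
    }
  }
  per_gap_mean <- rowMeans(rel)
  hs <- which.max(per_gap_mean)
  labels <- vapply(seq_len(nt), function(i) {
    l <- track_label(tracks[[i]])
    if (nzchar(l)) l else paste0("track", i)
  }, character(1))
  mean_len <- vapply(tracks, function(tr) {
    if (nrow(tr) == 0) NA_real_ else mean(segment_lengths(tr))
  }, numeric(1))
  per_track <- data.frame(
    track = labels,
    n_elements = vapply(tracks, n_intervals, numeric(1)),
    mean_segment_length = mean_len,
    relative_gap_overlap = colMeans(rel),
    stringsAsFactors = FALSE
  )
  mil <- vapply(tracks, function(tr) {
    tb <- total_bp(tr)
    if (tb == 0) NA_real_ else mean(segment_lengths(tr)) / tb
  }, numeric(1))
  structure(
    list(
      mean_relative_gap_overlap = mean(rel),
      mean_relative_start_overlap = mean(rel_s, na.rm = TRUE),
      mean_relative_middle_overlap = mean(rel_m, na.rm = TRUE),
      mean_relative_end_overlap = mean(rel_e, na.rm = TRUE),
      mean_interval_length_relative = mean(mil, na.rm = TRUE),
      hotspot = list(gap = as.data.frame(gaps[hs, , drop = FALSE]),
                     value = per_gap_mean[hs]),
      per_track_table = per_track,
      per_gap_mean = per_gap_mean,
      per_gap = data.frame(chrom = gaps$chrom, start = gaps$start,
                           end = gaps$end,
                           mean_relative_overlap = per_gap_mean,
                           stringsAsFactors = FALSE)
    ),
    class = "gap_overlap_profile"
  )
}

#' @export
print.gap_overlap_profile <- function(x, ...) {
  cat("<gap_overlap_profile>\n")
  cat(sprintf("  mean relative gap overlap:    %.4g\n", x$mean_relative_gap_overlap))
  cat(sprintf("  start / middle / end:         %.4g / %.4g / %.4g\n",
              x$mean_relative_start_overlap, x$mean_relative_middle_overlap,
              x$mean_relative_end_overlap))
  cat(sprintf("  hotspot: %s:%.0f-%.0f (value %.4g)\n",
              x$hotspot$gap$chrom, x$hotspot$gap$start, x$hotspot$gap$end,
              x$hotspot$value))
  cat(sprintf("  %d track(s) profiled\n", nrow(x$per_track_table)))
  invisible(x)
}

#' Write a gap-overlap profile as TSV
#'
#' Writes the per-track table plus a commented header carrying the
#' collection-level means; optionally a per-gap table.
#'
#' @param profile a [profile_gap_overlap()] result.
#' @param path output TSV path.
#' @param per_gap_path optional path for the per-gap mean relative overlaps.
#' @export
write_gap_profile <- function(profile, path, per_gap_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# mean_relative_gap_overlap=%.6g start=%.6g middle=%.6g end=%.6g mean_interval_length_relative=%.6g hotspot=%s:%.0f-%.0f hotspot_value=%.6g",
    profile$mean_relative_gap_overlap, profile$mean_relative_start_overlap,
    profile$mean_relative_middle_overlap, profile$mean_relative_end_overlap,
    profile$mean_interval_length_relative,
    profile$hotspot$gap$chrom, profile$hotspot$gap$start,
    profile$hotspot$gap$end, profile$hotspot$value), con)
  write.table(profile$per_track_table, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(per_gap_path)) {
    write.table(profile$per_gap, per_gap_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Relation between segment length and gap overlap across tracks
#'
#' One row per track: mean segment length and relative gap overlap, plus
#' the Spearman rank correlation between the two columns — the size-
#' dependence diagnostic (longer-element tracks tend to reach further into
#' gap flanks).
#'
#' @param tracks a list of at least two `interval_set`s.
#' @param gaps a non-empty gap `interval_set`.
#' @return `list(table =, spearman_rho =)`; `spearman_rho` is `NA` when the
#'   correlation is undefined (e.g. no track touches a gap).
#' @export
overlap_vs_segment_length <- function(tracks, gaps) {
  if (inherits(tracks, "interval_set")) tracks <- list(tracks)
  if (length(tracks) < 2) stop("need at least 2 tracks")
  prof <- profile_gap_overlap(tracks, gaps)
  tab <- prof$per_track_table[, c("track", "mean_segment_length",
                                  "relative_gap_overlap")]
  x <- tab$mean_segment_length
  y <- tab$relative_gap_overlap
  rho <- if (stats::sd(y) == 0 || stats::sd(x) == 0) NA_real_ else
    suppressWarnings(cor(x, y, method = "spearman"))
  list(table = tab, spearman_rho = rho)
}
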