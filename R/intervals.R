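#' Construct a genomic interval set (a "track")
#'
#' An interval set is a named, sorted collection of 0-based half-open
#' `(chrom, start, end)` regions, the common representation for both
#' genomic tracks and gap sets. On construction the set is canonicalized:
#' sorted by (chromosome, start) and, by default, same-chromosome
#' overlapping or bookended intervals are merged.
#'
#' @param chrom character vector of chromosome names (or a data.frame with
#'   columns `chrom`, `start`, `end`).
#' @param start,end numeric vectors, 0-based half-open.
#' @param label track label.
#' @param genome optional [genome()]; when given, chromosome names are
#'   validated and intervals extending past a chromosome end are clipped
#'   with a warning (tolerance for real-world BED dialect drift).
#' @param merge merge overlapping and bookended intervals (default). The
#'   shuffler disables merging so that the element length multiset is
#'   conserved exactly even when two placed elements happen to be bookended.
#' @return an object of class `interval_set`: a data.frame with columns
#'   `chrom`, `start`, `end` and a `label` attribute.
#' @export
#' @examples
#' interval_set(c("chr1", "chr1"), c(0, 5), c(10, 20), label = "demo")
interval_set <- function(chrom, start = NULL, end = NULL, label = "",
                         genome = NULL, merge = TRUE) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    chrom <- as.character(df$chrom)
    start <- as.numeric(df$start)
    end <- as.numeric(df$end)
  } else {
    chrom <- as.character(chrom)
    start <- as.numeric(start)
    end <- as.numeric(end)
  }
  if (length(chrom) == 1 && length(start) > 1) {
    chrom <- rep(chrom, length(start))
  }
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop("non-finite interval coordinates")
  }
  if (any(start < 0)) stop("interval start < 0")
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    stop(sprintf("interval with start >= end: %s:%.0f-%.0f",
                 chrom[i], start[i], end[i]))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), genome$names)
    if (length(unknown)) {
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    }
    lens <- genome$lengths[chrom]
    if (any(end > lens)) {
      warning(sprintf("%d interval(s) extend past the chromosome end; clipped",
                      sum(end > lens)))
      end <- pmin(end, lens)
      drop <- start >= end
      if (any(drop)) {
        chrom <- chrom[!drop]; start <- start[!drop]; end <- end[!drop]
      }
    }
    lev <- genome$names
  } else {
    lev <- sort(unique(chrom))
  }
  o <- order(match(chrom, lev), start, end)
  df <- data.frame(chrom = chrom[o], start = start[o], end = end[o],
                   stringsAsFactors = FALSE)
  if (merge && nrow(df) > 1) df <- merge_sorted(df)
  structure(df, class = c("interval_set", "data.frame"), label = label)
}

# Merge overlapping/bookended intervals of a (chrom, start)-sorted frame.
merge_sorted <- function(df) {
  newchrom <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)])
  # chromosome-wise running max of end, lagged by one row
  grp0 <- cumsum(newchrom)
  cme <- stats::ave(df$end, grp0, FUN = cummax)
  lag_cme <- c(-Inf, cme[-nrow(df)])
  lag_cme[newchrom] <- -Inf
  grp <- cumsum(newchrom | df$start > lag_cme)
  out <- data.frame(
    chrom = df$chrom[!duplicated(grp)],
    start = as.numeric(tapply(df$start, grp, min)),
    end = as.numeric(tapply(df$end, grp, max)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> '%s': %d interval(s), %.0f bp\n",
              attr(x, "label"), nrow(x), total_bp(x)))
  if (nrow(x) > 0) print(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more\n", nrow(x) - 5))
  invisible(x)
}

#' Number of intervals in a set
#' @param x an `interval_set`.
#' @export
n_intervals <- function(x) nrow(x)

#' Total covered base pairs of an interval set
#' @param x an `interval_set`.
#' @export
total_bp <- function(x) if (nrow(x) == 0) 0 else sum(x$end - x$start)

#' Segment lengths (bp) of an interval set
#' @param x an `interval_set`.
#' @export
segment_lengths <- function(x) as.numeric(x$end - x$start)

#' Track label of an interval set
#' @param x an `interval_set`.
#' @export
track_label <- function(x) attr(x, "label")

empty_interval_set <- function(label = "") {
  interval_set(character(0), numeric(0), numeric(0), label = label)
}

# Map an interval set to absolute (linearized) coordinates; returns sorted
# start/end numeric vectors.
linearize <- function(x, genome) {
  if (nrow(x) == 0) return(list(start = numeric(0), end = numeric(0)))
  unknown <- setdiff(unique(x$chrom), genome$names)
  if (length(unknown)) {
    stop("interval set has chromosome(s) absent from genome: ",
         paste(unknown, collapse = ", "))
  }
  if (any(x$end > genome$lengths[x$chrom])) {
    stop("interval(s) extend past chromosome end")
  }
  off <- genome$offsets[x$chrom]
  s <- unname(off + x$start)
  e <- unname(off + x$end)
  if (is.unsorted(s)) {
    o <- order(s)
    s <- s[o]; e <- e[o]
  }
  list(start = s, end = e)
}

# Inverse of linearize: absolute sorted coordinates back to an interval_set.
delinearize <- function(start, end, genome, label = "", merge = FALSE) {
  if (length(start) == 0) return(empty_interval_set(label))
  bounds <- c(unname(genome$offsets), genome$total)
  ci <- findInterval(start, bounds)
  chrom <- genome$names[ci]
  off <- genome$offsets[ci]
  interval_set(chrom, start - off, end - off, label = label,
               genome = genome, merge = merge)
}

#' Complement of an interval set within a genome
#'
#' Returns the exact per-chromosome set complement: the parts of the genome
#' not covered by `x`. Used to turn a gap set into the accessible
#' (gap-free) placement universe.
#'
#' @param x an `interval_set` (canonical, within the genome).
#' @param genome a [genome()].
#' @return an `interval_set` covering `genome` minus `x`.
#' @export
#' @examples
#' g <- genome(c(chr1 = 100))
#' gaps <- interval_set("chr1", 10, 20, label = "gaps")
#' complement(gaps, g)
complement <- function(x, genome) {
  stopifnot(inherits(x, "interval_set"), inherits(genome, "genome"))
  if (nrow(x) > 0) {
    unknown <- setdiff(unique(x$chrom), genome$names)
    if (length(unknown)) {
      stop("interval set has chromosome(s) absent from genome: ",
           paste(unknown, collapse = ", "))
    }
    if (any(x$end > genome$lengths[x$chrom])) {
      stop("interval(s) extend past chromosome end")
    }
  }
  out <- vector("list", length(genome$names))
  for (i in seq_along(genome$names)) {
    cn <- genome$names[i]
    len <- genome$lengths[[cn]]
    sub <- x[x$chrom == cn, , drop = FALSE]
    cs <- c(0, sub$end)
    ce <- c(sub$start, len)
    keep <- cs < ce
    out[[i]] <- data.frame(chrom = rep(cn, sum(keep)), start = cs[keep],
                           end = ce[keep], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  interval_set(df, label = paste0("complement(", attr(x, "label"), ")"),
               genome = genome)
}

#' Base-pair overlap between two interval sets
#'
#' The colocalization test statistic: the total number of bases covered by
#' both sets. Symmetric; `base_overlap(a, a)` equals `total_bp(a)`.
#'
#' @param a,b canonical `interval_set`s.
#' @return overlap in bp (numeric scalar).
#' @export
#' @examples
#' a <- interval_set("chr1", 0, 10)
#' b <- interval_set("chr1", 5, 15)
#' base_overlap(a, b)  # 5
base_overlap <- function(a, b) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  chroms <- sort(unique(c(a$chrom, b$chrom)))
  span <- vapply(chroms, function(cn) {
    max(a$end[a$chrom == cn], b$end[b$chrom == cn], 0)
  }, numeric(1))
  off <- cumsum(c(0, span[-length(span)]))
  names(off) <- chroms
  lin <- function(x) {
    s <- off[x$chrom] + x$start
    e <- off[x$chrom] + x$end
    o <- order(s)
    list(start = unname(s[o]), end = unname(e[o]))
  }
  la <- lin(a); lb <- lin(b)
  cpp_overlap_sorted(la$start, la$end, lb$start, lb$end)
}

#' Per-region base overlap of a track with a set of regions
#'
#' For each region, the number of its bases covered by `track`. This is the
#' workhorse behind the gap-overlap profiling statistics and window-based
#' coverage diagnostics.
#'
#' @param track an `interval_set`.
#' @param regions an `interval_set` (or plain data.frame with
#'   chrom/start/end); regions may overlap each other.
#' @return numeric vector of overlaps, one per row of `regions`, in bp.
#' @export
overlap_by_interval <- function(track, regions) {
  if (nrow(regions) == 0) return(numeric(0))
  if (nrow(track) == 0) return(numeric(nrow(regions)))
  out <- numeric(nrow(regions))
  for (cn in unique(regions$chrom)) {
    ri <- which(regions$chrom == cn)
    sub <- track[track$chrom == cn, , drop = FALSE]
    if (nrow(sub) == 0) next
    ts <- sub$start; te <- sub$end
    cum <- cumsum(te - ts)
    covfun <- function(x) {
      i <- findInterval(x, ts)
      out <- numeric(length(x))
      pos <- i > 0
      ii <- i[pos]
      out[pos] <- cum[ii] - pmax(0, te[ii] - pmax(x[pos], ts[ii]))
      out
    }
    out[ri] <- covfun(regions$end[ri]) - covfun(regions$start[ri])
  }
  out
}

#' The accessible placement space of a genome
#'
#' The placement universe of a null model: the whole genome, or the genome
#' minus a gap set ("the allowed parts of the genome"). Holds the
#' linearized accessible runs used by the constrained shuffler.
#'
#' @param genome a [genome()].
#' @param gaps optional `interval_set` of inaccessible regions; `NULL` (or
#'   an empty set) means the whole genome is accessible.
#' @return an object of class `accessible_space` with fields `genome`,
#'   `regions` (the gap complement as an `interval_set`), `run_start` /
#'   `run_len` (linearized runs) and `total_bp`.
#' @export
accessible_space <- function(genome, gaps = NULL) {
  stopifnot(inherits(genome, "genome"))
  if (is.null(gaps) || nrow(gaps) == 0) {
    regions <- interval_set(
      data.frame(chrom = genome$names, start = 0,
                 end = unname(genome$lengths), stringsAsFactors = FALSE),
      label = "accessible", genome = genome)
  } else {
    regions <- complement(gaps, genome)
    attr(regions, "label") <- "accessible"
  }
  lin <- linearize(regions, genome)
  structure(
    list(genome = genome, regions = regions,
         run_start = lin$start, run_len = lin$end - lin$start,
         total_bp = sum(lin$end - lin$start)),
    class = "accessible_space"
  )
}

#' @export
print.accessible_space <- function(x, ...) {
  cat(sprintf("<accessible_space> %.0f of %.0f bp accessible (%.2f%%), %d run(s)\n",
              x$total_bp, x$genome$total, 100 * x$total_bp / x$genome$total,
              length(x$run_len)))
  invisible(x)
}
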