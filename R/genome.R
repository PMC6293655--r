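#' Construct a genome (the coordinate universe)
#'
#' A genome is an ordered set of chromosomes with lengths, optionally
#' annotated with the position splitting each chromosome into p and q arms.
#' All coordinates in the package are 0-based half-open (BED convention).
#'
#' @param lengths named numeric vector of chromosome lengths in bp
#'   (names are chromosome names, order is kept).
#' @param arm_split optional named numeric vector: for a chromosome name,
#'   the position separating the p arm `[0, split)` from the q arm
#'   `[split, length)`. Must lie strictly inside the chromosome.
#' @return an object of class `genome` with fields `names`, `lengths`,
#'   `offsets` (cumulative start of each chromosome in the linearized
#'   coordinate space), `total` and `arm_split`.
#' @export
#' @examples
#' g <- genome(c(chr1 = 1000, chr2 = 500), arm_split = c(chr1 = 400))
#' g$total
genome <- function(lengths, arm_split = NULL) {
  nm <- names(lengths)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("chromosome names must be non-empty")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths))) {
    stop("chromosome lengths must be positive integers")
  }
  names(lengths) <- nm
  if (!is.null(arm_split)) {
    if (is.null(names(arm_split)) || !all(names(arm_split) %in% nm)) {
      stop("arm_split names must be chromosome names")
    }
    bad <- arm_split <= 0 | arm_split >= lengths[names(arm_split)]
    if (any(bad)) {
      stop("arm_split must lie strictly inside the chromosome: ",
           paste(names(arm_split)[bad], collapse = ", "))
    }
  }
  offsets <- cumsum(c(0, unname(lengths[-length(lengths)])))
  names(offsets) <- nm
  structure(
    list(names = nm, lengths = lengths, offsets = offsets,
         total = sum(lengths), arm_split = arm_split),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d chromosome(s), %.0f bp total\n",
              length(x$names), x$total))
  n <- min(length(x$names), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %s  %.0f bp%s\n", x$names[i], x$lengths[i],
                if (!is.null(x$arm_split) && x$names[i] %in% names(x$arm_split))
                  sprintf("  (arm split at %.0f)", x$arm_split[[x$names[i]]])
                else ""))
  }
  if (length(x$names) > n) cat(sprintf("  ... %d more\n", length(x$names) - n))
  invisible(x)
}

#' Read a UCSC-style chrom.sizes file
#'
#' Parses a two-or-more column tab-separated file of chromosome name and
#' length (extra columns are ignored), keeping file order.
#'
#' @param path path to the chrom.sizes file.
#' @return a [genome()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) stop("empty chrom.sizes file: ", path)
  nms <- character(length(keep))
  lens <- numeric(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) {
      stop(sprintf("chrom.sizes format error at line %d: expected >= 2 tab-separated columns", ln))
    }
    if (!grepl("^[0-9]+$", f[2])) {
      stop(sprintf("chrom.sizes format error at line %d: non-integer length '%s'", ln, f[2]))
    }
    len <- as.numeric(f[2])
    if (len <= 0) {
      stop(sprintf("chrom.sizes format error at line %d: non-positive length", ln))
    }
    nms[i] <- f[1]
    lens[i] <- len
  }
  if (anyDuplicated(nms)) {
    stop("chrom.sizes format error: duplicate chromosome name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(lens) <- nms
  genome(lens)
}

#' Write a genome as a chrom.sizes file
#'
#' @param g a [genome()].
#' @param path output path.
#' @export
write_chrom_sizes <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  writeLines(sprintf("%s\t%.0f", g$names, g$lengths), path)
  invisible(path)
}
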