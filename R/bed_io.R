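#' Read a BED3+ file into an interval set
#'
#' Reads tab-separated BED3-or-more lines into a canonical [interval_set()]
#' (sorted, same-chromosome overlapping or bookended intervals merged).
#' `track`, `browser` and `#` comment lines are tolerated and skipped;
#' columns beyond the third are ignored. With `ucsc_gap_table = TRUE` the
#' UCSC gap-table dump dialect is read instead: that table prepends a `bin`
#' column and appends gap-type columns, so chrom/start/end are taken from
#' columns 2-4.
#'
#' @param path path to the file.
#' @param genome optional [genome()]: chromosome names are validated
#'   (unknown names are an error) and intervals running past a chromosome
#'   end are clipped with a warning.
#' @param label track label; defaults to the file name.
#' @param ucsc_gap_table read the UCSC gap-table dialect (columns 2-4).
#' @return a canonical `interval_set`.
#' @export
read_bed <- function(path, genome = NULL, label = basename(path),
                     ucsc_gap_table = FALSE) {
  lines <- readLines(path)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
  keep <- which(!skip)
  if (length(keep) == 0) return(empty_interval_set(label))
  cols <- if (ucsc_gap_table) 2:4 else 1:3
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n <- length(keep)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < max(cols)) {
      stop(sprintf("BED format error at line %d: expected >= %d tab-separated columns",
                   keep[i], max(cols)))
    }
    s <- f[cols[2]]; e <- f[cols[3]]
    if (!grepl("^[0-9]+$", s) || !grepl("^[0-9]+$", e)) {
      stop(sprintf("BED format error at line %d: non-integer coordinates", keep[i]))
    }
    chrom[i] <- f[cols[1]]
    start[i] <- as.numeric(s)
    end[i] <- as.numeric(e)
    if (start[i] >= end[i]) {
      stop(sprintf("BED format error at line %d: start >= end (%s:%s-%s)",
                   keep[i], chrom[i], s, e))
    }
  }
  interval_set(chrom, start, end, label = label, genome = genome)
}

#' Write an interval set as a BED3 file
#'
#' Writes the canonical set so that `read_bed(write_bed(x))` reproduces `x`
#' exactly and re-serialization is byte-identical.
#'
#' @param x an `interval_set`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "interval_set"))
  if (nrow(x) == 0) {
    writeLines(character(0), path)
  } else {
    writeLines(sprintf("%s\t%.0f\t%.0f", x$chrom, x$start, x$end), path)
  }
  invisible(path)
}
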