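test_that("chrom.sizes parsing keeps file order and rejects malformed input", {
  f <- withr::local_tempfile()
  writeLines(c("chrT\t1000"), f)
  g <- read_chrom_sizes(f)
  expect_equal(g$names, "chrT")
  expect_equal(unname(g$lengths), 1000)

  writeLines(c("chr1\t100", "chr2\t200"), f)
  g <- read_chrom_sizes(f)
  expect_equal(g$total, 300)
  expect_equal(g$names, c("chr1", "chr2"))

  writeLines(c("chr1\t0"), f)
  expect_error(read_chrom_sizes(f), "line 1")
  writeLines(c("chr1\t100", "chr1\t50"), f)
  expect_error(read_chrom_sizes(f), "duplicate")
  writeLines(c("chr1\t100", "chr2\tfoo"), f)
  expect_error(read_chrom_sizes(f), "line 2")
  # extra columns ignored
  writeLines(c("chr1\t100\t/gbdb/whatever"), f)
  expect_equal(read_chrom_sizes(f)$total, 100)
})

test_that("genome construction enforces its invariants", {
  expect_error(genome(c(chr1 = 100, chr1 = 50)), "duplicate")
  expect_error(genome(c(chr1 = -5)), "positive")
  expect_error(genome(c(chr1 = 100), arm_split = c(chr1 = 100)), "strictly inside")
  expect_error(genome(c(chr1 = 100), arm_split = c(chrX = 50)), "chromosome names")
  g <- genome(c(chr1 = 100, chr2 = 50), arm_split = c(chr1 = 40))
  expect_equal(unname(g$offsets), c(0, 100))
})

test_that("BED reading canonicalizes, tolerates dialect lines, and validates", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t0\t10", "chr1\t5\t20"), f)
  x <- read_bed(f)
  expect_equal(nrow(x), 1)
  expect_equal(x$start, 0)
  expect_equal(x$end, 20)

  writeLines(character(0), f)
  expect_equal(nrow(read_bed(f)), 0)

  writeLines(c("track name=x", "# comment", "browser position chr1",
               "chr1\t0\t5\tname\t960\t+"), f)
  x <- read_bed(f)
  expect_equal(nrow(x), 1)

  writeLines(c("chr1\t10\t10"), f)
  expect_error(read_bed(f), "start >= end")
  writeLines(c("chr1\tx\t10"), f)
  expect_error(read_bed(f), "line 1")

  g <- toy_genome(chr1 = 100)
  writeLines(c("chr9\t0\t10"), f)
  expect_error(read_bed(f, genome = g), "chr9")
  writeLines(c("chr1\t90\t150"), f)
  expect_warning(x <- read_bed(f, genome = g), "clipped")
  expect_equal(x$end, 100)
})

test_that("UCSC gap-table dialect takes chrom/start/end from columns 2-4", {
  f <- withr::local_tempfile()
  writeLines(c("#bin\tchrom\tchromStart\tchromEnd\tix\tn\tsize\ttype\tbridge",
               "585\tchr1\t0\t10000\t1\tN\t10000\ttelomere\tno",
               "585\tchr1\t20000\t21000\t2\tN\t1000\tclone\tyes"), f)
  x <- read_bed(f, ucsc_gap_table = TRUE)
  expect_equal(nrow(x), 2)
  expect_equal(x$start, c(0, 20000))
  expect_equal(x$end, c(10000, 21000))
})

test_that("BED writing round-trips exactly and is byte-stable", {
  g <- toy_genome(chr1 = 5000, chr2 = 5000)
  x <- interval_set(c("chr2", "chr1", "chr1"), c(10, 500, 0),
                    c(40, 900, 100), label = "t", genome = g)
  f <- withr::local_tempfile()
  write_bed(x, f)
  y <- read_bed(f, genome = g, label = "t")
  expect_equal(as.data.frame(y), as.data.frame(x))

  write_bed(empty_set <- interval_set(character(0), numeric(0), numeric(0)), f)
  expect_length(readLines(f), 0)

  # one round-trip then byte-identical re-serialization
  withr::with_seed(11, {
    z <- random_iset(g, 100, max_len = 80)
  })
  f2 <- withr::local_tempfile()
  write_bed(z, f)
  write_bed(read_bed(f), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("canonicalization is idempotent and order-insensitive (bitmap oracle)", {
  withr::with_seed(202, {
    for (rep in 1:25) {
      g <- toy_genome(chr1 = 400, chr2 = 300)
      raw <- random_raw_intervals(g, 50, max_len = 60)
      shuf <- raw[sample.int(nrow(raw)), ]
      a <- interval_set(raw, genome = g)
      b <- interval_set(shuf, genome = g)
      expect_identical(as.data.frame(a), as.data.frame(b))
      # canonical set covers exactly the raw per-base occupancy
      v <- logical(g$total)
      off <- g$offsets[raw$chrom]
      for (i in seq_len(nrow(raw))) v[(off[i] + raw$start[i] + 1):(off[i] + raw$end[i])] <- TRUE
      expect_identical(bitmap_of(a, g), v)
      # idempotence
      c2 <- interval_set(as.data.frame(a), genome = g)
      expect_identical(as.data.frame(c2), as.data.frame(a))
      # no overlapping or bookended neighbours survive
      same <- a$chrom[-1] == a$chrom[-nrow(a)]
      if (any(same)) expect_true(all(a$start[-1][same] > a$end[-nrow(a)][same]))
    }
  })
})

test_that("complement matches the spec examples, involutes, and conserves length", {
  g <- toy_genome(chr1 = 100)
  gaps <- interval_set("chr1", 10, 20)
  cmp <- complement(gaps, g)
  expect_equal(cmp$start, c(0, 20))
  expect_equal(cmp$end, c(10, 100))

  empty <- interval_set(character(0), numeric(0), numeric(0))
  expect_equal(total_bp(complement(empty, g)), 100)

  full <- interval_set("chr1", 0, 100)
  expect_equal(nrow(complement(full, g)), 0)

  expect_error(complement(interval_set("chr1", 0, 500), g), "past chromosome end")

  withr::with_seed(303, {
    for (rep in 1:20) {
      g2 <- toy_genome(chrA = 150, chrB = 250)
      x <- random_iset(g2, 12, max_len = 40)
      cx <- complement(x, g2)
      expect_equal(total_bp(x) + total_bp(cx), g2$total)
      back <- complement(cx, g2)
      expect_equal(as.data.frame(back), as.data.frame(x), ignore_attr = TRUE)
      expect_identical(bitmap_of(cx, g2), !bitmap_of(x, g2))
    }
  })
})

test_that("base_overlap matches examples and elementary bounds", {
  a <- interval_set("chr1", 0, 10)
  b <- interval_set("chr1", 5, 15)
  expect_equal(base_overlap(a, b), 5)
  expect_equal(base_overlap(interval_set(character(0), numeric(0), numeric(0)), b), 0)
  expect_equal(base_overlap(a, a), total_bp(a))

  withr::with_seed(404, {
    for (rep in 1:20) {
      g <- toy_genome(chr1 = 600, chr2 = 400)
      x <- random_iset(g, 30, 50)
      y <- random_iset(g, 30, 50)
      ov <- base_overlap(x, y)
      expect_equal(ov, base_overlap(y, x))
      expect_lte(ov, min(total_bp(x), total_bp(y)))
    }
  })
})

test_that("base_overlap agrees with IRanges on random instances", {
  withr::with_seed(505, {
    g <- toy_genome(chr1 = 2000)
    for (rep in 1:10) {
      x <- random_iset(g, 40, 60)
      y <- random_iset(g, 40, 60)
      ir <- function(s) IRanges::IRanges(start = s$start + 1, end = s$end)
      expected <- sum(IRanges::width(IRanges::intersect(ir(x), ir(y))))
      expect_equal(base_overlap(x, y), expected)
    }
  })
})

test_that("overlap_by_interval counts per-region coverage exactly", {
  g <- toy_genome(chr1 = 1000)
  withr::with_seed(606, {
    track <- random_iset(g, 25, 40)
    regions <- random_raw_intervals(g, 15, 100)
    got <- overlap_by_interval(track, regions)
    bm <- bitmap_of(track, g)
    want <- vapply(seq_len(nrow(regions)), function(i) {
      sum(bm[(regions$start[i] + 1):regions$end[i]])
    }, numeric(1))
    expect_equal(got, want)
  })
})

test_that("accessible space bookkeeping matches the gap complement", {
  g <- toy_genome(chr1 = 100, chr2 = 60)
  gaps <- interval_set(c("chr1", "chr2"), c(10, 0), c(30, 60), label = "gaps")
  sp <- accessible_space(g, gaps)
  expect_equal(sp$total_bp, 160 - 20 - 60)
  expect_equal(sum(sp$run_len), sp$total_bp)
  expect_equal(total_bp(sp$regions) + total_bp(gaps), g$total)
  # empty gap set: whole genome accessible
  sp0 <- accessible_space(g)
  expect_equal(sp0$total_bp, g$total)
})
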