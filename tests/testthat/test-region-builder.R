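# Interval arithmetic and the element-catalog subtraction rules.

test_that("merge_intervals produces a minimal disjoint sorted cover", {
  m <- merge_intervals(intervals("chr1", c(10, 15), c(20, 30)))
  expect_equal(m[, c("start", "end")], data.frame(start = 10, end = 30))
  m <- merge_intervals(intervals("chr1", c(10, 20), c(20, 25)))
  expect_equal(m[, c("start", "end")], data.frame(start = 10, end = 25))
  m <- merge_intervals(intervals("chr1", c(30, 10), c(40, 20)))
  expect_equal(m[, c("start", "end")], data.frame(start = c(10, 30),
                                                  end = c(20, 40)))
  expect_equal(nrow(merge_intervals(intervals())), 0L)
})

test_that("subtract_intervals computes set differences", {
  s <- subtract_intervals(intervals("chr1", 0, 100), intervals("chr1", 40, 60))
  expect_equal(s[, c("start", "end")], data.frame(start = c(0, 60),
                                                  end = c(40, 100)))
  expect_equal(nrow(subtract_intervals(intervals("chr1", 0, 10),
                                       intervals("chr1", 0, 10))), 0L)
  s <- subtract_intervals(intervals("chr1", 0, 10), intervals("chr1", 20, 30))
  expect_equal(s[, c("start", "end")], data.frame(start = 0, end = 10))
})

test_that("merge/subtract lengths agree with a per-base membership oracle", {
  set.seed(14)
  for (rep in 1:25) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    mk <- function(n) {
      s <- sample(0:900, n); w <- sample(1:120, n, TRUE)
      intervals("chr1", s, s + w)
    }
    a <- mk(na); b <- mk(nb)
    in_set <- function(iv) {
      x <- rep(FALSE, 1100)
      for (i in seq_len(nrow(iv))) x[(iv$start[i] + 1):iv$end[i]] <- TRUE
      x
    }
    expect_equal(interval_length(merge_intervals(a)), sum(in_set(a)))
    expect_equal(interval_length(subtract_intervals(a, b)),
                 sum(in_set(a) & !in_set(b)))
    # len(a \ b) = len(a) - len(a ∩ b)
    expect_equal(interval_length(merge_intervals(subtract_intervals(a, b))),
                 sum(in_set(a)) - sum(in_set(a) & in_set(b)))
  }
})

test_that("splice regions take intron edges without double counting", {
  s <- build_splice_regions(intervals("chr1", 1000, 1200), flank = 50)
  expect_equal(s[, c("start", "end")],
               data.frame(start = c(1000, 1150), end = c(1050, 1200)))
  # flanks overlapping -> whole intron, single region
  s <- build_splice_regions(intervals("chr1", 1000, 1060), flank = 50)
  expect_equal(s[, c("start", "end")], data.frame(start = 1000, end = 1060))
  # flanks exactly tiling
  s <- build_splice_regions(intervals("chr1", 1000, 1100), flank = 50)
  expect_equal(s[, c("start", "end")], data.frame(start = 1000, end = 1100))
})

test_that("promoter windows are strand-aware and clipped", {
  lens <- c(chr1 = 50000)
  p <- build_promoters(data.frame(chrom = "chr1", tss = 10001, strand = "+"),
                       2500, lens)
  expect_equal(p[, c("start", "end")], data.frame(start = 7500, end = 10000))
  p <- build_promoters(data.frame(chrom = "chr1", tss = 10000, strand = "-"),
                       2500, lens)
  expect_equal(p[, c("start", "end")], data.frame(start = 10000, end = 12500))
  p <- build_promoters(data.frame(chrom = "chr1", tss = 100, strand = "+"),
                       2500, lens)
  expect_equal(p[, c("start", "end")], data.frame(start = 0, end = 99))
  expect_error(build_promoters(data.frame(chrom = "chr1", tss = 60000,
                                          strand = "+"), 2500, lens),
               "bounds")
})

test_that("catalog subtraction removes CDS from UTRs, 3'UTR from 5'UTR and everything from promoters", {
  g <- toy_genome(60000, seed = 5)
  # gene A (+): exon 20001-21000, CDS 20201-20800, UTR5 20001-20200,
  # UTR3 20801-21000 overlapping a crafted CDS of gene B (20901-21100);
  # gene B's 5' UTR 20801-20900 overlaps gene A's 3' UTR.
  gtf <- write_toy_gtf(list(
    c("gene", 20001, 21000, "+", "GA", "TA", "protein_coding"),
    c("transcript", 20001, 21000, "+", "GA", "TA", "protein_coding"),
    c("exon", 20001, 21000, "+", "GA", "TA", "protein_coding"),
    c("UTR", 20001, 20200, "+", "GA", "TA", "protein_coding"),
    c("CDS", 20201, 20800, "+", "GA", "TA", "protein_coding"),
    c("UTR", 20801, 21000, "+", "GA", "TA", "protein_coding"),
    c("gene", 20801, 21300, "+", "GB", "TB", "protein_coding"),
    c("transcript", 20801, 21300, "+", "GB", "TB", "protein_coding"),
    c("exon", 20801, 21300, "+", "GB", "TB", "protein_coding"),
    c("UTR", 20801, 20900, "+", "GB", "TB", "protein_coding"),
    c("CDS", 20901, 21100, "+", "GB", "TB", "protein_coding"),
    c("UTR", 21101, 21300, "+", "GB", "TB", "protein_coding")))
  cat <- build_catalog(gtf, g)
  seg_iv <- function(id) {
    s <- cat$elements[[id]]$segments
    intervals("chr1", s$start, s$end)
  }
  # gene A 3' UTR loses the bases covered by gene B's CDS (20901-21100 -> 0-based 20900-21100)
  expect_equal(seg_iv("GA:utr3")[, c("start", "end")],
               data.frame(start = 20800, end = 20900))
  # gene B 5' UTR overlaps gene A 3' UTR (global utr3 mask) -> removed entirely
  expect_false("GB:utr5" %in% names(cat$elements))
  expect_true(any(grepl("GB:utr5", attr(cat, "dropped"))))
  # promoter of gene B (upstream of TSS 20801) overlaps gene A CDS/UTRs -> holes
  pb <- seg_iv("GB:promoter")
  cds_a <- seg_iv("GA:cds")
  olap <- interval_length(subtract_intervals(pb, subtract_intervals(pb, cds_a)))
  expect_equal(olap, 0)
})

test_that("catalogs built from random annotations keep promoters/UTRs free of CDS", {
  spec <- synthetic_spec(seed = 21, n_genes = 8, n_lncrna = 2,
                         chrom_lengths = c(chr1 = 500000L))
  g <- generate_genome(spec)
  cat <- build_catalog(generate_annotation(spec, g), g)
  types <- vapply(cat$elements, `[[`, "", "element_type")
  ivs_of <- function(tt) {
    merge_intervals(do.call(rbind, lapply(cat$elements[types %in% tt],
      function(e) intervals(e$chrom, e$segments$start, e$segments$end))))
  }
  cds <- ivs_of("cds")
  for (tt in c("promoter", "utr5", "utr3", "lncrna")) {
    iv <- ivs_of(tt)
    expect_equal(interval_length(subtract_intervals(iv, cds)),
                 interval_length(iv), info = tt)
  }
  # 5' and 3' UTRs never share a base
  u5 <- ivs_of("utr5"); u3 <- ivs_of("utr3")
  expect_equal(interval_length(subtract_intervals(u5, u3)),
               interval_length(u5))
  # the index maps interior bases back to their element
  e <- cat$elements[[which(types == "cds")[1]]]
  p <- e$segments$start[1] + 1
  expect_true(e$element_id %in% elements_at(cat, e$chrom, p))
})

test_that("catalog round-trips through the BED-like TSV", {
  spec <- synthetic_spec(seed = 22, n_genes = 4, n_lncrna = 1,
                         chrom_lengths = c(chr1 = 300000L))
  g <- generate_genome(spec)
  cat <- build_catalog(generate_annotation(spec, g), g)
  f <- tempfile(fileext = ".tsv")
  write_catalog(cat, f)
  back <- read_catalog(f)
  expect_setequal(names(back$elements), names(cat$elements))
  for (id in names(cat$elements)) {
    expect_equal(back$elements[[id]]$segments, cat$elements[[id]]$segments,
                 info = id)
  }
})
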