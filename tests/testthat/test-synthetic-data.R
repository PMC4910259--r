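# The synthetic data generator: determinism, composition guarantees, and
# recovery of the generating signature.

test_that("generate_genome is deterministic with the requested GC content", {
  spec <- synthetic_spec(seed = 101, chrom_lengths = c(chr1 = 100000L),
                         gc = 0.5)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(unclass(g1), unclass(g2))
  s <- unclass(g1)[["chr1"]]
  gc <- (lengths(regmatches(s, gregexpr("[GC]", s)))) / nchar(s)
  expect_gt(gc, 0.48); expect_lt(gc, 0.52)
  # minimal chromosome still works end to end
  tiny <- generate_genome(synthetic_spec(seed = 1, chrom_lengths = c(c1 = 10L)))
  expect_equal(chrom_lengths(tiny)[["c1"]], 10L)
})

test_that("generated scores cover every substitution and hotspots top the element", {
  spec <- synthetic_spec(seed = 102, n_genes = 5, n_lncrna = 1,
                         chrom_lengths = c(chr1 = 300000L),
                         n_drivers = 1)
  g <- generate_genome(spec)
  cat <- build_catalog(generate_annotation(spec, g), g)
  st <- generate_scores(spec, g, cat)
  # completeness: 3 scores per element base
  el <- cat$elements[[5]]
  vec <- element_scores(st, el, uniform_signature(), g)
  expect_equal(nrow(vec), 3L * element_length(el))
  # hotspots exceed the 99th percentile of their element's other scores
  hs <- attr(st, "hotspots")
  expect_equal(nrow(hs), spec$n_hotspots)
  d <- hs$element_id[1]
  vd <- element_scores(st, cat$elements[[d]], uniform_signature(), g)
  bg <- vd$score[!(paste(vd$pos, vd$alt) %in% paste(hs$pos, hs$alt))]
  expect_true(all(hs$score > quantile(bg, 0.99)))
  # determinism
  st2 <- generate_scores(spec, g, cat)
  expect_identical(st2$table, st$table)
})

test_that("null cohorts validate cleanly and recover the generating signature", {
  # 250 samples x ~40 mutations ~ 10,000 SNVs
  spec <- synthetic_spec(seed = 103, n_samples = 250)
  ds <- generate_dataset(spec)
  expect_equal(attr(ds$cohort, "qc")$n_ref_mismatch, 0L)
  expect_equal(attr(ds$cohort, "qc")$n_retained,
               attr(ds$cohort, "qc")$n_input)
  expect_gt(n_mutations(ds$cohort), 9000)
  sig_hat <- compute_signature(ds$cohort, ds$genome, "cohort")
  tv <- 0.5 * sum(abs(sig_hat$probabilities -
                        spec$signature$probabilities))
  expect_lt(tv, 0.03)
})

test_that("datasets are reproducible end to end and driver cohorts mark truth", {
  spec <- synthetic_spec(seed = 104, n_genes = 6, n_lncrna = 1,
                         chrom_lengths = c(chr1 = 400000L),
                         n_samples = 10, muts_per_sample = 10,
                         n_drivers = 1, driver_samples = 5)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$cohort$mutations, d2$cohort$mutations)
  expect_identical(d1$store$table, d2$store$table)
  expect_length(d1$truth, 1L)
  expect_true(d1$truth %in% names(d1$catalog$elements))
  # driver samples carry the extra driver mutation
  in_driver <- observed_mean(d1$catalog$elements[[d1$truth]], d1$cohort,
                             d1$store)
  expect_gte(in_driver$n_samples, 5L)

  # file export round-trips through the standard readers
  dir <- tempfile()
  generate_dataset(spec, dir = dir)
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(unclass(g), unclass(d1$genome))
  ms <- validate_mutations(read_mutations(file.path(dir, "mutations.tsv")), g)
  expect_equal(n_mutations(ms), n_mutations(d1$cohort))
  st <- read_scores(file.path(dir, "scores.tsv"), provider = "synthetic")
  expect_equal(nrow(st$table), nrow(d1$store$table))
  cat2 <- build_catalog(file.path(dir, "annotation.gtf"), g)
  expect_setequal(names(cat2$elements), names(d1$catalog$elements))
})
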