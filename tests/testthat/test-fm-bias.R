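# Observed means, Monte-Carlo background, empirical p-values, BH adjustment.

test_that("observed_mean averages scored mutations and counts occurrences", {
  g <- toy_genome(300, seed = 12)
  pos <- c(101, 120)
  ref <- genome_base(g, "chr1", pos)
  alt <- vapply(ref, function(r) setdiff(c("A","C","G","T"), r)[1], "")
  st <- score_store(data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                               score = c(2, 4)))
  el <- toy_element(start = 100, end = 200)
  ms <- mutation_set(raw_muts("chr1", pos, ref, alt, c("s1", "s2")))
  ob <- observed_mean(el, ms, st)
  expect_equal(ob$observed_mean, 3)
  expect_equal(ob$k, 2L)

  # recurrent mutation: one position, three samples, each occurrence counts
  ms3 <- mutation_set(raw_muts("chr1", rep(pos[1], 3), ref[1], alt[1],
                               c("s1", "s2", "s3")))
  ob3 <- observed_mean(el, ms3, st)
  expect_equal(ob3$observed_mean, 2)
  expect_equal(ob3$k, 3L)
  expect_equal(ob3$n_samples, 3L)

  # an unscored mutation is dropped from the mean
  refu <- genome_base(g, "chr1", 150)
  msu <- mutation_set(rbind(ms$mutations,
    raw_muts("chr1", 150, refu, setdiff(c("A","C","G","T"), refu)[1], "s3")))
  obu <- observed_mean(el, msu, st)
  expect_equal(obu$observed_mean, 3)
  expect_equal(obu$k, 2L)
  expect_equal(obu$n_unscored, 1L)
})

test_that("sample_background handles degenerate pools and matches closed forms", {
  # single entry: every mean equals its score
  m <- sample_background(7, NULL, k = 3, n_iterations = 500)
  expect_equal(unique(m), 7)

  # k = 2 on a 3-entry weighted pool: mean/variance of sampled means match the
  # closed form of an i.i.d. size-2 draw (all 9 outcomes enumerated)
  set.seed(77)
  sc <- c(1, 3, 10); pr <- c(0.5, 0.3, 0.2)
  mu <- sum(sc * pr)
  v1 <- sum(sc^2 * pr) - mu^2
  N <- 40000
  m <- sample_background(sc, pr, k = 2, n_iterations = N)
  se_mean <- sqrt(v1 / 2 / N)
  expect_lt(abs(mean(m) - mu), 3 * se_mean)
  # variance of the mean of 2 draws is v1/2; compare within 3 MC SEs
  v_hat <- stats::var(m)
  se_var <- sqrt(2 / (N - 1)) * v1 / 2 * 2   # generous normal-theory bound
  expect_lt(abs(v_hat - v1 / 2), 3 * se_var)

  expect_error(sample_background(c(1, 2), c(0, 0), 1, 100), "zero")
})

test_that("empirical_p follows the count/N convention with tie saturation", {
  bg <- c(rep(1, 9998), 5, 6)
  expect_equal(empirical_p(4.5, bg), 2 / 10000)
  expect_equal(empirical_p(0.5, bg), 1)            # below every background mean
  expect_equal(empirical_p(1, rep(1, 100)), 1)     # constant pool, >= ties
  expect_equal(empirical_p(1, rep(1, 100), tie = "gt"), 0)
  expect_equal(empirical_p(4.5, bg, pseudocount = TRUE), 3 / 10001)
  # monotone in the observed mean for a fixed background
  ps <- vapply(seq(0, 7, by = 0.5), empirical_p, numeric(1), background = bg)
  expect_true(all(diff(ps) <= 0))
})

test_that("adjust_fdr applies BH over eligible elements only", {
  res <- data.frame(p_value = c(0.01, 0.02, 0.03), n_samples = c(3, 2, 5))
  out <- adjust_fdr(res, min_samples = 2)
  expect_equal(out$q_value, rep(0.03, 3))
  out1 <- adjust_fdr(data.frame(p_value = 0.004, n_samples = 4), 2)
  expect_equal(out1$q_value, 0.004)
  mix <- adjust_fdr(data.frame(p_value = c(0.004, 0.5),
                               n_samples = c(1, 2)), 2)
  expect_true(is.na(mix$q_value[1]))
  expect_equal(mix$q_value[2], 0.5)
  expect_warning(adjust_fdr(data.frame(p_value = 0.1, n_samples = 1), 2),
                 "threshold")
  # q >= p elementwise, q non-decreasing in p order
  set.seed(4)
  r <- data.frame(p_value = runif(50), n_samples = 2)
  q <- adjust_fdr(r, 2)$q_value
  expect_true(all(q >= r$p_value))
  expect_true(all(diff(q[order(r$p_value)]) >= -1e-15))
})

test_that("run_fml is deterministic, order-independent and finds the injected driver", {
  spec <- synthetic_spec(seed = 51, n_genes = 8, n_lncrna = 2,
                         chrom_lengths = c(chr1 = 500000L),
                         n_samples = 20, muts_per_sample = 15,
                         n_drivers = 1, driver_samples = 10)
  ds <- generate_dataset(spec)
  sig <- compute_signature(ds$cohort, ds$genome, "cohort")
  cfg <- fml_config(n_iterations = 1000, max_iterations = 8000, seed = 9)
  res1 <- run_fml(ds$catalog, ds$cohort, ds$store, sig, ds$genome, cfg)
  res2 <- run_fml(ds$catalog, ds$cohort, ds$store, sig, ds$genome, cfg)
  expect_identical(res1$p_value, res2$p_value)       # bit-identical reruns
  expect_equal(res1$element_id[1], ds$truth)         # driver ranks first
  expect_lt(res1$q_value[1], 0.1)
  expect_true(all(res1$q_value >= res1$p_value, na.rm = TRUE))
  expect_true(all(res1$n_mutations >= 1))

  # dropping some elements from the catalog does not change the others' p
  keep <- setdiff(names(ds$catalog$elements), res1$element_id[2])
  cat2 <- element_catalog(ds$catalog$elements[keep])
  res3 <- run_fml(cat2, ds$cohort, ds$store, sig, ds$genome, cfg)
  shared <- intersect(res3$element_id, res1$element_id)
  expect_equal(res3$p_value[match(shared, res3$element_id)],
               res1$p_value[match(shared, res1$element_id)])
})

test_that("run_fml returns an empty result for a cohort outside the catalog", {
  g <- toy_genome(2000, seed = 61)
  st <- toy_store(g, from = 2, to = 500)
  el <- toy_element(start = 100, end = 200)
  cat1 <- element_catalog(list(el))
  ref <- genome_base(g, "chr1", 1500)
  ms <- mutation_set(raw_muts("chr1", 1500, ref,
                              setdiff(c("A","C","G","T"), ref)[1], "s1"))
  res <- run_fml(cat1, ms, st, uniform_signature(), g)
  expect_equal(nrow(res), 0L)
})

test_that("per-sample sampling mode draws each mutation under its sample's signature", {
  spec <- synthetic_spec(seed = 52, n_genes = 5, n_lncrna = 0,
                         chrom_lengths = c(chr1 = 300000L),
                         n_samples = 8, muts_per_sample = 25)
  ds <- generate_dataset(spec)
  sigs <- compute_signature(ds$cohort, ds$genome, "per_sample")
  cfg <- fml_config(n_iterations = 500, max_iterations = 500, seed = 3,
                    sampling = "per_sample")
  res <- run_fml(ds$catalog, ds$cohort, ds$store, sigs, ds$genome, cfg)
  expect_gt(nrow(res), 0)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})
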