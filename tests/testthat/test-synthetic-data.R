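test_that("truth tables are reproducible from the seed", {
  spec <- toy_spec3()
  t1 <- sample_truth(spec, generator_params(), seed = 5)
  t2 <- sample_truth(spec, generator_params(), seed = 5)
  t3 <- sample_truth(spec, generator_params(), seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1$wmax_true, t3$wmax_true))
})

test_that("degenerate generator parameters collapse to the wild-type truth", {
  spec <- toy_spec3()
  pars <- generator_params(effect_mean = 0, effect_sd = 0,
                           epistasis_mean = 0, epistasis_sd = 0,
                           epistasis_sparsity = 0,
                           k_shift_mean = 0, k_shift_sd = 0,
                           dead_fraction = 0)
  tr <- sample_truth(spec, pars, seed = 1)
  expect_true(all(tr$wmax_true == 1))
  expect_true(all(tr$k_true == pars$k_baseline))
  expect_true(all(!tr$dead))
})

test_that("wild type anchors the truth and midpoints grow with distance", {
  spec <- spec5()
  tr <- sample_truth(spec, generator_params(), seed = 3)
  wt <- tr[tr$genotype == spec$wild_type_alleles, ]
  expect_equal(wt$wmax_true, 1)
  expect_equal(wt$k_true, generator_params()$k_baseline)
  expect_false(wt$dead)
  mean_k <- tapply(tr$k_true, tr$distance, mean)
  expect_true(all(diff(mean_k) > 0))
  expect_true(all(tr$k_true > 0))
  expect_true(all(tr$wmax_true[tr$dead] == 0))
})

test_that("selection reweights the pool by Hill activity", {
  spec <- toy_spec2()
  tr <- sample_truth(spec, generator_params(effect_mean = 0, effect_sd = 0,
                                            k_shift_mean = 0, k_shift_sd = 0,
                                            epistasis_sparsity = 0,
                                            dead_fraction = 0), seed = 1)
  # equal activities: post proportions match pre in expectation
  cs <- simulate_counts(tr, mg = 4, depth = 2e5, seed = 9)
  expect_identical(sum(cs$pre$count), 200000L)
  expect_identical(sum(cs$post$count), 200000L)
  expect_equal(cs$post$count / 2e5, cs$pre$count / 2e5, tolerance = 0.05)

  # 2:1 activity at equal pre proportions: expected post split 2/3 : 1/3
  tr2 <- tr
  tr2$wmax_true <- rep(1, 16)
  tr2$wmax_true[2] <- 2
  pool <- c(0.5, 0.5, rep(0, 14))
  cs2 <- simulate_counts(tr2, mg = 4, depth = 5e5, pool = pool, seed = 11)
  expect_equal(cs2$post$count[2] / 5e5, 2 / 3, tolerance = 0.01)
  expect_equal(cs2$post$count[1] / 5e5, 1 / 3, tolerance = 0.01)
})

test_that("dead genotypes never appear after selection", {
  spec <- toy_spec2()
  tr <- sample_truth(spec, generator_params(dead_fraction = 0), seed = 2)
  tr$dead[3] <- TRUE
  tr$wmax_true[3] <- 0
  cs <- simulate_counts(tr, mg = 8, depth = 1e5,
                        background = 1e-3, seed = 4)
  expect_identical(cs$post$count[3], 0L)
  expect_gt(cs$pre$count[3], 0L)
})

test_that("count simulation validates its inputs", {
  tr <- sample_truth(toy_spec2(), generator_params(), seed = 1)
  expect_error(simulate_counts(tr, mg = 0), "mg")
  expect_error(simulate_counts(tr, mg = 4, depth = 0), "depth")
  expect_error(simulate_counts(tr, mg = 4, pool = rep(0.5, 16)), "sum to 1")
})

test_that("FASTQ round trip recovers the counts exactly", {
  spec <- toy_spec2()
  tr <- sample_truth(spec, generator_params(), seed = 1)
  cs <- simulate_counts(tr, mg = 4, depth = 2000, seed = 3)
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  n <- write_fastq(cs$pre, spec, fq, contaminant_fraction = 0, seed = 5)
  expect_identical(n, 2000L)
  ct <- count_reads(fq, compile_matcher(spec))
  expect_identical(ct$counts$count, cs$pre$count)
  expect_identical(ct$total_rejected, 0L)
})

test_that("wild-type reads reproduce the reference sequence as DNA", {
  spec <- toy_spec2()
  counts <- data.frame(genotype = spec$wild_type_alleles, count = 10L)
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  write_fastq(counts, spec, fq)
  lines <- readLines(fq)
  seqs <- lines[seq(2, length(lines), by = 4)]
  expect_length(seqs, 10L)
  expect_true(all(seqs == chartr("U", "T", spec$reference_sequence)))
})

test_that("contaminant reads carry one off-target mutation and are rejected", {
  spec <- toy_spec2()
  counts <- data.frame(genotype = build_library(spec),
                       count = rep(625L, 16))
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  write_fastq(counts, spec, fq, contaminant_fraction = 0.1, seed = 8)
  ct <- count_reads(fq, compile_matcher(spec))
  # binomial(10^4, 0.1): ~1000 +- 4 sd
  expect_gt(ct$total_rejected, 1000 - 4 * sqrt(1e4 * 0.1 * 0.9))
  expect_lt(ct$total_rejected, 1000 + 4 * sqrt(1e4 * 0.1 * 0.9))
  expect_identical(ct$total_matched + ct$total_rejected, 10000L)
})

test_that("experiment simulation is deterministic in the master seed", {
  spec <- toy_spec2(mg_levels = c(2, 8), replicates = 2L)
  e1 <- simulate_experiment(spec, generator_params(depth = 1e4), seed = 9)
  e2 <- simulate_experiment(spec, generator_params(depth = 1e4), seed = 9)
  expect_identical(e1, e2)
})

test_that("dirichlet pools are proportions and flatten with concentration", {
  set.seed(1)
  p <- dirichlet_pool(100, 50)
  expect_equal(sum(p), 1)
  expect_true(all(p > 0))
  expect_identical(dirichlet_pool(10, Inf), rep(0.1, 10))
})
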