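test_that("simulation configs are validated", {
  expect_error(sim_config(population_size = 0), "population_size")
  expect_error(sim_config(mutation_rate = 1.5), "mutation_rate")
  expect_error(sim_config(generations = 0), "generations")
  expect_error(sim_config(replicates = 0), "replicates")
})

test_that("without mutation a monomorphic population never changes", {
  cfg <- sim_config(population_size = 50L, mutation_rate = 0,
                    generations = 40L, seed = 3L)
  W <- runif(16, 0.5, 2)
  tr <- run_simulation(W, cfg, start = "GA")
  expect_equal(tr$mean_fitness, rep(W[genotype_index("GA")], 41L))
  expect_identical(sum(tr$final_counts), 50L)
  expect_identical(tr$final_counts[genotype_index("GA")], 50L)
})

test_that("population size and mean fitness are exact on flat landscapes", {
  # mean fitness can only equal the constant if the population size is
  # exactly N at every generation
  cfg <- sim_config(population_size = 200L, mutation_rate = 0.05,
                    generations = 100L, seed = 11L)
  tr <- run_simulation(rep(2, 64), cfg, start = "AAA")
  expect_equal(tr$mean_fitness, rep(2, 101L))
  expect_identical(sum(tr$final_counts), 200L)
})

test_that("extinction is reported with the generation", {
  W <- rep(0, 16)
  W[genotype_index("GA")] <- 1
  cfg <- sim_config(population_size = 20L, mutation_rate = 0,
                    generations = 10L, seed = 1L)
  # start the whole population on a zero-fitness genotype
  start <- integer(16); start[1] <- 20L
  expect_error(run_simulation(W, cfg, start = start), "generation 1")
})

test_that("allele frequencies are a martingale under neutrality", {
  # 4 genotypes, uniform fitness, no mutation, mixed start
  cfg <- sim_config(population_size = 10L, mutation_rate = 0,
                    generations = 150L, seed = 1L)
  start <- c(5L, 5L, 0L, 0L)
  freq1 <- vapply(1:1500, function(r) {
    run_simulation(rep(1, 4), cfg, start = start, seed = 1000L + r
                   )$final_counts[1] / 10
  }, numeric(1))
  se <- sqrt(0.5 * 0.5 / 1500)  # binomial error of the replicate mean
  expect_lt(abs(mean(freq1) - 0.5), 4 * se)
  # under selection the fitter type beats its initial frequency
  fix2 <- vapply(1:600, function(r) {
    run_simulation(c(1, 2, 0, 0), cfg, start = start, seed = 5000L + r
                   )$final_counts[2] == 10L
  }, logical(1))
  expect_gt(mean(fix2), 0.5)
})

test_that("batch simulation is reproducible and averages its replicates", {
  W <- runif(64, 0.5, 2)
  cfg <- sim_config(population_size = 100L, mutation_rate = 0.02,
                    generations = 50L, replicates = 4L, seed = 9L)
  ts1 <- batch_simulate(W, cfg, "AAA")
  ts2 <- batch_simulate(W, cfg, "AAA")
  expect_identical(ts1$trajectories, ts2$trajectories)
  expect_equal(ts1$mean_trajectory, rowMeans(ts1$trajectories))
  cfg1 <- sim_config(population_size = 100L, mutation_rate = 0.02,
                     generations = 50L, replicates = 1L, seed = 9L)
  ts3 <- batch_simulate(W, cfg1, "AAA")
  expect_equal(ts3$mean_trajectory, ts3$trajectories[, 1])
  # flat landscape: cross-replicate mean is exactly 1 everywhere
  flat <- batch_simulate(rep(1, 64), cfg, "AAA")
  expect_true(all(flat$mean_trajectory == 1))
})

test_that("the starting genotype is maximally distant, viable and lowest-fit", {
  lib <- build_library(toy_spec2())
  M <- matrix(1, nrow = 16, ncol = 2, dimnames = list(lib, c(1, 8)))
  M["UU", ] <- 5                       # single top genotype at both levels
  M["CC", ] <- c(0.05, 0.15)           # lowest mean, distance 2 from UU
  cs <- choose_start(M)
  expect_identical(cs$distance, 2L)
  expect_false(cs$relaxed)
  expect_identical(cs$genotype, "CC")
  # ties on mean fitness break lexicographically
  M2 <- M; M2["AG", ] <- c(0.15, 0.05)
  expect_identical(choose_start(M2)$genotype, "AG")
  # zero-fitness genotypes are never chosen even if lowest
  M3 <- M; M3["AA", ] <- c(0, 0.01)
  expect_identical(choose_start(M3)$genotype, "CC")
})

test_that("fixation probabilities match the exact Markov chain at N = 10", {
  # two genotypes, fitness 1 and 2, no mutation: the offspring count of the
  # fit type is binomial(N, 2i / (N + i)); absorption probabilities solve
  # the linear system of the embedded chain
  N <- 10L
  P <- matrix(0, N + 1, N + 1)
  for (i in 0:N) P[i + 1, ] <- dbinom(0:N, N, 2 * i / (N + i))
  Q <- P[2:N, 2:N]
  b <- P[2:N, N + 1]
  u <- solve(diag(N - 1) - Q, b)       # start from i = 1..N-1
  p_true <- u[5]                        # i = 5: half the population fit
  cfg <- sim_config(population_size = N, mutation_rate = 0,
                    generations = 300L, seed = 1L)
  start <- c(5L, 5L, 0L, 0L)
  nrep <- 4000L
  fixed <- vapply(seq_len(nrep), function(r) {
    run_simulation(c(1, 2, 0, 0), cfg, start = start, seed = 20000L + r
                   )$final_counts[2] == N
  }, logical(1))
  p_hat <- mean(fixed)
  expect_lt(abs(p_hat - p_true), 4 * sqrt(p_true * (1 - p_true) / nrep))
})

test_that("logistic fits recover exact curves and flag degenerate input", {
  x <- 0:2000
  y <- 2 / (1 + exp(-0.1 * (x - 50)))
  f <- fit_logistic(x, y)
  expect_true(f$converged)
  expect_equal(f$L, 2, tolerance = 1e-4)
  expect_equal(f$k, 0.1, tolerance = 1e-4)
  expect_equal(f$x0, 50, tolerance = 1e-4)
  expect_false(fit_logistic(x, rep(1.3, 2001))$converged)
})

test_that("generation-50 fitness reads the trajectory at index 50", {
  cfg <- sim_config(population_size = 50L, mutation_rate = 0,
                    generations = 60L, replicates = 3L, seed = 2L)
  flat <- batch_simulate(rep(1, 16), cfg, "GA")
  expect_equal(g50(flat), 1)
  W <- rep(1, 16); W[genotype_index("GA")] <- 0.2
  low <- batch_simulate(W, cfg, "GA")
  expect_equal(g50(low), 0.2)
  short <- sim_config(population_size = 10L, generations = 20L,
                      replicates = 2L, seed = 2L)
  expect_error(g50(batch_simulate(rep(1, 16), short, "GA")), "shorter")
})
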