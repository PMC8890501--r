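test_that("square enumeration matches brute force on the 2-position library", {
  sq <- enumerate_squares(2)
  expect_identical(nrow(sq), 36L)
  # brute force: all unordered pairs of single substitutions at two
  # different positions applied to every genotype, deduplicated as corner sets
  lib <- build_library(toy_spec2())
  seen <- character(0)
  for (g in lib) {
    ch <- strsplit(g, "")[[1]]
    for (a in setdiff(c("A", "C", "G", "U"), ch[1]))
      for (b in setdiff(c("A", "C", "G", "U"), ch[2])) {
        gA <- paste0(a, ch[2]); gB <- paste0(ch[1], b); gAB <- paste0(a, b)
        seen <- c(seen, paste(sort(c(g, gA, gB, gAB)), collapse = "|"))
      }
  }
  expect_identical(length(unique(seen)), 36L)
  got <- apply(cbind(sq$i0, sq$iA, sq$iB, sq$iAB), 1, function(r)
    paste(sort(index_genotype(r, 2L)), collapse = "|"))
  expect_setequal(got, unique(seen))
  expect_identical(anyDuplicated(got), 0L)
})

test_that("square counts follow the closed form and corners are consistent", {
  expect_identical(nrow(enumerate_squares(1)), 0L)
  sq3 <- enumerate_squares(3)
  expect_identical(nrow(sq3), as.integer(4^1 * 36 * 3))
  g0 <- index_genotype(sq3$i0, 3L); gAB <- index_genotype(sq3$iAB, 3L)
  gA <- index_genotype(sq3$iA, 3L); gB <- index_genotype(sq3$iB, 3L)
  expect_true(all(hamming_distance(g0, gA) == 1L))
  expect_true(all(hamming_distance(g0, gB) == 1L))
  expect_true(all(hamming_distance(g0, gAB) == 2L))
  expect_true(all(hamming_distance(gA, gAB) == 1L))
})

test_that("epistasis classes follow the sign conditions", {
  expect_identical(as.character(classify_square(1, 0.5, 0.5, 0)), "none")
  expect_identical(as.character(classify_square(1, 0.8, 0.8, 0.3)),
                   "magnitude")
  expect_identical(as.character(classify_square(1, 0.2, 0.2, 1.5)),
                   "reciprocal_sign")
  expect_identical(as.character(classify_square(1, 1.2, 0.5, 0.4)), "sign")
  # zero-magnitude single effects count as sign-agreeing
  expect_identical(as.character(classify_square(1, 1, 0.5, 0.4)), "magnitude")
  expect_error(classify_square(1, NA, 1, 1), "finite")
})

test_that("classification tolerates eps and matches the oracle near ties", {
  # additive up to 1e-12 is 'none' under eps but 'sign'/'magnitude' at eps=0
  expect_identical(as.character(classify_square(1, 0.8, 0.6, 0.4 + 1e-12,
                                                eps = 1e-9)), "none")
  set.seed(11)
  W <- matrix(runif(4 * 2000, 0, 2), ncol = 4)
  got <- as.character(classify_square(W[, 1], W[, 2], W[, 3], W[, 4]))
  expect_identical(got, oracle_classify(W[, 1], W[, 2], W[, 3], W[, 4]))
})

test_that("classification is invariant to which corner anchors the square", {
  set.seed(21)
  W <- matrix(runif(4 * 500, 0, 2), ncol = 4)
  base <- classify_square(W[, 1], W[, 2], W[, 3], W[, 4])
  # rotations: each corner in turn as reference, partners relabeled
  rotA <- classify_square(W[, 2], W[, 1], W[, 4], W[, 3])
  rotB <- classify_square(W[, 3], W[, 4], W[, 1], W[, 2])
  rotAB <- classify_square(W[, 4], W[, 3], W[, 2], W[, 1])
  expect_identical(base, rotA)
  expect_identical(base, rotB)
  expect_identical(base, rotAB)
})

test_that("ruggedness fractions sum to one and skip missing corners", {
  set.seed(31)
  W <- runif(64, 0, 2)
  r <- ruggedness(W)
  expect_equal(r$f_none + r$f_magnitude + r$f_S + r$f_RS, 1)
  expect_equal(r$ruggedness, 2 * r$f_RS + r$f_S)
  expect_identical(r$n_skipped, 0L)
  W[1] <- NA
  r2 <- ruggedness(W)
  # genotype 1 is a corner of pos-pair squares anchored on or reaching it
  expect_gt(r2$n_skipped, 0L)
  expect_identical(r2$n_squares + r2$n_skipped, nrow(enumerate_squares(3)))
  expect_error(ruggedness(rep(NA_real_, 16)), "no square")
})

test_that("hand-built reciprocal-sign landscape matches brute-force fractions", {
  # two positions; make the wild-type corner and the double mutant high,
  # single mutants low, for alleles A/C at both positions; rest additive-ish
  lib <- build_library(toy_spec2())
  W <- additive_landscape(2, seed = 5)
  hi <- c("AA", "CC"); lo <- c("AC", "CA")
  W[match(hi, lib)] <- 2
  W[match(lo, lib)] <- 0.2
  r <- ruggedness(W)
  sq <- enumerate_squares(2)
  cls <- oracle_classify(W[sq$i0], W[sq$iA], W[sq$iB], W[sq$iAB])
  expect_equal(r$f_RS, mean(cls == "reciprocal_sign"))
  expect_equal(r$f_S, mean(cls == "sign"))
  expect_gt(r$f_RS, 0)
})

test_that("additive landscapes give zero ruggedness and zero roughness", {
  W <- additive_landscape(3, seed = 7)
  r <- ruggedness(W, eps = 1e-9)
  expect_equal(r$ruggedness, 0)
  expect_equal(r$f_none, 1)
  rs <- roughness_slope(W)
  expect_lt(rs$r, 1e-10)
  expect_equal(rs$ratio, 0, tolerance = 1e-8)
})

test_that("roughness fit equals the normal-equation oracle on the toy library", {
  set.seed(13)
  W <- runif(16, 0.1, 2)
  rs <- roughness_slope(W, reference = "GA")
  # independent oracle: explicit design matrix + solve()
  lib <- build_library(toy_spec2())
  ch <- do.call(rbind, strsplit(lib, ""))
  X <- cbind(1, do.call(cbind, lapply(1:2, function(k) {
    ref <- substring("GA", k, k)
    sapply(setdiff(c("A", "C", "G", "U"), ref), function(a)
      as.numeric(ch[, k] == a))
  })))
  beta <- solve(t(X) %*% X, t(X) %*% W)
  expect_equal(unname(rs$coefficients), unname(beta[-1, 1]), tolerance = 1e-10)
  expect_equal(rs$r, sqrt(mean((W - X %*% beta)^2)), tolerance = 1e-10)
  expect_equal(rs$s, mean(abs(beta[-1, 1])), tolerance = 1e-10)
})

test_that("perturbing one genotype of an additive landscape creates roughness", {
  W <- additive_landscape(2, seed = 9)
  expect_lt(roughness_slope(W)$r, 1e-10)
  W[5] <- W[5] + 0.5
  expect_gt(roughness_slope(W)$r, 0.01)
})

test_that("the r/s ratio is invariant to the reference-allele choice", {
  set.seed(17)
  W <- runif(64, 0.1, 2)
  r1 <- roughness_slope(W, reference = "AAA")
  r2 <- roughness_slope(W, reference = "GCU")
  expect_equal(r1$r, r2$r, tolerance = 1e-10)
})

test_that("ruggedness trend reproduces known rank correlations", {
  expect_equal(ruggedness_trend(1:8, 8:1)$rho, -1)
  expect_equal(ruggedness_trend(1:8, 1:8)$rho, 1)
  # replicate ties overlapping across levels: rho negative but above -1,
  # and equal to the rank-correlation oracle with average ranks
  mg <- rep(c(1, 2, 4, 8), each = 3)
  rg <- c(0.4, 0.4, 0.4, 0.4, 0.3, 0.3, 0.3, 0.2, 0.2, 0.2, 0.1, 0.1)
  tr <- ruggedness_trend(mg, rg)
  expect_equal(tr$rho, cor(rank(mg), rank(rg)))
  expect_lt(tr$rho, 0)
  expect_gt(tr$rho, -1)
  expect_warning(tr0 <- ruggedness_trend(1:5, rep(1, 5)), "constant")
  expect_true(is.na(tr0$rho))
})
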