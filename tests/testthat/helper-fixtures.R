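# Small libraries used across tests. The two-position toy keeps square
# enumeration brute-forceable; the five-position library gives ~1000
# genotypes for recovery suites.

toy_spec2 <- function(mg_levels = c(1, 2, 4, 8), replicates = 2L) {
  library_spec("GACGUAAC", c(3, 6), mg_levels = mg_levels,
               replicates = replicates)
}

toy_spec3 <- function(mg_levels = c(1, 2, 4, 8, 16, 48), replicates = 2L) {
  library_spec("GACGUAACGG", c(2, 5, 8), mg_levels = mg_levels,
               replicates = replicates)
}

spec5 <- function(mg_levels = c(1, 2, 3, 4, 6, 8, 16, 48), replicates = 3L) {
  library_spec("AACAGUCAUGCA", c(2, 4, 6, 9, 11), mg_levels = mg_levels,
               replicates = replicates)
}

# Independent sign-pattern oracle for epistasis classes: compute the sign of
# each mutation's effect in both backgrounds (zero counts as agreeing);
# both preserved -> magnitude, one flipped -> sign, both flipped ->
# reciprocal; additive squares -> none.
oracle_classify <- function(W0, WA, WB, WAB, eps = 0) {
  n <- length(W0)
  out <- character(n)
  for (i in seq_len(n)) {
    if (abs(WAB[i] + W0[i] - WA[i] - WB[i]) <= eps) { out[i] <- "none"; next }
    sgn <- function(x) if (abs(x) <= eps) 0 else sign(x)
    a1 <- sgn(WA[i] - W0[i]); a2 <- sgn(WAB[i] - WB[i])
    b1 <- sgn(WB[i] - W0[i]); b2 <- sgn(WAB[i] - WA[i])
    a_flip <- a1 * a2 < 0
    b_flip <- b1 * b2 < 0
    out[i] <- if (a_flip && b_flip) "reciprocal_sign"
              else if (a_flip || b_flip) "sign" else "magnitude"
  }
  out
}

# Exactly additive fitness over a library: intercept + per-position-allele
# effects summed (no epistasis by construction).
additive_landscape <- function(p, seed = 1) {
  set.seed(seed)
  eff <- matrix(rnorm(4 * p, 0, 0.2), nrow = 4)
  v <- 0:(4^p - 1)
  W <- rep(1, 4^p)
  for (k in seq_len(p)) {
    d <- (v %/% 4^(p - k)) %% 4
    W <- W + eff[d + 1, k]
  }
  W
}
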