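#' Parameters of the synthetic truth and sequencing generator
#'
#' The generator draws a ground-truth magnesium dose-response for every
#' genotype and then simulates the selection-and-sequencing experiment on top
#' of it. Activity of genotype g at concentration m follows the Hill model
#' `a_g(m) = wmax_g * m^h / (k_g^h + m^h)`.
#'
#' The truth model is multiplicative in activity (additive in log wmax):
#' each single mutation contributes a log-activity effect, a sparse set of
#' mutation pairs contributes an extra log-epistasis term, and each mutation
#' shifts the Hill midpoint additively (truncated below at `k_shift_floor`,
#' so mutations destabilize on average and midpoints grow with mutational
#' distance). A random fraction of genotypes is "dead" (no activity at any
#' concentration).
#'
#' @param effect_mean,effect_sd Normal distribution of per-mutation log
#'   activity effects. The negative default mean makes most mutations
#'   deleterious.
#' @param beneficial_scale Shrinkage applied to positive log-activity draws:
#'   losses in an already-optimized catalyst are unbounded, gains are small,
#'   so beneficial effects are scaled down by this factor.
#' @param epistasis_mean,epistasis_sd,epistasis_sparsity Normal distribution
#'   of pairwise log-epistasis terms and the fraction of (position, allele)
#'   pairs that carry one. The negative default mean makes epistasis
#'   predominantly negative (combinations worse than additive).
#' @param k_shift_mean,k_shift_sd,k_shift_floor Normal distribution of
#'   per-mutation midpoint shifts in mM, truncated below at the floor.
#' @param k_baseline Wild-type Hill midpoint in mM.
#' @param h_baseline Hill slope shared by all genotypes.
#' @param dead_fraction Probability that a mutant genotype is dead.
#' @param selection_background Nonspecific reaction rate, as a fraction of the
#'   wild type's saturated activity: every living genotype reacts at least at
#'   this rate regardless of folding, as real in vitro selections always
#'   carry some background. Flattens the selection signal below it.
#' @param depth Reads per condition-replicate (pre and post each).
#' @param pool_concentration Symmetric Dirichlet concentration of the
#'   pre-selection pool proportions; `Inf` gives an exactly even pool.
#' @param contaminant_fraction Fraction of written reads that carry one extra
#'   mutation outside the variable positions (rejected downstream).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(effect_mean = -0.5, effect_sd = 0.8,
                             epistasis_mean = -0.15, epistasis_sd = 0.25,
                             epistasis_sparsity = 0.10,
                             k_shift_mean = 1.5, k_shift_sd = 2.5,
                             k_shift_floor = 0,
                             beneficial_scale = 0.4,
                             k_baseline = 2, h_baseline = 3,
                             dead_fraction = 0.03,
                             selection_background = 1e-3,
                             depth = 1e7L,
                             pool_concentration = 50,
                             contaminant_fraction = 0) {
  p <- list(effect_mean = effect_mean, effect_sd = effect_sd,
            beneficial_scale = beneficial_scale,
            epistasis_mean = epistasis_mean, epistasis_sd = epistasis_sd,
            epistasis_sparsity = epistasis_sparsity,
            k_shift_mean = k_shift_mean, k_shift_sd = k_shift_sd,
            k_shift_floor = k_shift_floor,
            k_baseline = k_baseline, h_baseline = h_baseline,
            dead_fraction = dead_fraction,
            selection_background = selection_background,
            depth = as.integer(depth),
            pool_concentration = pool_concentration,
            contaminant_fraction = contaminant_fraction)
  with(p, {
    if (effect_sd < 0 || epistasis_sd < 0 || k_shift_sd < 0)
      stop("standard deviations must be >= 0")
    if (beneficial_scale < 0) stop("beneficial_scale must be >= 0")
    if (epistasis_sparsity < 0 || epistasis_sparsity > 1)
      stop("epistasis_sparsity must be in [0, 1]")
    if (dead_fraction < 0 || dead_fraction > 1)
      stop("dead_fraction must be in [0, 1]")
    if (selection_background < 0)
      stop("selection_background must be >= 0")
    if (depth < 1L) stop("depth must be >= 1")
    if (k_baseline <= 0 || h_baseline <= 0)
      stop("k_baseline and h_baseline must be positive")
    if (contaminant_fraction < 0 || contaminant_fraction > 1)
      stop("contaminant_fraction must be in [0, 1]")
  })
  structure(p, class = "generator_params")
}

#' Hill-model activity
#'
#' `a(m) = wmax * m^h / (k^h + m^h)`: saturating dose response with maximum
#' `wmax`, midpoint `k` (mM) and cooperativity `h`.
#'
#' @param m Concentration(s) in mM.
#' @param wmax,k,h Hill parameters (vectors recycle against `m`).
#' @return Numeric activity values.
#' @export
hill_activity <- function(m, wmax, k, h) {
  wmax * m^h / (k^h + m^h)
}

#' Draw a ground-truth table for a library
#'
#' @param spec A [library_spec()].
#' @param params A [generator_params()].
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @return A data.frame of class `truth_table` with one row per genotype in
#'   canonical order: `genotype`, `distance` (Hamming distance from wild
#'   type), `wmax_true`, `k_true` (mM), `h_true`, `dead`. The wild type has
#'   `wmax_true = 1`, `k_true = k_baseline` and is never dead.
#' @export
sample_truth <- function(spec, params = generator_params(), seed = 1L) {
  stopifnot(inherits(spec, "library_spec"),
            inherits(params, "generator_params"))
  set.seed(as.integer(seed))
  p <- length(spec$variable_positions)
  lib <- build_library(spec)
  n <- length(lib)
  wt <- spec$wild_type_alleles
  wt_idx <- genotype_index(wt, p)
  wt_d <- integer(p)
  wv <- wt_idx - 1L
  for (k in seq_len(p)) wt_d[k] <- (wv %/% 4L^(p - k)) %% 4L

  # per-(position, non-wild-type allele) single-mutation terms
  eff <- matrix(stats::rnorm(4L * p, params$effect_mean, params$effect_sd),
                nrow = 4L, ncol = p)           # rows: allele digit 0..3
  eff[eff > 0] <- eff[eff > 0] * params$beneficial_scale
  kshift <- matrix(pmax(stats::rnorm(4L * p, params$k_shift_mean,
                                     params$k_shift_sd),
                        params$k_shift_floor),
                   nrow = 4L, ncol = p)
  for (k in seq_len(p)) {
    eff[wt_d[k] + 1L, k] <- 0
    kshift[wt_d[k] + 1L, k] <- 0
  }

  # sparse pairwise log-epistasis terms between (pos_i, allele) and
  # (pos_j, allele), both non-wild-type
  pairs <- utils::combn(p, 2L)
  epi <- array(0, dim = c(4L, 4L, ncol(pairs)))
  for (pc in seq_len(ncol(pairs))) {
    i <- pairs[1L, pc]; j <- pairs[2L, pc]
    active <- matrix(stats::runif(16L) < params$epistasis_sparsity, 4L, 4L)
    val <- matrix(stats::rnorm(16L, params$epistasis_mean,
                               params$epistasis_sd), 4L, 4L)
    val[!active] <- 0
    val[wt_d[i] + 1L, ] <- 0
    val[, wt_d[j] + 1L] <- 0
    epi[, , pc] <- val
  }

  v <- 0:(n - 1L)
  digits <- matrix(0L, nrow = n, ncol = p)
  for (k in seq_len(p)) digits[, k] <- (v %/% 4L^(p - k)) %% 4L

  log_wmax <- numeric(n)
  k_true <- rep(params$k_baseline, n)
  for (k in seq_len(p)) {
    log_wmax <- log_wmax + eff[digits[, k] + 1L, k]
    k_true <- k_true + kshift[digits[, k] + 1L, k]
  }
  for (pc in seq_len(ncol(pairs))) {
    i <- pairs[1L, pc]; j <- pairs[2L, pc]
    log_wmax <- log_wmax +
      epi[cbind(digits[, i] + 1L, digits[, j] + 1L, pc)]
  }

  k_true <- pmax(k_true, 0.1)   # stabilization cannot push the midpoint to 0
  dead <- stats::runif(n) < params$dead_fraction
  dead[wt_idx] <- FALSE
  wmax <- exp(log_wmax)
  wmax[dead] <- 0

  out <- data.frame(genotype = lib,
                    distance = hamming_distance(lib, wt),
                    wmax_true = wmax,
                    k_true = k_true,
                    h_true = rep(params$h_baseline, n),
                    dead = dead,
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_table", "data.frame")
  attr(out, "wild_type") <- wt
  attr(out, "k_baseline") <- params$k_baseline
  out
}

#' True relative fitness implied by a truth table
#'
#' The expected outcome of an infinitely deep experiment: activity of each
#' genotype at concentration `m` divided by wild-type activity at `m`
#' (wild type = 1 by construction).
#'
#' @param truth A [sample_truth()] table.
#' @param m Magnesium concentration in mM (scalar).
#' @param background Nonspecific reaction rate added to every living
#'   genotype's activity (see [generator_params()]); 0 gives the pure
#'   Hill-model fitness.
#' @return Numeric vector of relative fitness in canonical genotype order.
#' @export
true_fitness <- function(truth, m, background = 0) {
  stopifnot(inherits(truth, "truth_table"), m > 0)
  wt <- attr(truth, "wild_type")
  a <- hill_activity(m, truth$wmax_true, truth$k_true, truth$h_true)
  a[!truth$dead] <- a[!truth$dead] + background
  wt_row <- match(wt, truth$genotype)
  a / a[wt_row]
}

#' Simulate pre- and post-selection sequencing counts
#'
#' Pre-selection counts are multinomial over the pool proportions; selection
#' reweights each genotype by its Hill-model activity at the given
#' concentration plus the nonspecific background (dead genotypes get weight
#' 0), and post-selection counts are multinomial over the renormalized
#' weights.
#'
#' @param truth A [sample_truth()] table.
#' @param mg Magnesium concentration in mM.
#' @param depth Reads drawn in each of the pre and post pools.
#' @param pool Pre-selection pool proportions in canonical genotype order
#'   (must sum to 1 within 1e-6); even pool when omitted.
#' @param background Nonspecific reaction rate (see [generator_params()]).
#' @param seed Optional integer seed applied before drawing.
#' @return A list with data.frames `pre` and `post` (columns `genotype`,
#'   `count`), the concentration and the pool used.
#' @export
simulate_counts <- function(truth, mg, depth = 1e5L, pool = NULL,
                            background = 0, seed = NULL) {
  stopifnot(inherits(truth, "truth_table"))
  if (mg <= 0) stop("mg must be positive")
  depth <- as.integer(depth)
  if (depth <= 0) stop("depth must be positive")
  n <- nrow(truth)
  if (is.null(pool)) pool <- rep(1 / n, n)
  if (length(pool) != n) stop("pool length must match the library")
  if (abs(sum(pool) - 1) > 1e-6) stop("pool proportions must sum to 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  act <- hill_activity(mg, truth$wmax_true, truth$k_true, truth$h_true) +
    background
  act[truth$dead] <- 0
  w <- pool * act
  if (sum(w) <= 0) stop("no genotype has positive selection weight")
  pre <- as.integer(stats::rmultinom(1L, depth, pool))
  post <- as.integer(stats::rmultinom(1L, depth, w / sum(w)))
  list(pre = data.frame(genotype = truth$genotype, count = pre,
                        stringsAsFactors = FALSE),
       post = data.frame(genotype = truth$genotype, count = post,
                         stringsAsFactors = FALSE),
       mg = mg, pool = pool)
}

#' Draw a pre-selection pool from a symmetric Dirichlet
#'
#' @param n Number of genotypes.
#' @param concentration Dirichlet concentration parameter; larger is more
#'   even, `Inf` gives the exactly even pool.
#' @return Proportions summing to 1.
#' @export
dirichlet_pool <- function(n, concentration = 50) {
  if (is.infinite(concentration)) return(rep(1 / n, n))
  g <- stats::rgamma(n, shape = concentration, rate = 1)
  g / sum(g)
}

#' Write a count table as FASTQ reads
#'
#' Each genotype's reads are the reference sequence with the genotype's
#' alleles substituted at the variable positions, written as DNA (U -> T)
#' with a constant Sanger quality string. A configurable fraction of reads
#' additionally carries one random substitution outside the variable
#' positions; these contaminants exercise the downstream exclusion filter.
#'
#' @param counts A data.frame with columns `genotype` and `count`.
#' @param spec The [library_spec()].
#' @param path Output file path (`.gz` suffix compresses).
#' @param contaminant_fraction Fraction of reads mutated outside the variable
#'   positions.
#' @param seed Optional seed for contaminant placement and read shuffling.
#' @return Invisibly, the number of reads written.
#' @export
write_fastq <- function(counts, spec, path, contaminant_fraction = 0,
                        seed = NULL) {
  stopifnot(inherits(spec, "library_spec"),
            all(c("genotype", "count") %in% names(counts)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  keep <- counts$count > 0L
  gts <- counts$genotype[keep]
  cts <- as.integer(counts$count[keep])
  ref <- strsplit(spec$reference_sequence, "", fixed = TRUE)[[1]]
  vp <- spec$variable_positions
  seqs <- vapply(gts, function(g) {
    s <- ref
    s[vp] <- strsplit(g, "", fixed = TRUE)[[1]]
    paste(s, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  reads <- rep(seqs, cts)
  n <- length(reads)
  if (n > 0L && contaminant_fraction > 0) {
    n_cont <- stats::rbinom(1L, n, contaminant_fraction)
    if (n_cont > 0L) {
      idx <- sample.int(n, n_cont)
      fixed_pos <- setdiff(seq_along(ref), vp)
      pos <- sample(fixed_pos, n_cont, replace = TRUE)
      for (k in seq_len(n_cont)) {
        s <- strsplit(reads[idx[k]], "", fixed = TRUE)[[1]]
        s[pos[k]] <- sample(setdiff(RNA_ALPHABET, s[pos[k]]), 1L)
        reads[idx[k]] <- paste(s, collapse = "")
      }
    }
  }
  if (n > 1L) reads <- reads[sample.int(n)]
  dna <- Biostrings::DNAStringSet(chartr("U", "T", reads))
  names(dna) <- sprintf("read_%d", seq_len(max(n, 0L)))
  qual <- Biostrings::BStringSet(rep(strrep("I", length(ref)), n))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(n)
}
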