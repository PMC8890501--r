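#' Configuration for Wright-Fisher simulations
#'
#' Defaults follow the study conditions: constant population size 1,000,
#' per-reproduction mutation probability 0.01, 2,000 generations, 100
#' replicates.
#'
#' @param population_size Constant population size N.
#' @param mutation_rate Probability that an offspring acquires one
#'   substitution (to a uniformly chosen single-step neighbor).
#' @param generations Number of generations simulated after the initial one.
#' @param replicates Independent simulation replicates.
#' @param start_genotype Genotype key, or `"auto"` to pick one with
#'   [choose_start()].
#' @param seed Master seed; per-replicate child seeds are derived from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(population_size = 1000L, mutation_rate = 0.01,
                       generations = 2000L, replicates = 100L,
                       start_genotype = "auto", seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              mutation_rate = mutation_rate,
              generations = as.integer(generations),
              replicates = as.integer(replicates),
              start_genotype = start_genotype,
              seed = as.integer(seed))
  if (cfg$population_size < 1L) stop("population_size must be >= 1")
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  if (cfg$generations < 1L) stop("generations must be >= 1")
  if (cfg$replicates < 1L) stop("replicates must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Choose the simulation starting genotype
#'
#' Deterministically selects a low-fitness genotype far from every adaptive
#' target: among genotypes whose Hamming distance to the top-fitness genotype
#' of every magnesium level equals the number of variable positions (the
#' maximum possible), it picks the one with the lowest mean fitness across
#' levels, breaking ties lexicographically. If no genotype attains the
#' maximum distance to all targets, the largest achievable minimum distance
#' is used and flagged.
#'
#' @param mean_matrix Genotypes-by-mg matrix of mean fitness in canonical
#'   genotype order (rownames = genotype keys).
#' @param target_distance Required distance to every per-mg top genotype;
#'   defaults to the genotype length.
#' @return List with `genotype`, `distance` (achieved minimum distance to the
#'   targets), `relaxed` flag, `top_genotypes` (per-mg argmax audit record)
#'   and `mean_fitness` of the choice.
#' @export
choose_start <- function(mean_matrix, target_distance = NULL) {
  gts <- rownames(mean_matrix)
  p <- nchar(gts[1])
  if (is.null(target_distance)) target_distance <- p
  tops <- gts[apply(mean_matrix, 2L, which.max)]
  dmat <- vapply(unique(tops), function(t)
    hamming_distance(gts, rep(t, length(gts))), integer(length(gts)))
  dmat <- matrix(dmat, nrow = length(gts))
  dmin <- apply(dmat, 1L, min)
  relaxed <- FALSE
  dstar <- target_distance
  # a founder population must be able to reproduce in every environment
  viable <- apply(mean_matrix, 1L, function(w) all(is.finite(w) & w > 0))
  if (!any(viable & dmin >= dstar)) {
    dstar <- max(dmin[viable])
    relaxed <- TRUE
  }
  cand <- which(viable & dmin >= dstar)
  mf <- rowMeans(mean_matrix, na.rm = TRUE)[cand]
  best <- cand[order(mf, gts[cand])][1]
  list(genotype = gts[best], distance = dmin[best], relaxed = relaxed,
       top_genotypes = stats::setNames(tops, colnames(mean_matrix)),
       mean_fitness = rowMeans(mean_matrix, na.rm = TRUE)[best])
}

#' Simulate one Wright-Fisher population on a landscape
#'
#' Discrete generations at constant size N. Each generation, N offspring are
#' drawn with replacement with probability proportional to parental fitness;
#' each offspring independently mutates with probability `mu` to one of its
#' 3p single-step neighbors, chosen uniformly. Genotypes with missing
#' fitness reproduce with fitness 0 (they can arise by mutation but leave no
#' offspring); if the whole population has fitness 0 the run stops with an
#' extinction error naming the generation.
#'
#' @param fitness Numeric vector of fitness in canonical genotype order
#'   (length 4^p); `NA` treated as 0 (tallied in the result).
#' @param config A [sim_config()]; `config$replicates` is ignored here.
#' @param start Starting genotype key, or an integer vector of genotype
#'   counts (canonical order, summing to N) for a polymorphic start.
#' @param seed Seed applied before the run (defaults to `config$seed`).
#' @return List of class `trajectory`: `mean_fitness` (length generations+1,
#'   generation 0 = initial population), `final_counts` (genotype counts at
#'   the last generation), `n_missing_fitness` (genotypes zeroed for missing
#'   fitness).
#' @export
run_simulation <- function(fitness, config, start, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  G <- 4L^round(log(length(fitness), 4))
  if (G != length(fitness)) stop("fitness must have length 4^p")
  p <- round(log(length(fitness), 4))
  n_missing <- sum(!is.finite(fitness))
  w <- fitness
  w[!is.finite(w)] <- 0
  if (any(w < 0)) stop("fitness must be >= 0")
  N <- config$population_size
  mu <- config$mutation_rate
  set.seed(as.integer(seed))
  counts <- integer(G)
  if (is.character(start)) {
    counts[genotype_index(start, p)] <- N
  } else {
    if (sum(start) != N) stop("polymorphic start must sum to population_size")
    counts[seq_along(start)] <- as.integer(start)
  }
  nb_cols <- 3L * p
  mean_fitness <- numeric(config$generations + 1L)
  mean_fitness[1L] <- sum(counts * w) / N
  for (gen in seq_len(config$generations)) {
    present <- which(counts > 0L)
    wt <- counts[present] * w[present]
    if (sum(wt) <= 0)
      stop("population extinct (total fitness 0) at generation ", gen)
    # monomorphic and mutation-free: nothing can change any more
    if (mu == 0 && length(present) == 1L) {
      mean_fitness[(gen + 1L):(config$generations + 1L)] <- w[present]
      return(trajectory_result(mean_fitness, counts, n_missing))
    }
    off <- as.integer(stats::rmultinom(1L, N, wt))
    counts <- integer(G)
    n_mut <- stats::rbinom(1L, N, mu)
    if (n_mut > 0L) {
      # which offspring mutate: sample parents of the mutants proportional
      # to offspring counts, then move each down one uniform neighbor edge
      mut_parent <- present[rep.int(seq_along(present), off)][
        sample.int(N, n_mut)]
      # remove mutants from their parents' offspring tally
      rm_tab <- tabulate(match(mut_parent, present), length(present))
      off <- off - rm_tab
      nb <- neighbor_indices(mut_parent, p)
      dest <- nb[cbind(seq_len(n_mut), sample.int(nb_cols, n_mut,
                                                  replace = TRUE))]
      dest_tab <- tabulate(dest, G)
      counts <- counts + dest_tab
    }
    counts[present] <- counts[present] + off
    mean_fitness[gen + 1L] <- sum(counts * w) / N
  }
  trajectory_result(mean_fitness, counts, n_missing)
}

trajectory_result <- function(mean_fitness, counts, n_missing) {
  structure(list(mean_fitness = mean_fitness, final_counts = counts,
                 n_missing_fitness = n_missing),
            class = "trajectory")
}

#' Run replicate simulations and summarize
#'
#' Independent replicates with child seeds derived deterministically from the
#' master seed.
#'
#' @inheritParams run_simulation
#' @param start Starting genotype key (or polymorphic count vector).
#' @return List of class `trajectory_set`: `trajectories` (generations+1 x
#'   replicates matrix of mean fitness), `mean_trajectory` (cross-replicate
#'   mean per generation), `generation` (0..generations), `config`.
#' @export
batch_simulate <- function(fitness, config, start) {
  child_seeds <- config$seed + 1000L * seq_len(config$replicates)
  trajs <- vapply(seq_len(config$replicates), function(r) {
    run_simulation(fitness, config, start, seed = child_seeds[r])$mean_fitness
  }, numeric(config$generations + 1L))
  trajs <- matrix(trajs, nrow = config$generations + 1L)
  structure(list(trajectories = trajs,
                 mean_trajectory = rowMeans(trajs),
                 generation = 0:config$generations,
                 config = config),
            class = "trajectory_set")
}

#' Fit the logistic growth curve to a mean trajectory
#'
#' Least squares of `f(x) = L / (1 + exp(-k (x - x0)))` where `L` is the
#' asymptotic mean fitness, `k` the growth rate per generation and `x0` the
#' midpoint in generations. Initialization: `L` at the trajectory maximum,
#' `x0` at the first generation exceeding half of it, `k` over a small grid.
#'
#' @param generation Generation indices.
#' @param mean_fitness Mean fitness at each generation.
#' @return List of class `logistic_fit`: `L`, `k`, `x0`, `residual` (RMS),
#'   `converged`, `reason`.
#' @export
fit_logistic <- function(generation, mean_fitness) {
  ok <- is.finite(generation) & is.finite(mean_fitness)
  x <- as.numeric(generation[ok]); y <- mean_fitness[ok]
  if (length(x) < 5L) stop("need >= 5 points for a logistic fit")
  if (stats::sd(y) < 1e-12 * max(abs(y), 1))
    return(structure(list(L = NA_real_, k = NA_real_, x0 = NA_real_,
                          residual = NA_real_, converged = FALSE,
                          reason = "constant trajectory"),
                     class = "logistic_fit"))
  L0 <- max(y)
  x00 <- x[which(y >= L0 / 2)[1]]
  best <- NULL
  for (k0 in c(0.01, 0.05, 0.2, 1)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ L / (1 + exp(-k * (x - x0))),
                        start = list(L = L0, k = k0, x0 = x00),
                        lower = c(L = 1e-8, k = 1e-6, x0 = min(x) - diff(range(x))),
                        upper = c(L = Inf, k = Inf, x0 = max(x) + diff(range(x))),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(structure(list(L = NA_real_, k = NA_real_, x0 = NA_real_,
                          residual = NA_real_, converged = FALSE,
                          reason = "optimizer failed"),
                     class = "logistic_fit"))
  cf <- stats::coef(best$fit)
  structure(list(L = unname(cf[["L"]]), k = unname(cf[["k"]]),
                 x0 = unname(cf[["x0"]]),
                 residual = sqrt(best$rss / length(x)),
                 converged = TRUE, reason = NA_character_),
            class = "logistic_fit")
}

#' Mean population fitness at generation 50
#'
#' Cross-replicate mean of the population mean fitness at generation 50
#' (generation 0 being the initial population): a simple summary of early
#' adaptation speed.
#'
#' @param trajectory_set A [batch_simulate()] result (or a `trajectory`).
#' @param generation Generation to read out (default 50).
#' @return Scalar mean fitness.
#' @export
g50 <- function(trajectory_set, generation = 50L) {
  if (inherits(trajectory_set, "trajectory")) {
    mf <- trajectory_set$mean_fitness
    if (length(mf) < generation + 1L) stop("trajectory shorter than generation ", generation)
    return(mf[generation + 1L])
  }
  stopifnot(inherits(trajectory_set, "trajectory_set"))
  if (nrow(trajectory_set$trajectories) < generation + 1L)
    stop("trajectories shorter than generation ", generation)
  mean(trajectory_set$trajectories[generation + 1L, ])
}
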