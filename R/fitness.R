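#' Per-genotype relative fitness from pre/post proportions
#'
#' Fitness is the enrichment ratio (post-selection proportion divided by
#' pre-selection proportion) normalized so the wild type equals 1:
#' `W(g) = [post(g)/pre(g)] / [post(wt)/pre(wt)]`.
#'
#' Genotypes absent before selection (`pre = 0`) have no defined enrichment
#' and are flagged missing (`NA`), not zero. Genotypes present before but
#' absent after selection get fitness 0. No pseudocounts are added.
#'
#' @param pre,post Proportion tables from [proportions()] over the same
#'   genotypes in the same order.
#' @param wild_type Wild-type genotype key; must have positive proportion in
#'   both pools.
#' @return Data.frame with columns `genotype` and `fitness` (`NA` = missing).
#' @export
compute_fitness <- function(pre, post, wild_type) {
  stopifnot(all(c("genotype", "proportion") %in% names(pre)),
            all(c("genotype", "proportion") %in% names(post)))
  if (!identical(pre$genotype, post$genotype))
    stop("pre and post tables must cover the same genotypes in the same order")
  iwt <- match(wild_type, pre$genotype)
  if (is.na(iwt)) stop("wild type not in the genotype table")
  if (pre$proportion[iwt] <= 0 || post$proportion[iwt] <= 0)
    stop("wild type has zero proportion pre- or post-selection; cannot normalize")
  wt_ratio <- post$proportion[iwt] / pre$proportion[iwt]
  fitness <- rep(NA_real_, nrow(pre))
  ok <- pre$proportion > 0
  fitness[ok] <- (post$proportion[ok] / pre$proportion[ok]) / wt_ratio
  data.frame(genotype = pre$genotype, fitness = fitness,
             stringsAsFactors = FALSE)
}

#' Aggregate replicate fitness tables
#'
#' Arithmetic mean across replicates with the coefficient of variation
#' (sample standard deviation over mean). Replicates where a genotype is
#' missing are excluded from its mean, with the number used reported.
#'
#' @param replicate_tables List of [compute_fitness()] tables over the same
#'   genotypes in the same order.
#' @return Data.frame with `genotype`, `mean_fitness`, `cv`, `n_reps`.
#'   Genotypes missing in every replicate have `mean_fitness = NA`; `cv` is
#'   `NA` where fewer than two replicates contribute or the mean is 0.
#' @export
aggregate_replicates <- function(replicate_tables) {
  stopifnot(is.list(replicate_tables), length(replicate_tables) >= 1L)
  gts <- replicate_tables[[1]]$genotype
  for (t in replicate_tables)
    if (!identical(t$genotype, gts))
      stop("replicate tables must cover the same genotypes in the same order")
  W <- vapply(replicate_tables, function(t) t$fitness,
              numeric(length(gts)))
  W <- matrix(W, nrow = length(gts))
  n <- rowSums(!is.na(W))
  mean_f <- ifelse(n > 0, rowMeans(W, na.rm = TRUE), NA_real_)
  sd_f <- apply(W, 1L, stats::sd, na.rm = TRUE)
  cv <- ifelse(n >= 2L & !is.na(mean_f) & mean_f > 0, sd_f / mean_f, NA_real_)
  data.frame(genotype = gts, mean_fitness = mean_f, cv = cv,
             n_reps = as.integer(n), stringsAsFactors = FALSE)
}

#' Full fitness landscape from per-condition count tables
#'
#' Convenience wrapper running [proportions()], [compute_fitness()] and
#' [aggregate_replicates()] for every magnesium level of an experiment.
#'
#' @param counts Nested list `counts[[mg]][[replicate]]`, each element a list
#'   with `pre` and `post` count data.frames (`genotype`, `count`).
#' @param spec The [library_spec()]; supplies the wild type and mg levels.
#' @return A list of class `fitness_landscape` with:
#'   `per_replicate` — data.frame (`genotype`, `mg`, `replicate`, `fitness`);
#'   `aggregated` — data.frame (`genotype`, `mg`, `mean_fitness`, `cv`,
#'   `n_reps`); `mean_matrix` — genotypes x mg matrix of replicate-mean
#'   fitness in canonical genotype order.
#' @export
fitness_landscape <- function(counts, spec) {
  stopifnot(inherits(spec, "library_spec"))
  wt <- spec$wild_type_alleles
  mg_levels <- spec$mg_levels
  if (length(counts) != length(mg_levels))
    stop("counts must have one element per mg level")
  per_rep <- list()
  agg <- list()
  mean_mat <- NULL
  for (mi in seq_along(mg_levels)) {
    reps <- counts[[mi]]
    tabs <- lapply(seq_along(reps), function(ri) {
      compute_fitness(proportions(reps[[ri]]$pre),
                      proportions(reps[[ri]]$post), wt)
    })
    for (ri in seq_along(tabs)) {
      per_rep[[length(per_rep) + 1L]] <-
        data.frame(genotype = tabs[[ri]]$genotype, mg = mg_levels[mi],
                   replicate = ri, fitness = tabs[[ri]]$fitness,
                   stringsAsFactors = FALSE)
    }
    a <- aggregate_replicates(tabs)
    agg[[mi]] <- data.frame(genotype = a$genotype, mg = mg_levels[mi],
                            mean_fitness = a$mean_fitness, cv = a$cv,
                            n_reps = a$n_reps, stringsAsFactors = FALSE)
    if (is.null(mean_mat))
      mean_mat <- matrix(NA_real_, nrow = nrow(a), ncol = length(mg_levels),
                         dimnames = list(a$genotype, mg_levels))
    mean_mat[, mi] <- a$mean_fitness
  }
  structure(list(per_replicate = do.call(rbind, per_rep),
                 aggregated = do.call(rbind, agg),
                 mean_matrix = mean_mat,
                 wild_type = wt, mg_levels = mg_levels),
            class = "fitness_landscape")
}
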