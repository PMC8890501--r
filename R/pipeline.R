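#' Write and read tab-separated tables
#'
#' Plain TSV with a header row, the interchange format for every pipeline
#' stage.
#'
#' @param x Data.frame to write.
#' @param path File path.
#' @return `write_tsv()` the path invisibly; `read_tsv()` a data.frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [library_spec()].
#' @param params A [generator_params()] (synthetic mode).
#' @param seed Master seed for every stochastic stage.
#' @param stages Character vector of stages to run, in dependency order, from
#'   `c("simulate", "fitness", "topography", "doseresponse", "evolve")`.
#' @param write_fastq_files Route synthetic counts through FASTQ and the
#'   variant counter (slow at full depth) instead of using the count tables
#'   directly.
#' @param sim Per-stage settings for the evolution stage: a [sim_config()].
#' @param eps Epistasis classification tolerance.
#' @param fitness_input Optional list with paths `per_replicate` and
#'   `aggregated` (TSVs as written by the fitness stage) to run downstream
#'   stages on precomputed fitness instead of synthetic data.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, spec = azoarcus_library_spec(),
                       params = generator_params(), seed = 1L,
                       stages = c("simulate", "fitness", "topography",
                                  "doseresponse", "evolve"),
                       write_fastq_files = FALSE,
                       sim = sim_config(generations = 300L, replicates = 10L),
                       eps = 0, fitness_input = NULL) {
  structure(list(out_dir = out_dir, spec = spec, params = params,
                 seed = as.integer(seed), stages = stages,
                 write_fastq_files = write_fastq_files, sim = sim, eps = eps,
                 fitness_input = fitness_input),
            class = "run_config")
}

#' Validate a run configuration
#'
#' @param config A [run_config()].
#' @return Character vector of violated invariants (length 0 when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  if (!inherits(config, "run_config")) return("not a run_config object")
  if (!inherits(config$spec, "library_spec"))
    v <- c(v, "spec is not a library_spec")
  else {
    if (is.unsorted(config$spec$mg_levels, strictly = TRUE))
      v <- c(v, "mg_levels not strictly increasing")
    if (any(config$spec$mg_levels <= 0)) v <- c(v, "mg_levels not positive")
    if (config$spec$replicates < 1L) v <- c(v, "replicates < 1")
  }
  if (!inherits(config$params, "generator_params"))
    v <- c(v, "params is not a generator_params")
  if (!inherits(config$sim, "sim_config")) v <- c(v, "sim is not a sim_config")
  bad <- setdiff(config$stages, c("simulate", "fitness", "topography",
                                  "doseresponse", "evolve"))
  if (length(bad)) v <- c(v, paste("unknown stage:", paste(bad, collapse = ", ")))
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    v <- c(v, "seed must be a single integer")
  v
}

#' Read a run configuration from YAML
#'
#' Top-level keys `out_dir`, `seed`, `stages`, `eps`, `write_fastq_files`,
#' plus nested `library` (fields of [library_spec()]), `generator` (fields of
#' [generator_params()]) and `simulation` (fields of [sim_config()]); omitted
#' keys fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- if (is.null(y$library)) azoarcus_library_spec()
          else do.call(library_spec, y$library)
  params <- if (is.null(y$generator)) generator_params()
            else do.call(generator_params, y$generator)
  sim <- if (is.null(y$simulation))
           sim_config(generations = 300L, replicates = 10L)
         else do.call(sim_config, y$simulation)
  args <- list(out_dir = if (is.null(y$out_dir)) "." else y$out_dir,
               spec = spec, params = params, sim = sim)
  for (k in c("seed", "stages", "eps", "write_fastq_files"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

#' Simulate the full selection experiment for a library
#'
#' Draws one truth table, one pre-selection pool per replicate, and pre/post
#' count tables for every (mg level, replicate) pair.
#'
#' @param spec A [library_spec()].
#' @param params A [generator_params()].
#' @param seed Master seed.
#' @return List with `truth`, `pools` (list per replicate) and `counts`
#'   (nested list `counts[[mg]][[replicate]]`, each with `pre`/`post`
#'   data.frames), shaped for [fitness_landscape()].
#' @export
simulate_experiment <- function(spec, params = generator_params(), seed = 1L) {
  truth <- sample_truth(spec, params, seed = seed)
  n <- nrow(truth)
  set.seed(as.integer(seed) + 1L)
  pools <- lapply(seq_len(spec$replicates), function(r)
    dirichlet_pool(n, params$pool_concentration))
  counts <- lapply(seq_along(spec$mg_levels), function(mi) {
    lapply(seq_len(spec$replicates), function(ri) {
      simulate_counts(truth, spec$mg_levels[mi], depth = params$depth,
                      pool = pools[[ri]],
                      background = params$selection_background,
                      seed = seed + 7919L * mi + 104729L * ri)[c("pre", "post")]
    })
  })
  list(truth = truth, pools = pools, counts = counts)
}

# Rebuild a fitness_landscape object from the stage TSVs.
load_fitness_tables <- function(fitness_input, spec) {
  per_rep <- read_tsv(fitness_input$per_replicate)
  agg <- read_tsv(fitness_input$aggregated)
  lib <- build_library(spec)
  M <- matrix(NA_real_, nrow = length(lib), ncol = length(spec$mg_levels),
              dimnames = list(lib, spec$mg_levels))
  for (mi in seq_along(spec$mg_levels)) {
    sub <- agg[agg$mg == spec$mg_levels[mi], ]
    M[sub$genotype, mi] <- sub$mean_fitness
  }
  structure(list(per_replicate = per_rep, aggregated = agg, mean_matrix = M,
                 wild_type = spec$wild_type_alleles,
                 mg_levels = spec$mg_levels),
            class = "fitness_landscape")
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order on synthetic data, writing
#' every output as TSV under the output directory plus a JSON manifest with
#' MD5 content hashes, stage timings and the master seed.
#'
#' @param config A [run_config()].
#' @return The manifest (also written to `manifest.json`), invisibly a list
#'   with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config: ", paste(problems, collapse = "; "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config$spec
  outputs <- character(0)
  timings <- list()
  results <- list()
  tic <- function() proc.time()[["elapsed"]]
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }

  stage <- function(name, enabled, fn) {
    if (!enabled) return(invisible(NULL))
    t0 <- tic()
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(tic() - t0, 3)
    res
  }

  exp_data <- stage("simulate", "simulate" %in% config$stages, function() {
    ex <- simulate_experiment(spec, config$params, seed = config$seed)
    emit(ex$truth, "truth.tsv")
    if (config$write_fastq_files) {
      matcher <- compile_matcher(spec)
      for (mi in seq_along(spec$mg_levels)) for (ri in seq_len(spec$replicates)) {
        for (phase in c("pre", "post")) {
          fq <- file.path(config$out_dir,
                          sprintf("reads_mg%g_rep%d_%s.fastq.gz",
                                  spec$mg_levels[mi], ri, phase))
          write_fastq(ex$counts[[mi]][[ri]][[phase]], spec, fq,
                      contaminant_fraction = config$params$contaminant_fraction,
                      seed = config$seed + mi * 131L + ri * 17L +
                        (phase == "post"))
          outputs <<- c(outputs, fq)
          ex$counts[[mi]][[ri]][[phase]] <- count_reads(fq, matcher)$counts
        }
      }
    }
    ex
  })
  results$experiment <- exp_data

  landscape <- stage("fitness", "fitness" %in% config$stages, function() {
    ls <- fitness_landscape(exp_data$counts, spec)
    emit(ls$per_replicate, "fitness_per_replicate.tsv")
    emit(ls$aggregated, "fitness_aggregated.tsv")
    ls
  })
  if (is.null(landscape) && !is.null(config$fitness_input))
    landscape <- load_fitness_tables(config$fitness_input, spec)
  results$landscape <- landscape

  topo <- stage("topography", "topography" %in% config$stages, function() {
    squares <- enumerate_squares(length(spec$variable_positions))
    rug_rows <- list()
    per_rep <- landscape$per_replicate
    for (mg in spec$mg_levels) {
      for (ri in seq_len(spec$replicates)) {
        w <- per_rep$fitness[per_rep$mg == mg & per_rep$replicate == ri]
        rg <- ruggedness(w, squares, eps = config$eps)
        rug_rows[[length(rug_rows) + 1L]] <-
          data.frame(mg = mg, replicate = ri, f_none = rg$f_none,
                     f_magnitude = rg$f_magnitude, f_S = rg$f_S,
                     f_RS = rg$f_RS, ruggedness = rg$ruggedness,
                     n_squares = rg$n_squares, n_skipped = rg$n_skipped)
      }
    }
    rug <- do.call(rbind, rug_rows)
    emit(rug, "ruggedness.tsv")
    trend <- ruggedness_trend(rug$mg, rug$ruggedness)
    rs_rows <- lapply(seq_along(spec$mg_levels), function(mi) {
      rs <- roughness_slope(landscape$mean_matrix[, mi],
                            reference = spec$wild_type_alleles)
      data.frame(mg = spec$mg_levels[mi], r = rs$r, s = rs$s, ratio = rs$ratio)
    })
    rs <- do.call(rbind, rs_rows)
    emit(rs, "roughness_slope.tsv")
    list(ruggedness = rug, trend = trend, roughness_slope = rs)
  })
  results$topography <- topo

  dr <- stage("doseresponse", "doseresponse" %in% config$stages, function() {
    fits <- fit_hill_all(landscape)
    filt <- filter_hill_fits(fits)
    emit(filt$fits, "hill_fits.tsv")
    emit(midpoints_by_distance(filt$kept, spec$wild_type_alleles),
         "midpoints_by_distance.tsv")
    decay_rows <- lapply(seq_along(spec$mg_levels), function(mi) {
      fb <- fitness_by_distance(landscape$mean_matrix[, mi],
                                spec$wild_type_alleles)
      dec <- fit_decay(fb$distance, fb$mean_fitness)
      data.frame(mg = spec$mg_levels[mi], alpha = dec$alpha, beta = dec$beta,
                 residual = dec$residual, domain = dec$domain)
    })
    decay <- do.call(rbind, decay_rows)
    emit(decay, "decay_fits.tsv")
    list(hill = filt, decay = decay)
  })
  results$doseresponse <- dr

  evo <- stage("evolve", "evolve" %in% config$stages, function() {
    M <- landscape$mean_matrix
    start <- if (identical(config$sim$start_genotype, "auto"))
      choose_start(M)$genotype else config$sim$start_genotype
    rows <- list(); traj_rows <- list()
    for (mi in seq_along(spec$mg_levels)) {
      w <- M[, mi]
      w[!is.finite(w)] <- 0
      cfg <- config$sim
      cfg$seed <- config$seed + 37L * mi
      ts <- batch_simulate(w, cfg, start)
      lf <- fit_logistic(ts$generation, ts$mean_trajectory)
      rows[[mi]] <- data.frame(mg = spec$mg_levels[mi], start = start,
                               L = lf$L, k = lf$k, x0 = lf$x0,
                               g50 = g50(ts), converged = lf$converged)
      traj_rows[[mi]] <- data.frame(mg = spec$mg_levels[mi],
                                    generation = ts$generation,
                                    mean_fitness = ts$mean_trajectory)
    }
    summary <- do.call(rbind, rows)
    emit(summary, "evolution_summary.tsv")
    emit(do.call(rbind, traj_rows), "evolution_mean_trajectories.tsv")
    list(summary = summary)
  })
  results$evolution <- evo

  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    timings_sec = timings,
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
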