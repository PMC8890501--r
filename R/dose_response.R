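#' Fit the Hill equation to one fitness-vs-magnesium profile
#'
#' Nonlinear least squares of `W(m) = wmax * m^h / (k^h + m^h)` by
#' Levenberg-Marquardt with a small multi-start over the Hill slope.
#' Initialization: `wmax` at the maximum observed fitness, `k` at the
#' concentration where the profile first crosses half its maximum (by linear
#' interpolation), `h` over \{0.5, 1, 2, 4\}; the best residual wins.
#' Parameters are bounded positive, with `k` capped at 10x the largest
#' concentration; fits ending on that bound or on near-constant data are
#' flagged unconverged.
#'
#' @param mg Concentrations in mM (>= 4 finite points required).
#' @param W Fitness values at those concentrations (same length; `NA` pairs
#'   are dropped).
#' @return A list of class `hill_fit`: `wmax`, `h`, `k`, `residual`
#'   (root-mean-square), `converged`, `reason` (why not, if not).
#' @export
fit_hill <- function(mg, W) {
  ok <- is.finite(mg) & is.finite(W)
  mg <- mg[ok]; W <- W[ok]
  if (length(mg) < 4L)
    return(hill_nofit("fewer than 4 finite points"))
  if (any(mg <= 0)) stop("mg levels must be positive")
  if (all(W <= 0))
    return(hill_nofit("all-zero profile"))
  if (stats::sd(W) < 1e-12 * max(abs(W)))
    return(hill_nofit("constant profile"))
  wmax0 <- max(W)
  half <- wmax0 / 2
  k0 <- {
    above <- which(W >= half)
    i <- above[1]
    if (i == 1L) mg[1]
    else mg[i - 1] + (half - W[i - 1]) * (mg[i] - mg[i - 1]) / (W[i] - W[i - 1])
  }
  k0 <- min(max(k0, min(mg) / 2), max(mg))
  k_cap <- 10 * max(mg)
  best <- NULL
  for (h0 in c(0.5, 1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(W ~ wmax * mg^h / (k^h + mg^h),
                        start = list(wmax = wmax0, h = h0, k = k0),
                        lower = c(wmax = 0, h = 1e-3, k = 1e-4),
                        upper = c(wmax = Inf, h = 50, k = k_cap),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(hill_nofit("optimizer failed from every start"))
  cf <- stats::coef(best$fit)
  at_bound <- cf[["k"]] > 0.999 * k_cap
  structure(list(wmax = unname(cf[["wmax"]]), h = unname(cf[["h"]]),
                 k = unname(cf[["k"]]),
                 residual = sqrt(best$rss / length(W)),
                 converged = !at_bound,
                 reason = if (at_bound) "midpoint at upper bound" else NA_character_),
            class = "hill_fit")
}

hill_nofit <- function(reason) {
  structure(list(wmax = NA_real_, h = NA_real_, k = NA_real_,
                 residual = NA_real_, converged = FALSE, reason = reason),
            class = "hill_fit")
}

#' Fit Hill curves to every genotype of a landscape
#'
#' @param landscape A [fitness_landscape()] (replicate-mean profiles are
#'   fitted), or a genotypes-by-mg numeric matrix with concentrations as
#'   column names.
#' @param genotypes Optional subset of genotype keys to fit.
#' @return Data.frame with one row per genotype: `genotype`, `wmax`, `h`,
#'   `k`, `residual`, `converged`, `reason`. Genotypes with a missing value
#'   at any concentration are not fitted (no imputation).
#' @export
fit_hill_all <- function(landscape, genotypes = NULL) {
  M <- if (inherits(landscape, "fitness_landscape")) landscape$mean_matrix
       else landscape
  mg <- as.numeric(colnames(M))
  if (anyNA(mg)) stop("matrix must have mg concentrations as column names")
  if (is.null(genotypes)) genotypes <- rownames(M)
  rows <- lapply(genotypes, function(g) {
    W <- M[g, ]
    f <- if (anyNA(W)) hill_nofit("missing fitness at some concentration")
         else fit_hill(mg, W)
    data.frame(genotype = g, wmax = f$wmax, h = f$h, k = f$k,
               residual = f$residual, converged = f$converged,
               reason = f$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter Hill fits to the interpretable set
#'
#' Keeps converged fits with maximum fitness strictly between `wmax_min` and
#' `wmax_max`, Hill slope below `h_max` and midpoint below `k_max` mM
#' (defaults: 0.15 < wmax < 3, h < 5, k < 16). Exclusions are tallied by the
#' first failing reason.
#'
#' @param fits Table from [fit_hill_all()].
#' @param wmax_min,wmax_max,h_max,k_max Filter bounds.
#' @return List with `kept` (subset data.frame, plus logical column `kept`
#'   added to the full table as `fits`) and `tally` (named exclusion counts).
#' @export
filter_hill_fits <- function(fits, wmax_min = 0.15, wmax_max = 3,
                             h_max = 5, k_max = 16) {
  reason <- rep(NA_character_, nrow(fits))
  reason[is.na(reason) & !fits$converged] <- "unconverged"
  reason[is.na(reason) & fits$wmax <= wmax_min] <- "wmax_low"
  reason[is.na(reason) & fits$wmax >= wmax_max] <- "wmax_high"
  reason[is.na(reason) & fits$h >= h_max] <- "slope_high"
  reason[is.na(reason) & fits$k >= k_max] <- "midpoint_high"
  keep <- is.na(reason)
  fits$kept <- keep
  fits$exclusion_reason <- reason
  tally <- table(factor(reason[!keep],
                        levels = c("unconverged", "wmax_low", "wmax_high",
                                   "slope_high", "midpoint_high")))
  list(kept = fits[keep, , drop = FALSE], fits = fits,
       tally = as.integer(tally) |> stats::setNames(names(tally)))
}

#' Summarize Hill parameters by mutational distance
#'
#' @param fits Table of (typically filtered) Hill fits with a `genotype`
#'   column.
#' @param wild_type Wild-type genotype key.
#' @return Data.frame with one row per distance 0..p: `distance`, `n`, mean
#'   and median of `k`, `h` and `wmax` (NA where the class is empty).
#' @export
midpoints_by_distance <- function(fits, wild_type) {
  p <- nchar(wild_type)
  d <- hamming_distance(fits$genotype, rep(wild_type, nrow(fits)))
  rows <- lapply(0:p, function(dd) {
    sub <- fits[d == dd, , drop = FALSE]
    summ <- function(x, f) if (nrow(sub)) f(x) else NA_real_
    data.frame(distance = dd, n = nrow(sub),
               k_mean = summ(sub$k, mean), k_median = summ(sub$k, stats::median),
               h_mean = summ(sub$h, mean), h_median = summ(sub$h, stats::median),
               wmax_mean = summ(sub$wmax, mean),
               wmax_median = summ(sub$wmax, stats::median))
  })
  do.call(rbind, rows)
}

#' Fit the directional-epistasis decay of fitness with distance
#'
#' Fits `W(n) = exp(-alpha * n^beta)` to mean fitness per mutational distance
#' (n = 1..p; n = 0 satisfies the model exactly and is excluded). `alpha`
#' measures the average deleterious effect of one mutation; `beta = 1` means
#' multiplicative (no directional epistasis), `beta > 1` predominantly
#' negative epistasis.
#'
#' The default fits in the log domain (`log W = -alpha * n^beta`), seeded by
#' the exact linearization `log(-log W) = log(alpha) + beta * log(n)`. If any
#' mean is non-positive the fit falls back to the direct domain and is
#' flagged.
#'
#' @param distance Integer vector of mutational distances (>= 1).
#' @param mean_fitness Mean fitness at each distance.
#' @param domain `"log"` (default) or `"direct"`.
#' @return List of class `decay_fit`: `alpha`, `beta`, `residual` (RMS in the
#'   fitted domain), `domain` (domain actually used), `fallback` flag.
#' @export
fit_decay <- function(distance, mean_fitness, domain = c("log", "direct")) {
  domain <- match.arg(domain)
  ok <- is.finite(distance) & is.finite(mean_fitness) & distance >= 1
  n <- as.numeric(distance[ok]); W <- mean_fitness[ok]
  if (length(n) < 3L) stop("need means at >= 3 distances")
  fallback <- FALSE
  if (domain == "log" && any(W <= 0)) {
    domain <- "direct"
    fallback <- TRUE
  }
  # linearization start (usable wherever 0 < W < 1)
  lin <- W > 0 & W < 1
  if (sum(lin) >= 2L) {
    lf <- stats::lm(log(-log(W[lin])) ~ log(n[lin]))
    a0 <- exp(stats::coef(lf)[[1]]); b0 <- stats::coef(lf)[[2]]
  } else {
    a0 <- 0.5; b0 <- 1
  }
  a0 <- min(max(a0, 1e-3), 20); b0 <- min(max(b0, 0.1), 5)
  if (domain == "log") {
    y <- log(W)
    fit <- minpack.lm::nlsLM(y ~ -alpha * n^beta,
                             start = list(alpha = a0, beta = b0),
                             lower = c(alpha = 1e-8, beta = 1e-3),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    fit <- minpack.lm::nlsLM(W ~ exp(-alpha * n^beta),
                             start = list(alpha = a0, beta = b0),
                             lower = c(alpha = 1e-8, beta = 1e-3),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  structure(list(alpha = unname(cf[["alpha"]]), beta = unname(cf[["beta"]]),
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 domain = domain, fallback = fallback),
            class = "decay_fit")
}

#' Mean fitness per mutational distance
#'
#' @param fitness Numeric vector in canonical genotype order.
#' @param wild_type Wild-type genotype key.
#' @return Data.frame `distance`, `n`, `mean_fitness` for distances 0..p.
#' @export
fitness_by_distance <- function(fitness, wild_type) {
  p <- nchar(wild_type)
  if (length(fitness) != 4L^p) stop("fitness must have length 4^p")
  lib <- index_genotype(seq_len(4L^p), p)
  d <- hamming_distance(lib, rep(wild_type, length(lib)))
  rows <- lapply(0:p, function(dd) {
    w <- fitness[d == dd]
    data.frame(distance = dd, n = sum(is.finite(w)),
               mean_fitness = mean(w, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
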