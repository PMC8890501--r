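#' Enumerate all mutational squares of a library
#'
#' A square is a set of four genotypes \{g, g+A, g+B, g+AB\} where A and B are
#' single substitutions at two different variable positions. Each geometric
#' square is yielded exactly once under a canonical anchoring: the anchor is
#' the lexicographically smallest corner, which forces its allele at both
#' focal positions to sort below the alternative allele (A < C < G < U).
#'
#' For p positions the count is 4^(p-2) * choose(4,2)^2 * choose(p,2); with
#' p = 7 that is 774,144 squares.
#'
#' @param n_positions Number of variable positions (>= 2 for any square to
#'   exist).
#' @return A data.frame with one row per square: canonical genotype indices of
#'   the four corners (`i0`, `iA`, `iB`, `iAB`), the two focal positions
#'   (`pos_i` < `pos_j`) and the anchor/alternative alleles at each
#'   (`ref_a`, `alt_a`, `ref_b`, `alt_b`, given as 0-based digits A=0..U=3).
#' @export
#' @examples
#' nrow(enumerate_squares(2)) # 36
enumerate_squares <- function(n_positions) {
  n <- as.integer(n_positions)
  if (n < 2L)
    return(data.frame(i0 = integer(0), iA = integer(0), iB = integer(0),
                      iAB = integer(0), pos_i = integer(0), pos_j = integer(0),
                      ref_a = integer(0), alt_a = integer(0),
                      ref_b = integer(0), alt_b = integer(0)))
  v <- 0:(4L^n - 1L)                     # all genotypes, 0-based index
  pairs <- utils::combn(n, 2L)
  ups <- list(c(0L, 1L), c(0L, 2L), c(0L, 3L), c(1L, 2L), c(1L, 3L), c(2L, 3L))
  chunks <- vector("list", ncol(pairs) * 36L)
  k <- 0L
  for (pc in seq_len(ncol(pairs))) {
    i <- pairs[1L, pc]; j <- pairs[2L, pc]
    wi <- 4L^(n - i); wj <- 4L^(n - j)
    di <- (v %/% wi) %% 4L
    dj <- (v %/% wj) %% 4L
    for (ua in ups) for (ub in ups) {
      sel <- which(di == ua[1L] & dj == ub[1L])
      da <- (ua[2L] - ua[1L]) * wi
      db <- (ub[2L] - ub[1L]) * wj
      k <- k + 1L
      chunks[[k]] <- data.frame(
        i0 = v[sel] + 1L, iA = v[sel] + da + 1L, iB = v[sel] + db + 1L,
        iAB = v[sel] + da + db + 1L,
        pos_i = i, pos_j = j,
        ref_a = ua[1L], alt_a = ua[2L], ref_b = ub[1L], alt_b = ub[2L])
    }
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}

#' Classify pairwise epistasis in a mutational square
#'
#' Given the fitness of the four corners of a square (reference `W0`, single
#' mutants `WA` and `WB`, double mutant `WAB`), the square is classified as:
#' \describe{
#'   \item{none}{additive, `WAB + W0 - WA - WB = 0` (within `eps`);}
#'   \item{magnitude}{epistatic, but each mutation's fitness effect has the
#'     same sign in both backgrounds;}
#'   \item{sign}{exactly one mutation's effect changes sign depending on the
#'     other's presence;}
#'   \item{reciprocal_sign}{both effects change sign.}
#' }
#' The sign tests are the triangle-equality conditions
#' `|WA - W0 + WAB - WB| = |WA - W0| + |WAB - WB|` (mutation A keeps its sign)
#' and the strict analogue for mutation B; effects of magnitude `<= eps` count
#' as sign-agreeing.
#'
#' @param W0,WA,WB,WAB Numeric vectors of corner fitness values (recycled).
#' @param eps Equality tolerance for the additivity and sign tests. The
#'   default `0` reproduces exact floating-point comparison; pass a relative
#'   tolerance times a typical fitness for noisy data.
#' @return Factor vector with levels `none`, `magnitude`, `sign`,
#'   `reciprocal_sign`.
#' @export
#' @examples
#' classify_square(1, 0.8, 0.8, 0.3)  # magnitude
#' classify_square(1, 0.2, 0.2, 1.5)  # reciprocal_sign
classify_square <- function(W0, WA, WB, WAB, eps = 0) {
  n <- max(length(W0), length(WA), length(WB), length(WAB))
  W0 <- rep_len(W0, n); WA <- rep_len(WA, n)
  WB <- rep_len(WB, n); WAB <- rep_len(WAB, n)
  if (any(!is.finite(c(W0, WA, WB, WAB))))
    stop("all four fitness values must be finite")
  dA0 <- WA - W0; dAB <- WAB - WB       # effect of mutation A in each background
  dB0 <- WB - W0; dBA <- WAB - WA       # effect of mutation B in each background
  additive <- abs(WAB + W0 - WA - WB) <= eps
  # |x+y| = |x|+|y| iff x and y do not have strictly opposite signs
  cond1 <- (abs(dA0) + abs(dAB) - abs(dA0 + dAB)) <= eps   # A keeps sign
  cond2 <- (abs(dB0) + abs(dBA) - abs(dB0 + dBA)) > eps    # B flips sign
  cls <- rep("sign", n)
  cls[cond1 & !cond2] <- "magnitude"
  cls[!cond1 & cond2] <- "reciprocal_sign"
  cls[additive] <- "none"
  factor(cls, levels = c("none", "magnitude", "sign", "reciprocal_sign"))
}

#' Landscape ruggedness from epistasis-class fractions
#'
#' Classifies every mutational square of one landscape slice (one condition,
#' one replicate or the replicate mean) and summarizes the class fractions.
#' Ruggedness is `2 * f_RS + f_S`, the fraction of sign-epistatic squares with
#' reciprocal sign counted twice; it ranges from 0 (no sign epistasis
#' anywhere) to 2 (all squares reciprocal).
#'
#' Squares with any corner missing (`NA` fitness) are excluded from the
#' fractions and tallied in `n_skipped`.
#'
#' @param fitness Numeric vector of fitness values in canonical genotype-index
#'   order (length 4^p), `NA` for genotypes without a fitness estimate.
#' @param squares Square table from [enumerate_squares()]; computed from the
#'   fitness length when omitted.
#' @param eps Tolerance passed to [classify_square()].
#' @return A list with `f_none`, `f_magnitude`, `f_S`, `f_RS`, `ruggedness`,
#'   `n_squares` (classified) and `n_skipped`.
#' @export
ruggedness <- function(fitness, squares = NULL, eps = 0) {
  p <- round(log(length(fitness), 4))
  if (4L^p != length(fitness))
    stop("fitness must have length 4^p for integer p")
  if (is.null(squares)) squares <- enumerate_squares(p)
  W0 <- fitness[squares$i0]; WA <- fitness[squares$iA]
  WB <- fitness[squares$iB]; WAB <- fitness[squares$iAB]
  ok <- is.finite(W0) & is.finite(WA) & is.finite(WB) & is.finite(WAB)
  if (!any(ok)) stop("no square has fitness at all four corners")
  cls <- classify_square(W0[ok], WA[ok], WB[ok], WAB[ok], eps = eps)
  f <- as.numeric(table(cls)) / length(cls)
  names(f) <- levels(cls)
  list(f_none = f[["none"]], f_magnitude = f[["magnitude"]],
       f_S = f[["sign"]], f_RS = f[["reciprocal_sign"]],
       ruggedness = 2 * f[["reciprocal_sign"]] + f[["sign"]],
       n_squares = sum(ok), n_skipped = sum(!ok))
}

#' Roughness-to-slope ratio of a landscape
#'
#' Fits the additive model of fitness effects by least squares: fitness is
#' regressed on indicator-coded alleles (intercept plus, for each variable
#' position, one coefficient per non-reference allele). Roughness `r` is the
#' root-mean-square residual of this fit; slope `s` is the mean absolute value
#' of the allele coefficients. Their ratio `r/s` is 0 for an exactly additive
#' landscape and grows with epistasis.
#'
#' @param fitness Numeric vector in canonical genotype-index order; `NA`
#'   genotypes are dropped from the fit.
#' @param reference Genotype key whose alleles are the reference level of the
#'   indicator coding (default: all-A, i.e. canonical index 1). Use the
#'   library's wild type or the fittest genotype as conventions require; `r`
#'   and `r/s` are invariant to this choice, `s` is not.
#' @return A list with `r`, `s`, `ratio`, the fitted `coefficients` (named
#'   `pos<k><allele>`) and `intercept`.
#' @export
roughness_slope <- function(fitness, reference = NULL) {
  p <- round(log(length(fitness), 4))
  if (4L^p != length(fitness))
    stop("fitness must have length 4^p for integer p")
  if (is.null(reference)) reference <- strrep("A", p)
  stopifnot(nchar(reference) == p)
  ref_digits <- genotype_index(reference, p) - 1L
  ref_d <- integer(p)
  for (k in seq_len(p)) ref_d[k] <- (ref_digits %/% 4L^(p - k)) %% 4L
  v <- which(is.finite(fitness)) - 1L
  y <- fitness[v + 1L]
  if (length(v) <= 3L * p + 1L)
    stop("not enough genotypes with fitness to fit the additive model")
  X <- matrix(0, nrow = length(v), ncol = 3L * p)
  cn <- character(3L * p)
  col <- 0L
  for (k in seq_len(p)) {
    d <- (v %/% 4L^(p - k)) %% 4L
    for (a in setdiff(0:3, ref_d[k])) {
      col <- col + 1L
      X[, col] <- as.numeric(d == a)
      cn[col] <- paste0("pos", k, RNA_ALPHABET[a + 1L])
    }
  }
  colnames(X) <- cn
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (fit$rank < ncol(X) + 1L) stop("singular additive design")
  r <- sqrt(mean(fit$residuals^2))
  coefs <- fit$coefficients[-1L]
  s <- mean(abs(coefs))
  list(r = r, s = s, ratio = if (s > 0) r / s else NA_real_,
       coefficients = coefs, intercept = unname(fit$coefficients[1L]))
}

#' Trend of ruggedness across magnesium concentrations
#'
#' Spearman rank correlation between magnesium concentration and landscape
#' ruggedness, with replicate landscapes entering as separate points.
#'
#' @param mg Numeric vector of magnesium concentrations (mM), one per
#'   ruggedness value.
#' @param ruggedness_values Numeric vector of the same length.
#' @return List with `rho`, `p_value`, `n`. Constant input gives `rho = NA`
#'   with a warning.
#' @export
ruggedness_trend <- function(mg, ruggedness_values) {
  stopifnot(length(mg) == length(ruggedness_values))
  if (length(mg) < 3L) stop("need at least 3 points for a trend")
  if (stats::sd(ruggedness_values) == 0 || stats::sd(mg) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(mg)))
  }
  ct <- suppressWarnings(
    stats::cor.test(mg, ruggedness_values, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(mg))
}
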