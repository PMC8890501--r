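# RNA alphabet used for all genotype keys, lexicographic order A < C < G < U.
RNA_ALPHABET <- c("A", "C", "G", "U")

#' Define a combinatorial ribozyme library
#'
#' A library spec describes a fixed reference sequence with a small set of
#' fully randomized positions. Every combination of the four nucleotides at
#' those positions is one genotype; the genotype key is the allele string read
#' off the variable positions in order.
#'
#' @param reference_sequence Reference (wild-type) sequence as a single RNA or
#'   DNA string; stored internally as RNA (`T` is converted to `U`).
#' @param variable_positions Strictly increasing integer vector of 1-based
#'   positions into `reference_sequence` that are randomized.
#' @param mg_levels Magnesium concentrations (mM) at which selections are run;
#'   strictly increasing, all positive.
#' @param replicates Number of experimental replicates per concentration.
#'
#' @return An object of class `library_spec` with fields
#'   `reference_sequence`, `variable_positions`, `wild_type_alleles` (read off
#'   the reference), `mg_levels` and `replicates`.
#' @export
#' @examples
#' spec <- library_spec("ACGUACGU", c(2, 5), mg_levels = c(1, 8))
#' spec$wild_type_alleles
library_spec <- function(reference_sequence, variable_positions,
                         mg_levels = c(1, 2, 3, 4, 6, 8, 16, 48),
                         replicates = 3L) {
  if (!is.character(reference_sequence) || length(reference_sequence) != 1L ||
      is.na(reference_sequence) || nchar(reference_sequence) == 0L)
    stop("reference_sequence must be a single non-empty string")
  ref <- toupper(gsub("T", "U", toupper(reference_sequence)))
  if (!grepl("^[ACGU]+$", ref))
    stop("reference_sequence contains characters outside A/C/G/U/T")
  vp <- as.integer(variable_positions)
  if (length(vp) == 0L || anyNA(vp))
    stop("variable_positions must be a non-empty integer vector")
  if (any(vp < 1L) || any(vp > nchar(ref)))
    stop("variable_positions out of reference bounds")
  if (is.unsorted(vp, strictly = TRUE))
    stop("variable_positions must be strictly increasing")
  mg <- as.numeric(mg_levels)
  if (length(mg) == 0L || anyNA(mg) || any(mg <= 0))
    stop("mg_levels must be positive")
  if (is.unsorted(mg, strictly = TRUE))
    stop("mg_levels must be strictly increasing")
  reps <- as.integer(replicates)
  if (length(reps) != 1L || is.na(reps) || reps < 1L)
    stop("replicates must be a positive integer")
  wt <- paste(substring(ref, vp, vp), collapse = "")
  structure(
    list(reference_sequence = ref,
         variable_positions = vp,
         wild_type_alleles = wt,
         mg_levels = mg,
         replicates = reps),
    class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat("Combinatorial library spec\n")
  cat("  reference length:   ", nchar(x$reference_sequence), " nt\n", sep = "")
  cat("  variable positions: ", paste(x$variable_positions, collapse = ", "),
      "\n", sep = "")
  cat("  wild-type alleles:  ", x$wild_type_alleles, "\n", sep = "")
  cat("  genotypes:          ", 4L^length(x$variable_positions), "\n", sep = "")
  cat("  mg levels (mM):     ", paste(x$mg_levels, collapse = ", "),
      "\n", sep = "")
  cat("  replicates:         ", x$replicates, "\n", sep = "")
  invisible(x)
}

#' The Azoarcus group I ribozyme library
#'
#' The default study system: a group I self-splicing intron with seven fully
#' randomized nucleotide positions (intron numbering 90, 119, 128, 153, 158,
#' 177 and 184), giving 4^7 = 16,384 genotypes, selected for reverse-splicing
#' activity at eight magnesium concentrations in triplicate. The stored
#' sequence is the transcribed region, which starts at intron position 9, so
#' sequence coordinates are intron coordinates minus 8.
#'
#' @param mg_levels,replicates Override the study defaults (8 concentrations,
#'   3 replicates).
#' @return A [library_spec()].
#' @export
#' @examples
#' azoarcus_library_spec()
azoarcus_library_spec <- function(mg_levels = c(1, 2, 3, 4, 6, 8, 16, 48),
                                  replicates = 3L) {
  ref <- paste0(
    "GTGCCTTGCGCCGGGAAACCACGCAAGGGATGGTGTCAAATTCGGCGAAACCTAAGCGCC",
    "CGCCCGGGCGTATGGCAACGCCGAGCCAAGCTTCGGCGCCTGCGCCGATGAAGGTGTAGA",
    "GACTAGACGGCACCCACCTAAGGCAAACGCTATGGTGAAGGCATAGTCCAGGGAGTGGCG",
    "AAAGTCACACAAACCGG")
  # intron positions 90..184 minus the 8 nt absent from the template
  library_spec(ref, c(90, 119, 128, 153, 158, 177, 184) - 8L,
               mg_levels = mg_levels, replicates = replicates)
}

#' Enumerate every genotype of a library
#'
#' Genotypes are allele strings over the variable positions, enumerated in
#' lexicographic order with A < C < G < U and the first variable position as
#' the most significant digit. This order is the canonical genotype index used
#' throughout the package (`genotype_index()` inverts it).
#'
#' @param spec A [library_spec()].
#' @return Character vector of 4^p genotype keys (p = number of variable
#'   positions), each combination exactly once.
#' @export
#' @examples
#' build_library(library_spec("AACC", c(1, 2)))
build_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  p <- length(spec$variable_positions)
  cols <- lapply(seq_len(p), function(i) {
    rep(RNA_ALPHABET, each = 4L^(p - i), times = 4L^(i - 1L))
  })
  do.call(paste0, cols)
}

#' Map genotype keys to canonical indices and back
#'
#' The canonical index is the 1-based rank of a genotype in the lexicographic
#' enumeration of [build_library()], i.e. the base-4 value of the allele string
#' (A=0, C=1, G=2, U=3) plus one.
#'
#' @param genotype Character vector of allele strings (RNA alphabet).
#' @param n_positions Number of variable positions (defaults to the string
#'   width of the first element).
#' @return `genotype_index()`: integer vector of indices in
#'   `1..4^n_positions`. `index_genotype()`: character vector of allele
#'   strings.
#' @export
genotype_index <- function(genotype, n_positions = nchar(genotype[1])) {
  if (length(genotype) == 0L) return(integer(0))
  stopifnot(all(nchar(genotype) == n_positions))
  m <- matrix(match(unlist(strsplit(genotype, "", fixed = TRUE)),
                    RNA_ALPHABET) - 1L,
              nrow = n_positions)
  if (anyNA(m)) stop("genotype contains non-ACGU characters")
  as.integer(colSums(m * 4L^((n_positions - 1L):0)) + 1L)
}

#' @rdname genotype_index
#' @param index Integer vector of canonical genotype indices.
#' @export
index_genotype <- function(index, n_positions) {
  v <- as.integer(index) - 1L
  if (any(v < 0L | v >= 4L^n_positions)) stop("index out of range")
  cols <- lapply((n_positions - 1L):0, function(p) {
    RNA_ALPHABET[(v %/% 4L^p) %% 4L + 1L]
  })
  do.call(paste0, cols)
}

#' Hamming distance between allele strings
#'
#' @param g1,g2 Character vectors of equal-length allele strings; recycled to
#'   a common length.
#' @return Integer vector of counts of differing positions.
#' @export
#' @examples
#' hamming_distance("AAAAAAA", "CAAAAAA")
hamming_distance <- function(g1, g2) {
  n <- max(length(g1), length(g2))
  g1 <- rep_len(g1, n); g2 <- rep_len(g2, n)
  if (n == 0L) return(integer(0))
  if (any(nchar(g1) != nchar(g2))) stop("genotype length mismatch")
  w <- nchar(g1[1])
  if (any(nchar(g1) != w)) stop("genotypes must share one length")
  m1 <- matrix(unlist(strsplit(g1, "", fixed = TRUE)), nrow = w)
  m2 <- matrix(unlist(strsplit(g2, "", fixed = TRUE)), nrow = w)
  as.integer(colSums(m1 != m2))
}

#' Single-substitution neighbors of a genotype
#'
#' @param g A single genotype key.
#' @return Character vector of the 3*p genotypes at Hamming distance 1,
#'   ordered by position then allele.
#' @export
#' @examples
#' neighbors("AA")
neighbors <- function(g) {
  stopifnot(is.character(g), length(g) == 1L)
  chars <- strsplit(g, "", fixed = TRUE)[[1]]
  if (!all(chars %in% RNA_ALPHABET)) stop("genotype contains non-ACGU characters")
  out <- character(0)
  for (i in seq_along(chars)) {
    for (a in setdiff(RNA_ALPHABET, chars[i])) {
      h <- chars; h[i] <- a
      out <- c(out, paste(h, collapse = ""))
    }
  }
  out
}

# Neighbor indices by index arithmetic: for canonical index v (0-based),
# digit at position p is (v %/% 4^(n-p)) %% 4; substituting allele a changes
# the index by (a - digit) * 4^(n-p). Returns an integer matrix with one row
# per input index and 3*n columns.
neighbor_indices <- function(index, n_positions) {
  v <- as.integer(index) - 1L
  out <- matrix(0L, nrow = length(v), ncol = 3L * n_positions)
  col <- 0L
  for (p in seq_len(n_positions)) {
    w <- 4L^(n_positions - p)
    d <- (v %/% w) %% 4L
    for (step in 1:3) {
      col <- col + 1L
      out[, col] <- v + ((d + step) %% 4L - d) * w + 1L
    }
  }
  out
}
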