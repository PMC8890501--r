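#' Compile a wildcard matcher for a library
#'
#' Builds the matcher that accepts exactly the reads equal to the reference
#' sequence everywhere except at the variable positions, where any nucleotide
#' is allowed; the alleles read off those positions identify the genotype.
#' Matching is case-insensitive and U/T-equivalent; reads of the wrong length
#' (indels) or carrying a substitution outside the variable positions are
#' rejected, as are reads with ambiguous bases (N) at a variable position.
#'
#' @param spec A [library_spec()].
#' @param allow_revcomp Also try the reverse complement of each read before
#'   rejecting it (off by default; the generator emits forward reads).
#' @return An object of class `variant_matcher`; its `pattern` field holds
#'   the equivalent regular expression.
#' @export
compile_matcher <- function(spec, allow_revcomp = FALSE) {
  stopifnot(inherits(spec, "library_spec"))
  ref <- spec$reference_sequence
  vp <- spec$variable_positions
  L <- nchar(ref)
  bounds <- c(0L, vp, L + 1L)
  seg_start <- utils::head(bounds, -1L) + 1L
  seg_end <- utils::tail(bounds, -1L) - 1L
  keep <- seg_start <= seg_end
  pattern <- paste0("^",
                    paste0(vapply(seq_along(vp), function(i) {
                      paste0(if (keep[i]) substring(ref, seg_start[i], seg_end[i]) else "",
                             "([ACGU])")
                    }, character(1)), collapse = ""),
                    if (keep[length(keep)])
                      substring(ref, seg_start[length(keep)], seg_end[length(keep)])
                    else "",
                    "$")
  structure(
    list(reference = ref, variable_positions = vp, length = L,
         seg_start = seg_start[keep], seg_end = seg_end[keep],
         segments = substring(ref, seg_start[keep], seg_end[keep]),
         pattern = pattern, allow_revcomp = allow_revcomp,
         n_positions = length(vp)),
    class = "variant_matcher")
}

# Vectorized matching of normalized RNA read strings against a matcher.
# Returns a character vector: the genotype key for matching reads, NA for
# rejected ones.
match_reads <- function(reads, matcher) {
  res <- rep(NA_character_, length(reads))
  ok <- nchar(reads) == matcher$length
  if (any(ok)) {
    sub <- reads[ok]
    good <- rep(TRUE, length(sub))
    for (s in seq_along(matcher$segments)) {
      good <- good & substring(sub, matcher$seg_start[s],
                               matcher$seg_end[s]) == matcher$segments[s]
    }
    vp <- matcher$variable_positions
    alle <- matrix("", nrow = length(sub), ncol = length(vp))
    for (k in seq_along(vp)) alle[, k] <- substring(sub, vp[k], vp[k])
    good <- good & rowSums(matrix(alle %in% RNA_ALPHABET,
                                  nrow = nrow(alle))) == length(vp)
    key <- do.call(paste0, as.data.frame(alle, stringsAsFactors = FALSE))
    res[ok][good] <- key[good]
  }
  res
}

normalize_reads <- function(x) chartr("T", "U", toupper(x))

#' Count library variants in a FASTQ file
#'
#' Streams the file in chunks, matches every read with the compiled matcher
#' and tallies one count per identified genotype. Reads that fail the matcher
#' (wrong length, off-target mutation, ambiguous base) are counted as
#' rejected.
#'
#' @param fastq_path Path to a FASTQ file (optionally gzip-compressed).
#' @param matcher A [compile_matcher()] object.
#' @param chunk_size Reads held in memory at a time.
#' @return A list of class `count_table`: data.frame `counts` (`genotype`,
#'   `count`, every library genotype in canonical order), `total_matched`,
#'   `total_rejected`, `total_reads`.
#' @export
count_reads <- function(fastq_path, matcher, chunk_size = 2e5L) {
  stopifnot(inherits(matcher, "variant_matcher"))
  if (!file.exists(fastq_path)) stop("FASTQ file not found: ", fastq_path)
  p <- matcher$n_positions
  tallies <- integer(4L^p)
  rejected <- 0L
  skip <- 0L
  repeat {
    chunk <- tryCatch(
      Biostrings::readBStringSet(fastq_path, format = "fastq",
                                 nrec = chunk_size, skip = skip),
      error = function(e) stop("malformed FASTQ record near read ",
                               skip + 1L, ": ", conditionMessage(e),
                               call. = FALSE))
    if (length(chunk) == 0L) break
    reads <- normalize_reads(as.character(chunk))
    keys <- match_reads(reads, matcher)
    if (matcher$allow_revcomp && anyNA(keys)) {
      miss <- which(is.na(keys))
      rc <- tryCatch(
        as.character(Biostrings::reverseComplement(
          Biostrings::RNAStringSet(reads[miss]))),
        error = function(e) NULL)
      if (!is.null(rc)) keys[miss] <- match_reads(normalize_reads(rc), matcher)
    }
    hit <- !is.na(keys)
    rejected <- rejected + sum(!hit)
    if (any(hit))
      tallies <- tallies + tabulate(genotype_index(keys[hit], p), 4L^p)
    skip <- skip + length(chunk)
    if (length(chunk) < chunk_size) break
  }
  lib <- index_genotype(seq_len(4L^p), p)
  structure(
    list(counts = data.frame(genotype = lib, count = tallies,
                             stringsAsFactors = FALSE),
         total_matched = sum(tallies),
         total_rejected = rejected,
         total_reads = sum(tallies) + rejected),
    class = "count_table")
}

#' Convert counts to proportions
#'
#' Each genotype's count divided by the total count of reads that matched any
#' library variant.
#'
#' @param counts A `count_table` from [count_reads()], or a data.frame with
#'   columns `genotype` and `count`.
#' @return Data.frame with columns `genotype` and `proportion` (summing to 1).
#' @export
proportions <- function(counts) {
  df <- if (inherits(counts, "count_table")) counts$counts else counts
  stopifnot(all(c("genotype", "count") %in% names(df)))
  total <- sum(df$count)
  if (total == 0L) stop("empty pool: no matched reads to normalize")
  data.frame(genotype = df$genotype, proportion = df$count / total,
             stringsAsFactors = FALSE)
}
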