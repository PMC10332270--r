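# Small shared helpers: sequence string utilities, RNG plumbing, validation.

#' @import data.table
#' @importFrom stats rbinom rlnorm rmultinom rnorm runif quantile median
#'   pchisq setNames
#' @importFrom utils head write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised over its input; only A/C/G/T (upper case) are handled, which is
#' all the simulator emits.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGT", "TGCA", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Reverse a plain string (used for quality strings of reversed mates).
str_rev <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Random DNA string(s) of the given lengths, under the current RNG state.
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute bases of `seq` at `positions`; each new base differs from the old.
mutate_at <- function(seq, positions) {
  if (length(positions) == 0L) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
  }
  paste(s, collapse = "")
}

# Apply i.i.d. per-base substitutions with probability `rate` to each string.
# Returns the mutated vector; untouched strings are returned as-is.
mutate_strings <- function(x, rate) {
  if (rate <= 0) return(x)
  lens <- nchar(x)
  nerr <- rbinom(length(x), lens, rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    x[i] <- mutate_at(x[i], sample.int(lens[i], nerr[i]))
  }
  x
}

# Hamming distance between equal-length strings (integer vectors are faster
# than strsplit for repeated calls).
hamming <- function(a, b) {
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  stopifnot(length(ia) == length(ib))
  sum(ia != ib)
}

# Count mismatches between the first nchar(primer) bases of each string in `x`
# and `primer`. Vectorised over `x`; positions beyond nchar(x) count as
# mismatches (incomplete primer).
prefix_mismatch <- function(x, primer) {
  k <- nchar(primer)
  mm <- integer(length(x))
  short <- nchar(x) < k
  for (i in seq_len(k)) {
    pc <- substr(primer, i, i)
    mm <- mm + (substr(x, i, i) != pc)
  }
  mm[short] <- k
  mm
}

# Phred quality string from integer scores (Sanger offset 33).
phred_string <- function(q, len) {
  strrep(intToUtf8(q + 33L), len)
}

# Integer Phred scores from a quality string.
phred_scores <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' Expected number of sequencing errors of a read
#'
#' Sum of per-base error probabilities \eqn{10^{-Q/10}} over the Phred scores
#' encoded in a quality string (Sanger offset 33).
#'
#' @param qual character vector of quality strings.
#' @return numeric vector of expected error counts.
#' @export
expected_errors <- function(qual) {
  uq <- unique(qual)
  ee <- vapply(uq, function(q) {
    if (nchar(q) == 0L) return(0)
    sum(10^(-phred_scores(q) / 10))
  }, numeric(1))
  unname(ee[match(qual, uq)])
}

# Derive a reproducible per-stage seed from a master seed and a stage name.
# Stable across sessions (pure arithmetic on the stage name's bytes).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
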