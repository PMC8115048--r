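#' @importFrom stats runif rbinom setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Sample a random DNA sequence
#'
#' @param n Sequence length in bases.
#' @param gc_fraction Target GC content as a proportion in \[0, 1\].
#' @return A single character string of A/C/G/T.
#' @export
random_dna <- function(n, gc_fraction = 0.5) {
  stopifnot(n >= 1, gc_fraction >= 0, gc_fraction <= 1)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# substitute characters at 1-based positions
subst_chars <- function(seq, pos, base) {
  ch <- seq_chars(seq)
  ch[pos] <- base
  paste(ch, collapse = "")
}

as_sequence_vector <- function(x) {
  if (methods::is(x, "DNAStringSet") || methods::is(x, "XStringSet")) {
    setNames(as.character(x), names(x))
  } else if (methods::is(x, "DNAString")) {
    as.character(x)
  } else if (is.character(x)) {
    x
  } else {
    stop("expected character vector or DNAStringSet of sequences")
  }
}

# k-mers of a character string at every start position
kmerize <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}
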