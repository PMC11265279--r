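## Internal sequence helpers shared by the aligner and the synthetic module.
## Contig sets are plain named DNAStringSet objects throughout the package.

.DNA <- c("A", "C", "G", "T")

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. draws over A/C/G/T using the current RNG stream; used by the
#' synthetic community generator and by tests.
#'
#' @param n length in bp
#' @return a character scalar
#' @export
randomDNA <- function(n) {
  paste(sample(.DNA, n, replace = TRUE), collapse = "")
}

#' Mutate a DNA sequence by random substitutions
#'
#' Substitution-only mutation: each position is replaced, with probability
#' `rate`, by one of the three other bases.  No indels are introduced, so the
#' expected alignment identity of the mutant against its source is `1 - rate`
#' exactly, which keeps clustering thresholds analytically predictable.
#'
#' @param seq character scalar (DNA)
#' @param rate per-base substitution probability in \[0, 1\]
#' @return mutated character scalar of the same length
#' @export
mutateSequence <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    repl <- vapply(chars[hit], function(b) {
      sample(setdiff(.DNA, b), 1L)
    }, character(1))
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

## coerce a contig set argument to a named character vector of sequences
.asSeqVector <- function(contigs) {
  if (is(contigs, "DNAStringSet")) {
    out <- as.character(contigs)
  } else if (is.character(contigs)) {
    out <- contigs
  } else {
    stop("contigs must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || anyDuplicated(names(out))) {
    stop("contig sequences must carry unique names")
  }
  toupper(out)
}

.revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
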