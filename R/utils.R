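#' Reverse complement of a nucleotide string
#'
#' @param seq character vector of sequences over the ACGTN alphabet.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Canonical form of a circular sequence
#'
#' Two assemblies of the same circular genome can differ by rotation and by
#' strand. This normalizes a circular sequence to the lexicographically
#' smallest rotation of the lexicographically smaller strand, so that two
#' circular sequences are equal iff they describe the same circle.
#'
#' @param seq a single nucleotide string.
#' @return the normalized string.
#' @export
normalize_circular <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  a <- cpp_least_rotation(seq)
  b <- cpp_least_rotation(cpp_revcomp(seq))
  if (a < b) a else b
}

# validate sequences: uppercase, ACGTN only; returns uppercased vector
check_nucleotides <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf("%s %d contains characters outside ACGTN", what,
                 which(bad)[1L]), call. = FALSE)
  }
  seq
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# derive a bounded sub-seed from a master seed and a stream index
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %%
               2147483647)
}
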