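#' @import methods
#' @importFrom stats setNames
NULL

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Normalize and validate an amino-acid sequence
#'
#' Upper-cases the input and checks that it contains only the twenty standard
#' residues plus, optionally, \code{X} for an unknown residue. The ambiguity
#' codes \code{B}, \code{Z}, \code{J} and the non-standard \code{U}/\code{O}
#' are rejected with an explicit error rather than silently remapped.
#'
#' @param x a character string, \code{AAString}, or anything coercible with
#'   \code{as.character}.
#' @param allowX allow \code{X} (unknown residue)? Default \code{TRUE}.
#' @param what label used in error messages.
#' @return the normalized uppercase sequence as a character string.
#' @export
normalizeSequence <- function(x, allowX = TRUE, what = "sequence") {
  x <- toupper(as.character(x)[1L])
  if (is.na(x) || nchar(x) == 0L)
    stop(what, " is empty")
  chars <- unique(strsplit(x, "")[[1]])
  allowed <- c(AA_STANDARD, if (allowX) "X")
  bad <- setdiff(chars, allowed)
  if (length(bad)) {
    if (any(bad %in% c("U", "B", "Z", "J", "O")))
      stop(what, " contains ambiguous or non-standard residue code(s): ",
           paste(intersect(bad, c("U", "B", "Z", "J", "O")), collapse = ", "),
           " (not supported; remove or replace explicitly)")
    stop(what, " contains invalid character(s): ", paste(bad, collapse = ", "))
  }
  x
}

## Evaluate expr under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## md5 of a character scalar (content digest; tools::md5sum is file-based).
stringDigest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(paste(x, collapse = "\n"), tf, eos = NULL)
  unname(tools::md5sum(tf))
}

## Split a sequence string into single characters.
seqChars <- function(x) strsplit(x, "")[[1]]

## Read a FASTA of amino-acid sequences as a named character vector.
readFastaSequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

writeFastaSequences <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(unlist(seqs)), filepath = path)
  invisible(path)
}
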