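#' Build an exact k-mer index over a reference proteome
#'
#' Indexes every length-\code{k} window of every record; windows containing
#' \code{X} (unknown residue) are skipped on both the index and the query
#' side, so an unknown residue can never support a match. Duplicate windows
#' accumulate all their source occurrences. A digest of the proteome content
#' is stored and propagated into every report, because the reference set and
#' release are inputs, not constants.
#'
#' @param proteome named character vector of sequences, an
#'   \code{AAStringSet}, or a path to a FASTA file.
#' @param k window length (default 9, the consecutive-peptide length used in
#'   self-similarity screening).
#' @return a \linkS4class{KmerIndex}.
#' @examples
#' idx <- buildKmerIndex(c(p1 = "ACDEFGHIKLMN"), k = 9)
#' idx  # 4 windows
#' @export
buildKmerIndex <- function(proteome, k = 9L) {
  stopifnot(k >= 1L)
  proteome <- asSequenceSet(proteome, what = "proteome")
  if (!length(proteome)) stop("empty proteome")
  map <- new.env(hash = TRUE, parent = emptyenv())
  nWindows <- 0L
  for (i in seq_along(proteome)) {
    seqi <- proteome[[i]]
    id <- names(proteome)[i]
    n <- nchar(seqi) - k + 1L
    if (n < 1L) next
    starts <- seq_len(n)
    wins <- substring(seqi, starts, starts + k - 1L)
    ok <- !grepl("X", wins, fixed = TRUE)
    for (j in which(ok)) {
      w <- wins[j]
      hit <- data.frame(id = id, start = starts[j], stringsAsFactors = FALSE)
      if (exists(w, envir = map, inherits = FALSE)) {
        assign(w, rbind(get(w, envir = map), hit), envir = map)
      } else assign(w, hit, envir = map)
    }
    nWindows <- nWindows + sum(ok)
  }
  new("KmerIndex", k = as.integer(k), map = map, nWindows = nWindows,
      nProteins = length(proteome),
      proteomeDigest = stringDigest(paste(names(proteome), proteome,
                                          sep = ":")))
}

## Coerce proteome/query inputs to a named character vector of validated
## uppercase sequences.
asSequenceSet <- function(x, what = "sequence set") {
  if (!length(x)) stop("empty ", what)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- readFastaSequences(x)
  } else if (methods::is(x, "XStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  empty <- names(x) == ""
  names(x)[empty] <- paste0("seq", which(empty))
  vapply(x, normalizeSequence, "", what = what)
}

#' Is a window an index key?
#'
#' @param index a KmerIndex.
#' @param window character vector of windows of length \code{kmerSize(index)}.
#' @return logical vector.
#' @export
hasWindow <- function(index, window) {
  vapply(window, function(w)
    exists(w, envir = index@map, inherits = FALSE), TRUE, USE.NAMES = FALSE)
}

windowSources <- function(index, window) {
  if (exists(window, envir = index@map, inherits = FALSE))
    get(window, envir = index@map)
  else data.frame(id = character(0), start = integer(0))
}

#' Scan a query sequence for windows shared with the reference proteome
#'
#' Reports every k-window of the query that occurs identically anywhere in
#' the indexed proteome (exact identity only; no I/L equivalence or
#' near-matching). Windows containing \code{X} never match.
#'
#' @param query a sequence (character/AAString) or single-record FASTA path.
#' @param index a \linkS4class{KmerIndex}.
#' @param queryId identifier recorded in the report.
#' @return a \linkS4class{HumannessReport}.
#' @export
scanSequence <- function(query, index, queryId = "query") {
  query <- normalizeSequence(query, what = "query")
  k <- index@k
  n <- nchar(query) - k + 1L
  if (n < 1L) {
    return(new("HumannessReport", queryId = queryId, k = k, nWindows = 0L,
               matches = emptyMatches(),
               proteomeDigest = index@proteomeDigest))
  }
  starts <- seq_len(n)
  wins <- substring(query, starts, starts + k - 1L)
  ok <- !grepl("X", wins, fixed = TRUE) & hasWindow(index, wins)
  rows <- lapply(which(ok), function(j) {
    src <- windowSources(index, wins[j])
    data.frame(query_start = starts[j], window = wins[j],
               protein_id = src$id, protein_start = src$start,
               stringsAsFactors = FALSE)
  })
  matches <- if (length(rows)) do.call(rbind, rows) else emptyMatches()
  new("HumannessReport", queryId = queryId, k = k, nWindows = n,
      matches = matches, proteomeDigest = index@proteomeDigest)
}

emptyMatches <- function() {
  data.frame(query_start = integer(0), window = character(0),
             protein_id = character(0), protein_start = integer(0),
             stringsAsFactors = FALSE)
}

#' Write a humanness report as TSV plus JSON summary
#'
#' The TSV holds one row per (matched window, source occurrence); the JSON
#' summary records the query id, window counts, distinct proteins hit, and
#' the proteome digest.
#'
#' @param report a HumannessReport.
#' @param tsvPath,jsonPath output paths (either may be NULL to skip).
#' @export
writeHumannessReport <- function(report, tsvPath = NULL, jsonPath = NULL) {
  if (!is.null(tsvPath))
    utils::write.table(report@matches, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(
      query_id = report@queryId, k = report@k,
      n_windows = report@nWindows,
      n_matched_windows = nMatchedWindows(report),
      distinct_proteins_hit = distinctProteinsHit(report),
      proteome_md5 = report@proteomeDigest),
      jsonPath, auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
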