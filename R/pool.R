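#' Build per-position substitution pools from a species-variant alignment
#'
#' For each requested sequence position, the allowed replacement residues
#' are those observed at least \code{minCount} times in the corresponding
#' alignment column, excluding gaps, \code{X}, and the residue currently at
#' that position; weights are the observed counts. Columns are located
#' through the scaffold row of the alignment: position p of the scaffold
#' maps to the column holding the scaffold's p-th residue. When a
#' \code{positionMap} from a \linkS4class{GraftPlan} is supplied, positions
#' are interpreted on the grafted sequence; insertion positions (no scaffold
#' column of their own) inherit the nearest scaffold column and are flagged
#' in the \code{inherited} slot.
#'
#' @param msa aligned sequences (named character vector, AAStringSet, or
#'   aligned-FASTA path); rows must share one length.
#' @param sequence the sequence the pools apply to (grafted or scaffold).
#' @param positions integer positions needing pools (default: all).
#' @param minCount minimum column count for a residue to enter a pool.
#' @param scaffoldRow name or index of the scaffold row in the alignment.
#' @param positionMap optional \code{positionMap} data.frame from a
#'   GraftPlan (columns grafted_pos, scaffold_pos, origin).
#' @return a \linkS4class{SubstitutionPool}.
#' @examples
#' msa <- c(sc = "ACDE", v1 = "ASDE", v2 = "ASDE")
#' buildSubstitutionPool(msa, "ACDE", positions = 2)  # pool {S: 2}
#' @export
buildSubstitutionPool <- function(msa, sequence, positions = NULL,
                                  minCount = 1L, scaffoldRow = 1L,
                                  positionMap = NULL) {
  stopifnot(minCount >= 1L)
  msa <- asAlignedSet(msa)
  sequence <- normalizeSequence(sequence, what = "sequence")
  if (is.null(positions)) positions <- seq_len(nchar(sequence))
  positions <- sort(unique(as.integer(positions)))
  if (any(positions < 1L | positions > nchar(sequence)))
    stop("positions outside the sequence")
  scafAln <- if (is.character(scaffoldRow)) {
    if (!scaffoldRow %in% rownames(msa))
      stop("scaffold row '", scaffoldRow, "' not in alignment")
    msa[scaffoldRow, ]
  } else msa[scaffoldRow, ]
  colOfScafPos <- which(scafAln != "-")
  scafLen <- length(colOfScafPos)
  resolveScaffoldPos <- function(p) {
    if (is.null(positionMap)) return(list(pos = p, inherited = FALSE))
    row <- positionMap[positionMap$grafted_pos == p, , drop = FALSE]
    if (nrow(row) == 0L) stop("position ", p, " not in the position map")
    sp <- row$scaffold_pos[1]
    if (!is.na(sp)) return(list(pos = sp, inherited = FALSE))
    ## insertion: inherit the nearest mapped scaffold position (left first)
    known <- positionMap[!is.na(positionMap$scaffold_pos), , drop = FALSE]
    if (nrow(known) == 0L) stop("position map has no scaffold positions")
    d <- abs(known$grafted_pos - p)
    near <- known[order(d, known$grafted_pos), ][1, ]
    list(pos = near$scaffold_pos, inherited = TRUE)
  }
  pools <- list()
  inherited <- integer(0)
  for (p in positions) {
    rs <- resolveScaffoldPos(p)
    if (rs$pos > scafLen)
      stop("position ", p, " has no alignment column ",
           "(scaffold position ", rs$pos, " beyond alignment)")
    if (rs$inherited) inherited <- c(inherited, p)
    col <- msa[, colOfScafPos[rs$pos]]
    col <- col[!col %in% c("-", ".", "X")]
    counts <- table(col)
    counts <- counts[counts >= minCount]
    current <- substr(sequence, p, p)
    counts <- counts[names(counts) != current]
    pools[[as.character(p)]] <- if (length(counts))
      setNames(as.numeric(counts), names(counts)) else numeric(0)
  }
  new("SubstitutionPool", pools = pools, inherited = inherited,
      params = list(minCount = minCount))
}

## Coerce an aligned sequence set into a character matrix (rows x columns).
asAlignedSet <- function(msa) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- readFastaSequences(msa)
  if (methods::is(msa, "XStringSet") || methods::is(msa, "AAMultipleAlignment"))
    msa <- setNames(as.character(msa), names(msa))
  msa <- toupper(msa)
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L)
    stop("alignment rows differ in length; supply an aligned FASTA")
  m <- do.call(rbind, strsplit(msa, ""))
  rownames(m) <- if (is.null(names(msa)))
    paste0("row", seq_along(msa)) else names(msa)
  m
}
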