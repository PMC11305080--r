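blosumMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Globally align the donor antigen to the scaffold homolog
#'
#' Needleman-Wunsch global alignment (via Biostrings) under a substitution
#' matrix and affine gap penalties; defaults BLOSUM62, gap open 11 and
#' extend 1. The traceback is deterministic, so repeated calls give the same
#' alignment.
#'
#' @param donor,scaffold sequences (character or AAString).
#' @param matrix substitution matrix name shipped with Biostrings
#'   (\code{"BLOSUM62"}, \code{"BLOSUM45"}, ...).
#' @param gapOpening,gapExtension positive gap penalties.
#' @return a \linkS4class{GraftAlignment}.
#' @examples
#' alignDonorScaffold("AAAA", "AAAA")  # identity, score 16
#' @export
alignDonorScaffold <- function(donor, scaffold, matrix = "BLOSUM62",
                               gapOpening = 11, gapExtension = 1) {
  donor <- normalizeSequence(donor, what = "donor")
  scaffold <- normalizeSequence(scaffold, what = "scaffold")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(donor), Biostrings::AAString(scaffold),
    type = "global", substitutionMatrix = blosumMatrix(matrix),
    gapOpening = gapOpening, gapExtension = gapExtension)
  ad <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  dc <- seqChars(ad); sc <- seqChars(as_)
  cm <- data.frame(
    column = seq_along(dc),
    donor_pos = ifelse(dc == "-", NA_integer_, cumsum(dc != "-")),
    scaffold_pos = ifelse(sc == "-", NA_integer_, cumsum(sc != "-")))
  new("GraftAlignment", alignedDonor = ad, alignedScaffold = as_,
      columnMap = cm, score = Biostrings::score(aln))
}

#' Transplant donor epitope stretches onto the scaffold
#'
#' Produces the grafted sequence: identical to the scaffold outside the
#' aligned span of every stretch, and identical to the donor stretch
#' residues inside. Within a stretch span, a scaffold-gap column inserts the
#' donor residue (recorded as an insertion) and a donor-gap column drops the
#' scaffold residue (recorded as a deletion).
#'
#' @param scaffold,donor the two sequences the alignment was built from.
#' @param stretches an \linkS4class{EpitopeStretches} over donor positions.
#' @param alignment a \linkS4class{GraftAlignment} of (donor, scaffold).
#' @return list with \code{sequence} (the grafted sequence) and \code{plan}
#'   (a \linkS4class{GraftPlan}).
#' @export
transplantStretches <- function(scaffold, donor, stretches, alignment) {
  donor <- normalizeSequence(donor, what = "donor")
  scaffold <- normalizeSequence(scaffold, what = "scaffold")
  if (gsub("-", "", alignment@alignedDonor) != donor ||
      gsub("-", "", alignment@alignedScaffold) != scaffold)
    stop("alignment does not correspond to the supplied donor/scaffold")
  r <- stretches@ranges
  if (length(r) && max(IRanges::end(r)) > nchar(donor))
    stop("stretch outside donor range")
  cm <- alignment@columnMap
  dc <- seqChars(alignment@alignedDonor)
  sc <- seqChars(alignment@alignedScaffold)
  inStretch <- rep(FALSE, nrow(cm))
  for (i in seq_along(r)) {
    colStart <- which(!is.na(cm$donor_pos) &
                      cm$donor_pos == IRanges::start(r)[i])
    colEnd <- which(!is.na(cm$donor_pos) & cm$donor_pos == IRanges::end(r)[i])
    inStretch[colStart:colEnd] <- TRUE
  }
  out <- character(0)
  tpos <- integer(0)
  posMap <- list()
  subs <- list(); ins <- list(); dels <- list()
  g <- 0L
  for (cl in seq_len(nrow(cm))) {
    dp <- cm$donor_pos[cl]; sp <- cm$scaffold_pos[cl]
    if (inStretch[cl]) {
      if (!is.na(dp)) {
        g <- g + 1L
        out[g] <- dc[cl]
        tpos <- c(tpos, g)
        posMap[[g]] <- c(g, sp)
        if (is.na(sp)) {
          ins[[length(ins) + 1L]] <- data.frame(grafted_pos = g,
                                                residue = dc[cl])
        } else if (sc[cl] != dc[cl]) {
          subs[[length(subs) + 1L]] <- data.frame(scaffold_pos = sp,
                                                  from = sc[cl], to = dc[cl])
        }
      } else if (!is.na(sp)) {
        dels[[length(dels) + 1L]] <- data.frame(scaffold_pos = sp,
                                                residue = sc[cl])
      }
    } else if (!is.na(sp)) {
      g <- g + 1L
      out[g] <- sc[cl]
      posMap[[g]] <- c(g, sp)
    }
  }
  pm <- do.call(rbind, posMap)
  positionMap <- data.frame(
    grafted_pos = pm[, 1], scaffold_pos = pm[, 2],
    origin = ifelse(seq_len(g) %in% tpos,
                    ifelse(is.na(pm[, 2]), "epitope_insertion", "epitope"),
                    "scaffold"))
  grafted <- paste(out, collapse = "")
  emptyDf <- function(...) {
    cols <- list(...)
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  plan <- new("GraftPlan",
    stretches = stretches,
    transplantedPositions = tpos,
    transplantedResidues = out[tpos],
    substitutions = if (length(subs)) do.call(rbind, subs) else
      emptyDf(scaffold_pos = integer(0), from = character(0),
              to = character(0)),
    insertions = if (length(ins)) do.call(rbind, ins) else
      emptyDf(grafted_pos = integer(0), residue = character(0)),
    deletions = if (length(dels)) do.call(rbind, dels) else
      emptyDf(scaffold_pos = integer(0), residue = character(0)),
    positionMap = positionMap,
    graftedLength = g)
  list(sequence = grafted, plan = plan)
}

#' Write a graft plan as JSON
#'
#' @param plan a GraftPlan.
#' @param path output path.
#' @export
writeGraftPlan <- function(plan, path) {
  jsonlite::write_json(list(
    stretches = stretchesAsData(plan@stretches),
    transplanted_positions = plan@transplantedPositions,
    transplanted_residues = paste(plan@transplantedResidues, collapse = ""),
    substitutions = plan@substitutions,
    insertions = plan@insertions,
    deletions = plan@deletions,
    grafted_length = plan@graftedLength),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
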