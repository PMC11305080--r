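#' Per-residue buried surface area against one partner
#'
#' BSA of each target-chain residue is the sum over its atoms of
#' SASA(target chains alone) minus SASA(full complex), clamped at zero
#' (quadrature noise can produce tiny negative sums). Both SASA passes share
#' one quadrature frame, so residues out of reach of every partner atom get
#' exactly zero.
#'
#' @param model a \linkS4class{StructureModel} of the complex.
#' @param partition a \linkS4class{ChainPartition}; both chain sets must be
#'   present in the model.
#' @param probeRadius,nPoints see \code{\link{computeSasa}}.
#' @return data.frame with one row per target residue (columns \code{chain},
#'   \code{resno}, \code{insert}, \code{resid}, \code{bsa_A2}), in chain
#'   order.
#' @export
perResidueBsa <- function(model, partition, probeRadius = 1.4,
                          nPoints = 960L) {
  checkPartition(model, partition)
  target <- subsetChains(model, partition@targetChains)
  frame <- canonicalFrame(as.matrix(target@atoms[, c("x", "y", "z")]))
  both <- subsetChains(model, c(partition@targetChains,
                                partition@partnerChains))
  sasaComplex <- computeSasa(both, probeRadius, nPoints, frame = frame)
  sasaAlone <- computeSasa(target, probeRadius, nPoints, frame = frame)
  isTarget <- both@atoms$chain %in% partition@targetChains
  diff <- sasaAlone - sasaComplex[isTarget]
  key <- paste(target@atoms$chain, target@atoms$resno, target@atoms$insert,
               sep = "\r")
  res <- residueTable(target)
  res$bsa_A2 <- pmax(0, as.numeric(
    tapply(diff, factor(key, levels = unique(key)), sum)))
  rownames(res) <- NULL
  res
}

#' Map structure residues to 1-based donor sequence positions
#'
#' Aligns each target chain's extracted one-letter sequence to the donor
#' sequence (global on the chain, local on the donor, BLOSUM62) and returns
#' the author-numbering to donor-position correspondence. A chain whose
#' aligned identity falls below \code{minIdentity} is a hard error (it guards
#' against numbering mix-ups); chain residues aligned to a donor gap are
#' dropped with a warning.
#'
#' @param model a StructureModel.
#' @param chains target chain ids.
#' @param donor donor sequence (character or AAString).
#' @param minIdentity minimum fraction identity over aligned columns.
#' @return data.frame(chain, resno, insert, donor_pos).
#' @export
mapDonorNumbering <- function(model, chains, donor, minIdentity = 0.8) {
  donor <- normalizeSequence(donor, what = "donor")
  out <- NULL
  for (ch in chains) {
    cs <- chainSequence(model, ch)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(cs), Biostrings::AAString(donor),
      type = "global-local", substitutionMatrix = blosumMatrix("BLOSUM62"),
      gapOpening = 11, gapExtension = 1)
    ap <- seqChars(as.character(Biostrings::alignedPattern(aln)))
    as_ <- seqChars(as.character(Biostrings::alignedSubject(aln)))
    donorOffset <- aln@subject@range@start - 1L
    ci <- cumsum(ap != "-")
    di <- cumsum(as_ != "-") + donorOffset
    both <- ap != "-" & as_ != "-"
    ident <- sum(ap[both] == as_[both]) / max(1L, sum(both))
    if (ident < minIdentity)
      stop("chain ", ch, " maps to the donor with identity ",
           sprintf("%.2f", ident), " < ", minIdentity,
           "; refusing the numbering map")
    if (any(ap != "-" & as_ == "-"))
      warning("chain ", ch, ": ", sum(ap != "-" & as_ == "-"),
              " residue(s) have no donor position and are dropped")
    res <- residueTable(model, ch)
    keep <- both[ap != "-"]
    map <- data.frame(res[keep, c("chain", "resno", "insert")],
                      donor_pos = di[both])
    out <- rbind(out, map)
  }
  rownames(out) <- NULL
  out
}

#' Assemble a multi-partner footprint profile on donor numbering
#'
#' Runs \code{\link{perResidueBsa}} for each partner complex, maps structure
#' numbering to donor positions, and assembles the per-residue,
#' per-partner BSA table. Donor positions not modeled in a structure carry
#' BSA 0 and are flagged per partner in the profile.
#'
#' @param complexes named list (names are partner complex ids); each element
#'   a list with \code{model} (StructureModel) and \code{partition}
#'   (ChainPartition).
#' @param donor donor sequence.
#' @param probeRadius,nPoints see \code{\link{computeSasa}}.
#' @return a \linkS4class{FootprintProfile}.
#' @export
buildFootprint <- function(complexes, donor, probeRadius = 1.4,
                           nPoints = 960L) {
  donor <- normalizeSequence(donor, what = "donor")
  if (is.null(names(complexes)) || any(names(complexes) == ""))
    stop("complexes must be a named list (partner ids)")
  dlen <- nchar(donor)
  dres <- seqChars(donor)
  rows <- list()
  unmodeled <- list()
  for (pid in names(complexes)) {
    cx <- complexes[[pid]]
    bsa <- perResidueBsa(cx$model, cx$partition, probeRadius, nPoints)
    map <- mapDonorNumbering(cx$model, cx$partition@targetChains, donor)
    key <- function(d) paste(d$chain, d$resno, d$insert, sep = "\r")
    bsa$donor_pos <- map$donor_pos[match(key(bsa), key(map))]
    bsa <- bsa[!is.na(bsa$donor_pos), , drop = FALSE]
    full <- numeric(dlen)
    full[bsa$donor_pos] <- bsa$bsa_A2
    rows[[pid]] <- data.frame(
      donor_pos = seq_len(dlen), residue = dres, partner_id = pid,
      bsa_A2 = full, stringsAsFactors = FALSE)
    unmodeled[[pid]] <- setdiff(seq_len(dlen), bsa$donor_pos)
  }
  new("FootprintProfile", bsa = do.call(rbind, c(rows, make.row.names = FALSE)),
      partnerIds = names(complexes), donorLength = as.integer(dlen),
      unmodeled = unmodeled)
}

#' Donor positions contacted by a partner
#'
#' Positions whose buried surface area against the given partner is at least
#' \code{bsaThreshold} (default 1 square Angstrom — the working definition of
#' "contacted"; no structural cutoff is universal, so it is configurable).
#'
#' @param profile a \linkS4class{FootprintProfile}.
#' @param partnerId one of \code{partnerIds(profile)}.
#' @param bsaThreshold minimum BSA in square Angstrom (>= 0).
#' @return sorted integer vector of donor positions.
#' @export
contactResidues <- function(profile, partnerId, bsaThreshold = 1.0) {
  stopifnot(bsaThreshold >= 0)
  if (!partnerId %in% profile@partnerIds)
    stop("unknown partner id: ", partnerId)
  b <- profile@bsa
  sort(b$donor_pos[b$partner_id == partnerId & b$bsa_A2 >= bsaThreshold])
}

#' All per-partner contact sets of a profile
#'
#' @inheritParams contactResidues
#' @return named list of integer vectors.
#' @export
contactSets <- function(profile, bsaThreshold = 1.0) {
  setNames(lapply(profile@partnerIds, contactResidues, profile = profile,
                  bsaThreshold = bsaThreshold), profile@partnerIds)
}

#' Select epitope-critical residue stretches
#'
#' A donor position is critical when it appears in at least
#' \code{minPartners} of the partner contact sets. Critical positions are
#' merged into maximal runs in which consecutive critical positions are at
#' most \code{gapMerge + 1} apart (i.e. up to \code{gapMerge} non-critical
#' residues are bridged). Each stretch records the union of partners
#' contacting any of its critical positions. The result is independent of
#' the order of the contact sets.
#'
#' @param contactSets named list: partner id -> integer donor positions.
#' @param minPartners minimum number of supporting partners (>= 1).
#' @param gapMerge maximum bridged gap (>= 0).
#' @param donor optional donor sequence; when given, each stretch carries its
#'   donor residue string.
#' @return an \linkS4class{EpitopeStretches}.
#' @examples
#' selectEpitopeStretches(list(A = c(5, 6, 9, 20), B = c(5, 6, 9)),
#'                        minPartners = 2, gapMerge = 2)
#' @export
selectEpitopeStretches <- function(contactSets, minPartners = 2L,
                                   gapMerge = 2L, donor = NULL) {
  stopifnot(minPartners >= 1L, gapMerge >= 0L)
  if (is.null(names(contactSets)))
    stop("contactSets must be named by partner id")
  counts <- table(unlist(lapply(contactSets, unique)))
  critical <- sort(as.integer(names(counts)[counts >= minPartners]))
  if (!length(critical)) {
    return(new("EpitopeStretches", ranges = IRanges::IRanges(),
               partners = list(), residues = character(0),
               params = list(minPartners = minPartners, gapMerge = gapMerge)))
  }
  breaks <- which(diff(critical) > gapMerge + 1L)
  startIdx <- c(1L, breaks + 1L)
  endIdx <- c(breaks, length(critical))
  starts <- critical[startIdx]
  ends <- critical[endIdx]
  partnerNames <- sort(names(contactSets))
  partners <- lapply(seq_along(starts), function(i) {
    inRun <- critical[critical >= starts[i] & critical <= ends[i]]
    sort(partnerNames[vapply(partnerNames, function(p)
      any(inRun %in% contactSets[[p]]), TRUE)])
  })
  residues <- if (is.null(donor)) rep("", length(starts)) else {
    donor <- normalizeSequence(donor, what = "donor")
    vapply(seq_along(starts), function(i)
      substr(donor, starts[i], ends[i]), "")
  }
  new("EpitopeStretches",
      ranges = IRanges::IRanges(start = starts, end = ends),
      partners = partners, residues = residues,
      params = list(minPartners = minPartners, gapMerge = gapMerge))
}

#' Write a footprint profile as TSV
#'
#' Columns: donor_pos, residue, partner_id, bsa_A2.
#'
#' @param profile a FootprintProfile.
#' @param path output path.
#' @export
writeFootprintTsv <- function(profile, path) {
  utils::write.table(profile@bsa, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

stretchesAsData <- function(stretches) {
  r <- stretches@ranges
  data.frame(start = IRanges::start(r), end = IRanges::end(r),
             residues = stretches@residues,
             partners = vapply(stretches@partners, paste, "",
                               collapse = ","),
             stringsAsFactors = FALSE)
}

#' Write epitope stretches as TSV or JSON
#'
#' @param stretches an EpitopeStretches.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
writeStretches <- function(stretches, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- stretchesAsData(stretches)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(
      params = stretches@params,
      stretches = lapply(seq_len(nrow(df)), function(i) list(
        start = df$start[i], end = df$end[i], residues = df$residues[i],
        partners = stretches@partners[[i]]))),
      path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
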