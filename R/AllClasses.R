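#' @importClassesFrom IRanges IRanges
#' @importClassesFrom S4Vectors DataFrame
NULL

#' StructureModel: protein chains of a complex structure
#'
#' Holds the polymer protein atoms of one model of a PDB/mmCIF entry after
#' filtering (waters, ions, glycans and other hetero groups removed, one
#' conformer per atom). Atoms carry coordinates in Angstrom and a van der
#' Waals radius assigned from a fixed element table.
#'
#' @slot sourceId character, e.g. a PDB accession or file name.
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid} (3-letter residue name), \code{elety} (atom
#'   name), \code{element}, \code{x}, \code{y}, \code{z}, \code{radius}.
#' @exportClass StructureModel
setClass("StructureModel",
  slots = c(sourceId = "character", atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z", "radius")
  if (!all(need %in% names(a)))
    return(paste("atoms lacks column(s):",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0L) return("model has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(a$radius <= 0)) return("non-positive atom radius")
  TRUE
})

#' ChainPartition: antigen vs partner chain assignment
#'
#' @slot targetChains chain ids of the donor antigen.
#' @slot partnerChains chain ids of the binding partner (receptor or
#'   antibody); disjoint from \code{targetChains}.
#' @exportClass ChainPartition
setClass("ChainPartition",
  slots = c(targetChains = "character", partnerChains = "character"))

setValidity("ChainPartition", function(object) {
  if (!length(object@targetChains)) return("no target chains")
  if (!length(object@partnerChains)) return("no partner chains")
  if (length(intersect(object@targetChains, object@partnerChains)))
    return("target and partner chains overlap")
  TRUE
})

#' FootprintProfile: per-residue buried surface area against each partner
#'
#' BSA(residue, partner) = sum over the residue's atoms of
#' SASA(target chains alone) - SASA(full complex), clamped at zero.
#' Positions are 1-based donor sequence positions obtained by aligning each
#' structure chain to the donor sequence; donor positions never modeled in a
#' structure carry BSA 0 and are listed in \code{unmodeled}.
#'
#' @slot bsa data.frame with columns \code{donor_pos}, \code{residue}
#'   (1-letter donor residue), \code{partner_id}, \code{bsa_A2}.
#' @slot partnerIds character, the partner complex ids covered.
#' @slot donorLength integer, length of the donor sequence.
#' @slot unmodeled named list: partner id -> integer donor positions not
#'   resolved in that structure.
#' @exportClass FootprintProfile
setClass("FootprintProfile",
  slots = c(bsa = "data.frame", partnerIds = "character",
            donorLength = "integer", unmodeled = "list"))

setValidity("FootprintProfile", function(object) {
  b <- object@bsa
  need <- c("donor_pos", "residue", "partner_id", "bsa_A2")
  if (!all(need %in% names(b)))
    return("bsa table lacks required columns")
  if (nrow(b) && any(b$bsa_A2 < 0)) return("negative BSA (must be clamped)")
  if (nrow(b) && !all(b$partner_id %in% object@partnerIds))
    return("bsa table references unknown partner ids")
  TRUE
})

#' EpitopeStretches: contiguous donor stretches selected for transplantation
#'
#' Maximal runs of donor positions contacted by at least \code{minPartners}
#' partners, with gaps up to \code{gapMerge} non-critical residues bridged.
#' Stretches are disjoint and sorted by start.
#'
#' @slot ranges IRanges over 1-based donor positions (inclusive ends).
#' @slot partners CharacterList, partners supporting each stretch.
#' @slot residues character, donor residues over each stretch (may be empty
#'   strings when no donor sequence was supplied).
#' @slot params list echoing \code{minPartners}, \code{gapMerge}.
#' @exportClass EpitopeStretches
setClass("EpitopeStretches",
  slots = c(ranges = "IRanges", partners = "list", residues = "character",
            params = "list"))

setValidity("EpitopeStretches", function(object) {
  r <- object@ranges
  n <- length(r)
  if (length(object@partners) != n || length(object@residues) != n)
    return("slot lengths disagree")
  if (n > 1L) {
    s <- IRanges::start(r); e <- IRanges::end(r)
    if (is.unsorted(s, strictly = TRUE)) return("stretches not sorted")
    if (any(s[-1L] <= e[-n])) return("stretches overlap")
  }
  TRUE
})

#' KmerIndex: exact k-mer index over a reference proteome
#'
#' Maps every length-k window (free of \code{X}) of every proteome record to
#' its source proteins and 1-based start positions. Used to detect query
#' windows identical to a reference ("self") peptide.
#'
#' @slot k integer window length (default 9).
#' @slot map environment hashing window string -> data.frame(id, start).
#' @slot nWindows integer, number of window occurrences indexed.
#' @slot nProteins integer, number of proteome records.
#' @slot proteomeDigest character, md5 digest of the proteome content,
#'   recorded in every report (the reference release is an input, not a
#'   constant).
#' @exportClass KmerIndex
setClass("KmerIndex",
  slots = c(k = "integer", map = "environment", nWindows = "integer",
            nProteins = "integer", proteomeDigest = "character"))

#' HumannessReport: exact-match report of a query against a KmerIndex
#'
#' @slot queryId character.
#' @slot k integer.
#' @slot nWindows integer, number of k-windows in the query.
#' @slot matches data.frame with columns \code{query_start}, \code{window},
#'   \code{protein_id}, \code{protein_start}, sorted by \code{query_start};
#'   one row per (matched window, source occurrence).
#' @slot proteomeDigest character, digest of the index's proteome.
#' @exportClass HumannessReport
setClass("HumannessReport",
  slots = c(queryId = "character", k = "integer", nWindows = "integer",
            matches = "data.frame", proteomeDigest = "character"))

setValidity("HumannessReport", function(object) {
  m <- object@matches
  need <- c("query_start", "window", "protein_id", "protein_start")
  if (!all(need %in% names(m))) return("matches lacks required columns")
  if (nrow(m) && is.unsorted(m$query_start)) return("matches not sorted")
  if (length(unique(m$query_start)) > object@nWindows)
    return("more matched windows than query windows")
  TRUE
})

#' GraftAlignment: gapped donor/scaffold correspondence
#'
#' A global pairwise alignment between the donor antigen and the scaffold
#' homolog, with a per-column position map used to transplant stretches.
#'
#' @slot alignedDonor,alignedScaffold equal-length gapped strings.
#' @slot columnMap data.frame with columns \code{column}, \code{donor_pos},
#'   \code{scaffold_pos} (NA at a gap).
#' @slot score numeric alignment score.
#' @exportClass GraftAlignment
setClass("GraftAlignment",
  slots = c(alignedDonor = "character", alignedScaffold = "character",
            columnMap = "data.frame", score = "numeric"))

setValidity("GraftAlignment", function(object) {
  if (nchar(object@alignedDonor) != nchar(object@alignedScaffold))
    return("aligned strings differ in length")
  cm <- object@columnMap
  if (nrow(cm) != nchar(object@alignedDonor))
    return("column map length mismatch")
  dp <- cm$donor_pos[!is.na(cm$donor_pos)]
  sp <- cm$scaffold_pos[!is.na(cm$scaffold_pos)]
  if (is.unsorted(dp, strictly = TRUE) || is.unsorted(sp, strictly = TRUE))
    return("positions not strictly increasing")
  TRUE
})

#' GraftPlan: record of an epitope transplantation
#'
#' @slot stretches the EpitopeStretches transplanted.
#' @slot transplantedPositions integer, 1-based positions in the grafted
#'   sequence carrying donor epitope residues.
#' @slot transplantedResidues character vector, the donor residues expected
#'   at those positions (epitope-integrity reference).
#' @slot substitutions data.frame(scaffold_pos, from, to).
#' @slot insertions data.frame(grafted_pos, residue) scaffold-gap columns
#'   inside a stretch.
#' @slot deletions data.frame(scaffold_pos, residue) scaffold residues
#'   dropped at donor-gap columns inside a stretch.
#' @slot positionMap data.frame(grafted_pos, scaffold_pos, origin) mapping
#'   every grafted position back to the scaffold (NA scaffold_pos for
#'   insertions, which inherit the nearest scaffold column downstream uses).
#' @slot graftedLength integer.
#' @exportClass GraftPlan
setClass("GraftPlan",
  slots = c(stretches = "EpitopeStretches",
            transplantedPositions = "integer",
            transplantedResidues = "character",
            substitutions = "data.frame", insertions = "data.frame",
            deletions = "data.frame", positionMap = "data.frame",
            graftedLength = "integer"))

setValidity("GraftPlan", function(object) {
  if (length(object@transplantedPositions) !=
      length(object@transplantedResidues))
    return("transplanted positions/residues length mismatch")
  if (any(object@transplantedPositions > object@graftedLength))
    return("transplanted position beyond grafted sequence")
  TRUE
})

#' SubstitutionPool: allowed replacements per position
#'
#' For each sequence position, the amino acids observed at least
#' \code{minCount} times in the corresponding species-alignment column,
#' excluding gaps, \code{X}, and the current residue; weights are the
#' observed counts.
#'
#' @slot pools named list: position (as character) -> named numeric vector of
#'   replacement weights.
#' @slot inherited integer, positions whose pool was inherited from the
#'   nearest scaffold column (graft insertions), flagged in reports.
#' @slot params list echoing \code{minCount}.
#' @exportClass SubstitutionPool
setClass("SubstitutionPool",
  slots = c(pools = "list", inherited = "integer", params = "list"))

setValidity("SubstitutionPool", function(object) {
  for (p in object@pools) {
    if (length(p) && (is.null(names(p)) || any(p <= 0)))
      return("pool weights must be named and positive")
  }
  TRUE
})

#' DesignCandidate: a (possibly mutated) grafted sequence with its audit
#'
#' @slot sequence character, the final amino-acid sequence.
#' @slot mutations data.frame(position, from, to, windows_destroyed),
#'   in application order.
#' @slot humanness HumannessReport of \code{sequence} (full rescan).
#' @slot epitopeIntact logical: the sequence restricted to the transplanted
#'   positions equals the donor stretch residues.
#' @slot status one of \code{clean}, \code{infeasible},
#'   \code{budget_exhausted}.
#' @slot offending data.frame of matched windows that could not be destroyed
#'   (non-empty only for status \code{infeasible}).
#' @exportClass DesignCandidate
setClass("DesignCandidate",
  slots = c(sequence = "character", mutations = "data.frame",
            humanness = "HumannessReport", epitopeIntact = "logical",
            status = "character", offending = "data.frame"))

setValidity("DesignCandidate", function(object) {
  if (!object@status %in% c("clean", "infeasible", "budget_exhausted"))
    return("invalid status")
  if (object@status == "clean" && nrow(object@humanness@matches) > 0L)
    return("clean candidate with residual matches")
  TRUE
})
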