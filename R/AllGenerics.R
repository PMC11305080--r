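#' Accessors
#'
#' Small accessor generics for the package's S4 classes, so code never
#' reaches into slots directly.
#'
#' @param x an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setMethod("chainIds", "StructureModel", function(x) unique(x@atoms$chain))

#' @rdname accessors
#' @export
setGeneric("bsaTable", function(x) standardGeneric("bsaTable"))
#' @rdname accessors
#' @export
setMethod("bsaTable", "FootprintProfile", function(x) x@bsa)

#' @rdname accessors
#' @export
setGeneric("partnerIds", function(x) standardGeneric("partnerIds"))
#' @rdname accessors
#' @export
setMethod("partnerIds", "FootprintProfile", function(x) x@partnerIds)

#' @rdname accessors
#' @export
setGeneric("stretchRanges", function(x) standardGeneric("stretchRanges"))
#' @rdname accessors
#' @export
setMethod("stretchRanges", "EpitopeStretches", function(x) x@ranges)

#' @rdname accessors
#' @export
setGeneric("stretchPartners", function(x) standardGeneric("stretchPartners"))
#' @rdname accessors
#' @export
setMethod("stretchPartners", "EpitopeStretches", function(x) x@partners)

#' @rdname accessors
#' @export
setGeneric("stretchResidues", function(x) standardGeneric("stretchResidues"))
#' @rdname accessors
#' @export
setMethod("stretchResidues", "EpitopeStretches", function(x) x@residues)

#' @rdname accessors
#' @export
setMethod("length", "EpitopeStretches", function(x) length(x@ranges))

#' @rdname accessors
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))
#' @rdname accessors
#' @export
setMethod("kmerSize", "KmerIndex", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("kmerSize", "HumannessReport", function(x) x@k)

#' @rdname accessors
#' @export
setGeneric("matchTable", function(x) standardGeneric("matchTable"))
#' @rdname accessors
#' @export
setMethod("matchTable", "HumannessReport", function(x) x@matches)

#' @rdname accessors
#' @export
setGeneric("nMatchedWindows", function(x) standardGeneric("nMatchedWindows"))
#' @rdname accessors
#' @export
setMethod("nMatchedWindows", "HumannessReport",
          function(x) length(unique(x@matches$query_start)))

#' @rdname accessors
#' @export
setGeneric("distinctProteinsHit",
           function(x) standardGeneric("distinctProteinsHit"))
#' @rdname accessors
#' @export
setMethod("distinctProteinsHit", "HumannessReport",
          function(x) length(unique(x@matches$protein_id)))

#' @rdname accessors
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))
#' @rdname accessors
#' @export
setMethod("columnMap", "GraftAlignment", function(x) x@columnMap)

#' @rdname accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname accessors
#' @export
setMethod("alignmentScore", "GraftAlignment", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("transplantedPositions",
           function(x) standardGeneric("transplantedPositions"))
#' @rdname accessors
#' @export
setMethod("transplantedPositions", "GraftPlan",
          function(x) x@transplantedPositions)

#' @rdname accessors
#' @export
setGeneric("positionPools", function(x) standardGeneric("positionPools"))
#' @rdname accessors
#' @export
setMethod("positionPools", "SubstitutionPool", function(x) x@pools)

#' @rdname accessors
#' @export
setGeneric("candidateSequence",
           function(x) standardGeneric("candidateSequence"))
#' @rdname accessors
#' @export
setMethod("candidateSequence", "DesignCandidate", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("mutationTable", function(x) standardGeneric("mutationTable"))
#' @rdname accessors
#' @export
setMethod("mutationTable", "DesignCandidate", function(x) x@mutations)

#' @rdname accessors
#' @export
setGeneric("designStatus", function(x) standardGeneric("designStatus"))
#' @rdname accessors
#' @export
setMethod("designStatus", "DesignCandidate", function(x) x@status)

#' @rdname accessors
#' @export
setGeneric("epitopeIntact", function(x) standardGeneric("epitopeIntact"))
#' @rdname accessors
#' @export
setMethod("epitopeIntact", "DesignCandidate", function(x) x@epitopeIntact)

#' @rdname accessors
#' @export
setGeneric("humanness", function(x) standardGeneric("humanness"))
#' @rdname accessors
#' @export
setMethod("humanness", "DesignCandidate", function(x) x@humanness)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  res <- unique(a[c("chain", "resno", "insert")])
  cat("StructureModel '", object@sourceId, "': ",
      length(unique(a$chain)), " chain(s), ", nrow(res), " residues, ",
      nrow(a), " atoms\n", sep = "")
  for (ch in unique(a$chain))
    cat("  chain ", ch, ": ",
        sum(!duplicated(a[a$chain == ch, c("resno", "insert")])),
        " residues\n", sep = "")
})

setMethod("show", "ChainPartition", function(object) {
  cat("ChainPartition: target {",
      paste(object@targetChains, collapse = ","), "} vs partner {",
      paste(object@partnerChains, collapse = ","), "}\n", sep = "")
})

setMethod("show", "FootprintProfile", function(object) {
  b <- object@bsa
  cat("FootprintProfile: donor length ", object@donorLength, ", ",
      length(object@partnerIds), " partner(s)\n", sep = "")
  for (p in object@partnerIds) {
    bp <- b[b$partner_id == p, ]
    cat(sprintf("  %s: %d residues with BSA > 0 (total %.1f A^2)\n",
                p, sum(bp$bsa_A2 > 0), sum(bp$bsa_A2)))
  }
})

setMethod("show", "EpitopeStretches", function(object) {
  n <- length(object@ranges)
  cat("EpitopeStretches: ", n, " stretch(es)",
      " (minPartners=", object@params$minPartners,
      ", gapMerge=", object@params$gapMerge, ")\n", sep = "")
  if (n) {
    s <- IRanges::start(object@ranges); e <- IRanges::end(object@ranges)
    for (i in seq_len(n))
      cat(sprintf("  [%d, %d] %s  partners: %s\n", s[i], e[i],
                  object@residues[i],
                  paste(object@partners[[i]], collapse = ",")))
  }
})

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex: k=", object@k, ", ", length(ls(object@map)),
      " distinct windows from ", object@nWindows, " occurrences over ",
      object@nProteins, " proteins\n  proteome md5 ", object@proteomeDigest,
      "\n", sep = "")
})

setMethod("show", "HumannessReport", function(object) {
  cat("HumannessReport for '", object@queryId, "': ",
      nMatchedWindows(object), "/", object@nWindows, " windows match (k=",
      object@k, "), ", distinctProteinsHit(object),
      " distinct protein(s) hit\n", sep = "")
})

setMethod("show", "GraftAlignment", function(object) {
  cat("GraftAlignment: ", nrow(object@columnMap), " columns, score ",
      object@score, "\n", sep = "")
})

setMethod("show", "GraftPlan", function(object) {
  cat("GraftPlan: ", length(object@stretches@ranges), " stretch(es), ",
      length(object@transplantedPositions), " transplanted positions (",
      nrow(object@substitutions), " substitutions, ",
      nrow(object@insertions), " insertions, ",
      nrow(object@deletions), " deletions)\n", sep = "")
})

setMethod("show", "SubstitutionPool", function(object) {
  nonEmpty <- sum(vapply(object@pools, length, 1L) > 0L)
  cat("SubstitutionPool: ", length(object@pools), " positions (",
      nonEmpty, " with allowed replacements; minCount=",
      object@params$minCount, ")\n", sep = "")
})

setMethod("show", "DesignCandidate", function(object) {
  cat("DesignCandidate: status '", object@status, "', ",
      nrow(object@mutations), " mutation(s), ",
      nMatchedWindows(object@humanness), " residual self-window(s), ",
      "epitope ", if (object@epitopeIntact) "intact" else "BROKEN",
      "\n", sep = "")
})
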