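#' Eliminate reference-proteome k-mers by constrained greedy point mutation
#'
#' Greedy deimmunization loop: rescan the sequence against the k-mer index;
#' among all (mutable position, pooled replacement) moves that do not create
#' any new indexed window, apply the one destroying the most currently
#' matched windows; repeat. Ties are broken deterministically by higher pool
#' weight of the replacement, then lower position, then alphabetical
#' replacement. The loop stops with status \code{clean} (no matches left),
#' \code{infeasible} (some matched window admits no legal destroying
#' mutation), or \code{budget_exhausted}; failure is a status, never an
#' exception. Immutable positions (the transplanted epitope and any
#' user-locked sites) are never touched. The final sequence is re-verified
#' by a full rescan.
#'
#' @param seq the sequence to deimmunize.
#' @param index a \linkS4class{KmerIndex} over the reference proteome.
#' @param pool a \linkS4class{SubstitutionPool}; positions without a pool
#'   entry are effectively immutable.
#' @param immutable integer positions that must not be mutated.
#' @param maxMutations mutation budget (default 50).
#' @param plan optional \linkS4class{GraftPlan}; when given, the epitope
#'   integrity flag is computed against its transplanted residues.
#' @param queryId id recorded in the embedded humanness report.
#' @return a \linkS4class{DesignCandidate}.
#' @export
dehumanize <- function(seq, index, pool, immutable = integer(0),
                       maxMutations = 50L, plan = NULL, queryId = "design") {
  seq <- normalizeSequence(seq, what = "sequence")
  k <- index@k
  chars <- seqChars(seq)
  len <- length(chars)
  if (any(immutable < 1L | immutable > len))
    stop("immutable positions outside the sequence")
  immutable <- as.integer(immutable)
  mutations <- data.frame(position = integer(0), from = character(0),
                          to = character(0), windows_destroyed = integer(0),
                          destroyed = character(0), stringsAsFactors = FALSE)
  status <- NULL
  offending <- emptyMatches()
  repeat {
    current <- paste(chars, collapse = "")
    report <- scanSequence(current, index, queryId = queryId)
    mstarts <- sort(unique(report@matches$query_start))
    if (!length(mstarts)) { status <- "clean"; break }
    if (nrow(mutations) >= maxMutations) {
      status <- "budget_exhausted"; break
    }
    covered <- sort(unique(unlist(lapply(mstarts, function(s)
      s:(s + k - 1L)))))
    candidates <- setdiff(covered, immutable)
    best <- NULL
    for (p in candidates) {
      pp <- pool@pools[[as.character(p)]]
      if (!length(pp)) next
      covering <- mstarts[p >= mstarts & p <= mstarts + k - 1L]
      nd <- length(covering)
      for (aa in sort(names(pp))) {
        if (aa == chars[p]) next
        newChars <- chars
        newChars[p] <- aa
        ws <- max(1L, p - k + 1L):min(len - k + 1L, p)
        if (length(ws) < 1L || ws[1] > ws[length(ws)]) ws <- integer(0)
        newWins <- vapply(ws, function(s)
          paste(newChars[s:(s + k - 1L)], collapse = ""), "")
        newWins <- newWins[!grepl("X", newWins, fixed = TRUE)]
        if (length(newWins) && any(hasWindow(index, newWins))) next
        w <- pp[[aa]]
        if (is.null(best) || nd > best$nd ||
            (nd == best$nd && w > best$w)) {
          best <- list(p = p, aa = aa, nd = nd, w = w, covering = covering)
        }
      }
    }
    if (is.null(best)) {
      status <- "infeasible"
      offending <- report@matches
      break
    }
    destroyedWins <- vapply(best$covering, function(s)
      paste0(s, ":", paste(chars[s:(s + k - 1L)], collapse = "")), "")
    mutations <- rbind(mutations, data.frame(
      position = best$p, from = chars[best$p], to = best$aa,
      windows_destroyed = best$nd,
      destroyed = paste(destroyedWins, collapse = ","),
      stringsAsFactors = FALSE))
    chars[best$p] <- best$aa
  }
  finalSeq <- paste(chars, collapse = "")
  finalReport <- scanSequence(finalSeq, index, queryId = queryId)
  intact <- if (is.null(plan)) NA else
    identical(chars[plan@transplantedPositions], plan@transplantedResidues)
  new("DesignCandidate", sequence = finalSeq, mutations = mutations,
      humanness = finalReport, epitopeIntact = intact, status = status,
      offending = offending)
}

#' Parse mutation strings like "K21Q"
#'
#' @param x character vector, each element \code{<from><1-based
#'   position><to>}.
#' @return data.frame(position, from, to).
#' @examples
#' parseMutations(c("K21Q", "R218E"))
#' @export
parseMutations <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("cannot parse mutation(s): ",
                     paste(x[bad], collapse = ", "))
  data.frame(position = as.integer(vapply(m, `[`, "", 3L)),
             from = toupper(vapply(m, `[`, "", 2L)),
             to = toupper(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Apply named point variants to a sequence
#'
#' Applies substitutions such as liability-removing variants (e.g. cleavage
#' site removal K21Q, R218E), guarding against numbering-convention mistakes:
#' each variant's from-residue must match the sequence at its position.
#'
#' @param seq a sequence.
#' @param variants a data.frame(position, from, to) or character vector of
#'   mutation strings (see \code{\link{parseMutations}}).
#' @return the mutated sequence (same length).
#' @examples
#' applyVariants("AKCD", "K2Q")
#' @export
applyVariants <- function(seq, variants) {
  seq <- normalizeSequence(seq, what = "sequence")
  if (is.character(variants)) variants <- parseMutations(variants)
  if (nrow(variants) == 0L) return(seq)
  chars <- seqChars(seq)
  for (i in seq_len(nrow(variants))) {
    p <- variants$position[i]
    if (p < 1L || p > length(chars))
      stop("variant position ", p, " outside the sequence")
    if (chars[p] != variants$from[i])
      stop("from-residue mismatch at position ", p, ": sequence has ",
           chars[p], ", variant expects ", variants$from[i])
    if (variants$from[i] == variants$to[i])
      stop("variant at position ", p, " does not change the residue")
    chars[p] <- variants$to[i]
  }
  paste(chars, collapse = "")
}

#' Evaluate a design candidate
#'
#' Recomputes the computable acceptance checks of a design: residual
#' reference-proteome matches (fresh rescan), epitope integrity against the
#' graft plan, mutation count, and per-mutation provenance (which matched
#' windows each mutation destroyed).
#'
#' @param candidate a \linkS4class{DesignCandidate}.
#' @param index the \linkS4class{KmerIndex} used for the design.
#' @param plan the \linkS4class{GraftPlan} of the transplant.
#' @param donor optional donor sequence; when given, the plan's transplanted
#'   residues are cross-checked against the donor stretches.
#' @return a list report (n_matches, epitope_intact, n_mutations, status,
#'   mutations, proteome_md5).
#' @export
evaluateDesign <- function(candidate, index, plan, donor = NULL) {
  rescan <- scanSequence(candidate@sequence, index,
                         queryId = candidate@humanness@queryId)
  chars <- seqChars(candidate@sequence)
  intact <- identical(chars[plan@transplantedPositions],
                      plan@transplantedResidues)
  if (!is.null(donor)) {
    donor <- normalizeSequence(donor, what = "donor")
    r <- plan@stretches@ranges
    want <- unlist(lapply(seq_along(r), function(i)
      seqChars(substr(donor, IRanges::start(r)[i], IRanges::end(r)[i]))))
    if (!identical(plan@transplantedResidues, want))
      warning("graft plan residues disagree with the donor stretches")
  }
  list(status = candidate@status,
       n_matches = nMatchedWindows(rescan),
       epitope_intact = intact,
       n_mutations = nrow(candidate@mutations),
       mutations = candidate@mutations,
       proteome_md5 = index@proteomeDigest)
}

#' Write the mutation table as TSV
#'
#' Columns: position, from, to, windows_destroyed, destroyed (the
#' "start:window" list each mutation eliminated).
#'
#' @param candidate a DesignCandidate.
#' @param path output path.
#' @export
writeMutationsTsv <- function(candidate, path) {
  utils::write.table(candidate@mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
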