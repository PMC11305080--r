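## Repeating 20-letter pattern used for deterministic toy chain sequences.
cycledSequence <- function(n) {
  paste(rep_len(AA_STANDARD, n), collapse = "")
}

#' Generate a seeded decoy proteome
#'
#' Uniform random sequences over a chosen alphabet; deterministic for a
#' fixed seed (the caller's RNG stream is untouched).
#'
#' @param nProteins number of records (>= 1).
#' @param lengthRange integer (min, max) record length.
#' @param alphabet amino-acid subset (default the 20 standard residues).
#' @param seed integer seed.
#' @return named character vector of sequences (ids P001, P002, ...).
#' @export
generateProteome <- function(nProteins, lengthRange = c(50L, 200L),
                             alphabet = AA_STANDARD, seed = 1L) {
  stopifnot(nProteins >= 1L, lengthRange[1] >= 1L,
            lengthRange[2] >= lengthRange[1])
  if (!length(alphabet)) stop("empty alphabet")
  withSeed(seed, {
    lens <- lengthRange[1] +
      sample.int(lengthRange[2] - lengthRange[1] + 1L, nProteins,
                 replace = TRUE) - 1L
    setNames(vapply(lens, function(L)
      paste(sample(alphabet, L, replace = TRUE), collapse = ""), ""),
      sprintf("P%03d", seq_len(nProteins)))
  })
}

#' Plant query windows into a decoy proteome
#'
#' Copies chosen k-windows of the query into chosen proteome records, so the
#' query acquires known shared windows ("self" peptides) with recorded
#' ground truth. Plants that write conflicting residues to the same proteome
#' position are an error.
#'
#' @param query the query sequence.
#' @param proteome named character vector of records.
#' @param plantSpec data.frame(query_pos, protein, protein_pos), all 1-based.
#' @param k window length.
#' @return list with \code{proteome} (modified records) and \code{planted}
#'   (data.frame query_start, window, protein_id, protein_start).
#' @export
plantSharedWindows <- function(query, proteome, plantSpec, k = 9L) {
  query <- normalizeSequence(query, what = "query")
  if (nrow(plantSpec) == 0L)
    return(list(proteome = proteome,
                planted = data.frame(query_start = integer(0),
                                     window = character(0),
                                     protein_id = character(0),
                                     protein_start = integer(0))))
  written <- list()  # per protein: named char vector pos -> residue
  out <- proteome
  planted <- NULL
  for (i in seq_len(nrow(plantSpec))) {
    qp <- plantSpec$query_pos[i]
    pid <- as.character(plantSpec$protein[i])
    tp <- plantSpec$protein_pos[i]
    if (qp < 1L || qp + k - 1L > nchar(query))
      stop("query window at ", qp, " does not fit the query")
    if (!pid %in% names(out)) stop("unknown protein: ", pid)
    if (tp < 1L || tp + k - 1L > nchar(out[[pid]]))
      stop("window does not fit protein ", pid, " at ", tp)
    win <- substr(query, qp, qp + k - 1L)
    wchars <- seqChars(win)
    prev <- written[[pid]]
    for (j in seq_len(k)) {
      key <- as.character(tp + j - 1L)
      if (!is.null(prev) && key %in% names(prev) &&
          prev[[key]] != wchars[j])
        stop("contradictory plants overlap in protein ", pid,
             " at position ", key)
      prev[key] <- wchars[j]
    }
    written[[pid]] <- prev
    substr(out[[pid]], tp, tp + k - 1L) <- win
    planted <- rbind(planted, data.frame(
      query_start = qp, window = win, protein_id = pid, protein_start = tp,
      stringsAsFactors = FALSE))
  }
  list(proteome = out, planted = planted)
}

#' Generate a toy two-chain complex with a controllable interface
#'
#' Builds single-sphere residues (radius 1.9 Angstrom, carbon-like) on
#' straight backbones at 3.8 Angstrom spacing. The target chain A lies along
#' x; each contact span gets a partner chain placed at
#' \code{interChainDistance} from the span's residues. Partner spheres at a
#' span edge lean inward just enough that every target residue outside the
#' span stays beyond the occlusion horizon \code{2*(radius + probeRadius)}
#' (with a 0.1 Angstrom margin) from every partner atom, so its buried
#' surface area is exactly zero. Expected contacts are the span positions
#' when \code{interChainDistance} is below the horizon, and empty otherwise.
#'
#' Combinations that cannot satisfy both constraints (e.g. a very small
#' distance, or a one-residue span with neighbours on both sides) raise a
#' "geometrically impossible" error.
#'
#' @param nTarget number of target-chain residues.
#' @param nPartner partner residues per span; in the contact regime this
#'   must equal the span length (the impossible cases error out).
#' @param interChainDistance target-to-partner sphere-centre distance in
#'   Angstrom.
#' @param contactSpan integer (start, end) on the target chain, or a list of
#'   such spans (one partner chain each).
#' @param seed integer; only consumed by \code{jitter}.
#' @param jitter sd of Gaussian coordinate noise (default 0: geometry is
#'   seed-independent).
#' @param radius sphere radius (default 1.9).
#' @param probeRadius probe radius defining the occlusion horizon.
#' @param targetSeq optional target-chain sequence (defaults to a cycled
#'   20-letter pattern).
#' @return list(model, partition, expectedContacts, params).
#' @export
generateToyComplex <- function(nTarget, nPartner = NULL,
                               interChainDistance = 3.3,
                               contactSpan = c(5L, 8L), seed = 1L,
                               jitter = 0, radius = 1.9, probeRadius = 1.4,
                               targetSeq = NULL) {
  spans <- if (is.list(contactSpan)) contactSpan else list(contactSpan)
  spans <- lapply(spans, as.integer)
  ord <- order(vapply(spans, `[`, 1L, 1L))
  spans <- spans[ord]
  for (s in spans)
    if (s[1] < 1L || s[2] > nTarget || s[1] > s[2])
      stop("contact span outside the target chain")
  if (length(spans) > 1L) {
    e <- vapply(spans, `[`, 1L, 2L)[-length(spans)]
    s2 <- vapply(spans, `[`, 1L, 1L)[-1L]
    if (any(s2 <= e)) stop("contact spans overlap")
  }
  spacing <- 3.8
  R <- radius + probeRadius
  horizon <- 2 * R
  margin <- 0.1
  d <- interChainDistance
  if (is.null(targetSeq)) targetSeq <- cycledSequence(nTarget)
  targetSeq <- normalizeSequence(targetSeq, what = "targetSeq")
  if (nchar(targetSeq) != nTarget) stop("targetSeq length != nTarget")
  tAA <- seqChars(targetSeq)
  contact <- d < horizon
  mkRes <- function(chain, idx, aa, x, y, z) data.frame(
    chain = chain, resno = idx, insert = "", resid = bio3d::aa123(aa),
    elety = "CA", element = "C", x = x, y = y, z = z, radius = radius,
    stringsAsFactors = FALSE)
  atoms <- mkRes("A", seq_len(nTarget), tAA, (seq_len(nTarget) - 1) * spacing,
                 0, 0)
  partnerChains <- character(0)
  expected <- integer(0)
  nPartnerVec <- if (is.null(nPartner))
    vapply(spans, function(s) s[2] - s[1] + 1L, 1L)
  else rep_len(as.integer(nPartner), length(spans))
  for (si in seq_along(spans)) {
    sp <- spans[[si]]
    m <- sp[2] - sp[1] + 1L
    chain <- LETTERS[si + 1L]
    partnerChains <- c(partnerChains, chain)
    np <- nPartnerVec[si]
    if (!contact) {
      ## out of reach: a plain parallel chain of np residues
      x <- (sp[1] - 1 + seq_len(np) - 1) * spacing
      atoms <- rbind(atoms, mkRes(chain, seq_len(np), rep("G", np), x, d, 0))
      next
    }
    if (np != m)
      stop("geometrically impossible parameters: in the contact regime the ",
           "partner chain must have exactly one residue per span position ",
           "(need ", m, ", got ", np, ")")
    ## inward lean for span-edge residues with an outside neighbour
    aLean <- ((horizon + margin)^2 - d^2 - spacing^2) / (2 * spacing)
    aLean <- max(0, aLean)
    if (aLean > d)
      stop("geometrically impossible parameters: distance ", d,
           " too small to keep residues next to the span buried-area free")
    x <- (sp[1] - 1 + seq_len(m) - 1) * spacing
    y <- rep(d, m)
    leanY <- sqrt(d^2 - aLean^2)
    needLeft <- sp[1] > 1L
    needRight <- sp[2] < nTarget
    if (m == 1L && needLeft && needRight && aLean > 0)
      stop("geometrically impossible parameters: a single-residue span ",
           "with neighbours on both sides cannot be isolated at distance ", d)
    if (needLeft && aLean > 0) { x[1] <- x[1] + aLean; y[1] <- leanY }
    if (needRight && aLean > 0) { x[m] <- x[m] - aLean; y[m] <- leanY }
    atoms <- rbind(atoms, mkRes(chain, seq_len(m), rep("G", m), x, y, 0))
    expected <- c(expected, sp[1]:sp[2])
  }
  if (jitter > 0) {
    noise <- withSeed(seed, matrix(stats::rnorm(3 * nrow(atoms), 0, jitter),
                                   ncol = 3))
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }
  list(model = structureModel(atoms, sourceId = "toy_complex"),
       partition = chainPartition("A", partnerChains),
       expectedContacts = sort(unique(expected)),
       params = list(nTarget = nTarget, spans = spans, d = d, seed = seed,
                     jitter = jitter, radius = radius,
                     probeRadius = probeRadius, targetSeq = targetSeq))
}

#' Generate a species-variant alignment by per-column substitution
#'
#' Each variant row mutates every column independently with probability
#' \code{subRate} to a uniformly chosen different residue (no indels, so
#' alignment columns coincide with base positions). Per-column residue
#' counts over all rows (base included) are returned as ground truth.
#'
#' @param base the base (scaffold) sequence; emitted as row \code{base}.
#' @param nSequences number of variant rows.
#' @param subRate per-column substitution probability in [0, 1].
#' @param seed integer seed.
#' @param alphabet residues to draw substitutions from.
#' @return list(msa = named character vector (base first), truth = residue
#'   x position count matrix).
#' @export
generateSpeciesMsa <- function(base, nSequences, subRate, seed = 1L,
                               alphabet = AA_STANDARD) {
  stopifnot(subRate >= 0, subRate <= 1, nSequences >= 1L)
  base <- normalizeSequence(base, what = "base")
  L <- nchar(base)
  bchars <- seqChars(base)
  rows <- withSeed(seed, {
    lapply(seq_len(nSequences), function(i) {
      hit <- stats::runif(L) < subRate
      out <- bchars
      for (j in which(hit)) {
        choices <- setdiff(alphabet, out[j])
        out[j] <- choices[sample.int(length(choices), 1L)]
      }
      out
    })
  })
  msa <- c(base = base,
           setNames(vapply(rows, paste, "", collapse = ""),
                    paste0("var", seq_len(nSequences))))
  mat <- rbind(bchars, do.call(rbind, rows))
  truth <- vapply(seq_len(L), function(j)
    table(factor(mat[, j], levels = AA_STANDARD)), integer(20L))
  dimnames(truth) <- list(AA_STANDARD, NULL)
  list(msa = msa, truth = truth)
}

#' Assemble a complete seeded pipeline fixture
#'
#' Bundles everything one end-to-end design run needs, with recorded ground
#' truth: a 20-residue toy donor chain bound by two partner complexes (each
#' contacting spans 5-8 and 12-14 through two partner chains), a divergent
#' scaffold, a species-variant alignment of the scaffold, and a decoy
#' proteome with two query windows of the grafted sequence planted into it
#' (at grafted positions 1 and 11). The alignment is adjusted, if necessary,
#' so every planted window overlaps at least one mutable position with a
#' non-empty substitution pool, keeping the deimmunization stage feasible by
#' construction; the returned column counts reflect the adjustment.
#'
#' @param seed integer master seed; sub-generators consume derived seeds
#'   (seed, seed+1, seed+2) in a fixed documented order.
#' @param nTarget donor length (default 20).
#' @param spans list of contact spans (default list(c(5,8), c(12,14))).
#' @param scaffoldDivergence per-position substitution rate donor ->
#'   scaffold (default 0.3).
#' @param msaRows,msaSubRate species-alignment shape (default 8 rows, 0.1).
#' @param nProteins,proteinLengths decoy proteome shape.
#' @param k window length (default 9).
#' @return list with donor, scaffold, msa (+ truth), proteome, planted
#'   ground truth, complexes (named list of model/partition), expected
#'   contacts and stretches, and the parameters used.
#' @export
syntheticFixture <- function(seed = 7L, nTarget = 20L,
                             spans = list(c(5L, 8L), c(12L, 14L)),
                             scaffoldDivergence = 0.3, msaRows = 8L,
                             msaSubRate = 0.1, nProteins = 12L,
                             proteinLengths = c(40L, 80L), k = 9L) {
  donor <- cycledSequence(nTarget)
  ## scaffold: seeded homolog of the donor
  scaffold <- withSeed(seed, {
    ch <- seqChars(donor)
    hit <- stats::runif(nTarget) < scaffoldDivergence
    for (j in which(hit)) {
      choices <- setdiff(AA_STANDARD, ch[j])
      ch[j] <- choices[sample.int(length(choices), 1L)]
    }
    paste(ch, collapse = "")
  })
  complexes <- list(
    P1 = generateToyComplex(nTarget, contactSpan = spans, seed = seed,
                            targetSeq = donor),
    P2 = generateToyComplex(nTarget, contactSpan = spans, seed = seed,
                            targetSeq = donor))
  expectedStretches <- do.call(rbind, lapply(spans, function(s)
    data.frame(start = s[1], end = s[2])))
  ## grafted sequence (donor and scaffold are equal length; the pipeline
  ## recomputes this through the real alignment + transplant path)
  stretches <- selectEpitopeStretches(
    setNames(lapply(c("P1", "P2"), function(p)
      unlist(lapply(spans, function(s) s[1]:s[2]))), c("P1", "P2")),
    minPartners = 2L, gapMerge = 2L, donor = donor)
  aln <- alignDonorScaffold(donor, scaffold)
  graft <- transplantStretches(scaffold, donor, stretches, aln)
  grafted <- graft$sequence
  msa <- generateSpeciesMsa(scaffold, msaRows, msaSubRate, seed = seed + 1L)
  ## guarantee feasibility: each planted window must cover a mutable
  ## position whose alignment column is not fully conserved
  plantAt <- c(1L, min(11L, nchar(grafted) - k + 1L))
  immutable <- graft$plan@transplantedPositions
  msaMat <- asAlignedSet(msa$msa)
  for (qp in plantAt) {
    covered <- setdiff(qp:(qp + k - 1L), immutable)
    covered <- covered[covered <= nchar(scaffold)]
    varied <- vapply(covered, function(p)
      length(unique(msaMat[, p])) > 1L, TRUE)
    if (!any(varied)) {
      p <- covered[1]
      cur <- msaMat[1, p]
      msaMat["var1", p] <- setdiff(AA_STANDARD, cur)[1]
    }
  }
  msa$msa <- setNames(apply(msaMat, 1, paste, collapse = ""),
                      rownames(msaMat))
  msa$truth <- vapply(seq_len(ncol(msaMat)), function(j)
    table(factor(msaMat[, j], levels = AA_STANDARD)), integer(20L))
  dimnames(msa$truth) <- list(AA_STANDARD, NULL)
  proteome <- generateProteome(nProteins, proteinLengths, seed = seed + 2L)
  plantSpec <- data.frame(query_pos = plantAt,
                          protein = names(proteome)[c(1L, 2L)],
                          protein_pos = c(10L, 5L))
  planted <- plantSharedWindows(grafted, proteome, plantSpec, k = k)
  list(seed = seed, donor = donor, scaffold = scaffold, grafted = grafted,
       msa = msa$msa, msaTruth = msa$truth,
       proteome = planted$proteome, planted = planted$planted,
       complexes = complexes,
       expectedContacts = sort(unlist(lapply(spans, function(s) s[1]:s[2]))),
       expectedStretches = expectedStretches,
       stretches = stretches, graftPlan = graft$plan, k = k,
       params = list(nTarget = nTarget, spans = spans,
                     scaffoldDivergence = scaffoldDivergence,
                     msaRows = msaRows, msaSubRate = msaSubRate,
                     nProteins = nProteins, proteinLengths = proteinLengths))
}

#' Write a synthetic fixture to disk as standard formats
#'
#' Emits PDB complexes, FASTA sequences, an aligned FASTA, the ground truth
#' as JSON, and a ready-to-run pipeline configuration, so the fixture also
#' exercises the real file readers.
#'
#' @param fixture result of \code{\link{syntheticFixture}}.
#' @param dir output directory (created if needed).
#' @return path of the written config file.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  for (pid in names(fixture$complexes))
    writeModelPdb(fixture$complexes[[pid]]$model, fp(paste0(pid, ".pdb")))
  writeFastaSequences(c(donor = fixture$donor), fp("donor.fasta"))
  writeFastaSequences(c(scaffold = fixture$scaffold), fp("scaffold.fasta"))
  writeFastaSequences(fixture$proteome, fp("proteome.fasta"))
  writeFastaSequences(fixture$msa, fp("msa.fasta"))
  jsonlite::write_json(list(
    seed = fixture$seed, planted = fixture$planted,
    expected_contacts = fixture$expectedContacts,
    expected_stretches = fixture$expectedStretches,
    grafted = fixture$grafted),
    fp("truth.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cfg <- list(
    seed = fixture$seed, k = fixture$k,
    probe_radius = 1.4, n_points = 960L, bsa_threshold = 1.0,
    min_partners = 2L, gap_merge = 2L,
    alignment = list(matrix = "BLOSUM62", gap_opening = 11,
                     gap_extension = 1),
    min_count = 1L, max_mutations = 50L,
    locked_positions = list(), liability_variants = list(),
    donor = "donor.fasta", scaffold = "scaffold.fasta",
    proteome = "proteome.fasta", msa = "msa.fasta", scaffold_row = "base",
    complexes = setNames(lapply(names(fixture$complexes), function(pid) {
      part <- fixture$complexes[[pid]]$partition
      list(path = paste0(pid, ".pdb"),
           target_chains = as.list(part@targetChains),
           partner_chains = as.list(part@partnerChains))
    }), names(fixture$complexes)),
    out_dir = "out")
  yaml::write_yaml(cfg, fp("config.yaml"))
  fp("config.yaml")
}
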