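## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (hash index, quadrature, greedy loop).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Naive O(n*m) substring scan: every k-window of the query checked against
## every record by fixed-string search. Windows containing X never match.
oracleScan <- function(query, proteome, k = 9L) {
  n <- nchar(query) - k + 1L
  out <- NULL
  if (n < 1L) return(data.frame(query_start = integer(0),
                                protein_id = character(0),
                                protein_start = integer(0)))
  for (s in seq_len(n)) {
    win <- substr(query, s, s + k - 1L)
    if (grepl("X", win, fixed = TRUE)) next
    for (pid in names(proteome)) {
      ## manual fixed-string search so overlapping occurrences are found
      allhits <- integer(0)
      from <- 1L
      repeat {
        h <- regexpr(win, substr(proteome[[pid]], from,
                                 nchar(proteome[[pid]])), fixed = TRUE)
        if (h < 0) break
        allhits <- c(allhits, from + h - 1L)
        from <- from + h
      }
      if (length(allhits))
        out <- rbind(out, data.frame(query_start = s, protein_id = pid,
                                     protein_start = allhits))
    }
  }
  if (is.null(out)) data.frame(query_start = integer(0),
                               protein_id = character(0),
                               protein_start = integer(0)) else out
}

## Closed-form exposed area of a sphere of expanded radius R = r + probe
## occluded by one equal sphere at centre distance d (spherical cap).
capExposedArea <- function(r, probe, d) {
  R <- r + probe
  if (d >= 2 * R) return(4 * pi * R^2)
  h <- R - d / 2
  4 * pi * R^2 - 2 * pi * R * h
}

## Exhaustive affine-gap global alignment score by recursion over tiny
## strings (states: 0 = diagonal, 1 = gap in s2, 2 = gap in s1).
## Gap of length L costs open + extend * L, matching the package convention.
enumAlignScore <- function(s1, s2, mat, open = 11, extend = 1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i > length(a) && j > length(b)) 0
    else {
      best <- -Inf
      if (i <= length(a) && j <= length(b))
        best <- max(best, mat[a[i], b[j]] + rec(i + 1L, j + 1L, 0L))
      if (i <= length(a))  # consume a[i] against a gap in s2
        best <- max(best, -(if (state == 1L) 0 else open) - extend +
                      rec(i + 1L, j, 1L))
      if (j <= length(b))
        best <- max(best, -(if (state == 2L) 0 else open) - extend +
                      rec(i, j + 1L, 2L))
      best
    }
    memo[[key]] <- res
    res
  }
  rec(1L, 1L, 0L)
}

## Fully permissive substitution pool: every position may become any of the
## other 19 residues with weight 1.
makeFullPool <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  pools <- lapply(seq_along(chars), function(p)
    setNames(rep(1, 19), setdiff(AA20, chars[p])))
  names(pools) <- as.character(seq_along(chars))
  new("SubstitutionPool", pools = pools, inherited = integer(0),
      params = list(minCount = 1L))
}

## Number of query windows present in the index (light rescan used by the
## brute-force minimality search).
countMatchedWindows <- function(chars, index) {
  k <- kmerSize(index)
  n <- length(chars) - k + 1L
  if (n < 1L) return(0L)
  seqstr <- paste(chars, collapse = "")
  wins <- substring(seqstr, seq_len(n), seq_len(n) + k - 1L)
  wins <- wins[!grepl("X", wins, fixed = TRUE)]
  sum(hasWindow(index, wins))
}

## Does any single pooled mutation at a non-immutable position clear all
## matched windows? (exhaustive over positions x replacements)
existsSingleClean <- function(seq, index, pool, immutable = integer(0)) {
  chars <- strsplit(seq, "")[[1]]
  k <- kmerSize(index)
  n <- length(chars) - k + 1L
  seqstr <- paste(chars, collapse = "")
  wins <- substring(seqstr, seq_len(n), seq_len(n) + k - 1L)
  mstarts <- which(!grepl("X", wins, fixed = TRUE) & hasWindow(index, wins))
  if (!length(mstarts)) return(TRUE)
  covered <- setdiff(unique(unlist(lapply(mstarts, function(s)
    s:(s + k - 1L)))), immutable)
  pools <- positionPools(pool)
  for (p in covered) {
    pp <- pools[[as.character(p)]]
    for (aa in names(pp)) {
      if (aa == chars[p]) next
      mutated <- chars
      mutated[p] <- aa
      if (countMatchedWindows(mutated, index) == 0L) return(TRUE)
    }
  }
  FALSE
}

randomAASeq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                 collapse = "")

## Random planted deimmunization fixture with known window count.
## Returns NULL if the random plant collided with pre-existing matches.
plantedFixture <- function(seed, nWindows = 1L, k = 9L) {
  set.seed(seed)
  ## decorrelated proteome stream: drawing query and proteome from nearby
  ## offsets of one stream creates long accidental shared substrings
  proteome <- generateProteome(8L, c(30L, 50L), seed = 100000L + seed)
  qlen <- sample(28:40, 1)
  query <- randomAASeq(qlen)
  starts <- if (nWindows == 1L) sample(qlen - k + 1L, 1L) else {
    s1 <- sample(qlen - 2L * k + 1L, 1L)
    ## second window overlapping (shared positions) or disjoint
    s2 <- if (runif(1) < 0.5) s1 + sample(1:(k - 1L), 1L) else s1 + k
    c(s1, min(s2, qlen - k + 1L))
  }
  starts <- unique(starts)
  spec <- data.frame(query_pos = starts,
                     protein = names(proteome)[seq_along(starts)],
                     protein_pos = 5L)
  planted <- plantSharedWindows(query, proteome, spec, k = k)
  index <- buildKmerIndex(planted$proteome, k = k)
  rep0 <- scanSequence(query, index)
  ## matched can exceed planted when a plant's flanking residue happens to
  ## extend the shared run; `matched` is the fixture's effective truth
  list(query = query, proteome = planted$proteome, index = index,
       starts = starts, matched = sort(unique(matchTable(rep0)$query_start)),
       k = k)
}
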