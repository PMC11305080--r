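test_that("a sequence with no self-windows is a clean fixed point", {
  idx <- buildKmerIndex(generateProteome(5, c(30, 40), seed = 1), k = 9)
  seqq <- paste(rep(c("K", "R", "H"), 12), collapse = "")
  ## verify the premise, then the fixed point
  stopifnot(nMatchedWindows(scanSequence(seqq, idx)) == 0)
  cand <- dehumanize(seqq, idx, makeFullPool(seqq))
  expect_equal(designStatus(cand), "clean")
  expect_equal(nrow(mutationTable(cand)), 0L)
  expect_equal(candidateSequence(cand), seqq)
})

test_that("one planted window falls to one mutation verified by rescan", {
  fx <- plantedFixture(31, nWindows = 1L)
  stopifnot(identical(fx$matched, fx$starts))
  ## single mutable position inside the window
  start <- fx$starts[1]
  mutable <- start + 2L
  immutable <- setdiff(seq_len(nchar(fx$query)), mutable)
  pool <- makeFullPool(fx$query)
  cand <- dehumanize(fx$query, fx$index, pool, immutable = immutable)
  expect_equal(designStatus(cand), "clean")
  expect_equal(nrow(mutationTable(cand)), 1L)
  expect_equal(mutationTable(cand)$position, mutable)
  ## independent naive rescan of the final sequence
  expect_equal(nrow(oracleScan(candidateSequence(cand), fx$proteome)), 0L)
})

test_that("overlapping windows are cleared with one shared mutation", {
  ## plant a shared 10-mer: two overlapping 9-mer windows
  set.seed(55)
  proteome <- generateProteome(6, c(30, 50), seed = 56)
  query <- randomAASeq(30)
  s <- 8L
  spec <- data.frame(query_pos = c(s, s + 1L),
                     protein = c("P001", "P001"),
                     protein_pos = c(5L, 6L))
  planted <- plantSharedWindows(query, proteome, spec)
  idx <- buildKmerIndex(planted$proteome)
  stopifnot(nMatchedWindows(scanSequence(query, idx)) == 2L)
  cand <- dehumanize(query, idx, makeFullPool(query))
  expect_equal(designStatus(cand), "clean")
  expect_equal(nrow(mutationTable(cand)), 1L)
  ## the mutation hits a position covered by both windows
  p <- mutationTable(cand)$position
  expect_true(p >= s + 1L && p <= s + 9L)
  ## brute force: a single destroying mutation exists
  expect_true(existsSingleClean(query, idx, makeFullPool(query)))
})

test_that("a window locked inside the epitope is infeasible, not an error", {
  fx <- plantedFixture(77, nWindows = 1L)
  stopifnot(identical(fx$matched, fx$starts))
  start <- fx$starts[1]
  immutable <- start:(start + fx$k - 1L)
  cand <- dehumanize(fx$query, fx$index, makeFullPool(fx$query),
                     immutable = immutable)
  expect_equal(designStatus(cand), "infeasible")
  expect_equal(nrow(mutationTable(cand)), 0L)
  expect_true(start %in% cand@offending$query_start)
})

test_that("the mutation budget stops the loop with budget_exhausted", {
  fx <- plantedFixture(91, nWindows = 2L)
  stopifnot(identical(fx$matched, fx$starts))
  cand <- dehumanize(fx$query, fx$index, makeFullPool(fx$query),
                     maxMutations = 0L)
  expect_equal(designStatus(cand), "budget_exhausted")
  expect_equal(candidateSequence(cand), fx$query)
})

test_that("greedy replacements never create new indexed windows", {
  for (seed in c(11, 23, 47)) {
    fx <- plantedFixture(seed, nWindows = 2L)
    stopifnot(length(fx$matched) >= 1L)
    cand <- dehumanize(fx$query, fx$index, makeFullPool(fx$query))
    if (designStatus(cand) != "clean") next
    expect_equal(nrow(oracleScan(candidateSequence(cand), fx$proteome)), 0L)
    ## matched-window count strictly decreases per recorded step
    expect_true(all(mutationTable(cand)$windows_destroyed >= 1L))
  }
})

test_that("named variants apply with a from-residue guard", {
  seqq <- paste0("A", paste(rep("G", 19), collapse = ""), "K",
                 paste(rep("G", 10), collapse = ""))
  out <- applyVariants(seqq, "K21Q")
  expect_equal(substr(out, 21, 21), "Q")
  expect_equal(nchar(out), nchar(seqq))
  expect_equal(substr(out, 1, 20), substr(seqq, 1, 20))
  expect_equal(applyVariants(seqq, character(0)), seqq)
  expect_error(applyVariants(seqq, "R21E"), "from-residue mismatch")
  ## inverse pair restores the sequence
  expect_equal(applyVariants(applyVariants(seqq, "K21Q"), "Q21K"), seqq)
})

test_that("mutation strings parse and malformed ones fail loudly", {
  v <- parseMutations(c("K21Q", "R218E"))
  expect_equal(v$position, c(21L, 218L))
  expect_equal(v$from, c("K", "R"))
  expect_equal(v$to, c("Q", "E"))
  expect_error(parseMutations("K21"), "cannot parse")
})

test_that("evaluateDesign reports residual matches and epitope integrity", {
  fx <- syntheticFixture(7)
  idx <- buildKmerIndex(fx$proteome, k = fx$k)
  pool <- buildSubstitutionPool(fx$msa, fx$grafted, scaffoldRow = "base",
                                positionMap = fx$graftPlan@positionMap)
  cand <- dehumanize(fx$grafted, idx, pool,
                     immutable = transplantedPositions(fx$graftPlan),
                     plan = fx$graftPlan)
  rep <- evaluateDesign(cand, idx, fx$graftPlan, donor = fx$donor)
  expect_equal(rep$n_matches, 0L)
  expect_true(rep$epitope_intact)
  expect_equal(rep$n_mutations, nrow(mutationTable(cand)))
  ## a candidate mutated inside the epitope is flagged as broken
  broken <- cand
  ch <- strsplit(candidateSequence(cand), "")[[1]]
  tp <- transplantedPositions(fx$graftPlan)[1]
  ch[tp] <- setdiff(AA20, ch[tp])[1]
  broken@sequence <- paste(ch, collapse = "")
  broken@status <- "budget_exhausted"  # keep validity while humanness stale
  rep2 <- evaluateDesign(broken, idx, fx$graftPlan)
  expect_false(rep2$epitope_intact)
})
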