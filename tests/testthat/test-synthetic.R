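test_that("proteome generation is seeded, shaped, and alphabet-bound", {
  p <- generateProteome(10, c(50, 50), seed = 1)
  expect_length(p, 10L)
  expect_true(all(nchar(p) == 50L))
  expect_identical(p, generateProteome(10, c(50, 50), seed = 1))
  expect_false(identical(p, generateProteome(10, c(50, 50), seed = 2)))
  restricted <- generateProteome(5, c(30, 30), alphabet = c("D", "E"),
                                 seed = 3)
  expect_true(all(grepl("^[DE]+$", restricted)))
  expect_error(generateProteome(5, c(30, 30), alphabet = character(0)),
               "empty alphabet")
})

test_that("planting copies windows and keeps contradictions out", {
  query <- paste(rep(AA20, 2), collapse = "")
  proteome <- generateProteome(3, c(30, 30), seed = 4)
  res <- plantSharedWindows(query, proteome,
    data.frame(query_pos = 11L, protein = "P002", protein_pos = 8L))
  expect_equal(substr(res$proteome[["P002"]], 8, 16), substr(query, 11, 19))
  expect_equal(res$planted$query_start, 11L)
  ## same window into two proteins: one matched window, two sources
  res2 <- plantSharedWindows(query, proteome,
    data.frame(query_pos = c(3L, 3L), protein = c("P001", "P003"),
               protein_pos = c(2L, 9L)))
  r <- scanSequence(query, buildKmerIndex(res2$proteome))
  m <- matchTable(r)[matchTable(r)$query_start == 3L, ]
  expect_setequal(m$protein_id, c("P001", "P003"))
  ## empty spec is the identity
  res3 <- plantSharedWindows(query, proteome,
    data.frame(query_pos = integer(0), protein = character(0),
               protein_pos = integer(0)))
  expect_identical(res3$proteome, proteome)
  ## contradictory overlap errors out
  expect_error(plantSharedWindows(query, proteome,
    data.frame(query_pos = c(1L, 3L), protein = "P001",
               protein_pos = c(5L, 6L))), "contradictory")
})

test_that("toy complexes honour the contact span and the non-contact limit", {
  far <- generateToyComplex(10, 6, 20, c(4, 7), seed = 1)
  expect_length(far$expectedContacts, 0L)
  bsa <- perResidueBsa(far$model, far$partition)
  expect_equal(bsa$bsa_A2, rep(0, 10))
  near <- generateToyComplex(12, NULL, 3.3, c(5, 8), seed = 1)
  profile <- buildFootprint(list(P = near), donor = near$params$targetSeq)
  expect_equal(contactResidues(profile, "P"), 5:8)
})

test_that("toy-complex geometry is seed-independent when jitter is zero", {
  a <- generateToyComplex(10, NULL, 3.3, c(5, 8), seed = 1)
  b <- generateToyComplex(10, NULL, 3.3, c(5, 8), seed = 2)
  expect_identical(atomTable(a$model), atomTable(b$model))
  aj <- generateToyComplex(10, NULL, 3.3, c(5, 8), seed = 1, jitter = 0.05)
  bj <- generateToyComplex(10, NULL, 3.3, c(5, 8), seed = 1, jitter = 0.05)
  cj <- generateToyComplex(10, NULL, 3.3, c(5, 8), seed = 2, jitter = 0.05)
  expect_identical(atomTable(aj$model), atomTable(bj$model))
  expect_false(identical(atomTable(aj$model), atomTable(cj$model)))
})

test_that("impossible toy geometries raise explicit errors", {
  ## partner count must match the span in the contact regime
  expect_error(generateToyComplex(10, 6, 3.3, c(5, 8), seed = 1),
               "geometrically impossible")
  ## too-close spacing cannot isolate the span neighbours
  expect_error(generateToyComplex(10, NULL, 0.8, c(5, 8), seed = 1),
               "geometrically impossible")
  ## single interior residue cannot lean both ways
  expect_error(generateToyComplex(10, NULL, 3.3, c(5, 5), seed = 1),
               "geometrically impossible")
  expect_error(generateToyComplex(10, NULL, 3.3, c(5, 12), seed = 1),
               "outside the target chain")
})

test_that("species MSA generation matches its recorded column truth", {
  base <- paste(rep_len(AA20, 25), collapse = "")
  m0 <- generateSpeciesMsa(base, 4, subRate = 0, seed = 1)
  expect_true(all(m0$msa == base))
  m <- generateSpeciesMsa(base, 5, subRate = 0.4, seed = 9)
  expect_identical(m$msa, generateSpeciesMsa(base, 5, 0.4, seed = 9)$msa)
  mat <- do.call(rbind, strsplit(unname(m$msa), ""))
  for (j in c(1, 12, 25)) {
    counts <- table(factor(mat[, j], levels = AA20))
    expect_equal(as.integer(counts), unname(m$truth[, j]))
  }
  ## full substitution leaves no base residue in variant rows
  m1 <- generateSpeciesMsa(base, 3, subRate = 1, seed = 2)
  varMat <- do.call(rbind, strsplit(unname(m1$msa[-1]), ""))
  baseCh <- strsplit(base, "")[[1]]
  expect_true(all(varMat != matrix(baseCh, 3, 25, byrow = TRUE)))
})

test_that("the bundled fixture is self-consistent with its ground truth", {
  fx <- syntheticFixture(7)
  ## planted windows are recovered by a real scan of the grafted sequence
  idx <- buildKmerIndex(fx$proteome, k = fx$k)
  r <- scanSequence(fx$grafted, idx)
  expect_setequal(matchTable(r)$query_start, fx$planted$query_start)
  ## footprints recover the generated spans through the full BSA path
  profile <- buildFootprint(fx$complexes, fx$donor)
  st <- selectEpitopeStretches(contactSets(profile), 2, 2, donor = fx$donor)
  expect_equal(IRanges::start(stretchRanges(st)), fx$expectedStretches$start)
  expect_equal(IRanges::end(stretchRanges(st)), fx$expectedStretches$end)
  ## byte-identical regeneration
  fx2 <- syntheticFixture(7)
  expect_identical(fx$proteome, fx2$proteome)
  expect_identical(fx$msa, fx2$msa)
  expect_identical(atomTable(fx$complexes$P1$model),
                   atomTable(fx2$complexes$P1$model))
  expect_false(identical(syntheticFixture(8)$proteome, fx$proteome))
})
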