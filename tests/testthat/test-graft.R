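test_that("identity alignment scores as the diagonal matrix sum", {
  a <- alignDonorScaffold("AAAA", "AAAA")
  expect_equal(alignmentScore(a), 16)  # 4 x BLOSUM62[A,A]
  cm <- columnMap(a)
  expect_equal(cm$donor_pos, 1:4)
  expect_equal(cm$scaffold_pos, 1:4)
})

test_that("a single-residue pair aligns to one gapless column", {
  a <- alignDonorScaffold("A", "C")
  expect_equal(nrow(columnMap(a)), 1L)
  expect_false(any(is.na(columnMap(a))))
})

test_that("the optimal gap placement matches an exhaustive DP oracle", {
  a <- alignDonorScaffold("ACDE", "ACE")
  expect_equal(a@alignedDonor, "ACDE")
  expect_equal(a@alignedScaffold, "AC-E")  # gap under the D column
  b62 <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  for (pair in list(c("ACDE", "ACE"), c("WKR", "WR"), c("AC", "AGC"),
                    c("MKV", "MKV"), c("A", "W"))) {
    got <- alignmentScore(alignDonorScaffold(pair[1], pair[2]))
    want <- enumAlignScore(pair[1], pair[2], b62)
    expect_equal(got, want, info = paste(pair, collapse = "/"))
  }
})

test_that("transplant substitutes donor stretch residues onto the scaffold", {
  donor <- "AAACDEAAAA"; scaffold <- "AAAAAAAAAA"
  st <- selectEpitopeStretches(list(A = 4:6, B = 4:6), 2, 0, donor = donor)
  g <- transplantStretches(scaffold, donor, st,
                           alignDonorScaffold(donor, scaffold))
  expect_equal(g$sequence, "AAACDEAAAA")
  expect_equal(nrow(g$plan@substitutions), 3L)
  expect_equal(transplantedPositions(g$plan), 4:6)
  expect_equal(g$plan@transplantedResidues, c("C", "D", "E"))
})

test_that("an empty stretch list grafts the scaffold unchanged", {
  st <- selectEpitopeStretches(list(A = integer(0)), 1, 0)
  g <- transplantStretches("ACDEFG", "AGDEFG", st,
                           alignDonorScaffold("AGDEFG", "ACDEFG"))
  expect_equal(g$sequence, "ACDEFG")
  expect_equal(length(transplantedPositions(g$plan)), 0L)
  expect_equal(nrow(g$plan@substitutions), 0L)
})

test_that("a scaffold gap inside a stretch becomes an insertion", {
  ## hand-constructed alignment: donor ACDEF vs scaffold ACEF (D unmatched)
  aln <- new("GraftAlignment", alignedDonor = "ACDEF",
             alignedScaffold = "AC-EF",
             columnMap = data.frame(column = 1:5,
                                    donor_pos = 1:5,
                                    scaffold_pos = c(1L, 2L, NA, 3L, 4L)),
             score = 0)
  st <- selectEpitopeStretches(list(A = 2:4, B = 2:4), 2, 0, donor = "ACDEF")
  g <- transplantStretches("ACEF", "ACDEF", st, aln)
  expect_equal(g$sequence, "ACDEF")          # one longer than the scaffold
  expect_equal(nchar(g$sequence), 5L)
  expect_equal(nrow(g$plan@insertions), 1L)
  expect_equal(g$plan@insertions$residue, "D")
})

test_that("a donor gap inside a stretch deletes the scaffold residue", {
  aln <- new("GraftAlignment", alignedDonor = "AC-EF",
             alignedScaffold = "ACDEF",
             columnMap = data.frame(column = 1:5,
                                    donor_pos = c(1L, 2L, NA, 3L, 4L),
                                    scaffold_pos = 1:5),
             score = 0)
  st <- selectEpitopeStretches(list(A = 2:3, B = 2:3), 2, 0, donor = "ACEF")
  g <- transplantStretches("ACDEF", "ACEF", st, aln)
  expect_equal(g$sequence, "ACEF")
  expect_equal(nrow(g$plan@deletions), 1L)
  expect_equal(g$plan@deletions$residue, "D")
})

test_that("a stretch beyond the donor is rejected", {
  st <- selectEpitopeStretches(list(A = 8:9, B = 8:9), 2, 0)
  expect_error(
    transplantStretches("ACDE", "ACDE", st, alignDonorScaffold("ACDE", "ACDE")),
    "outside donor")
})

test_that("graft integrity holds on randomized homolog pairs", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(25:45, 1)
    donor <- randomAASeq(n)
    ## scaffold: diverged copy with occasional indels
    ch <- strsplit(donor, "")[[1]]
    mut <- runif(n) < 0.25
    ch[mut] <- vapply(which(mut), function(j)
      sample(setdiff(AA20, ch[j]), 1), "")
    if (runif(1) < 0.5) ch <- ch[-sample(n, sample(1:2, 1))]   # deletions
    if (runif(1) < 0.5) {                                      # insertion
      at <- sample(length(ch), 1)
      ch <- append(ch, sample(AA20, 1), after = at)
    }
    scaffold <- paste(ch, collapse = "")
    s1 <- sort(sample(2:(n - 12), 2))
    st <- selectEpitopeStretches(
      list(A = c(s1[1]:(s1[1] + 3), s1[2]:(s1[2] + 2)),
           B = c(s1[1]:(s1[1] + 3), s1[2]:(s1[2] + 2))),
      2, 0, donor = donor)
    if (length(st) < 1) next
    aln <- alignDonorScaffold(donor, scaffold)
    g <- transplantStretches(scaffold, donor, st, aln)
    gch <- strsplit(g$sequence, "")[[1]]
    pm <- g$plan@positionMap
    ## donor residues inside the stretches
    expect_equal(gch[transplantedPositions(g$plan)],
                 g$plan@transplantedResidues)
    expect_equal(paste(g$plan@transplantedResidues, collapse = ""),
                 paste(stretchResidues(st), collapse = ""))
    ## scaffold residues outside the stretch columns
    outside <- pm[pm$origin == "scaffold", ]
    sch <- strsplit(scaffold, "")[[1]]
    expect_equal(gch[outside$grafted_pos], sch[outside$scaffold_pos])
    ## bookkeeping: length change = insertions - deletions
    expect_equal(nchar(g$sequence),
                 nchar(scaffold) + nrow(g$plan@insertions) -
                   nrow(g$plan@deletions))
  }
})
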