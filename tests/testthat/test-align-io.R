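test_that("plain FASTA parses into one alignment without annotation", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACDE", ">s2", "ACDF"), f)
  alns <- readAnnotatedFasta(f)
  expect_length(alns, 1)
  aln <- alns[[1]]
  expect_equal(nSeqs(aln), 2)
  expect_equal(nSites(aln), 4)
  expect_true(all(is.na(ssMatrix(aln))))
  expect_true(all(is.na(rsaMatrix(aln))))
})

test_that("digit-encoded 3D records decode to decile bin midpoints", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "AC-D", ">s1|3D", "3707", ">s2", "ACDE"), f)
  aln <- readAnnotatedFasta(f)[[1]]
  expect_equal(unname(rsaMatrix(aln)["s1", ]), c(0.35, 0.75, 0.05, 0.75))
})

test_that("decimal and percentage 3D bodies are accepted", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACDE", ">s1|3D", "0.1 35 0.9 NA",
               ">s2", "ACDF"), f)
  aln <- readAnnotatedFasta(f)[[1]]
  expect_equal(unname(rsaMatrix(aln)["s1", ]), c(0.1, 0.35, 0.9, NA))
})

test_that("annotation errors are hard and name the offending sequence", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "AC-D", ">s1|2D", "HHC", ">s2", "ACDE"), f)
  expect_error(readAnnotatedFasta(f), "s1")

  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACDE", ">s2", "ACDF", ">ghost|2D", "HHEE"), f2)
  expect_error(readAnnotatedFasta(f2), "ghost")

  f3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACXE", ">s2", "ACDF"), f3)
  expect_error(readAnnotatedFasta(f3), "illegal residue")
})

test_that("multi-alignment files split at comment lines and keep ids", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("# famA", ">s1", "ACDE", ">s2", "ACDF", "",
               "# famB", ">t1", "KR", ">t2", "KE"), f)
  alns <- readAnnotatedFasta(f)
  expect_length(alns, 2)
  expect_equal(vapply(alns, alignmentId, ""), c("famA", "famB"))
  expect_equal(nSites(alns[[2]]), 2)
})

test_that("gap characters '.', '~' and '-' are normalized on input", {
  aln <- AnnotatedAlignment("g", c(s1 = "A.C~D-E", s2 = "AACCDDE"))
  expect_equal(sum(residueMatrix(aln) == "-"), 3)
})

test_that("write/read round-trip preserves residues, ss and rsa", {
  spec <- fixtureSpec(nFamilies = 2, nSites = 60, annotate = TRUE,
                      seed = 5)
  alns <- simulateAlignments(spec)
  f <- withr::local_tempfile(fileext = ".fa")
  writeAnnotatedFasta(alns, f)
  back <- readAnnotatedFasta(f)
  expect_length(back, 2)
  for (k in 1:2) {
    expect_identical(residueMatrix(back[[k]]), residueMatrix(alns[[k]]))
    expect_identical(ssMatrix(back[[k]]), ssMatrix(alns[[k]]))
    expect_equal(rsaMatrix(back[[k]]), rsaMatrix(alns[[k]]),
                 tolerance = 1e-3)
  }
})

test_that("assignGroups attaches codes, errors on missing ids, warns on empty groups", {
  aln <- AnnotatedAlignment("f", c(s1 = "ACDE", s2 = "ACDF"))
  sch <- GroupScheme(c("meso", "psychro"),
                     c(s1 = "meso", s2 = "psychro"))
  out <- assignGroups(aln, sch)
  expect_equal(unname(groupCodes(out)), c(1, 2))
  expect_true(all(is.na(groupCodes(aln))))  # input unmodified

  schMissing <- GroupScheme(c("meso", "psychro"), c(s1 = "meso"))
  expect_error(assignGroups(aln, schMissing), "s2")

  sch3 <- GroupScheme(c("meso", "inter", "psychro"),
                      c(s1 = "meso", s2 = "psychro"))
  expect_warning(assignGroups(aln, sch3), "inter")
})

test_that("three-group scheme assigns consecutive ordinal codes", {
  ids <- paste0("s", 1:6)
  aln <- AnnotatedAlignment("f", setNames(rep("ACDE", 6), ids))
  sch <- GroupScheme(c("m", "i", "p"),
                     setNames(rep(c("m", "i", "p"), each = 2), ids))
  expect_equal(unname(groupCodes(assignGroups(aln, sch))),
               c(1, 1, 2, 2, 3, 3))
})

test_that("group config YAML round-trips labels, assignments and strata", {
  sch <- GroupScheme(c("meso", "psychro"),
                     c(s1 = "meso", s2 = "psychro"),
                     c(s1 = "orderA", s2 = NA))
  f <- withr::local_tempfile(fileext = ".yaml")
  writeGroupConfig(sch, f)
  back <- readGroupConfig(f)
  expect_equal(groupLabels(back), c("meso", "psychro"))
  expect_equal(groupCode(back, "psychro"), 2L)
})

test_that("site filtering respects ss classes and the consensus boundary", {
  aln <- AnnotatedAlignment("f", c(s1 = "ACDEF", s2 = "ACDEF"),
                            ss = list(s1 = "HHEEC", s2 = "HHEEC"))
  kept <- filterSites(aln, siteFilter(ss = "H"))
  expect_equal(siteIndex(kept), c(1L, 2L))

  ## split vote at exactly the consensus fraction passes (>= convention)
  aln2 <- AnnotatedAlignment("f", c(s1 = "ACDEF", s2 = "ACDEF"),
                             ss = list(s1 = "HHEEC", s2 = "EHEEC"))
  kept2 <- filterSites(aln2, siteFilter(ss = "H", consensus = 0.5))
  expect_true(1L %in% siteIndex(kept2))
})

test_that("exposure filtering splits surface from core at the threshold", {
  rsa <- list(s1 = c(0.3, 0.4, 0.1, 0.2), s2 = c(0.3, 0.4, 0.1, 0.24))
  aln <- AnnotatedAlignment("f", c(s1 = "ACDE", s2 = "ACDF"), rsa = rsa)
  surf <- filterSites(aln, siteFilter(exposure = "surface"))
  expect_equal(siteIndex(surf), c(1L, 2L))
  core <- filterSites(aln, siteFilter(exposure = "core"))
  expect_equal(siteIndex(core), c(3L, 4L))
})

test_that("filtering is the identity for the all-pass filter and shrinks otherwise", {
  spec <- fixtureSpec(nFamilies = 1, nSites = 80, annotate = TRUE,
                      seed = 9)
  aln <- simulateAlignments(spec)[[1]]
  expect_identical(siteIndex(filterSites(aln, siteFilter())),
                   siteIndex(aln))
  sub <- filterSites(aln, siteFilter(ss = c("H", "E"),
                                     exposure = "surface"))
  expect_lte(nSites(sub), nSites(aln))
  expect_true(all(diff(siteIndex(sub)) > 0))
})

test_that("filters demanding absent annotation raise a hard error", {
  aln <- AnnotatedAlignment("f", c(s1 = "ACDE", s2 = "ACDF"))
  expect_error(filterSites(aln, siteFilter(ss = "H")), "secondary")
  expect_error(filterSites(aln, siteFilter(exposure = "core")), "RSA")
})
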