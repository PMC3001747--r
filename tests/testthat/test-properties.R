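test_that("bundled scales are complete, finite and documented", {
  scales <- loadPropertyScales()
  expect_true(all(c("hydrophobicity", "volume", "charge_ph7", "polarity",
                    "flexibility") %in% names(scales)))
  for (sc in scales) {
    expect_length(scaleValues(sc), 20)
    expect_true(all(is.finite(scaleValues(sc))))
    expect_true(nzchar(sc@source))
  }
  ch <- scaleValues(scales$charge_ph7)
  expect_equal(unname(ch[c("D", "E", "K", "R", "H")]),
               c(-1, -1, 1, 1, 0))
  expect_equal(sum(ch != 0), 4)
})

test_that("user scale files parse and incomplete ones name the missing residue", {
  f <- withr::local_tempfile(fileext = ".tsv")
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  writeLines(c("# name: toy", paste(aas, seq_along(aas), sep = "\t")), f)
  sc <- readPropertyScaleFile(f)
  expect_equal(scaleName(sc[[1]]), "toy")
  expect_equal(unname(scaleValues(sc[[1]])["A"]), 1)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(aas[-20], seq_len(19), sep = "\t"), f2)
  expect_error(readPropertyScaleFile(f2), "V")
})

test_that("AAindex1 records are accepted", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "H TEST0001",
    "D A toy index",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     1.      2.      3.      4.      5.      6.      7.      8.      9.     10.",
    "    11.     12.     13.     14.     15.     16.     17.     18.     19.     20.",
    "//"), f)
  sc <- readPropertyScaleFile(f)[["TEST0001"]]
  expect_equal(unname(scaleValues(sc)[c("A", "I", "L", "V")]),
               c(1, 10, 11, 20))
})

test_that("mean property averages over non-gap residues at selected sites", {
  vals <- setNames(rep(0, 20), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  vals["A"] <- 1
  sc <- new("PropertyScale", name = "indA", values = vals, source = "test")
  expect_equal(meanProperty("AAC-", sc), 2 / 3)
  const <- new("PropertyScale", name = "const",
               values = setNames(rep(4.2, 20), names(vals)),
               source = "test")
  expect_equal(meanProperty("ACDKW-", const), 4.2)
  allGap <- meanProperty("---", sc)
  expect_true(is.na(allGap))
  expect_true("not_computable" %in% attr(allGap, "flags"))
})

test_that("surface-filtered means match the hand-selected columns", {
  aln <- AnnotatedAlignment(
    "f", c(s1 = "ADKW", s2 = "ADKW"),
    rsa = list(s1 = c(0.1, 0.3, 0.5, 0.1), s2 = c(0.1, 0.3, 0.5, 0.1)))
  surf <- filterSites(aln, siteFilter(exposure = "surface",
                                      rsaThreshold = 0.25))
  expect_equal(siteIndex(surf), c(2L, 3L))
  sc <- loadPropertyScales()$hydrophobicity
  got <- meanProperty(residueMatrix(surf)["s1", ], sc)
  expect_equal(got, mean(scaleValues(sc)[c("D", "K")]))
})

test_that("family slopes reproduce exact linear cases including two points", {
  aln <- AnnotatedAlignment("f", c(a = "AAAA", b = "KKKK"),
                            group = c(1, 3))
  sc <- loadPropertyScales()$charge_ph7
  fs <- familySlopes(list(aln), sc)   # Y: 0 and 1 at X 1 and 3
  expect_equal(fs$beta1, 0.5)
  expect_equal(fs$nSeqs, 2)

  ## Y exactly linear in X
  aln2 <- AnnotatedAlignment("f2",
    c(a = "AAAA", b = "AAAK", c = "AAKK", d = "AKKK"),
    group = c(1, 2, 3, 4))
  fs2 <- familySlopes(list(aln2), sc)
  expect_equal(fs2$beta1, 0.25)
})

test_that("alignments without two distinct groups are skipped with a warning", {
  sc <- loadPropertyScales()$hydrophobicity
  good <- AnnotatedAlignment("g", c(a = "AAKK", b = "KKAA"),
                             group = c(1, 2))
  bad <- AnnotatedAlignment("b", c(a = "AAKK", b = "KKAA"),
                            group = c(1, 1))
  expect_warning(fs <- familySlopes(list(good, bad), sc), "skipped")
  expect_equal(nrow(fs), 1)
  expect_error(suppressWarnings(familySlopes(list(bad), sc)), "distinct")
})

test_that("the property trend test reduces to plain Mann-Kendall for one alignment", {
  spec <- fixtureSpec(nFamilies = 1, nSites = 150, seed = 47)
  aln <- simulateAlignments(spec)[[1]]
  sc <- loadPropertyScales()$hydrophobicity
  tr <- propertyTrendTest(list(aln), sc)
  y <- vapply(seq_len(nSeqs(aln)), function(i)
    meanProperty(residueMatrix(aln)[i, ], sc), 0)
  direct <- mannKendall(unname(groupCodes(aln)), y)
  expect_equal(trendS(tr), trendS(direct))
  expect_equal(trendP(tr), trendP(direct))
})

test_that("affine scale changes rescale slopes and leave the MK p unchanged", {
  spec <- fixtureSpec(nFamilies = 6, nSites = 150,
                      propertySlope = list(scale = "hydrophobicity",
                                           beta1 = 0.05, noiseSd = 0),
                      seed = 53)
  alns <- simulateAlignments(spec)
  sc <- loadPropertyScales()$hydrophobicity
  scaled <- new("PropertyScale", name = "affine",
                values = 3 * scaleValues(sc) + 7, source = "test")
  fs1 <- familySlopes(alns, sc)
  fs2 <- familySlopes(alns, scaled)
  expect_equal(fs2$beta1, 3 * fs1$beta1)
  expect_equal(trendP(propertyTrendTest(alns, scaled)),
               trendP(propertyTrendTest(alns, sc)))
})

test_that("ranked slopes are a sorted permutation of the family slopes", {
  spec <- fixtureSpec(nFamilies = 8, nSites = 100, seed = 59)
  alns <- simulateAlignments(spec)
  sc <- loadPropertyScales()$volume
  fs <- familySlopes(alns, sc)
  p <- plotRankedSlopes(fs)
  drawn <- ggplot2::layer_data(p, 2)$y
  expect_equal(length(drawn), nrow(fs))
  expect_equal(drawn, sort(fs$beta1))
})

test_that("stratified property regression recovers parallel strata exactly", {
  sc <- loadPropertyScales()$charge_ph7
  ## strata differ by a constant charge offset; shared slope in X
  seqs <- c(a1 = "AAAA", a2 = "AAKK", a3 = "AKKK",
            b1 = "KKAA", b2 = "KKKA", b3 = "KKKK")
  aln <- AnnotatedAlignment("f", seqs,
                            group = c(1, 2, 3, 1, 2, 3),
                            stratum = rep(c("sA", "sB"), each = 3))
  ## Y(sA) = 0, 0.5, 0.75 ; Y(sB) = 0.5, 0.75, 1 -- not exactly parallel,
  ## so fit a constructed numeric case through the same code path instead
  r <- suppressWarnings(
    olsTrend(c(1, 2, 3, 11, 12, 13), c(1, 2, 3, 1, 2, 3),
             strata = rep(c("sA", "sB"), each = 3)))
  expect_equal(slopeCoef(r), 1)
  expect_equal(strataOffsets(r), c(sB = 10))

  onestratum <- AnnotatedAlignment("f", seqs[1:4],
                                   group = c(1, 2, 3, 1),
                                   stratum = rep("sA", 4))
  expect_warning(r2 <- stratifiedPropertyRegression(onestratum, sc),
                 "unstratified")
  expect_s4_class(r2, "RegressionResult")
})

test_that("stratified property regression matches olsTrend on the same data", {
  spec <- fixtureSpec(nFamilies = 1, nSites = 200,
                      groups = c(m = 4, i = 4, p = 4),
                      strata = c("oA", "oB"), seed = 61)
  aln <- simulateAlignments(spec)[[1]]
  sc <- loadPropertyScales()$hydrophobicity
  r <- stratifiedPropertyRegression(aln, sc)
  y <- vapply(seq_len(nSeqs(aln)), function(i)
    meanProperty(residueMatrix(aln)[i, ], sc), 0)
  direct <- olsTrend(y, unname(groupCodes(aln)),
                     strata = unname(strata(aln)))
  expect_equal(slopeCoef(r), slopeCoef(direct))
  expect_equal(slopeP(r), slopeP(direct))
})

test_that("the property trend test holds its nominal level on null fixtures", {
  nSim <- 200
  sc <- loadPropertyScales()$hydrophobicity
  rej <- 0
  for (i in seq_len(nSim)) {
    alns <- simulateAlignments(fixtureSpec(nFamilies = 20, nSites = 150,
                                           seed = 70000 + i))
    rej <- rej + (trendP(propertyTrendTest(alns, sc)) < 0.05)
  }
  band <- 3 * sqrt(0.05 * 0.95 / nSim)
  expect_lt(abs(rej / nSim - 0.05), band)
})

test_that("family slopes on null fixtures are centred at zero", {
  sc <- loadPropertyScales()$hydrophobicity
  alns <- simulateAlignments(fixtureSpec(nFamilies = 40, nSites = 200,
                                         seed = 71001))
  b <- familySlopes(alns, sc)$beta1
  expect_lt(abs(mean(b)), 2 * sd(b) / sqrt(length(b)))
})
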