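test_that("pairwise identity counts both-aligned columns only", {
  expect_equal(as.numeric(pairwiseIdentity("AAAA", "AAAT")), 0.75)
  expect_equal(as.numeric(pairwiseIdentity("AA--", "AA-A")), 1.0)
  expect_equal(as.numeric(pairwiseIdentity("ACDE", "ACDE")), 1.0)
  p <- pairwiseIdentity("A---", "-AAA")
  expect_equal(as.numeric(p), 0)
  expect_true("no_overlap" %in% attr(p, "flags"))
  expect_error(pairwiseIdentity("AAA", "AA"), "length")
})

test_that("greedy Jones pairing picks highest identities, each sequence once", {
  ## identity matrix [[0.9, 0.5], [0.6, 0.8]] -> (M1,P1), (M2,P2)
  M <- c(M1 = "AAAAAAAAAA", M2 = "CCCCCCAAAA")
  P <- c(P1 = "AAAAAAAAAC", P2 = "CCCCCCAACC")
  pr <- jonesPairing(M, P)
  expect_equal(pr$pairs$idA, c("M1", "M2"))
  expect_equal(pr$pairs$idB, c("P1", "P2"))
  expect_equal(nrow(pr$pairs), 2)
  expect_equal(anyDuplicated(c(pr$pairs$idA, pr$pairs$idB)), 0)
})

test_that("greedy pairing is documented-greedy, not optimal; the optimal option differs", {
  ## mutation blocks chosen so the single best pair (M1,P1) is not part of
  ## the best total matching
  base <- function(v) paste(v, collapse = "")
  A <- rep("A", 100)
  M1 <- A
  P1 <- A; P1[1:4] <- "C"                       # id(M1,P1) = 0.96
  P2 <- A; P2[5:9] <- "C"                       # id(M1,P2) = 0.95
  M2 <- A; M2[c(1:4, 10:14)] <- "C"             # id(M2,P1) = 0.95
  gm <- c(M1 = base(M1), M2 = base(M2))
  gp <- c(P1 = base(P1), P2 = base(P2))
  im <- outer(1:2, 1:2, Vectorize(function(i, j)
    as.numeric(pairwiseIdentity(gm[i], gp[j]))))
  expect_equal(im[1, 1], 0.96)
  expect_equal(im[1, 2], 0.95)
  expect_equal(im[2, 1], 0.95)
  expect_equal(im[2, 2], 0.86)
  ## brute force over both possible matchings: greedy is suboptimal here
  totGreedy <- im[1, 1] + im[2, 2]
  totSwap <- im[1, 2] + im[2, 1]
  expect_gt(totSwap, totGreedy)
  greedy <- jonesPairing(gm, gp)
  expect_equal(greedy$pairs$idB[greedy$pairs$idA == "M1"], "P1")
  opt <- jonesPairing(gm, gp, method = "optimal")
  expect_equal(opt$pairs$idB[opt$pairs$idA == "M1"], "P2")
})

test_that("within-group pairing yields floor(n/2) disjoint pairs", {
  ids <- paste0("s", 1:5)
  set.seed(81)
  seqs <- setNames(replicate(5, paste(sample(c("A", "C", "D"), 30,
                                             replace = TRUE),
                                      collapse = "")), ids)
  pr <- jonesPairing(seqs)
  expect_equal(nrow(pr$pairs), 2)
  expect_length(pr$unpaired, 1)
  expect_equal(anyDuplicated(c(pr$pairs$idA, pr$pairs$idB)), 0)
})

test_that("SP counting follows the worked single-pair cases", {
  aln <- AnnotatedAlignment("f", c(m = "AC", p = "AD"), group = c(1, 2))
  m <- spMatrix(list(aln), 1, 2)
  expect_equal(spCounts(m)["C", "D"], 1)
  expect_equal(sum(spCounts(m)), 1)

  alnGap <- AnnotatedAlignment("f", c(m = "A-", p = "AC"),
                               group = c(1, 2))
  mg <- spMatrix(list(alnGap), 1, 2)
  expect_equal(spCounts(mg)["~", "C"], 1)

  ## both-gap columns are skipped
  alnBoth <- AnnotatedAlignment("f", c(m = "A-C", p = "A-D"),
                                group = c(1, 2))
  expect_equal(sum(spCounts(spMatrix(list(alnBoth), 1, 2))), 1)
})

test_that("total SP count equals an independent per-column mismatch recount", {
  spec <- fixtureSpec(nFamilies = 4, nSites = 150, gapRate = 0.05,
                      groups = c(m = 3, p = 3), seed = 29)
  alns <- simulateAlignments(spec)
  m <- spMatrix(alns, 1, 2)
  recount <- 0
  for (aln in alns) {
    res <- residueMatrix(aln)
    g <- unname(groupCodes(aln))
    pr <- jonesPairing(res[g == 1, , drop = FALSE],
                       res[g == 2, , drop = FALSE])
    for (k in seq_len(nrow(pr$pairs))) {
      ra <- res[pr$pairs$idA[k], ]
      rb <- res[pr$pairs$idB[k], ]
      for (j in seq_along(ra))
        if (!(ra[j] == "-" && rb[j] == "-") && ra[j] != rb[j])
          recount <- recount + 1
    }
  }
  expect_equal(sum(spCounts(m)), recount)
})

test_that("within-group matrices are exactly symmetric with zero diagonal", {
  spec <- fixtureSpec(nFamilies = 3, nSites = 120, gapRate = 0.03,
                      groups = c(m = 4, p = 2), seed = 37)
  alns <- simulateAlignments(spec)
  w <- spMatrix(alns, 1, 1, kind = "symmetric_within")
  expect_identical(spCounts(w), t(spCounts(w)))
  expect_true(all(diag(spCounts(w)) == 0))
})

test_that("representative matrix averages all ordered pairs and scales back exactly", {
  aln1 <- AnnotatedAlignment("f", c(m = "AC", p = "AD"), group = c(1, 2))
  r1 <- representativeSPMatrix(list(aln1), 1, 2)
  expect_equal(r1@gMP, 1)
  expect_equal(spCounts(r1)["C", "D"], 1)

  aln2 <- AnnotatedAlignment("f", c(m1 = "AC", m2 = "AC", p = "AD"),
                             group = c(1, 1, 2))
  r2 <- representativeSPMatrix(list(aln2), 1, 2)
  expect_equal(r2@gMP, 2)
  expect_equal(spCounts(r2)["C", "D"], 1.0)

  ## representative x G_MP = cumulative over all ordered pairs (brute)
  spec <- fixtureSpec(nFamilies = 2, nSites = 80, groups = c(m = 3, p = 2),
                      seed = 41)
  alns <- simulateAlignments(spec)
  rep_ <- representativeSPMatrix(alns, 1, 2)
  brute <- matrix(0, 21, 21, dimnames = dimnames(spCounts(rep_)))
  for (aln in alns) {
    res <- residueMatrix(aln)
    g <- unname(groupCodes(aln))
    for (i in which(g == 1)) for (j in which(g == 2)) {
      ra <- ifelse(res[i, ] == "-", "~", res[i, ])
      rb <- ifelse(res[j, ] == "-", "~", res[j, ])
      for (col in seq_along(ra))
        if (ra[col] != rb[col])
          brute[ra[col], rb[col]] <- brute[ra[col], rb[col]] + 1
    }
  }
  expect_equal(spCounts(rep_) * rep_@gMP, brute)
})

test_that("pooling into a target collects its column and conserves totals", {
  aln <- AnnotatedAlignment("f", c(m = "CCC", p = "DDD"), group = c(1, 2))
  m <- spMatrix(list(aln), 1, 2)
  pool <- poolSubstitutions(m, "D")
  expect_equal(pool$totalInto, 3)
  allTargets <- sum(vapply(c(rownames(spCounts(m))),
                           function(t) poolSubstitutions(m, t)$totalInto,
                           0))
  expect_equal(allTargets, sum(spCounts(m)))
})

test_that("the bias test lays out the adaptation-vs-background table correctly", {
  f <- new("SPMatrix", counts = local({
    cts <- matrix(0, 21, 21, dimnames = list(protrend:::SUB_STATES,
                                             protrend:::SUB_STATES))
    cts["K", "R"] <- 89
    cts["K", "A"] <- 1000
    cts["K", "G"] <- 754
    cts
  }), kind = "directional_between", groupFrom = 1L, groupTo = 2L,
  nPairs = 10L, gMP = 0)
  b <- new("SPMatrix", counts = local({
    cts <- matrix(0, 21, 21, dimnames = list(protrend:::SUB_STATES,
                                             protrend:::SUB_STATES))
    cts["K", "R"] <- 14; cts["R", "K"] <- 14
    cts["K", "A"] <- 514; cts["A", "K"] <- 514
    cts
  }), kind = "symmetric_within", groupFrom = 1L, groupTo = 1L,
  nPairs = 10L, gMP = 0)
  bt <- substitutionBiasTest(f, b, "K", "R")
  expect_equal(c(bt$table@a, bt$table@b, bt$table@c, bt$table@d),
               c(89, 1754, 14, 514))
  ## the mid-p is strictly smaller than the conventional exact p
  expect_lt(bt$p, enumFisherP(89, 1754, 14, 514))
  expect_equal(bt$direction, "favoured")
})

test_that("identical forward and background proportions are non-significant and undirected", {
  mk <- function(kr, ka, kind) {
    cts <- matrix(0, 21, 21, dimnames = list(protrend:::SUB_STATES,
                                             protrend:::SUB_STATES))
    cts["K", "R"] <- kr; cts["K", "A"] <- ka
    if (kind == "symmetric_within") {
      cts["R", "K"] <- kr; cts["A", "K"] <- ka
    }
    new("SPMatrix", counts = cts, kind = kind, groupFrom = 1L,
        groupTo = if (kind == "symmetric_within") 1L else 2L,
        nPairs = 5L, gMP = 0)
  }
  bt <- substitutionBiasTest(mk(10, 40, "directional_between"),
                             mk(10, 40, "symmetric_within"), "K", "R")
  expect_gt(bt$p, 0.8)
  expect_equal(bt$direction, "undefined")

  extreme <- substitutionBiasTest(mk(20, 0, "directional_between"),
                                  mk(0, 20, "symmetric_within"),
                                  "K", "R")
  expect_equal(extreme$direction, "favoured")
  expect_equal(extreme$p, enumMidP(20, 0, 0, 20))

  noData <- substitutionBiasTest(mk(0, 0, "directional_between"),
                                 mk(5, 5, "symmetric_within"), "K", "R")
  expect_true("not_testable" %in% noData$flags)
  expect_true(is.na(noData$p))
})

test_that("the full scan flags a BY subset of the raw-p flags", {
  spec <- fixtureSpec(nFamilies = 8, nSites = 200,
                      groups = c(m = 3, p = 3),
                      substitutionBias = list(x = "K", y = "R",
                                              multiplier = 3),
                      seed = 43)
  alns <- simulateAlignments(spec)
  fwd <- spMatrix(alns, 1, 2)
  bg <- spMatrix(alns, 1, 1, kind = "symmetric_within")
  scan <- substitutionScan(fwd, bg)
  ok <- !is.na(scan$p)
  flaggedQ <- scan$x[ok][scan$qBY[ok] < 0.05]
  flaggedP <- scan$x[ok][scan$p[ok] < 0.05]
  expect_true(all(paste(flaggedQ) %in% paste(flaggedP)))
  expect_true(all(scan$qBY[ok] >= scan$p[ok] - 1e-12))
})

test_that("stratified MH bias test reduces and cancels as constructed", {
  t1 <- contingency2x2(8, 2, 2, 8)
  single <- mantelHaenszelBias(list(s1 = t1))
  expect_equal(single$commonOR, 16)

  twoSame <- mantelHaenszelBias(list(s1 = t1, s2 = t1))
  expect_equal(twoSame$commonOR, 16)

  opposing <- mantelHaenszelBias(list(s1 = contingency2x2(8, 2, 2, 8),
                                      s2 = contingency2x2(2, 8, 8, 2)))
  expect_equal(opposing$commonOR, 1)
  expect_gt(opposing$p, 0.5)
})
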