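## Independent oracles used by the tests.  These deliberately avoid the
## package's own code paths: plain loops, choose(), and full enumeration.

## Hypergeometric probabilities of all tables with the observed margins.
enumTableProbs <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  list(k = k, probs = probs, pobs = probs[k == a])
}

## Conventional two-sided Fisher exact p (probability ordering).
enumFisherP <- function(a, b, c, d) {
  e <- enumTableProbs(a, b, c, d)
  sum(e$probs[e$probs <= e$pobs * (1 + 1e-7)])
}

## Two-sided mid-p: strictly-less-probable mass plus half the tied mass.
enumMidP <- function(a, b, c, d) {
  e <- enumTableProbs(a, b, c, d)
  tied <- abs(e$probs - e$pobs) <= 1e-7 * e$pobs
  sum(e$probs[e$probs < e$pobs & !tied]) + 0.5 * sum(e$probs[tied])
}

## Brute-force Kendall S by double loop.
bruteS <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  s
}

## All permutations of 1..n (rows of a matrix).
allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1L))
  sub <- allPerms(n - 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- matrix(0L, nrow(sub), n)
    m[, 1] <- i
    m[, -1] <- ifelse(sub >= i, sub + 1L, sub)
    out[[i]] <- m
  }
  do.call(rbind, out)
}

## Exact two-sided permutation p for the Mann-Kendall S: proportion of
## permutations of y with |S| at least the observed |S|.
permMKp <- function(x, y) {
  n <- length(x)
  P <- allPerms(n)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  Sall <- numeric(nrow(P))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    Sall <- Sall + sign(x[j] - x[i]) * sign(y[P[, j]] - y[P[, i]])
  }
  sObs <- bruteS(x, y)
  mean(abs(Sall) >= abs(sObs))
}

## Exact two-sided signed-rank p by full 2^n sign enumeration (midranks).
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  Wall <- 0
  for (i in seq_len(n)) Wall <- c(Wall, Wall + r[i])
  2 * min(mean(Wall >= W), mean(Wall <= W))
}

## Benjamini-Yekutieli by the printed step-up formula.
handBY <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- pmin(1, p[o] * m * cm / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

## Mantel-Haenszel common odds ratio by the defining formula.
handMHOR <- function(tables) {
  num <- sum(sapply(tables, function(t) t[1] * t[4] / sum(t)))
  den <- sum(sapply(tables, function(t) t[2] * t[3] / sum(t)))
  num / den
}

## Small annotated alignment shared across tests.
toyAlignment <- function() {
  AnnotatedAlignment(
    "toy",
    c(m1 = "ACDKA", m2 = "ACDKC", p1 = "ACDRA", p2 = "ACERC"),
    ss = list(m1 = "HHEEC", m2 = "HHEEC", p1 = "HHEEC", p2 = "HHEEC"),
    rsa = list(m1 = c(0.1, 0.3, 0.5, 0.1, 0.9),
               m2 = c(0.1, 0.3, 0.5, 0.1, 0.9),
               p1 = c(0.1, 0.3, 0.5, 0.1, 0.9),
               p2 = c(0.1, 0.3, 0.5, 0.1, 0.9)),
    group = c(1, 1, 2, 2))
}
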