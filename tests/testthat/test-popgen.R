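# Microsatellite statistics: GenePop I/O, diversity, allelic richness,
# Weir-Cockerham theta, null alleles, HWE, Nei's Da / NJ, Mantel, AMOVA.

test_that("GenePop files parse allele pairs and missing codes", {
  f <- tempfile(fileext = ".gen")
  writeLines(c("toy file", "locA", "Pop",
               "p1 ,  001002", "p1 ,  000000", "p1 ,  003003"), f)
  tab <- readGenepop(f)
  expect_equal(lociNames(tab), "locA")
  g <- genotypeMatrix(tab, 1)
  expect_equal(g[1, ], c(1L, 2L))
  expect_true(all(is.na(g[2, ])))
  expect_equal(g[3, ], c(3L, 3L))
})

test_that("GenePop round trips preserve random tables in both dialects", {
  set.seed(31)
  for (digits in c(2, 3)) {
    pairs <- lapply(1:3, function(p) {
      m <- matrix(sample(1:9, 8 * 6, replace = TRUE), 8, 6)
      m[sample(48, 4)] <- NA
      m
    })
    tab <- makeGenotypeTable(pairs)
    f <- tempfile(fileext = ".gen")
    writeGenepop(tab, f, digits = digits)
    back <- readGenepop(f)
    expect_equal(lapply(back@genotypes, unname),
                 lapply(tab@genotypes, unname))
    expect_equal(back@loci, tab@loci)
  }
})

test_that("malformed GenePop rows fail with a line number", {
  f <- tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "locB", "Pop", "p1 , 001002"), f)
  expect_error(readGenepop(f), "line 5")
  f2 <- tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "Pop", "p1 , 001002", "p1 , 0102"), f2)
  expect_error(readGenepop(f2), "dialect")
})

test_that("diversity statistics match hand computations", {
  # {AA, AB, AB, BB, AB}: Ho = 3/5, p_A = 1/2, He = (10/9) * 0.5
  tab <- makeGenotypeTable(list(rbind(c(1, 1), c(1, 2), c(1, 2),
                                      c(2, 2), c(1, 2))))
  div <- diversityStats(tab)
  expect_equal(div$Ho, 0.6)
  expect_equal(div$HeRaw, 0.5)
  expect_equal(div$He, 10 / 9 * 0.5, tolerance = 1e-12)
  expect_equal(div$FIS, 1 - 0.6 / (10 / 9 * 0.5), tolerance = 1e-12)
  # all heterozygous
  allHet <- makeGenotypeTable(list(rbind(c(1, 2), c(1, 2), c(1, 2))))
  expect_equal(diversityStats(allHet)$Ho, 1)
  # monomorphic: Ho = He = 0, FIS undefined
  mono <- makeGenotypeTable(list(rbind(c(1, 1), c(1, 1))))
  dm <- diversityStats(mono)
  expect_equal(dm$Ho, 0); expect_equal(dm$He, 0); expect_true(is.na(dm$FIS))
})

test_that("unbiased He converges to 1 - sum(p^2) for large samples", {
  g <- sampleGenotypesFromFreqs(c(0.5, 0.3, 0.2), 1e4, seed = 2)
  tab <- makeGenotypeTable(list(g))
  div <- diversityStats(tab)
  expect_lt(abs(div$He - div$HeRaw), 1e-3)
  expect_lt(abs(div$He - (1 - sum(c(0.5, 0.3, 0.2)^2))), 0.02)
})

test_that("allelic richness: monomorphic = 1, g = n recovers the count, enumeration oracle", {
  mono <- makeGenotypeTable(list(rbind(c(1, 1), c(1, 1), c(1, 1))))
  expect_equal(allelicRichness(mono, g = 2)[1, 1], 1)
  tab <- makeGenotypeTable(list(rbind(c(1, 2), c(2, 3), c(3, 3), c(1, 4))))
  expect_equal(allelicRichness(tab, g = 4)[1, 1], 4) # observed allele count
  # 2n = 10 gene copies with counts {6, 4}, g = 2 (4 copies drawn):
  # exhaustive average of distinct alleles over all C(10, 4) subsets
  counts <- c(6, 4)
  copies <- rep(1:2, counts)
  subs <- combn(10, 4)
  oracle <- mean(apply(subs, 2, function(idx) length(unique(copies[idx]))))
  tab2 <- makeGenotypeTable(list(rbind(c(1, 1), c(1, 1), c(1, 1), c(2, 2),
                                       c(2, 2))))
  # pop has 5 individuals: counts 6 and 4, rarefy to g = 2 individuals
  expect_equal(allelicRichness(tab2, g = 2)[1, 1], oracle, tolerance = 1e-12)
  expect_error(allelicRichness(tab2, g = 6), "exceeds")
})

test_that("allelic richness is monotone in the rarefaction size", {
  g <- sampleGenotypesFromFreqs(c(0.4, 0.3, 0.2, 0.1), 30, seed = 3)
  tab <- makeGenotypeTable(list(g))
  ar <- vapply(1:30, function(gg) allelicRichness(tab, g = gg)[1, 1], 1)
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("theta is 1 for fixed differences and ~0 under panmixia", {
  fixed <- makeGenotypeTable(list(
    matrix(1L, 20, 2), matrix(2L, 20, 2)))
  expect_equal(pairwiseFst(fixed)$overall, 1)
  # two samples from identical frequencies
  p <- c(0.4, 0.3, 0.2, 0.1)
  same <- makeGenotypeTable(list(sampleGenotypesFromFreqs(p, 100, seed = 4),
                                 sampleGenotypesFromFreqs(p, 100, seed = 5)))
  expect_lt(abs(pairwiseFst(same)$overall), 0.02)
})

test_that("theta matches an independent variance-component transcription", {
  set.seed(6)
  pairs <- lapply(c(12, 20, 16), function(n)
    sampleGenotypesFromFreqs(runif(4), n, seed = n))
  tab <- makeGenotypeTable(pairs)
  got <- pairwiseFst(tab)$overall
  # independent oracle: Weir & Cockerham (1984) a, b, c computed directly
  r <- 3
  n <- vapply(pairs, nrow, 1)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(unlist(pairs)))
  A <- B <- C <- 0
  for (al in alleles) {
    p_i <- vapply(pairs, function(g) mean(g == al), 1)
    h_i <- vapply(pairs, function(g) mean((g[, 1] == al) != (g[, 2] == al)), 1)
    pbar <- sum(n * p_i) / sum(n)
    s2 <- sum(n * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h_i) / sum(n)
    A <- A + (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    hbar / 4) / (nbar - 1))
    B <- B + (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                      (2 * nbar - 1) / (4 * nbar) * hbar)
    C <- C + hbar / 2
  }
  expect_equal(got, A / (A + B + C), tolerance = 1e-12)
})

test_that("populations with no data are excluded from FST with a warning", {
  tab <- makeGenotypeTable(list(matrix(1L, 5, 2), matrix(2L, 5, 2),
                                matrix(NA_integer_, 3, 2)))
  expect_warning(out <- pairwiseFst(tab), "no genotypes")
  expect_equal(dim(out$pairwise), c(2L, 2L))
})

test_that("null-allele EM: near zero at HWE, recovers planted nulls, flags confounding", {
  # genotype counts exactly at Hardy-Weinberg proportions, no blanks
  g <- rbind(matrix(rep(c(1, 1), 36), ncol = 2, byrow = TRUE),
             matrix(rep(c(1, 2), 48), ncol = 2, byrow = TRUE),
             matrix(rep(c(2, 2), 16), ncol = 2, byrow = TRUE))
  em <- nullAlleleEM(makeGenotypeTable(list(g)), 1, 1)
  expect_lt(em$estimate, 1e-4)
  expect_true(em$converged)
  # planted null allele at frequency 0.15
  ests <- vapply(1:3, function(s) {
    set.seed(s)
    n <- 200
    pv <- c(0.35, 0.3, 0.2) # visible; null = 0.15
    al <- matrix(sample(4, 2 * n, replace = TRUE, prob = c(pv, 0.15)), n, 2)
    obs <- t(apply(al, 1, sort))
    obs[obs[, 1] == 4 & obs[, 2] == 4, ] <- NA       # null homozygote: blank
    hetNull <- obs[, 2] == 4 & !is.na(obs[, 2])
    obs[hetNull, 2] <- obs[hetNull, 1]               # appears homozygous
    nullAlleleEM(makeGenotypeTable(list(obs)), 1, 1)$estimate
  }, 1)
  expect_true(all(ests >= 0.08 & ests <= 0.22))
  # all-homozygote single-allele data: confounded, flagged, bounded
  conf <- nullAlleleEM(makeGenotypeTable(list(matrix(1L, 30, 2))), 1, 1)
  expect_true(conf$flagged)
  expect_lt(conf$estimate, 0.5)
})

test_that("HWE exact test: equilibrium counts accept, excess heterozygotes reject", {
  # 2-allele counts at Levene expectation
  hw <- rbind(matrix(rep(c(1, 1), 25), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 2), 50), ncol = 2, byrow = TRUE),
              matrix(rep(c(2, 2), 25), ncol = 2, byrow = TRUE))
  out <- hweTest(makeGenotypeTable(list(hw)), 1, 1)
  expect_equal(out$method, "enumeration")
  expect_gt(out$p, 0.5)
  # 20 individuals, all heterozygous: enumeration oracle computed directly
  allHet <- makeGenotypeTable(list(matrix(rep(c(1L, 2L), 20), ncol = 2,
                                          byrow = TRUE)))
  got <- hweTest(allHet, 1, 1)
  n <- 20; n1 <- 20; n2 <- 20
  hs <- seq(0, 20, by = 2)
  logP <- lfactorial(n) + lfactorial(n1) + lfactorial(n2) -
    lfactorial(2 * n) + hs * log(2) - lfactorial((n1 - hs) / 2) -
    lfactorial(hs) - lfactorial((n2 - hs) / 2)
  pOracle <- sum(exp(logP[logP <= logP[hs == 20] + 1e-9]))
  expect_equal(got$p, pOracle, tolerance = 1e-12)
  expect_lt(got$p, 0.01)
  # monomorphic convention
  expect_equal(hweTest(makeGenotypeTable(list(matrix(1L, 10, 2))), 1, 1)$p, 1)
  # multi-allelic Monte Carlo path is seeded and sane
  set.seed(7)
  g3 <- sampleGenotypesFromFreqs(c(0.5, 0.3, 0.2), 40, seed = 8)
  mc1 <- hweTest(makeGenotypeTable(list(g3)), 1, 1, mcIterations = 2000,
                 seed = 9)
  mc2 <- hweTest(makeGenotypeTable(list(g3)), 1, 1, mcIterations = 2000,
                 seed = 9)
  expect_equal(mc1$method, "monte-carlo")
  expect_identical(mc1$p, mc2$p)
  expect_gt(mc1$p, 0.05) # data were drawn under HWE
})

test_that("Bonferroni correction scales by the number of tests", {
  p <- matrix(c(0.01, 0.2, NA, 0.004), 2)
  out <- bonferroniCorrect(p)
  expect_equal(out[1, 1], 0.03)
  expect_equal(out[2, 2], 0.012)
  expect_equal(out[2, 1], 0.6)
  expect_true(is.na(out[1, 2]))
})

test_that("Nei's Da: zero for identical populations, one for fixed differences", {
  p <- c(0.6, 0.4)
  same <- makeGenotypeTable(list(sampleGenotypesFromFreqs(p, 50, seed = 10),
                                 sampleGenotypesFromFreqs(p, 50, seed = 10)))
  expect_equal(neiDa(same)[1, 2], 0, tolerance = 1e-12) # identical samples
  fixed <- makeGenotypeTable(list(matrix(1L, 10, 2), matrix(2L, 10, 2)))
  expect_equal(neiDa(fixed)[1, 2], 1)
})

test_that("NJ on four populations picks the split the four-point condition picks", {
  set.seed(11)
  # two similar pairs: (1,2) share frequencies, (3,4) share frequencies
  pA <- c(0.7, 0.2, 0.1); pB <- c(0.1, 0.2, 0.7)
  tab <- makeGenotypeTable(list(
    sampleGenotypesFromFreqs(pA, 40, seed = 1),
    sampleGenotypesFromFreqs(pA, 40, seed = 2),
    sampleGenotypesFromFreqs(pB, 40, seed = 3),
    sampleGenotypesFromFreqs(pB, 40, seed = 4)))
  d <- neiDa(tab)
  tree <- neiDaNJ(tab, bootstrap = 20, seed = 5)
  # four-point enumeration: the NJ split minimizes the paired sum
  sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  expect_equal(which.min(sums), 1L)
  split <- ape::prop.part(tree)
  # tree must contain the bipartition {pop1, pop2} | {pop3, pop4}
  tips <- tree$tip.label
  pairSets <- lapply(split, function(s) sort(tips[s]))
  expect_true(any(vapply(pairSets, function(s)
    identical(s, c("pop1", "pop2")) || identical(s, c("pop3", "pop4")),
    TRUE)))
  expect_error(neiDaNJ(makeGenotypeTable(list(matrix(1L, 4, 2),
                                              matrix(1L, 4, 2)))),
               "at least 3")
})

test_that("Mantel: exact correlations, degeneracy flag, vegan agreement", {
  set.seed(12)
  a <- as.matrix(dist(matrix(rnorm(20), 10)))
  expect_equal(mantelTest(a, a, permutations = 99)$r, 1)
  expect_equal(mantelTest(a, -a, permutations = 99,
                          alternative = "less")$r, -1)
  flat <- matrix(0, 5, 5)
  expect_true(mantelTest(flat, flat)$flagged)
  b <- as.matrix(dist(matrix(rnorm(20), 10)))
  ours <- mantelTest(a, b, permutations = 999, seed = 1)
  skip_if_not_installed("vegan")
  veg <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - veg$signif), 0.1)
})

test_that("Mantel p is stable under joint relabeling of both matrices", {
  set.seed(14)
  a <- as.matrix(dist(matrix(rnorm(16), 8)))
  b <- a + as.matrix(dist(matrix(rnorm(16), 8)))
  p1 <- mantelTest(a, b, permutations = 9999, seed = 2)$p
  perm <- sample(8)
  p2 <- mantelTest(a[perm, perm], b[perm, perm], permutations = 9999,
                   seed = 2)$p
  expect_lt(abs(p1 - p2), 0.05)
})

test_that("Mantel null p-values are uniform for independent matrices", {
  set.seed(15)
  ps <- vapply(1:100, function(i) {
    a <- as.matrix(dist(rnorm(10)))
    b <- as.matrix(dist(rnorm(10)))
    mantelTest(a, b, permutations = 199, seed = i,
               alternative = "greater")$p
  }, 1)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("AMOVA: fixed populations put ~100% among, identical data flag", {
  fixed <- makeGenotypeTable(list(matrix(1L, 15, 2), matrix(2L, 15, 2)))
  out <- amova(fixed, permutations = 99)
  expect_gt(out$components$pct[1], 99.9)
  expect_lt(out$p[["PhiST"]], 0.05)
  ident <- makeGenotypeTable(list(matrix(1L, 10, 2), matrix(1L, 10, 2)))
  expect_true(amova(ident, permutations = 0)$flagged)
})

test_that("AMOVA components equal a direct sums-of-squares transcription", {
  set.seed(16)
  pairs <- lapply(1:4, function(p)
    sampleGenotypesFromFreqs(runif(3) + (p > 2), 10 + 2 * p, seed = 20 + p))
  tab <- makeGenotypeTable(pairs)
  grouping <- setNames(c("G1", "G1", "G2", "G2"), popNames(tab))
  out <- amova(tab, grouping = grouping, permutations = 0)
  # naive oracle: pairwise allele-difference distances computed per pair
  G <- do.call(rbind, pairs)
  pops <- rep(1:4, vapply(pairs, nrow, 1))
  N <- nrow(G)
  dd <- matrix(0, N, N)
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    s <- 0
    ai <- G[i, 1:2]; aj <- G[j, 1:2]
    shared <- sum(pmin(table(factor(ai, levels = 1:4)),
                       table(factor(aj, levels = 1:4))))
    dd[i, j] <- dd[j, i] <- 2 - shared
  }
  ssTot <- sum(dd[upper.tri(dd)]) / N
  ssWP <- sum(vapply(1:4, function(p) {
    idx <- which(pops == p)
    sum(dd[idx, idx][upper.tri(dd[idx, idx])]) / length(idx)
  }, 1))
  grp <- c(1, 1, 2, 2)[pops]
  ssWG <- sum(vapply(1:2, function(g) {
    idx <- which(grp == g)
    sum(dd[idx, idx][upper.tri(dd[idx, idx])]) / length(idx)
  }, 1))
  ssAP <- ssWG - ssWP
  ssAG <- ssTot - ssWG
  expect_equal(out$components$SS, c(ssAG, ssAP, ssWP, ssTot),
               tolerance = 1e-10)
  expect_equal(sum(out$components$pct[1:3]), 100, tolerance = 1e-10)
})

test_that("singleton populations are dropped from AMOVA with a warning", {
  tab <- makeGenotypeTable(list(matrix(1L, 10, 2), matrix(2L, 10, 2),
                                matrix(1L, 1, 2)))
  expect_warning(out <- amova(tab, permutations = 0), "singleton")
  expect_equal(out$components$df[1], 1) # two populations remain
})

test_that("theta and AMOVA Phi-ST agree on balanced two-population data", {
  D <- matrix(c(0, 2, 2, 0), 2); dimnames(D) <- list(c("a", "b"), c("a", "b"))
  g <- simulateGenotypes(D, nLoci = 5, nAlleles = 6, Ne = 100, lambda = 1,
                         generations = 100, sampleSizes = 40,
                         missingRate = 0, seed = 17)
  theta <- pairwiseFst(g)$overall
  phi <- amova(g, permutations = 0)$phi[["PhiST"]]
  expect_lt(abs(theta - phi), 0.02)
})
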