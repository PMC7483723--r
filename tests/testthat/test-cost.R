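# Ecological costs and distances: scaling, per-cell costs, path sums and
# the origin-destination matrix.

test_that("min-max scaling maps values and intervals consistently", {
  v <- matrix(c(3, 5, 7), 3, 1, dimnames = list(NULL, "X"))
  sc <- scaleVariables(v)
  expect_equal(as.vector(sc$scaled), c(0, 0.5, 1))
  expect_equal(scaleInterval(c(5, 7), sc$anchors[, "X"]), c(0.5, 1))
  # anchors: every non-constant variable spans exactly [0, 1]
  net <- makeRandomTreeNetwork(50, seed = 2)
  sc2 <- scaleVariables(cellVariables(net))
  expect_equal(unname(apply(sc2$scaled, 2, min)), rep(0, 4))
  expect_equal(unname(apply(sc2$scaled, 2, max)), rep(1, 4))
  const <- matrix(c(1, 1, 1), 3, 1, dimnames = list(NULL, "C"))
  expect_warning(sc3 <- scaleVariables(const), "constant")
  expect_equal(as.vector(sc3$scaled), c(0, 0, 0))
})

test_that("per-variable cost is the distance to the closed interval", {
  expect_equal(variableCost(0.7, c(0.2, 0.5)), 0.2)
  expect_equal(variableCost(0.2, c(0.2, 0.5)), 0) # boundary inclusive
  expect_equal(variableCost(0.5, c(0.2, 0.5)), 0)
  expect_equal(variableCost(0, c(1, 1)), 1)       # maximal
  expect_equal(variableCost(c(0, 0.3, 0.9), c(0.25, 0.5)),
               c(0.25, 0, 0.4))
})

test_that("cell cost is the Euclidean point-to-box distance (clamping oracle)", {
  expect_equal(cellCost(c(0.3, 0.4, 0, 0)), 0.5) # 3-4-5
  expect_equal(cellCost(rep(0, 4)), 0)
  set.seed(13)
  for (i in 1:200) {
    x <- runif(4)
    lo <- runif(4); hi <- pmin(1, lo + runif(4))
    costs <- vapply(1:4, function(j) variableCost(x[j], c(lo[j], hi[j])), 1)
    clamped <- pmin(pmax(x, lo), hi) # nearest point inside the box
    expect_equal(cellCost(costs), sqrt(sum((x - clamped)^2)),
                 tolerance = 1e-14)
  }
})

test_that("the cost field obeys its bounds and zero-set characterization", {
  net <- makeRandomTreeNetwork(120, seed = 4)
  box <- apply(cellVariables(net), 2, quantile, probs = c(0.2, 0.7))
  cf <- costField(net, box)
  expect_true(all(cf@total >= 0))
  expect_true(all(cf@total <= sqrt(4)))
  inside <- rowSums(cf@costs) == 0
  expect_equal(cf@total == 0, inside)
  expect_true(any(inside) && any(!inside))
})

test_that("affine transforms of raw variables leave costs unchanged", {
  net <- makeRandomTreeNetwork(80, seed = 5)
  box <- apply(cellVariables(net), 2, quantile, probs = c(0.25, 0.75))
  cf1 <- costField(net, box)
  vars2 <- cellVariables(net)
  box2 <- box
  shifts <- c(10, -3, 100, 0.5); scales <- c(7, 0.2, 3, 40)
  for (j in 1:4) {
    vars2[, j] <- scales[j] * vars2[, j] + shifts[j]
    box2[, j] <- scales[j] * box2[, j] + shifts[j]
  }
  cf2 <- costField(setVariables(net, vars2), box2)
  expect_equal(cf1@total, cf2@total, tolerance = 1e-12)
  expect_equal(cf1@costs, cf2@costs, tolerance = 1e-12)
})

test_that("ecological distance sums path costs exactly once per cell", {
  # 3-cell chain with known costs
  net <- makeRandomTreeNetwork(3, seed = 1)
  net@downstream <- c(2L, 3L, NA_integer_)
  net@elevation <- c(3, 2, 1)
  cf <- costField(net, apply(cellVariables(net), 2, range)) # zero everywhere
  cf@total <- c(0.1, 0.2, 0.3)
  cf@costs <- matrix(cf@total / 2, 3, 4)                    # keep validity out
  expect_equal(as.numeric(ecologicalDistance(net, cf, 1, 3)), 0.6)
  expect_equal(as.numeric(ecologicalDistance(net, cf, 2, 2)), 0.2)
})

test_that("distances match a BFS path-sum oracle on random trees", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    net <- makeRandomTreeNetwork(150, seed = seed)
    box <- apply(cellVariables(net), 2, quantile, probs = c(0.3, 0.6))
    cf <- costField(net, box)
    g <- igraph::graph_from_edgelist(
      cbind(seq_len(149), net@downstream[1:149]), directed = FALSE)
    set.seed(seed)
    for (k in 1:6) {
      ab <- sample(150, 2)
      oracle <- sum(cf@total[as.integer(
        igraph::shortest_paths(g, ab[1], ab[2])$vpath[[1]])])
      expect_equal(as.numeric(ecologicalDistance(net, cf, ab[1], ab[2])),
                   oracle)
    }
  }
})

test_that("chain additivity holds: d(a,c) = d(a,b) + d(b,c) - cost(b)", {
  net <- makeRandomTreeNetwork(100, seed = 7)
  cf <- costField(net, apply(cellVariables(net), 2, quantile,
                             probs = c(0.4, 0.6)))
  set.seed(3)
  for (k in 1:10) {
    ac <- sample(100, 2)
    path <- pathBetween(net, ac[1], ac[2])
    b <- path[sample(length(path), 1)]
    dac <- as.numeric(ecologicalDistance(net, cf, ac[1], ac[2]))
    dab <- as.numeric(ecologicalDistance(net, cf, ac[1], b))
    dbc <- as.numeric(ecologicalDistance(net, cf, b, ac[2]))
    expect_equal(dac, dab + dbc - cf@total[b], tolerance = 1e-12)
  }
})

test_that("OD matrices are symmetric tree metrics with the right shape", {
  net <- makeRandomTreeNetwork(120, seed = 8)
  cf <- costField(net, apply(cellVariables(net), 2, quantile,
                             probs = c(0.3, 0.7)))
  sites <- setNames(sample(120, 12), paste0("s", 1:12))
  od <- odMatrix(net, cf, sites)
  d <- distanceMatrix(od)
  expect_equal(diag(d), setNames(rep(0, 12), paste0("s", 1:12)))
  expect_equal(d, t(d))
  expect_equal(sum(upper.tri(d)), 12 * 11 / 2)
  # entries agree with the single-pair computation
  for (k in 1:8) {
    ij <- sample(12, 2)
    expect_equal(d[ij[1], ij[2]],
                 as.numeric(ecologicalDistance(net, cf, sites[ij[1]],
                                               sites[ij[2]])))
  }
  # distance bounded by path length x sqrt(#variables)
  expect_true(all(d <= od@pathLength * sqrt(4) + 1e-12))
  # triangle inequality on a tree metric
  expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
})

test_that("an all-suitable network has zero distances everywhere", {
  net <- makeRandomTreeNetwork(60, seed = 9)
  cf <- costField(net, apply(cellVariables(net), 2, range)) # box = full range
  sites <- setNames(c(5L, 20L, 50L), c("a", "b", "c"))
  od <- odMatrix(net, cf, sites)
  expect_true(all(distanceMatrix(od) == 0))
})

test_that("cross-basin site pairs are missing, not infinite", {
  net <- extractNetwork(d8Flow(generateDEM(10, 10, method = "ramp")), 1)
  cf <- costField(setVariables(net, matrix(runif(400), 100, 4,
    dimnames = list(NULL, c("FFP", "RWQ", "ALT", "MMT")))),
    rbind(rep(0.4, 4), rep(0.6, 4)))
  sites <- setNames(c(1L, 95L), c("a", "b")) # different ramp columns
  od <- odMatrix(net, cf, sites)
  expect_true(is.na(distanceMatrix(od)["a", "b"]))
  expect_equal(diag(distanceMatrix(od)), c(a = 0, b = 0))
})

test_that("variable contributions equal an exhaustive per-cell recount", {
  net <- makeRandomTreeNetwork(90, seed = 10)
  cf <- costField(net, apply(cellVariables(net), 2, quantile,
                             probs = c(0.3, 0.7)))
  cells <- sample(90, 40)
  vc <- variableContribution(cf, cells)
  for (j in seq_len(ncol(cf@costs))) {
    cnt <- sum(vapply(cells, function(p) cf@costs[p, j] > 0, TRUE))
    expect_equal(vc$pctPositive[[j]], 100 * cnt / 40)
  }
  expect_equal(vc$meanCost, mean(cf@total[cells]))
  expect_error(variableContribution(cf, integer(0)), "empty")
})

test_that("suitable fractions: tau = 0 gives 100%, zero-cost gives 100%", {
  rs <- makeRiverscape(48, threshold = 20)
  net <- rs$network
  occ <- sampleOccurrences(net, apply(cellVariables(net), 2, quantile,
                                      probs = c(0.1, 0.8)),
                           80, prevalence = 0.5, detectionNoise = 0.05,
                           seed = 2)
  fit <- fitSuitability(occ, nTrees = 200, seed = 2)
  sf0 <- suitableFraction(net, fit, tau = 0)
  expect_equal(sf0[["model"]], 100)
  cfFree <- costField(net, apply(cellVariables(net), 2, range))
  expect_equal(suitableFraction(net, cf = cfFree)[["cost"]], 100)
})
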