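# Fixtures are built in code. Two kinds of networks are used throughout:
# "real" ones extracted from small synthetic DEMs, and hand-built trees
# whose topology is fully known so brute-force oracles are easy.

# a small fractal riverscape with variables attached
makeRiverscape <- function(n = 64, threshold = 25, demSeed = 1,
                           layerSeed = 2) {
  dem <- generateDEM(n, n, seed = demSeed)
  flow <- d8Flow(fillDepressions(dem))
  net <- extractNetwork(flow, threshold)
  env <- generateEnvLayers(flow, net, seed = layerSeed)
  list(dem = dem, flow = flow, network = env$network, layers = env$layers)
}

# random tree on n cells laid out as an n x 1 grid: cell i's downstream is a
# random higher-indexed cell (elevation decreases with index), cell n is the
# outlet; a known topology for path/catchment/distance oracles
makeRandomTreeNetwork <- function(n, seed = 1, nVars = 4) {
  n <- as.integer(n)
  set.seed(seed)
  downstream <- c(vapply(seq_len(n - 1), function(i)
    if (i == n - 1) n else sample((i + 1):n, 1), 1L), NA_integer_)
  acc <- rep(1, n)
  for (i in seq_len(n - 1)) acc[downstream[i]] <- acc[downstream[i]] + acc[i]
  vars <- matrix(runif(n * nVars), n, nVars,
                 dimnames = list(NULL, c("FFP", "RWQ", "ALT", "MMT")[seq_len(nVars)]))
  new("RiverNetwork", dims = c(n, 1L), cellSize = 100,
      cells = seq_len(n), downstream = downstream, accumulation = acc,
      elevation = as.numeric(n:1), variables = vars,
      siteIndex = setNames(integer(0), character(0)))
}

# hand-built Y-shaped network used for delineation tests:
#   T1 -> T2 -> M3 joins the main stem M1 -> ... -> M6 at M3;
#   siblings S1 -> J and S2 -> J, with J -> M5.
# positions: M1..M6 = 1..6, T1 = 7, T2 = 8, S1 = 9, S2 = 10, J = 11
makeYNetwork <- function() {
  downstream <- c(2L, 3L, 4L, 5L, 6L, NA_integer_, # M1..M6
                  8L, 3L,                          # T1 -> T2 -> M3
                  11L, 11L, 5L)                    # S1, S2 -> J -> M5
  # main stem carries more drainage than either tributary at its junctions
  acc <- c(3, 4, 7, 8, 12, 13, 1, 2, 1, 1, 3)
  elev <- c(60, 50, 40, 30, 20, 10, 80, 70, 80, 79, 25)
  new("RiverNetwork", dims = c(11L, 1L), cellSize = 100,
      cells = 1:11, downstream = downstream, accumulation = acc,
      elevation = elev,
      variables = matrix(0.5, 11, 1, dimnames = list(NULL, "V")),
      siteIndex = setNames(integer(0), character(0)))
}

# independent sink scan: interior data cells with no strictly lower
# 8-neighbour (the brute-force oracle for depression filling)
countSinks <- function(dem) {
  nr <- nrow(dem); nc <- ncol(dem)
  sinks <- 0L
  for (r in 2:(nr - 1)) {
    for (c in 2:(nc - 1)) {
      if (!is.finite(dem[r, c])) next
      nb <- c(dem[r - 1, c - 1], dem[r - 1, c], dem[r - 1, c + 1],
              dem[r, c - 1], dem[r, c + 1],
              dem[r + 1, c - 1], dem[r + 1, c], dem[r + 1, c + 1])
      if (!any(nb < dem[r, c], na.rm = TRUE)) sinks <- sinks + 1L
    }
  }
  sinks
}

# brute-force flow accumulation by memoised recursion over the children
# relation (independent of the high-to-low sweep in d8Flow)
recursiveAccumulation <- function(flow) {
  dirv <- as.vector(flow$dir)
  n <- length(dirv)
  children <- split(which(!is.na(dirv)), dirv[!is.na(dirv)])
  memo <- rep(NA_real_, n)
  rec <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    kids <- children[[as.character(i)]]
    val <- 1 + if (is.null(kids)) 0 else sum(vapply(kids, rec, 1))
    memo[i] <<- val
    val
  }
  acc <- flow$acc
  out <- acc
  for (i in which(is.finite(flow$dem))) out[i] <- rec(i)
  out
}

# genotype table built directly from per-population allele-pair lists;
# pairs is a list (per pop) of n x 2L integer matrices
makeGenotypeTable <- function(pairs, loci = NULL) {
  L <- ncol(pairs[[1]]) / 2
  new("GenotypeTable",
      loci = if (is.null(loci)) sprintf("L%d", seq_len(L)) else loci,
      pops = sprintf("pop%d", seq_along(pairs)),
      genotypes = lapply(pairs, function(m) {
        storage.mode(m) <- "integer"
        m
      }),
      trueFreqs = list())
}

# diploid genotypes drawn from explicit allele frequencies under HWE
sampleGenotypesFromFreqs <- function(freqs, n, seed = 1) {
  set.seed(seed)
  alleles <- sample(length(freqs), 2 * n, replace = TRUE, prob = freqs)
  t(apply(matrix(alleles, n, 2), 1, sort))
}
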