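## End-to-end orchestration on synthetic data: simulate a riverscape,
## extract the network, fit the habitat model, build the cost field and
## ecological distances, cluster populations, overlay protected areas,
## simulate genotypes and compute the population-genetic battery. Every
## random stage consumes its own sub-seed derived from the master seed, so
## a run is reproducible end to end.

#' Default pipeline configuration
#'
#' The defaults describe the emulated study system: a 100 m-resolution
#' mountain riverscape, four environmental variables, 274 survey sites at
#' prevalence 126/274, roughly half the landscape protected, and 23
#' populations genotyped at 5 microsatellite loci with 10-66 individuals
#' each. \code{gridShape} is kept modest so a full run stays interactive.
#'
#' @return nested configuration list; any entry can be overridden before
#'   passing to [runPipeline()].
#' @export
defaultConfig <- function() {
  list(
    seed = 1,
    riverscape = list(
      gridShape = c(96, 96), cellSize = 100, channelThreshold = 25,
      elevRange = c(3, 1420), roughness = 0.55, paCoverage = 0.5),
    occurrences = list(
      nSites = 274, prevalence = 126 / 274, detectionNoise = 0.05,
      trueSuitability = NULL),  # NULL: per-variable quantile box, see below
    suitabilityQuantiles = c(0.1, 0.8),
    model = list(nTrees = 5000, mtry = 2, gridSize = 100),
    populations = list(nPops = 23, nLoci = 5, nAlleles = 8, Ne = 100,
                       lambda = 0.5, migrationRate = 0.1, generations = 200,
                       missingRate = 0.01),
    clustering = list(k = "auto"),
    tests = list(mantelPermutations = 999, amovaPermutations = 99),
    outDir = NULL)
}

## deterministic sub-seeds, one per named stage
.stageSeed <- function(seed, stage) {
  offsets <- c(dem = 11L, landcover = 23L, layers = 37L, pa = 41L,
               occ = 53L, fit = 67L, geno = 79L, tests = 97L)
  (as.integer(seed) * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full fragmentation pipeline on synthetic data
#'
#' @param config a configuration list ([defaultConfig()]), or the path to a
#'   YAML file with the same structure (missing entries fall back to the
#'   defaults).
#' @return a report list: per-stage seeds, the suitability table
#'   (sampled/true/predicted range and overlap per variable), suitable
#'   network fractions, the cluster summary table, cost comparisons, and
#'   the population-genetic results (FST, Mantel, AMOVA, NJ tree as
#'   Newick). Written to \code{outDir} (JSON + Markdown + stage outputs)
#'   when configured.
#' @export
runPipeline <- function(config = defaultConfig()) {
  if (is.character(config)) config <- .mergeConfig(read_yaml(config))
  cfg <- config
  seed <- cfg$seed
  ## --- riverscape ---
  rs <- cfg$riverscape
  dem <- generateDEM(rs$gridShape[1], rs$gridShape[2], cellSize = rs$cellSize,
                     elevRange = rs$elevRange, roughness = rs$roughness,
                     seed = .stageSeed(seed, "dem"))
  flow <- d8Flow(fillDepressions(dem), cellSize = rs$cellSize)
  network <- extractNetwork(flow, rs$channelThreshold)
  env <- generateEnvLayers(flow, network, seed = .stageSeed(seed, "layers"))
  network <- env$network
  pa <- generateProtectedAreas(network, coverage = rs$paCoverage,
                               seed = .stageSeed(seed, "pa"))
  paFlags <- paOverlay(network, pa)
  ## --- occurrences ---
  oc <- cfg$occurrences
  box <- oc$trueSuitability
  if (is.null(box)) {
    q <- cfg$suitabilityQuantiles
    box <- apply(cellVariables(network), 2, quantile, probs = q)
  }
  box <- .asBox(box, colnames(cellVariables(network)))
  occ <- sampleOccurrences(network, box, oc$nSites, oc$prevalence,
                           oc$detectionNoise, paFlags = paFlags,
                           seed = .stageSeed(seed, "occ"))
  ## --- habitat model, cutoff, ranges ---
  md <- cfg$model
  fit <- fitSuitability(occ, nTrees = md$nTrees, mtry = md$mtry,
                        seed = .stageSeed(seed, "fit"))
  tau <- prevalenceCutoff(fit)
  vars <- fit@predictors
  curves <- lapply(setNames(vars, vars), responseCurve, fit = fit,
                   gridSize = md$gridSize)
  ranges <- sapply(vars, function(v)
    suppressWarnings(suitabilityRange(curves[[v]], tau)))
  observed <- sapply(vars, function(v) range(occ[[v]][occ$presence == 1]))
  suitTable <- data.frame(
    variable = vars,
    sampled_lo = apply(cellVariables(network), 2, min)[vars],
    sampled_hi = apply(cellVariables(network), 2, max)[vars],
    true_lo = box[1, vars], true_hi = box[2, vars],
    observed_lo = observed[1, ], observed_hi = observed[2, ],
    predicted_lo = ranges[1, ], predicted_hi = ranges[2, ],
    overlap_pct = vapply(vars, function(v)
      rangeOverlapPct(observed[, v], ranges[, v]), 1))
  ## --- cost field + ecological distances between populations ---
  cf <- costField(network, ranges)
  pres <- occ[occ$presence == 1, ]
  ## populations live on the largest connected drainage (one tree): distances
  ## across basins are undefined, so cross-basin presences are not candidates
  outlet <- vapply(pres$cell, function(s) {
    ch <- .chainToOutlet(network, s); ch[length(ch)]
  }, 1L)
  mainOutlet <- as.integer(names(which.max(table(outlet))))
  pres <- pres[outlet == mainOutlet, ]
  nPops <- min(cfg$populations$nPops, nrow(pres))
  popRows <- pres[order(pres$cell), ][unique(round(seq(1, nrow(pres),
                                                 length.out = nPops))), ]
  popSites <- setNames(popRows$cell, sprintf("P%02d", seq_len(nrow(popRows))))
  od <- odMatrix(network, cf, popSites)
  ## --- clustering + delineation + summary ---
  part <- wardCluster(od, k = cfg$clustering$k)
  assign <- clusterAssignment(part)
  clusterCells <- lapply(seq_len(part@k), function(ci)
    delineateClusterNetwork(network, popSites[assign == ci]))
  names(clusterCells) <- paste0("C", seq_len(part@k))
  connector <- connectorCells(network, popSites, assign, clusterCells)
  sumTab <- summaryTable(clusterCells, connector, cf, paFlags)
  allCells <- sort(unique(unlist(clusterCells)))
  costCmp <- if (length(allCells) && length(connector))
    compareCosts(cf@total[allCells], cf@total[connector]) else NULL
  paCmp <- if (any(paFlags) && any(!paFlags))
    compareCosts(cf@total[paFlags], cf@total[!paFlags]) else NULL
  suitPct <- suitableFraction(network, fit, tau, cf)
  ## --- genotypes + population genetics ---
  pg <- cfg$populations
  geno <- simulateGenotypes(od, nLoci = pg$nLoci, nAlleles = pg$nAlleles,
                            Ne = pg$Ne, lambda = pg$lambda,
                            migrationRate = pg$migrationRate,
                            generations = pg$generations,
                            missingRate = pg$missingRate,
                            seed = .stageSeed(seed, "geno"))
  fst <- pairwiseFst(geno)
  linFst <- fst$pairwise / (1 - fst$pairwise)
  diag(linFst) <- 0
  mant <- mantelTest(linFst, od@d[popNames(geno), popNames(geno)],
                     permutations = cfg$tests$mantelPermutations,
                     seed = .stageSeed(seed, "tests"))
  amv <- amova(geno, grouping = setNames(paste0("C", assign[popNames(geno)]),
                                         popNames(geno)),
               permutations = cfg$tests$amovaPermutations,
               seed = .stageSeed(seed, "tests"))
  treeNewick <- if (length(popNames(geno)) >= 3)
    write.tree(neiDaNJ(geno)) else NA_character_
  div <- diversityStats(geno)
  report <- list(
    seed = seed,
    stageSeeds = sapply(c("dem", "layers", "pa", "occ", "fit", "geno",
                          "tests"), function(s) .stageSeed(seed, s)),
    network = list(nCells = networkSize(network),
                   nOutlets = nOutlets(network),
                   threshold = rs$channelThreshold),
    model = list(oobError = fit@oobError, importance = fit@importance,
                 tau = as.numeric(tau),
                 observedPrevalence = attr(tau, "observedPrevalence"),
                 predictedPrevalence = attr(tau, "predictedPrevalence")),
    suitability = suitTable,
    suitableFraction = suitPct,
    nPopulations = length(popSites),
    k = part@k,
    clusterSummary = sumTab,
    costComparison = list(withinVsConnector = costCmp, paVsOutside = paCmp),
    popgen = list(overallFst = fst$overall,
                  fstRange = range(fst$pairwise[upper.tri(fst$pairwise)]),
                  meanHo = mean(div$Ho, na.rm = TRUE),
                  meanHe = mean(div$He, na.rm = TRUE),
                  mantel = mant[c("r", "p")],
                  amovaPctAmong = amv$components$pct[1],
                  amovaP = amv$p[["PhiST"]],
                  njTree = treeNewick))
  if (!is.null(cfg$outDir)) .writeReport(report, cfg, network, occ, od, geno)
  report
}

.mergeConfig <- function(user, base = defaultConfig()) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(user[[nm]], base[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

.writeReport <- function(report, cfg, network, occ, od, geno) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  write_json(report[setdiff(names(report), "clusterSummary")],
             file.path(cfg$outDir, "report.json"),
             auto_unbox = TRUE, digits = 10, force = TRUE)
  write.csv(report$clusterSummary,
            file.path(cfg$outDir, "cluster_summary.csv"), row.names = FALSE)
  write.csv(report$suitability,
            file.path(cfg$outDir, "suitability_ranges.csv"),
            row.names = FALSE)
  writeNetworkCSV(network, file.path(cfg$outDir, "network"))
  writeOccurrences(occ, file.path(cfg$outDir, "occurrences.csv"))
  writeOdMatrix(od, file.path(cfg$outDir, "od_matrix.csv"))
  writeGenepop(geno, file.path(cfg$outDir, "genotypes.gen"))
  md <- c(
    "# Riverscape fragmentation report", "",
    sprintf("- seed: %d", report$seed),
    sprintf("- network: %d channel cells, %d outlets (threshold %d)",
            report$network$nCells, report$network$nOutlets,
            report$network$threshold),
    sprintf("- model OOB error: %.1f%% (tau = %.3f)",
            100 * report$model$oobError[["overall"]], report$model$tau),
    sprintf("- suitable network: %.1f%% (model) / %.1f%% (zero cost)",
            report$suitableFraction[["model"]],
            report$suitableFraction[["cost"]]),
    sprintf("- %d populations in %d clusters", report$nPopulations,
            report$k),
    sprintf("- overall FST: %.3f; Mantel r = %.3f (p = %.4f)",
            report$popgen$overallFst, report$popgen$mantel$r,
            report$popgen$mantel$p),
    sprintf("- AMOVA: %.1f%% of variation among populations (p = %.3f)",
            report$popgen$amovaPctAmong, report$popgen$amovaP))
  writeLines(md, file.path(cfg$outDir, "report.md"))
  invisible(NULL)
}
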