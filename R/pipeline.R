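## End-to-end orchestration: simulated (or on-disk) inputs -> per-species
## trait estimates -> trait/climate table -> comparative statistics ->
## reproducible, hashed report.

pipelineLog <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(...))
}

# Extract species traits from simulated raw inputs with known truth.
simulateAndExtract <- function(cfg) {
  seed <- cfg$seed
  ## the two-subgenus sampling design has several species per subgenus
  ## (8 and 6 in the study); resample the tree deterministically until the
  ## root bipartition is comparably balanced, so the subgenus indicator is
  ## a usable covariate rather than a single-species dummy
  minClade <- max(2L, min(4L, cfg$nSpecies %/% 3L))
  tree <- NULL
  for (j in 0:50) {
    cand <- simulatePhylogeny(cfg$nSpecies, seed = childSeed(seed, 1 + j))
    split <- table(rootBipartition(cand))
    if (length(split) == 2L && min(split) >= minClade) {
      tree <- cand
      break
    }
  }
  stopIfNot(!is.null(tree), "could not simulate a balanced root split")
  climate <- simulateClimate(cfg$nSpecies, seed = childSeed(seed, 2))
  tr <- cfg$traits
  simP50 <- simulateTraitClimate(tree, climate, beta = tr$p50Beta,
                                 lambdaResid = tr$lambdaResid,
                                 sigma2 = tr$sigma2p50,
                                 seed = childSeed(seed, 3),
                                 traitName = "p50")
  simGmin <- simulateTraitClimate(tree, climate, beta = tr$gminBeta,
                                  lambdaResid = tr$lambdaResid,
                                  sigma2 = tr$sigma2gmin,
                                  seed = childSeed(seed, 4),
                                  traitName = "gmin")
  simTp <- simulateTraitClimate(tree, climate, beta = tr$tpBeta,
                                lambdaResid = tr$lambdaResid,
                                sigma2 = tr$sigma2tp,
                                seed = childSeed(seed, 5),
                                traitName = "tp")
  trueP50 <- traitData(simP50$table)$p50
  trueGmin <- traitData(simGmin$table)$gmin
  trueTp <- traitData(simTp$table)$tp
  pc1 <- simP50$truth$pc1
  op <- cfg$optical; co <- cfg$conductance
  ## keep truths inside the physically simulable ranges
  trueP50 <- pmin(pmax(trueP50, op$psiEnd + 0.8), op$psiStart - 0.8)
  tempRange <- range(co$temps)
  trueTp <- pmin(pmax(trueTp, tempRange[1] + 4), tempRange[2] - 5)
  trueGmin <- pmax(trueGmin, 0.5)
  outlierSpecies <- NA_character_
  if (isTRUE(tr$outlier)) {
    ## plant a low-gmin outlier at the coolest/wettest site (lowest PC1),
    ## where the model predicts the highest conductance
    k <- which.min(pc1)
    trueGmin[k] <- max(trueGmin[k] + tr$outlierDelta, 0.3)
    outlierSpecies <- tree$tip.label[k]
  }

  n <- cfg$nSpecies
  p50Est <- p50Se <- gminEst <- gminSe <- tpEst <- numeric(n)
  warningsList <- character(0)
  for (s in seq_len(n)) {
    reps <- numeric(op$nReplicates)
    for (r in seq_len(op$nReplicates)) {
      sim <- simulateDrydownImages(
        p50 = trueP50[s], slopeVc = op$slopeVc, height = op$height,
        width = op$width, nFrames = op$nFrames, psiStart = op$psiStart,
        psiEnd = op$psiEnd, noiseSd = op$noiseSd,
        shrinkEvents = op$shrinkEvents, nEvents = op$nEvents,
        sizeRange = op$sizeRange,
        seed = childSeed(seed, 1000 + s * 10 + r))
      reps[r] <- opticalP50(sim$stack, sim$trace,
                            diffThreshold = op$diffThreshold,
                            minEventPx = op$minEventPx)$p50
    }
    sp <- speciesP50(reps)
    p50Est[s] <- sp$mean; p50Se[s] <- sp$se

    pts <- list()
    g25 <- numeric(0)
    for (r in seq_len(co$nReplicates)) {
      sim <- simulateMassSeries(
        temps = co$temps, gminRef = trueGmin[s],
        slopeBelow = co$slopeBelow, slopeAbove = co$slopeAbove,
        tp = trueTp[s], rh = co$rh, leafArea = co$leafArea, sla = co$sla,
        initialStomatalG = co$initialStomatalG, closureTau = co$closureTau,
        duration = co$duration, dt = co$dt,
        noiseSdMass = co$noiseSdMass, patm = co$patm,
        seed = childSeed(seed, 5000 + s * 10 + r))
      for (ms in sim$series) {
        cp <- gminAtTemperature(ms, window = co$window, relTol = co$relTol,
                                doubleSided = co$doubleSided,
                                patm = co$patm)
        pts[[length(pts) + 1L]] <- cp
        if (abs(cp@temperature - min(co$temps)) < 1e-9)
          g25 <- c(g25, cp@gmin)
      }
    }
    gminEst[s] <- mean(g25)
    gminSe[s] <- if (length(g25) > 1) sd(g25) / sqrt(length(g25))
                 else NA_real_
    tpEst[s] <- phaseTransition(speciesTp(pts))
  }

  d <- data.frame(species = tree$tip.label,
                  subgenus = unname(rootBipartition(tree)),
                  p50 = p50Est, p50_se = p50Se,
                  gmin = gminEst, gmin_se = gminSe, tp = tpEst,
                  stringsAsFactors = FALSE)
  d <- cbind(d, climate)
  list(tree = tree, table = newTraitClimateTable(d),
       truth = list(p50 = trueP50, gmin = trueGmin, tp = trueTp,
                    pc1 = pc1, gminBeta = cfg$traits$gminBeta,
                    p50Beta = cfg$traits$p50Beta,
                    outlierSpecies = outlierSpecies),
       warnings = warningsList)
}

pglsSummaryDf <- function(fit) {
  ct <- coefTable(fit)
  ct$lambda <- fit@lambdaUsed
  ct$r_squared <- fit@rSquared
  ct
}

#' Run the full analysis pipeline
#'
#' With `simulate = TRUE` (the default), generates a phylogeny, climate
#' table and per-species raw inputs (image stacks with known P50; drydown
#' mass series with known g_min(T) and breakpoint), extracts the three
#' hydraulic traits exactly as for real data, and runs the comparative
#' stage: climate PCA, phylogenetic signal (K and lambda) for each trait
#' and PC1, PGLS of each trait against PC1 + subgenus, Cook's-distance
#' influence screening with a refit excluding flagged species for g_min,
#' a P50 regression against minimum temperature, and a Bonferroni
#' correction over the two-member P50 family. With `simulate = FALSE`, a
#' tree and a species-mean trait table are read from `inputs.tree` /
#' `inputs.table` and only the comparative stage runs.
#'
#' The report is deterministic given the config (including its seed); its
#' `hash` field is the MD5 of the numerical content.
#'
#' @param config a config list or YAML path (see [validateConfig()] and
#'   [defaultConfig()]).
#' @return A list of class `"hydrophyloReport"`: `configHash`, `version`,
#'   `table` (the assembled [TraitClimateTable-class]), `pca`, `signal`,
#'   `pgls`, `outliers`, `truth` (when simulated), `warnings`, `hash`.
#' @export
runPipeline <- function(config = NULL) {
  cfg <- validateConfig(config)
  warningsSeen <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warningsSeen <<- c(warningsSeen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  if (isTRUE(cfg$simulate)) {
    pipelineLog(cfg, "simulating raw inputs and extracting traits")
    ext <- collect(simulateAndExtract(cfg))
    tree <- ext$tree; table <- ext$table; truth <- ext$truth
  } else {
    pipelineLog(cfg, "reading tree and table from disk")
    tree <- readPhylogeny(cfg$inputs$tree)
    table <- readTraitClimateTable(cfg$inputs$table)
    truth <- NULL
  }
  d <- traitData(table)

  ## climate PCA and PC1 scores attached to the table
  climCols <- intersect(.CLIMATE_VARS, names(d))
  stopIfNot(length(climCols) >= 2, "need at least 2 climate columns")
  pca <- collect(climatePCA(d[, climCols, drop = FALSE]))
  d$pc1 <- pcaScores(pca)[, 1]
  table <- newTraitClimateTable(d)

  ## phylogenetic signal per trait and for PC1
  nPerm <- cfg$comparative$nPerm
  traitsAvail <- intersect(c("p50", "gmin", "tp"), names(d))
  signal <- list()
  for (i in seq_along(c(traitsAvail, "pc1"))) {
    nm <- c(traitsAvail, "pc1")[i]
    v <- setNames(d[[nm]], d$species)
    v <- v[!is.na(v)]
    signal[[nm]] <- collect(phyloSignal(
      if (length(v) < ape::Ntip(tree))
        ape::drop.tip(tree, setdiff(tree$tip.label, names(v))) else tree,
      v, nPerm = nPerm, seed = childSeed(cfg$seed, 7000 + i),
      traitName = nm))
  }

  ## PGLS of each trait against PC1 + subgenus
  pgls <- list()
  for (nm in traitsAvail)
    pgls[[nm]] <- collect(pglsFit(stats::as.formula(paste(nm,
      "~ pc1 + subgenus")), table, tree, lambda = "ML"))

  ## influence screening on the g_min model; refit without flagged species
  outliers <- list(flagged = character(0), cooksD = numeric(0),
                   refit = NULL)
  if ("gmin" %in% names(pgls)) {
    cd <- cooksD(pgls[["gmin"]])
    flagged <- influentialSpecies(pgls[["gmin"]],
                                  cutoff = cfg$comparative$cooksCutoff)
    outliers$flagged <- flagged
    outliers$cooksD <- cd
    if (length(flagged)) {
      keep <- d[!d$species %in% flagged, , drop = FALSE]
      ## dropping a flagged species can empty one subgenus; the indicator
      ## is then omitted from the refit
      refitForm <- if (length(unique(keep$subgenus)) > 1)
        gmin ~ pc1 + subgenus else gmin ~ pc1
      outliers$refit <- collect(pglsFit(refitForm,
        newTraitClimateTable(keep),
        ape::drop.tip(tree, flagged), lambda = "ML"))
    }
  }

  ## the second P50 analysis (vs minimum temperature) and the Bonferroni
  ## family over the two P50 climate regressions
  p50Family <- NULL
  if ("p50" %in% traitsAvail && "minT" %in% names(d)) {
    fitMinT <- collect(pglsFit(p50 ~ minT + subgenus, table, tree,
                               lambda = "ML"))
    pgls[["p50_minT"]] <- fitMinT
    pRaw <- c(pc1 = unname(pgls[["p50"]]@pValues["pc1"]),
              minT = unname(fitMinT@pValues["minT"]))
    p50Family <- data.frame(predictor = names(pRaw), p = pRaw,
                            p_bonferroni = bonferroniAdjust(pRaw, m = 2L),
                            row.names = NULL)
  }

  report <- list(
    configHash = attr(cfg, "hash"),
    version = as.character(packageVersion("hydrophylo")),
    table = table,
    pca = list(varExplained = varExplained(pca),
               loadings = pcaLoadings(pca)),
    signal = signal,
    pgls = pgls,
    p50Family = p50Family,
    outliers = outliers,
    truth = truth,
    warnings = warningsSeen)
  report$hash <- reportHash(report)
  class(report) <- c("hydrophyloReport", "list")
  if (!is.null(cfg$outDir)) writeReport(report, cfg$outDir)
  report
}

# Numerical content of a report, as a plain nested list of numbers; the
# basis of the reproducibility hash.
reportNumbers <- function(report) {
  d <- traitData(report$table)
  sig <- lapply(report$signal, function(s)
    list(k = s@k, pK = s@pK, lambda = s@lambdaHat, pLambda = s@pLambda))
  pg <- lapply(report$pgls, function(f)
    list(coef = as.list(f@coefficients), se = as.list(f@se),
         p = as.list(f@pValues), lambda = f@lambdaUsed, r2 = f@rSquared))
  list(traits = lapply(d[, vapply(d, is.numeric, logical(1)), drop = FALSE],
                       as.numeric),
       varExplained = report$pca$varExplained,
       signal = sig, pgls = pg,
       cooksD = as.list(report$outliers$cooksD),
       flagged = report$outliers$flagged)
}

#' Reproducibility hash of a pipeline report
#'
#' MD5 of the report's numerical content (trait estimates, PCA variance,
#' signal and PGLS statistics, influence diagnostics), serialized to 12
#' significant digits. Two runs with the same configuration produce the
#' same hash.
#'
#' @param report a `"hydrophyloReport"` from [runPipeline()].
#' @return Character MD5 hash.
#' @export
reportHash <- function(report) {
  configHash(reportNumbers(report))
}

#' Write a pipeline report to disk
#'
#' Writes `traits.csv` (the assembled species table), `pgls_<trait>.csv`
#' coefficient tables, `cooks_d.csv`, `pca.csv` and a machine-readable
#' `report.json` holding every scalar, into `dir`.
#'
#' @param report a `"hydrophyloReport"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(traitData(report$table), file.path(dir, "traits.csv"),
            row.names = FALSE)
  for (nm in names(report$pgls))
    write.csv(pglsSummaryDf(report$pgls[[nm]]),
              file.path(dir, paste0("pgls_", nm, ".csv")),
              row.names = FALSE)
  if (length(report$outliers$cooksD))
    write.csv(data.frame(species = names(report$outliers$cooksD),
                         cooks_d = unname(report$outliers$cooksD)),
              file.path(dir, "cooks_d.csv"), row.names = FALSE)
  write.csv(data.frame(component = seq_along(report$pca$varExplained),
                       var_explained_pct = report$pca$varExplained),
            file.path(dir, "pca.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(list(config_hash = report$configHash, version = report$version,
           hash = report$hash, warnings = report$warnings),
      reportNumbers(report)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
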