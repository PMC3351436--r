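.configError <- function(...) {
  stop(errorCondition(paste0(...), class = c("allodynConfigError", "error")))
}

.stageError <- function(stage, e) {
  stop(errorCondition(paste0("stage '", stage, "' failed: ",
                             conditionMessage(e)),
                      class = c("allodynStageError", "error"), stage = stage))
}

.runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) .stageError(stage, e))
}

.cfgGet <- function(cfg, path, default = NULL) {
  for (k in path) {
    if (is.null(cfg)) return(default)
    cfg <- cfg[[k]]
  }
  if (is.null(cfg)) default else cfg
}

#' Run the full apo/holo perturbation pipeline
#'
#' Executes every analysis stage whose inputs the config names (any subset
#' of: apo/holo trajectories, HSQC peak tables, relaxation tables, ePHOGSY
#' NOE/ROE tables), classifies each residue per stage, and builds the
#' cross-technique consensus: residues flagged by at least `consensus`
#' (default 2) independent stages. The report is a pure function of the
#' inputs and parameters -- no timestamps -- so a rerun is byte-identical.
#'
#' Config structure (YAML file or an equivalent nested list):
#' \preformatted{
#' range: [25, 155]            # required analysis window
#' trajectories:
#'   apo: apo.traj             # coord-table / PDB / DCD, see readTrajectory
#'   holo: holo.traj
#'   format: table             # optional (default auto)
#'   atom: CA                  # optional
#' fluctuation: {k: 1.0, minLen: 3}
#' strain: {cutoff: 8.0, window: 50, k: 1.0, minLen: 3}
#' peaks:
#'   apo: apo_hsqc.tsv
#'   holo: holo_hsqc.tsv
#'   alpha: 0.154
#'   cspK: 3
#'   upThr: 1.5
#'   downThr: 0.67
#' relaxation:
#'   apo: apo_relax.tsv
#'   holo: holo_relax.tsv
#'   exchangeK: 1.0
#'   deltaS2: 0.1              # |S2 change| that counts as a dynamics change
#' ephogsy:
#'   apoNoe: ..., apoRoe: ..., holoNoe: ..., holoRoe: ...
#'   changeFrac: 0.5
#' consensus: 2
#' }
#' Relative input paths are resolved against the config file's directory.
#'
#' @param config path to a YAML config file, or a nested list.
#' @param outDir optional output directory; when given, writes
#'   `report.json` plus per-stage TSV artifacts (matrices, profiles,
#'   per-residue tables).
#' @return a [PerturbationReport-class].
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfgDir <- "."
  if (is.character(config)) {
    if (!file.exists(config)) .configError("config file not found: ", config)
    cfgDir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .configError("config must be a file path or a list")
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else
    file.path(cfgDir, p)
  range <- as.numeric(.cfgGet(config, "range"))
  if (length(range) != 2L) .configError("config must state 'range: [first, last]'")

  hasTraj <- !is.null(.cfgGet(config, c("trajectories", "apo")))
  hasPeaks <- !is.null(.cfgGet(config, c("peaks", "apo")))
  hasRelax <- !is.null(.cfgGet(config, c("relaxation", "apo")))
  hasEphogsy <- !is.null(.cfgGet(config, c("ephogsy", "apoNoe")))
  if (!any(c(hasTraj, hasPeaks, hasRelax, hasEphogsy)))
    .configError("config names no inputs (trajectories / peaks / relaxation / ephogsy)")

  inputFiles <- character(0)
  stages <- character(0)
  params <- list(range = range)
  artifacts <- list()
  perResidue <- list()   # named list of data.frames keyed on residue

  if (hasTraj) {
    tcfg <- config$trajectories
    fmt <- .cfgGet(tcfg, "format", "auto")
    atom <- .cfgGet(tcfg, "atom", "CA")
    apoPath <- resolve(tcfg$apo); holoPath <- resolve(tcfg$holo)
    if (is.null(holoPath)) .configError("trajectories need both apo and holo")
    inputFiles <- c(inputFiles, apoPath, holoPath)
    k <- .cfgGet(config, c("fluctuation", "k"), 1)
    minLen <- .cfgGet(config, c("fluctuation", "minLen"), 3)
    cutoff <- .cfgGet(config, c("strain", "cutoff"), 8)
    window <- .cfgGet(config, c("strain", "window"), 50)
    ks <- .cfgGet(config, c("strain", "k"), 1)
    minLenS <- .cfgGet(config, c("strain", "minLen"), 3)
    params$fluctuation <- list(k = k, minLen = minLen)
    params$strain <- list(cutoff = cutoff, window = window, k = ks,
                          minLen = minLenS)
    df <- .runStage("fluctuation", {
      apo <- readTrajectory(apoPath, fmt, selection = atom)
      holo <- readTrajectory(holoPath, fmt, selection = atom)
      dfApo <- distanceFluctuation(apo, range)
      dfHolo <- distanceFluctuation(holo, range)
      diffM <- differenceMatrix(dfHolo, dfApo)
      list(apo = dfApo, holo = dfHolo, diff = diffM,
           regions = callPerturbedRegions(diffM, k = k, minLen = minLen),
           trajApo = apo, trajHolo = holo)
    })
    st <- .runStage("strain", {
      nmA <- neighborMap(df$trajApo, cutoff = cutoff, range = range)
      nmH <- neighborMap(df$trajHolo, cutoff = cutoff, range = range)
      pa <- averageStrainProfile(strainSeries(df$trajApo, nmA, window = window))
      ph <- averageStrainProfile(strainSeries(df$trajHolo, nmH, window = window))
      list(apo = pa, holo = ph,
           hotspots = strainHotspots(pa, ph, k = ks, minLen = minLenS))
    })
    stages <- c(stages, "fluctuation", "strain")
    ids <- residueIds(df$diff)
    inRegion <- function(calls, ids) {
      lab <- rep("none", length(ids))
      for (i in seq_len(nrow(calls)))
        lab[ids >= calls$first[i] & ids <= calls$last[i]] <- calls$direction[i]
      lab
    }
    perResidue$fluctuation <- data.frame(
      residue = ids, dfRegion = inRegion(df$regions, ids))
    perResidue$strain <- data.frame(
      residue = ids, strainRegion = inRegion(st$hotspots, ids))
    artifacts$dfApo <- df$apo; artifacts$dfHolo <- df$holo
    artifacts$dfDiff <- df$diff
    artifacts$dfRegions <- df$regions
    artifacts$strainApo <- st$apo; artifacts$strainHolo <- st$holo
    artifacts$strainHotspots <- st$hotspots
  }

  if (hasPeaks) {
    pcfg <- config$peaks
    apoPath <- resolve(pcfg$apo); holoPath <- resolve(pcfg$holo)
    if (is.null(holoPath)) .configError("peaks need both apo and holo")
    inputFiles <- c(inputFiles, apoPath, holoPath)
    alpha <- .cfgGet(pcfg, "alpha", 0.154)
    cspK <- .cfgGet(pcfg, "cspK", 3)
    upThr <- .cfgGet(pcfg, "upThr", 1.5)
    downThr <- .cfgGet(pcfg, "downThr", 0.67)
    params$peaks <- list(alpha = alpha, cspK = cspK, upThr = upThr,
                         downThr = downThr)
    res <- .runStage("csp", {
      apo <- readPeakTable(apoPath); holo <- readPeakTable(holoPath)
      cr <- cspSignificance(csp(apo, holo, alpha = alpha), k = cspK)
      ic <- intensityChange(apo, holo, upThr = upThr, downThr = downThr)
      list(csp = cr, intensity = ic)
    })
    stages <- c(stages, "csp", "intensity")
    bb <- !res$csp$sidechain
    perResidue$csp <- data.frame(residue = res$csp$residue[bb],
                                 cspFlag = res$csp$significant[bb])
    bbI <- !res$intensity$sidechain
    perResidue$intensity <- data.frame(residue = res$intensity$residue[bbI],
                                       intensityClass = res$intensity$class[bbI])
    artifacts$csp <- res$csp
    artifacts$intensity <- res$intensity
  }

  if (hasRelax) {
    rcfg <- config$relaxation
    apoPath <- resolve(rcfg$apo); holoPath <- resolve(rcfg$holo)
    if (is.null(holoPath)) .configError("relaxation needs both apo and holo")
    inputFiles <- c(inputFiles, apoPath, holoPath)
    exK <- .cfgGet(rcfg, "exchangeK", 1)
    dS2 <- .cfgGet(rcfg, "deltaS2", 0.1)
    params$relaxation <- list(exchangeK = exK, deltaS2 = dS2)
    rx <- .runStage("exchange", {
      apo <- readRelaxationTable(apoPath)
      holo <- readRelaxationTable(holoPath)
      list(apo = exchangeFlags(apo, k = exK),
           holo = exchangeFlags(holo, k = exK), dsApo = apo, dsHolo = holo)
    })
    mf <- .runStage("modelfree", {
      list(apo = fitDataset(rx$dsApo, range),
           holo = fitDataset(rx$dsHolo, range))
    })
    stages <- c(stages, "exchange", "modelfree")
    exA <- rx$apo[, c("residue", "flagged")]
    names(exA)[2] <- "exchangeApo"
    exH <- rx$holo[, c("residue", "flagged")]
    names(exH)[2] <- "exchangeHolo"
    ex <- merge(exA, exH, by = "residue", all = TRUE)
    ex$exchangeChanged <- !is.na(ex$exchangeApo) & !is.na(ex$exchangeHolo) &
      xor(ex$exchangeApo, ex$exchangeHolo)
    perResidue$exchange <- ex
    ra <- residueData(mf$apo)[, c("residue", "s2")]
    rh <- residueData(mf$holo)[, c("residue", "s2")]
    names(ra)[2] <- "s2Apo"; names(rh)[2] <- "s2Holo"
    ms <- merge(ra, rh, by = "residue", all = TRUE)
    dd <- ms$s2Holo - ms$s2Apo
    ms$deltaS2Class <- ifelse(is.na(dd), NA_character_,
                       ifelse(dd > dS2, "increased",
                       ifelse(dd < -dS2, "decreased", "unchanged")))
    perResidue$modelfree <- ms
    artifacts$exchangeApo <- rx$apo; artifacts$exchangeHolo <- rx$holo
    artifacts$modelfreeApo <- mf$apo; artifacts$modelfreeHolo <- mf$holo
  }

  if (hasEphogsy) {
    ecfg <- config$ephogsy
    paths <- vapply(c("apoNoe", "apoRoe", "holoNoe", "holoRoe"),
                    function(k) resolve(ecfg[[k]]), character(1))
    inputFiles <- c(inputFiles, paths)
    cf <- .cfgGet(ecfg, "changeFrac", 0.5)
    params$ephogsy <- list(changeFrac = cf)
    hy <- .runStage("hydration", {
      pts <- lapply(paths, readPeakTable)
      ephogsyClassify(pts[[1]], pts[[2]], pts[[3]], pts[[4]], changeFrac = cf)
    })
    stages <- c(stages, "hydration")
    perResidue$hydration <- data.frame(
      residue = hy$residue, hydrationChange = hy$noeChange | hy$roeChange)
    artifacts$hydration <- hy
  }

  # assemble per-residue table over the union of residues
  ids <- sort(unique(unlist(lapply(perResidue, `[[`, "residue"))))
  tab <- data.frame(residue = as.integer(ids))
  for (p in perResidue) tab <- merge(tab, p, by = "residue", all.x = TRUE)
  tab <- tab[order(tab$residue), , drop = FALSE]
  rownames(tab) <- NULL

  col <- function(nm) {
    x <- tab[[nm]]
    if (is.null(x)) rep(NA, nrow(tab)) else x
  }
  flagCols <- list(
    csp = function() col("cspFlag") %in% TRUE,
    intensity = function() col("intensityClass") %in%
      c("increased", "decreased", "appeared", "disappeared"),
    exchange = function() col("exchangeChanged") %in% TRUE,
    modelfree = function() col("deltaS2Class") %in% c("increased", "decreased"),
    fluctuation = function() col("dfRegion") %in% c("quenched", "enhanced"),
    strain = function() col("strainRegion") %in% c("quenched", "enhanced"),
    hydration = function() col("hydrationChange") %in% TRUE)
  nFlags <- rep(0L, nrow(tab))
  for (s in names(flagCols)) {
    if (!s %in% stages) next
    nFlags <- nFlags + as.integer(flagCols[[s]]())
  }
  tab$stagesFlagged <- nFlags
  consensusMin <- .cfgGet(config, "consensus", 2)
  params$stages <- stages
  params$consensusMin <- consensusMin
  consensus <- as.integer(tab$residue[nFlags >= consensusMin])

  prov <- list(
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(inputFiles)), basename(inputFiles))),
    package = "allodyn",
    version = as.character(utils::packageVersion("allodyn")))

  report <- new("PerturbationReport", residueTable = tab,
                consensus = consensus, parameters = params, provenance = prov)
  if (!is.null(outDir)) .writePipelineArtifacts(report, artifacts, outDir)
  report
}

.writePipelineArtifacts <- function(report, artifacts, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  w <- function(obj, name) {
    p <- file.path(outDir, name)
    if (is(obj, "DistanceFluctuation") || is(obj, "FluctuationDifference"))
      writeMatrixTSV(obj, p)
    else if (is(obj, "StrainProfile"))
      utils::write.table(
        data.frame(residue = residueIds(obj), strain = unname(values(obj))),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    else if (is(obj, "ModelFreeFit"))
      utils::write.table(residueData(obj), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    else if (is.data.frame(obj))
      utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  map <- c(dfApo = "df_apo.tsv", dfHolo = "df_holo.tsv", dfDiff = "df_diff.tsv",
           dfRegions = "df_regions.tsv", strainApo = "strain_apo.tsv",
           strainHolo = "strain_holo.tsv", strainHotspots = "strain_hotspots.tsv",
           csp = "csp.tsv", intensity = "intensity.tsv",
           exchangeApo = "exchange_apo.tsv", exchangeHolo = "exchange_holo.tsv",
           modelfreeApo = "modelfree_apo.tsv", modelfreeHolo = "modelfree_holo.tsv",
           hydration = "hydration.tsv")
  for (nm in names(artifacts)) if (nm %in% names(map)) w(artifacts[[nm]], map[nm])
  writePerturbationReport(report, file.path(outDir, "report.json"))
  invisible(outDir)
}

#' Serialize a perturbation report to JSON
#'
#' Versioned JSON with the per-residue table, consensus set, parameters and
#' provenance (input hashes, package version). Deliberately contains no
#' timestamp, so identical inputs give byte-identical files.
#'
#' @param report a [PerturbationReport-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePerturbationReport <- function(report, path) {
  stopifnot(is(report, "PerturbationReport"))
  writeReportJSON(list(
    schema_version = "1.0",
    parameters = report@parameters,
    provenance = report@provenance,
    consensus = report@consensus,
    residues = report@residueTable), path)
}

#' Attach region annotations to a report
#'
#' Maps residue ranges to labels (e.g. secondary-structure elements) and adds
#' an `annotation` column to the residue table. Overlapping ranges attach all
#' their labels, separated by `"; "`. An annotation table with zero rows
#' leaves the report unchanged.
#'
#' @param report a [PerturbationReport-class].
#' @param annotations path to a TSV with header columns `first`, `last`,
#'   `label`, or an equivalent data.frame.
#' @return the annotated [PerturbationReport-class].
#' @export
annotateRegions <- function(report, annotations) {
  stopifnot(is(report, "PerturbationReport"))
  ann <- if (is.character(annotations))
    utils::read.table(annotations, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else annotations
  if (!nrow(ann)) return(report)
  stopifnot(all(c("first", "last", "label") %in% names(ann)))
  tab <- report@residueTable
  lab <- vapply(tab$residue, function(r) {
    hit <- ann$label[ann$first <= r & ann$last >= r]
    paste(hit, collapse = "; ")
  }, character(1))
  tab$annotation <- lab
  report@residueTable <- tab
  report
}
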