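# End-to-end orchestration on synthetic or user-supplied ROI sessions.

#' AAL region labels and approximate network grouping
#'
#' The packaged region -> network map (TSV under `extdata/aal_rsn_map.tsv`)
#' assigns each of the 116 AAL anatomical labels to a resting-state-network
#' style group (Visual I/II/III, Auditory, Sensorymotor, DMN, Executive
#' Function, Limbic, Basal Ganglia, Cerebellum). The assignment is an
#' editable reporting approximation — the exact AAL-to-network lookup is a
#' modelling choice, not ground truth — and is used only for grouped
#' summaries.
#'
#' @return `aalRegionLabels`: character vector of 116 labels;
#'   `defaultRegionGrouping`: named character vector region -> network.
#' @export
defaultRegionGrouping <- function() {
  path <- system.file("extdata", "aal_rsn_map.tsv", package = "fractalBOLD",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$network, df$region)
}

#' @rdname defaultRegionGrouping
#' @export
aalRegionLabels <- function() {
  names(defaultRegionGrouping())
}

#' Build a validated pipeline run configuration
#'
#' Collects every tunable of the end-to-end run. The synthetic defaults
#' emulate the study structure: 116 AAL-labelled regions at TR = 1.8 s,
#' 60-trial sessions whose stimulus-locked 12 s windows concatenate to 400
#' frames per phase, resting sessions of 400 frames cut into 6-frame blocks
#' and shuffled, per-region Hurst targets of 0.9-1.2 at rest and 0.5-0.9
#' under task, and eight correlated region blocks (c = 0.6).
#'
#' @param outDir output directory (created if missing).
#' @param seed master integer seed; all stage randomness derives from it.
#' @param nSubjects number of synthetic subjects.
#' @param tods time-of-day labels.
#' @param tasks task labels (resting state is always added).
#' @param nRegions number of regions; 116 uses AAL labels.
#' @param nTrials,tr,window trial schedule and segmentation parameters.
#' @param dfaOrder DFA/DCCA detrending order m.
#' @param dccQ,dccS rho(q, s) parameters.
#' @param eigenCutoff,nClusters eigen-ensemble selection and clustering.
#' @param hurstRest,hurstTask per-region Hurst targets (recycled).
#' @param blocks,blockCorrelation correlated block structure (recycled).
#' @param restFrames resting session length before block shuffling.
#' @param restSegmentFrames block length of the shuffled-segment control.
#' @param scalogramRegion region index for the example scalogram.
#' @return a validated configuration list of class "fbRunConfig".
#' @export
runConfig <- function(outDir, seed = 1L, nSubjects = 3L,
                      tods = "morning", tasks = c("GLO", "SEM"),
                      nRegions = 116L, nTrials = 60L, tr = 1.8,
                      window = 12.0, dfaOrder = 2L, dccQ = 1, dccS = 10L,
                      eigenCutoff = 2.0, nClusters = 15L,
                      hurstRest = seq(0.9, 1.2, length.out = nRegions),
                      hurstTask = seq(0.5, 0.9, length.out = nRegions),
                      blocks = rep(seq_len(8L), length.out = nRegions),
                      blockCorrelation = 0.6,
                      restFrames = 400L, restSegmentFrames = 6L,
                      scalogramRegion = 1L) {
  nRegions <- as.integer(nRegions)
  labels <- if (nRegions == 116L) aalRegionLabels() else
    sprintf("ROI%03d", seq_len(nRegions))
  cfg <- list(outDir = outDir, seed = as.integer(seed),
              nSubjects = as.integer(nSubjects), tods = tods,
              tasks = tasks, nRegions = nRegions, regionLabels = labels,
              nTrials = as.integer(nTrials), tr = tr, window = window,
              dfaOrder = as.integer(dfaOrder), dccQ = dccQ,
              dccS = as.integer(dccS), eigenCutoff = eigenCutoff,
              nClusters = as.integer(nClusters),
              hurstRest = rep_len(hurstRest, nRegions),
              hurstTask = rep_len(hurstTask, nRegions),
              blocks = rep_len(as.integer(blocks), nRegions),
              blockCorrelation = blockCorrelation,
              restFrames = as.integer(restFrames),
              restSegmentFrames = as.integer(restSegmentFrames),
              scalogramRegion = as.integer(scalogramRegion))
  stopifnot(cfg$nSubjects >= 1L, cfg$nRegions >= 2L, cfg$tr > 0,
            cfg$window > 0, length(cfg$tasks) >= 1L)
  class(cfg) <- "fbRunConfig"
  cfg
}

writeTidyTSV <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- formatNum(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' Executes the complete workflow: simulate task and resting sessions,
#' segment task sessions into encoding/retrieval concatenations and build
#' shuffled-segment resting controls; estimate per-region H (DFA on
#' session-averaged fluctuation curves) and beta (session-averaged
#' periodograms); compute rho(q, s) matrices per session; derive the
#' per-region condition-difference profile against rest; pool, select
#' (lambda > cutoff), cluster and compare the eigenvalue ensemble; and
#' write every artefact, the serialised configuration and a stage manifest
#' to `config$outDir`. Identical configuration + seed gives byte-identical
#' numeric outputs.
#'
#' @param config a configuration from \code{\link{runConfig}}.
#' @return Invisibly, a list with the exponent table, difference profile,
#'   clustered ensemble, comparison table and output paths.
#' @export
runFullPipeline <- function(config) {
  stopifnot(inherits(config, "fbRunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  stamp <- function(stage, t0)
    manifest[[stage]] <<- list(seconds = round(as.numeric(
      difftime(Sys.time(), t0, units = "secs")), 3))

  t0 <- Sys.time()
  schedule <- generateEventSchedule(config$nTrials, config$tr,
                                    seed = childSeeds(config$seed, 1L))
  taskFrames <- requiredFrames(schedule, config$tr, config$window)
  grid <- expand.grid(subject = sprintf("sub%02d",
                                        seq_len(config$nSubjects)),
                      tod = config$tods, task = config$tasks,
                      stringsAsFactors = FALSE)
  restGrid <- expand.grid(subject = sprintf("sub%02d",
                                            seq_len(config$nSubjects)),
                          tod = config$tods, stringsAsFactors = FALSE)
  seeds <- childSeeds(config$seed + 1L, nrow(grid) + 2L * nrow(restGrid))

  sessions <- list()   # phase-preprocessed matrices with provenance
  for (i in seq_len(nrow(grid))) {
    spec <- surrogateSpec(
      nRegions = config$nRegions, nFrames = taskFrames, tr = config$tr,
      hurst = config$hurstTask, blocks = config$blocks,
      blockCorrelation = config$blockCorrelation,
      regionLabels = config$regionLabels, seed = seeds[i])
    raw <- generateROISurrogate(spec)
    for (ph in c("encoding", "retrieval")) {
      seg <- extractPhaseSegments(raw, schedule, ph, config$window)
      sessions[[length(sessions) + 1L]] <- list(
        x = seg, subject = grid$subject[i], tod = grid$tod[i],
        task = grid$task[i], phase = ph)
    }
  }
  for (i in seq_len(nrow(restGrid))) {
    spec <- surrogateSpec(
      nRegions = config$nRegions, nFrames = config$restFrames,
      tr = config$tr, hurst = config$hurstRest, blocks = config$blocks,
      blockCorrelation = config$blockCorrelation,
      regionLabels = config$regionLabels,
      seed = seeds[nrow(grid) + i])
    raw <- generateROISurrogate(spec)
    ctrl <- makeRestControl(raw, config$restSegmentFrames,
                            seed = seeds[nrow(grid) + nrow(restGrid) + i])
    sessions[[length(sessions) + 1L]] <- list(
      x = ctrl, subject = restGrid$subject[i], tod = restGrid$tod[i],
      task = "rest", phase = "rest")
  }
  stamp("simulate_segment", t0)

  # --- fractal exponents: session-averaged curves per (tod, task, phase)
  t0 <- Sys.time()
  meta <- do.call(rbind, lapply(sessions, function(s) data.frame(
    subject = s$subject, tod = s$tod, task = s$task, phase = s$phase,
    stringsAsFactors = FALSE)))
  condKey <- paste(meta$tod, meta$task, meta$phase, sep = "|")
  expRows <- list()
  for (ck in unique(condKey)) {
    members <- which(condKey == ck)
    n <- nFrames(sessions[[members[1L]]]$x)
    scales <- dfaScales(n)
    for (r in seq_len(config$nRegions)) {
      fcurves <- lapply(members, function(i)
        dfaFluctuation(boldValues(sessions[[i]]$x)[, r], scales,
                       config$dfaOrder))
      scurves <- lapply(members, function(i)
        psdCurve(boldValues(sessions[[i]]$x)[, r]))
      hf <- fitScaling(averageCurves(fcurves))
      bf <- fitScaling(averageCurves(scurves), psdFitRange(n))
      mm <- meta[members[1L], ]
      expRows[[length(expRows) + 1L]] <- data.frame(
        tod = mm$tod, task = mm$task, phase = mm$phase,
        region = config$regionLabels[r],
        H = hf@exponent, H_se = hf@stderr, H_r2 = hf@rSquared,
        beta = bf@exponent, beta_se = bf@stderr, beta_r2 = bf@rSquared,
        stringsAsFactors = FALSE)
    }
  }
  exponents <- do.call(rbind, expRows)
  writeTidyTSV(exponents, file.path(config$outDir, "exponents.tsv"))
  stamp("fractal_exponents", t0)

  # --- rho(q, s) matrices per session
  t0 <- Sys.time()
  dccs <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    dccs[[i]] <- correlationMatrix(
      s$x, "rho_q", q = config$dccQ, s = config$dccS, m = config$dfaOrder,
      provenance = c(subject = s$subject, tod = s$tod, task = s$task,
                     phase = s$phase))
    writeDCCMatrix(dccs[[i]], file.path(config$outDir, sprintf(
      "dcc_%s_%s_%s_%s.tsv", s$subject, s$tod, s$task, s$phase)))
  }
  stamp("dcc_matrices", t0)

  # --- condition-difference profile vs rest (subject/tod-averaged)
  t0 <- Sys.time()
  condOf <- ifelse(meta$task == "rest", "rest",
                   paste(meta$task, meta$phase, sep = "_"))
  meanMats <- lapply(split(seq_along(dccs), condOf),
                     function(ii) averageDCC(dccs[ii]))
  profile <- conditionDifferenceProfile(meanMats, "rest")
  writeTidyTSV(profile, file.path(config$outDir, "diff_profile.tsv"))
  stamp("difference_profile", t0)

  # --- ensemble eigenanalysis
  t0 <- Sys.time()
  ens <- eigenEnsemble(dccs, meta)
  ens <- selectLarge(ens, config$eigenCutoff)
  ens <- clusterEigenvectors(ens, config$nClusters)
  entries <- cbind(ensembleConfig(ens),
                   eigenvalue = eigenvalues(ens),
                   cluster = clusterLabels(ens))
  writeTidyTSV(entries, file.path(config$outDir, "eigen_entries.tsv"))
  for (pos in seq_along(clusterOrder(ens))) {
    cl <- clusterOrder(ens)[pos]
    al <- alignAndAverage(ens, cl)
    writeTidyTSV(data.frame(region = config$regionLabels,
                            mean = al$mean, se = al$se,
                            stringsAsFactors = FALSE),
                 file.path(config$outDir,
                           sprintf("aligned_cluster_%02d.tsv", pos)))
  }
  comparison <- compareClusteredEigenvalues(ens, "task")
  writeTidyTSV(comparison, file.path(config$outDir,
                                     "eigen_comparison.tsv"))
  jsonlite::write_json(comparison,
                       file.path(config$outDir, "eigen_comparison.json"),
                       dataframe = "rows", digits = NA)
  stamp("eigen_ensemble", t0)

  # --- example scalogram
  t0 <- Sys.time()
  sc <- waveletScalogram(
    boldValues(sessions[[1L]]$x)[, config$scalogramRegion])
  scdf <- data.frame(scale = rep(sc@scales, ncol(sc@amplitudes)),
                     position = rep(sc@positions, each = nrow(sc@amplitudes)),
                     amplitude = as.vector(sc@amplitudes))
  writeTidyTSV(scdf, file.path(config$outDir, "scalogram.tsv"))
  stamp("scalogram", t0)

  cfgOut <- config
  class(cfgOut) <- NULL
  jsonlite::write_json(cfgOut, file.path(config$outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(exponents = exponents, profile = profile, ensemble = ens,
                 comparison = comparison, outDir = config$outDir,
                 schedule = schedule))
}

#' Group per-region exponent estimates by network
#'
#' @param fits data.frame with columns `region`, `H` and `beta` (e.g. the
#'   exponents table of \code{\link{runFullPipeline}}, optionally
#'   pre-filtered to one condition).
#' @param grouping named character vector region -> group (default
#'   \code{\link{defaultRegionGrouping}}); regions without a mapping are
#'   grouped as "unassigned" with a warning.
#' @return data.frame with one row per group (map order preserved,
#'   "unassigned" last): n, mean and SD of H and beta.
#' @export
summarizeExponents <- function(fits, grouping = defaultRegionGrouping()) {
  stopifnot(all(c("region", "H", "beta") %in% names(fits)))
  g <- unname(grouping[fits$region])
  if (anyNA(g)) {
    warning("unmapped region(s) grouped as 'unassigned': ",
            paste(unique(fits$region[is.na(g)]), collapse = ", "))
    g[is.na(g)] <- "unassigned"
  }
  order <- unique(c(intersect(unique(unname(grouping)), unique(g)),
                    "unassigned"))
  order <- order[order %in% g]
  out <- lapply(order, function(grp) {
    sub <- fits[g == grp, , drop = FALSE]
    data.frame(group = grp, n = nrow(sub),
               H_mean = mean(sub$H), H_sd = sd(sub$H),
               beta_mean = mean(sub$beta), beta_sd = sd(sub$beta),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
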