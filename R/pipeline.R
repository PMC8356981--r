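# Pipeline orchestration: cohort -> construction schemes -> community
# detection -> null tests -> between-scan agreement -> consensus -> hub
# cartography -> reliability statistics -> pair ranking.

#' Build a grid-run configuration
#'
#' @param cohort list describing the cohort source. Synthetic (default):
#'   `list(type = "synthetic", nSubjects, nNodes, nModules, pIn, pOut,
#'   weightNoiseSd, rewireFraction)`; or `list(type = "manifest", path = ...)`
#'   pointing to a [writeCohort()] manifest (manifest cohorts carry a single
#'   matrix per session, so only the NS-based schemes A and D are available
#'   for them).
#' @param schemes scheme symbols/ids to run (default all seven).
#' @param algorithms hard algorithms to run (default the four multi-scale
#'   criteria plus the Newman baseline).
#' @param scales optional named numeric vector of per-algorithm scales.
#' @param nSurrogates surrogates per quality permutation test (the reference
#'   1000; the default 99 is a fast screening setting).
#' @param nBootstrap resamples for the between-scan NMI bootstrap.
#' @param nQualityGraphs how many subjects' session-1 graphs get a quality
#'   permutation test per pair (their median p is the pair's quality p).
#' @param referenceSparsity sparsity anchoring the thresholded schemes D-G:
#'   a numeric density, or `"auto"` to match the nine-metric OMST scheme's
#'   sparsity exactly. The default 0.15 keeps the thresholded graphs above the
#'   percolation threshold of the synthetic cohorts (at "auto" they sit at
#'   spanning-tree density and are almost surely disconnected, in which case
#'   the affected subject-sessions are dropped with a logged diagnostic).
#' @param zHub,pConnector hub-cartography thresholds.
#' @param seed master seed; every stage derives sub-seeds from it.
#' @param outDir artifact directory ("" disables artifact writing).
#' @return A [RunConfig-class].
#' @export
runConfig <- function(cohort = list(type = "synthetic", nSubjects = 20,
                                    nNodes = 40, nModules = 4, pIn = 0.8,
                                    pOut = 0.05, weightNoiseSd = 0.1,
                                    rewireFraction = 0.05),
                      schemes = schemeIds()$symbol,
                      algorithms = c("mscd_afg", "mscd_rb", "mscd_rn",
                                     "mscd_so", "newman"),
                      scales = numeric(0),
                      nSurrogates = 99L, nBootstrap = 199L,
                      nQualityGraphs = 1L, referenceSparsity = 0.15,
                      zHub = 2.5, pConnector = 0.30,
                      seed = 1L, outDir = "") {
  new("RunConfig", cohort = cohort, schemes = as.character(schemes),
      algorithms = as.character(algorithms), scales = scales,
      nSurrogates = as.integer(nSurrogates),
      nBootstrap = as.integer(nBootstrap),
      nQualityGraphs = as.integer(nQualityGraphs),
      referenceSparsity = referenceSparsity,
      zHub = zHub, pConnector = pConnector,
      seed = as.integer(seed), outDir = outDir)
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip losslessly through the file.
#'
#' @param path YAML file path.
#' @return `readRunConfig`: a [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  scales <- if (length(y$scales)) unlist(y$scales) else numeric(0)
  runConfig(cohort = y$cohort, schemes = y$schemes,
            algorithms = y$algorithms, scales = scales,
            nSurrogates = y$nSurrogates, nBootstrap = y$nBootstrap,
            nQualityGraphs = y$nQualityGraphs,
            referenceSparsity = y$referenceSparsity, zHub = y$zHub,
            pConnector = y$pConnector, seed = y$seed, outDir = y$outDir)
}

#' @rdname readRunConfig
#' @param config a [RunConfig-class].
#' @export
writeRunConfig <- function(config, path) {
  y <- list(cohort = config@cohort, schemes = config@schemes,
            algorithms = config@algorithms,
            scales = as.list(config@scales),
            nSurrogates = config@nSurrogates, nBootstrap = config@nBootstrap,
            nQualityGraphs = config@nQualityGraphs,
            referenceSparsity = config@referenceSparsity, zHub = config@zHub,
            pConnector = config@pConnector, seed = config@seed,
            outDir = config@outDir)
  yaml::write_yaml(y, path)
  invisible(path)
}

.loadCohort <- function(config) {
  ch <- config@cohort
  if (identical(ch$type, "manifest")) return(readCohort(ch$path))
  nModules <- if (is.null(ch$nModules)) 4 else ch$nModules
  sizes <- rep(ch$nNodes %/% nModules, nModules)
  sizes[nModules] <- sizes[nModules] + ch$nNodes - sum(sizes)
  testRetestCohort(
    nSubjects = ch$nSubjects, nNodes = ch$nNodes, moduleSizes = sizes,
    pIn = ch$pIn, pOut = ch$pOut,
    noise = sessionNoiseSpec(weightNoiseSd = ch$weightNoiseSd,
                             rewireFraction = ch$rewireFraction),
    seed = config@seed, withStacks = TRUE)
}

# all requested scheme outputs for one subject-session; scheme C is computed
# once; the thresholded schemes use `refSparsity` ("auto" = C's sparsity)
.applySchemes <- function(cohort, subject, session, schemes,
                          refSparsity = "auto", maxTrees = 10) {
  stack <- cohortStack(cohort, subject, session)
  ids <- vapply(schemes, .resolveScheme, character(1))
  out <- list()
  if (is.null(stack)) {
    W <- cohortGraph(cohort, subject, session)
    for (i in seq_along(ids)) {
      out[[schemes[i]]] <- switch(
        ids[i],
        "NS-OMST" = maxNormalize(omstFilter(W, maxTrees)@filtered),
        "NS-thr" = {
          if (identical(refSparsity, "auto"))
            stop("scheme NS-thr on a manifest cohort needs a numeric ",
                 "referenceSparsity")
          maxNormalize(thresholdToSparsity(W, refSparsity))
        },
        stop("scheme ", ids[i], " needs a metric stack; manifest cohorts ",
             "support schemes A and D only"))
    }
    return(out)
  }
  C <- NULL
  if ("9m-OMST" %in% ids ||
      (identical(refSparsity, "auto") &&
       any(!(ids %in% c("NS-OMST", "NS+FA-OMST"))))) {
    C <- maxNormalize(omstFilter(integrateMetrics(stack, metricNames()),
                                 maxTrees)@filtered)
  }
  spars <- if (identical(refSparsity, "auto")) sparsityOf(C)
           else as.numeric(refSparsity)
  for (i in seq_along(ids)) {
    out[[schemes[i]]] <- if (ids[i] == "9m-OMST") C
      else applyScheme(ids[i], stack, referenceSparsity = spars,
                       maxTrees = maxTrees)
  }
  out
}

.pairDir <- function(outDir, scheme, algorithm) {
  file.path(outDir, paste(gsub("[^A-Za-z0-9]+", "_", scheme), algorithm,
                          sep = "__"))
}

.writePairArtifacts <- function(dir, partitions, consensus, representative,
                                summaryRow) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  part <- do.call(rbind, lapply(names(partitions), function(s) {
    do.call(rbind, lapply(c("1", "2"), function(sess)
      data.frame(subject = s, session = sess,
                 node = seq_len(nNodes(partitions[[s]][[sess]])),
                 community = communityLabels(partitions[[s]][[sess]]))))
  }))
  write.table(part, file.path(dir, "partitions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeConnectomeMatrix(coProbabilities(consensus),
                        file.path(dir, "consensus_probabilities.tsv"),
                        labels = FALSE)
  writePartitionTable(representative, file.path(dir, "representative.tsv"))
  write.table(summaryRow, file.path(dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

.evaluatePair <- function(cohort, schemeGraphs, scheme, algorithm, config,
                          si, ai) {
  subjects <- subjectIds(cohort)
  scale <- if (algorithm %in% names(config@scales))
    config@scales[[algorithm]] else NULL
  partitions <- list()
  kept <- character(0)
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    # both sessions share the subject's detection seed so that identical
    # session graphs yield identical partitions (zero-noise determinism)
    p <- tryCatch(list(
      "1" = detectCommunities(schemeGraphs[[s]][["1"]], algorithm,
                              scale = scale,
                              seed = .subSeed(config@seed, si, ai, k)),
      "2" = detectCommunities(schemeGraphs[[s]][["2"]], algorithm,
                              scale = scale,
                              seed = .subSeed(config@seed, si, ai, k))),
      error = function(e) {
        message("  dropping subject ", s, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(p)) {
      partitions[[s]] <- list("1" = p[["1"]]$partition,
                              "2" = p[["2"]]$partition)
      kept <- c(kept, s)
    }
  }
  if (length(kept) < 2) stop("fewer than 2 subjects usable for this pair")

  # between-scan agreement + bootstrap p
  agr <- .groupAgreementPvalue(partitions, nResamples = config@nBootstrap,
                               seed = .subSeed(config@seed, si, ai, 3))

  # quality permutation test on the first nQualityGraphs subjects (session 1)
  nq <- min(config@nQualityGraphs, length(kept))
  qp <- vapply(seq_len(nq), function(k) {
    qualityPermutationTest(schemeGraphs[[kept[k]]][["1"]], algorithm,
                           scale = scale, nSurrogates = config@nSurrogates,
                           seed = .subSeed(config@seed, si, ai, 4, k))$pValue
  }, numeric(1))
  qualityP <- stats::median(qp)

  # consensus across subjects x sessions
  flat <- unlist(lapply(partitions, function(x) list(x[["1"]], x[["2"]])),
                 recursive = FALSE)
  consensus <- buildConsensusMatrix(flat)
  representative <- consensusPartition(consensus, algorithm, scale = scale,
                                       seed = .subSeed(config@seed, si, ai, 5))
  consSim <- consensusIndividualSimilarity(representative, flat)
  consSimPerSubject <- vapply(kept, function(s)
    mean(c(nmiHard(representative, partitions[[s]][["1"]]),
           nmiHard(representative, partitions[[s]][["2"]]))), numeric(1))

  # nodal modular metrics, ICC, hub agreement
  nNode <- nNodes(cohortGraph(cohort, kept[1], 1))
  Pmat <- list("1" = matrix(NA_real_, length(kept), nNode),
               "2" = matrix(NA_real_, length(kept), nNode))
  Zmat <- Pmat
  roles <- list()
  for (k in seq_along(kept)) {
    s <- kept[k]
    roles[[s]] <- list()
    for (sess in c("1", "2")) {
      g <- schemeGraphs[[s]][[sess]]
      part <- partitions[[s]][[sess]]
      P <- participationCoefficient(g, part)
      z <- withinModuleZscore(g, part)
      Pmat[[sess]][k, ] <- P
      Zmat[[sess]][k, ] <- z
      roles[[s]][[sess]] <- classifyHubs(P, z, config@zHub, config@pConnector)
    }
  }
  iccOf <- function(mats) {
    if (length(kept) < 3) return(NA_real_)
    mean(vapply(seq_len(nNode), function(i)
      iccTwoSession(cbind(mats[["1"]][, i], mats[["2"]][, i])), numeric(1)))
  }
  agrConn <- agreementIndex(roles, "connector")
  agrProv <- agreementIndex(roles, "provincial")

  betweenScanPerSubject <- vapply(kept, function(s)
    nmiHard(partitions[[s]][["1"]], partitions[[s]][["2"]]), numeric(1))

  summaryRow <- data.frame(
    scheme = scheme, algorithm = algorithm,
    nSubjects = length(kept),
    betweenScanNmi = agr$agreement, nmiP = agr$pValue,
    qualityP = qualityP,
    consensusSimilarity = consSim,
    iccP = iccOf(Pmat), iccZ = iccOf(Zmat),
    meanConnectorAgreement = mean(agrConn),
    meanProvincialAgreement = mean(agrProv),
    nConsistentConnectors = sum(agrConn == 1),
    nConsistentProvincials = sum(agrProv == 1),
    stringsAsFactors = FALSE)

  list(summary = summaryRow, partitions = partitions, consensus = consensus,
       representative = representative,
       perSubject = data.frame(scheme = scheme, algorithm = algorithm,
                               subject = kept,
                               betweenScanNmi = betweenScanPerSubject,
                               consensusSimilarity = consSimPerSubject,
                               stringsAsFactors = FALSE))
}

#' Run the full scheme-by-algorithm repeatability grid
#'
#' Orchestrates the whole analysis for every (graph-construction scheme,
#' community-detection algorithm) pair: per-subject per-session construction
#' and partitioning, quality permutation test, between-scan NMI with bootstrap
#' significance, consensus matrix with representative partition and
#' consensus-individual similarity, nodal P/z reliability (ICC), hub agreement
#' indices, two-way ANOVAs over the grid, and the final ranking. A failure in
#' one pair logs a diagnostic and skips that pair rather than aborting the
#' grid. With a non-empty `outDir` all artifacts are written as delimited
#' text, and pairs whose summary file already exists are skipped on rerun.
#'
#' @param config a [RunConfig-class] (see [runConfig()]).
#' @return list with `evaluations` (one row per pair), `ranking` (gated and
#'   ordered, see [rankPairs()]), `perSubject` (per-subject replicate values),
#'   `anovaNmi` and `anovaConsensus` (two-way ANOVA tables; NULL when fewer
#'   than 2 levels per factor), and `cohort`.
#' @export
runGrid <- function(config = runConfig()) {
  cohort <- .loadCohort(config)
  subjects <- subjectIds(cohort)
  hasOut <- nzchar(config@outDir)
  if (hasOut) dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)

  # construct every scheme's graphs once per subject-session
  message("constructing schemes for ", length(subjects), " subjects x 2 sessions")
  graphsByScheme <- lapply(config@schemes, function(sch) NULL)
  names(graphsByScheme) <- config@schemes
  for (s in subjects) {
    for (sess in c("1", "2")) {
      gs <- .applySchemes(cohort, s, sess, config@schemes,
                          refSparsity = config@referenceSparsity)
      for (sch in config@schemes) {
        graphsByScheme[[sch]][[s]][[sess]] <- gs[[sch]]
      }
    }
  }

  evaluations <- list(); perSubject <- list()
  for (si in seq_along(config@schemes)) {
    sch <- config@schemes[si]
    for (ai in seq_along(config@algorithms)) {
      algo <- config@algorithms[ai]
      pairId <- paste(sch, algo, sep = ":")
      pdir <- if (hasOut) .pairDir(config@outDir, sch, algo) else ""
      sfile <- file.path(pdir, "summary.tsv")
      if (hasOut && file.exists(sfile)) {
        message("pair ", pairId, ": found existing summary, skipping")
        evaluations[[pairId]] <- read.table(sfile, header = TRUE, sep = "\t",
                                            stringsAsFactors = FALSE)
        next
      }
      t0 <- Sys.time()
      res <- tryCatch(
        .evaluatePair(cohort, graphsByScheme[[sch]], sch, algo, config, si, ai),
        error = function(e) {
          message("pair ", pairId, " failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      message(sprintf("pair %s done in %.1fs (NMI %.3f, consensus %.3f)",
                      pairId, as.numeric(Sys.time() - t0, units = "secs"),
                      res$summary$betweenScanNmi,
                      res$summary$consensusSimilarity))
      evaluations[[pairId]] <- res$summary
      perSubject[[pairId]] <- res$perSubject
      if (hasOut)
        .writePairArtifacts(pdir, res$partitions, res$consensus,
                            res$representative, res$summary)
    }
  }
  if (length(evaluations) == 0) stop("every pair failed")
  evaluations <- do.call(rbind, evaluations)
  rownames(evaluations) <- NULL
  perSubject <- if (length(perSubject)) do.call(rbind, perSubject) else NULL
  if (!is.null(perSubject)) rownames(perSubject) <- NULL

  anovaOn <- function(col) {
    if (is.null(perSubject)) return(NULL)
    grid <- data.frame(scheme = perSubject$scheme,
                       algorithm = perSubject$algorithm,
                       response = perSubject[[col]])
    if (length(unique(grid$scheme)) < 2 ||
        length(unique(grid$algorithm)) < 2) return(NULL)
    tryCatch(anovaTwoWay(grid), error = function(e) NULL)
  }

  ranking <- rankPairs(evaluations)
  out <- list(evaluations = evaluations, ranking = ranking,
              perSubject = perSubject,
              anovaNmi = anovaOn("betweenScanNmi"),
              anovaConsensus = anovaOn("consensusSimilarity"),
              cohort = cohort)
  if (hasOut) {
    write.table(evaluations, file.path(config@outDir, "evaluations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ranking, file.path(config@outDir, "ranking.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeRunConfig(config, file.path(config@outDir, "config.yaml"))
  }
  out
}
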