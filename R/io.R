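# Plain-text input/output: square delimited matrices with an optional header
# row of node labels, node/community tables, and cohort manifests.

#' Read a connectome matrix from a delimited text file
#'
#' Accepts whitespace- or comma-delimited square numeric matrices, optionally
#' preceded by a single header row of node labels.
#'
#' @param path file path.
#' @return A [Connectome-class].
#' @export
readConnectomeMatrix <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  headerish <- any(is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), if (sep == ",") "," else "\\s+")[[1]]))))
  tab <- read.table(path, header = headerish, sep = sep,
                    check.names = FALSE, comment.char = "")
  labels <- if (headerish) colnames(tab) else NULL
  W <- as.matrix(tab)
  W <- (W + t(W)) / 2  # tolerate asymmetry from limited print precision
  diag(W) <- 0
  Connectome(W, labels)
}

#' Write a connectome matrix as delimited text
#'
#' @param x a [Connectome-class] or matrix.
#' @param path destination file.
#' @param labels logical, write the node labels as a header row.
#' @export
writeConnectomeMatrix <- function(x, path, labels = TRUE) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  if (labels && is(x, "Connectome")) colnames(W) <- nodeLabels(x)
  write.table(W, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = labels && is(x, "Connectome"))
  invisible(path)
}

#' Read / write a hard partition as a node,community table
#'
#' @param path file path of a two-column (node, community) table with header.
#' @return `readPartitionTable`: a [HardPartition-class].
#' @export
readPartitionTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  HardPartition(tab$community[order(tab$node)])
}

#' @rdname readPartitionTable
#' @param partition a [HardPartition-class].
#' @export
writePartitionTable <- function(partition, path) {
  tab <- data.frame(node = seq_len(nNodes(partition)),
                    community = communityLabels(partition))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to a directory with a manifest
#'
#' Writes every subject-session matrix as delimited text plus a tab-separated
#' manifest (`subject`, `session`, `path`, `ground_truth`) and, when present,
#' the ground-truth partitions.
#'
#' @param cohort a [Cohort-class].
#' @param dir destination directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in subjectIds(cohort)) {
    gtPath <- ""
    if (!is.null(cohort@groundTruth[[s]])) {
      gtPath <- file.path(dir, paste0(s, "_truth.tsv"))
      writePartitionTable(cohort@groundTruth[[s]], gtPath)
    }
    for (sess in c("1", "2")) {
      p <- file.path(dir, sprintf("%s_ses%s.tsv", s, sess))
      writeConnectomeMatrix(cohortGraph(cohort, s, sess), p)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, session = sess, path = basename(p),
        ground_truth = basename(gtPath), stringsAsFactors = FALSE)
    }
  }
  manifest <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest file
#'
#' @param manifestPath path to a manifest written by [writeCohort()] (paths in
#'   the manifest are resolved relative to its directory).
#' @return A [Cohort-class] (without metric stacks).
#' @export
readCohort <- function(manifestPath) {
  base <- dirname(manifestPath)
  man <- read.table(manifestPath, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  man$session <- as.character(man$session)
  subjects <- unique(man$subject)
  graphs <- list(); gt <- list()
  for (s in subjects) {
    rows <- man[man$subject == s, ]
    if (!all(c("1", "2") %in% rows$session))
      stop("subject ", s, " is missing a session in the manifest")
    graphs[[s]] <- list(
      "1" = readConnectomeMatrix(file.path(base, rows$path[rows$session == "1"])),
      "2" = readConnectomeMatrix(file.path(base, rows$path[rows$session == "2"])))
    gtFile <- rows$ground_truth[1]
    if (!is.na(gtFile) && nzchar(gtFile))
      gt[[s]] <- readPartitionTable(file.path(base, gtFile))
  }
  new("Cohort", subjects = subjects, graphs = graphs, stacks = list(),
      groundTruth = gt)
}
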