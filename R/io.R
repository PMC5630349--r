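# Delimited-text readers and writers for studies, matrices and
# BrainNet-compatible exports. All formats are plain text: regional
# time series and connectivity matrices as tab-separated tables, motion
# traces as the 6-column whitespace convention (3 translations in mm,
# 3 rotations in degrees), study manifests as TSV, ground truth as
# JSON.

#' Write a synthetic study to a directory
#'
#' Lays out per-subject time-series files (`timeseries/<id>.tsv`: one
#' header line of node labels, then one row per ROI), motion files
#' (`motion/<id>.txt`: 6 whitespace-delimited columns), a subjects
#' manifest (`subjects.tsv`: id, group, age, behavioural scores) and a
#' ground-truth sidecar (`ground_truth.json`: generator spec, true
#' edge lists, true nodal values).
#'
#' @param dataset a `connectome_dataset` from [simulate_study].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(dataset, dir) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  for (id in dataset$subjects$id) {
    ts <- dataset$timeseries[[id]]
    con <- file.path(dir, "timeseries", paste0(id, ".tsv"))
    writeLines(paste(ts$labels, collapse = "\t"), con)
    utils::write.table(ts$signal, con, append = TRUE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(format(dataset$motion[[id]], digits = 10),
                       file.path(dir, "motion", paste0(id, ".txt")),
                       sep = " ", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  manifest <- cbind(dataset$subjects,
                    dataset$behavior[, setdiff(names(dataset$behavior), "id"),
                                     drop = FALSE])
  utils::write.table(manifest, file.path(dir, "subjects.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- list(
    spec = unclass(dataset$spec),
    true_nodal_values = dataset$true_nodal_values,
    edges = lapply(dataset$true_graphs, function(g) {
      idx <- which(upper.tri(g) & g == 1)
      cbind(i = row(g)[idx], j = col(g)[idx])
    })
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_timeseries_file <- function(path, tr) {
  labels <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  mat <- as.matrix(utils::read.table(path, skip = 1, sep = "\t"))
  if (!is.numeric(mat))
    stop_input("non-numeric cells in time-series file ", path)
  dimnames(mat) <- NULL
  roi_ts(mat, tr = tr, labels = labels,
         id = sub("\\.tsv$", "", basename(path)))
}

read_motion_file <- function(path) {
  mat <- as.matrix(utils::read.table(path))
  if (ncol(mat) != 6)
    stop_input(sprintf("motion file %s has %d columns; expected 6", path,
                       ncol(mat)))
  if (!is.numeric(mat))
    stop_input("non-numeric cells in motion file ", path)
  dimnames(mat) <- list(NULL, c("x", "y", "z", "pitch", "roll", "yaw"))
  mat
}

#' Read a study directory
#'
#' Loads the manifest, per-subject time series and motion traces
#' written by [write_study] (or laid out in the same shape by hand),
#' validating that the subject sets match one-to-one and that every
#' motion file has the 6-column rigid-body format.
#'
#' @param dir study directory.
#' @param tr sampling interval in seconds.
#' @return A `connectome_dataset` (without true graphs unless the
#'   ground-truth sidecar is present).
#' @export
read_study <- function(dir, tr = 3) {
  manifest_path <- file.path(dir, "subjects.tsv")
  if (!file.exists(manifest_path))
    stop_input("no subjects.tsv manifest in ", dir)
  manifest <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  ts_files <- list.files(file.path(dir, "timeseries"), pattern = "\\.tsv$")
  ts_ids <- sub("\\.tsv$", "", ts_files)
  orphans <- setdiff(manifest$id, ts_ids)
  extras <- setdiff(ts_ids, manifest$id)
  if (length(orphans))
    stop_input("manifest subjects without time-series files: ",
               paste(orphans, collapse = ", "))
  if (length(extras))
    stop_input("time-series files without manifest rows: ",
               paste(extras, collapse = ", "))
  timeseries <- motion <- stats::setNames(vector("list", nrow(manifest)),
                                          manifest$id)
  for (id in manifest$id) {
    timeseries[[id]] <- read_timeseries_file(
      file.path(dir, "timeseries", paste0(id, ".tsv")), tr)
    mfile <- file.path(dir, "motion", paste0(id, ".txt"))
    if (file.exists(mfile)) motion[[id]] <- read_motion_file(mfile)
  }
  score_cols <- intersect(c("total", "attention", "motor", "nonplanning"),
                          names(manifest))
  behavior <- manifest[, c("id", score_cols), drop = FALSE]
  truth_path <- file.path(dir, "ground_truth.json")
  true_graphs <- NULL
  spec <- NULL
  true_nodal <- NULL
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    n_nodes <- truth$spec$n_nodes
    true_graphs <- lapply(truth$edges, function(e) {
      g <- matrix(0, n_nodes, n_nodes)
      e <- as.matrix(e)
      g[e] <- 1
      g + t(g)
    })
    spec <- do.call(ground_truth_spec, truth$spec[
      intersect(names(truth$spec), names(formals(ground_truth_spec)))])
    true_nodal <- truth$true_nodal_values
  }
  structure(
    list(subjects = manifest[, c("id", "group", "age")],
         timeseries = timeseries, motion = motion,
         true_graphs = true_graphs, behavior = behavior,
         true_nodal_values = true_nodal, spec = spec),
    class = "connectome_dataset"
  )
}

#' Write a connectivity matrix as delimited text
#'
#' @param z symmetric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(z, path) {
  utils::write.table(z, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write an edge list for a binary graph
#'
#' Tab-delimited `i j` pairs, 1-based node indices, upper triangle
#' only.
#'
#' @param adj binary adjacency matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(adj, path) {
  idx <- which(upper.tri(adj) & adj == 1)
  utils::write.table(data.frame(i = row(adj)[idx], j = col(adj)[idx]),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a graph in BrainNet Viewer text format
#'
#' Writes `<prefix>.node` (x y z colour size label, one row per node)
#' and `<prefix>.edge` (full adjacency matrix) for surface rendering.
#' Coordinates default to zeros when none are supplied.
#'
#' @param adj binary adjacency matrix.
#' @param prefix output path prefix.
#' @param coords optional `N x 3` coordinate matrix (mm).
#' @param labels optional node labels.
#' @param size per-node size column (defaults to degree).
#' @return `prefix`, invisibly.
#' @export
write_brainnet <- function(adj, prefix, coords = NULL, labels = NULL,
                           size = NULL) {
  n <- nrow(adj)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  if (is.null(size)) size <- rowSums(adj)
  node <- data.frame(coords[, 1], coords[, 2], coords[, 3],
                     colour = 1, size = size, label = labels)
  utils::write.table(node, paste0(prefix, ".node"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(adj, paste0(prefix, ".edge"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Load a region-label table
#'
#' Reads a tab-separated table with columns `index`, `name`,
#' `abbreviation`, `hemisphere` defining the network nodes. The
#' packaged default is the 90-region AAL cerebral parcellation.
#'
#' @param path table path; defaults to the packaged AAL-90 table.
#' @return Data frame with the four columns, indices contiguous from 1.
#' @export
region_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aal90_regions.tsv",
                        package = "rsconnectome")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("index", "name", "abbreviation", "hemisphere")
  if (!all(need %in% names(tab)))
    stop_input("region table must have columns: ",
               paste(need, collapse = ", "))
  if (!identical(as.integer(tab$index), seq_len(nrow(tab))))
    stop_input("region indices must be contiguous 1..N")
  if (anyDuplicated(tab$abbreviation))
    stop_input("region abbreviations must be unique")
  tab
}
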