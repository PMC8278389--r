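#' Read a dihedral time series from a COLVAR-style or CSV file
#'
#' Parses the whitespace-delimited COLVAR dialect written by common
#' biasing engines: the first non-empty line must be a header of the form
#' `#! FIELDS time tauA tauB ...` naming every column. Later `#!` comment
#' lines are ignored, except a second `#! FIELDS` line that changes the
#' column set, which is an error (a restarted run with a different layout
#' must not be silently concatenated). Plain CSV with a header row is
#' supported via `format = "csv"`.
#'
#' Angles are wrapped to `[-pi, pi)` on read. Rows containing
#' non-numeric entries are rejected with the offending line number rather
#' than silently dropped.
#'
#' @param path file path.
#' @param angle_columns character vector of column names holding torsional
#'   angles. For CSV input defaults to every column except `time`.
#' @param time_column optional name of the time column (default `"time"`
#'   when present).
#' @param bias_column optional name of the total-bias column (kJ/mol).
#' @param energy_columns optional named character vector with any of the
#'   names `solute`, `solvent`, `solute_solvent` mapping to file columns.
#' @param degrees logical; angles stored in degrees (converted on read).
#' @param format `"colvar"` (default) or `"csv"`.
#' @return a [dihedral_trajectory()].
#' @export
read_colvar <- function(path, angle_columns = NULL, time_column = NULL,
                        bias_column = NULL, energy_columns = NULL,
                        degrees = FALSE, format = c("colvar", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty input file: ", path)

  if (format == "colvar") {
    first <- trimws(lines[nonblank[1]])
    if (!startsWith(first, "#! FIELDS"))
      stop("not a COLVAR file: first non-empty line must start with '#! FIELDS'")
    fields <- strsplit(first, "[[:space:]]+")[[1]][-(1:2)]
    if (!length(fields)) stop("'#! FIELDS' header names no columns")
    body_idx <- nonblank[-1]
    is_comment <- startsWith(trimws(lines[body_idx]), "#!")
    later_fields <- grepl("^#![[:space:]]*FIELDS", trimws(lines[body_idx]))
    if (any(later_fields)) {
      redecl <- trimws(lines[body_idx[later_fields]])
      redecl_fields <- lapply(strsplit(redecl, "[[:space:]]+"),
                              function(x) x[-(1:2)])
      changed <- !vapply(redecl_fields, identical, logical(1), y = fields)
      if (any(changed))
        stop("'#! FIELDS' changes mid-file at line ",
             body_idx[later_fields][changed][1])
      is_comment[later_fields] <- TRUE
    }
    data_idx <- body_idx[!is_comment]
    if (!length(data_idx)) stop("COLVAR file has a header but no data rows")
    toks <- strsplit(trimws(lines[data_idx]), "[[:space:]]+")
    nf <- lengths(toks)
    if (any(nf != length(fields)))
      stop(sprintf("ragged row at line %d: %d fields, header declares %d",
                   data_idx[which(nf != length(fields))[1]],
                   nf[nf != length(fields)][1], length(fields)))
    raw <- suppressWarnings(
      matrix(as.numeric(unlist(toks)), ncol = length(fields), byrow = TRUE))
    if (anyNA(raw)) {
      bad <- which(apply(is.na(raw), 1, any))[1]
      stop(sprintf("non-numeric entry at line %d", data_idx[bad]))
    }
    colnames(raw) <- fields
    tab <- as.data.frame(raw)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE)
    fields <- names(tab)
    numeric_ok <- vapply(tab, is.numeric, logical(1))
    if (any(!numeric_ok))
      stop("non-numeric column(s) in CSV input: ",
           paste(fields[!numeric_ok], collapse = ", "))
  }

  need <- function(cols) {
    missing <- setdiff(cols, fields)
    if (length(missing))
      stop("column(s) not present in file header: ",
           paste(missing, collapse = ", "))
  }
  if (is.null(time_column) && "time" %in% fields) time_column <- "time"
  if (is.null(angle_columns))
    angle_columns <- setdiff(fields, c(time_column, bias_column,
                                       unname(energy_columns)))
  need(angle_columns)
  if (!is.null(time_column)) need(time_column)
  if (!is.null(bias_column)) need(bias_column)
  ecol <- function(key) {
    if (is.null(energy_columns) || !key %in% names(energy_columns)) return(NULL)
    need(energy_columns[[key]])
    tab[[energy_columns[[key]]]]
  }
  dihedral_trajectory(
    as.matrix(tab[angle_columns]),
    angle_names = angle_columns,
    time = if (!is.null(time_column)) tab[[time_column]] else NULL,
    bias = if (!is.null(bias_column)) tab[[bias_column]] else NULL,
    energy_solute = ecol("solute"),
    energy_solvent = ecol("solvent"),
    energy_solute_solvent = ecol("solute_solvent"),
    degrees = degrees)
}

#' Write a trajectory in the COLVAR dialect
#'
#' @param traj a [dihedral_trajectory()].
#' @param path output path.
#' @param bias_column,energy_prefix names used for the optional columns.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(traj, path, bias_column = "metad.bias",
                         energy_prefix = "ene") {
  assert_trajectory(traj)
  cols <- list()
  if (!is.null(traj$time)) cols$time <- traj$time
  for (j in seq_along(traj$angle_names))
    cols[[traj$angle_names[j]]] <- traj$angles[, j]
  if (!is.null(traj$bias)) cols[[bias_column]] <- traj$bias
  if (!is.null(traj$energy_solute))
    cols[[paste0(energy_prefix, ".solute")]] <- traj$energy_solute
  if (!is.null(traj$energy_solvent))
    cols[[paste0(energy_prefix, ".solvent")]] <- traj$energy_solvent
  if (!is.null(traj$energy_solute_solvent))
    cols[[paste0(energy_prefix, ".solute_solvent")]] <- traj$energy_solute_solvent
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(cols), collapse = " ")), con)
  m <- do.call(cbind, cols)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- fingerprint serialization -------------------------------------------

#' Write / read fingerprint sets as self-describing JSON text
#'
#' The on-disk format records the format version, the shared periodic bin
#' edges, the angle names, and per cluster the normalized per-angle
#' probabilities and nonzero-support masks. Probabilities are written at
#' full precision so that a read after write reproduces the set exactly.
#'
#' @param fingerprints a `fingerprint_set` (see [build_fingerprints()]).
#' @param path file path.
#' @return `read_fingerprints` returns a `fingerprint_set`;
#'   `write_fingerprints` returns `path` invisibly.
#' @export
write_fingerprints <- function(fingerprints, path) {
  if (!inherits(fingerprints, "fingerprint_set"))
    stop("expected a 'fingerprint_set' object")
  payload <- list(
    format = "torsmap-fingerprints",
    version = 1L,
    angle_names = fingerprints$angle_names,
    bin_edges = fingerprints$bin_edges,
    support_min_count = fingerprints$support_min_count,
    clusters = lapply(fingerprints$clusters, function(cl) {
      list(cluster_id = cl$cluster_id,
           n_frames = cl$n_frames,
           probs = cl$probs,         # n_bins x n_angles
           support = cl$support)
    }))
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyDataFrame = FALSE)
  if (!identical(payload$format, "torsmap-fingerprints"))
    stop("format error: not a torsmap fingerprint file")
  if (!identical(as.integer(payload$version), 1L))
    stop("format error: unsupported fingerprint file version ",
         payload$version)
  required <- c("angle_names", "bin_edges", "clusters")
  if (!all(required %in% names(payload)))
    stop("format error: missing field(s) ",
         paste(setdiff(required, names(payload)), collapse = ", "))
  angle_names <- as.character(payload$angle_names)
  bin_edges <- as.numeric(payload$bin_edges)
  as_mat <- function(x, mode) {
    m <- if (is.matrix(x)) x
    else if (is.list(x)) do.call(rbind, lapply(x, unlist))
    else matrix(x, ncol = 1L)
    storage.mode(m) <- mode
    m
  }
  clusters <- lapply(payload$clusters, function(cl) {
    probs <- as_mat(cl$probs, "double")
    support <- as_mat(cl$support, "logical")
    colnames(probs) <- colnames(support) <- angle_names
    sums <- colSums(probs)
    if (any(abs(sums - 1) > 1e-6))
      stop("format error: fingerprint probabilities do not sum to 1 for ",
           "cluster ", cl$cluster_id, " (max deviation ",
           format(max(abs(sums - 1))), ")")
    list(cluster_id = as.integer(cl$cluster_id),
         n_frames = as.integer(cl$n_frames),
         probs = probs, support = support)
  })
  new_fingerprint_set(clusters, bin_edges, angle_names,
                      support_min_count =
                        as.integer(payload$support_min_count %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- distance matrix container -------------------------------------------

#' Persist / load a pairwise distance matrix
#'
#' Distance matrices grow as O(N^2), so they are persisted in a compact
#' binary container (magic `TDMX`, version, N, a provenance string for the
#' weight vector, the full row-major double matrix, and a checksum that is
#' verified on read). [write_distance_text()] offers a plain three-column
#' text export (`i j d`, upper triangle) for interoperability.
#'
#' @param D a `distance_matrix` object (see [distance_matrix()]).
#' @param path file path.
#' @return `read_distance_matrix` returns a `distance_matrix`.
#' @export
write_distance_matrix <- function(D, path) {
  if (!inherits(D, "distance_matrix")) stop("expected a 'distance_matrix'")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TDMX"), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(as.integer(D$n_points), con, size = 4, endian = "little")
  id <- charToRaw(D$weight_vector_id %||% "")
  writeBin(length(id), con, size = 4, endian = "little")
  if (length(id)) writeBin(id, con)
  vals <- as.numeric(D$values)
  writeBin(sum(vals), con, size = 8, endian = "little")
  writeBin(vals, con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, "TDMX")) stop("format error: not a TDMX container")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (version != 1L) stop("format error: unsupported TDMX version ", version)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  idlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  id <- if (idlen > 0) rawToChar(readBin(con, "raw", idlen)) else ""
  checksum <- readBin(con, "double", 1, size = 8, endian = "little")
  vals <- readBin(con, "double", as.double(n) * n, size = 8,
                  endian = "little")
  if (length(vals) != n * n) stop("format error: truncated TDMX payload")
  # the sum is recomputed in the same order it was written, so any
  # payload corruption that survives must cancel below one ulp
  if (!identical(sum(vals), checksum))
    stop("checksum mismatch reading distance matrix: file is corrupt")
  new_distance_matrix(matrix(vals, n, n), weight_vector_id = id)
}

#' @rdname write_distance_matrix
#' @export
write_distance_text <- function(D, path) {
  if (!inherits(D, "distance_matrix")) stop("expected a 'distance_matrix'")
  ut <- which(upper.tri(D$values), arr.ind = TRUE)
  utils::write.table(
    data.frame(i = ut[, 1], j = ut[, 2], d = D$values[ut]),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

# ---- cluster result serialization ----------------------------------------

#' Write / read a clustering result as JSON
#'
#' @param model a `cluster_model` (see [density_peaks()]).
#' @param path file path.
#' @export
write_cluster_model <- function(model, path) {
  if (!inherits(model, "cluster_model")) stop("expected a 'cluster_model'")
  payload <- list(format = "torsmap-clusters", version = 1L,
                  d_c = model$d_c, rho = model$rho, delta = model$delta,
                  nearest_higher = model$nearest_higher,
                  centers = model$centers, labels = model$labels,
                  is_core = model$is_core)
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              na = "null"), path)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  if (!identical(payload$format, "torsmap-clusters"))
    stop("format error: not a torsmap cluster file")
  nh <- as.integer(payload$nearest_higher)
  structure(list(rho = as.integer(payload$rho),
                 delta = as.numeric(payload$delta),
                 nearest_higher = nh,
                 centers = as.integer(payload$centers),
                 labels = as.integer(payload$labels),
                 is_core = as.logical(payload$is_core),
                 d_c = as.numeric(payload$d_c)),
            class = "cluster_model")
}
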