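# Readers/writers for frame images (TIFF, one file per frame) and cell
# tables (frame / cell_id / mesh). The canonical on-disk table dialect is
# CSV with the mesh flattened as a JSON array of rows; a best-effort
# converter handles tables pickled by the original Python tooling.

#' Assemble a cell table from records
#'
#' @param frame,cell_id Integer vectors (non-negative); `(frame, cell_id)`
#'   must be unique.
#' @param mesh List of [cell_mesh()] objects (coercible matrices allowed).
#' @return A tibble with columns `frame`, `cell_id` and list-column `mesh`.
#' @export
cell_table <- function(frame, cell_id, mesh) {
  frame <- as.integer(frame); cell_id <- as.integer(cell_id)
  if (length(frame) != length(cell_id) || length(frame) != length(mesh)) {
    stop_validation("frame, cell_id and mesh must have equal length")
  }
  if (any(is.na(frame)) || any(frame < 0L) || any(is.na(cell_id)) || any(cell_id < 0L)) {
    stop_validation("frame and cell_id must be non-negative integers")
  }
  if (anyDuplicated(paste(frame, cell_id))) {
    stop_validation("duplicate (frame, cell_id) pairs in cell table")
  }
  mesh <- lapply(mesh, function(m) if (is_cell_mesh(m)) m else cell_mesh(m))
  tibble::tibble(frame = frame, cell_id = cell_id, mesh = mesh)
}

#' Read all TIFF frames from a directory
#'
#' Frames are ordered by lexicographic filename and indexed 0, 1, ...;
#' images are loaded losslessly (native integer values preserved).
#'
#' @param directory_path Directory containing one TIFF file per frame.
#' @return Named list of numeric matrices; names are frame indices as
#'   strings ("0", "1", ...), in filename order.
#' @export
read_image_frames <- function(directory_path) {
  if (!dir.exists(directory_path)) {
    stop_input(sprintf("image directory not found: %s", directory_path))
  }
  files <- sort(list.files(directory_path, pattern = "\\.tiff?$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) {
    stop_input(sprintf("no TIFF files in directory: %s", directory_path))
  }
  frames <- lapply(files, function(f) {
    img <- tryCatch(tiff::readTIFF(f, as.is = TRUE),
                    error = function(e) stop_format(
                      sprintf("cannot read TIFF file %s: %s", f, conditionMessage(e))))
    img <- as.matrix(img)
    if (!all(is.finite(img))) stop_format(sprintf("non-finite pixel values in %s", f))
    img
  })
  names(frames) <- as.character(seq_along(frames) - 1L)
  frames
}

#' Write frame images as one 16-bit TIFF per frame
#'
#' Pixel values are rounded and clamped to the 16-bit range; filenames are
#' `frame_0000.tif`, `frame_0001.tif`, ... so lexicographic order equals
#' frame order.
#'
#' @param frames List of numeric matrices (frame order).
#' @param directory_path Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_image_frames <- function(frames, directory_path) {
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    img <- pmin(pmax(round(frames[[i]]), 0), 65535)
    paths[i] <- file.path(directory_path, sprintf("frame_%04d.tif", i - 1L))
    tiff::writeTIFF(img / 65535, paths[i], bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(paths)
}

#' Read a cell table from CSV
#'
#' Expects columns `frame`, `cell_id`, `mesh` where `mesh` is a
#' JSON-encoded n x 4 array. Records whose mesh fails validation (too few
#' rows, non-finite values, self-intersecting outline) are dropped with a
#' warning; the drop count is attached as attribute `n_dropped`.
#'
#' @param path CSV file path.
#' @param one_based Subtract 1 from all mesh coordinates on import, for
#'   tables exported by 1-based tools.
#' @return A [cell_table()] tibble.
#' @export
read_cell_table <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop_input(sprintf("cell table not found: %s", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) stop_format(
                   sprintf("cannot parse %s as CSV: %s", path, conditionMessage(e))))
  req <- c("frame", "cell_id", "mesh")
  if (!all(req %in% names(df))) {
    stop_format(sprintf("unknown cell-table dialect in %s: need columns %s",
                        path, paste(req, collapse = ", ")))
  }
  if (anyDuplicated(paste(df$frame, df$cell_id))) {
    stop_validation(sprintf("duplicate (frame, cell_id) pairs in %s", path))
  }
  meshes <- vector("list", nrow(df))
  ok <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    m <- tryCatch({
      mm <- jsonlite::fromJSON(df$mesh[i])
      mm <- matrix(as.numeric(mm), ncol = ncol(mm))
      if (one_based) mm <- mm - 1
      cell_mesh(mm)
    }, error = function(e) NULL)
    if (!is.null(m)) { meshes[[i]] <- m; ok[i] <- TRUE }
  }
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    warn(sprintf("dropped %d record(s) with unparseable or invalid meshes from %s",
                 n_dropped, path))
  }
  out <- cell_table(df$frame[ok], df$cell_id[ok], meshes[ok])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a cell table to CSV
#'
#' @param records A [cell_table()] tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cell_table <- function(records, path) {
  mesh_json <- vapply(records$mesh, function(m) {
    as.character(jsonlite::toJSON(unclass(m)[, , drop = FALSE], digits = NA))
  }, character(1))
  df <- data.frame(frame = records$frame, cell_id = records$cell_id,
                   mesh = mesh_json, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Best-effort reader for pickled cell tables
#'
#' Converts a table pickled by the original Python tooling (pandas
#' DataFrame with columns `frame`, `cell_id`, `mesh`) to the canonical CSV
#' dialect by shelling out to a system `python` with pandas, then reads it
#' with [read_cell_table()]. Requires such a python on the PATH.
#'
#' @inheritParams read_cell_table
#' @return A [cell_table()] tibble.
#' @export
read_cell_table_pickle <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop_input(sprintf("cell table not found: %s", path))
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop_format("no python interpreter available to read pickled tables")
  tmp <- tempfile(fileext = ".csv")
  script <- paste(
    "import sys, json, pandas as pd",
    "df = pd.read_pickle(sys.argv[1])",
    "df = df[['frame', 'cell_id', 'mesh']].copy()",
    "df['mesh'] = df['mesh'].map(lambda m: json.dumps([[float(v) for v in row] for row in m]))",
    "df.to_csv(sys.argv[2], index=False)",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(script), shQuote(path), shQuote(tmp)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(tmp)) {
    stop_format(sprintf("failed to convert pickled table %s via python", path))
  }
  on.exit(unlink(tmp))
  read_cell_table(tmp, one_based = one_based)
}
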