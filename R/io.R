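#' Read a point cloud
#'
#' Reads LAS 1.2+ (uncompressed), PLY (ascii or binary little-endian) and
#' XYZ/CSV text point clouds. Coordinates are taken to be meters. A `tree_id`
#' extra dimension (LAS), `tree_id` vertex property (PLY) or fourth column
#' (text) is preserved as per-point labels; the LAS classification field is
#' deliberately ignored because its semantics differ by producer.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"las"`, `"laz"`, `"ply"`, `"xyz"`,
#'   `"csv"`. `"auto"` resolves from the file extension.
#' @return a [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "las", "laz", "ply",
                                              "xyz", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_point_cloud: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, las = "las", laz = "laz", ply = "ply",
                     xyz = "xyz", txt = "xyz", csv = "csv",
                     stop("read_point_cloud: cannot resolve format from ",
                          "extension '", ext, "'"))
  }
  cloud <- switch(format,
    las = read_las(path),
    laz = stop("read_point_cloud: LAZ (compressed LAS) is not supported; ",
               "decompress to LAS first"),
    ply = read_ply(path),
    xyz = read_xyz_text(path, sep = ""),
    csv = read_xyz_text(path, sep = ","))
  if (npoints(cloud) == 0L)
    stop("read_point_cloud: '", path, "' contains no points")
  cloud$source_id <- basename(path)
  cloud
}

#' Write a labeled point cloud
#'
#' Writes per-point tree assignments. LAS output carries the tree id as an
#' unsigned 16-bit extra dimension named `tree_id` (0 = noise); CSV output
#' has header `x,y,z,tree_id`.
#'
#' @param cloud a labeled [point_cloud()].
#' @param path output file path.
#' @param format `"las"`, `"csv"` or `"ply"`; `"auto"` resolves from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_labeled_cloud <- function(cloud, path,
                                format = c("auto", "las", "laz", "csv",
                                           "ply")) {
  format <- match.arg(format)
  if (is.null(cloud$labels))
    stop("write_labeled_cloud: cloud has no labels")
  if (max(c(0L, cloud$labels)) > 65535L)
    stop("write_labeled_cloud: more than 65535 trees cannot be stored in ",
         "an unsigned 16-bit tree_id")
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     las = "las", laz = "laz", csv = "csv", ply = "ply",
                     stop("write_labeled_cloud: cannot resolve format"))
  switch(format,
    las = write_las(cloud, path),
    laz = stop("write_labeled_cloud: LAZ output is not supported; ",
               "write LAS and compress externally"),
    csv = {
      df <- data.frame(x = cloud$coords[, 1], y = cloud$coords[, 2],
                       z = cloud$coords[, 3], tree_id = cloud$labels)
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    },
    ply = write_ply(cloud, path))
  invisible(path)
}

# text point clouds: whitespace- or comma-separated x y z [tree_id],
# header tolerated on input
read_xyz_text <- function(path, sep = "") {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop("read_point_cloud: '", path, "' is empty (no points)")
  has_header <- grepl("[A-Za-z]", first)
  df <- tryCatch(
    utils::read.table(path, header = has_header, sep = sep,
                      comment.char = "#", blank.lines.skip = TRUE),
    error = function(e) stop("read_point_cloud: malformed record in '",
                             path, "': ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("read_point_cloud: '", path, "' is empty")
  if (ncol(df) < 3L)
    stop("read_point_cloud: '", path, "' has fewer than 3 columns")
  for (j in 1:3) if (!is.numeric(df[[j]]))
    stop("read_point_cloud: non-numeric coordinate column in '", path, "'")
  labels <- if (ncol(df) >= 4L && is.numeric(df[[4]])) as.integer(df[[4]])
  point_cloud(as.matrix(df[, 1:3]), labels = labels)
}

#' Read a scanner trajectory
#'
#' Reads an ordered polyline from a CSV with columns x, y, z and optional t.
#' Row order is preserved.
#'
#' @param path CSV file path.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("read_trajectory: no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = has_header, sep = ",")
  if (nrow(df) < 3L)
    stop("read_trajectory: at least 3 positions are required, got ",
         nrow(df))
  ts <- if (ncol(df) >= 4L) as.numeric(df[[4]])
  trajectory(as.matrix(df[, 1:3]), timestamps = ts)
}

#' Write a stem map
#'
#' Writes detected tree locations as CSV `tree_id,x,y`.
#'
#' @param locations matrix or data frame with columns tree_id, x, y (e.g.
#'   `coef()` of a fitted segmentation).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stem_map <- function(locations, path) {
  df <- as.data.frame(locations)
  names(df)[1:3] <- c("tree_id", "x", "y")
  utils::write.csv(df[, 1:3], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a DTM as an ESRI ASCII raster
#'
#' @param dtm a `dtm_grid` from [build_dtm()].
#' @param path output file path.
#' @param nodata value written for empty cells (there are none after
#'   interpolation; the header field is still required).
#' @return `path`, invisibly.
#' @export
write_dtm_asc <- function(dtm, path, nodata = -9999) {
  stopifnot(inherits(dtm, "dtm_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nrow(dtm$z)),   # z is indexed [ix, iy]
    sprintf("nrows %d", ncol(dtm$z)),
    sprintf("xllcorner %.6f", dtm$origin[1]),
    sprintf("yllcorner %.6f", dtm$origin[2]),
    sprintf("cellsize %.6f", dtm$cell_size),
    sprintf("NODATA_value %s", format(nodata))), con)
  # ESRI ASCII rows run north to south: highest y row first
  z <- dtm$z
  z[is.na(z)] <- nodata
  for (iy in seq_len(ncol(z))) {
    row <- z[, ncol(z) - iy + 1L]
    writeLines(paste(format(row, trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}
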