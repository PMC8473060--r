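# PLY reader (ascii + binary_little_endian) and ascii writer.
# Only the "vertex" element is used; x/y/z are required, a scalar
# "tree_id" (or "label") property is read as labels if present.

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readLines(con, n = 1L) != "ply")
    stop("read_point_cloud: '", path, "' is not a PLY file")
  fmt <- NULL
  elements <- list() # each: list(name, count, props = data.frame(name, type))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("read_point_cloud: unterminated PLY header in '", path, "'")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element")
      elements[[length(elements) + 1L]] <-
        list(name = tok[2], count = as.integer(tok[3]),
             props = list())
    else if (tok[1] == "property") {
      if (tok[2] == "list")
        stop("read_point_cloud: PLY list properties are not supported ",
             "(element '", elements[[length(elements)]]$name, "')")
      el <- elements[[length(elements)]]
      el$props[[length(el$props) + 1L]] <- c(type = tok[2], name = tok[3])
      elements[[length(elements)]] <- el
    } else if (tok[1] == "end_header") break
  }
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("read_point_cloud: unsupported PLY format '", fmt, "'")
  vi <- which(vapply(elements, function(e) e$name == "vertex", logical(1)))
  if (length(vi) != 1L)
    stop("read_point_cloud: PLY file has no vertex element")

  read_element <- function(el, ascii) {
    types <- vapply(el$props, `[[`, "", "type")
    names_ <- vapply(el$props, `[[`, "", "name")
    if (ascii) {
      lines <- readLines(con, n = el$count)
      vals <- matrix(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))),
                     ncol = length(types), byrow = TRUE)
    } else {
      sizes <- unname(ply_type_size[types])
      if (anyNA(sizes))
        stop("read_point_cloud: unknown PLY property type")
      rec <- sum(sizes)
      buf <- readBin(con, raw(), n = rec * el$count)
      m <- matrix(buf, nrow = rec)
      vals <- matrix(NA_real_, nrow = el$count, ncol = length(types))
      off <- 0L
      for (j in seq_along(types)) {
        rows <- (off + 1L):(off + sizes[j])
        bytes <- as.vector(m[rows, , drop = FALSE])
        vals[, j] <- switch(types[j],
          float = , float32 = readBin(bytes, numeric(), el$count, size = 4,
                                      endian = "little"),
          double = , float64 = readBin(bytes, numeric(), el$count, size = 8,
                                       endian = "little"),
          char = , int8 = readBin(bytes, integer(), el$count, size = 1,
                                  signed = TRUE),
          uchar = , uint8 = readBin(bytes, integer(), el$count, size = 1,
                                    signed = FALSE),
          short = , int16 = readBin(bytes, integer(), el$count, size = 2,
                                    signed = TRUE, endian = "little"),
          ushort = , uint16 = readBin(bytes, integer(), el$count, size = 2,
                                      signed = FALSE, endian = "little"),
          readBin(bytes, integer(), el$count, size = 4, endian = "little"))
        off <- off + sizes[j]
      }
    }
    colnames(vals) <- names_
    vals
  }

  ascii <- fmt == "ascii"
  vals <- NULL
  for (k in seq_along(elements)) {
    v <- read_element(elements[[k]], ascii)
    if (k == vi) { vals <- v; if (!ascii) break } # later elements unused
  }
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(vals)))
    stop("read_point_cloud: PLY vertex element lacks x/y/z")
  lab_col <- intersect(c("tree_id", "label"), colnames(vals))
  labels <- if (length(lab_col)) as.integer(vals[, lab_col[1]])
  point_cloud(vals[, need, drop = FALSE], labels = labels)
}

write_ply <- function(cloud, path) {
  n <- npoints(cloud)
  has_lab <- !is.null(cloud$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property double x", "property double y", "property double z",
               if (has_lab) "property ushort tree_id",
               "end_header"), con)
  df <- as.data.frame(cloud$coords)
  if (has_lab) df$tree_id <- cloud$labels
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
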