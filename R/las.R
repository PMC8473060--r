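# Minimal LAS 1.2 reader/writer (uncompressed, point formats 0-3).
# The writer emits point format 0 records with a trailing unsigned 16-bit
# extra dimension named "tree_id", described by a standard Extra Bytes VLR
# (user id "LASF_Spec", record id 4), scale 0.001 m and offset at the floor
# of the cloud's min corner: millimeter precision covers the 1-3 cm relative
# accuracy of handheld scanners.

LAS_HEADER_SIZE <- 227L
LAS_EB_TYPE_U16 <- 3L # Extra Bytes data_type code for unsigned short

u16_raw <- function(v) {
  v <- as.integer(v)
  as.vector(rbind(as.raw(v %% 256L), as.raw(v %/% 256L)))
}
u32_raw <- function(v) {
  v <- as.numeric(v)
  b <- sapply(v, function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                      (x %/% 65536) %% 256,
                                      (x %/% 16777216) %% 256)))
  as.vector(b)
}
chr_raw <- function(s, width) {
  b <- charToRaw(s)
  c(b[seq_len(min(length(b), width))],
    raw(max(0L, width - length(b))))
}
# nul-terminated fixed-width string field
raw_str <- function(r) {
  z <- which(r == as.raw(0))
  if (length(z)) r <- r[seq_len(z[1] - 1L)]
  trimws(rawToChar(r))
}
read_u16 <- function(raws) as.integer(raws[1]) + 256L * as.integer(raws[2])
read_u32 <- function(raws) sum(as.numeric(raws) * 256^(0:3))

write_las <- function(cloud, path) {
  n <- npoints(cloud)
  xyz <- cloud$coords
  scale <- 0.001
  off <- if (n > 0) floor(apply(xyz, 2, min)) else c(0, 0, 0)
  xi <- as.integer(round((xyz[, 1] - off[1]) / scale))
  yi <- as.integer(round((xyz[, 2] - off[2]) / scale))
  zi <- as.integer(round((xyz[, 3] - off[3]) / scale))
  labels <- if (is.null(cloud$labels)) integer(n) else cloud$labels

  rec_len <- 22L # point format 0 (20 bytes) + uint16 tree_id
  # Extra Bytes VLR: 54-byte VLR header + one 192-byte descriptor
  vlr <- c(u16_raw(0L), chr_raw("LASF_Spec", 16L), u16_raw(4L),
           u16_raw(192L), chr_raw("extra bytes", 32L),
           u16_raw(0L),                      # reserved
           as.raw(LAS_EB_TYPE_U16), as.raw(0L),
           chr_raw("tree_id", 32L), raw(4L), # name, unused
           raw(24L * 5L),                    # no_data/min/max/scale/offset
           chr_raw("tree id (0 = noise)", 32L))
  offset_to_points <- LAS_HEADER_SIZE + length(vlr)

  header <- c(
    charToRaw("LASF"), u16_raw(0L), u16_raw(0L), raw(16L),
    as.raw(1L), as.raw(2L),                        # version 1.2
    chr_raw("stemseg", 32L), chr_raw("stemseg", 32L),
    u16_raw(1L), u16_raw(2026L),                   # day/year
    u16_raw(LAS_HEADER_SIZE), u32_raw(offset_to_points), u32_raw(1L),
    as.raw(0L), u16_raw(rec_len), u32_raw(n),
    u32_raw(c(n, 0, 0, 0, 0)),
    writeBin(c(scale, scale, scale, off,
               if (n > 0) max(xyz[, 1]) else 0, if (n > 0) min(xyz[, 1]) else 0,
               if (n > 0) max(xyz[, 2]) else 0, if (n > 0) min(xyz[, 2]) else 0,
               if (n > 0) max(xyz[, 3]) else 0, if (n > 0) min(xyz[, 3]) else 0),
             raw(), size = 8, endian = "little"))
  stopifnot(length(header) == LAS_HEADER_SIZE)

  rec <- matrix(as.raw(0), nrow = rec_len, ncol = n)
  rec[1:4, ] <- matrix(writeBin(xi, raw(), size = 4, endian = "little"), 4L)
  rec[5:8, ] <- matrix(writeBin(yi, raw(), size = 4, endian = "little"), 4L)
  rec[9:12, ] <- matrix(writeBin(zi, raw(), size = 4, endian = "little"), 4L)
  rec[15, ] <- as.raw(0x09)                        # return 1 of 1
  rec[21:22, ] <- matrix(u16_raw(labels), 2L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(vlr, con)
  writeBin(as.vector(rec), con)
  invisible(path)
}

read_las <- function(path) {
  raw_all <- readBin(path, raw(), n = file.info(path)$size)
  if (length(raw_all) < LAS_HEADER_SIZE ||
      rawToChar(raw_all[1:4]) != "LASF")
    stop("read_point_cloud: '", path, "' is not a LAS file (bad signature)")
  ver <- as.integer(raw_all[25:26])
  offset_to_points <- read_u32(raw_all[97:100])
  n_vlr <- read_u32(raw_all[101:104])
  pt_format <- as.integer(raw_all[105])
  if (pt_format >= 128L)
    stop("read_point_cloud: '", path, "' is LAZ-compressed; not supported")
  rec_len <- read_u16(raw_all[106:107])
  n <- read_u32(raw_all[108:111])
  header_size <- read_u16(raw_all[95:96])
  scales <- readBin(raw_all[132:155], double(), n = 3, endian = "little")
  offs <- readBin(raw_all[156:179], double(), n = 3, endian = "little")

  base_len <- switch(as.character(pt_format),
                     "0" = 20L, "1" = 28L, "2" = 26L, "3" = 34L,
                     stop("read_point_cloud: unsupported LAS point format ",
                          pt_format))
  if (rec_len < base_len)
    stop("read_point_cloud: corrupt LAS record length in '", path, "'")

  # scan VLRs for an Extra Bytes descriptor named tree_id
  tree_id_offset <- NA_integer_ # byte offset of tree_id within extra bytes
  pos <- header_size
  for (v in seq_len(n_vlr)) {
    if (pos + 54L > length(raw_all)) break
    uid <- raw_str(raw_all[(pos + 3L):(pos + 18L)])
    rid <- read_u16(raw_all[(pos + 19L):(pos + 20L)])
    rlen <- read_u16(raw_all[(pos + 21L):(pos + 22L)])
    body <- if (rlen > 0L) raw_all[(pos + 55L):(pos + 54L + rlen)]
            else raw(0)
    if (uid == "LASF_Spec" && rid == 4L) {
      eb_off <- 0L
      for (k in seq_len(rlen %/% 192L)) {
        d <- body[((k - 1L) * 192L + 1L):(k * 192L)]
        dtype <- as.integer(d[3])
        nm <- raw_str(d[5:36])
        sz <- c(1L, 1L, 2L, 2L, 4L, 4L, 8L, 8L, 4L, 8L)[dtype]
        if (nm == "tree_id" && dtype == LAS_EB_TYPE_U16)
          tree_id_offset <- eb_off
        eb_off <- eb_off + sz
      }
    }
    pos <- pos + 54L + rlen
  }

  if (n == 0L) return(point_cloud(matrix(numeric(0), 0, 3)))
  pts <- raw_all[(offset_to_points + 1L):(offset_to_points + n * rec_len)]
  if (length(pts) < n * rec_len)
    stop("read_point_cloud: truncated LAS point data in '", path, "' ",
         "(record count ", n, " not present)")
  m <- matrix(pts, nrow = rec_len)
  int_of <- function(rows)
    readBin(as.vector(m[rows, ]), integer(), n = n, size = 4,
            endian = "little")
  x <- int_of(1:4) * scales[1] + offs[1]
  y <- int_of(5:8) * scales[2] + offs[2]
  z <- int_of(9:12) * scales[3] + offs[3]
  labels <- NULL
  if (!is.na(tree_id_offset)) {
    r0 <- base_len + tree_id_offset
    labels <- readBin(as.vector(m[(r0 + 1L):(r0 + 2L), ]), integer(),
                      n = n, size = 2, signed = FALSE, endian = "little")
  }
  point_cloud(cbind(x, y, z), labels = labels)
}
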