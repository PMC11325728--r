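#' Read and write point clouds
#'
#' Supported formats: `las` (binary LAS 1.2, point format 0, coordinates
#' only, default 1 mm scale), `xyz` (whitespace-separated text, full double
#' precision) and `ply` (ASCII PLY). `laz` is recognized but compressed
#' input is not handled; decompress to LAS first. Round-trips preserve
#' coordinates exactly for `xyz`/`ply` and to within half the scaled-integer
#' quantization step (0.5 mm at the default scale) for `las`.
#'
#' @param path File path. When `format` is omitted it is taken from the
#'   file extension.
#' @param format One of `"las"`, `"laz"`, `"xyz"`, `"ply"`.
#' @param cloud A point cloud.
#' @param scale LAS scaled-integer resolution (meters), default 1 mm.
#' @return `read_cloud` returns a point cloud tibble.
#' @export
read_cloud <- function(path, format = NULL) {
  format <- guess_format(path, format)
  if (identical(format, "laz")) {
    stop("LAZ (compressed LAS) is not supported; decompress to LAS first")
  }
  if (!format %in% c("las", "xyz", "ply")) {
    stop("unknown point cloud format: ", format)
  }
  if (!file.exists(path)) stop("cannot read point cloud: ", path)
  switch(format,
    xyz = read_cloud_xyz(path),
    ply = read_cloud_ply(path),
    las = read_cloud_las(path))
}

#' @rdname read_cloud
#' @export
write_cloud <- function(cloud, path, format = NULL, scale = 0.001) {
  format <- guess_format(path, format)
  switch(format,
    xyz = write_cloud_xyz(cloud, path),
    ply = write_cloud_ply(cloud, path),
    las = write_cloud_las(cloud, path, scale = scale),
    laz = stop("LAZ (compressed LAS) is not supported; write LAS instead"),
    stop("unknown point cloud format: ", format))
  invisible(path)
}

guess_format <- function(path, format) {
  if (!is.null(format)) return(tolower(format))
  tolower(tools::file_ext(path))
}

read_cloud_xyz <- function(path) {
  if (file.size(path) == 0) return(point_cloud())
  m <- as.matrix(read.table(path))
  if (nrow(m) == 0) return(point_cloud())
  as_point_cloud(m[, 1:3, drop = FALSE])
}

write_cloud_xyz <- function(cloud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(cloud) > 0) {
    writeLines(sprintf("%.17g %.17g %.17g", cloud$x, cloud$y, cloud$z), con)
  }
  invisible(path)
}

read_cloud_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ASCII PLY file: ", path)
  if (!any(grepl("^format ascii", lines))) stop("only ASCII PLY is supported")
  nvert <- as.integer(sub("element vertex ", "", grep("^element vertex ", lines, value = TRUE)[1]))
  if (is.na(nvert)) stop("PLY header lacks a vertex element")
  if (nvert == 0) return(point_cloud())
  body <- lines[(end + 1):(end + nvert)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                             function(v) as.numeric(v[1:3])))
  as_point_cloud(m)
}

write_cloud_ply <- function(cloud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(cloud)),
               "property double x", "property double y", "property double z",
               "end_header"), con)
  if (nrow(cloud) > 0) {
    writeLines(sprintf("%.17g %.17g %.17g", cloud$x, cloud$y, cloud$z), con)
  }
  invisible(path)
}

# --- minimal LAS 1.2, point data format 0 (coordinates only) ---------------

LAS_HEADER_SIZE <- 227L
LAS_RECORD_LEN <- 20L

write_cloud_las <- function(cloud, path, scale = 0.001) {
  n <- nrow(cloud)
  off <- if (n > 0) c(min(cloud$x), min(cloud$y), min(cloud$z)) else c(0, 0, 0)
  qx <- if (n > 0) as.integer(round((cloud$x - off[1]) / scale)) else integer()
  qy <- if (n > 0) as.integer(round((cloud$y - off[2]) / scale)) else integer()
  qz <- if (n > 0) as.integer(round((cloud$z - off[3]) / scale)) else integer()
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeChar("LASF", con, nchars = 4, eos = NULL)
  wb(integer(2), 2)                              # file source id, global encoding
  wb(raw(16), 1)                                 # project GUID
  writeBin(as.raw(c(1, 2)), con)                 # version 1.2
  writeChar(formatC("tls4d", width = 32, flag = "-"), con, nchars = 32, eos = NULL)
  writeChar(formatC("tls4d", width = 32, flag = "-"), con, nchars = 32, eos = NULL)
  wb(c(1L, 2026L), 2)                            # creation day/year
  wb(LAS_HEADER_SIZE, 2)
  wb(LAS_HEADER_SIZE, 4)                         # offset to point data
  wb(0L, 4)                                      # number of VLRs
  writeBin(as.raw(0), con)                       # point data format 0
  wb(LAS_RECORD_LEN, 2)
  wb(n, 4)
  wb(c(n, 0L, 0L, 0L, 0L), 4)                    # points by return
  writeBin(as.double(rep(scale, 3)), con, endian = "little")
  writeBin(as.double(off), con, endian = "little")
  bb <- if (n > 0) {
    c(max(cloud$x), min(cloud$x), max(cloud$y), min(cloud$y),
      max(cloud$z), min(cloud$z))
  } else rep(0, 6)
  writeBin(as.double(bb), con, endian = "little")
  if (n > 0) {
    rec <- matrix(as.raw(0), nrow = LAS_RECORD_LEN, ncol = n)
    rec[1:4, ] <- matrix(writeBin(qx, raw(), size = 4, endian = "little"), nrow = 4)
    rec[5:8, ] <- matrix(writeBin(qy, raw(), size = 4, endian = "little"), nrow = 4)
    rec[9:12, ] <- matrix(writeBin(qz, raw(), size = 4, endian = "little"), nrow = 4)
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

read_cloud_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path)
  invisible(readBin(con, "raw", 20))             # source id .. GUID
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  invisible(readBin(con, "raw", 64))             # system id + software
  invisible(readBin(con, "integer", 2, size = 2, endian = "little"))
  header_size <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  data_offset <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  fmt <- as.integer(readBin(con, "raw", 1))
  rec_len <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", 5, size = 4, endian = "little"))
  scale <- readBin(con, "double", 3, endian = "little")
  offset <- readBin(con, "double", 3, endian = "little")
  if (fmt > 5) stop("unsupported LAS point data format: ", fmt)
  if (n < 0) stop("LAS files with >= 2^31 points are not supported")
  seek(con, data_offset)
  if (n == 0) return(point_cloud())
  raw_data <- readBin(con, "raw", n * rec_len)
  if (length(raw_data) < n * rec_len) stop("truncated LAS point data")
  m <- matrix(raw_data, nrow = rec_len)
  dec <- function(rows) readBin(as.vector(m[rows, ]), "integer", n = n,
                                size = 4, endian = "little")
  point_cloud(x = dec(1:4) * scale[1] + offset[1],
              y = dec(5:8) * scale[2] + offset[2],
              z = dec(9:12) * scale[3] + offset[3])
}

#' Read and write rigid transforms as plain text
#'
#' One 4x4 homogeneous matrix, row-major, four whitespace-separated numbers
#' per line.
#'
#' @param tf A `rigid_transform`.
#' @param path File path.
#' @export
write_transform <- function(tf, path) {
  m <- transform_matrix(tf)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  transform_from_matrix(m)
}
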