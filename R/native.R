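#' Write / read a cube in the package's native binary container
#'
#' A single binary file: an ASCII magic line, a JSON header (array shapes and
#' flags), then the named arrays (mz, intensities column-major, coords,
#' labels) as little-endian doubles/integers. The round trip is lossless:
#' `read_native(write_native(cube))` reproduces the cube bit-exactly.
#'
#' @param cube An `msi_cube`.
#' @param path Output file path.
#' @return `write_native` returns `path` invisibly; `read_native` returns the
#'   `msi_cube`.
#' @export
write_native <- function(cube, path) {
  header <- list(
    format = "dcims-cube", version = 1L,
    n_pixels = n_pixels(cube), n_channels = n_channels(cube),
    mask_shape = cube$mask_shape,
    has_labels = !is.null(cube$region_labels)
  )
  hraw <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("DCIMSCUBE1\n"), con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(cube$mz, con, size = 8L, endian = "little")
  writeBin(as.vector(cube$intensities), con, size = 8L, endian = "little")
  writeBin(as.vector(cube$coords), con, size = 4L, endian = "little")
  if (!is.null(cube$region_labels))
    writeBin(cube$region_labels, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_native
#' @export
read_native <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 11L))
  if (!identical(magic, "DCIMSCUBE1\n"))
    stop("integrity error: ", path, " is not a dcims native cube (bad magic)")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L || hlen > 1e6)
    stop("integrity error: corrupt header length in ", path)
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  np <- header$n_pixels; nc <- header$n_channels
  expected <- 11 + 4 + hlen + 8 * nc + 8 * np * nc + 4 * 2 * np +
    if (isTRUE(header$has_labels)) 4 * np else 0
  if (file.size(path) != expected)
    stop("integrity error: ", path, " is truncated or corrupt (expected ",
         expected, " bytes, found ", file.size(path), ")")
  mz <- readBin(con, "double", nc, size = 8L, endian = "little")
  intens <- matrix(readBin(con, "double", np * nc, size = 8L, endian = "little"),
                   np, nc)
  coords <- matrix(readBin(con, "integer", 2L * np, size = 4L, endian = "little"),
                   np, 2L)
  labels <- if (isTRUE(header$has_labels))
    readBin(con, "integer", np, size = 4L, endian = "little") else NULL
  msi_cube(intens, mz, coords, header$mask_shape, labels)
}

#' Write / read an embedding as CSV
#'
#' Plain-text interchange for embeddings: header row `x,y,dim1..dimk`, one row
#' per pixel in cube order.
#'
#' @param embedding An `msi_embedding`.
#' @param cube The source `msi_cube` (supplies pixel coordinates).
#' @param path CSV file path.
#' @return `write_embedding_csv` returns `path` invisibly; `read_embedding_csv`
#'   returns an `msi_embedding` (coordinates only; `params` records the file).
#' @export
write_embedding_csv <- function(embedding, cube, path) {
  co <- embedding$coordinates
  if (nrow(co) != n_pixels(cube))
    stop("embedding and cube pixel counts differ")
  df <- data.frame(cube$coords, co)
  colnames(df) <- c("x", "y", paste0("dim", seq_len(ncol(co))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_csv
#' @export
read_embedding_csv <- function(path) {
  df <- utils::read.csv(path)
  dims <- grep("^dim", colnames(df))
  if (length(dims) == 0L) stop("no dim columns in ", path)
  msi_embedding(as.matrix(df[, dims, drop = FALSE]),
                params = list(source = path))
}

#' Write / read region labels as CSV (header `x,y,label`)
#'
#' @param cube A labelled `msi_cube`.
#' @param path CSV file path.
#' @return The path (write) or an integer label vector in file order (read).
#' @export
write_labels_csv <- function(cube, path) {
  if (is.null(cube$region_labels)) stop("cube has no region labels")
  df <- data.frame(cube$coords, label = cube$region_labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path)
  as.integer(df$label)
}
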