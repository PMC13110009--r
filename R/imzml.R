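# Continuous-mode imzML reader/writer.
#
# imzML splits a dataset into an XML part (.imzML, mzML with imaging
# extensions) and a binary part (.ibd) holding the arrays. In continuous mode
# all spectra share one m/z array; per-spectrum cvParams give the external
# offset/length of each array in the .ibd file. Only continuous mode is
# supported: processed mode (one m/z axis per spectrum) cannot be represented
# as a dense datacube without re-binning.

IMS_CONTINUOUS <- "IMS:1000030"
IMS_PROCESSED  <- "IMS:1000031"
IMS_POS_X      <- "IMS:1000050"
IMS_POS_Y      <- "IMS:1000051"
IMS_OFFSET     <- "IMS:1000102"
IMS_ARR_LEN    <- "IMS:1000103"
MS_MZ_ARRAY    <- "MS:1000514"
MS_INT_ARRAY   <- "MS:1000515"
MS_FLOAT64     <- "MS:1000523"
MS_FLOAT32     <- "MS:1000521"

ibd_path_for <- function(path) {
  cand <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(cand, path)) cand <- paste0(path, ".ibd")
  cand
}

cv <- function(accession, name, value = NULL) {
  at <- c(cvRef = strsplit(accession, ":")[[1]][1], accession = accession,
          name = name)
  if (!is.null(value)) at <- c(at, value = as.character(value))
  at
}

#' Write an MSI datacube as continuous-mode imzML
#'
#' Produces an `.imzML`/`.ibd` pair. The shared m/z axis and all intensity
#' arrays are stored as 64-bit little-endian floats, so
#' `read_imzml(write_imzml(cube))` round-trips to full double precision.
#' Region labels have no imzML representation and are not written.
#'
#' @param cube An `msi_cube`.
#' @param path Output path ending in `.imzML`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(cube, path) {
  ibd <- ibd_path_for(path)
  # deterministic 16-byte UUID derived from the cube content
  h <- rlang::hash(list(cube$mz, cube$intensities, cube$coords))
  uuid <- as.raw(strtoi(substring(h, seq(1, 31, 2), seq(2, 32, 2)), 16L))
  np <- n_pixels(cube); nc <- n_channels(cube)

  con <- file(ibd, "wb")
  writeBin(uuid, con)
  writeBin(cube$mz, con, size = 8L, endian = "little")
  for (i in seq_len(np))
    writeBin(cube$intensities[i, ], con, size = 8L, endian = "little")
  close(con)

  mz_offset <- 16
  int_offsets <- 16 + 8 * nc + 8 * nc * (seq_len(np) - 1)

  doc <- xml2::xml_new_root("mzML",
    xmlns = "http://psi.hupo.org/ms/mzml", version = "1.1")
  fd <- xml2::xml_add_child(doc, "fileDescription")
  fc <- xml2::xml_add_child(fd, "fileContent")
  do.call(xml2::xml_add_child,
          c(list(fc, "cvParam"), as.list(cv(IMS_CONTINUOUS, "continuous"))))
  do.call(xml2::xml_add_child,
          c(list(fc, "cvParam"),
            as.list(cv("IMS:1000080", "universally unique identifier",
                       paste0("{", h, "}")))))

  rpg <- xml2::xml_add_child(doc, "referenceableParamGroupList", count = "2")
  for (grp in list(list(id = "mzArray", acc = MS_MZ_ARRAY, nm = "m/z array"),
                   list(id = "intensityArray", acc = MS_INT_ARRAY,
                        nm = "intensity array"))) {
    g <- xml2::xml_add_child(rpg, "referenceableParamGroup", id = grp$id)
    do.call(xml2::xml_add_child,
            c(list(g, "cvParam"), as.list(cv(grp$acc, grp$nm))))
    do.call(xml2::xml_add_child,
            c(list(g, "cvParam"), as.list(cv(MS_FLOAT64, "64-bit float"))))
    do.call(xml2::xml_add_child,
            c(list(g, "cvParam"), as.list(cv("MS:1000576", "no compression"))))
    do.call(xml2::xml_add_child,
            c(list(g, "cvParam"), as.list(cv("IMS:1000101", "external data", "true"))))
  }

  run <- xml2::xml_add_child(doc, "run", id = "run0")
  sl <- xml2::xml_add_child(run, "spectrumList", count = as.character(np))
  for (i in seq_len(np)) {
    sp <- xml2::xml_add_child(sl, "spectrum", id = paste0("spectrum=", i),
                              index = as.character(i - 1),
                              defaultArrayLength = as.character(nc))
    scl <- xml2::xml_add_child(sp, "scanList", count = "1")
    sc <- xml2::xml_add_child(scl, "scan")
    do.call(xml2::xml_add_child,
            c(list(sc, "cvParam"),
              as.list(cv(IMS_POS_X, "position x", cube$coords[i, "x"]))))
    do.call(xml2::xml_add_child,
            c(list(sc, "cvParam"),
              as.list(cv(IMS_POS_Y, "position y", cube$coords[i, "y"]))))
    bal <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")
    specs <- list(list(ref = "mzArray", off = mz_offset),
                  list(ref = "intensityArray", off = int_offsets[i]))
    for (s in specs) {
      ba <- xml2::xml_add_child(bal, "binaryDataArray",
                                encodedLength = as.character(8 * nc))
      xml2::xml_add_child(ba, "referenceableParamGroupRef", ref = s$ref)
      do.call(xml2::xml_add_child,
              c(list(ba, "cvParam"),
                as.list(cv(IMS_OFFSET, "external offset", s$off))))
      do.call(xml2::xml_add_child,
              c(list(ba, "cvParam"),
                as.list(cv(IMS_ARR_LEN, "external array length", nc))))
      do.call(xml2::xml_add_child,
              c(list(ba, "cvParam"),
                as.list(cv("IMS:1000104", "external encoded length", 8 * nc))))
      xml2::xml_add_child(ba, "binary")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a continuous-mode imzML file
#'
#' Parses the XML part, checks the file really is continuous mode, and reads
#' the shared m/z axis plus one intensity array per spectrum from the `.ibd`
#' companion at the external offsets the XML declares. Both 32- and 64-bit
#' float arrays are understood; intensities are promoted to double. Pixel
#' order follows the file's spectrum order, and the 1-based imzML pixel
#' indices are kept 1-based (matching R indexing).
#'
#' @param path Path to the `.imzML` file; the `.ibd` pair must sit beside it.
#' @return An `msi_cube` (unlabelled).
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd))
    stop("missing binary companion file: ", ibd)

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  acc_of <- function(node) xml2::xml_attr(node, "accession")

  mode_params <- xml2::xml_find_all(
    doc, sprintf("//fileContent/cvParam[@accession='%s' or @accession='%s']",
                 IMS_CONTINUOUS, IMS_PROCESSED))
  modes <- vapply(mode_params, acc_of, character(1))
  if (IMS_PROCESSED %in% modes)
    stop("unsupported imzML mode: 'processed' (per-spectrum m/z axes); ",
         "only continuous-mode imzML is supported")
  if (!(IMS_CONTINUOUS %in% modes))
    stop("imzML file does not declare continuous mode")

  # referenceable param groups: array role and float width per group id
  groups <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  ginfo <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    accs <- vapply(xml2::xml_find_all(g, "cvParam"), acc_of, character(1))
    ginfo[[id]] <- list(
      role = if (MS_MZ_ARRAY %in% accs) "mz"
             else if (MS_INT_ARRAY %in% accs) "intensity" else NA_character_,
      bytes = if (MS_FLOAT32 %in% accs) 4L else 8L)
  }

  spectra <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
  np <- length(spectra)
  if (np == 0L) stop("imzML file contains no spectra")

  param_val <- function(node, accession) {
    p <- xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", accession))
    as.numeric(xml2::xml_attr(p, "value"))
  }

  coords <- matrix(0L, np, 2L)
  int_meta <- vector("list", np)
  mz_meta <- NULL
  for (i in seq_len(np)) {
    sp <- spectra[[i]]
    coords[i, ] <- c(param_val(sp, IMS_POS_X), param_val(sp, IMS_POS_Y))
    for (ba in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(ba, "referenceableParamGroupRef"), "ref")
      role <- ginfo[[ref]]$role
      accs <- vapply(xml2::xml_find_all(ba, "cvParam"), acc_of, character(1))
      bytes <- if (MS_FLOAT32 %in% accs) 4L
               else if (MS_FLOAT64 %in% accs) 8L else ginfo[[ref]]$bytes
      meta <- list(offset = param_val(ba, IMS_OFFSET),
                   len = param_val(ba, IMS_ARR_LEN), bytes = bytes)
      if (identical(role, "mz")) {
        if (is.null(mz_meta)) mz_meta <- meta
      } else if (identical(role, "intensity")) int_meta[[i]] <- meta
    }
  }
  if (is.null(mz_meta)) stop("no m/z array declared in ", path)

  con <- file(ibd, "rb")
  on.exit(close(con))
  read_arr <- function(meta) {
    seek(con, where = meta$offset, origin = "start")
    readBin(con, "double", n = meta$len, size = meta$bytes, endian = "little")
  }
  mz <- read_arr(mz_meta)
  intens <- matrix(0, np, mz_meta$len)
  for (i in seq_len(np)) intens[i, ] <- read_arr(int_meta[[i]])

  msi_cube(intens, mz, coords, c(max(coords[, 1]), max(coords[, 2])))
}
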