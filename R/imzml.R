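#' Write an MSI dataset as imzML (processed mode)
#'
#' Emits the standard two-file representation: an XML part (`.imzML`) with
#' per-spectrum coordinates and external-array offsets, and a binary part
#' (`.ibd`) opening with the 16-byte UUID that links the pair. m/z arrays
#' are stored as 64-bit floats, intensities as 32-bit floats (the common
#' encoding; intensity round-trips are exact only to float32). Spectra are
#' written in acquisition (scan) order.
#'
#' @param ds An [msi_dataset()].
#' @param path Output path ending in `.imzML`; the `.ibd` is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(ds, path) {
  stopifnot(inherits(ds, "msi_dataset"))
  if (!grepl("\\.imzML$", path)) path <- paste0(path, ".imzML")
  ibd_path <- sub("\\.imzML$", ".ibd", path)

  ord <- order(ds$pixels$scan_index)
  px <- ds$pixels[ord, , drop = FALSE]
  sp <- ds$spectra[ord]

  uuid <- content_uuid(ds)
  con <- file(ibd_path, "wb")
  writeBin(uuid, con)
  offset <- 16
  recs <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    mz <- as.numeric(sp[[i]]$mz)
    it <- as.numeric(sp[[i]]$intensity)
    n <- length(mz)
    writeBin(mz, con, size = 8, endian = "little")
    mz_off <- offset; offset <- offset + 8 * n
    writeBin(it, con, size = 4, endian = "little")
    it_off <- offset; offset <- offset + 4 * n
    recs[[i]] <- list(n = n, mz_off = mz_off, it_off = it_off,
                      x = px$x[i] + 1L, y = px$y[i] + 1L)
  }
  close(con)

  uuid_str <- format_uuid(uuid)
  hdr <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '  <fileDescription>',
    '    <fileContent>',
    '      <cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>', uuid_str),
    '    </fileContent>',
    '  </fileDescription>',
    '  <referenceableParamGroupList count="2">',
    '    <referenceableParamGroup id="mzArray">',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '    </referenceableParamGroup>',
    '    <referenceableParamGroup id="intensityArray">',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
    '      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>',
    '    </referenceableParamGroup>',
    '  </referenceableParamGroupList>',
    sprintf('  <run id="run0" defaultInstrumentConfigurationRef="IC0">'),
    sprintf('    <spectrumList count="%d">', length(sp)))

  body <- vapply(seq_along(sp), function(i) {
    r <- recs[[i]]
    paste0(
      sprintf('      <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n', i - 1L, i, r$n),
      '        <scanList count="1"><scan>\n',
      sprintf('          <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n', r$x),
      sprintf('          <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n', r$y),
      '        </scan></scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      sprintf('          <binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/><cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/><cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/><binary/></binaryDataArray>\n', r$mz_off, r$n),
      sprintf('          <binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/><cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/><cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/><binary/></binaryDataArray>\n', r$it_off, r$n),
      '        </binaryDataArrayList>\n',
      '      </spectrum>')
  }, character(1))

  tail <- c('    </spectrumList>', '  </run>', '</mzML>')
  writeLines(c(hdr, body, tail), path, useBytes = TRUE)
  invisible(path)
}

#' Read an imzML (processed mode) file into an MSI dataset
#'
#' Parses the XML part, verifies that the `.ibd` binary part opens with the
#' matching UUID, and reads the external m/z (float64) and intensity
#' (float32) arrays. Spectra order in the file defines `scan_index`;
#' 1-based imzML positions are converted to this package's 0-based
#' convention.
#'
#' @param path Path to the `.imzML` file.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ibd_path <- sub("\\.imzML$", ".ibd", path)
  if (!file.exists(ibd_path)) stop("missing binary part: ", ibd_path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  uuid_node <- xml2::xml_find_first(
    doc, ".//fileContent/cvParam[@accession='IMS:1000080']")
  uuid_xml <- gsub("[{}-]", "", xml2::xml_attr(uuid_node, "value"))

  ibd_size <- file.info(ibd_path)$size
  con <- file(ibd_path, "rb")
  on.exit(close(con))
  uuid_ibd <- readBin(con, "raw", 16L)
  if (!identical(tolower(uuid_xml),
                 paste(sprintf("%02x", as.integer(uuid_ibd)), collapse = "")))
    stop("ibd checksum mismatch: UUID in ", ibd_path,
         " does not match the imzML header")

  spectra_nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  n <- length(spectra_nodes)
  if (n == 0L) stop("imzML contains no spectra: ", path)

  pixels <- data.frame(pixel_id = integer(n), x = integer(n), y = integer(n),
                       scan_index = seq_len(n) - 1L)
  spectra <- vector("list", n)
  skipped <- 0L
  for (i in seq_len(n)) {
    node <- spectra_nodes[[i]]
    x <- as.integer(xml2::xml_attr(
      xml2::xml_find_first(node, ".//cvParam[@accession='IMS:1000050']"), "value"))
    y <- as.integer(xml2::xml_attr(
      xml2::xml_find_first(node, ".//cvParam[@accession='IMS:1000051']"), "value"))
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    dat <- list(mz = numeric(0), intensity = numeric(0))
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, ".//referenceableParamGroupRef"), "ref")
      off <- as.numeric(xml2::xml_attr(
        xml2::xml_find_first(arr, ".//cvParam[@accession='IMS:1000102']"), "value"))
      len <- as.integer(xml2::xml_attr(
        xml2::xml_find_first(arr, ".//cvParam[@accession='IMS:1000103']"), "value"))
      sz <- if (ref == "mzArray") 8L else 4L
      if (off + sz * len > ibd_size)
        stop(sprintf("ibd checksum mismatch: array at offset %.0f overruns %s",
                     off, ibd_path))
      seek(con, where = off, origin = "start")
      v <- readBin(con, "double", n = len, size = sz, endian = "little")
      dat[[if (ref == "mzArray") "mz" else "intensity"]] <- v
    }
    if (is.na(x) || is.na(y)) { skipped <- skipped + 1L; next }
    pixels$x[i] <- x - 1L
    pixels$y[i] <- y - 1L
    pixels$pixel_id[i] <- i
    spectra[[i]] <- dat
  }
  if (skipped > 0L) {
    message(skipped, " spectra without coordinates skipped")
    keep <- !vapply(spectra, is.null, logical(1))
    pixels <- pixels[keep, , drop = FALSE]
    pixels$scan_index <- rank(pixels$scan_index) - 1L
    spectra <- spectra[keep]
  }
  msi_dataset(pixels, spectra, metadata = list(mode = "processed"))
}

# Deterministic 16-byte content identifier (UUID field of the imzML pair).
content_uuid <- function(ds) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  writeBin(as.numeric(c(nrow(ds$pixels), ds$pixels$x, ds$pixels$y,
                        unlist(lapply(ds$spectra, function(s)
                          c(length(s$mz), sum(s$mz), sum(s$intensity)))))),
           con, size = 8)
  close(con)
  md5 <- tools::md5sum(tf)[[1]]
  as.raw(strtoi(substring(md5, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

format_uuid <- function(bytes) {
  hx <- sprintf("%02x", as.integer(bytes))
  paste0(paste(hx[1:4], collapse = ""), "-", paste(hx[5:6], collapse = ""),
         "-", paste(hx[7:8], collapse = ""), "-",
         paste(hx[9:10], collapse = ""), "-",
         paste(hx[11:16], collapse = ""))
}
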