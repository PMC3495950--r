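# Minimal mzML reader/writer for profile MS1 spectra.
# Arrays are 64-bit little-endian floats, base64, uncompressed (the mzML
# "no compression" encoding). Subject/replicate/group metadata travel as
# userParam elements so a write/read cycle preserves them.

b64_doubles <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                         size = 8, endian = "little"))

doubles_b64 <- function(txt) readBin(jsonlite::base64_dec(txt), "numeric",
                                     n = .Machine$integer.max %/% 8,
                                     size = 8, endian = "little")

#' Read and write mzML spectrum files
#'
#' A deliberately small mzML profile: MS1 spectra with uncompressed 64-bit
#' m/z and intensity arrays. `write_spectrum_mzml()` emits files that
#' `read_spectrum_mzml()` round-trips to equal arrays within float
#' precision; vendor files using zlib compression or 32-bit arrays are out
#' of scope.
#'
#' @param path file path.
#' @return `read_spectrum_mzml()` returns a `SpectrumSet` (no common grid).
#' @export
read_spectrum_mzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("not a parseable mzML file: ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  spectra <- lapply(nodes, function(nd) {
    arrays <- xml2::xml_find_all(nd, ".//binaryDataArray")
    mz <- NULL; y <- NULL
    for (arr in arrays) {
      acc <- xml2::xml_attr(xml2::xml_find_all(arr, "cvParam"), "accession")
      vals <- doubles_b64(xml2::xml_text(xml2::xml_find_first(arr, "binary")))
      if ("MS:1000514" %in% acc) mz <- vals
      if ("MS:1000515" %in% acc) y <- vals
    }
    if (is.null(mz) || is.null(y))
      stop("spectrum missing m/z or intensity array")
    up <- xml2::xml_find_all(nd, "userParam")
    meta <- stats::setNames(xml2::xml_attr(up, "value"),
                            xml2::xml_attr(up, "name"))
    spectrum(mz, y,
             id = xml2::xml_attr(nd, "id"),
             subject = if (!is.na(meta["subject"])) meta[["subject"]] else
               xml2::xml_attr(nd, "id"),
             replicate = if (!is.na(meta["replicate"]))
               as.integer(meta[["replicate"]]) else 1L,
             group = if (!is.na(meta["group"])) meta[["group"]] else "QC")
  })
  spectrum_set(spectra)
}

#' @rdname read_spectrum_mzml
#' @param set a `SpectrumSet` to write.
#' @export
write_spectrum_mzml <- function(set, path) {
  stopifnot(inherits(set, "SpectrumSet"))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c('<?xml version="1.0" encoding="utf-8"?>',
             '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
             '  <run id="run1">',
             sprintf('    <spectrumList count="%d">', length(set$spectra)))
  for (i in seq_along(set$spectra)) {
    s <- set$spectra[[i]]
    lines <- c(lines,
      sprintf('      <spectrum index="%d" id="%s" defaultArrayLength="%d">',
              i - 1L, esc(s$id), length(s$mz)),
      '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '        <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>',
      sprintf('        <userParam name="subject" value="%s"/>', esc(s$subject)),
      sprintf('        <userParam name="replicate" value="%d"/>', s$replicate),
      sprintf('        <userParam name="group" value="%s"/>', s$group),
      '        <binaryDataArrayList count="2">',
      '          <binaryDataArray>',
      '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      paste0('            <binary>', b64_doubles(s$mz), '</binary>'),
      '          </binaryDataArray>',
      '          <binaryDataArray>',
      '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      paste0('            <binary>', b64_doubles(s$intensity), '</binary>'),
      '          </binaryDataArray>',
      '        </binaryDataArrayList>',
      '      </spectrum>')
  }
  lines <- c(lines, '    </spectrumList>', '  </run>', '</mzML>')
  writeLines(lines, path)
  invisible(path)
}
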