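# Minimal GIFTI metric (.func.gii) support: a single FLOAT32 data array per
# file, encodings ASCII / Base64Binary / GZipBase64Binary, little-endian.
# Only what the surface pipeline needs; geometry arrays are out of scope.

read_gifti_metric <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error: '", path,
                                           "' is not valid XML: ",
                                           conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (root != "GIFTI") stop("format error: root element is <", root, ">, expected <GIFTI>")
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) != 1L) {
    stop("format error: expected exactly 1 DataArray, found ", length(arrays))
  }
  arr <- arrays[[1]]
  dtype <- xml2::xml_attr(arr, "DataType")
  if (!dtype %in% c("NIFTI_TYPE_FLOAT32", "NIFTI_TYPE_FLOAT64")) {
    stop("format error: unsupported DataType '", dtype, "'")
  }
  enc <- xml2::xml_attr(arr, "Encoding")
  endian <- xml2::xml_attr(arr, "Endian")
  if (!is.na(endian) && endian == "BigEndian") {
    stop("format error: BigEndian data not supported")
  }
  dim0 <- as.integer(xml2::xml_attr(arr, "Dim0"))
  data_node <- xml2::xml_find_first(arr, ".//Data")
  if (inherits(data_node, "xml_missing")) stop("format error: DataArray has no <Data> element")
  txt <- xml2::xml_text(data_node)
  size <- if (dtype == "NIFTI_TYPE_FLOAT32") 4L else 8L
  values <- switch(enc,
    "ASCII" = as.numeric(strsplit(trimws(txt), "\\s+")[[1]]),
    "Base64Binary" = readBin(jsonlite::base64_dec(gsub("\\s", "", txt)),
                             "double", n = dim0, size = size, endian = "little"),
    "GZipBase64Binary" = readBin(
      memDecompress(jsonlite::base64_dec(gsub("\\s", "", txt)), type = "gzip"),
      "double", n = dim0, size = size, endian = "little"),
    stop("format error: unsupported Encoding '", enc, "'")
  )
  if (!is.na(dim0) && length(values) != dim0) {
    stop("dimension error: Dim0 = ", dim0, " but ", length(values), " values decoded")
  }
  values
}

write_gifti_metric <- function(values, path, encoding = "GZipBase64Binary") {
  values <- as.numeric(values)
  raw_data <- writeBin(values, raw(), size = 4L, endian = "little")
  payload <- switch(encoding,
    "ASCII" = paste(format(values, digits = 9, trim = TRUE), collapse = " "),
    "Base64Binary" = jsonlite::base64_enc(raw_data),
    "GZipBase64Binary" = jsonlite::base64_enc(memCompress(raw_data, type = "gzip")),
    stop("unsupported Encoding '", encoding, "'")
  )
  payload <- gsub("\n", "", payload)
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="1">\n',
    '<DataArray Intent="NIFTI_INTENT_NONE" DataType="NIFTI_TYPE_FLOAT32" ',
    'ArrayIndexingOrder="RowMajorOrder" Dimensionality="1" Dim0="',
    length(values), '" Encoding="', encoding,
    '" Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">\n',
    '<Data>', payload, '</Data>\n',
    '</DataArray>\n</GIFTI>\n'
  )
  writeLines(doc, path, sep = "")
  invisible(path)
}
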