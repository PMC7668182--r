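#' One scalar per vertex of one hemisphere
#'
#' A `vertex_map` is a numeric vector of length V with a hemisphere label and
#' an optional subject identifier; units depend on context (z, t, r, ...).
#'
#' @param values numeric vector, one value per mesh vertex.
#' @param hemisphere `"left"` or `"right"`.
#' @param subject_id optional identifier.
#' @return A classed numeric vector (`vertex_map`).
#' @export
vertex_map <- function(values, hemisphere = c("left", "right"), subject_id = NULL) {
  hemisphere <- match.arg(hemisphere)
  structure(as.numeric(values), hemisphere = hemisphere,
            subject_id = subject_id, class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  cat("vertex_map (", attr(x, "hemisphere"), "), V = ", length(x), sep = "")
  if (!is.null(attr(x, "subject_id"))) cat(", subject ", attr(x, "subject_id"), sep = "")
  cat("\n")
  print(utils::head(as.numeric(x)))
  invisible(x)
}

vm_values <- function(x) {
  if (inherits(x, "vertex_map")) as.numeric(x) else as.numeric(x)
}

#' Left/right vertex correspondence
#'
#' The pairing is stored as an integer vector `p` with `p[i]` the homologous
#' vertex on the other hemisphere; it must be an involution (`p[p[i]] == i`)
#' so that mirroring twice is the identity.
#'
#' @param pairing integer vector of partner indices (1-based).
#' @return An integer vector of class `correspondence_map`.
#' @export
correspondence_map <- function(pairing) {
  pairing <- as.integer(pairing)
  V <- length(pairing)
  if (any(pairing < 1L | pairing > V)) stop("correspondence error: index out of range")
  if (!identical(pairing[pairing], seq_len(V))) {
    stop("correspondence error: pairing is not a bijective involution")
  }
  structure(pairing, class = "correspondence_map")
}

#' Mirror a vertex map onto the opposite hemisphere
#'
#' Carries each value to its homologous vertex under the correspondence and
#' flips the hemisphere label; applying it twice returns the input.
#'
#' @param map a [vertex_map()].
#' @param corr a [correspondence_map()].
#' @return A [vertex_map()] on the other hemisphere.
#' @export
mirror_map <- function(map, corr) {
  stopifnot(inherits(map, "vertex_map"))
  if (length(map) != length(corr)) {
    stop("correspondence error: map has ", length(map),
         " vertices but pairing covers ", length(corr))
  }
  out <- numeric(length(map))
  out[corr] <- as.numeric(map)
  vertex_map(out,
             hemisphere = if (attr(map, "hemisphere") == "left") "right" else "left",
             subject_id = attr(map, "subject_id"))
}

#' Read a vertex map from disk
#'
#' @param path file path.
#' @param format `"tsv"` (one value per line) or `"gifti"` (GIFTI metric,
#'   `.func.gii`, single data array).
#' @param hemisphere hemisphere label to attach.
#' @param subject_id optional identifier to attach.
#' @return A [vertex_map()]; values appear in file order.
#' @export
read_vertex_map <- function(path, format = c("tsv", "gifti"),
                            hemisphere = "right", subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  values <- switch(format,
    tsv = {
      v <- tryCatch(scan(path, what = numeric(), quiet = TRUE),
                    error = function(e) stop("format error reading TSV '", path,
                                             "': ", conditionMessage(e)))
      v
    },
    gifti = read_gifti_metric(path)
  )
  vertex_map(values, hemisphere = hemisphere, subject_id = subject_id)
}

#' Write a vertex map to disk
#'
#' @param map a [vertex_map()] or numeric vector.
#' @param path destination file.
#' @param format `"tsv"` or `"gifti"`. TSV round-trips exactly; GIFTI stores
#'   float32 so round-trips within single precision.
#' @return `path`, invisibly.
#' @export
write_vertex_map <- function(map, path, format = c("tsv", "gifti")) {
  format <- match.arg(format)
  values <- vm_values(map)
  switch(format,
    tsv = writeLines(format(values, digits = 17, scientific = TRUE, trim = TRUE), path),
    gifti = write_gifti_metric(values, path)
  )
  invisible(path)
}

#' Read / write a vertex mask
#'
#' Masks are stored as one 0-based vertex index per line and converted to
#' 1-based on read.
#'
#' @param path file path.
#' @return Sorted integer vector of 1-based vertex indices.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  idx <- scan(path, what = integer(), quiet = TRUE)
  if (anyDuplicated(idx)) stop("mask error: duplicate indices in ", path)
  if (any(idx < 0L)) stop("mask error: negative index in ", path)
  sort(idx + 1L)
}

#' @rdname read_mask
#' @param mask integer vector of 1-based indices.
#' @export
write_mask <- function(mask, path) {
  writeLines(as.character(sort(as.integer(mask)) - 1L), path)
  invisible(path)
}

#' Read a correspondence map from a two-column TSV of 0-based index pairs
#'
#' Each line `a<TAB>b` pairs left vertex `a` with right vertex `b` (0-based on
#' disk). Every vertex must appear exactly once across the two columns of its
#' hemisphere.
#'
#' @param path file path.
#' @param n_vertices number of vertices per hemisphere.
#' @return A [correspondence_map()].
#' @export
read_correspondence <- function(path, n_vertices) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("left", "right"))
  p <- rep(NA_integer_, n_vertices)
  p[tab$left + 1L] <- tab$right + 1L
  if (anyNA(p)) stop("correspondence error: vertex ", which(is.na(p))[1] - 1L,
                     " has no pair in ", path)
  correspondence_map(p)
}
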