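#' Per-subject reward-related asymmetry map
#'
#' Mirrors the left-hemisphere map onto the right mesh through the vertex
#' correspondence and takes, at every mask vertex, the signed difference
#' right minus left and its absolute value. The signed convention is fixed as
#' right - left throughout the package, so positive values mean right
#' dominance. The unsigned map is the quantity tested at the group level: it
#' detects lateralization regardless of its direction in each subject.
#'
#' @param left_map,right_map [vertex_map()]s of the two hemispheres (same V).
#' @param corr a [correspondence_map()] pairing the hemispheres.
#' @param mask integer vector of right-hemisphere mask vertices.
#' @return An `asym_map`: list with `signed` and `unsigned` (length-V numeric,
#'   `NA` outside the mask), `mask`, and `subject_id`.
#' @export
rra_map <- function(left_map, right_map, corr, mask) {
  l <- vm_values(left_map); r <- vm_values(right_map)
  if (length(l) != length(r)) stop("dimension error: hemisphere maps differ in length")
  mirrored <- numeric(length(l))
  mirrored[corr] <- l
  bad <- mask[!is.finite(r[mask]) | !is.finite(mirrored[mask])]
  if (length(bad) > 0) {
    stop("data error: non-finite value inside mask at vertex ", bad[1])
  }
  signed <- unsigned <- rep(NA_real_, length(r))
  signed[mask] <- r[mask] - mirrored[mask]
  unsigned[mask] <- abs(signed[mask])
  structure(list(signed = signed, unsigned = unsigned, mask = sort(as.integer(mask)),
                 subject_id = attr(right_map, "subject_id")),
            class = "asym_map")
}

#' @export
print.asym_map <- function(x, ...) {
  cat("asym_map over ", length(x$mask), " mask vertices; mean unsigned = ",
      signif(mean(x$unsigned[x$mask]), 4), "\n", sep = "")
  invisible(x)
}

#' z-score map values across mask vertices
#'
#' Standardizes a subject's map to mean 0 and SD 1 across the mask, the
#' within-subject normalization applied before the spatial randomization
#' test. For an `asym_map` the unsigned values are standardized (the unsigned
#' map is the one submitted to the cluster test).
#'
#' @param x an `asym_map`, or a numeric/[vertex_map()] vector.
#' @param mask mask vertices (required unless `x` is an `asym_map`).
#' @return Length-V numeric vector, z-scored inside the mask, `NA` outside.
#' @export
zscore_within_mask <- function(x, mask = NULL) {
  if (inherits(x, "asym_map")) {
    mask <- x$mask
    values <- x$unsigned
  } else {
    if (is.null(mask)) stop("mask is required for plain vectors")
    values <- vm_values(x)
  }
  v <- values[mask]
  if (length(v) < 2L) stop("degenerate-data error: mask has fewer than 2 vertices")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("degenerate-data error: zero variance within mask")
  out <- rep(NA_real_, length(values))
  out[mask] <- (v - mean(v)) / s
  out
}

#' One-sample Student t test with explicit degenerate handling
#'
#' Classical two-tailed one-sample t against `null_mean` (df = n - 1).
#' Zero-variance samples are reported, not dropped: all values equal to the
#' null mean give t = 0, p = 1; all equal to some other value give infinite t
#' and p = 0; both are flagged `degenerate`.
#'
#' @param values per-subject scalars.
#' @param null_mean null-hypothesis mean.
#' @return List with `t`, `df`, `p`, `mean`, `degenerate`.
#' @export
group_onesample_t <- function(values, null_mean = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values for a one-sample t test")
  if (any(!is.finite(values))) stop("data error: non-finite values")
  n <- length(values)
  if (stats::sd(values) == 0) {
    if (values[1] == null_mean) {
      return(list(t = 0, df = n - 1L, p = 1, mean = values[1], degenerate = TRUE))
    }
    return(list(t = sign(values[1] - null_mean) * Inf, df = n - 1L, p = 0,
                mean = values[1], degenerate = TRUE))
  }
  ht <- stats::t.test(values, mu = null_mean)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean = mean(values), degenerate = FALSE)
}

#' Mean map value over a region
#'
#' Arithmetic mean of per-vertex values over a region mask; the per-subject
#' "coefficient" extracted from a significant cluster.
#'
#' @param map numeric vector, [vertex_map()], or `asym_map`.
#' @param region nonempty integer vector of vertex indices within the map.
#' @param which for an `asym_map`, `"signed"` or `"unsigned"`.
#' @return Scalar mean.
#' @export
extract_region_coefficient <- function(map, region, which = c("signed", "unsigned")) {
  if (length(region) == 0L) stop("empty region")
  values <- if (inherits(map, "asym_map")) {
    which <- match.arg(which)
    map[[which]]
  } else {
    vm_values(map)
  }
  if (any(region < 1L | region > length(values))) {
    stop("region index outside the map's domain")
  }
  mean(values[region])
}
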