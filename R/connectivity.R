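#' Pearson correlation of two time series
#'
#' Plain sample Pearson r, with the degenerate cases made explicit: series
#' must be equal length (>= 3) and nonconstant. Raw r is used throughout the
#' package (no Fisher z-transform), because connectivity profiles are
#' averaged and reported on the correlation scale.
#'
#' @param x,y numeric series.
#' @return Scalar correlation.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("series must have length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation error: constant series")
  }
  stats::cor(x, y)
}

#' Seed-to-target connectivity profile
#'
#' Correlates every seed vertex's series with every target vertex's series.
#' Self-pairs appear as 1. Targets with constant series give undefined
#' entries (`NA`), which downstream averages exclude pairwise with the
#' denominator adjusted.
#'
#' @param ts T x V time-series matrix (timepoints by vertices). Series need
#'   not be demeaned; Pearson correlation is mean-invariant.
#' @param seeds integer vector of seed column indices (row order of the
#'   result follows this order).
#' @param targets integer vector of target columns; default all V columns.
#' @return A `connectivity_profile`: list with `matrix` (n_seeds x m),
#'   `seeds`, `m`, and `undefined` (target columns with constant series).
#' @export
seed_profile <- function(ts, seeds, targets = NULL) {
  ts <- as.matrix(ts)
  if (is.null(targets)) targets <- seq_len(ncol(ts))
  if (any(seeds < 1L | seeds > ncol(ts))) stop("seed index out of range")
  if (any(targets < 1L | targets > ncol(ts))) stop("target index out of range")
  sd_t <- apply(ts[, targets, drop = FALSE], 2, stats::sd)
  sd_s <- apply(ts[, seeds, drop = FALSE], 2, stats::sd)
  if (any(sd_s == 0)) {
    stop("undefined-correlation error: constant seed series at vertex ",
         seeds[which(sd_s == 0)[1]])
  }
  mat <- suppressWarnings(stats::cor(ts[, seeds, drop = FALSE],
                                     ts[, targets, drop = FALSE]))
  undefined <- targets[sd_t == 0]
  mat[, sd_t == 0] <- NA_real_
  structure(list(matrix = mat, seeds = as.integer(seeds),
                 m = length(targets), undefined = as.integer(undefined)),
            class = "connectivity_profile")
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat("connectivity_profile: ", nrow(x$matrix), " seeds x ", x$m, " targets\n", sep = "")
  invisible(x)
}

#' Incremental group PCA (MIGP) pseudo-time-series
#'
#' Streams subjects through a running PCA: the running state is stacked with
#' each subject's (per-vertex demeaned) series and replaced by the projection
#' onto the top `internal_dim` temporal eigenvectors of the stack. Because
#' the state's spatial Gram matrix equals that of all data seen so far (up to
#' truncation), the output closely approximates the principal subspace of the
#' full temporal concatenation without ever forming it; with
#' `internal_dim >= sum(T_i)` the equality is exact. The result is a
#' pseudo-time-series of `out_dim` rows, comparable in size to one subject's
#' run, used for group-level connectivity.
#'
#' @param subject_series ordered list of T_i x V matrices (shared V).
#' @param internal_dim running-state dimension; default `2 * out_dim`.
#' @param out_dim rows of the returned pseudo-time-series.
#' @param rng_seed reserved for optional subject-order randomization; subjects
#'   are processed in the order given.
#' @return A `group_timeseries`: list with `matrix` (out_dim x V),
#'   `internal_dim`, `n_subjects`.
#' @export
migp <- function(subject_series, out_dim, internal_dim = 2L * out_dim,
                 rng_seed = NULL) {
  stopifnot(is.list(subject_series), length(subject_series) > 0)
  V <- ncol(subject_series[[1]])
  if (internal_dim < out_dim) stop("internal_dim must be >= out_dim")
  W <- NULL
  for (s in seq_along(subject_series)) {
    X <- as.matrix(subject_series[[s]])
    if (ncol(X) != V) {
      stop("dimension error: subject ", s, " has ", ncol(X),
           " vertices, expected ", V)
    }
    X <- sweep(X, 2, colMeans(X))  # demean per vertex
    S <- rbind(W, X)
    k <- min(internal_dim, nrow(S))
    eg <- eigen(tcrossprod(S), symmetric = TRUE)
    W <- crossprod(eg$vectors[, seq_len(k), drop = FALSE], S)
  }
  if (nrow(W) < out_dim) stop("fewer stacked timepoints than out_dim")
  structure(list(matrix = W[seq_len(out_dim), , drop = FALSE],
                 internal_dim = as.integer(internal_dim),
                 n_subjects = length(subject_series)),
            class = "group_timeseries")
}

ts_matrix <- function(x) {
  if (inherits(x, "group_timeseries")) x$matrix else as.matrix(x)
}

#' Functional connectivity asymmetry of paired seed vertices
#'
#' For each homologous seed pair i, the mean absolute difference between the
#' left and right whole-brain connectivity profiles:
#' `FCA(i) = sum_j |CO_L(i, j) - CO_R(i, j)| / m`. Undefined entries are
#' excluded pairwise with the denominator adjusted. FCA is nonnegative, zero
#' iff the paired rows are identical, and symmetric in its two profile
#' arguments.
#'
#' @param left_profile,right_profile `connectivity_profile`s with the same
#'   target count and seed rows paired in order (row i of each is the
#'   homologous pair).
#' @return An `fca_map`: list with `values` (length n_seeds), `seeds` (the
#'   left profile's seed indices), `m`.
#' @export
fca_map <- function(left_profile, right_profile) {
  L <- left_profile$matrix; R <- right_profile$matrix
  if (ncol(L) != ncol(R)) {
    stop("dimension error: profiles have different target counts (",
         ncol(L), " vs ", ncol(R), ")")
  }
  if (nrow(L) != nrow(R)) stop("dimension error: profiles have different seed counts")
  values <- rowMeans(abs(L - R), na.rm = TRUE)
  structure(list(values = values, seeds = left_profile$seeds, m = ncol(L)),
            class = "fca_map")
}

#' Subject- or group-level FCA map over a seed mask
#'
#' Convenience wrapper: builds the left- and right-seed whole-brain profiles
#' from a pair of hemisphere time series (whole brain = all 2V vertices of
#' both hemispheres, seeds included) and returns the FCA coefficient of every
#' seed pair as a vertex map over the mask.
#'
#' @param ts_left,ts_right T x V time-series matrices of the two hemispheres.
#' @param seed_mask integer vector of seed vertices (left-hemisphere indices).
#' @param corr [correspondence_map()]; the right homologue of left vertex v
#'   is `corr[v]`.
#' @return Length-V numeric vector: FCA at seed-mask vertices, `NA` elsewhere.
#' @export
fca_from_series <- function(ts_left, ts_right, seed_mask, corr = NULL) {
  V <- ncol(ts_left)
  if (ncol(ts_right) != V) stop("dimension error: hemispheres differ in V")
  if (is.null(corr)) corr <- correspondence_map(seq_len(V))
  wb <- cbind(ts_left, ts_right)
  left_prof <- seed_profile(wb, seeds = seed_mask)
  right_prof <- seed_profile(wb, seeds = V + corr[seed_mask])
  fca <- fca_map(left_prof, right_prof)
  out <- rep(NA_real_, V)
  out[seed_mask] <- fca$values
  out
}

#' Mean connectivity strength of each seed
#'
#' Per-seed mean of the profile's correlations over all targets (undefined
#' entries excluded).
#'
#' @param profile a `connectivity_profile`.
#' @return Numeric vector, one mean per seed.
#' @export
mean_connectivity_strength <- function(profile) {
  rowMeans(profile$matrix, na.rm = TRUE)
}

#' Define a network mask by seed-correlation thresholding
#'
#' Vertices whose mean correlation with the seed vertices exceeds
#' `threshold_r`, excluding the seed itself.
#'
#' @param group_ts `group_timeseries` or T x V matrix.
#' @param seed integer vector of seed vertices.
#' @param threshold_r correlation threshold in (0, 1).
#' @return Sorted integer mask (possibly empty, with a warning).
#' @export
network_from_seed <- function(group_ts, seed, threshold_r) {
  if (threshold_r <= 0 || threshold_r >= 1) {
    stop("threshold_r must be in (0, 1)")
  }
  ts <- ts_matrix(group_ts)
  cm <- rowMeans(suppressWarnings(stats::cor(ts, ts[, seed, drop = FALSE])))
  members <- setdiff(which(!is.na(cm) & cm > threshold_r), seed)
  if (length(members) == 0L) warning("no vertex exceeds the threshold; empty network")
  sort(members)
}
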