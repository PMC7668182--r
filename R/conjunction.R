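#' Conjunction (intersection) of two cluster masks
#'
#' The "functional asymmetry (FA) cluster": the set intersection of the
#' significant activity-asymmetry and connectivity-asymmetry clusters.
#'
#' @param a,b integer masks on the same mesh.
#' @return Sorted integer mask; empty with a warning if the masks are
#'   disjoint.
#' @export
conjunction_mask <- function(a, b) {
  out <- sort(intersect(as.integer(a), as.integer(b)))
  if (length(out) == 0L) warning("conjunction is empty")
  out
}

#' Correlation between two per-subject asymmetry indices
#'
#' Pearson r between paired subject coefficients (e.g. RRA vs FCA in the FA
#' cluster), with the two-tailed p from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y paired per-subject coefficients (n >= 3).
#' @return A one-row [tibble::tibble()] with `r`, `n`, `p`.
#' @export
cross_index_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("coefficient vectors must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation error: constant coefficient vector")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ht$estimate), n = length(x), p = ht$p.value)
}

#' Combined functional-asymmetry coefficient per subject
#'
#' The FA coefficient is the mean of the RRA and FCA coefficients. Because
#' the two live on different scales (z-units vs correlation units), each is
#' z-scored across subjects before averaging by default; `standardize =
#' FALSE` averages the raw values.
#'
#' @param rra,fca paired per-subject coefficients.
#' @param standardize z-score each vector across subjects first.
#' @return A [tibble::tibble()] with `subject`, `rra`, `fca`, `fa`.
#' @export
fa_coefficients <- function(rra, fca, standardize = TRUE) {
  if (length(rra) != length(fca)) stop("coefficient vectors must be paired")
  a <- rra; b <- fca
  if (standardize) {
    a <- as.numeric(scale(a)); b <- as.numeric(scale(b))
  }
  tibble::tibble(subject = seq_along(rra), rra = rra, fca = fca,
                 fa = (a + b) / 2)
}

#' Screen behavioural covariates against FA coefficients
#'
#' One Pearson correlation per covariate, missing entries dropped pairwise
#' (per-covariate n reported); a covariate is flagged significant when its
#' two-tailed p falls below `alpha`. Covariates with fewer than 3 paired
#' observations are flagged untestable.
#'
#' @param fa_coeffs per-subject FA coefficients.
#' @param covariates data frame, one row per subject, one column per
#'   covariate; `NA`s allowed.
#' @param alpha significance threshold (default 0.001, a fixed
#'   multiple-comparison allowance for large behavioural batteries).
#' @return A [tibble::tibble()] with `covariate`, `n`, `r`, `p`,
#'   `significant`, `testable`.
#' @export
covariate_screen <- function(fa_coeffs, covariates, alpha = 0.001) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(fa_coeffs)) {
    stop("covariates must have one row per subject")
  }
  if (ncol(covariates) < 1L) stop("need at least one covariate")
  rows <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    ok <- is.finite(fa_coeffs) & is.finite(v)
    n <- sum(ok)
    if (n < 3L || stats::sd(v[ok]) == 0 || stats::sd(fa_coeffs[ok]) == 0) {
      return(tibble::tibble(covariate = nm, n = n, r = NA_real_, p = NA_real_,
                            significant = FALSE, testable = FALSE))
    }
    ht <- stats::cor.test(fa_coeffs[ok], v[ok], method = "pearson")
    tibble::tibble(covariate = nm, n = n, r = unname(ht$estimate), p = ht$p.value,
                   significant = ht$p.value < alpha, testable = TRUE)
  })
  do.call(rbind, rows)
}

#' Hemispheric temporal-SNR control in a region
#'
#' Computes each subject's temporal SNR (mean over SD of the raw series) per
#' vertex, averages it over the region per hemisphere, and paired-t-tests
#' left vs right across subjects. Vertices with zero temporal SD are excluded
#' with the count reported. A nonsignificant result supports the asymmetry
#' statistics not being driven by hemispheric signal-quality differences.
#'
#' @param ts_left,ts_right lists (one element per subject) of raw T x V
#'   time-series matrices.
#' @param region integer mask of left-hemisphere vertices.
#' @param corr [correspondence_map()]; right homologues are `corr[region]`.
#' @return List with `t`, `df`, `p`, `mean_diff` (right minus left),
#'   `snr_left`, `snr_right`, `n_excluded`.
#' @export
snr_check <- function(ts_left, ts_right, region, corr = NULL) {
  stopifnot(length(ts_left) == length(ts_right))
  n <- length(ts_left)
  if (n < 2L) stop("need at least 2 subjects")
  if (is.null(corr)) corr <- correspondence_map(seq_len(ncol(ts_left[[1]])))
  region_r <- corr[region]
  excluded <- 0L
  tsnr_region <- function(ts, idx) {
    X <- as.matrix(ts)[, idx, drop = FALSE]
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    keep <- sdv > 0
    excluded <<- excluded + sum(!keep)
    if (!any(keep)) return(NA_real_)
    mean(mu[keep] / sdv[keep])
  }
  snr_l <- vapply(ts_left, tsnr_region, numeric(1), idx = region)
  snr_r <- vapply(ts_right, tsnr_region, numeric(1), idx = region_r)
  d <- snr_r - snr_l
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = n - 1L, p = 1, mean_diff = mean(d),
                snr_left = snr_l, snr_right = snr_r, n_excluded = excluded))
  }
  ht <- stats::t.test(snr_r, snr_l, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_diff = mean(d), snr_left = snr_l, snr_right = snr_r,
       n_excluded = excluded)
}
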