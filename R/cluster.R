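# Cluster-mass inference on the mesh: group t-maps, supra-threshold connected
# components, and the Fisher randomization null of per-subject within-mask
# spatial shuffles.

# adjacency restricted to the mask, in mask-local indices
mask_local_adjacency <- function(adjacency, mask) {
  V <- attr(adjacency, "n_vertices")
  if (any(mask < 1L | mask > V)) stop("mesh error: mask vertex outside adjacency")
  local <- integer(V)
  local[mask] <- seq_along(mask)
  lapply(adjacency[mask], function(nb) local[nb[local[nb] > 0L]])
}

# vectorized one-sample t against 0 per column; zero-variance columns give
# t = 0 when the mean is 0 and +/-Inf otherwise (flagged by the caller)
columnwise_t <- function(X) {
  n <- nrow(X)
  cm <- colMeans(X)
  v <- (colSums(X * X) - n * cm * cm) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  t <- ifelse(se > 0, cm / se, ifelse(cm == 0, 0, sign(cm) * Inf))
  t
}

# connected components of supra-threshold vertices; local indices in, list of
# (vertices, mass) out
supra_components <- function(t_loc, adj_local, threshold) {
  supra <- which(t_loc > threshold)
  if (length(supra) == 0L) return(list())
  M <- length(t_loc)
  in_supra <- logical(M); in_supra[supra] <- TRUE
  visited <- logical(M)
  out <- list()
  for (v in supra) {
    if (visited[v]) next
    visited[v] <- TRUE
    stack <- v
    members <- integer(0)
    while (length(stack) > 0) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, u)
      nb <- adj_local[[u]]
      nb <- nb[in_supra[nb] & !visited[nb]]
      visited[nb] <- TRUE
      stack <- c(stack, nb)
    }
    out[[length(out) + 1L]] <- list(vertices = sort(members),
                                    mass = sum(t_loc[members]))
  }
  out[order(vapply(out, `[[`, numeric(1), "mass"), decreasing = TRUE)]
}

as_value_matrix <- function(subject_maps, mask) {
  if (is.matrix(subject_maps)) {
    if (ncol(subject_maps) == length(mask)) return(subject_maps)
    return(subject_maps[, mask, drop = FALSE])
  }
  rows <- lapply(subject_maps, function(m) {
    v <- if (inherits(m, "asym_map")) m$unsigned else vm_values(m)
    v[mask]
  })
  do.call(rbind, rows)
}

#' Vertex-wise group one-sample t map
#'
#' Per-vertex one-sample t of the subject values against 0 across the mask.
#' Vertices with zero between-subject variance get t = 0 (mean 0) or
#' infinite t (nonzero mean) and are flagged in the `degenerate` attribute.
#'
#' @param subject_maps list of per-subject maps (numeric vectors,
#'   [vertex_map()]s or `asym_map`s, from which the unsigned values are
#'   taken), or an n x V (or n x length(mask)) matrix.
#' @param mask integer mask vertices.
#' @return Length-V [vertex_map()]-like numeric vector with t values inside
#'   the mask and `NA` outside; attribute `degenerate` lists flagged vertices.
#' @export
group_t_map <- function(subject_maps, mask) {
  X <- as_value_matrix(subject_maps, mask)
  if (nrow(X) < 2L) stop("need at least 2 subjects")
  t_loc <- columnwise_t(X)
  V <- max(mask)
  out <- rep(NA_real_, V)
  out[mask] <- t_loc
  attr(out, "degenerate") <- mask[!is.finite(t_loc) | (t_loc == 0 & colMeans(X) == 0 &
                                                         apply(X, 2, stats::sd) == 0)]
  out
}

#' Supra-threshold clusters on the mesh
#'
#' Connected components (triangle-edge adjacency) of mask vertices whose t
#' value exceeds the threshold, with the cluster mass = sum of t over
#' members; sorted by descending mass. One-sided: only positive exceedances
#' count, since the tested maps (unsigned asymmetry, FCA) are nonnegative.
#'
#' @param t_map length-V numeric vector of t values (`NA` allowed outside the
#'   mask).
#' @param mask integer mask vertices.
#' @param adjacency `mesh_adjacency` covering the mask.
#' @param threshold cluster-forming threshold (z/t units).
#' @return List of clusters, each `list(vertices, mass)` with global vertex
#'   indices; empty list if nothing is supra-threshold.
#' @export
find_clusters <- function(t_map, mask, adjacency, threshold) {
  adj_local <- mask_local_adjacency(adjacency, mask)
  comps <- supra_components(as.numeric(t_map)[mask], adj_local, threshold)
  lapply(comps, function(cl) list(vertices = mask[cl$vertices], mass = cl$mass))
}

#' Fisher randomization cluster-mass test
#'
#' Tests vertex-wise group asymmetry maps for spatially clustered effects.
#' Observed clusters are the supra-threshold connected components of the
#' group one-sample t map. The null is built by independently shuffling each
#' subject's (z-scored) values uniformly at random across the mask and
#' recording the maximal cluster mass of each shuffle; this contrasts
#' "more asymmetric here than elsewhere in the mask" against spatial
#' exchangeability. Each observed cluster's corrected p-value is
#' `(1 + #\{null max >= mass\}) / (1 + n_perm)` (ties count toward the null;
#' with `plus_one = FALSE` the plain proportion of larger null maxima is
#' returned instead).
#'
#' @param subject_maps per-subject maps (see [group_t_map()]); one map per
#'   subject, z-scored within the mask unless `zscore = TRUE` (default), in
#'   which case the standardization is applied here.
#' @param mask integer mask vertices.
#' @param adjacency `mesh_adjacency`.
#' @param threshold_z cluster-forming threshold applied to the group t map
#'   (default 2.3, i.e. p = 0.01 one-sided normal).
#' @param n_perm number of random shuffles (>= 100).
#' @param rng_seed integer seed for reproducibility.
#' @param zscore standardize each subject's values across the mask first.
#' @param plus_one use the (1 + k) / (1 + n) estimator (never exactly zero).
#' @return A `cluster_test`: list with `t_map` (length-V, `NA` outside mask),
#'   `threshold`, `clusters` (each `vertices`, `mass`, `p_corr`),
#'   `null_max_mass`, `n_perm`, `rng_seed`, `n_subjects`.
#' @export
fisher_randomization_test <- function(subject_maps, mask, adjacency,
                                      threshold_z = 2.3, n_perm = 1000L,
                                      rng_seed = NULL, zscore = TRUE,
                                      plus_one = TRUE) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  X <- as_value_matrix(subject_maps, mask)
  n <- nrow(X); M <- ncol(X)
  if (n < 2L) stop("need at least 2 subjects")
  if (zscore) {
    X <- t(apply(X, 1, function(v) {
      s <- stats::sd(v)
      if (s == 0) stop("degenerate-data error: zero variance within mask")
      (v - mean(v)) / s
    }))
  }
  adj_local <- mask_local_adjacency(adjacency, mask)
  t_loc <- columnwise_t(X)
  comps <- supra_components(t_loc, adj_local, threshold_z)

  if (!is.null(rng_seed)) set.seed(rng_seed)
  null_max <- numeric(n_perm)
  Xp <- X
  for (p in seq_len(n_perm)) {
    for (i in seq_len(n)) Xp[i, ] <- X[i, sample.int(M)]
    tp <- columnwise_t(Xp)
    cp <- supra_components(tp, adj_local, threshold_z)
    null_max[p] <- if (length(cp)) cp[[1]]$mass else 0
  }

  clusters <- lapply(comps, function(cl) {
    k <- sum(null_max >= cl$mass)
    p_corr <- if (plus_one) (1 + k) / (1 + n_perm) else k / n_perm
    list(vertices = mask[cl$vertices], mass = cl$mass, p_corr = p_corr)
  })
  V <- max(mask)
  t_full <- rep(NA_real_, V)
  t_full[mask] <- t_loc
  structure(list(t_map = t_full, threshold = threshold_z, clusters = clusters,
                 null_max_mass = null_max, n_perm = as.integer(n_perm),
                 rng_seed = rng_seed, n_subjects = n),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("cluster_test: ", length(x$clusters), " supra-threshold cluster(s), ",
      "threshold z > ", x$threshold, ", ", x$n_perm, " randomizations\n", sep = "")
  for (cl in x$clusters) {
    cat("  cluster of ", length(cl$vertices), " vertices, mass ",
        signif(cl$mass, 5), ", p_corr = ", signif(cl$p_corr, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Smallest corrected p-value of a cluster test
#'
#' @param result a `cluster_test`.
#' @return Minimum `p_corr` over clusters, or `NA` if there is no cluster.
#' @export
min_p_corr <- function(result) {
  if (length(result$clusters) == 0L) return(NA_real_)
  min(vapply(result$clusters, `[[`, numeric(1), "p_corr"))
}
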