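# Independent oracles and small fixtures shared across tests. Each oracle is
# a deliberately naive implementation (loops, enumeration, explicit algebra)
# kept separate from the package's code paths.

# brute-force adjacency: scan every triangle pair of edges
oracle_adjacency <- function(mesh) {
  V <- mesh$n_vertices
  adj <- lapply(seq_len(V), function(i) integer(0))
  for (f in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[f, ]
    for (a in tri) for (b in tri) {
      if (a != b) adj[[a]] <- union(adj[[a]], b)
    }
  }
  lapply(adj, sort)
}

# brute-force FCA: O(n * m) double loop
oracle_fca <- function(L, R) {
  n <- nrow(L); m <- ncol(L)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (j in seq_len(m)) {
      d <- abs(L[i, j] - R[i, j])
      if (is.finite(d)) { acc <- acc + d; cnt <- cnt + 1 }
    }
    out[i] <- acc / cnt
  }
  out
}

# independent flood fill over supra-threshold vertices (global indices)
oracle_components <- function(t_map, mask, adj, threshold) {
  supra <- mask[!is.na(t_map[mask]) & t_map[mask] > threshold]
  unseen <- supra
  comps <- list()
  while (length(unseen) > 0) {
    comp <- unseen[1]
    repeat {
      grown <- unique(c(comp, intersect(unlist(adj[comp]), supra)))
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    comps[[length(comps) + 1L]] <- list(vertices = sort(comp),
                                        mass = sum(t_map[comp]))
    unseen <- setdiff(unseen, comp)
  }
  comps[order(vapply(comps, `[[`, numeric(1), "mass"), decreasing = TRUE)]
}

# one-sample t statistic from first principles
oracle_t <- function(v, mu = 0) {
  n <- length(v)
  (mean(v) - mu) / (sqrt(sum((v - mean(v))^2) / (n - 1)) / sqrt(n))
}

# balanced 2x2x2 ANOVA sums of squares via explicit orthogonal projections
# (sum-to-zero coding; every effect has one column, orthogonal under balance)
oracle_anova_ss <- function(tab) {
  y <- tab$mean_connectivity
  s <- ifelse(tab$seed_hemisphere == "R", 1, -1)
  n <- ifelse(tab$network == "ExN", 1, -1)
  h <- ifelse(tab$network_hemisphere == "R", 1, -1)
  cols <- list(seed = s, network = n, net_hemi = h,
               seed_network = s * n, seed_net_hemi = s * h,
               network_net_hemi = n * h, three_way = s * n * h)
  ss <- vapply(cols, function(x) sum(x * y)^2 / sum(x * x), numeric(1))
  total <- sum((y - mean(y))^2)
  c(ss, residual = total - sum(ss))
}

# principal angles (radians) between the row spaces of A and B
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(t(A)))
  qb <- qr.Q(qr(t(B)))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1))
}

# a 4-vertex path graph as a mesh_adjacency (1-2-3-4)
path4_adjacency <- function() {
  structure(list(2L, c(1L, 3L), c(2L, 4L), 3L),
            class = "mesh_adjacency", n_vertices = 4L)
}

# small default cohort configuration for fast tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 6L, V_brain = 162L, V_mask = 40L, T_len = 60L,
                   planted_size = 8L, network_size = 20L, rng_seed = 42L)
  defaults[names(args)] <- args
  do.call(simulation_config, defaults)
}
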