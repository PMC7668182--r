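#' Triangulated hemisphere surface mesh
#'
#' A `surface_mesh` is the spatial substrate for all vertex-wise analyses:
#' vertex coordinates in mm, a triangle list, and a hemisphere label. Cluster
#' contiguity ("contiguous points") is defined through triangle-edge adjacency
#' derived from this object.
#'
#' Vertices and triangle indices are 1-based inside R; on-disk formats that use
#' 0-based indices are converted on read/write.
#'
#' @param vertex_coords numeric matrix, V x 3, vertex positions (mm).
#' @param triangles integer matrix, F x 3, 1-based vertex indices per triangle.
#' @param hemisphere `"left"` or `"right"`.
#' @return An object of class `surface_mesh` with elements `vertex_coords`,
#'   `triangles`, `hemisphere` and `n_vertices`.
#' @export
surface_mesh <- function(vertex_coords, triangles, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  vertex_coords <- as.matrix(vertex_coords)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertex_coords) != 3L) stop("vertex_coords must be a V x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an F x 3 matrix")
  V <- nrow(vertex_coords)
  if (any(triangles < 1L) || any(triangles > V)) {
    stop("mesh error: triangle vertex index out of range [1, ", V, "]")
  }
  structure(
    list(vertex_coords = vertex_coords, triangles = triangles,
         hemisphere = hemisphere, n_vertices = V),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh (", x$hemisphere, "): ", x$n_vertices, " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

#' Vertex adjacency from shared triangle edges
#'
#' Two vertices are neighbours iff they share a triangle edge. This is the
#' contiguity relation used by the cluster statistic; it is symmetric by
#' construction.
#'
#' @param mesh a [surface_mesh()].
#' @return A list of length V; element `i` is the sorted integer vector of
#'   neighbours of vertex `i`. Carries class `mesh_adjacency`.
#' @export
build_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  tr <- mesh$triangles
  # the three edges of every triangle, both directions
  from <- c(tr[, 1], tr[, 2], tr[, 1], tr[, 3], tr[, 2], tr[, 3])
  to   <- c(tr[, 2], tr[, 1], tr[, 3], tr[, 1], tr[, 3], tr[, 2])
  V <- mesh$n_vertices
  adj <- split(to, factor(from, levels = seq_len(V)))
  adj <- lapply(adj, function(v) sort(unique(v)))
  names(adj) <- NULL
  structure(adj, class = "mesh_adjacency", n_vertices = V)
}

#' Subdivided-icosahedron sphere mesh
#'
#' Builds the canonical icosphere used by the synthetic cohort generator:
#' a regular icosahedron (12 vertices, 20 triangles) subdivided `subdivisions`
#' times, vertices projected to a sphere of radius `radius` mm. Vertex counts
#' follow 10 * 4^s + 2 (12, 42, 162, 642, 2562, ...).
#'
#' @param subdivisions non-negative integer.
#' @param radius sphere radius in mm.
#' @param hemisphere label for the resulting mesh.
#' @return A [surface_mesh()].
#' @export
icosphere <- function(subdivisions = 0L, radius = 100, hemisphere = "right") {
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    verts_list <- asplit(verts, 1)
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midpoint_cache[[key]]
      if (is.null(idx)) {
        verts_list[[length(verts_list) + 1L]] <<- (verts[a, ] + verts[b, ]) / 2
        idx <- length(verts_list)
        midpoint_cache[[key]] <- idx
      }
      idx
    }
    new_faces <- vector("list", nrow(faces) * 4L)
    for (f in seq_len(nrow(faces))) {
      a <- faces[f, 1]; b <- faces[f, 2]; c_ <- faces[f, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
      new_faces[[4 * f - 3]] <- c(a, ab, ca)
      new_faces[[4 * f - 2]] <- c(b, bc, ab)
      new_faces[[4 * f - 1]] <- c(c_, ca, bc)
      new_faces[[4 * f]]     <- c(ab, bc, ca)
    }
    verts <- do.call(rbind, verts_list)
    faces <- do.call(rbind, new_faces)
  }
  verts <- verts / sqrt(rowSums(verts^2)) * radius
  surface_mesh(verts, faces, hemisphere)
}

#' Contiguous patch of vertices grown from a centre
#'
#' Deterministic breadth-first region growing: vertices are added ring by ring
#' (ties broken by vertex index) until `size` vertices are collected. Used to
#' define analysis masks, planted regions and network patches on synthetic
#' meshes.
#'
#' @param adjacency a `mesh_adjacency` (see [build_adjacency()]).
#' @param center starting vertex index.
#' @param size number of vertices in the patch.
#' @param avoid integer vector of vertices the patch must not enter.
#' @return Sorted integer vector of vertex indices (a mask).
#' @export
mesh_patch <- function(adjacency, center, size, avoid = integer(0)) {
  V <- attr(adjacency, "n_vertices")
  if (center %in% avoid) stop("patch centre lies in the avoided set")
  if (size < 1L) stop("patch size must be positive")
  visited <- logical(V)
  visited[avoid] <- TRUE
  out <- integer(0)
  frontier <- center
  visited[center] <- TRUE
  while (length(out) < size && length(frontier) > 0) {
    take <- utils::head(frontier, size - length(out))
    out <- c(out, take)
    nxt <- sort(unique(unlist(adjacency[frontier], use.names = FALSE)))
    frontier <- nxt[!visited[nxt]]
    visited[frontier] <- TRUE
  }
  if (length(out) < size) {
    stop("mesh too small to grow a patch of ", size, " vertices from vertex ", center)
  }
  sort(out)
}
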