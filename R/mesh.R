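#' Triangulated source-space meshes
#'
#' A `meg_mesh` is the ground space for all source estimates and geodesic
#' computations in this package: a triangulated surface with vertex
#' coordinates in millimetres, an edge graph weighted by Euclidean edge
#' lengths, and a hemisphere label per vertex.  The template source space is
#' built from two icosphere halves that carry no cross-hemisphere edges, so
#' geodesic distances between hemispheres are infinite by construction --
#' which is exactly the semantics the wrong-hemisphere outlier rule of the
#' evaluation module relies on.
#'
#' @name meg_mesh
#' @keywords internal
NULL

new_meg_mesh <- function(vertices, triangles, hemisphere) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3L,
            is.matrix(triangles), ncol(triangles) == 3L)
  m <- structure(
    list(vertices = vertices,
         triangles = triangles,
         hemisphere = hemisphere),
    class = "meg_mesh")
  e <- mesh_edges(m)
  m$edges <- e$edges
  m$edge_lengths <- e$lengths
  m$graph <- igraph::graph_from_edgelist(e$edges, directed = FALSE)
  # isolated-vertex guard: make sure the graph knows about every vertex
  if (igraph::vcount(m$graph) < nrow(vertices)) {
    m$graph <- igraph::add_vertices(m$graph,
                                    nrow(vertices) - igraph::vcount(m$graph))
  }
  igraph::E(m$graph)$weight <- e$lengths
  m
}

#' @export
print.meg_mesh <- function(x, ...) {
  cat(sprintf("<meg_mesh> %d vertices, %d triangles, %d edges\n",
              nrow(x$vertices), nrow(x$triangles), nrow(x$edges)))
  cat(sprintf("  hemispheres: %s\n",
              paste(sprintf("%s=%d", names(table(x$hemisphere)),
                            as.integer(table(x$hemisphere))),
                    collapse = ", ")))
  invisible(x)
}

# unique undirected edges and their Euclidean lengths
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  d <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                       mesh$vertices[e[, 2L], , drop = FALSE])^2))
  list(edges = e, lengths = d)
}

# base icosahedron with unit circumradius
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, triangles = f)
}

#' Build an icosphere mesh
#'
#' Recursively subdivides a regular icosahedron, reprojecting every new
#' vertex onto the sphere.  Subdivision level `s` yields `10 * 4^s + 2`
#' vertices and `20 * 4^s` triangles; level 4 gives the 2562 vertices per
#' hemisphere used by the template source space.
#'
#' @param subdivisions Non-negative integer number of subdivision passes
#'   (at most 7).
#' @param radius Sphere radius in millimetres; must be positive.
#' @return A [meg_mesh] with all vertices at distance `radius` from the
#'   origin and a single hemisphere label `"single"`.
#' @examples
#' m <- build_icosphere(0, 1)
#' nrow(m$vertices)  # 12
#' @export
build_icosphere <- function(subdivisions, radius = 35) {
  if (length(subdivisions) != 1L || is.na(subdivisions) ||
      subdivisions < 0 || subdivisions != round(subdivisions)) {
    stop("`subdivisions` must be a single non-negative integer", call. = FALSE)
  }
  if (subdivisions > 7) {
    stop("`subdivisions` > 7 would produce an unreasonably large mesh",
         call. = FALSE)
  }
  if (length(radius) != 1L || is.na(radius) || radius <= 0) {
    stop("`radius` must be a single positive number", call. = FALSE)
  }
  ico <- icosahedron()
  v <- ico$vertices
  f <- ico$triangles
  for (s in seq_len(subdivisions)) {
    n_v <- nrow(v)
    # midpoint cache keyed by ordered vertex pair
    key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
    ek <- key(edges[, 1L], edges[, 2L])
    uniq <- !duplicated(ek)
    mid_of <- match(ek, ek[uniq])
    mids <- (v[edges[uniq, 1L], , drop = FALSE] +
               v[edges[uniq, 2L], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    n_f <- nrow(f)
    m12 <- n_v + mid_of[seq_len(n_f)]
    m23 <- n_v + mid_of[n_f + seq_len(n_f)]
    m13 <- n_v + mid_of[2L * n_f + seq_len(n_f)]
    f <- rbind(cbind(f[, 1L], m12, m13),
               cbind(f[, 2L], m23, m12),
               cbind(f[, 3L], m13, m23),
               cbind(m12, m23, m13))
  }
  new_meg_mesh(v * radius, f, rep("single", nrow(v)))
}

#' Build the two-hemisphere template source space
#'
#' Places two icosphere copies side by side along the x axis, their centres
#' `hemisphere_gap` millimetres apart, and labels vertices `"left"`
#' (negative x offset) and `"right"`.  No edges connect the copies, so the
#' edge graph has exactly two components and cross-hemisphere geodesic
#' distances are infinite.  The defaults keep the two spheres disjoint
#' (gap > 2 * radius, a 2 mm inter-hemispheric fissure): overlapping
#' hemisphere spheres would place left and right sources at nearly the
#' same physical location, making their leadfield columns degenerate and
#' mirror-ghost artefacts unavoidable.
#'
#' @inheritParams build_icosphere
#' @param hemisphere_gap Distance in mm between the two sphere centres;
#'   values below `2 * radius` interpenetrate the hemispheres.
#' @return A [meg_mesh] with `2 * (10 * 4^subdivisions + 2)` vertices.
#' @export
build_template_space <- function(subdivisions = 4, radius = 35,
                                 hemisphere_gap = 72) {
  if (length(hemisphere_gap) != 1L || is.na(hemisphere_gap) ||
      hemisphere_gap < 0) {
    stop("`hemisphere_gap` must be a single non-negative number",
         call. = FALSE)
  }
  half <- build_icosphere(subdivisions, radius)
  n <- nrow(half$vertices)
  off <- c(hemisphere_gap / 2, 0, 0)
  lv <- sweep(half$vertices, 2L, off, `-`)
  rv <- sweep(half$vertices, 2L, off, `+`)
  vertices <- rbind(lv, rv)
  triangles <- rbind(half$triangles, half$triangles + n)
  m <- new_meg_mesh(vertices, triangles,
                    c(rep("left", n), rep("right", n)))
  m$hemisphere_centers <- rbind(left = -off, right = off)
  m$radius <- radius
  m
}

#' Geodesic distances along the mesh edge graph
#'
#' Shortest-path (Dijkstra) distance from `source_vertex` to every vertex,
#' with edge weights equal to Euclidean edge lengths in mm.  Vertices in a
#' different connected component (the other hemisphere of a template space)
#' receive `Inf`.
#'
#' @param mesh A [meg_mesh].
#' @param source_vertex Vertex index (1-based), or a vector of indices in
#'   which case a `length(source_vertex) x P` matrix is returned.
#' @return Numeric vector of distances in mm (or a matrix for several
#'   sources).
#' @export
geodesic_distances <- function(mesh, source_vertex) {
  p <- nrow(mesh$vertices)
  if (any(is.na(source_vertex)) || any(source_vertex < 1) ||
      any(source_vertex > p) || any(source_vertex != round(source_vertex))) {
    stop("invalid `source_vertex` index", call. = FALSE)
  }
  d <- igraph::distances(mesh$graph, v = source_vertex,
                         algorithm = "dijkstra")
  if (length(source_vertex) == 1L) drop(d) else d
}

#' Vertex indices of one hemisphere
#' @param mesh A [meg_mesh].
#' @param hemi `"left"` or `"right"` (or any label present in the mesh).
#' @return Integer vector of vertex indices.
#' @export
hemisphere_vertices <- function(mesh, hemi) {
  which(mesh$hemisphere == hemi)
}

#' Export a mesh to OFF text format
#'
#' Plain-text Object File Format export for inspection in external mesh
#' viewers.
#'
#' @param mesh A [meg_mesh].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)),
             con)
  utils::write.table(format(mesh$vertices, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
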