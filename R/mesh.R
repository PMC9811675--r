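#' Synthetic two-hemisphere cortical mesh
#'
#' Places `n` vertices per hemisphere on a sphere of the given radius using a
#' deterministic Fibonacci spiral (near-uniform spacing), applies a seeded
#' random rotation, and offsets the hemispheres along x by five radii so they
#' are geometrically and topologically disjoint. Adjacency is a symmetrized
#' k-nearest-neighbour graph (k = min(6, n-1)) with a connectivity repair
#' pass, giving a connected sphere-like mesh with vertex degrees >= 3 and no
#' cross-hemisphere edges. For n = 4 each hemisphere is the complete graph on
#' four vertices (a tetrahedron).
#'
#' @param n_vertices_per_hemisphere Vertices per hemisphere (>= 4).
#' @param radius_mm Sphere radius in mm.
#' @param seed Integer seed for the random rotation.
#' @return An object of class `cortical_mesh` with fields `coords`
#'   (2n x 3 matrix, mm), `hemisphere` (character "L"/"R"), and `edges`
#'   (two-column integer matrix of undirected edges, a < b).
#' @export
make_mesh <- function(n_vertices_per_hemisphere, radius_mm, seed = 1L) {
  n <- as.integer(n_vertices_per_hemisphere)
  if (n < 4L) stop("need at least 4 vertices per hemisphere to triangulate")
  pts <- fibonacci_sphere(n, radius_mm)
  rot <- withr::with_seed(derive_seed(seed, "mesh-rotation"), random_rotation())
  pts <- pts %*% rot
  offset <- 2.5 * radius_mm
  coords <- rbind(sweep(pts, 2L, c(-offset, 0, 0), "+"),
                  sweep(pts, 2L, c(+offset, 0, 0), "+"))
  hemisphere <- rep(c("L", "R"), each = n)
  k <- min(6L, n - 1L)
  edges <- rbind(knn_edges(coords[seq_len(n), , drop = FALSE], k, 0L),
                 knn_edges(coords[n + seq_len(n), , drop = FALSE], k, n))
  mesh <- structure(list(coords = coords, hemisphere = hemisphere,
                         edges = edges, radius_mm = radius_mm),
                    class = "cortical_mesh")
  validate_mesh(mesh)
}

fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr_d)
  q %*% diag(sign(diag(qr.R(qr_d))))
}

# symmetrized kNN edges within one hemisphere, repaired to a single component
knn_edges <- function(pts, k, id_offset) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    cbind(pmin(i, nb), pmax(i, nb))
  }))
  pairs <- unique(pairs)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  while (comp$no > 1L) {  # link the closest pair across the two nearest parts
    a <- which(comp$membership == 1L)
    b <- which(comp$membership != 1L)
    dd <- d[a, b, drop = FALSE]
    ij <- arrayInd(which.min(dd), dim(dd))
    e <- sort(c(a[ij[1L]], b[ij[2L]]))
    pairs <- rbind(pairs, e)
    g <- igraph::add_edges(g, e)
    comp <- igraph::components(g)
  }
  unname(pairs + id_offset)
}

validate_mesh <- function(mesh) {
  e <- mesh$edges
  if (any(e[, 1L] == e[, 2L])) stop("mesh has self-edges")
  if (any(mesh$hemisphere[e[, 1L]] != mesh$hemisphere[e[, 2L]])) {
    stop("mesh has cross-hemisphere edges")
  }
  deg <- tabulate(c(e), nbins = nrow(mesh$coords))
  if (any(deg < 3L)) stop("mesh vertex with degree < 3")
  mesh
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat("<cortical_mesh> ", nrow(x$coords), " vertices (",
      sum(x$hemisphere == "L"), " L / ", sum(x$hemisphere == "R"),
      " R), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Searchlight patch membership
#'
#' All vertices within `radius_mm` Euclidean distance of the center vertex,
#' restricted to the center's hemisphere (patches never cross the midline).
#' Always contains the center; radius 0 gives a singleton.
#'
#' @param mesh A `cortical_mesh` (see [make_mesh]).
#' @param center Vertex id (row index into `mesh$coords`).
#' @param radius_mm Patch radius in mm.
#' @return Integer vector of vertex ids.
#' @export
patch_vertices <- function(mesh, center, radius_mm = 20) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  center <- as.integer(center)
  if (center < 1L || center > nrow(mesh$coords)) {
    stop("unknown center vertex: ", center)
  }
  d2 <- colSums((t(mesh$coords) - mesh$coords[center, ])^2)
  hits <- which(d2 <= radius_mm^2 & mesh$hemisphere == mesh$hemisphere[center])
  sort(unique(c(center, hits)))
}

#' Write / read a mesh as a TSV pair
#'
#' `<prefix>_vertices.tsv` holds (id, hemisphere, x_mm, y_mm, z_mm);
#' `<prefix>_edges.tsv` holds (id_a, id_b).
#'
#' @param mesh A `cortical_mesh` (see [make_mesh]).
#' @param prefix Path prefix for the two files.
#' @return `write_mesh_tsv` returns the two paths invisibly; `read_mesh_tsv`
#'   a `cortical_mesh` (see [make_mesh]).
#' @export
write_mesh_tsv <- function(mesh, prefix) {
  vp <- paste0(prefix, "_vertices.tsv")
  ep <- paste0(prefix, "_edges.tsv")
  utils::write.table(
    data.frame(id = seq_len(nrow(mesh$coords)), hemisphere = mesh$hemisphere,
               x_mm = mesh$coords[, 1L], y_mm = mesh$coords[, 2L],
               z_mm = mesh$coords[, 3L]),
    vp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id_a = mesh$edges[, 1L],
                                id_b = mesh$edges[, 2L]),
                     ep, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vertices = vp, edges = ep))
}

#' @rdname write_mesh_tsv
#' @export
read_mesh_tsv <- function(prefix) {
  v <- utils::read.delim(paste0(prefix, "_vertices.tsv"))
  e <- utils::read.delim(paste0(prefix, "_edges.tsv"))
  v <- v[order(v$id), ]
  mesh <- structure(list(coords = as.matrix(v[, c("x_mm", "y_mm", "z_mm")]),
                         hemisphere = v$hemisphere,
                         edges = cbind(e$id_a, e$id_b), radius_mm = NA_real_),
                    class = "cortical_mesh")
  dimnames(mesh$coords) <- NULL
  validate_mesh(mesh)
}
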