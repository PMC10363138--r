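#' Build a bounding volume hierarchy over mesh faces
#'
#' Top-down median split on the longest centroid axis; construction is
#' deterministic for a fixed mesh. The index backs [closestPoint()] and
#' [rayCast()].
#'
#' @param mesh a `triMesh`.
#' @param leafSize maximum faces per leaf.
#' @return object of class `bvhIndex`.
#' @export
buildBVH <- function(mesh, leafSize = 4L) {
  stopifnot(inherits(mesh, "triMesh"))
  if (nrow(mesh$faces) == 0L) stop("cannot index an empty mesh")
  ptr <- bvh_build_cpp(mesh$vertices, mesh$faces, as.integer(leafSize))
  structure(list(ptr = ptr, mesh = mesh, leafSize = as.integer(leafSize)),
            class = "bvhIndex")
}

#' @export
print.bvhIndex <- function(x, ...) {
  cat(sprintf("bvhIndex over %d faces (leaf size %d)\n",
              nrow(x$mesh$faces), x$leafSize))
  invisible(x)
}

#' Globally nearest point on the indexed surface
#'
#' Best-first traversal with a priority queue; boxes whose lower bound exceeds
#' the current best distance are pruned, so the returned distance is the
#' global point-to-surface minimum.
#'
#' @param index a `bvhIndex`.
#' @param query numeric vector (one point) or k x 3 matrix.
#' @return list of class `closestHit`: `distance` (mm, >= 0), `point`
#'   (foot point on the surface), `face` (1-based index), `bary`
#'   (barycentric coordinates of the foot in that face).
#' @export
closestPoint <- function(index, query) {
  stopifnot(inherits(index, "bvhIndex"))
  if (is.null(dim(query))) query <- matrix(query, ncol = 3L)
  query <- as.matrix(query)
  storage.mode(query) <- "double"
  out <- bvh_closest_cpp(index$ptr, query)
  class(out) <- "closestHit"
  out
}

#' First ray hit on the indexed surface
#'
#' Two-sided intersection; the smallest non-negative ray parameter wins. Rays
#' starting exactly on the surface report the origin (t = 0). Misses yield NA.
#'
#' @param index a `bvhIndex`.
#' @param origins k x 3 matrix (or length-3 vector).
#' @param directions k x 3 matrix (or length-3 vector); need not be unit.
#' @return list: `t`, `point` (k x 3), `face`; NA where the ray misses.
#' @export
rayCast <- function(index, origins, directions) {
  stopifnot(inherits(index, "bvhIndex"))
  if (is.null(dim(origins))) origins <- matrix(origins, ncol = 3L)
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3L)
  if (nrow(directions) == 1L && nrow(origins) > 1L)
    directions <- directions[rep(1L, nrow(origins)), , drop = FALSE]
  origins <- as.matrix(origins); directions <- as.matrix(directions)
  storage.mode(origins) <- "double"; storage.mode(directions) <- "double"
  bvh_ray_cpp(index$ptr, origins, directions)
}

#' Leaf inventory of a BVH (for structural audits)
#' @param index a `bvhIndex`.
#' @return list: `lo`,`hi` (leaf boxes), `faces` (list of face ids per leaf),
#'   `root` (2 x 3 root box).
#' @export
bvhLeaves <- function(index) {
  stopifnot(inherits(index, "bvhIndex"))
  bvh_leaves_cpp(index$ptr)
}
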