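#' Sharpness fields of a mesh
#'
#' Two discrete sharpness measures drive margin detection:
#'
#' * per vertex, the cotangent-weighted Laplacian of the coordinates,
#'   `(1/Omega_i) * sum_{(i,j)} ((cot a_ij + cot b_ij)/2) (v_i - v_j)`,
#'   whose magnitude approximates mean curvature -- large on creases;
#' * per edge, an adjusted length `e'_ij = ((n1 . n2 + 1) / 2) * e_ij`
#'   computed from the two incident unit face normals, so edges across sharp
#'   dihedrals become short (coplanar faces keep `e' = e`, perpendicular
#'   normals halve the length, fold-backs collapse to 0). Boundary edges keep
#'   their original length.
#'
#' Cotangents are clamped to `[-cotClamp, cotClamp]` to survive sliver
#' triangles in scanned meshes. The vertex cell area `Omega_i` is barycentric
#' by default (one third of the incident triangle areas, robust to obtuse
#' triangles); `"mixed"` selects the Voronoi-safe mixed area.
#'
#' @param mesh a `triMesh` (edge-manifold).
#' @param vertexArea `"barycentric"` or `"mixed"`.
#' @param cotClamp clamp bound for cotangent weights.
#' @return object of class `sharpnessFields`: `laplacian` (n x 3, 1/mm),
#'   `magnitude` (n), `cellArea` (n, mm^2), `edges` (E x 2), `edgeLength`,
#'   `adjFactor` (in \[0, 1\] on interior edges), `adjLength`, `boundary`
#'   (logical per edge).
#' @export
sharpnessFields <- function(mesh, vertexArea = c("barycentric", "mixed"),
                            cotClamp = 100) {
  vertexArea <- match.arg(vertexArea)
  stopifnot(inherits(mesh, "triMesh"))
  ed <- meshEdges(mesh)
  if (ed$maxIncident > 2L) stop("mesh is not edge-manifold")
  V <- mesh$vertices
  n <- nrow(V)

  cotOf <- function(vOpp, vA, vB) {
    # cot of the angle at vOpp subtended by edge (vA, vB)
    u <- V[vA, , drop = FALSE] - V[vOpp, , drop = FALSE]
    w <- V[vB, , drop = FALSE] - V[vOpp, , drop = FALSE]
    dt <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    cn <- sqrt(rowSums(cr^2))
    pmin(pmax(dt / pmax(cn, 1e-300), -cotClamp), cotClamp)
  }
  ei <- ed$edges[, 1L]; ej <- ed$edges[, 2L]
  cot1 <- cotOf(ed$opp1, ei, ej)
  cot2 <- ifelse(is.na(ed$opp2), 0,
                 cotOf(ifelse(is.na(ed$opp2), ed$opp1, ed$opp2), ei, ej))
  w <- (cot1 + cot2) / 2

  # accumulate w * (v_i - v_j) at i and the negative at j
  dv <- V[ei, , drop = FALSE] - V[ej, , drop = FALSE]
  contrib <- rbind(w * dv, -w * dv)
  grp <- c(ei, ej)
  acc <- rowsum(contrib, grp)
  L <- matrix(0, n, 3L)
  L[as.integer(rownames(acc)), ] <- acc

  Omega <- vertexCellAreas(mesh, vertexArea)
  noFace <- Omega <= 0
  if (any(noFace))
    warning(sum(noFace), " vertex/vertices with no incident face excluded from sharpness")
  L <- L / ifelse(Omega > 0, Omega, Inf)
  mag <- sqrt(rowSums(L^2))

  N <- mesh$normals
  boundary <- is.na(ed$face2)
  dotn <- rep(1, length(ei))
  intn <- !boundary
  dotn[intn] <- rowSums(N[ed$face1[intn], , drop = FALSE] *
                        N[ed$face2[intn], , drop = FALSE])
  factor <- ifelse(boundary, 1, pmin(pmax((dotn + 1) / 2, 0), 1))

  structure(list(laplacian = L, magnitude = mag, cellArea = Omega,
                 edges = ed$edges, edgeLength = ed$length,
                 adjFactor = factor, adjLength = factor * ed$length,
                 boundary = boundary),
            class = "sharpnessFields")
}

#' @export
print.sharpnessFields <- function(x, ...) {
  cat(sprintf("sharpnessFields: %d vertices, %d edges (%d boundary)\n",
              nrow(x$laplacian), nrow(x$edges), sum(x$boundary)))
  cat(sprintf("  vertex sharpness |L|: median %.4f, max %.4f 1/mm\n",
              stats::median(x$magnitude), max(x$magnitude)))
  invisible(x)
}

vertexCellAreas <- function(mesh, method) {
  V <- mesh$vertices; F <- mesh$faces
  n <- nrow(V)
  if (method == "barycentric") {
    acc <- rowsum(rep(mesh$areas / 3, 3L), c(F[, 1L], F[, 2L], F[, 3L]))
    out <- numeric(n)
    out[as.integer(rownames(acc))] <- acc
    return(out)
  }
  # mixed Voronoi (Meyer et al.): Voronoi area at non-obtuse corners,
  # area/2 at an obtuse corner, area/4 at the other two
  a <- V[F[, 1L], , drop = FALSE]
  b <- V[F[, 2L], , drop = FALSE]
  c_ <- V[F[, 3L], , drop = FALSE]
  l2 <- cbind(rowSums((b - c_)^2), rowSums((a - c_)^2), rowSums((a - b)^2)) # opposite each corner
  cotc <- function(p, q, r) {
    u <- q - p; w <- r - p
    dt <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    dt / pmax(sqrt(rowSums(cr^2)), 1e-300)
  }
  ct <- cbind(cotc(a, b, c_), cotc(b, c_, a), cotc(c_, a, b))
  obtuse <- ct < 0
  anyObt <- rowSums(obtuse) > 0L
  A <- mesh$areas
  corner <- matrix(0, nrow(F), 3L)
  # Voronoi corner areas for non-obtuse triangles:
  # corner i gets (l_j^2 cot_j + l_k^2 cot_k)/8 over the two adjacent edges
  vor <- cbind(l2[, 2] * ct[, 2] + l2[, 3] * ct[, 3],
               l2[, 1] * ct[, 1] + l2[, 3] * ct[, 3],
               l2[, 1] * ct[, 1] + l2[, 2] * ct[, 2]) / 8
  corner[!anyObt, ] <- vor[!anyObt, , drop = FALSE]
  if (any(anyObt)) {
    half <- obtuse[anyObt, , drop = FALSE]
    corner[anyObt, ] <- A[anyObt] / 4
    corner[anyObt, ][half] <- rep(A[anyObt], 3L)[as.vector(half)] / 2
  }
  acc <- rowsum(as.vector(corner), as.vector(F))
  out <- numeric(n)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Export per-vertex sharpness as PLY vertex quality (debug aid)
#'
#' Writes an ASCII PLY with a `quality` vertex property holding the Laplacian
#' magnitude.
#' @param mesh a `triMesh`. @param fields matching [sharpnessFields()].
#' @param path output path.
#' @export
writeSharpnessPLY <- function(mesh, fields, path) {
  V <- mesh$vertices; F <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z",
           "property double quality",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.9g %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3], fields$magnitude)
  fl <- sprintf("3 %d %d %d", F[, 1L] - 1L, F[, 2L] - 1L, F[, 3L] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}
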