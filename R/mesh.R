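#' Triangle mesh
#'
#' Constructs a `triMesh`: vertex coordinates (millimetres), 1-based face
#' indices, per-face unit normals and areas (mm^2). Faces with (numerically)
#' zero area are rejected; use [cleanMesh()] to drop them instead.
#'
#' @param vertices numeric matrix, n x 3.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @return object of class `triMesh` with elements `vertices`, `faces`,
#'   `normals` (per face, unit length), `areas`.
#' @export
triMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) == 0L || nrow(vertices) == 0L)
    stop("degenerate input: empty mesh")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face index out of range")
  if (anyNA(vertices) || anyNA(faces)) stop("NA in mesh data")
  g <- faceGeometry(vertices, faces)
  if (any(g$areas <= 0))
    stop("degenerate (zero-area) face present; clean the mesh first")
  structure(list(vertices = vertices, faces = faces,
                 normals = g$normals, areas = g$areas),
            class = "triMesh")
}

faceGeometry <- function(V, F) {
  e1 <- V[F[, 2L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  e2 <- V[F[, 3L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nrm <- sqrt(rowSums(cr^2))
  normals <- cr / ifelse(nrm > 0, nrm, 1)
  list(normals = normals, areas = nrm / 2)
}

#' @export
print.triMesh <- function(x, ...) {
  b <- meshBounds(x)
  cat(sprintf("triMesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bounds [mm]: x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
              b[1, 1], b[2, 1], b[1, 2], b[2, 2], b[1, 3], b[2, 3]))
  cat(sprintf("  surface area: %.3f mm^2\n", sum(x$areas)))
  invisible(x)
}

#' Mesh bounding box
#' @param mesh a `triMesh`.
#' @return 2 x 3 matrix, rows = min/max.
#' @export
meshBounds <- function(mesh) {
  rbind(apply(mesh$vertices, 2L, min), apply(mesh$vertices, 2L, max))
}

#' Clean a raw vertex/face soup
#'
#' Merges duplicate vertices (within `tol`, the load-time merge tolerance;
#' STL repeats every vertex per facet) and drops degenerate faces.
#'
#' @param vertices n x 3 matrix. @param faces m x 3 index matrix.
#' @param tol merge tolerance in mm.
#' @return `triMesh`; attribute `cleaning` records counts.
#' @export
cleanMesh <- function(vertices, faces, tol = 1e-6) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  key <- apply(round(vertices / tol), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  newV <- vertices[first, , drop = FALSE]
  newF <- matrix(map[faces], ncol = 3L)
  # drop faces with repeated vertices or zero area
  degen <- newF[, 1L] == newF[, 2L] | newF[, 2L] == newF[, 3L] | newF[, 1L] == newF[, 3L]
  newF <- newF[!degen, , drop = FALSE]
  if (nrow(newF) > 0L) {
    g <- faceGeometry(newV, newF)
    keep <- g$areas > 1e-12
    newF <- newF[keep, , drop = FALSE]
  }
  if (nrow(newF) == 0L) stop("degenerate input: no faces left after cleaning")
  m <- triMesh(newV, newF)
  attr(m, "cleaning") <- c(rawVertices = nrow(vertices), mergedVertices = nrow(newV),
                           rawFaces = nrow(faces), keptFaces = nrow(newF))
  m
}

#' Edge table of a mesh
#'
#' Unique undirected edges with incident faces and opposite vertices. Used by
#' the sharpness fields, manifold checks and graph construction.
#'
#' @param mesh a `triMesh`.
#' @return list: `edges` (E x 2 vertex indices, i < j), `length` (mm),
#'   `face1`,`face2` (second is NA on boundary edges), `opp1`,`opp2`
#'   (vertex opposite the edge in each incident face), `maxIncident`.
#' @export
meshEdges <- function(mesh) {
  F <- mesh$faces
  n <- nrow(mesh$vertices)
  hi <- c(F[, 1L], F[, 2L], F[, 3L])
  hj <- c(F[, 2L], F[, 3L], F[, 1L])
  hface <- rep.int(seq_len(nrow(F)), 3L)
  hopp <- c(F[, 3L], F[, 1L], F[, 2L])
  a <- pmin(hi, hj); b <- pmax(hi, hj)
  key <- (as.double(a) - 1) * n + as.double(b)
  ord <- order(key, hface)
  ks <- key[ord]
  newg <- c(TRUE, ks[-1L] != ks[-length(ks)])
  eid.sorted <- cumsum(newg)
  E <- eid.sorted[length(eid.sorted)]
  pos <- seq_along(ks) - rep.int(which(newg), tabulate(eid.sorted)) + 1L
  face1 <- rep(NA_integer_, E); face2 <- rep(NA_integer_, E)
  opp1 <- rep(NA_integer_, E); opp2 <- rep(NA_integer_, E)
  ei <- rep(NA_integer_, E); ej <- rep(NA_integer_, E)
  sel1 <- pos == 1L; sel2 <- pos == 2L
  face1[eid.sorted[sel1]] <- hface[ord][sel1]
  opp1[eid.sorted[sel1]] <- hopp[ord][sel1]
  ei[eid.sorted[sel1]] <- a[ord][sel1]
  ej[eid.sorted[sel1]] <- b[ord][sel1]
  face2[eid.sorted[sel2]] <- hface[ord][sel2]
  opp2[eid.sorted[sel2]] <- hopp[ord][sel2]
  maxInc <- max(tabulate(eid.sorted))
  len <- sqrt(rowSums((mesh$vertices[ei, , drop = FALSE] -
                       mesh$vertices[ej, , drop = FALSE])^2))
  list(edges = cbind(ei, ej), length = len, face1 = face1, face2 = face2,
       opp1 = opp1, opp2 = opp2, maxIncident = maxInc)
}

#' Is the mesh edge-manifold (every edge borders at most two faces)?
#' @param mesh a `triMesh`.
#' @export
isEdgeManifold <- function(mesh) meshEdges(mesh)$maxIncident <= 2L

#' Vertex adjacency list
#' @param mesh a `triMesh`.
#' @return list of integer vectors, one per vertex (sorted, unique).
#' @export
vertexAdjacency <- function(mesh) {
  ed <- meshEdges(mesh)$edges
  n <- nrow(mesh$vertices)
  adj <- split(c(ed[, 2L], ed[, 1L]),
               factor(c(ed[, 1L], ed[, 2L]), levels = seq_len(n)))
  lapply(adj, function(v) sort(unique(v)))
}

#' Rigid transform
#'
#' @param rotation 3 x 3 orthonormal matrix, det +1.
#' @param translation length-3 vector (mm).
#' @param rms RMS residual (mm) of the fit that produced it, if any.
#' @return object of class `rigidTransform`.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0), rms = NA_real_) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rms = rms), class = "rigidTransform")
}

#' @export
print.rigidTransform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigidTransform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  if (!is.na(x$rms)) cat(sprintf(", rms %.6f mm", x$rms))
  cat("\n")
  invisible(x)
}

#' Apply a rigid transform to a mesh or point matrix
#' @param x `triMesh` or n x 3 matrix. @param transform a `rigidTransform`.
#' @return transformed object of the same kind.
#' @export
applyTransform <- function(x, transform) {
  if (inherits(x, "triMesh")) {
    V <- x$vertices %*% t(transform$rotation) +
      matrix(transform$translation, nrow(x$vertices), 3, byrow = TRUE)
    triMesh(V, x$faces)
  } else {
    x <- as.matrix(x)
    x %*% t(transform$rotation) + matrix(transform$translation, nrow(x), 3, byrow = TRUE)
  }
}

# orthonormal basis perpendicular to unit axis p
axisBasis <- function(p) {
  p <- p / sqrt(sum(p^2))
  ref <- if (abs(p[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * p) * p
  u <- u / sqrt(sum(u^2))
  v <- c(p[2] * u[3] - p[3] * u[2],
         p[3] * u[1] - p[1] * u[3],
         p[1] * u[2] - p[2] * u[1])
  list(p = p, u = u, v = v)
}
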