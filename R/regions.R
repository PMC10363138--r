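#' Axial lower boundary: the margin translated onto the prepared surface
#'
#' The margin polyline is translated by `offset` along the path of insertion;
#' each translated point is cast horizontally (perpendicular to the axis,
#' toward the axis line) onto the prepared mesh, and the resulting closed
#' polyline directly above the margin is the lower boundary of the axial wall
#' area -- equivalently the upper boundary of the margin band.
#'
#' @param preparedIndex `bvhIndex` over the prepared mesh.
#' @param loop a `marginLoop` or k x 3 coordinate matrix.
#' @param axis insertion axis (unit 3-vector).
#' @param offset translation along the axis, mm (0 returns the margin itself).
#' @return k x 3 matrix of boundary coordinates (closed, ordered as the margin).
#' @export
axialLowerBoundary <- function(preparedIndex, loop, axis = c(0, 0, 1), offset) {
  coords <- if (inherits(loop, "marginLoop")) loop$coords else as.matrix(loop)
  axis <- axis / sqrt(sum(axis^2))
  center <- colMeans(coords)
  origins <- coords + matrix(axis * offset, nrow(coords), 3L, byrow = TRUE)
  toCenter <- sweep(-origins, 2L, center, `+`)
  toCenter <- toCenter - as.numeric(toCenter %*% axis) %o% axis
  nrm <- sqrt(rowSums(toCenter^2))
  if (any(nrm < 1e-12)) stop("region error: margin point on the axis")
  dirs <- toCenter / nrm
  hit <- rayCast(preparedIndex, origins, dirs)
  miss <- is.na(hit$t)
  if (mean(miss) > 0.1)
    stop("region error: no intersection above the margin at offset ", offset)
  pts <- hit$point
  if (any(miss)) { # isolated misses: carry the neighbouring hit
    ok <- which(!miss)
    for (i in which(miss)) {
      j <- ok[which.min(pmin(abs(ok - i), nrow(pts) - abs(ok - i)))]
      pts[i, ] <- pts[j, ]
    }
  }
  pts
}

#' Axial upper boundary by interior division toward the occlusal plane
#'
#' Each lower-boundary vertex is joined to its vertical projection on the
#' occlusal-side flat surface (the plane perpendicular to the axis at the
#' height of the highest prepared vertex); the point dividing that segment in
#' ratio `t : (1 - t)` is mapped back onto the prepared mesh by a closest-point
#' query. Where the wall ends below the division height the boundary clamps to
#' the wall top, so per-side band heights follow the occlusal anatomy.
#'
#' @param prepared the prepared `triMesh`.
#' @param preparedIndex its `bvhIndex`.
#' @param lower k x 3 lower-boundary coordinates.
#' @param axis insertion axis.
#' @param tRatio interior-division ratio in (0, 1).
#' @return k x 3 matrix of upper-boundary coordinates.
#' @export
axialUpperBoundary <- function(prepared, preparedIndex, lower,
                               axis = c(0, 0, 1), tRatio = 0.5) {
  if (tRatio <= 0 || tRatio >= 1) stop("region error: tRatio must be in (0, 1)")
  axis <- axis / sqrt(sum(axis^2))
  hTop <- max(prepared$vertices %*% axis)
  hLow <- as.numeric(lower %*% axis)
  if (any(hLow >= hTop)) stop("region error: lower boundary above occlusal plane")
  m <- lower + (tRatio * (hTop - hLow)) %o% axis
  up <- closestPoint(preparedIndex, m)$point
  if (nrow(unique(round(up, 9))) < 3L) stop("region error: upper boundary collapsed")
  up
}

#' Split axial faces into buccal/lingual/mesial/distal quadrants
#'
#' Faces are assigned by the azimuth of their centroid about the insertion
#' axis, measured from the mesial direction: mesial \[-45, 45), buccal
#' \[45, 135), distal \[135, 225), lingual \[225, 315) degrees (right-handed,
#' buccal 90 degrees counter-clockwise from mesial).
#'
#' @param prepared the prepared `triMesh`.
#' @param axialFaces integer face indices of the axial band.
#' @param axis insertion axis.
#' @param mesialDir mesial direction (projected perpendicular to `axis`).
#' @return named list `B`, `L`, `M`, `D` of face index vectors.
#' @export
splitQuadrants <- function(prepared, axialFaces, axis = c(0, 0, 1),
                           mesialDir = c(1, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  m <- mesialDir - sum(mesialDir * axis) * axis
  if (sqrt(sum(m^2)) < 1e-9) stop("mesialDir parallel to axis")
  m <- m / sqrt(sum(m^2))
  b <- c(axis[2] * m[3] - axis[3] * m[2],
         axis[3] * m[1] - axis[1] * m[3],
         axis[1] * m[2] - axis[2] * m[1]) # buccal = axis x mesial
  F <- prepared$faces[axialFaces, , drop = FALSE]
  cen <- (prepared$vertices[F[, 1L], , drop = FALSE] +
          prepared$vertices[F[, 2L], , drop = FALSE] +
          prepared$vertices[F[, 3L], , drop = FALSE]) / 3
  rel <- sweep(cen, 2L, colMeans(cen))
  az <- atan2(as.numeric(rel %*% b), as.numeric(rel %*% m)) * 180 / pi
  az <- (az + 360) %% 360
  sector <- ifelse(az < 45 | az >= 315, "M",
            ifelse(az < 135, "B", ifelse(az < 225, "D", "L")))
  out <- list(B = axialFaces[sector == "B"], L = axialFaces[sector == "L"],
              M = axialFaces[sector == "M"], D = axialFaces[sector == "D"])
  empty <- names(out)[lengths(out) == 0L]
  if (length(empty))
    warning("empty quadrant(s): ", paste(empty, collapse = ", "),
            " (taper undefined for that side)")
  out
}

#' Standard points on the anatomical occlusal surface
#'
#' Seven labelled landmarks: the five cusp tips (MB, DB, DC, ML, DL) and the
#' mesial/distal marginal ridge points (MR, DR). These are inputs, supplied
#' once per reference tooth.
#'
#' @param coords 7 x 3 matrix with rownames among MB, DB, DC, ML, DL, MR, DR.
#' @param anatomical optional `triMesh` to validate that the points lie on it.
#' @return matrix of class `standardPoints`.
#' @export
standardPoints <- function(coords, anatomical = NULL) {
  coords <- as.matrix(coords)
  need <- c("MB", "DB", "DC", "ML", "DL", "MR", "DR")
  if (is.null(rownames(coords)) || !all(need %in% rownames(coords)) ||
      anyDuplicated(rownames(coords)))
    stop("standard points must carry unique labels MB, DB, DC, ML, DL, MR, DR")
  coords <- coords[need, , drop = FALSE]
  if (!is.null(anatomical)) {
    d <- closestPoint(buildBVH(anatomical), coords)$distance
    if (max(d) > 1e-6)
      stop("standard point(s) off the anatomical mesh: max deviation ",
           format(max(d)), " mm")
  }
  structure(coords, class = c("standardPoints", "matrix"))
}

#' Occlusal reduction area
#'
#' Each standard point is dropped along the perpendicular to the prepared
#' surface (its closest-point foot); the feet are connected in cyclic
#' azimuthal order by geodesic (Euclidean-weighted) shortest paths on the edge
#' graph, and the faces enclosed by that boundary form the occlusal area.
#'
#' @param prepared the prepared `triMesh`.
#' @param preparedIndex its `bvhIndex`.
#' @param pts [standardPoints()] (or 7 x 3 matrix).
#' @param axis insertion axis.
#' @return list: `faces` (enclosed face indices), `boundaryVertices` (closed
#'   vertex cycle), `feet` (7 x 3 foot points).
#' @export
occlusalArea <- function(prepared, preparedIndex, pts, axis = c(0, 0, 1)) {
  pts <- as.matrix(pts)
  feet <- closestPoint(preparedIndex, pts)$point
  rownames(feet) <- rownames(pts)
  V <- prepared$vertices
  center <- colMeans(feet)
  cc <- cylCoords(feet, axis, center = center)
  if (max(cc$r) < 1e-9 || length(unique(round(cc$az, 6))) < 3L)
    stop("region error: feet are not cyclically orderable")
  ord <- order(cc$az)
  # nearest mesh vertices to the ordered feet
  vids <- vapply(ord, function(i)
    which.min(rowSums(sweep(V, 2L, feet[i, ])^2)), integer(1L))
  ed <- meshEdges(prepared)
  g <- igraph::graph_from_edgelist(ed$edges, directed = FALSE)
  cyc <- integer(0)
  k <- length(vids)
  for (i in seq_len(k)) {
    sp <- suppressWarnings(igraph::shortest_paths(
      g, from = vids[i], to = vids[if (i == k) 1L else i + 1L],
      weights = ed$length, output = "vpath"))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) == 0L) stop("region error: feet not connected on the mesh")
    cyc <- c(cyc, path[-length(path)])
  }
  faces <- enclosedFaces(prepared, ed, cyc, seedPoint = center)
  list(faces = faces, boundaryVertices = cyc, feet = feet)
}

# faces enclosed by a closed vertex cycle: flood fill over face adjacency,
# blocked at edges traversed by the cycle, from the face nearest seedPoint
enclosedFaces <- function(mesh, ed, cycle, seedPoint) {
  n <- nrow(mesh$vertices)
  cyc2 <- c(cycle[-1L], cycle[1L])
  a <- pmin(cycle, cyc2); b <- pmax(cycle, cyc2)
  blocked <- unique((as.double(a) - 1) * n + as.double(b))
  ekey <- (as.double(ed$edges[, 1L]) - 1) * n + as.double(ed$edges[, 2L])
  eBlocked <- ekey %in% blocked
  F <- mesh$faces
  cen <- (mesh$vertices[F[, 1L], , drop = FALSE] +
          mesh$vertices[F[, 2L], , drop = FALSE] +
          mesh$vertices[F[, 3L], , drop = FALSE]) / 3
  seed <- which.min(rowSums(sweep(cen, 2L, as.numeric(seedPoint))^2))
  nf <- nrow(F)
  # face adjacency lists from the edge table
  pass <- !eBlocked & !is.na(ed$face2)
  nbr <- split(c(ed$face2[pass], ed$face1[pass]),
               c(ed$face1[pass], ed$face2[pass]))
  visited <- logical(nf)
  queue <- seed
  visited[seed] <- TRUE
  while (length(queue)) {
    nxt <- unique(unlist(nbr[as.character(queue)], use.names = FALSE))
    nxt <- nxt[!is.na(nxt) & !visited[nxt]]
    visited[nxt] <- TRUE
    queue <- nxt
  }
  if (sum(visited) > nf / 2)
    stop("region error: occlusal boundary is not closed (flood fill escaped)")
  which(visited)
}

#' Partition the prepared crown into margin band, axial quadrants and
#' occlusal area
#'
#' Composes [axialLowerBoundary()], [axialUpperBoundary()],
#' [splitQuadrants()] and [occlusalArea()] into a `regionPartition`. Axial
#' faces are those whose centroid height (along the axis) lies between the
#' azimuth-interpolated lower and upper boundaries; band faces lie between
#' margin and lower boundary.
#'
#' @param prepared the prepared `triMesh`.
#' @param preparedIndex its `bvhIndex`.
#' @param loop the detected `marginLoop`.
#' @param pts [standardPoints()].
#' @param cfg a [marginConfig()].
#' @return object of class `regionPartition`: boundary loops, face index sets
#'   `axial` (list B/L/M/D), `occlusal`, `band`, plus `feet`.
#' @export
buildRegions <- function(prepared, preparedIndex, loop, pts, cfg) {
  axis <- cfg$axis
  lower <- axialLowerBoundary(preparedIndex, loop, axis, cfg$offset)
  upper <- axialUpperBoundary(prepared, preparedIndex, lower, axis, cfg$tRatio)
  occ <- occlusalArea(prepared, preparedIndex, pts, axis)

  V <- prepared$vertices
  F <- prepared$faces
  cen <- (V[F[, 1L], , drop = FALSE] + V[F[, 2L], , drop = FALSE] +
          V[F[, 3L], , drop = FALSE]) / 3
  center <- colMeans(loop$coords)
  ccF <- cylCoords(cen, axis, center = center)
  hOf <- function(coords) {
    cc <- cylCoords(coords, axis, center = center)
    list(az = cc$az, h = cc$h)
  }
  interpH <- function(bnd, azQuery) {
    o <- order(bnd$az)
    az <- bnd$az[o]; h <- bnd$h[o]
    az <- c(az[length(az)] - 2 * pi, az, az[1L] + 2 * pi)
    h <- c(h[length(h)], h, h[1L])
    stats::approx(az, h, xout = azQuery, ties = "ordered")$y
  }
  bM <- hOf(loop$coords); bL <- hOf(lower); bU <- hOf(upper)
  zM <- interpH(bM, ccF$az); zL <- interpH(bL, ccF$az); zU <- interpH(bU, ccF$az)
  axialIdx <- which(ccF$h > zL & ccF$h <= zU)
  axialIdx <- setdiff(axialIdx, occ$faces)
  bandIdx <- which(ccF$h > zM & ccF$h <= zL)
  quads <- splitQuadrants(prepared, axialIdx, axis, cfg$mesialDir)
  structure(list(margin = loop, lowerBoundary = lower, upperBoundary = upper,
                 axial = quads, occlusal = occ$faces, band = bandIdx,
                 feet = occ$feet, occlusalBoundary = occ$boundaryVertices),
            class = "regionPartition")
}

#' @export
print.regionPartition <- function(x, ...) {
  cat("regionPartition:\n")
  cat(sprintf("  axial faces  B %d, L %d, M %d, D %d\n",
              length(x$axial$B), length(x$axial$L),
              length(x$axial$M), length(x$axial$D)))
  cat(sprintf("  occlusal faces %d, band faces %d\n",
              length(x$occlusal), length(x$band)))
  invisible(x)
}
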