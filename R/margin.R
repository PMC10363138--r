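#' Margin search configuration
#'
#' Parameters of margin detection and the downstream region split.
#'
#' * `eps`: error bound in mm for the divergence walk. The two registered
#'   surfaces coincide below the margin; where their distance first exceeds
#'   `eps` the walk has crossed the margin. Must exceed scan noise (the
#'   generator's default noise is 10 microns) and the vertex merge tolerance.
#' * `seedCount`: number of initial search vertices placed around the root.
#' * `axis`: path of insertion, unit 3-vector (default +z).
#' * `mesialDir`: mesial direction, used for quadrant splitting (default +x);
#'   buccal is 90 degrees counter-clockwise from mesial about the axis.
#' * `seedHeightFrac`: seed height as a fraction of the bounding-box height
#'   above the mesh bottom (default 0.25, i.e. in the root area).
#' * `offset`: height in mm of the axial lower boundary above the margin
#'   (the margin band spans margin -> lower boundary).
#' * `tRatio`: interior-division ratio placing the axial upper boundary
#'   between the lower boundary and the occlusal-side flat surface.
#'
#' @param eps error bound (mm).
#' @param seedCount integer >= 3.
#' @param axis,mesialDir 3-vectors (normalized internally).
#' @param seedHeightFrac fraction in (0, 1).
#' @param offset mm.
#' @param tRatio in (0, 1).
#' @return list of class `marginConfig`.
#' @export
marginConfig <- function(eps = 0.15, seedCount = 12L, axis = c(0, 0, 1),
                         mesialDir = c(1, 0, 0), seedHeightFrac = 0.25,
                         offset = 0.4, tRatio = 0.5) {
  if (eps <= 1e-6) stop("eps must exceed the vertex merge tolerance")
  if (seedCount < 3L) stop("seedCount must be >= 3")
  axis <- axis / sqrt(sum(axis^2))
  m <- mesialDir - sum(mesialDir * axis) * axis
  if (sqrt(sum(m^2)) < 1e-9) stop("mesialDir must not be parallel to axis")
  m <- m / sqrt(sum(m^2))
  if (tRatio <= 0 || tRatio >= 1) stop("tRatio must lie in (0, 1)")
  structure(list(eps = eps, seedCount = as.integer(seedCount), axis = axis,
                 mesialDir = m, seedHeightFrac = seedHeightFrac,
                 offset = offset, tRatio = tRatio),
            class = "marginConfig")
}

# heights along axis and azimuth about the axis line through `center`
cylCoords <- function(V, axis, center = colMeans(V)) {
  B <- axisBasis(axis)
  rel <- sweep(V, 2L, center)
  h <- as.numeric(rel %*% B$p)
  x <- as.numeric(rel %*% B$u)
  y <- as.numeric(rel %*% B$v)
  list(h = h, az = atan2(y, x), r = sqrt(x^2 + y^2))
}

#' Initial search vertices in the root area
#'
#' Places `seedCount` vertices at equal azimuth increments about the insertion
#' axis, at the configured root height. Deterministic: each seed is the vertex
#' minimizing the combined (arc, height) offset from its target; ties break to
#' the lowest index.
#'
#' @param mesh the registered anatomical `triMesh`.
#' @param cfg a [marginConfig()].
#' @return integer vector of vertex indices, length `cfg$seedCount`.
#' @export
seedVertices <- function(mesh, cfg) {
  V <- mesh$vertices
  cc <- cylCoords(V, cfg$axis)
  hRange <- range(cc$h)
  hSeed <- hRange[1] + cfg$seedHeightFrac * diff(hRange)
  rMed <- stats::median(cc$r)
  targets <- 2 * pi * (seq_len(cfg$seedCount) - 1L) / cfg$seedCount
  seeds <- integer(cfg$seedCount)
  for (k in seq_len(cfg$seedCount)) {
    dAz <- abs(((cc$az - targets[k] + pi) %% (2 * pi)) - pi)
    cost <- (rMed * dAz)^2 + (cc$h - hSeed)^2
    seeds[k] <- which.min(cost)
  }
  if (max(abs(cc$h[seeds] - hSeed)) > 0.25 * diff(hRange))
    stop("seeding error: no vertices near the configured root height")
  seeds
}

#' Walk a seed crown-ward to the first divergence from the prepared surface
#'
#' From the seed, repeatedly steps to the neighbouring vertex with the
#' greatest projection on the insertion axis while the closest distance to the
#' prepared surface stays below `eps`; the first vertex whose distance exceeds
#' `eps` (beyond the error bound, hence past the margin) is returned.
#'
#' @param anatomical the anatomical `triMesh`.
#' @param preparedIndex `bvhIndex` over the prepared mesh.
#' @param seed vertex index on the anatomical mesh.
#' @param cfg a [marginConfig()].
#' @param adjacency optional precomputed [vertexAdjacency()] of `anatomical`.
#' @return vertex index of the divergence point on the anatomical mesh.
#' @export
traceToMargin <- function(anatomical, preparedIndex, seed, cfg,
                          adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- vertexAdjacency(anatomical)
  V <- anatomical$vertices
  h <- as.numeric(V %*% cfg$axis)
  cur <- seed
  for (step in seq_len(nrow(V))) {
    d <- closestPoint(preparedIndex, V[cur, , drop = FALSE])$distance
    if (d > cfg$eps) return(cur)
    nb <- adjacency[[cur]]
    if (length(nb) == 0L || max(h[nb]) <= h[cur])
      stop("no-margin-found: walk from seed ", seed,
           " reached the mesh top without exceeding eps")
    cur <- nb[which.max(h[nb])]
  }
  stop("no-margin-found: walk from seed ", seed, " did not terminate")
}

#' Snap a candidate to the sharpest nearby vertex on the prepared mesh
#'
#' Maps the candidate point to its nearest prepared-mesh vertex, then
#' hill-climbs over 1-ring neighbours to a local maximum of the Laplacian
#' sharpness magnitude (at most `maxHops` hops; plateaus keep the current
#' vertex, ties break to the lowest index).
#'
#' @param prepared the prepared `triMesh`.
#' @param fields [sharpnessFields()] of `prepared`.
#' @param candidate 3D point.
#' @param adjacency optional precomputed [vertexAdjacency()] of `prepared`.
#' @param maxHops hop bound.
#' @return vertex index on the prepared mesh.
#' @export
refineOnPrepared <- function(prepared, fields, candidate, adjacency = NULL,
                             maxHops = 20L) {
  if (is.null(adjacency)) adjacency <- vertexAdjacency(prepared)
  V <- prepared$vertices
  d2 <- rowSums(sweep(V, 2L, as.numeric(candidate))^2)
  cur <- which.min(d2)
  mag <- fields$magnitude
  for (hop in seq_len(maxHops)) {
    nb <- adjacency[[cur]]
    if (length(nb) == 0L) break
    best <- nb[which.max(mag[nb])]
    if (mag[best] > mag[cur]) cur <- best else break
  }
  cur
}

#' Connect margin anchors into a closed loop by sharpness-weighted paths
#'
#' Anchors are sorted by azimuth about the insertion axis; consecutive pairs
#' are joined by the shortest path on the mesh edge graph weighted by the
#' adjusted edge lengths `e'` (sharp edges are short, so the path follows the
#' crease); the concatenation is the closed margin loop.
#'
#' @param prepared the prepared `triMesh`.
#' @param fields [sharpnessFields()] of `prepared`.
#' @param anchors vertex indices on the prepared mesh (>= 3 distinct).
#' @param axis insertion axis (unit 3-vector).
#' @return object of class `marginLoop`: `vertices` (cyclic, first not
#'   repeated), `coords`, `length` (mm, closed polyline), `anchors` (in
#'   cyclic azimuthal order).
#' @export
connectMargin <- function(prepared, fields, anchors, axis = c(0, 0, 1)) {
  anchors <- unique(as.integer(anchors))
  if (length(anchors) < 3L) stop("need at least 3 distinct anchors")
  V <- prepared$vertices
  cc <- cylCoords(V, axis, center = colMeans(V[anchors, , drop = FALSE]))
  ord <- order(cc$az[anchors], anchors)
  anchors <- anchors[ord]
  g <- igraph::graph_from_edgelist(fields$edges, directed = FALSE)
  wts <- pmax(fields$adjLength, 1e-12)
  loop <- integer(0)
  k <- length(anchors)
  for (i in seq_len(k)) {
    from <- anchors[i]
    to <- anchors[if (i == k) 1L else i + 1L]
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = from, to = to, weights = wts,
                             output = "vpath"))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) == 0L)
      stop(sprintf("connectivity error: no path between anchors %d and %d", from, to))
    loop <- c(loop, path[-length(path)])
  }
  coords <- V[loop, , drop = FALSE]
  seg <- coords[c(seq_len(nrow(coords))[-1L], 1L), , drop = FALSE] - coords
  structure(list(vertices = loop, coords = coords,
                 length = sum(sqrt(rowSums(seg^2))), anchors = anchors),
            class = "marginLoop")
}

#' @export
print.marginLoop <- function(x, ...) {
  cat(sprintf("marginLoop: %d vertices, length %.3f mm, %d anchors\n",
              length(x$vertices), x$length, length(x$anchors)))
  invisible(x)
}

# project a closed loop onto the plane perpendicular to axis -> 2D polygon
projectLoop <- function(coords, axis) {
  B <- axisBasis(axis)
  cbind(as.numeric(coords %*% B$u), as.numeric(coords %*% B$v))
}

shoelaceArea <- function(P) {
  n <- nrow(P)
  j <- c(seq_len(n)[-1L], 1L)
  sum(P[, 1] * P[j, 2] - P[j, 1] * P[, 2]) / 2
}

polyPerimeter <- function(P) {
  n <- nrow(P)
  j <- c(seq_len(n)[-1L], 1L)
  sum(sqrt(rowSums((P[j, , drop = FALSE] - P)^2)))
}

#' Margin band width from projected perimeters
#'
#' Projects the margin loop (outer perimeter) and the axial lower boundary
#' (inner perimeter) onto the plane perpendicular to the path of insertion;
#' the band area is the difference of the two shoelace polygon areas and the
#' average width divides it by the mean of the two perimeters. For concentric
#' circles this is exactly the annulus identity `width = r2 - r1`.
#'
#' @param loop a [connectMargin()] result or k x 3 coordinate matrix (outer).
#' @param inner axial lower boundary coordinates, k x 3 (inner).
#' @param axis insertion axis.
#' @return object of class `marginBand`: `area` (mm^2), `outerPerimeter`,
#'   `innerPerimeter` (mm), `width` (mm).
#' @export
marginBandWidth <- function(loop, inner, axis = c(0, 0, 1)) {
  outerC <- if (inherits(loop, "marginLoop")) loop$coords else as.matrix(loop)
  innerC <- as.matrix(inner)
  Po <- projectLoop(outerC, axis)
  Pi <- projectLoop(innerC, axis)
  ao <- abs(shoelaceArea(Po)); ai <- abs(shoelaceArea(Pi))
  if (ao <= 0 || ai < 0) stop("projection error: degenerate projected polygon")
  if (ai > ao) stop("projection error: inner polygon larger than outer")
  area <- ao - ai
  perims <- c(polyPerimeter(Po), polyPerimeter(Pi))
  width <- area / mean(perims)
  if (width <= .Machine$double.eps^0.5)
    warning("margin band has (near-)zero width")
  structure(list(area = area, outerPerimeter = perims[1],
                 innerPerimeter = perims[2], width = width),
            class = "marginBand")
}

#' @export
print.marginBand <- function(x, ...) {
  cat(sprintf("marginBand: width %.3f mm (area %.3f mm^2, perimeters %.3f / %.3f mm)\n",
              x$width, x$area, x$outerPerimeter, x$innerPerimeter))
  invisible(x)
}
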