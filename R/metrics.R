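#' Taper of a face relative to the path of insertion
#'
#' `90 - angle(p, n_f)` in degrees: 0 for a wall parallel to the axis,
#' positive when the wall converges occlusally, negative for an undercut.
#'
#' @param normals face unit normal(s), 3-vector or m x 3 matrix.
#' @param axis path of insertion (unit 3-vector).
#' @return taper in degrees (vector).
#' @export
faceTaper <- function(normals, axis = c(0, 0, 1)) {
  if (is.null(dim(normals))) normals <- matrix(normals, ncol = 3L)
  nn <- sqrt(rowSums(normals^2))
  if (any(nn < 1e-12)) stop("geometry error: zero-length normal")
  axis <- axis / sqrt(sum(axis^2))
  ct <- as.numeric(normals %*% axis) / nn
  90 - acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Area-weighted average taper of a face set
#'
#' `T = 90 - (1/A) * sum_f a_f * acos(p . n_f / |p||n_f|)`, `A = sum_f a_f`.
#'
#' @param mesh a `triMesh`.
#' @param faces face indices.
#' @param axis path of insertion.
#' @return list: `taper` (degrees), `area` (mm^2).
#' @export
averageTaper <- function(mesh, faces, axis = c(0, 0, 1)) {
  if (length(faces) == 0L) stop("taper-undefined: empty face set")
  a <- mesh$areas[faces]
  axis <- axis / sqrt(sum(axis^2))
  ang <- acos(pmin(1, pmax(-1, as.numeric(mesh$normals[faces, , drop = FALSE] %*% axis))))
  list(taper = 90 - sum(a * ang * 180 / pi) / sum(a), area = sum(a))
}

#' Total occlusal convergence from an axial quadrant partition
#'
#' Per-quadrant area-weighted tapers and their contralateral sums:
#' `TOC_BL = T_B + T_L`, `TOC_MD = T_M + T_D`.
#'
#' @param mesh the prepared `triMesh`.
#' @param partition a `regionPartition` (or a list with element `axial`).
#' @param axis path of insertion.
#' @return object of class `taperResult`: `taper` (named B/L/M/D, degrees),
#'   `area` (named, mm^2), `tocMD`, `tocBL` (degrees).
#' @export
totalOcclusalConvergence <- function(mesh, partition, axis = c(0, 0, 1)) {
  quads <- partition$axial
  res <- lapply(c(B = "B", L = "L", M = "M", D = "D"), function(s) {
    if (length(quads[[s]]) == 0L)
      stop("taper-undefined: empty ", s, " quadrant")
    averageTaper(mesh, quads[[s]], axis)
  })
  taper <- vapply(res, `[[`, numeric(1L), "taper")
  area <- vapply(res, `[[`, numeric(1L), "area")
  structure(list(taper = taper, area = area,
                 tocMD = unname(taper["M"] + taper["D"]),
                 tocBL = unname(taper["B"] + taper["L"])),
            class = "taperResult")
}

#' @export
print.taperResult <- function(x, ...) {
  cat(sprintf("taperResult: T_B %.2f, T_L %.2f, T_M %.2f, T_D %.2f deg\n",
              x$taper["B"], x$taper["L"], x$taper["M"], x$taper["D"]))
  cat(sprintf("  TOC_MD %.2f deg, TOC_BL %.2f deg\n", x$tocMD, x$tocBL))
  invisible(x)
}

#' Cusp reduction: shortest distance to the prepared surface
#'
#' The reduction at a standard point on the anatomical tooth is the
#' closest-point distance to the prepared mesh.
#'
#' @param point 3-vector or k x 3 matrix of standard points.
#' @param preparedIndex `bvhIndex` over the prepared mesh.
#' @return distance(s) in mm.
#' @export
cuspReduction <- function(point, preparedIndex) {
  closestPoint(preparedIndex, point)$distance
}

#' One specimen's measurement set
#'
#' @param specimen id.
#' @param reductionMB,reductionDB,reductionML,reductionDL cusp reductions (mm).
#' @param tocMD,tocBL total occlusal convergence (degrees).
#' @param marginWidth margin-band width (mm).
#' @return object of class `measurementSet`.
#' @export
measurementSet <- function(specimen, reductionMB, reductionDB, reductionML,
                           reductionDL, tocMD, tocBL, marginWidth) {
  red <- c(reductionMB, reductionDB, reductionML, reductionDL)
  if (any(red < 0)) stop("reductions must be >= 0")
  if (marginWidth <= 0) stop("margin width must be > 0")
  structure(list(specimen = specimen,
                 reductionMB = reductionMB, reductionDB = reductionDB,
                 reductionML = reductionML, reductionDL = reductionDL,
                 tocMD = tocMD, tocBL = tocBL, marginWidth = marginWidth),
            class = "measurementSet")
}

#' @export
print.measurementSet <- function(x, ...) {
  cat(sprintf("measurementSet [%s]\n", format(x$specimen)))
  cat(sprintf("  reductions MB %.2f, DB %.2f, ML %.2f, DL %.2f mm\n",
              x$reductionMB, x$reductionDB, x$reductionML, x$reductionDL))
  cat(sprintf("  TOC MD %.2f, BL %.2f deg; margin width %.2f mm\n",
              x$tocMD, x$tocBL, x$marginWidth))
  invisible(x)
}

#' @export
as.data.frame.measurementSet <- function(x, ...) {
  data.frame(specimen = x$specimen, reductionMB = x$reductionMB,
             reductionDB = x$reductionDB, reductionML = x$reductionML,
             reductionDL = x$reductionDL, tocMD = x$tocMD, tocBL = x$tocBL,
             marginWidth = x$marginWidth)
}

#' Evaluate one specimen end to end
#'
#' Runs the full automated evaluation on a registered anatomical/prepared
#' pair: margin detection (seed, trace, refine, connect), margin-band width,
#' region partition, tapers/TOC and cusp reductions. Marginal-ridge
#' reductions are measured the same way but only logged (the rubric has no
#' ridge criterion). With `register = TRUE` the anatomical mesh is first
#' aligned to the prepared mesh by ICP; the default assumes a pre-registered
#' pair.
#'
#' @param anatomical,prepared `triMesh` pair in a common frame (mm).
#' @param pts [standardPoints()] on the anatomical mesh.
#' @param cfg a [marginConfig()].
#' @param specimen id for the report.
#' @param register run ICP before evaluating.
#' @param minReduction also compute the experimental minimum-reduction metric
#'   (smallest anatomical-to-prepared distance over the occlusal area).
#' @return a [measurementSet()]; attributes `partition` (`regionPartition`),
#'   `grades`-ready values and `log` (eps, anchors, areas, ridge reductions,
#'   optional `minReduction`).
#' @export
evaluateSpecimen <- function(anatomical, prepared, pts, cfg = marginConfig(),
                             specimen = "specimen", register = FALSE,
                             minReduction = FALSE) {
  stopifnot(inherits(anatomical, "triMesh"), inherits(prepared, "triMesh"))
  pts <- as.matrix(pts)
  if (register) {
    tf <- icpRegister(anatomical, prepared)
    anatomical <- applyTransform(anatomical, tf)
    pts <- applyTransform(pts, tf)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  prepIdx <- stage("mesh_core", buildBVH(prepared))
  fields <- stage("sharpness", sharpnessFields(prepared))
  adjA <- vertexAdjacency(anatomical)
  adjP <- vertexAdjacency(prepared)
  seeds <- stage("margin", seedVertices(anatomical, cfg))
  candidates <- stage("margin", vapply(seeds, function(s)
    traceToMargin(anatomical, prepIdx, s, cfg, adjA), integer(1L)))
  anchors <- stage("margin", vapply(candidates, function(v)
    refineOnPrepared(prepared, fields, anatomical$vertices[v, ], adjP),
    integer(1L)))
  loop <- stage("margin", connectMargin(prepared, fields, anchors, cfg$axis))
  part <- stage("regions", buildRegions(prepared, prepIdx, loop, pts, cfg))
  band <- stage("margin", marginBandWidth(loop, part$lowerBoundary, cfg$axis))
  toc <- stage("metrics", totalOcclusalConvergence(prepared, part, cfg$axis))
  red <- stage("metrics", cuspReduction(pts, prepIdx))
  names(red) <- rownames(pts)
  ms <- measurementSet(specimen,
                       reductionMB = red[["MB"]], reductionDB = red[["DB"]],
                       reductionML = red[["ML"]], reductionDL = red[["DL"]],
                       tocMD = toc$tocMD, tocBL = toc$tocBL,
                       marginWidth = band$width)
  log <- list(eps = cfg$eps, offset = cfg$offset, tRatio = cfg$tRatio,
              seedCount = cfg$seedCount, anchors = loop$anchors,
              quadrantAreas = toc$area, taper = toc$taper,
              bandArea = band$area,
              ridgeReductions = red[c("MR", "DR")],
              distalCuspReduction = red[["DC"]])
  if (minReduction) {
    # experimental: minimum reduction over the occlusal area
    occV <- unique(as.vector(prepared$faces[part$occlusal, ]))
    anaIdx <- buildBVH(anatomical)
    log$minReduction <- min(closestPoint(anaIdx, prepared$vertices[occV, , drop = FALSE])$distance)
  }
  attr(ms, "partition") <- part
  attr(ms, "log") <- log
  ms
}
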