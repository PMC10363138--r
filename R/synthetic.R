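#' Phantom specification
#'
#' Parameters of the synthetic abutment pair. The prepared phantom is a
#' surface of revolution with sector-dependent walls: a root cylinder up to
#' the margin circle, a concave quarter-circle chamfer fillet (sharp ~90
#' degree crease exactly at the margin, tangent to the axial wall at its top,
#' so the margin is the unique dominant sharp feature), four tapered wall
#' sectors (one per quadrant, possibly negative = undercut), and a flat
#' occlusal table. The anatomical phantom shares the root (the two surfaces
#' coincide below the margin, which is what the divergence walk exploits),
#' continues the crown as a cylinder, and raises compact cusp bumps above the
#' prepared table by exactly the specified reductions, so every target
#' quantity has an analytic ground truth.
#'
#' @param marginRadius margin circle radius (mm).
#' @param marginHeight margin height above the root bottom (mm).
#' @param chamferWidth chamfer width (mm); also the projected margin-band width.
#' @param taper named degrees for walls B, L, M, D (negative = undercut).
#' @param wallHeight axial wall height (mm).
#' @param reduction named mm for cusps MB, DB, ML, DL.
#' @param distalCuspHeight,ridgeHeight heights of the ungraded distal cusp and
#'   marginal ridge bumps (mm).
#' @param cornerBlend azimuthal half-width (degrees) of the smooth taper
#'   transition at each sector boundary, emulating rounded line angles.
#'   Within these bands the surface taper genuinely deviates from the
#'   plateau values, so the per-quadrant ground truth is obtained by
#'   integrating the as-built surface (see `truth$taper`), with the nominal
#'   plateaus kept alongside in `truth$taperNominal`.
#' @param cuspRadius radial distance of the seven standard features (mm).
#' @param bumpWidth support radius of each cusp bump (mm); must stay below the
#'   smallest inter-feature distance so tip heights are exact.
#' @param resolution target edge length (mm); must resolve the chamfer
#'   (`resolution < chamferWidth / 2`).
#' @param noiseSD Gaussian noise along vertex normals (mm); default 10 microns,
#'   emulating scanner precision. Must stay well below the error bound.
#' @param seed RNG seed for the noise.
#' @return list of class `phantomSpec`.
#' @export
phantomSpec <- function(marginRadius = 4.5, marginHeight = 5,
                        chamferWidth = 0.4,
                        taper = c(B = 6, L = 6, M = 6, D = 6),
                        wallHeight = 4,
                        reduction = c(MB = 1.5, DB = 1.5, ML = 1.5, DL = 1.5),
                        distalCuspHeight = 1.2, ridgeHeight = 0.8,
                        cornerBlend = 6, cuspRadius = 1.3, bumpWidth = 0.45,
                        resolution = 0.12, noiseSD = 0.01, seed = 1L) {
  if (!(marginRadius > chamferWidth && chamferWidth > 0))
    stop("generation error: need marginRadius > chamferWidth > 0")
  if (resolution >= chamferWidth / 2)
    stop("generation error: resolution must be below chamferWidth/2 to resolve the crease")
  if (noiseSD >= 0.05)
    stop("generation error: noise must stay well below the error bound")
  if (!all(c("B", "L", "M", "D") %in% names(taper)))
    stop("taper must name B, L, M, D")
  if (!all(c("MB", "DB", "ML", "DL") %in% names(reduction)))
    stop("reduction must name MB, DB, ML, DL")
  if (any(reduction < 0)) stop("generation error: reductions must be >= 0")
  # smallest inter-feature distance (DB at 135 deg vs distal cusp at 157.5 deg)
  minSep <- 2 * cuspRadius * sin(pi * 11.25 / 180)
  if (bumpWidth >= minSep)
    stop("generation error: bumpWidth must be below the feature separation ",
         format(minSep))
  structure(list(marginRadius = marginRadius, marginHeight = marginHeight,
                 chamferWidth = chamferWidth, taper = taper[c("B", "L", "M", "D")],
                 wallHeight = wallHeight,
                 reduction = reduction[c("MB", "DB", "ML", "DL")],
                 distalCuspHeight = distalCuspHeight, ridgeHeight = ridgeHeight,
                 cornerBlend = cornerBlend,
                 cuspRadius = cuspRadius, bumpWidth = bumpWidth,
                 resolution = resolution, noiseSD = noiseSD,
                 seed = as.integer(seed)),
            class = "phantomSpec")
}

# quadrant taper (degrees) at azimuth az (radians), mesial at 0
sectorTaper <- function(az, taper) {
  deg <- (az * 180 / pi) %% 360
  out <- numeric(length(deg))
  out[deg < 45 | deg >= 315] <- taper[["M"]]
  out[deg >= 45 & deg < 135] <- taper[["B"]]
  out[deg >= 135 & deg < 225] <- taper[["D"]]
  out[deg >= 225 & deg < 315] <- taper[["L"]]
  out
}

# tan(taper) blended smoothly across a band at each sector boundary,
# emulating the rounded line angles of a real preparation; the wall radius is
# continuous and C1 in azimuth. Within the band the surface taper deviates
# from the plateau values, which is why the phantom ground truth integrates
# the as-built surface (truthQuadrantTaper) instead of assuming the nominal
# plateau
sectorTanSmooth <- function(az, taper, halfwDeg = 2) {
  deg <- (az * 180 / pi) %% 360
  tn <- tan(sectorTaper(az, taper) * pi / 180)
  order4 <- c("M", "B", "D", "L") # sectors starting at -45, 45, 135, 225
  for (k in seq_len(4L)) {
    b <- 45 + 90 * (k - 1L)
    lo <- order4[k]; hi <- order4[if (k == 4L) 1L else k + 1L]
    d <- ((deg - b + 180) %% 360) - 180
    inb <- abs(d) < halfwDeg
    s <- 0.5 + 0.5 * sin(pi * d[inb] / (2 * halfwDeg))
    tn[inb] <- (1 - s) * tan(taper[[lo]] * pi / 180) +
      s * tan(taper[[hi]] * pi / 180)
  }
  tn
}

# revolve a profile: rows are list(type="center", z=) or
# list(type="ring", radius=, z=) with radius/z scalar or length-ntheta,
# ordered bottom-center -> up -> top-center for outward orientation
revolveMesh <- function(rows, ntheta) {
  th <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  Vl <- list(); start <- integer(length(rows)); nv <- 0L
  for (k in seq_along(rows)) {
    r <- rows[[k]]
    start[k] <- nv + 1L
    if (r$type == "center") {
      Vl[[k]] <- matrix(c(0, 0, r$z), 1L, 3L)
      nv <- nv + 1L
    } else {
      rad <- rep_len(r$radius, ntheta)
      z <- rep_len(r$z, ntheta)
      Vl[[k]] <- cbind(rad * cos(th), rad * sin(th), z)
      nv <- nv + ntheta
    }
  }
  V <- do.call(rbind, Vl)
  Fl <- list()
  cidx <- seq_len(ntheta)
  cnext <- c(cidx[-1L], 1L)
  for (k in seq_len(length(rows) - 1L)) {
    a <- rows[[k]]; b <- rows[[k + 1L]]
    sa <- start[k]; sb <- start[k + 1L]
    if (a$type == "center" && b$type == "ring") {
      Fl[[k]] <- cbind(sa, sb + cnext - 1L, sb + cidx - 1L)
    } else if (a$type == "ring" && b$type == "center") {
      Fl[[k]] <- cbind(sa + cidx - 1L, sa + cnext - 1L, sb)
    } else if (a$type == "ring" && b$type == "ring") {
      Fl[[k]] <- rbind(cbind(sa + cidx - 1L, sa + cnext - 1L, sb + cnext - 1L),
                       cbind(sa + cidx - 1L, sb + cnext - 1L, sb + cidx - 1L))
    } else stop("two adjacent center rows")
  }
  list(vertices = V, faces = do.call(rbind, Fl), start = start, thetas = th)
}

# area-weighted vertex normals
vertexNormals <- function(V, F) {
  g <- faceGeometry(V, F)
  wn <- g$normals * g$areas
  acc <- rowsum(rbind(wn, wn, wn), c(F[, 1L], F[, 2L], F[, 3L]))
  N <- matrix(0, nrow(V), 3L)
  N[as.integer(rownames(acc)), ] <- acc
  nn <- sqrt(rowSums(N^2))
  N / ifelse(nn > 0, nn, 1)
}

#' Generate a phantom anatomical/prepared pair with known ground truth
#'
#' @param spec a [phantomSpec()].
#' @return list: `anatomical`, `prepared` (`triMesh`), `pts`
#'   ([standardPoints()], the seven feature vertices after noise), `truth`
#'   (nominal taper/TOC/reductions/margin geometry), `spec`.
#' @export
makePhantomPair <- function(spec = phantomSpec()) {
  r <- spec$marginRadius; hm <- spec$marginHeight; cw <- spec$chamferWidth
  H <- spec$wallHeight; res <- spec$resolution
  ztop <- hm + cw + H
  ntheta <- 16L * max(6L, ceiling(2 * pi * r / res / 16))
  th <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  tanT <- sectorTanSmooth(th, spec$taper, halfwDeg = spec$cornerBlend)

  ringSeq <- function(from, to, step, dropFirst = TRUE) {
    k <- max(2L, ceiling(abs(to - from) / step))
    s <- seq(from, to, length.out = k + 1L)
    if (dropFirst) s[-1L] else s
  }

  ## prepared profile
  rowsP <- list(list(type = "center", z = 0))
  for (rr in ringSeq(0, r, 0.5)[-max(1L, length(ringSeq(0, r, 0.5)))])
    rowsP[[length(rowsP) + 1L]] <- list(type = "ring", radius = rr, z = 0)
  for (z in seq(0, hm, length.out = max(2L, ceiling(hm / 0.3)) + 1L))
    rowsP[[length(rowsP) + 1L]] <- list(type = "ring", radius = r, z = z)
  # the last root ring sits exactly at (r, hm): the margin crease
  narc <- max(4L, ceiling((pi / 2 * cw) / res))
  for (phi in seq(-pi / 2, -pi, length.out = narc + 1L)[-1L])
    rowsP[[length(rowsP) + 1L]] <-
      list(type = "ring", radius = r + cw * cos(phi), z = hm + cw + cw * sin(phi))
  for (z in ringSeq(hm + cw, ztop, 0.25)) {
    rad <- (r - cw) - (z - hm - cw) * tanT
    rowsP[[length(rowsP) + 1L]] <- list(type = "ring", radius = rad, z = z)
  }
  rTopTheta <- (r - cw) - H * tanT
  nTop <- max(2L, ceiling(min(rTopTheta) / 0.3))
  for (s in seq(1, 0, length.out = nTop + 1L)[-c(1L, nTop + 1L)])
    rowsP[[length(rowsP) + 1L]] <- list(type = "ring", radius = s * rTopTheta, z = ztop)
  rowsP[[length(rowsP) + 1L]] <- list(type = "center", z = ztop)
  prepRaw <- revolveMesh(rowsP, ntheta)

  ## anatomical profile (same root; crown cylinder; cusped cap)
  feats <- phantomFeatures(spec)
  bump <- function(x, y) {
    h <- numeric(length(x))
    for (i in seq_len(nrow(feats))) {
      d <- sqrt((x - feats$x[i])^2 + (y - feats$y[i])^2)
      inside <- d < spec$bumpWidth
      h[inside] <- h[inside] +
        feats$height[i] * cos(pi / 2 * d[inside] / spec$bumpWidth)^2
    }
    h
  }
  rowsA <- list(list(type = "center", z = 0))
  for (rr in ringSeq(0, r, 0.5)[-max(1L, length(ringSeq(0, r, 0.5)))])
    rowsA[[length(rowsA) + 1L]] <- list(type = "ring", radius = rr, z = 0)
  for (z in seq(0, hm, length.out = max(2L, ceiling(hm / 0.3)) + 1L))
    rowsA[[length(rowsA) + 1L]] <- list(type = "ring", radius = r, z = z)
  for (z in ringSeq(hm, ztop, 0.15))
    rowsA[[length(rowsA) + 1L]] <- list(type = "ring", radius = r, z = z)
  capRadii <- c(ringSeq(r, spec$cuspRadius, 2.5 * res),
                ringSeq(spec$cuspRadius, 0, 2.5 * res))
  capRadii <- capRadii[capRadii > 1e-9]
  capStartRow <- length(rowsA) + 1L
  for (rr in capRadii) {
    zr <- ztop + bump(rr * cos(th), rr * sin(th))
    rowsA[[length(rowsA) + 1L]] <- list(type = "ring", radius = rr, z = zr)
  }
  rowsA[[length(rowsA) + 1L]] <- list(type = "center", z = ztop + bump(0, 0))
  anaRaw <- revolveMesh(rowsA, ntheta)

  ## locate the feature vertices (ring at cuspRadius, spokes at feature azimuths)
  cuspRingRow <- capStartRow + which.min(abs(capRadii - spec$cuspRadius)) - 1L
  ringStart <- anaRaw$start[cuspRingRow]
  spoke <- round(feats$az / 360 * ntheta) %% ntheta + 1L
  featIdx <- ringStart + spoke - 1L

  ## seeded noise along vertex normals
  addNoise <- function(raw) {
    if (spec$noiseSD <= 0) return(raw$vertices)
    raw$vertices + spec$noiseSD *
      rnorm(nrow(raw$vertices)) * vertexNormals(raw$vertices, raw$faces)
  }
  set.seed(spec$seed)
  Va <- addNoise(anaRaw)
  Vp <- addNoise(prepRaw)
  anatomical <- triMesh(Va, anaRaw$faces)
  prepared <- triMesh(Vp, prepRaw$faces)
  pts <- Va[featIdx, , drop = FALSE]
  rownames(pts) <- feats$label
  pts <- standardPoints(pts)

  tq <- truthQuadrantTaper(spec)
  truth <- list(taper = tq$taper,
                tocMD = unname(tq$taper[["M"]] + tq$taper[["D"]]),
                tocBL = unname(tq$taper[["B"]] + tq$taper[["L"]]),
                taperNominal = spec$taper,
                reduction = spec$reduction,
                marginWidth = cw, marginRadius = r, marginHeight = hm,
                tableHeight = ztop, axis = c(0, 0, 1), mesialDir = c(1, 0, 0))
  list(anatomical = anatomical, prepared = prepared, pts = pts,
       truth = truth, spec = spec)
}

#' Ground-truth quadrant tapers of a phantom by surface integration
#'
#' Integrates the taper over the as-built analytic wall surface
#' `R(theta, z) = R0 - (z - z0) tanT(theta)` (with the smooth corner blends),
#' area-weighted, per 90-degree quadrant, over the same axial window the
#' pipeline measures (from the chamfer top up to the interior-division
#' height). This is an independent oracle: a dense quadrature on the smooth
#' surface, never touching the mesh or the measurement code path. On plateau
#' sectors it returns the nominal taper exactly; across rounded line angles
#' the area-weighted quadrant taper genuinely differs from the plateau value.
#'
#' @param spec a [phantomSpec()].
#' @param tRatio interior-division ratio of the measured window.
#' @param nTheta,nZ quadrature resolution.
#' @return list: `taper` (named B/L/M/D degrees), `area` (mm^2).
#' @export
truthQuadrantTaper <- function(spec, tRatio = 0.5, nTheta = 4096L, nZ = 160L) {
  r0 <- spec$marginRadius - spec$chamferWidth
  z0 <- spec$marginHeight + spec$chamferWidth
  ztop <- z0 + spec$wallHeight
  th <- 2 * pi * (seq_len(nTheta) - 0.5) / nTheta
  w <- sectorTanSmooth(th, spec$taper, spec$cornerBlend)
  h <- 1e-5
  wp <- (sectorTanSmooth(th + h, spec$taper, spec$cornerBlend) -
         sectorTanSmooth(th - h, spec$taper, spec$cornerBlend)) / (2 * h)
  # window top: foot of the interior-division point on the wall profile
  z2 <- z0 + tRatio * (ztop - z0) / (1 + w^2)
  deg <- (th * 180 / pi) %% 360
  sector <- ifelse(deg < 45 | deg >= 315, "M",
            ifelse(deg < 135, "B", ifelse(deg < 225, "D", "L")))
  sumA <- c(B = 0, L = 0, M = 0, D = 0)
  sumAT <- c(B = 0, L = 0, M = 0, D = 0)
  dth <- 2 * pi / nTheta
  for (j in seq_len(nZ)) {
    u <- (j - 0.5) / nZ
    z <- z0 + u * (z2 - z0)
    R <- r0 - (z - z0) * w
    Rt <- -(z - z0) * wp
    nn <- sqrt(Rt^2 + R^2 * (1 + w^2))
    ang <- acos(pmin(1, pmax(-1, w * R / nn)))
    dA <- nn * dth * (z2 - z0) / nZ
    taperDeg <- 90 - ang * 180 / pi
    for (s in c("B", "L", "M", "D")) {
      sel <- sector == s
      sumA[s] <- sumA[s] + sum(dA[sel])
      sumAT[s] <- sumAT[s] + sum(dA[sel] * taperDeg[sel])
    }
  }
  list(taper = sumAT / sumA, area = sumA)
}

phantomFeatures <- function(spec) {
  lab <- c("MB", "DB", "DC", "ML", "DL", "MR", "DR")
  az <- c(45, 135, 157.5, 315, 225, 0, 180)
  h <- c(spec$reduction[["MB"]], spec$reduction[["DB"]], spec$distalCuspHeight,
         spec$reduction[["ML"]], spec$reduction[["DL"]],
         spec$ridgeHeight, spec$ridgeHeight)
  data.frame(label = lab, az = az,
             x = spec$cuspRadius * cos(az * pi / 180),
             y = spec$cuspRadius * sin(az * pi / 180),
             height = h, stringsAsFactors = FALSE)
}

#' Evaluation config matched to a phantom
#'
#' Convenience: a [marginConfig()] whose band offset equals the phantom's
#' chamfer width (the band then spans exactly the chamfer) and whose error
#' bound sits between the noise floor and the divergence scale of the pair
#' (the two surfaces separate by about the chamfer width just above the
#' margin, so `eps` must stay clearly below that).
#' @param spec a [phantomSpec()]. @param ... overrides passed to [marginConfig()].
#' @export
phantomConfig <- function(spec, ...) {
  args <- list(...)
  if (is.null(args$offset)) args$offset <- spec$chamferWidth
  if (is.null(args$eps))
    args$eps <- min(0.15, max(6 * spec$noiseSD, spec$chamferWidth / 2))
  do.call(marginConfig, args)
}

#' Write a phantom pair to disk
#'
#' Binary STL pair plus a ground-truth JSON sidecar and the standard points as
#' CSV; byte-identical for a fixed spec (deterministic noise).
#'
#' @param spec a [phantomSpec()]. @param dir output directory.
#' @return paths, invisibly.
#' @export
writePhantomPair <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- makePhantomPair(spec)
  pa <- file.path(dir, "anatomical.stl")
  pp <- file.path(dir, "prepared.stl")
  pj <- file.path(dir, "truth.json")
  pc <- file.path(dir, "standard_points.csv")
  writeMesh(ph$anatomical, pa)
  writeMesh(ph$prepared, pp)
  jsonlite::write_json(ph$truth, pj, auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(label = rownames(ph$pts), x = ph$pts[, 1],
                       y = ph$pts[, 2], z = ph$pts[, 3]),
            pc, row.names = FALSE)
  invisible(c(anatomical = pa, prepared = pp, truth = pj, points = pc))
}

#' The packaged 35-specimen measurement table
#'
#' Returns the packaged reference table of automated measurements for the 35
#' prepared molars (columns: the four graded cusp reductions in mm, the two
#' TOC values in degrees, and the margin width in mm). The CSV is
#' checksum-verified at load.
#'
#' @return data frame with 35 rows and columns `specimen`, `reductionMB`,
#'   `reductionDB`, `reductionML`, `reductionDL`, `tocMD`, `tocBL`,
#'   `marginWidth`.
#' @export
table1Fixture <- function() {
  path <- system.file("extdata", "sae_measurements.csv", package = "toothprep",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  expected <- "852c6287b4801739131d68aee6cc97e6"
  if (!identical(sum, expected))
    stop("fixture integrity check failed: md5 ", sum)
  df <- read.csv(path)
  stopifnot(nrow(df) == 35L)
  df
}

#' Simulate repeated ordinal rating rounds
#'
#' Round 1 reproduces the exact rubric points for every specimen; later
#' rounds flip each grade by one step (up or down, clamped to 0-2) with
#' probability `flipProb`, emulating imperfect repeat scoring by a human
#' rater. Seeded and reproducible.
#'
#' @param measurements measurement data frame (e.g. [table1Fixture()]).
#' @param rubric grading rubric.
#' @param rounds number of rating rounds.
#' @param flipProb per-cell flip probability for rounds after the first.
#' @param seed RNG seed.
#' @return named list (one per criterion) of specimens x rounds integer
#'   matrices of points.
#' @export
makeRatings <- function(measurements, rubric = defaultRubric(), rounds = 3L,
                        flipProb = 0, seed = 1L) {
  if (flipProb < 0 || flipProb > 1) stop("flipProb must be in [0, 1]")
  base <- attr(scoreTable(measurements, rubric), "points")
  set.seed(seed)
  out <- lapply(colnames(base), function(k) {
    m <- matrix(base[, k], nrow(base), rounds)
    if (rounds > 1L && flipProb > 0) {
      for (j in 2:rounds) {
        flip <- runif(nrow(m)) < flipProb
        dir <- sample(c(-1L, 1L), nrow(m), replace = TRUE)
        m[flip, j] <- pmin(pmax(m[flip, j] + dir[flip], 0L), 2L)
      }
    }
    colnames(m) <- paste0("round", seq_len(rounds))
    m
  })
  names(out) <- colnames(base)
  out
}
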