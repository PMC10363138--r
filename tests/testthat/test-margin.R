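test_that("seeds sit at equal azimuth increments at the root height", {
  cyl <- cylinderMesh(r = 2, h = 10, nz = 30, ntheta = 48)
  cfg <- marginConfig(seedCount = 12L)
  seeds <- seedVertices(cyl, cfg)
  expect_length(seeds, 12L)
  az <- (atan2(cyl$vertices[seeds, 2], cyl$vertices[seeds, 1]) * 180 / pi) %% 360
  target <- (0:11) * 30
  spacing <- 360 / 48
  expect_true(all(pmin(abs(az - target), 360 - abs(az - target)) <= spacing + 1e-9))
  # heights near 25% of the bounding box
  expect_true(all(abs(cyl$vertices[seeds, 3] - 2.5) < 0.5))
  # 4 seeds on a square prism: one per side
  sq <- triMesh(rbind(c(1,0,0), c(0,1,0), c(-1,0,0), c(0,-1,0),
                      c(1,0,4), c(0,1,4), c(-1,0,4), c(0,-1,4)),
                rbind(c(1,2,6), c(1,6,5), c(2,3,7), c(2,7,6),
                      c(3,4,8), c(3,8,7), c(4,1,5), c(4,5,8)))
  s4 <- seedVertices(sq, marginConfig(seedCount = 4L))
  expect_length(unique(s4), 4L)
})

test_that("seeds on the phantom lie below the known margin plane", {
  ph <- cachedPhantom("small", smallSpec())
  cfg <- phantomConfig(ph$spec)
  seeds <- seedVertices(ph$anatomical, cfg)
  expect_true(all(ph$anatomical$vertices[seeds, 3] < ph$truth$marginHeight))
})

test_that("the crown-ward walk stops at the first divergence", {
  # two sheets identical below z = 7; above it the 'prepared' sheet leans away
  n <- 41
  zl <- seq(0, 12, length.out = n)
  mk <- function(lean) {
    g <- expand.grid(y = seq(0, 6, length.out = 21), z = zl)
    x <- ifelse(g$z > 7, lean * (g$z - 7), 0)
    V <- cbind(x, g$y, g$z)
    idx <- function(i, j) (i - 1L) * 21L + j
    fs <- list(); k <- 0
    for (i in seq_len(n - 1L)) for (j in seq_len(20L)) {
      k <- k + 1
      fs[[k]] <- rbind(c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                       c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
    }
    triMesh(V, do.call(rbind, fs))
  }
  anat <- mk(0); prep <- mk(1)
  cfg <- marginConfig(eps = 0.15)
  idx <- buildBVH(prep)
  adj <- vertexAdjacency(anat)
  seed <- which.min(anat$vertices[, 3] + abs(anat$vertices[, 2] - 3))
  cand <- traceToMargin(anat, idx, seed, cfg, adj)
  dz <- zl[2] - zl[1]
  expect_lt(abs(anat$vertices[cand, 3] - 7), 2 * dz + cfg$eps * sqrt(2))
  # identical pair: walk reaches the top without diverging
  expect_error(traceToMargin(anat, buildBVH(anat), seed, cfg, adj),
               "no-margin-found")
  # eps larger than the maximum deviation behaves the same
  cfgBig <- marginConfig(eps = 10)
  expect_error(traceToMargin(anat, idx, seed, cfgBig, adj), "no-margin-found")
})

test_that("refinement hill-climbs to the crease and is a fixed point there", {
  ph <- cachedPhantom("small", smallSpec())
  prep <- ph$prepared
  fld <- sharpnessFields(prep)
  adj <- vertexAdjacency(prep)
  r <- ph$truth$marginRadius; hm <- ph$truth$marginHeight
  # candidate hovering 0.3 mm above the crease
  v <- refineOnPrepared(prep, fld, c(r, 0, hm + 0.3), adj)
  cc <- sqrt(sum(prep$vertices[v, 1:2]^2))
  expect_lt(abs(cc - r), 0.12)
  expect_lt(abs(prep$vertices[v, 3] - hm), 0.12)
  # already-sharpest vertex stays put
  expect_equal(refineOnPrepared(prep, fld, prep$vertices[v, ], adj), v)
  # uniform sharpness plateau: the nearest vertex is kept via tie-break
  g <- flatGrid(6)
  fg <- sharpnessFields(g)
  fg$magnitude[] <- 0
  q <- g$vertices[8, ] + c(0.01, 0.01, 0.2)
  expect_equal(refineOnPrepared(g, fg, q, vertexAdjacency(g)), 8L)
})

test_that("sharpness-weighted paths trace the margin circle", {
  ph <- cachedPhantom("small", smallSpec())
  ev <- cachedEval("small", smallSpec())
  part <- attr(ev, "partition")
  loop <- part$margin
  co <- loop$coords
  r <- ph$truth$marginRadius; hm <- ph$truth$marginHeight
  rms <- sqrt(mean((sqrt(co[, 1]^2 + co[, 2]^2) - r)^2 + (co[, 3] - hm)^2))
  expect_lt(rms, 0.1)
  # anchors appear in cyclic azimuthal order
  az <- atan2(co[match(loop$anchors, loop$vertices), 2],
              co[match(loop$anchors, loop$vertices), 1])
  expect_true(all(diff(order(az)) == 1) || all(diff(order(az)) == -1))
  # consecutive loop vertices share a mesh edge
  ed <- meshEdges(ph$prepared)
  n <- nrow(ph$prepared$vertices)
  ekeys <- (pmin(ed$edges[, 1], ed$edges[, 2]) - 1) * as.double(n) +
    pmax(ed$edges[, 1], ed$edges[, 2])
  lv <- loop$vertices; lv2 <- c(lv[-1], lv[1])
  lkeys <- (pmin(lv, lv2) - 1) * as.double(n) + pmax(lv, lv2)
  expect_true(all(lkeys %in% ekeys))
  # shortest-path lower bound: loop at least as long as the anchor hull
  P <- co[match(loop$anchors, loop$vertices), 1:2]
  hull <- chull(P)
  hullPerim <- sum(sqrt(rowSums((P[hull, ] - P[c(hull[-1], hull[1]), ])^2)))
  expect_gte(loop$length, hullPerim - 1e-6)
})

test_that("paths fall back to geodesics where no sharp feature exists", {
  g <- flatGrid(12, extent = 10)
  fld <- sharpnessFields(g)
  anchors <- c(1L, 12L, 144L)
  loop <- connectMargin(g, fld, anchors, axis = c(0, 0, 1))
  expect_true(all(anchors %in% loop$vertices))
  # on a flat sheet e' = e, so the loop equals the Euclidean-weighted loop
  ed <- meshEdges(g)
  gI <- igraph::graph_from_edgelist(ed$edges, directed = FALSE)
  sp <- igraph::shortest_paths(gI, from = 1L, to = 12L, weights = ed$length,
                               output = "vpath")
  expect_equal(sum(fld$adjLength) / sum(fld$edgeLength), 1, tolerance = 1e-12)
  expect_gte(loop$length, 2 * sqrt(10^2 + 10^2) - 1)
})

test_that("three anchors on a small ring close in cyclic order", {
  cyl <- cylinderMesh(r = 2, h = 2, nz = 4, ntheta = 12)
  fld <- sharpnessFields(cyl)
  mid <- which(abs(cyl$vertices[, 3] - 1) < 0.4)
  az <- atan2(cyl$vertices[mid, 2], cyl$vertices[mid, 1])
  anchors <- mid[c(which.min(abs(az)), which.min(abs(az - 2)),
                   which.min(abs(az + 2)))]
  loop <- connectMargin(cyl, fld, anchors, axis = c(0, 0, 1))
  expect_true(all(anchors %in% loop$vertices))
  expect_gte(length(loop$vertices), 3L)
})

test_that("margin band width obeys the annulus identity", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circ <- function(r) cbind(r * cos(th), r * sin(th), 0)
  band <- marginBandWidth(circ(5), circ(4))
  expect_equal(band$width, 1, tolerance = 1e-4) # polygonal circles
  expect_equal(band$area, pi * 9, tolerance = 0.01)
  # degenerate: identical perimeters
  expect_warning(b0 <- marginBandWidth(circ(4), circ(4)), "zero width")
  expect_equal(b0$width, 0)
  # inner larger than outer is a projection error
  expect_error(marginBandWidth(circ(4), circ(5)), "projection error")
})

test_that("the margin loop is rigid-invariant as a vertex set", {
  spec <- smallSpec()
  ph <- cachedPhantom("small", spec)
  ev <- cachedEval("small", spec)
  v1 <- sort(unique(attr(ev, "partition")$margin$vertices))
  R <- rotAxis(c(1, 2, 3), 23)
  tf <- rigidTransform(R, c(5, -2, 1))
  cfg2 <- phantomConfig(spec, axis = as.numeric(R %*% c(0, 0, 1)),
                        mesialDir = as.numeric(R %*% c(1, 0, 0)))
  ms2 <- evaluateSpecimen(applyTransform(ph$anatomical, tf),
                          applyTransform(ph$prepared, tf),
                          applyTransform(ph$pts, tf), cfg2)
  v2 <- sort(unique(attr(ms2, "partition")$margin$vertices))
  common <- length(intersect(v1, v2)) / length(union(v1, v2))
  expect_gt(common, 0.95) # same crease ring up to anchor placement
  expect_equal(ms2$marginWidth, ev$marginWidth, tolerance = 0.01)
  expect_equal(ms2$tocMD, ev$tocMD, tolerance = 0.15)
})
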