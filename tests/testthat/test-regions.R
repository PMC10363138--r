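test_that("the axial lower boundary is the margin swept up the surface", {
  cyl <- cylinderMesh(r = 2, h = 10, nz = 40, ntheta = 60)
  idx <- buildBVH(cyl)
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  margin <- cbind(2 * cos(th), 2 * sin(th), 2)
  b <- axialLowerBoundary(idx, margin, c(0, 0, 1), offset = 0.4)
  expect_equal(unname(b[, 3]), rep(2.4, 60), tolerance = 0.3) # mesh resolution
  expect_equal(sqrt(b[, 1]^2 + b[, 2]^2), rep(2, 60), tolerance = 0.01)
  # offset 0 returns the margin itself
  b0 <- axialLowerBoundary(idx, margin, c(0, 0, 1), offset = 0)
  expect_equal(unname(b0), unname(margin), tolerance = 1e-6)
  # offset beyond the mesh top cannot intersect
  expect_error(axialLowerBoundary(idx, margin, c(0, 0, 1), offset = 20),
               "region error")
})

test_that("the upper boundary divides toward the occlusal plane", {
  sq <- triMesh(rbind(c(1,1,0), c(-1,1,0), c(-1,-1,0), c(1,-1,0),
                      c(1,1,4), c(-1,1,4), c(-1,-1,4), c(1,-1,4)),
                rbind(c(1,2,6), c(1,6,5), c(2,3,7), c(2,7,6),
                      c(3,4,8), c(3,8,7), c(4,1,5), c(4,5,8),
                      c(5,6,7), c(5,7,8)))
  idx <- buildBVH(sq)
  lower <- rbind(c(1, 0.5, 0.5), c(-1, 0.5, 0.5), c(-1, -0.5, 0.5), c(1, -0.5, 0.5))
  up <- axialUpperBoundary(sq, idx, lower, c(0, 0, 1), tRatio = 0.5)
  expect_equal(unname(up[, 3]), rep(2.25, 4), tolerance = 1e-6) # 0.5 + 0.5*(4-0.5)
  # t -> 0 collapses onto the lower boundary
  up0 <- axialUpperBoundary(sq, idx, lower, c(0, 0, 1), tRatio = 1e-6)
  expect_equal(unname(up0), unname(lower), tolerance = 1e-4)
  expect_error(axialUpperBoundary(sq, idx, lower, c(0, 0, 1), tRatio = 1.2),
               "region error")
})

test_that("quadrant assignment follows centroid azimuth from the mesial axis", {
  sq <- triMesh(rbind(c(1,1,0), c(-1,1,0), c(-1,-1,0), c(1,-1,0),
                      c(1,1,4), c(-1,1,4), c(-1,-1,4), c(1,-1,4)),
                rbind(c(1,2,6), c(1,6,5),   # +y wall
                      c(2,3,7), c(2,7,6),   # -x wall
                      c(3,4,8), c(3,8,7),   # -y wall
                      c(4,1,5), c(4,5,8))) # +x wall
  q <- splitQuadrants(sq, seq_len(8L), c(0, 0, 1), c(1, 0, 0))
  expect_equal(sort(q$M), c(7L, 8L)) # +x wall is mesial
  expect_equal(sort(q$B), c(1L, 2L)) # +y wall is buccal (90 deg CCW)
  expect_equal(sort(q$D), c(3L, 4L))
  expect_equal(sort(q$L), c(5L, 6L))
  # rotating the mesial direction by 90 degrees permutes the quadrants
  q2 <- splitQuadrants(sq, seq_len(8L), c(0, 0, 1), c(0, 1, 0))
  expect_equal(sort(q2$M), sort(q$B))
  expect_equal(sort(q2$B), sort(q$D))
  expect_equal(sort(q2$L), sort(q$M))
  # empty quadrant warns
  expect_warning(splitQuadrants(sq, c(1L, 2L), c(0, 0, 1), c(1, 0, 0)),
                 "empty quadrant")
})

test_that("cone quadrants split the lateral area evenly", {
  rows <- c(list(list(type = "center", z = 0)),
            lapply(seq(0.25, 0.75, by = 0.25), function(s)
              list(type = "ring", radius = 3 * s, z = 0)),
            lapply(seq(1, 0.02, length.out = 30), function(s)
              list(type = "ring", radius = 3 * s, z = 6 * (1 - s))),
            list(list(type = "center", z = 6)))
  raw <- toothprep:::revolveMesh(rows, 64)
  cone <- triMesh(raw$vertices, raw$faces)
  cen <- (cone$vertices[cone$faces[, 1], ] + cone$vertices[cone$faces[, 2], ] +
          cone$vertices[cone$faces[, 3], ]) / 3
  lateral <- which(cen[, 3] > 0.5 & cen[, 3] < 5)
  q <- splitQuadrants(cone, lateral, c(0, 0, 1), c(1, 0, 0))
  areas <- vapply(q, function(f) sum(cone$areas[f]), numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.02)
})

test_that("occlusal area encloses the standard-point feet", {
  ph <- cachedPhantom("small", smallSpec())
  prep <- ph$prepared
  idx <- buildBVH(prep)
  occ <- occlusalArea(prep, idx, ph$pts, c(0, 0, 1))
  ztop <- ph$truth$tableHeight
  # feet drop perpendicular onto the flat table
  expect_equal(unname(occ$feet[, 3]), rep(ztop, 7), tolerance = 0.05)
  # noise lets the foot slide a little sideways on the table
  expect_equal(unname(occ$feet["MB", 1:2]), unname(ph$pts["MB", 1:2]),
               tolerance = 0.25)
  # a point already on the surface is its own foot
  onSurf <- closestPoint(idx, c(0.5, 0.5, ztop))$point
  expect_equal(unname(closestPoint(idx, onSurf)$distance), 0, tolerance = 1e-9)
  # enclosed faces lie on the occlusal table
  cen <- (prep$vertices[prep$faces[occ$faces, 1], ] +
          prep$vertices[prep$faces[occ$faces, 2], ] +
          prep$vertices[prep$faces[occ$faces, 3], ]) / 3
  expect_true(all(cen[, 3] > ztop - 0.1))
  # enclosed area is near the polygon spanned by the feet
  polyA <- abs(toothprep:::shoelaceArea(occ$feet[chull(occ$feet[, 1:2]), 1:2]))
  expect_lt(abs(sum(prep$areas[occ$faces]) - polyA) / polyA, 0.35)
})

test_that("the full partition is disjoint and accounts the crown surface", {
  ph <- cachedPhantom("small", smallSpec())
  ev <- cachedEval("small", smallSpec())
  part <- attr(ev, "partition")
  quadAll <- unlist(part$axial)
  expect_equal(anyDuplicated(quadAll), 0L)
  expect_equal(length(intersect(quadAll, part$occlusal)), 0L)
  expect_equal(length(intersect(quadAll, part$band)), 0L)
  # occlusal faces sit above the axial upper boundary
  prep <- ph$prepared
  cenO <- (prep$vertices[prep$faces[part$occlusal, 1], ] +
           prep$vertices[prep$faces[part$occlusal, 2], ] +
           prep$vertices[prep$faces[part$occlusal, 3], ]) / 3
  expect_true(all(cenO[, 3] >= max(part$upperBoundary[, 3]) - 1e-6))
  # area accounting: regions never exceed the crown-side surface
  crownArea <- sum(prep$areas[
    (prep$vertices[prep$faces[, 1], 3] +
     prep$vertices[prep$faces[, 2], 3] +
     prep$vertices[prep$faces[, 3], 3]) / 3 > ph$truth$marginHeight])
  regionArea <- sum(prep$areas[c(quadAll, part$occlusal, part$band)])
  expect_lte(regionArea, crownArea + 1e-6)
})
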