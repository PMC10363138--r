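test_that("phantom specs enforce their geometric invariants", {
  expect_error(phantomSpec(marginRadius = 0.3, chamferWidth = 0.4), "generation error")
  expect_error(phantomSpec(resolution = 0.3, chamferWidth = 0.4), "resolve the crease")
  expect_error(phantomSpec(noiseSD = 0.1), "error bound")
  expect_error(phantomSpec(bumpWidth = 2), "feature separation")
  expect_error(phantomSpec(reduction = c(MB = -1, DB = 1, ML = 1, DL = 1)), ">= 0")
  expect_error(phantomSpec(taper = c(B = 1, L = 1)), "name B, L, M, D")
})

test_that("phantom pairs are manifold and coincide below the margin", {
  spec <- smallSpec()
  ph <- cachedPhantom("small", spec)
  expect_true(isEdgeManifold(ph$anatomical))
  expect_true(isEdgeManifold(ph$prepared))
  # shared root: anatomical vertices below the margin lie on the prepared mesh
  below <- ph$anatomical$vertices[, 3] < spec$marginHeight - 0.2
  d <- closestPoint(buildBVH(ph$prepared),
                    ph$anatomical$vertices[below, , drop = FALSE])$distance
  # both meshes carry independent noise: allow the extreme-value tail
  expect_lt(max(d), 6 * spec$noiseSD + 1e-3)
  # standard points are mesh vertices with the constructed heights
  ztop <- ph$truth$tableHeight
  expect_equal(unname(ph$pts["MB", 3] - ztop),
               unname(spec$reduction["MB"]), tolerance = 4 * spec$noiseSD)
  d0 <- closestPoint(buildBVH(ph$anatomical), ph$pts)$distance
  expect_lt(max(d0), 1e-9)
  # margin crease vertices sit on the constructed circle
  cc <- sqrt(ph$prepared$vertices[, 1]^2 + ph$prepared$vertices[, 2]^2)
  crease <- abs(ph$prepared$vertices[, 3] - spec$marginHeight) < 0.02 &
    abs(cc - spec$marginRadius) < 0.05
  expect_gt(sum(crease), 50)
})

test_that("noiseless phantoms are exact; noise is seeded and reproducible", {
  spec0 <- smallSpec(noiseSD = 0)
  ph0 <- makePhantomPair(spec0)
  ztop <- ph0$truth$tableHeight
  expect_equal(unname(ph0$pts[c("MB", "DB", "ML", "DL"), 3]) - ztop,
               unname(spec0$reduction), tolerance = 1e-12)
  ph1 <- makePhantomPair(smallSpec(seed = 5))
  ph2 <- makePhantomPair(smallSpec(seed = 5))
  expect_identical(ph1$anatomical$vertices, ph2$anatomical$vertices)
  ph3 <- makePhantomPair(smallSpec(seed = 6))
  expect_false(identical(ph1$anatomical$vertices, ph3$anatomical$vertices))
})

test_that("ground-truth quadrant tapers integrate the as-built surface", {
  sym <- phantomSpec(taper = c(B = 7, L = 7, M = 7, D = 7), noiseSD = 0)
  tq <- truthQuadrantTaper(sym)
  expect_equal(unname(tq$taper), rep(7, 4), tolerance = 1e-3)
  mix <- phantomSpec(taper = c(B = 4, L = 6, M = 12, D = 18), noiseSD = 0)
  tm <- truthQuadrantTaper(mix)
  # plateau dominates but rounded line angles pull toward the neighbours
  expect_lt(max(abs(tm$taper[c("B", "L", "M", "D")] - c(4, 6, 12, 18))), 1)
  expect_lt(tm$taper[["D"]], 18)
  expect_gt(tm$taper[["B"]], 4)
  expect_true(all(tm$area > 0))
  # undercuts keep their sign
  uc <- phantomSpec(taper = c(B = -4, L = 10, M = 6, D = 6), noiseSD = 0)
  expect_lt(truthQuadrantTaper(uc)$taper[["B"]], 0)
})

test_that("phantom files are deterministic and round-trip with their truth", {
  spec <- smallSpec(resolution = 0.22)
  d1 <- file.path(tempdir(), "ph1"); d2 <- file.path(tempdir(), "ph2")
  p1 <- writePhantomPair(spec, d1)
  p2 <- writePhantomPair(spec, d2)
  expect_identical(unname(tools::md5sum(p1[["prepared"]])),
                   unname(tools::md5sum(p2[["prepared"]])))
  expect_identical(unname(tools::md5sum(p1[["anatomical"]])),
                   unname(tools::md5sum(p2[["anatomical"]])))
  truth <- jsonlite::read_json(p1[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$marginWidth, spec$chamferWidth)
  m <- readMesh(p1[["prepared"]])
  expect_true(isEdgeManifold(m))
})

test_that("the packaged measurement table matches its printed source", {
  df <- table1Fixture()
  expect_equal(nrow(df), 35L)
  expect_equal(unlist(df[1, -1], use.names = FALSE),
               c(1.09, 1.28, 1.65, 1.40, 25.03, 9.81, 0.38))
  expect_equal(df$tocBL[23], 0.79)
  expect_equal(round(mean(df$reductionMB), 2), 1.39)
  expect_equal(round(mean(df$reductionML), 2), 1.88)
  expect_equal(round(mean(df$reductionDL), 2), 1.59)
  expect_equal(round(mean(df$marginWidth), 2), 0.36)
})

test_that("simulated rating rounds flip grades as configured", {
  df <- table1Fixture()
  r0 <- makeRatings(df, rounds = 3, flipProb = 0, seed = 2)
  expect_named(r0, c("reductionMB", "reductionDB", "reductionML",
                     "reductionDL", "tocMD", "tocBL"))
  for (m in r0) {
    expect_equal(m[, 1], m[, 2])
    expect_equal(m[, 1], m[, 3])
    expect_equal(iccCronbach(m)$value, 1)
  }
  # forced flips differ from round 1 and lower alpha below 1
  r1 <- makeRatings(df, rounds = 3, flipProb = 1, seed = 2)
  changed <- vapply(r1, function(m) any(m[, 2] != m[, 1]), logical(1))
  expect_true(all(changed))
  aMB <- iccCronbach(r1$reductionMB)$value
  expect_lt(aMB, 1)
  # all values stay on the 0-2 scale
  expect_true(all(unlist(r1) %in% 0:2))
  # reproducible under the same seed
  expect_identical(makeRatings(df, rounds = 3, flipProb = 0.3, seed = 9),
                   makeRatings(df, rounds = 3, flipProb = 0.3, seed = 9))
  # moderate flipping keeps agreement high but imperfect
  set.seed(1)
  vals <- vapply(1:20, function(s)
    iccCronbach(makeRatings(df, rounds = 3, flipProb = 0.1, seed = s)$reductionDL)$value,
    numeric(1))
  expect_true(all(vals > 0.5 & vals <= 1))
})
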