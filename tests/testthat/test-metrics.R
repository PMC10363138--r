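test_that("face taper follows the sign convention", {
  expect_equal(faceTaper(c(1, 0, 0)), 0) # wall parallel to the axis
  a10 <- 80 * pi / 180
  expect_equal(faceTaper(c(sin(a10), 0, cos(a10))), 10, tolerance = 1e-9)
  a95 <- 95 * pi / 180
  expect_equal(faceTaper(c(sin(a95), 0, cos(a95))), -5, tolerance = 1e-9)
  expect_error(faceTaper(c(0, 0, 0)), "zero-length")
})

test_that("area-weighted taper equals a brute-force summation oracle", {
  ph <- cachedPhantom("small", smallSpec())
  prep <- ph$prepared
  cen <- (prep$vertices[prep$faces[, 1], ] + prep$vertices[prep$faces[, 2], ] +
          prep$vertices[prep$faces[, 3], ]) / 3
  sel <- which(cen[, 3] > 4 & cen[, 3] < 5.5)
  got <- averageTaper(prep, sel)
  # independent summation
  ang <- acos(pmin(1, pmax(-1, prep$normals[sel, 3])))
  oracle <- 90 - sum(prep$areas[sel] * ang * 180 / pi) / sum(prep$areas[sel])
  expect_equal(got$taper, oracle, tolerance = 1e-12)
  expect_equal(got$area, sum(prep$areas[sel]), tolerance = 1e-12)
  # two faces, areas 1 and 3, tapers 0 and 8 -> weighted mean 6
  w <- c(1, 3); tp <- c(0, 8)
  expect_equal(90 - sum(w * (90 - tp)) / sum(w), 6)
  expect_error(averageTaper(prep, integer(0)), "taper-undefined")
})

test_that("frustum and cylinder walls give their analytic tapers", {
  frustum <- function(T) {
    tanT <- tan(T * pi / 180)
    rows <- lapply(seq(0, 4, length.out = 24), function(z)
      list(type = "ring", radius = 3 - z * tanT, z = z))
    raw <- toothprep:::revolveMesh(rows, 96)
    triMesh(raw$vertices, raw$faces)
  }
  m6 <- frustum(6)
  expect_equal(averageTaper(m6, seq_len(nrow(m6$faces)))$taper, 6,
               tolerance = 0.1)
  m0 <- frustum(0)
  expect_equal(averageTaper(m0, seq_len(nrow(m0$faces)))$taper, 0,
               tolerance = 0.05)
})

test_that("TOC sums the contralateral tapers exactly", {
  ev <- cachedEval("small", smallSpec())
  log <- attr(ev, "log")
  expect_equal(ev$tocMD, unname(log$taper["M"] + log$taper["D"]), tolerance = 1e-12)
  expect_equal(ev$tocBL, unname(log$taper["B"] + log$taper["L"]), tolerance = 1e-12)
  # quadrant weights sum to the quadrant areas
  part <- attr(ev, "partition")
  ph <- cachedPhantom("small", smallSpec())
  expect_equal(unname(log$quadrantAreas["B"]),
               sum(ph$prepared$areas[part$axial$B]), tolerance = 1e-12)
})

test_that("angles are scale-free, lengths scale linearly", {
  spec <- smallSpec()
  ph <- cachedPhantom("small", spec)
  ev <- cachedEval("small", spec)
  s <- 2.5
  anat <- triMesh(ph$anatomical$vertices * s, ph$anatomical$faces)
  prep <- triMesh(ph$prepared$vertices * s, ph$prepared$faces)
  pts <- ph$pts * s
  class(pts) <- class(ph$pts)
  cfg <- phantomConfig(spec, offset = spec$chamferWidth * s,
                       eps = min(0.15, spec$chamferWidth / 2) * s)
  ms <- evaluateSpecimen(anat, prep, pts, cfg)
  expect_equal(ms$tocMD, ev$tocMD, tolerance = 0.2)
  expect_equal(ms$tocBL, ev$tocBL, tolerance = 0.2)
  expect_equal(ms$reductionMB, s * ev$reductionMB, tolerance = 0.05 * s)
  expect_equal(ms$marginWidth, s * ev$marginWidth, tolerance = 0.1 * s)
})

test_that("cusp reduction measures the constructed removal", {
  spec <- smallSpec()
  ph <- cachedPhantom("small", spec)
  idx <- buildBVH(ph$prepared)
  red <- cuspReduction(ph$pts, idx)
  names(red) <- rownames(ph$pts)
  for (k in c("MB", "DB", "ML", "DL"))
    expect_equal(unname(red[k]), unname(spec$reduction[k]), tolerance = 0.05)
  # anatomical equal to prepared: distance zero
  expect_equal(cuspReduction(ph$prepared$vertices[1, ], idx), 0,
               tolerance = 1e-9)
})

test_that("the full evaluation recovers every phantom target", {
  spec <- smallSpec()
  ph <- cachedPhantom("small", spec)
  ms <- cachedEval("small", spec)
  expect_s3_class(ms, "measurementSet")
  expect_equal(ms$reductionMB, unname(ph$truth$reduction["MB"]), tolerance = 0.05)
  expect_equal(ms$reductionDL, unname(ph$truth$reduction["DL"]), tolerance = 0.05)
  expect_equal(ms$tocMD, ph$truth$tocMD, tolerance = 0.5)
  expect_equal(ms$tocBL, ph$truth$tocBL, tolerance = 0.5)
  expect_equal(ms$marginWidth, ph$truth$marginWidth, tolerance = 0.1 * ph$truth$marginWidth)
  log <- attr(ms, "log")
  expect_equal(log$eps, phantomConfig(spec)$eps)
  expect_length(log$anchors, 12L)
  # ridge reductions measured but reported in the log only
  expect_true(all(is.finite(log$ridgeReductions)))
  # identical pair fails with the stage named
  expect_error(evaluateSpecimen(ph$prepared, ph$prepared, ph$pts,
                                phantomConfig(spec)),
               "\\[margin\\].*no-margin-found")
})

test_that("an undercut wall yields a negative taper component", {
  spec <- smallSpec(taper = c(B = -4, L = 10, M = 6, D = 6), seed = 13)
  ph <- cachedPhantom("undercut_small", spec)
  ms <- cachedEval("undercut_small", spec)
  log <- attr(ms, "log")
  expect_lt(log$taper[["B"]], 0)
  expect_equal(log$taper[["B"]], ph$truth$taper[["B"]], tolerance = 0.4)
  expect_equal(ms$tocBL, ph$truth$tocBL, tolerance = 0.5)
})

test_that("the experimental minimum-reduction metric stays below cusp values", {
  spec <- smallSpec()
  ph <- cachedPhantom("small", spec)
  ms <- evaluateSpecimen(ph$anatomical, ph$prepared, ph$pts,
                         phantomConfig(spec), minReduction = TRUE)
  log <- attr(ms, "log")
  expect_true(is.finite(log$minReduction))
  expect_lte(log$minReduction,
             min(ms$reductionMB, ms$reductionDB, ms$reductionML, ms$reductionDL) + 1e-9)
})

test_that("measurement sets validate and convert to data frames", {
  ms <- measurementSet("s1", 1.5, 1.5, 1.2, 1.2, 12, 12, 0.4)
  df <- as.data.frame(ms)
  expect_equal(df$tocMD, 12)
  expect_error(measurementSet("s", -0.1, 1, 1, 1, 10, 10, 0.4), ">= 0")
  expect_error(measurementSet("s", 1, 1, 1, 1, 10, 10, 0), "> 0")
})
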