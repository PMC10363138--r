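# Shared fixtures, built in code. Phantoms are cached across test files.

phantomStore <- new.env(parent = emptyenv())

cachedPhantom <- function(key, spec) {
  if (is.null(phantomStore[[key]])) phantomStore[[key]] <- makePhantomPair(spec)
  phantomStore[[key]]
}

cachedEval <- function(key, spec, ...) {
  ekey <- paste0(key, "_eval")
  if (is.null(phantomStore[[ekey]])) {
    ph <- cachedPhantom(key, spec)
    phantomStore[[ekey]] <- evaluateSpecimen(ph$anatomical, ph$prepared, ph$pts,
                                             phantomConfig(spec), ...)
  }
  phantomStore[[ekey]]
}

# small quick phantom used throughout the unit tests
smallSpec <- function(...) {
  args <- list(marginRadius = 3, marginHeight = 3, chamferWidth = 0.5,
               wallHeight = 3, resolution = 0.2)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantomSpec, args)
}

# open rectangular terrain sheet; asymmetric, good for ICP and graph tests
terrainMesh <- function(n = 25, extent = 10, seed = 3) {
  set.seed(seed)
  g <- expand.grid(x = seq(0, extent, length.out = n),
                   y = seq(0, extent, length.out = n))
  z <- sin(g$x * 0.8) * 1.5 + cos(g$y * 0.5) * 2 + 0.3 * sin(g$x * g$y * 0.3)
  V <- cbind(g$x, g$y, z)
  idx <- function(i, j) (i - 1L) * n + j
  fs <- vector("list", (n - 1L)^2)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in seq_len(n - 1L)) {
    k <- k + 1L
    fs[[k]] <- rbind(c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                     c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  triMesh(V, do.call(rbind, fs))
}

# planar grid in the z = 0 plane
flatGrid <- function(n = 10, extent = 1) {
  g <- expand.grid(x = seq(0, extent, length.out = n),
                   y = seq(0, extent, length.out = n))
  V <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (i - 1L) * n + j
  fs <- vector("list", (n - 1L)^2)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in seq_len(n - 1L)) {
    k <- k + 1L
    fs[[k]] <- rbind(c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                     c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  triMesh(V, do.call(rbind, fs))
}

# closed lat-long sphere
sphereMesh <- function(r = 5, nlat = 40, nlon = 60) {
  lat <- seq(-pi / 2, pi / 2, length.out = nlat)[-c(1, nlat)]
  rows <- c(list(list(type = "center", z = -r)),
            lapply(lat, function(la)
              list(type = "ring", radius = r * cos(la), z = r * sin(la))),
            list(list(type = "center", z = r)))
  raw <- toothprep:::revolveMesh(rows, nlon)
  triMesh(raw$vertices, raw$faces)
}

# closed cylinder (flat caps) via the same lattice builder
cylinderMesh <- function(r = 2, h = 10, nz = 20, ntheta = 48) {
  rows <- c(list(list(type = "center", z = 0)),
            lapply(seq(0.25, 0.75, by = 0.25) * r, function(s)
              list(type = "ring", radius = s, z = 0)),
            lapply(seq(0, h, length.out = nz), function(z)
              list(type = "ring", radius = r, z = z)),
            lapply(rev(seq(0.25, 0.75, by = 0.25)) * r, function(s)
              list(type = "ring", radius = s, z = h)),
            list(list(type = "center", z = h)))
  raw <- toothprep:::revolveMesh(rows, ntheta)
  triMesh(raw$vertices, raw$faces)
}

rotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# generic rotation about an arbitrary axis
rotAxis <- function(axis, deg) {
  a <- deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

asciiCubeSTL <- function(path) {
  # unit cube, 12 facets, every vertex repeated per facet (36 raw vertices)
  v <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
             c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  quads <- list(c(1,4,3,2), c(5,6,7,8), c(1,2,6,5), c(2,3,7,6),
                c(3,4,8,7), c(4,1,5,8))
  lines <- "solid cube"
  for (q in quads) for (tri in list(q[c(1,2,3)], q[c(1,3,4)])) {
    lines <- c(lines, " facet normal 0 0 0", "  outer loop",
               sprintf("   vertex %g %g %g", v[tri, 1], v[tri, 2], v[tri, 3]),
               "  endloop", " endfacet")
  }
  writeLines(c(lines, "endsolid cube"), path)
  path
}
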