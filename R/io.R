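#' Read a triangle mesh from STL or PLY
#'
#' Reads binary or ASCII STL, or PLY (ascii / binary_little_endian), then
#' cleans the result: duplicate vertices within `tol` (default 1e-6 mm) are
#' merged and zero-area faces dropped. STL carries no units; coordinates are
#' taken as millimetres.
#'
#' @param path file path.
#' @param format `"auto"` (by extension + content sniffing), `"stl"` or `"ply"`.
#' @param tol vertex merge tolerance in mm.
#' @return a [triMesh()]; attribute `cleaning` holds raw/merged counts.
#' @export
readMesh <- function(path, format = c("auto", "stl", "ply"), tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "ply") "ply" else if (ext == "stl") "stl" else {
      head4 <- readBin(path, "raw", 4L)
      if (rawToChar(head4[1:3]) == "ply") "ply" else "stl"
    }
  }
  raw <- switch(format, stl = readSTL(path), ply = readPLY(path))
  cleanMesh(raw$vertices, raw$faces, tol = tol)
}

stlIsBinary <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L)
  if (!is.na(ntri) && ntri > 0 && sz == 84 + 50 * as.double(ntri)) return(TRUE)
  # fall back to the "solid" heuristic
  !startsWith(trimws(rawToChar(hdr[1:5])), "solid")
}

readSTL <- function(path) {
  if (stlIsBinary(path)) readSTLBinary(path) else readSTLAscii(path)
}

readSTLBinary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L)
  if (is.na(ntri) || ntri <= 0) stop("format error: bad binary STL facet count")
  rec <- readBin(con, "raw", 50L * ntri)
  if (length(rec) < 50L * ntri) stop("format error: truncated binary STL")
  keep <- rep.int(seq_len(48L), ntri) + rep(seq.int(0L, by = 50L, length.out = ntri), each = 48L)
  vals <- readBin(rec[keep], "double", n = 12L * ntri, size = 4L)
  m <- matrix(vals, ncol = 12L, byrow = TRUE) # normal xyz, v1, v2, v3
  V <- matrix(NA_real_, 3L * ntri, 3L)
  V[seq(1L, by = 3L, length.out = ntri), ] <- m[, 4:6, drop = FALSE]
  V[seq(2L, by = 3L, length.out = ntri), ] <- m[, 7:9, drop = FALSE]
  V[seq(3L, by = 3L, length.out = ntri), ] <- m[, 10:12, drop = FALSE]
  list(vertices = V, faces = matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE))
}

readSTLAscii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("vertex", txt, fixed = TRUE, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("format error: cannot parse ASCII STL")
  nums <- scan(text = gsub("[^0-9eE+. -]", "", sub(".*vertex", "", vl)),
               quiet = TRUE)
  if (length(nums) != 3L * length(vl)) stop("format error: bad ASCII STL vertex line")
  V <- matrix(nums, ncol = 3L, byrow = TRUE)
  list(vertices = V, faces = matrix(seq_len(nrow(V)), ncol = 3L, byrow = TRUE))
}

plyTypeSize <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)

readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLinesRaw(con)
    hdr <- c(hdr, ln)
    if (identical(ln, "end_header")) break
    if (length(hdr) > 1000L) stop("format error: PLY header not terminated")
  }
  if (!startsWith(hdr[1], "ply")) stop("format error: not a PLY file")
  fmtLine <- grep("^format ", hdr, value = TRUE)
  fmt <- strsplit(trimws(fmtLine[1]), "\\s+")[[1]][2]
  # parse elements
  elems <- list(); cur <- NULL
  for (ln in hdr) {
    tk <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tk[1] == "element") {
      cur <- tk[2]
      elems[[cur]] <- list(count = as.integer(tk[3]), props = list())
    } else if (tk[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1L]] <-
        if (tk[2] == "list") list(list = TRUE, countType = tk[3], type = tk[4], name = tk[5])
        else list(list = FALSE, type = tk[2], name = tk[3])
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("format error: PLY lacks vertex/face elements")
  nv <- elems$vertex$count; nf <- elems$face$count
  vprops <- elems$vertex$props
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    vlines <- rest[seq_len(nv)]
    vals <- scan(text = vlines, quiet = TRUE)
    np <- length(vprops)
    vm <- matrix(vals, nrow = nv, ncol = np, byrow = TRUE)
    nm <- vapply(vprops, `[[`, "", "name")
    V <- vm[, match(c("x", "y", "z"), nm), drop = FALSE]
    flines <- rest[nv + seq_len(nf)]
    ftok <- strsplit(trimws(flines), "\\s+")
    F <- t(vapply(ftok, function(t) as.integer(t[2:4]) + 1L, integer(3L)))
    if (any(vapply(ftok, function(t) as.integer(t[1]), integer(1L)) != 3L))
      stop("format error: only triangular PLY faces supported")
  } else if (fmt == "binary_little_endian") {
    nm <- vapply(vprops, `[[`, "", "name")
    tys <- vapply(vprops, `[[`, "", "type")
    if (any(vapply(vprops, `[[`, TRUE, "list"))) stop("format error: list vertex property")
    sizes <- plyTypeSize[tys]
    rec <- sum(sizes)
    raw <- readBin(con, "raw", nv * rec)
    off <- cumsum(c(0L, sizes[-length(sizes)]))
    readCol <- function(j) {
      idx <- rep(seq_len(sizes[j]), nv) +
        rep(seq.int(0L, by = rec, length.out = nv), each = sizes[j]) + off[j]
      ty <- tys[j]
      if (ty %in% c("float", "float32")) readBin(raw[idx], "double", nv, size = 4L)
      else if (ty %in% c("double", "float64")) readBin(raw[idx], "double", nv, size = 8L)
      else if (ty %in% c("int", "int32")) readBin(raw[idx], "integer", nv, size = 4L)
      else if (ty %in% c("uchar", "uint8")) as.double(readBin(raw[idx], "integer", nv, size = 1L, signed = FALSE))
      else stop("format error: unsupported PLY vertex type ", ty)
    }
    V <- cbind(readCol(which(nm == "x")), readCol(which(nm == "y")), readCol(which(nm == "z")))
    # faces: assume one list property (count uchar/int, indices int)
    fp <- elems$face$props[[1]]
    cntSz <- plyTypeSize[[fp$countType]]
    idxSz <- plyTypeSize[[fp$type]]
    F <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", 1L, size = cntSz, signed = cntSz > 1L)
      if (cnt != 3L) stop("format error: only triangular PLY faces supported")
      F[i, ] <- readBin(con, "integer", 3L, size = idxSz) + 1L
    }
  } else stop("format error: unsupported PLY format ", fmt)
  list(vertices = V, faces = F)
}

readLinesRaw <- function(con) {
  out <- raw()
  repeat {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L) stop("format error: unexpected EOF in header")
    if (ch == as.raw(10L)) break
    out <- c(out, ch)
  }
  sub("\r$", "", rawToChar(out))
}

#' Write a triangle mesh
#'
#' STL is written binary by default (or ASCII); PLY is written ASCII, with
#' optional per-vertex RGB colors (uchar), the format used for color-coded
#' grade overlays.
#'
#' @param mesh a `triMesh`.
#' @param path output path.
#' @param format `"auto"` (by extension), `"stl"` or `"ply"`.
#' @param binary for STL: write the binary dialect (default TRUE).
#' @param vertexColors optional n x 3 integer matrix (0-255) for PLY.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "stl", "ply"),
                      binary = TRUE, vertexColors = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "ply") "ply" else "stl"
  if (format == "stl") {
    if (binary) writeSTLBinary(mesh, path) else writeSTLAscii(mesh, path)
  } else writePLYAscii(mesh, path, vertexColors)
  invisible(path)
}

writeSTLBinary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L)
  V <- mesh$vertices; F <- mesh$faces; N <- mesh$normals
  block <- matrix(0, nf, 12L)
  block[, 1:3] <- N
  block[, 4:6] <- V[F[, 1L], , drop = FALSE]
  block[, 7:9] <- V[F[, 2L], , drop = FALSE]
  block[, 10:12] <- V[F[, 3L], , drop = FALSE]
  fl <- writeBin(as.numeric(t(block)), raw(), size = 4L)
  rec <- matrix(as.raw(0L), 50L, nf)
  rec[1:48, ] <- matrix(fl, 48L, nf)
  writeBin(as.vector(rec), con)
}

writeSTLAscii <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces; N <- mesh$normals
  nf <- nrow(F)
  lines <- character(2L + 7L * nf)
  lines[1] <- "solid toothprep"
  body <- vapply(seq_len(nf), function(i) {
    paste(sprintf("facet normal %.9g %.9g %.9g", N[i, 1], N[i, 2], N[i, 3]),
          "  outer loop",
          sprintf("    vertex %.9g %.9g %.9g", V[F[i, 1], 1], V[F[i, 1], 2], V[F[i, 1], 3]),
          sprintf("    vertex %.9g %.9g %.9g", V[F[i, 2], 1], V[F[i, 2], 2], V[F[i, 2], 3]),
          sprintf("    vertex %.9g %.9g %.9g", V[F[i, 3], 1], V[F[i, 3], 2], V[F[i, 3], 3]),
          "  endloop", "endfacet", sep = "\n")
  }, character(1L))
  writeLines(c("solid toothprep", body, "endsolid toothprep"), path)
}

writePLYAscii <- function(mesh, path, vertexColors = NULL) {
  V <- mesh$vertices; F <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z")
  if (!is.null(vertexColors)) {
    stopifnot(nrow(vertexColors) == nrow(V), ncol(vertexColors) == 3L)
    hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  vl <- if (is.null(vertexColors)) {
    sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
  } else {
    sprintf("%.9g %.9g %.9g %d %d %d", V[, 1], V[, 2], V[, 3],
            as.integer(vertexColors[, 1]), as.integer(vertexColors[, 2]),
            as.integer(vertexColors[, 3]))
  }
  fl <- sprintf("3 %d %d %d", F[, 1L] - 1L, F[, 2L] - 1L, F[, 3L] - 1L)
  writeLines(c(hdr, vl, fl), path)
}

#' Export an ordered 3D polyline as CSV
#' @param coords k x 3 matrix. @param path output path.
#' @export
writePolylineCSV <- function(coords, path) {
  df <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
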