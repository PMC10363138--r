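#' Default grading rubric for anatomic contour crown preparations
#'
#' Six criteria: the four graded cusp reductions (mm) and the two total
#' occlusal convergences (degrees). Each criterion has an acceptable interval
#' (grade A, 2 points, green), two marginal intervals flanking it (grade B,
#' 1 point, yellow) and everything else unacceptable (grade C, 0 points, red);
#' for TOC any undercut (negative value) is unacceptable.
#'
#' Boundary convention: a value exactly on an acceptable/marginal boundary
#' takes the better grade (A); exactly on a marginal/unacceptable boundary it
#' stays marginal (B). So for the buccal cusps 1.0 and 2.5 mm grade B while
#' 1.5 and 2.0 mm grade A.
#'
#' @return object of class `gradingRubric`: per criterion `acceptable`
#'   (c(lo, hi)), `marginalLo`, `marginalHi` (outer marginal bounds), `unit`;
#'   plus `points` and `colors` maps.
#' @export
defaultRubric <- function() {
  crit <- list(
    reductionMB = list(acceptable = c(1.5, 2.0), marginalLo = 1.0, marginalHi = 2.5, unit = "mm"),
    reductionDB = list(acceptable = c(1.5, 2.0), marginalLo = 1.0, marginalHi = 2.5, unit = "mm"),
    reductionML = list(acceptable = c(1.0, 1.5), marginalLo = 0.5, marginalHi = 2.0, unit = "mm"),
    reductionDL = list(acceptable = c(1.0, 1.5), marginalLo = 0.5, marginalHi = 2.0, unit = "mm"),
    tocMD = list(acceptable = c(6, 20), marginalLo = 0, marginalHi = 30, unit = "deg"),
    tocBL = list(acceptable = c(6, 20), marginalLo = 0, marginalHi = 30, unit = "deg"))
  structure(list(criteria = crit,
                 points = c(A = 2L, B = 1L, C = 0L),
                 colors = list(A = c(0L, 170L, 0L), B = c(255L, 200L, 0L),
                               C = c(220L, 30L, 30L),
                               ungraded = c(128L, 128L, 128L))),
            class = "gradingRubric")
}

#' Grade a single measured value
#'
#' Deterministic bin lookup under the rubric's boundary convention.
#'
#' @param criterion criterion name (e.g. `"reductionMB"`, `"tocBL"`).
#' @param value measured value (mm or degrees, full precision).
#' @param rubric a [defaultRubric()]-shaped rubric.
#' @return list: `grade` ("A"/"B"/"C"), `points` (2/1/0).
#' @export
gradeValue <- function(criterion, value, rubric = defaultRubric()) {
  cr <- rubric$criteria[[criterion]]
  if (is.null(cr)) stop("rubric error: unknown criterion ", criterion)
  a <- cr$acceptable
  grade <-
    if (value >= a[1] && value <= a[2]) "A"
    else if ((value >= cr$marginalLo && value < a[1]) ||
             (value > a[2] && value <= cr$marginalHi)) "B"
    else "C"
  list(grade = grade, points = unname(rubric$points[grade]))
}

#' Score one specimen's measurements
#'
#' Grades the six rubric criteria and totals the points (0-12). The margin
#' width is reported alongside but not graded.
#'
#' @param m a [measurementSet()] (or list/one-row data frame with the six
#'   criterion fields).
#' @param rubric grading rubric.
#' @return object of class `gradeReport`: `table` (criterion, value, grade,
#'   points), `total`, `specimen`, `marginWidth`.
#' @export
scoreSpecimen <- function(m, rubric = defaultRubric()) {
  need <- names(rubric$criteria)
  vals <- lapply(need, function(k) m[[k]])
  missing <- need[vapply(vals, function(v) is.null(v) || is.na(v), logical(1L))]
  if (length(missing))
    stop("incomplete-measurement error: missing ", paste(missing, collapse = ", "))
  g <- lapply(seq_along(need), function(i) gradeValue(need[i], vals[[i]], rubric))
  tab <- data.frame(criterion = need,
                    value = unlist(vals),
                    grade = vapply(g, `[[`, character(1L), "grade"),
                    points = vapply(g, `[[`, integer(1L), "points"),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, total = sum(tab$points),
                 specimen = if (!is.null(m$specimen)) m$specimen else NA,
                 marginWidth = if (!is.null(m$marginWidth)) m$marginWidth else NA_real_),
            class = "gradeReport")
}

#' @export
print.gradeReport <- function(x, ...) {
  cat(sprintf("gradeReport [%s]: total %d / 12\n", format(x$specimen), x$total))
  print(x$table, row.names = FALSE)
  if (!is.na(x$marginWidth))
    cat(sprintf("  margin width %.2f mm (ungraded)\n", x$marginWidth))
  invisible(x)
}

#' Per-criterion score summary over a measurement table
#'
#' Grades every row and returns the arithmetic mean and sample SD of the
#' 0/1/2 points per criterion.
#'
#' @param measurements data frame with the six criterion columns (e.g.
#'   [table1Fixture()] or rbind-ed `as.data.frame(measurementSet)` rows).
#' @param rubric grading rubric.
#' @return data frame: criterion, meanPoints, sdPoints, n. With a single
#'   specimen the SD is reported as 0 and flagged via attribute
#'   `sdUndefined`.
#' @export
scoreTable <- function(measurements, rubric = defaultRubric()) {
  measurements <- as.data.frame(measurements)
  if (nrow(measurements) == 0L) stop("input error: no measurements")
  need <- names(rubric$criteria)
  if (!all(need %in% names(measurements)))
    stop("input error: missing columns ",
         paste(setdiff(need, names(measurements)), collapse = ", "))
  pts <- vapply(need, function(k)
    vapply(measurements[[k]], function(v) gradeValue(k, v, rubric)$points,
           integer(1L)),
    integer(nrow(measurements)))
  pts <- matrix(pts, nrow = nrow(measurements),
                dimnames = list(NULL, need))
  out <- data.frame(criterion = need,
                    meanPoints = colMeans(pts),
                    sdPoints = if (nrow(pts) > 1L) apply(pts, 2L, sd) else 0,
                    n = nrow(pts), row.names = NULL)
  if (nrow(pts) == 1L) attr(out, "sdUndefined") <- TRUE
  attr(out, "points") <- pts
  out
}

#' Color-code a prepared mesh by its grades
#'
#' Paints each graded region with its grade color: the axial M/D quadrants by
#' the mesiodistal TOC grade, B/L by the buccolingual TOC grade, and the
#' occlusal area by the grade of the nearest graded cusp; everything ungraded
#' (margin band, root) is neutral grey. Colors are written per vertex, PLY.
#'
#' @param prepared the prepared `triMesh`.
#' @param partition matching `regionPartition`.
#' @param report matching `gradeReport`.
#' @param path optional output PLY path.
#' @return list: `vertexColors` (n x 3, 0-255), `faceGrade` (per-face label,
#'   NA where ungraded); writes the PLY when `path` is given.
#' @export
colorizeMesh <- function(prepared, partition, report, path = NULL) {
  rub <- defaultRubric()
  gr <- setNames(report$table$grade, report$table$criterion)
  nf <- nrow(prepared$faces)
  faceGrade <- rep(NA_character_, nf)
  faceGrade[partition$axial$M] <- gr[["tocMD"]]
  faceGrade[partition$axial$D] <- gr[["tocMD"]]
  faceGrade[partition$axial$B] <- gr[["tocBL"]]
  faceGrade[partition$axial$L] <- gr[["tocBL"]]
  # occlusal faces take the grade of the nearest graded cusp foot
  occ <- partition$occlusal
  if (length(occ)) {
    cusps <- c("MB", "DB", "ML", "DL")
    feet <- partition$feet[cusps, , drop = FALSE]
    F <- prepared$faces[occ, , drop = FALSE]
    cen <- (prepared$vertices[F[, 1L], , drop = FALSE] +
            prepared$vertices[F[, 2L], , drop = FALSE] +
            prepared$vertices[F[, 3L], , drop = FALSE]) / 3
    d2 <- vapply(seq_len(4L), function(k)
      rowSums(sweep(cen, 2L, feet[k, ])^2), numeric(length(occ)))
    nearest <- cusps[max.col(-matrix(d2, ncol = 4L))]
    faceGrade[occ] <- gr[paste0("reduction", nearest)]
  }
  n <- nrow(prepared$vertices)
  vcol <- matrix(rep(rub$colors$ungraded, each = n), n, 3L)
  for (g in c("C", "B", "A")) { # better grades win shared vertices
    fs <- which(faceGrade == g)
    if (!length(fs)) next
    vs <- unique(as.vector(prepared$faces[fs, ]))
    vcol[vs, ] <- matrix(rub$colors[[g]], length(vs), 3L, byrow = TRUE)
  }
  if (!is.null(path)) writeMesh(prepared, path, format = "ply", vertexColors = vcol)
  list(vertexColors = vcol, faceGrade = faceGrade)
}
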