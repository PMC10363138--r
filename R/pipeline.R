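#' Run a full evaluation from files and write the report bundle
#'
#' Thin orchestration over [evaluateSpecimen()] and [scoreSpecimen()]: reads
#' the mesh pair and standard points, evaluates, grades, and writes
#' `report.json` (schema-versioned: all seven measurements, six grades,
#' total), the margin polyline CSV and the color-coded PLY into `outDir`.
#'
#' @param anatomicalPath,preparedPath mesh files (STL or PLY, mm).
#' @param pointsPath CSV with columns label,x,y,z for the seven standard
#'   points.
#' @param outDir output directory.
#' @param cfg a [marginConfig()].
#' @param specimen id used in the report.
#' @param register run ICP before evaluating.
#' @param rubric grading rubric.
#' @param debug also write the sharpness PLY and boundary polylines.
#' @return list: `measurements`, `report`, `files` (paths written), invisibly.
#' @export
runEvaluation <- function(anatomicalPath, preparedPath, pointsPath, outDir,
                          cfg = marginConfig(), specimen = NULL,
                          register = FALSE, rubric = defaultRubric(),
                          debug = FALSE) {
  anatomical <- readMesh(anatomicalPath)
  prepared <- readMesh(preparedPath)
  ptsDf <- read.csv(pointsPath)
  if (!all(c("label", "x", "y", "z") %in% names(ptsDf)))
    stop("points CSV needs columns label, x, y, z")
  pts <- as.matrix(ptsDf[, c("x", "y", "z")])
  rownames(pts) <- ptsDf$label
  pts <- standardPoints(pts, anatomical)
  if (is.null(specimen))
    specimen <- tools::file_path_sans_ext(basename(preparedPath))
  ms <- evaluateSpecimen(anatomical, prepared, pts, cfg, specimen = specimen,
                         register = register)
  report <- scoreSpecimen(ms, rubric)
  part <- attr(ms, "partition")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c(report = file.path(outDir, "report.json"),
             margin = file.path(outDir, "margin_polyline.csv"),
             colored = file.path(outDir, "graded.ply"))
  jsonlite::write_json(
    list(schema = "toothprep-report/1",
         specimen = specimen,
         measurements = unclass(ms)[-1L],
         grades = setNames(as.list(report$table$grade), report$table$criterion),
         points = setNames(as.list(report$table$points), report$table$criterion),
         total = report$total,
         config = list(eps = cfg$eps, seedCount = cfg$seedCount,
                       offset = cfg$offset, tRatio = cfg$tRatio,
                       axis = cfg$axis, mesialDir = cfg$mesialDir)),
    files[["report"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writePolylineCSV(part$margin$coords, files[["margin"]])
  colorizeMesh(prepared, part, report, path = files[["colored"]])
  if (debug) {
    writeSharpnessPLY(prepared, sharpnessFields(prepared),
                      file.path(outDir, "sharpness.ply"))
    writePolylineCSV(part$lowerBoundary, file.path(outDir, "axial_lower.csv"))
    writePolylineCSV(part$upperBoundary, file.path(outDir, "axial_upper.csv"))
  }
  invisible(list(measurements = ms, report = report, files = files))
}

#' Per-criterion score means from a measurement CSV
#'
#' Reads a CSV shaped like [table1Fixture()] (columns `reductionMB` ...
#' `tocBL`; extra columns ignored) and returns the per-criterion mean and SD
#' of the rubric points.
#'
#' @param path CSV path (or a data frame).
#' @param rubric grading rubric.
#' @return [scoreTable()] data frame.
#' @export
gradeTableCSV <- function(path, rubric = defaultRubric()) {
  df <- if (is.data.frame(path)) path else {
    out <- try(read.csv(path), silent = TRUE)
    if (inherits(out, "try-error")) stop("input error: cannot read CSV ", path)
    out
  }
  scoreTable(df, rubric)
}
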