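## End-to-end orchestration: scans in -> registration -> measurements ->
## reports, plus the simulation and reliability entry points used by the
## command-line interface (inst/cli/torsotopo.R).

#' Measure a batch of torso scans
#'
#' For every input mesh: register the template atlas, transfer landmarks,
#' compute the measurement suite for the declared pose, and write JSON and
#' CSV outputs. Failures are reported per scan and the batch continues.
#'
#' @param inputs character vector of mesh paths (OBJ/PLY/STL).
#' @param poses pose tag per scan ("EOS", "A-pose", "Adam"); recycled.
#' @param atlas a \linkS4class{TemplateAtlas}, a serialized atlas base path,
#'   or NULL for the packaged default.
#' @param outDir output directory (created if needed).
#' @param params registration parameters from \code{\link{nicpParams}}.
#' @param nProfile number of profile levels (odd, >= 21).
#' @param verbose print per-scan progress.
#' @return invisible data.frame: scan, pose, status, residual_rms, message;
#'   suites are written to \code{outDir}.
#' @export
runMeasure <- function(inputs, poses = "EOS", atlas = NULL, outDir = "measure_out",
                       params = nicpParams(), nProfile = 201L, verbose = TRUE) {
  if (nProfile < 21L || nProfile %% 2L == 0L)
    stop("nProfile must be odd and >= 21")
  if (is.null(atlas)) atlas <- templateAtlas()
  else if (is.character(atlas)) atlas <- readAtlas(atlas)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  poses <- rep_len(poses, length(inputs))
  log <- list()
  for (i in seq_along(inputs)) {
    scanPath <- inputs[i]
    res <- tryCatch({
      scan <- readMesh(scanPath)
      reg <- registerScan(atlas, scan, params = params)
      suite <- measureAll(reg, pose = poses[i], nProfile = nProfile)
      base <- tools::file_path_sans_ext(basename(scanPath))
      writeSuite(suite, file.path(outDir, paste0(base, "_suite.json")),
                 meta = list(scan = scanPath))
      writeSuite(suite, file.path(outDir, paste0(base, "_suite.csv")),
                 meta = list(scan = scanPath))
      if (verbose)
        message(sprintf("[%d/%d] %s: residual RMS %.3f mm", i, length(inputs),
                        basename(scanPath), residualRMS(reg)))
      data.frame(scan = scanPath, pose = poses[i], status = "ok",
                 residual_rms = residualRMS(reg), message = "")
    }, error = function(e) {
      if (verbose) message(sprintf("[%d/%d] %s: FAILED (%s)", i, length(inputs),
                                   basename(scanPath), conditionMessage(e)))
      data.frame(scan = scanPath, pose = poses[i], status = "error",
                 residual_rms = NA_real_, message = conditionMessage(e))
    })
    log[[i]] <- res
  }
  out <- do.call(rbind, log)
  write.csv(out, file.path(outDir, "run_log.csv"), row.names = FALSE)
  invisible(out)
}

#' Simulate a study cohort: meshes, ground truth and rating table
#'
#' Generates \code{nSubjects} parametric torsos, writes their meshes (OBJ)
#' and landmark sets (JSON), a ground-truth CSV of the injected shape
#' parameters, and the long-format rating table of a crossed reliability
#' study. Fully reproducible from the seed.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param outDir output directory.
#' @param seed base seed.
#' @param mode rating-table mode: "proxy" (closed-form variance components)
#'   or "pipeline" (each scan perturbed and measured).
#' @return invisible list(truth, study) of the two data frames.
#' @export
runSimulate <- function(design, outDir = "sim_out", seed = 1L, mode = "proxy") {
  if (design@nSubjects < 1) stop("nSubjects must be >= 1")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  truthRows <- list()
  for (i in seq_len(design@nSubjects)) {
    set.seed(seed * 10000L + i)
    sc <- 1 + rnorm(1, 0, design@bmiScaleSD)
    spec <- torsoSpec(rot = runif(1, 2, 15), bow = runif(1, 2, 25),
                      hump = runif(1, 0, 10),
                      aCtrl = torsoSpec()@aCtrl * sc,
                      bCtrl = torsoSpec()@bCtrl * sc,
                      nLevels = 24L, nAround = 64L)
    gen <- generateTorso(spec)
    writeMesh(gen$mesh, file.path(outDir, sprintf("subject%02d.obj", i)))
    writeLandmarks(gen$landmarks, file.path(outDir, sprintf("subject%02d_landmarks.json", i)))
    truthRows[[i]] <- data.frame(subject = i, rot_deg = spec@rot,
                                 bow_mm = spec@bow, hump_mm = spec@hump,
                                 scale = sc,
                                 spine_length_cm = gen$truth$spineLength,
                                 xsa_mid_dm2 = gen$truth$xsa(0.5) / 1e4)
  }
  truth <- do.call(rbind, truthRows)
  write.csv(truth, file.path(outDir, "ground_truth.csv"), row.names = FALSE)
  study <- simulateRatingStudy(design, seed = seed, mode = mode)
  write.csv(study, file.path(outDir, "study.csv"), row.names = FALSE)
  invisible(list(truth = truth, study = study))
}

#' Reliability report from a long-format study CSV
#'
#' @param study path to a study CSV or a data.frame with columns subject,
#'   rater, placement, trial, parameter, value.
#' @param out optional output CSV path for the report.
#' @return the report data.frame (see \code{\link{reliabilityReport}}).
#' @export
runReliability <- function(study, out = NULL) {
  if (is.character(study)) study <- read.csv(study)
  rep_ <- reliabilityReport(study)
  if (!is.null(out)) write.csv(rep_, out, row.names = FALSE)
  rep_
}
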