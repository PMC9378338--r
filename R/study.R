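## Scan-protocol emulation: pose/rater noise models for repeated "scans" of
## the same subject, and simulation of full crossed rating studies
## (subjects x raters x placements x trials).
##
## The scan protocol being emulated: each pose is scanned twice without the
## subject moving (test-retest), the subject then steps out and is
## repositioned before the sequence is recorded again (remove-replace), and
## the whole procedure is repeated with a second rater.

#' Reliability study design
#'
#' @slot nSubjects number of subjects.
#' @slot nRaters,nTrials raters (default 2) and scans per placement (2).
#' @slot sigmaPose between-placement posture noise: named numeric with
#'   \code{rot} (degrees, axial rotation amplitude) and \code{bow} (mm).
#' @slot sigmaTrial within-placement noise: named numeric with \code{rot}
#'   (degrees, rigid jitter), \code{trans} (mm) and \code{vertex} (mm,
#'   per-vertex reconstruction noise).
#' @slot sigmaRater per-rater guidance bias (degrees of pose rotation).
#' @slot sdSubject,sdRater,sdTrial,sdPlacement closed-form proxy-mode
#'   standard deviations of the subject, rater, residual and placement
#'   variance components.
#' @slot bmiScaleSD per-subject relative scaling SD of the semi-axes
#'   (the BMI proxy).
#' @slot seed base seed.
#' @export
setClass("StudyDesign", representation(
  nSubjects = "integer", nRaters = "integer", nTrials = "integer",
  sigmaPose = "numeric", sigmaTrial = "numeric", sigmaRater = "numeric",
  sdSubject = "numeric", sdRater = "numeric", sdTrial = "numeric",
  sdPlacement = "numeric", bmiScaleSD = "numeric", seed = "integer"
))

setValidity("StudyDesign", function(object) {
  if (object@nSubjects < 1) return("nSubjects must be >= 1")
  if (any(c(object@sigmaPose, object@sigmaTrial, object@sigmaRater,
            object@sdSubject, object@sdRater, object@sdTrial,
            object@sdPlacement, object@bmiScaleSD) < 0))
    return("all noise scales must be >= 0")
  TRUE
})

#' Construct a StudyDesign
#'
#' Default noise levels emulate cooperative subjects: between-placement
#' posture changes of about 1.5 degrees axial rotation and 3 mm lateral bow,
#' within-placement sway of 0.3 degrees / 1 mm, and 0.3 mm surface
#' reconstruction noise.
#'
#' @param nSubjects number of subjects.
#' @param nRaters,nTrials raters and scans per placement.
#' @param sigmaPose,sigmaTrial,sigmaRater posture/trial/rater noise scales
#'   (see \linkS4class{StudyDesign}).
#' @param sdSubject,sdRater,sdTrial,sdPlacement proxy-mode variance
#'   component SDs.
#' @param bmiScaleSD per-subject semi-axis scaling SD.
#' @param seed base seed.
#' @return a \linkS4class{StudyDesign}.
#' @export
studyDesign <- function(nSubjects = 10L, nRaters = 2L, nTrials = 2L,
                        sigmaPose = c(rot = 1.5, bow = 3),
                        sigmaTrial = c(rot = 0.3, trans = 1, vertex = 0.3),
                        sigmaRater = 0.5,
                        sdSubject = 3, sdRater = 0.5, sdTrial = 0.5,
                        sdPlacement = 0, bmiScaleSD = 0.08, seed = 1L) {
  new("StudyDesign", nSubjects = as.integer(nSubjects),
      nRaters = as.integer(nRaters), nTrials = as.integer(nTrials),
      sigmaPose = sigmaPose, sigmaTrial = sigmaTrial, sigmaRater = sigmaRater,
      sdSubject = sdSubject, sdRater = sdRater, sdTrial = sdTrial,
      sdPlacement = sdPlacement, bmiScaleSD = bmiScaleSD,
      seed = as.integer(seed))
}

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d subjects x %d raters x 2 placements x %d trials\n",
              object@nSubjects, object@nRaters, object@nTrials))
})

smallRotation <- function(anglesDeg) {
  a <- anglesDeg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Simulate a repeated scan of a subject
#'
#' Test-retest applies a small rigid jitter plus per-vertex reconstruction
#' noise; remove-replace additionally re-samples the posture parameters
#' (axial rotation and lateral bow offsets) before regenerating the surface.
#' Deterministic given the seed.
#'
#' @param torso result of \code{\link{generateTorso}}.
#' @param design a \linkS4class{StudyDesign}.
#' @param condition "test-retest" or "remove-replace".
#' @param seed integer seed for this scan.
#' @param raterBiasDeg systematic pose-rotation bias of the rater's guidance
#'   (degrees), applied in remove-replace conditions.
#' @return list with \code{mesh}, \code{landmarks}, \code{spec}.
#' @export
perturbScan <- function(torso, design, condition = c("test-retest", "remove-replace"),
                        seed, raterBiasDeg = 0) {
  condition <- match.arg(condition)
  set.seed(seed)
  spec <- torso$spec
  if (condition == "remove-replace") {
    spec@rot <- spec@rot + rnorm(1, 0, design@sigmaPose["rot"]) + raterBiasDeg
    spec@bow <- spec@bow + rnorm(1, 0, design@sigmaPose["bow"])
    gen <- generateTorso(spec)
    mesh <- gen$mesh; lm <- gen$landmarks
  } else {
    mesh <- torso$mesh; lm <- torso$landmarks
  }
  R <- smallRotation(rnorm(3, 0, design@sigmaTrial["rot"]))
  tr <- rnorm(3, 0, design@sigmaTrial["trans"])
  V <- mesh@vertices %*% t(R) + matrix(tr, nrow(mesh@vertices), 3, byrow = TRUE)
  if (design@sigmaTrial["vertex"] > 0)
    V <- V + matrix(rnorm(length(V), 0, design@sigmaTrial["vertex"]), nrow(V), 3)
  C <- lm@coords %*% t(R) + matrix(tr, nrow(lm@coords), 3, byrow = TRUE)
  rownames(C) <- rownames(lm@coords)
  list(mesh = TriMesh(V, mesh@faces), landmarks = LandmarkSet(C), spec = spec)
}

#' Simulate a crossed rating study
#'
#' Produces the long-format rating table of a full crossed design
#' (subjects x raters x 2 placements x trials). In \code{proxy} mode values
#' are drawn from the closed-form variance-component model
#' value = subject + rater + placement + residual, whose population
#' ICC(2,1) is sigma_subj^2 / (sigma_subj^2 + sigma_rater^2 +
#' sigma_trial^2); in \code{pipeline} mode each scan is generated with
#' \code{\link{perturbScan}} and measured with \code{\link{measureAll}}
#' through the atlas correspondence.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param specPopulation optional function(i) returning the
#'   \linkS4class{TorsoSpec} of subject i (pipeline mode).
#' @param seed base seed.
#' @param mode "proxy" or "pipeline".
#' @param parameters measurement names to report (pipeline mode).
#' @return data.frame with columns subject, rater, placement, trial,
#'   condition, parameter, value (+ bmi); attribute \code{popICC} carries
#'   the population ICC (proxy mode).
#' @export
simulateRatingStudy <- function(design, specPopulation = NULL, seed = 1L,
                                mode = c("proxy", "pipeline"),
                                parameters = c("bsr_max_deg", "centroid_dev_mm",
                                               "spine_length_cm")) {
  mode <- match.arg(mode)
  if (design@nSubjects < 3 && mode == "proxy")
    stop("need at least 3 subjects")
  n <- design@nSubjects; k <- design@nRaters; q <- design@nTrials
  if (mode == "proxy") {
    set.seed(seed)
    subj <- rnorm(n, 0, design@sdSubject)
    rater <- rnorm(k, 0, design@sdRater)
    rows <- expand.grid(trial = seq_len(q), placement = 1:2,
                        rater = seq_len(k), subject = seq_len(n))
    plKey <- paste(rows$subject, rows$rater, rows$placement, sep = ".")
    uk <- unique(plKey)
    plEff <- setNames(rnorm(length(uk), 0, design@sdPlacement), uk)
    val <- subj[rows$subject] + rater[rows$rater] + plEff[plKey] +
      rnorm(nrow(rows), 0, design@sdTrial)
    out <- data.frame(subject = rows$subject, rater = rows$rater,
                      placement = rows$placement, trial = rows$trial,
                      condition = paste0("placement", rows$placement),
                      parameter = "proxy", value = val)
    attr(out, "popICC") <- design@sdSubject^2 /
      (design@sdSubject^2 + design@sdRater^2 + design@sdTrial^2)
    return(out)
  }

  ## pipeline mode
  if (is.null(specPopulation)) {
    specPopulation <- function(i) {
      set.seed(seed * 10000L + i)
      sc <- 1 + rnorm(1, 0, design@bmiScaleSD)
      torsoSpec(rot = runif(1, 2, 15), bow = runif(1, 2, 25),
                hump = runif(1, 0, 10),
                aCtrl = torsoSpec()@aCtrl * sc, bCtrl = torsoSpec()@bCtrl * sc,
                nLevels = 24L, nAround = 64L)
    }
  }
  atlasCache <- new.env(parent = emptyenv())
  rows <- list()
  for (i in seq_len(n)) {
    spec <- specPopulation(i)
    base <- generateTorso(spec)
    key <- paste(spec@nLevels, spec@nAround)
    if (!exists(key, envir = atlasCache))
      assign(key, templateAtlas(spec@nLevels, spec@nAround), envir = atlasCache)
    atl <- get(key, envir = atlasCache)
    set.seed(seed * 1000L + i)
    raterBias <- rnorm(k, 0, design@sigmaRater)
    bmi <- 21 + 40 * (mean(spec@aCtrl) / mean(torsoSpec()@aCtrl) - 1)
    for (r in seq_len(k)) for (p in 1:2) {
      placed <- perturbScan(base, design,
                            condition = if (p == 1) "test-retest" else "remove-replace",
                            seed = seed * 100000L + i * 100L + r * 10L + p,
                            raterBiasDeg = raterBias[r])
      for (tr in seq_len(q)) {
        scan <- perturbScan(list(mesh = placed$mesh, landmarks = placed$landmarks,
                                 spec = placed$spec),
                            design, condition = "test-retest",
                            seed = seed * 1000000L + i * 1000L + r * 100L + p * 10L + tr)
        reg <- new("RegisteredTorso", mesh = scan$mesh, atlas = atl,
                   residualRMS = 0)
        suite <- measureAll(reg, landmarks = scan$landmarks,
                            pose = spec@pose, nProfile = 101L)
        v <- measurementValues(suite)[parameters]
        rows[[length(rows) + 1]] <- data.frame(
          subject = i, rater = r, placement = p, trial = tr,
          condition = paste0("placement", p),
          parameter = parameters, value = unname(v), bmi = bmi)
      }
    }
  }
  do.call(rbind, rows)
}
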