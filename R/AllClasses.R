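#' @import methods
#' @importFrom stats aov coef lm median pf pt qf quantile rnorm runif sd t.test
#'   var cor.test p.adjust setNames
#' @importFrom utils head read.csv tail write.csv
#' @importFrom tools file_ext file_path_sans_ext
#' @importFrom grDevices chull
#' @useDynLib torsotopo, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Internal unit convention: all coordinates are millimetres. Reporting units
## (cm, dm^2, L, mm, degrees) are applied at the measurement boundary only.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Triangle mesh
#'
#' A triangle surface mesh in millimetre coordinates. Faces are
#' counter-clockwise when seen from outside. The \code{watertight} flag is
#' verified at construction time: every edge shared by exactly two faces with
#' consistent orientation.
#'
#' @slot vertices numeric matrix, n x 3 (mm).
#' @slot faces integer matrix, m x 3, 1-based vertex indices.
#' @slot watertight logical scalar.
#' @export
setClass("TriMesh", representation(
  vertices = "matrix",
  faces = "matrix",
  watertight = "logical"
))

setValidity("TriMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must be n x 3")
  if (ncol(f) != 3L) return("faces must be m x 3")
  if (nrow(f) > 0 && (min(f) < 1L || max(f) > nrow(v)))
    return("face indices out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    return("degenerate faces (repeated vertex index)")
  TRUE
})

#' Construct a TriMesh
#'
#' Builds a \linkS4class{TriMesh}, removing zero-area faces and verifying
#' watertightness (every edge shared by exactly two faces, opposite
#' orientation).
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 matrix of 1-based vertex indices, counter-clockwise
#'   from outside.
#' @return A \linkS4class{TriMesh}.
#' @export
TriMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  ## drop zero-area faces
  if (nrow(faces) > 0) {
    a <- vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 2], , drop = FALSE]
    cc <- vertices[faces[, 3], , drop = FALSE]
    cr <- crossRows(b - a, cc - a)
    area2 <- sqrt(rowSums(cr^2))
    faces <- faces[area2 > 1e-12, , drop = FALSE]
  }
  wt <- checkWatertight(vertices, faces)
  new("TriMesh", vertices = vertices, faces = faces, watertight = wt$watertight)
}

#' @describeIn TriMesh-class number of vertices and faces
#' @param object a TriMesh
#' @export
setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces, %s\n",
              nrow(object@vertices), nrow(object@faces),
              if (object@watertight) "watertight" else "open"))
})

#' @rdname TriMesh-class
#' @param x a TriMesh
#' @export
vertices <- function(x) x@vertices

#' @rdname TriMesh-class
#' @export
faces <- function(x) x@faces

#' @rdname TriMesh-class
#' @export
isWatertight <- function(x) x@watertight

#' Oriented plane
#'
#' @slot point numeric length-3 point on the plane (mm).
#' @slot normal unit normal (|n| = 1 within 1e-9).
#' @export
setClass("Plane", representation(point = "numeric", normal = "numeric"))

setValidity("Plane", function(object) {
  if (length(object@point) != 3L || length(object@normal) != 3L)
    return("point and normal must be length 3")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be unit length")
  TRUE
})

#' @rdname Plane-class
#' @param point length-3 point on the plane (mm).
#' @param normal length-3 normal vector (normalized internally).
#' @export
Plane <- function(point, normal) {
  n <- as.numeric(normal)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("zero-length plane normal")
  new("Plane", point = as.numeric(point), normal = n / nn)
}

#' Planar cross-section of a mesh
#'
#' A closed, simple, counter-clockwise polygon obtained by slicing a
#' watertight mesh with a plane, expressed in an in-plane orthonormal basis
#' \code{(u, v)} where \code{u} is the lateral and \code{v} the
#' anteroposterior direction.
#'
#' @slot plane the slicing \linkS4class{Plane}.
#' @slot polygon k x 2 matrix of in-plane coordinates (mm), counter-clockwise,
#'   not repeating the first point.
#' @slot levelT level fraction in [0, 1] along the trunk (NA when unknown).
#' @slot basis 2 x 3 matrix; rows are the in-plane axes u and v.
#' @slot origin3d 3D origin of the in-plane coordinate system.
#' @export
setClass("CrossSection", representation(
  plane = "Plane",
  polygon = "matrix",
  levelT = "numeric",
  basis = "matrix",
  origin3d = "numeric"
))

setValidity("CrossSection", function(object) {
  if (nrow(object@polygon) < 3L) return("polygon needs >= 3 vertices")
  if (ncol(object@polygon) != 2L) return("polygon must be k x 2")
  if (!all(dim(object@basis) == c(2L, 3L))) return("basis must be 2 x 3")
  TRUE
})

setMethod("show", "CrossSection", function(object) {
  cat(sprintf("CrossSection: %d vertices, area %.1f mm^2, t = %s\n",
              nrow(object@polygon), polygonArea(object),
              format(object@levelT)))
})

#' Named anatomical landmark set
#'
#' Nine named 3D landmark positions (mm): PSIS_L, PSIS_R, ASIS_L, ASIS_R,
#' XP (xiphoid process), JN (jugular notch), SP_L2, SP_T8, SP_C7, optionally
#' extended with evaluation-only points (e.g. AC_L, AC_R).
#'
#' @slot coords named k x 3 matrix of positions (mm).
#' @export
setClass("LandmarkSet", representation(coords = "matrix"))

CORE_LANDMARKS <- c("PSIS_L", "PSIS_R", "ASIS_L", "ASIS_R",
                    "XP", "JN", "SP_L2", "SP_T8", "SP_C7")

setValidity("LandmarkSet", function(object) {
  if (ncol(object@coords) != 3L) return("coords must be k x 3")
  miss <- setdiff(CORE_LANDMARKS, rownames(object@coords))
  if (length(miss)) return(paste("missing landmarks:", paste(miss, collapse = ", ")))
  TRUE
})

#' @rdname LandmarkSet-class
#' @param coords named k x 3 matrix (or coercible) of landmark positions.
#' @export
LandmarkSet <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  new("LandmarkSet", coords = coords)
}

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet: %d landmarks (%s)\n", nrow(object@coords),
              paste(head(rownames(object@coords), 4), collapse = ", ")))
})

#' @rdname LandmarkSet-class
#' @param x a LandmarkSet
#' @param name landmark name
#' @export
landmark <- function(x, name) {
  if (!name %in% rownames(x@coords)) stop("missing landmark: ", name)
  as.numeric(x@coords[name, ])
}

#' @rdname LandmarkSet-class
#' @export
landmarkNames <- function(x) rownames(x@coords)

#' Symmetric torso template atlas
#'
#' The anatomical reference frame of all measurements: a watertight
#' grid-connectivity torso mesh with an exact left/right symmetry map,
#' landmark vertex indices, the dorsal midline vertex chain from the PSIS
#' level to C7, and per-face anatomical region labels.
#'
#' @slot mesh the template \linkS4class{TriMesh}.
#' @slot symmetryMap integer involution on vertex indices pairing left/right.
#' @slot landmarkIndex named integer vector of landmark vertex indices.
#' @slot midlineChain ordered vertex indices along the dorsal midline,
#'   PSIS level to C7 level.
#' @slot faceLabels factor over faces with levels dorsal_left, dorsal_right,
#'   ventral_left, ventral_right, cap.
#' @slot levels numeric vector of level parameters t for each vertex ring.
#' @slot gridDim integer c(nLevels, nAround) of the vertex grid.
#' @export
setClass("TemplateAtlas", representation(
  mesh = "TriMesh",
  symmetryMap = "integer",
  landmarkIndex = "integer",
  midlineChain = "integer",
  faceLabels = "factor",
  levels = "numeric",
  gridDim = "integer"
))

setValidity("TemplateAtlas", function(object) {
  s <- object@symmetryMap
  if (length(s) != nrow(object@mesh@vertices)) return("symmetryMap length mismatch")
  if (!all(s[s] == seq_along(s))) return("symmetryMap is not an involution")
  miss <- setdiff(CORE_LANDMARKS, names(object@landmarkIndex))
  if (length(miss)) return(paste("missing landmark indices:", paste(miss, collapse = ", ")))
  if (!all(s[object@midlineChain] == object@midlineChain))
    return("midline chain vertices must be fixed points of the symmetry map")
  if (!object@mesh@watertight) return("template must be watertight")
  TRUE
})

setMethod("show", "TemplateAtlas", function(object) {
  cat(sprintf("TemplateAtlas: %d x %d grid, %d vertices, %d landmarks, midline chain %d\n",
              object@gridDim[1], object@gridDim[2], nrow(object@mesh@vertices),
              length(object@landmarkIndex), length(object@midlineChain)))
})

#' Atlas deformed into scan space
#'
#' The template mesh deformed to fit a raw scan: same connectivity (hence
#' full per-vertex anatomical correspondence with the atlas), watertight, with
#' the registration residual recorded.
#'
#' @slot mesh deformed \linkS4class{TriMesh} in scan space.
#' @slot atlas the source \linkS4class{TemplateAtlas}.
#' @slot residualRMS point-to-surface RMS residual (mm).
#' @export
setClass("RegisteredTorso", representation(
  mesh = "TriMesh",
  atlas = "TemplateAtlas",
  residualRMS = "numeric"
))

setValidity("RegisteredTorso", function(object) {
  if (nrow(object@mesh@vertices) != nrow(object@atlas@mesh@vertices))
    return("vertex count differs from atlas")
  if (!identical(dim(object@mesh@faces), dim(object@atlas@mesh@faces)))
    return("face count differs from atlas")
  TRUE
})

setMethod("show", "RegisteredTorso", function(object) {
  cat(sprintf("RegisteredTorso: %d vertices, residual RMS %.3f mm\n",
              nrow(object@mesh@vertices), object@residualRMS))
})

#' @rdname RegisteredTorso-class
#' @param x a RegisteredTorso
#' @export
residualRMS <- function(x) x@residualRMS

#' Landmark-derived anatomical body frame
#'
#' Right-handed orthonormal triad: \code{lateralU} points to the patient's
#' left, \code{anteriorV} anteriorly, \code{longitudinalW} cranially.
#' The reference for angular measurements is the coronal plane for upright
#' poses and the floor plane for Adam's bend.
#'
#' @slot origin PSIS centroid (mm).
#' @slot lateralU,anteriorV,longitudinalW unit axes.
#' @slot c7 position of C7 (mm), defining the t = 1 level.
#' @slot pose one of "EOS", "A-pose", "Adam".
#' @slot referenceMode "coronal" or "floor".
#' @slot floorNormal unit floor normal (used when referenceMode = "floor").
#' @slot landmarks the \linkS4class{LandmarkSet} the frame was built from.
#' @export
setClass("BodyFrame", representation(
  origin = "numeric",
  lateralU = "numeric",
  anteriorV = "numeric",
  longitudinalW = "numeric",
  c7 = "numeric",
  pose = "character",
  referenceMode = "character",
  floorNormal = "numeric",
  landmarks = "LandmarkSet"
))

setValidity("BodyFrame", function(object) {
  R <- rbind(object@lateralU, object@anteriorV, object@longitudinalW)
  if (max(abs(R %*% t(R) - diag(3))) > 1e-8) return("axes not orthonormal")
  if (det(R) < 0) return("frame must be right-handed")
  if (!object@pose %in% c("EOS", "A-pose", "Adam")) return("unknown pose")
  if (object@referenceMode == "floor" && object@pose != "Adam")
    return("floor reference is used only for the Adam pose")
  TRUE
})

setMethod("show", "BodyFrame", function(object) {
  cat(sprintf("BodyFrame (%s, %s reference): origin (%.1f, %.1f, %.1f) mm\n",
              object@pose, object@referenceMode,
              object@origin[1], object@origin[2], object@origin[3]))
})

#' Fourth-order harmonic fit of the back symmetry line
#'
#' x(t) = a0 + sum_k a_k cos(2 pi k t) + b_k sin(2 pi k t), k = 1..4,
#' for t in [0, 1]; x is the lateral deviation in mm.
#'
#' @slot a0 constant term (mm).
#' @slot a,b cosine / sine coefficients, length 4 (mm).
#' @slot residRMS residual RMS of the least-squares fit (mm).
#' @export
setClass("HarmonicFit", representation(
  a0 = "numeric", a = "numeric", b = "numeric", residRMS = "numeric"
))

setValidity("HarmonicFit", function(object) {
  if (length(object@a) != 4L || length(object@b) != 4L)
    return("exactly order 4: a and b must have length 4")
  TRUE
})

setMethod("show", "HarmonicFit", function(object) {
  cat(sprintf("HarmonicFit (order 4): a0 = %.2f mm, resid RMS %.3f mm\n",
              object@a0, object@residRMS))
})

#' Evaluate a harmonic fit
#' @param fit a \linkS4class{HarmonicFit}
#' @param t level fractions in [0, 1]
#' @return lateral deviation x(t) in mm
#' @export
evalHarmonic <- function(fit, t) {
  x <- rep(fit@a0, length(t))
  for (k in 1:4)
    x <- x + fit@a[k] * cos(2 * pi * k * t) + fit@b[k] * sin(2 * pi * k * t)
  x
}

#' Derivative dx/dt of a harmonic fit
#' @inheritParams evalHarmonic
#' @return dx/dt in mm per unit t
#' @export
evalHarmonicDeriv <- function(fit, t) {
  d <- numeric(length(t))
  for (k in 1:4)
    d <- d + 2 * pi * k * (-fit@a[k] * sin(2 * pi * k * t) +
                             fit@b[k] * cos(2 * pi * k * t))
  d
}

#' Suite of trunk-shape measurements
#'
#' All reported quantities for one scan, in the reporting units of the
#' clinical tables: cm (spine length), dm^2 (areas), L (volumes), mm
#' (centroid deviation), degrees (angles). Signed angular/lateral values use
#' the convention positive = toward / on the patient's left.
#' In the Adam (forward bend) pose only spine length, back area and the BSR
#' family are computed; the remaining measures are standing-pose only and are
#' set to NA.
#'
#' @slot values named numeric vector of measurements.
#' @slot pose pose tag.
#' @slot suppressed names of measures not applicable in this pose.
#' @export
setClass("MeasurementSuite", representation(
  values = "numeric", pose = "character", suppressed = "character"
))

MEASURE_NAMES <- c("spine_length_cm", "back_area_dm2",
                   "back_area_left_dm2", "back_area_right_dm2",
                   "xsa_L2_dm2", "xsa_T8_dm2", "xsa_JN_dm2",
                   "xsv_L2_T8_L", "xsv_XP_JN_L", "xsv_PSIS_JN_L",
                   "bsr_25_deg", "bsr_50_deg", "bsr_75_deg", "bsr_max_deg",
                   "centroid_dev_mm", "axis_max_deg", "qangle_deg")

setValidity("MeasurementSuite", function(object) {
  miss <- setdiff(MEASURE_NAMES, names(object@values))
  if (length(miss)) return(paste("missing measures:", paste(miss, collapse = ", ")))
  TRUE
})

setMethod("show", "MeasurementSuite", function(object) {
  cat(sprintf("MeasurementSuite (%s pose):\n", object@pose))
  v <- object@values[MEASURE_NAMES]
  for (nm in names(v))
    cat(sprintf("  %-22s %s\n", nm, if (is.na(v[nm])) "NA (standing poses only)"
                else sprintf("%8.3f", v[nm])))
})

#' @rdname MeasurementSuite-class
#' @param x a MeasurementSuite
#' @export
measurementValues <- function(x) x@values

#' ICC(2,1) result
#'
#' Two-way random effects, absolute agreement, single rater intraclass
#' correlation with 95% confidence bounds and the underlying mean squares.
#'
#' @slot icc point estimate.
#' @slot ciLow,ciHigh 95% confidence bounds.
#' @slot msr,msc,mse mean squares for rows (subjects), columns (raters), error.
#' @slot n,k numbers of subjects and raters.
#' @export
setClass("IccResult", representation(
  icc = "numeric", ciLow = "numeric", ciHigh = "numeric",
  msr = "numeric", msc = "numeric", mse = "numeric",
  n = "integer", k = "integer"
))

setValidity("IccResult", function(object) {
  if (object@icc > 1 + 1e-12) return("icc must be <= 1")
  if (object@ciLow > object@icc + 1e-9 || object@ciHigh < object@icc - 1e-9)
    return("confidence bounds must bracket the estimate")
  TRUE
})

setMethod("show", "IccResult", function(object) {
  cat(sprintf("ICC(2,1) = %.3f [%.3f, %.3f] (n = %d subjects, k = %d raters)\n",
              object@icc, object@ciLow, object@ciHigh, object@n, object@k))
})
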