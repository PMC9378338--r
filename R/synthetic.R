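## Parametric scoliotic-torso generator with analytic ground truth, and the
## symmetric template atlas built from the same surface machinery.
##
## Section model at trunk level t (t = 0 at PSIS, 1 at C7; the mesh carries a
## small flesh margin beyond both): an ellipse with semi-axes a(t) (lateral)
## and b(t) (anteroposterior), plus two small symmetric paraspinal
## prominences on the dorsal side (radial Gaussian bumps at +/- paraPhi from
## the dorsal midline) and an optional one-sided dorsal hump. Real backs are
## not convex: the paraspinal prominences are what a scoliometer rests on,
## and without them the posterior supporting line would be insensitive to
## axial rotation. The section is rotated by theta(t) (positive rotates the
## patient's left side posteriorly) and displaced laterally by the bow
## c(t) = A sin(pi t).

#' Parametric torso specification
#'
#' @slot H trunk height PSIS to C7 (mm).
#' @slot aCtrl,bCtrl spline control values for the lateral / anteroposterior
#'   semi-axis profiles a(t), b(t), at uniform knots over the meshed span.
#' @slot bow lateral bow amplitude A (mm); c(t) = A sin(pi t).
#' @slot rot axial rotation amplitude Theta (degrees); theta(t) = Theta sin(pi t).
#' @slot hump one-sided dorsal hump amplitude (mm) at azimuth humpPhi.
#' @slot humpPhi,humpSigma hump centre and width (radians from dorsal midline).
#' @slot para paraspinal prominence amplitude (mm), symmetric pair.
#' @slot paraPhi,paraSigma prominence centre and width (radians).
#' @slot groove spinal-groove depth (mm) at the dorsal midline.
#' @slot grooveSigma groove width (radians).
#' @slot backP superellipse exponent of the dorsal half (2 = elliptic,
#'   larger = flatter back).
#' @slot nLevels,nAround mesh resolution of the core trunk span.
#' @slot pose "EOS", "A-pose" or "Adam".
#' @slot flex forward-flexion angle for the Adam pose (degrees).
#' @slot seed integer seed tag (the generator itself is deterministic).
#' @export
setClass("TorsoSpec", representation(
  H = "numeric", aCtrl = "numeric", bCtrl = "numeric",
  bow = "numeric", rot = "numeric",
  hump = "numeric", humpPhi = "numeric", humpSigma = "numeric",
  para = "numeric", paraPhi = "numeric", paraSigma = "numeric",
  groove = "numeric", grooveSigma = "numeric", backP = "numeric",
  nLevels = "integer", nAround = "integer",
  pose = "character", flex = "numeric", seed = "integer"
))

setValidity("TorsoSpec", function(object) {
  if (object@H <= 0) return("H must be positive")
  if (any(object@aCtrl <= 10) || any(object@bCtrl <= 10))
    return("semi-axes must exceed 10 mm everywhere")
  if (object@nLevels < 16L) return("nLevels >= 16 required")
  if (object@nAround < 32L) return("nAround >= 32 required")
  if (abs(object@bow) >= min(object@aCtrl))
    return("bow amplitude too large for the semi-axis profile (self-intersection)")
  if (!object@pose %in% c("EOS", "A-pose", "Adam")) return("unknown pose")
  TRUE
})

setMethod("show", "TorsoSpec", function(object) {
  cat(sprintf("TorsoSpec: H = %.0f mm, bow %.1f mm, rotation %.1f deg, hump %.1f mm, %d x %d grid, %s pose\n",
              object@H, object@bow, object@rot, object@hump,
              object@nLevels, object@nAround, object@pose))
})

#' Construct a TorsoSpec
#'
#' Defaults describe an adolescent trunk: height 470 mm PSIS to C7, lateral
#' semi-axis 150 mm at the pelvis narrowing to 120 mm at the shoulders,
#' anteroposterior semi-axis around 105 mm, 6 mm paraspinal prominences.
#'
#' @param H trunk height (mm).
#' @param aCtrl,bCtrl semi-axis spline control values (mm), uniform knots.
#' @param bow lateral bow amplitude A (mm).
#' @param rot axial rotation amplitude Theta (degrees).
#' @param hump one-sided dorsal hump amplitude (mm); positive humps the left.
#' @param humpPhi,humpSigma hump centre/width in radians from dorsal midline.
#' @param para,paraPhi,paraSigma paraspinal prominence amplitude (mm),
#'   centre and width (radians).
#' @param groove,grooveSigma spinal-groove depth (mm) and width (radians)
#'   at the dorsal midline.
#' @param backP dorsal superellipse exponent; 2 gives a pure ellipse, the
#'   default 4 a flattened back as on real torsos.
#' @param nLevels,nAround mesh resolution over the core trunk span.
#' @param pose pose tag; "Adam" applies a forward flexion.
#' @param flex Adam forward-flexion angle (degrees).
#' @param seed integer tag carried on the spec.
#' @return a \linkS4class{TorsoSpec}.
#' @export
torsoSpec <- function(H = 470,
                      aCtrl = c(152, 148, 140, 138, 142, 138, 128, 120),
                      bCtrl = c(108, 105, 100, 98, 100, 102, 98, 92),
                      bow = 0, rot = 0,
                      hump = 0, humpPhi = pi / 4, humpSigma = pi / 8,
                      para = 6, paraPhi = 40 * pi / 180, paraSigma = 18 * pi / 180,
                      groove = 5, grooveSigma = 8 * pi / 180, backP = 4,
                      nLevels = 48L, nAround = 96L,
                      pose = "EOS", flex = 75, seed = 1L) {
  new("TorsoSpec", H = H, aCtrl = aCtrl, bCtrl = bCtrl, bow = bow, rot = rot,
      hump = hump, humpPhi = humpPhi, humpSigma = humpSigma,
      para = para, paraPhi = paraPhi, paraSigma = paraSigma,
      groove = groove, grooveSigma = grooveSigma, backP = backP,
      nLevels = as.integer(nLevels), nAround = as.integer(nAround),
      pose = pose, flex = flex, seed = as.integer(seed))
}

T_MARGIN <- 0.05   # flesh margin below PSIS / above C7, in t units
N_MARGIN <- 3L     # level rings in each margin

torsoLevels <- function(nCore) {
  c(seq(-T_MARGIN, 0, length.out = N_MARGIN + 1L)[-(N_MARGIN + 1L)],
    seq(0, 1, length.out = nCore),
    seq(1, 1 + T_MARGIN, length.out = N_MARGIN + 1L)[-1L])
}

clamp01 <- function(t) pmin(1, pmax(0, t))

## semi-axis profile evaluators (natural cubic spline over the meshed span)
axisFun <- function(ctrl) {
  kn <- seq(-T_MARGIN, 1 + T_MARGIN, length.out = length(ctrl))
  stats::splinefun(kn, ctrl, method = "natural")
}

## section boundary in the horizontal plane at level t, for azimuths phi
## (radians from the dorsal midline, increasing toward the patient's left).
## Returns k x 2 matrix (x = lateral toward left, y = anterior).
sectionBoundary <- function(spec, t, phi) {
  aF <- axisFun(spec@aCtrl); bF <- axisFun(spec@bCtrl)
  a <- aF(t); b <- bF(t)
  phi <- wrapPi(phi)
  x <- a * sin(phi)
  dorsal <- abs(phi) < pi / 2
  y <- numeric(length(phi))
  ## dorsal half: superellipse |x/a|^p + |y/b|^p = 1 (flat back for p > 2)
  s <- abs(sin(phi[dorsal]))
  y[dorsal] <- -b * (1 - s^spec@backP)^(1 / spec@backP)
  y[!dorsal] <- -b * cos(phi[!dorsal])
  r <- sqrt(x^2 + y^2)
  bump <- spec@para * (exp(-(wrapPi(phi - spec@paraPhi))^2 / (2 * spec@paraSigma^2)) +
                         exp(-(wrapPi(phi + spec@paraPhi))^2 / (2 * spec@paraSigma^2)))
  bump <- bump - spec@groove * exp(-phi^2 / (2 * spec@grooveSigma^2))
  if (spec@hump != 0) {
    w <- sin(pi * clamp01(t))
    bump <- bump + spec@hump * w *
      exp(-(wrapPi(phi - spec@humpPhi))^2 / (2 * spec@humpSigma^2))
  }
  scale <- 1 + bump / r
  x <- x * scale; y <- y * scale
  th <- spec@rot * pi / 180 * sin(pi * clamp01(t))
  cbind(x * cos(th) + y * sin(th) + spec@bow * sin(pi * clamp01(t)),
        -x * sin(th) + y * cos(th))
}

wrapPi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y
}

## Adam forward flexion: rotate (y, z) about the lateral axis through the
## PSIS level so the trunk top moves anteriorly; beta grows smoothly with t.
flexPoint <- function(p, t, flexDeg) {
  beta <- flexDeg * pi / 180 * clamp01(t)^1.5
  cbind(p[, 1],
        p[, 2] * cos(beta) + p[, 3] * sin(beta),
        -p[, 2] * sin(beta) + p[, 3] * cos(beta))
}

landmarkGridSpec <- function(nAround) {
  jOff <- round(asin(0.3) / (2 * pi) * nAround)
  jHalf <- nAround %/% 2L
  list(
    PSIS_L = c(t = 0,    j = jOff),
    PSIS_R = c(t = 0,    j = nAround - jOff),
    ASIS_L = c(t = 0,    j = jHalf - jOff),
    ASIS_R = c(t = 0,    j = jHalf + jOff),
    SP_L2  = c(t = 0.25, j = 0),
    SP_T8  = c(t = 0.55, j = 0),
    SP_C7  = c(t = 1,    j = 0),
    XP     = c(t = 0.70, j = jHalf),
    JN     = c(t = 0.95, j = jHalf)
  )
}

#' Generate a watertight parametric scoliotic torso
#'
#' Builds the stacked-section surface described by a \linkS4class{TorsoSpec},
#' closes it with end caps, places the nine anatomical landmarks analytically
#' on grid vertices, and returns analytic/quadrature ground truth for the
#' shape parameters.
#'
#' @param spec a \linkS4class{TorsoSpec}.
#' @return list with elements \code{mesh} (\linkS4class{TriMesh}),
#'   \code{landmarks} (\linkS4class{LandmarkSet}), \code{truth} (list: see
#'   Details) and \code{spec}.
#' @details \code{truth} contains \code{xsa(t)} (enclosed section area, mm^2,
#'   by dense-boundary quadrature), \code{centroidU(t)} (lateral section
#'   centroid, mm), \code{theta(t)} (axial rotation, degrees),
#'   \code{sliceVolume(t1, t2)} (quadrature volume, L),
#'   \code{obliqueXsa(plane)} and \code{obliqueVolume(planeLo, planeHi)}
#'   (quadrature oracles for oblique anatomy-frame planes, mm^2 / L; upright
#'   poses only), \code{midline(t)} (dorsal midline points) and
#'   \code{spineLength} (cm, PSIS centroid to C7 along the dorsal midline).
#' @export
generateTorso <- function(spec) {
  validObject(spec)
  tgrid <- torsoLevels(spec@nLevels)
  nL <- length(tgrid); nA <- spec@nAround
  phi <- 2 * pi * (0:(nA - 1L)) / nA

  V <- matrix(0, nL * nA + 2L, 3)
  for (i in seq_len(nL)) {
    t <- tgrid[i]
    xy <- sectionBoundary(spec, t, phi)
    V[(i - 1L) * nA + seq_len(nA), ] <- cbind(xy, t * spec@H)
  }
  vb <- nL * nA + 1L; vt <- nL * nA + 2L
  V[vb, ] <- c(colMeans(V[seq_len(nA), 1:2, drop = FALSE]), tgrid[1] * spec@H)
  V[vt, ] <- c(colMeans(V[(nL - 1L) * nA + seq_len(nA), 1:2, drop = FALSE]),
               tgrid[nL] * spec@H)

  idx <- function(i, j) (i - 1L) * nA + (j %% nA) + 1L
  F <- matrix(0L, 2L * (nL - 1L) * nA + 2L * nA, 3)
  r <- 0L
  for (i in seq_len(nL - 1L)) {
    for (j in 0:(nA - 1L)) {
      F[r + 1L, ] <- c(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L))
      F[r + 2L, ] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j))
      r <- r + 2L
    }
  }
  for (j in 0:(nA - 1L)) {
    F[r + 1L, ] <- c(vb, idx(1L, j + 1L), idx(1L, j)); r <- r + 1L
  }
  for (j in 0:(nA - 1L)) {
    F[r + 1L, ] <- c(vt, idx(nL, j), idx(nL, j + 1L)); r <- r + 1L
  }

  ## landmarks on grid vertices
  lgs <- landmarkGridSpec(nA)
  lmIdx <- vapply(lgs, function(g) {
    i <- which.min(abs(tgrid - g["t"]))
    idx(i, as.integer(g["j"]))
  }, integer(1))

  if (spec@pose == "Adam")
    V <- flexPoint(V, V[, 3] / spec@H, spec@flex)

  mesh <- TriMesh(V, F)
  lmCoords <- V[lmIdx, , drop = FALSE]
  rownames(lmCoords) <- names(lmIdx)
  lm <- LandmarkSet(lmCoords)

  truth <- makeGroundTruth(spec)
  list(mesh = mesh, landmarks = lm, landmarkIndex = lmIdx,
       truth = truth, spec = spec)
}

## dense-boundary quadrature ground truth
makeGroundTruth <- function(spec, nPhi = 4096L) {
  phi <- 2 * pi * (0:(nPhi - 1L)) / nPhi
  aF <- axisFun(spec@aCtrl); bF <- axisFun(spec@bCtrl)
  xsa <- function(t) vapply(t, function(ti)
    shoelace(fixCCW(sectionBoundary(spec, ti, phi))), numeric(1))
  centroidU <- function(t) vapply(t, function(ti)
    polygonCentroid(fixCCW(sectionBoundary(spec, ti, phi)))[1], numeric(1))
  theta <- function(t) spec@rot * sin(pi * clamp01(t))
  sliceVolume <- function(t1, t2, n = 401L) {
    ts <- seq(t1, t2, length.out = n)
    A <- xsa(ts)
    ## trapezoid over z = t H
    sum((A[-1] + A[-n]) / 2 * diff(ts)) * spec@H / 1e6
  }
  midline <- function(t) {
    xy <- do.call(rbind, lapply(t, function(ti) sectionBoundary(spec, ti, 0)))
    p <- cbind(xy, t * spec@H)
    if (spec@pose == "Adam") p <- flexPoint(p, t, spec@flex)
    p
  }
  ## spine length truth: PSIS centroid then dense dorsal midline
  lgs <- landmarkGridSpec(spec@nAround)
  psis <- do.call(rbind, lapply(c("PSIS_L", "PSIS_R"), function(nm) {
    g <- lgs[[nm]]
    phj <- 2 * pi * (g["j"] %% spec@nAround) / spec@nAround
    p <- cbind(sectionBoundary(spec, g["t"], phj), g["t"] * spec@H)
    if (spec@pose == "Adam") p <- flexPoint(p, g["t"], spec@flex)
    p
  }))
  ## quadrature oracles for oblique (anatomy-frame) measurement planes;
  ## valid for upright poses (no flexion applied)
  tFull <- seq(-T_MARGIN, 1 + T_MARGIN, length.out = 2001L)
  obliqueXsa <- function(plane, nPhi2 = 2048L) {
    ph <- 2 * pi * (0:(nPhi2 - 1L)) / nPhi2
    ## boundary position along the plane normal, sampled on a fine t grid
    g <- vapply(tFull, function(ti) {
      xy <- sectionBoundary(spec, ti, ph)
      (xy[, 1] - plane@point[1]) * plane@normal[1] +
        (xy[, 2] - plane@point[2]) * plane@normal[2] +
        (ti * spec@H - plane@point[3]) * plane@normal[3]
    }, numeric(nPhi2))                       # nPhi2 x length(tFull)
    ## per azimuth, the t where the boundary crosses the plane
    tc <- vapply(seq_len(nPhi2), function(j) {
      gj <- g[j, ]
      i <- which(gj[-1] * gj[-length(gj)] <= 0)[1]
      if (is.na(i)) return(NA_real_)
      t0 <- tFull[i]; t1 <- tFull[i + 1L]
      t0 + (t1 - t0) * gj[i] / (gj[i] - gj[i + 1L])
    }, numeric(1))
    if (any(is.na(tc))) stop("plane leaves the meshed trunk span")
    P <- do.call(rbind, lapply(seq_len(nPhi2), function(j) {
      xy <- sectionBoundary(spec, tc[j], ph[j])
      c(xy[1], xy[2], tc[j] * spec@H)
    }))
    n <- plane@normal
    aAx <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- aAx - sum(aAx * n) * n; u <- u / sqrt(sum(u^2))
    v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
           n[1] * u[2] - n[2] * u[1])
    rel <- P - matrix(plane@point, nrow(P), 3, byrow = TRUE)
    abs(shoelace(cbind(rel %*% u, rel %*% v)))
  }
  obliqueVolume <- function(planeLo, planeHi, nz = 1601L, nPhi2 = 1024L) {
    ph <- 2 * pi * (0:(nPhi2 - 1L)) / nPhi2
    tz <- seq(-T_MARGIN, 1 + T_MARGIN, length.out = nz)
    areas <- vapply(tz, function(ti) {
      P <- cbind(sectionBoundary(spec, ti, ph), ti * spec@H)
      P <- clipPolyHalfspace(P, planeLo, keepBelow = FALSE)
      if (nrow(P) < 3) return(0)
      P <- clipPolyHalfspace(P, planeHi, keepBelow = TRUE)
      if (nrow(P) < 3) return(0)
      abs(shoelace(P[, 1:2, drop = FALSE]))
    }, numeric(1))
    sum((areas[-1] + areas[-nz]) / 2 * diff(tz)) * spec@H / 1e6
  }
  tden <- seq(0, 1, length.out = 2001L)
  ml <- midline(tden)
  spineLength <- polylineArclength(rbind(colMeans(psis), ml))
  ## landmark levels as snapped to the mesh grid
  tgrid <- torsoLevels(spec@nLevels)
  landmarkT <- vapply(lgs, function(g)
    tgrid[which.min(abs(tgrid - g["t"]))], numeric(1))
  list(xsa = xsa, centroidU = centroidU, theta = theta,
       sliceVolume = sliceVolume, obliqueXsa = obliqueXsa,
       obliqueVolume = obliqueVolume, midline = midline,
       spineLength = spineLength, landmarkT = landmarkT,
       aFun = aF, bFun = bF)
}

fixCCW <- function(p) if (shoelace(p) < 0) p[nrow(p):1, , drop = FALSE] else p

#' Build the symmetric torso template atlas
#'
#' The template is the zero-deformation torso of \code{\link{generateTorso}}:
#' mirror symmetry, landmark vertex indices, the dorsal midline chain and
#' anatomical face labels are exact by construction.
#'
#' @param nLevels,nAround template grid resolution (core trunk span).
#' @param spec optional \linkS4class{TorsoSpec} overriding the default
#'   symmetric shape (bow, rotation and hump are forced to zero).
#' @return a \linkS4class{TemplateAtlas}.
#' @export
templateAtlas <- function(nLevels = 48L, nAround = 96L, spec = NULL) {
  if (is.null(spec))
    spec <- torsoSpec(nLevels = nLevels, nAround = nAround)
  spec@bow <- 0; spec@rot <- 0; spec@hump <- 0; spec@pose <- "EOS"
  gt <- generateTorso(spec)
  tgrid <- torsoLevels(spec@nLevels)
  nL <- length(tgrid); nA <- spec@nAround
  nV <- nL * nA + 2L

  sym <- integer(nV)
  for (i in seq_len(nL)) for (j in 0:(nA - 1L))
    sym[(i - 1L) * nA + j + 1L] <- (i - 1L) * nA + ((nA - j) %% nA) + 1L
  sym[nL * nA + 1L] <- nL * nA + 1L
  sym[nL * nA + 2L] <- nL * nA + 2L

  midChain <- integer(0)
  for (i in seq_len(nL))
    if (tgrid[i] >= -1e-12 && tgrid[i] <= 1 + 1e-12)
      midChain <- c(midChain, (i - 1L) * nA + 1L)

  ## face labels follow the quad construction order in generateTorso
  labs <- character(nrow(gt$mesh@faces))
  r <- 0L
  for (i in seq_len(nL - 1L)) {
    for (j in 0:(nA - 1L)) {
      phiMid <- 2 * pi * (j + 0.5) / nA
      lab <- if (phiMid < pi / 2) "dorsal_left"
      else if (phiMid < pi) "ventral_left"
      else if (phiMid < 3 * pi / 2) "ventral_right"
      else "dorsal_right"
      labs[r + 1L] <- lab; labs[r + 2L] <- lab
      r <- r + 2L
    }
  }
  labs[(r + 1L):length(labs)] <- "cap"
  new("TemplateAtlas", mesh = gt$mesh, symmetryMap = sym,
      landmarkIndex = gt$landmarkIndex, midlineChain = midChain,
      faceLabels = factor(labs, levels = c("dorsal_left", "dorsal_right",
                                           "ventral_left", "ventral_right", "cap")),
      levels = tgrid, gridDim = c(nL, nA))
}

#' Serialize / load a template atlas (PLY + JSON sidecar)
#'
#' @param atlas a \linkS4class{TemplateAtlas}.
#' @param path base path; writes \code{<path>.ply} and \code{<path>.json}.
#' @export
writeAtlas <- function(atlas, path) {
  writeMesh(atlas@mesh, paste0(path, ".ply"))
  side <- list(symmetryMap = atlas@symmetryMap,
               landmarkIndex = as.list(atlas@landmarkIndex),
               midlineChain = atlas@midlineChain,
               faceLabels = as.character(atlas@faceLabels),
               levels = atlas@levels,
               gridDim = atlas@gridDim)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(path) {
  mesh <- readMesh(paste0(path, ".ply"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("TemplateAtlas", mesh = mesh,
      symmetryMap = as.integer(side$symmetryMap),
      landmarkIndex = setNames(as.integer(unlist(side$landmarkIndex)),
                               names(side$landmarkIndex)),
      midlineChain = as.integer(side$midlineChain),
      faceLabels = factor(side$faceLabels,
                          levels = c("dorsal_left", "dorsal_right",
                                     "ventral_left", "ventral_right", "cap")),
      levels = as.numeric(side$levels),
      gridDim = as.integer(side$gridDim))
}
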