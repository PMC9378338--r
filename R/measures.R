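## The nine trunk-shape measurement families, computed from a
## RegisteredTorso in a landmark-derived body frame.
##
## Sign conventions (the clinical tables report signed values without
## defining the sign): positive BSR / trunk axis = the patient's LEFT side
## is more posterior; positive centroid deviation / Qangle = deviation
## toward the patient's left. lateralU points to the patient's left.

#' Build the anatomical body frame from landmarks
#'
#' Origin at the PSIS centroid; longitudinal axis toward C7; lateral axis
#' from the PSIS pair (pointing to the patient's left), orthogonalized
#' against the longitudinal axis; anterior axis completes the right-handed
#' triad. For the Adam pose the angular reference is the floor plane.
#'
#' @param landmarks a \linkS4class{LandmarkSet} with the nine core landmarks.
#' @param pose "EOS", "A-pose" or "Adam".
#' @param floorNormal unit floor normal (Adam pose only; default +z).
#' @return a \linkS4class{BodyFrame}.
#' @export
buildBodyFrame <- function(landmarks, pose = "EOS", floorNormal = c(0, 0, 1)) {
  pl <- landmark(landmarks, "PSIS_L")
  pr <- landmark(landmarks, "PSIS_R")
  c7 <- landmark(landmarks, "SP_C7")
  if (sqrt(sum((pl - pr)^2)) < 1e-6) stop("coincident PSIS landmarks")
  origin <- (pl + pr) / 2
  w <- normalize(c7 - origin)
  uRaw <- pl - pr                     # +u = patient left
  u <- normalize(uRaw - sum(uRaw * w) * w)
  v <- cross3(w, u)
  new("BodyFrame", origin = origin, lateralU = u, anteriorV = v,
      longitudinalW = w, c7 = c7, pose = pose,
      referenceMode = if (pose == "Adam") "floor" else "coronal",
      floorNormal = normalize(floorNormal), landmarks = landmarks)
}

#' Transverse plane at a trunk level fraction
#'
#' @param frame a \linkS4class{BodyFrame}.
#' @param t level fraction in [0, 1]: 0 = PSIS level, 1 = C7 level.
#' @return a \linkS4class{Plane} with normal along the longitudinal axis.
#' @export
levelPlane <- function(frame, t) {
  if (t < 0 || t > 1) stop("level fraction t must be in [0, 1]")
  span <- sum((frame@c7 - frame@origin) * frame@longitudinalW)
  Plane(frame@origin + t * span * frame@longitudinalW, frame@longitudinalW)
}

## In-plane basis for transverse slices: u = lateral reference (coronal
## reference for upright poses, floor line for Adam), v completes.
sliceBasis <- function(frame) {
  w <- frame@longitudinalW
  if (frame@referenceMode == "floor") {
    d <- cross3(frame@floorNormal, w)
    if (sqrt(sum(d^2)) < 1e-6)
      stop("floor reference undefined: trunk axis parallel to floor normal")
    u <- normalize(d)
    if (sum(u * frame@lateralU) < 0) u <- -u
  } else {
    u <- frame@lateralU
  }
  rbind(u, cross3(w, u))
}

## Slice the registered torso at level t; largest loop or NULL.
trunkSlice <- function(reg, frame, t, basis = sliceBasis(frame)) {
  secs <- sliceMesh(reg@mesh, levelPlane(frame, t), frameBasis = basis,
                    levelT = t)
  if (!length(secs)) return(NULL)
  if (length(secs) > 1)
    warning(sprintf("multiple loops at t = %.3f: extra loops suggest a registration failure", t))
  secs[[1]]
}

sliceProfile <- function(reg, frame, nLevels = 201L) {
  basis <- sliceBasis(frame)
  ts <- seq(0, 1, length.out = nLevels)
  lapply(ts, function(t) trunkSlice(reg, frame, t, basis))
}

#' Registered view of a generated torso
#'
#' A torso produced by \code{\link{generateTorso}} shares the template's
#' grid connectivity, so it is its own registration: this wraps it as a
#' \linkS4class{RegisteredTorso} with exact correspondence (residual 0).
#'
#' @param torso result of \code{\link{generateTorso}}.
#' @param atlas optional matching \linkS4class{TemplateAtlas}; built at the
#'   spec's resolution when omitted.
#' @return a \linkS4class{RegisteredTorso}.
#' @export
asRegisteredTorso <- function(torso, atlas = NULL) {
  if (is.null(atlas))
    atlas <- templateAtlas(nLevels = torso$spec@nLevels,
                           nAround = torso$spec@nAround)
  new("RegisteredTorso", mesh = torso$mesh, atlas = atlas, residualRMS = 0)
}

#' Spine length
#'
#' Arclength of the dorsal midline from the PSIS centroid to C7, along the
#' registered midline chain.
#'
#' @param reg a \linkS4class{RegisteredTorso}.
#' @return length in cm.
#' @export
spineLength <- function(reg) {
  v <- reg@mesh@vertices
  chain <- v[reg@atlas@midlineChain, , drop = FALSE]
  li <- reg@atlas@landmarkIndex
  psisC <- (v[li["PSIS_L"], ] + v[li["PSIS_R"], ]) / 2
  polylineArclength(rbind(psisC, chain))
}

#' Back surface area
#'
#' Area of the dorsal torso surface bounded cranially by the C7 level and
#' caudally by the PSIS level, as the sum of the left and right dorsal
#' halves (each reported separately as well).
#'
#' @param reg a \linkS4class{RegisteredTorso}.
#' @param frame a \linkS4class{BodyFrame}.
#' @return list with \code{total}, \code{left}, \code{right} in dm^2.
#' @export
backArea <- function(reg, frame) {
  pl <- levelPlane(frame, 0)
  ph <- levelPlane(frame, 1)
  labs <- reg@atlas@faceLabels
  left <- regionSurfaceArea(reg@mesh, which(labs == "dorsal_left"), pl, ph)
  right <- regionSurfaceArea(reg@mesh, which(labs == "dorsal_right"), pl, ph)
  list(total = left + right, left = left, right = right)
}

landmarkForLevel <- c(L2 = "SP_L2", T8 = "SP_T8", JN = "JN")

#' Cross-sectional area at a named landmark level
#'
#' Enclosed area of the transverse slice through the named landmark (L2, T8
#' or JN); the largest loop is the torso outline.
#'
#' @inheritParams backArea
#' @param at one of "L2", "T8", "JN".
#' @return area in dm^2.
#' @export
crossSectionArea <- function(reg, frame, at = c("L2", "T8", "JN")) {
  at <- match.arg(at)
  p <- landmark(frame@landmarks, landmarkForLevel[[at]])
  t <- levelFractionOf(frame, p)
  sec <- trunkSlice(reg, frame, clampLevel(t))
  if (is.null(sec)) stop("empty slice at ", at, " level")
  a <- polygonArea(sec) / 1e4
  if (a < 1) warning("cross-section below 1 dm^2 at ", at,
                     ": possible registration failure")
  a
}

levelFractionOf <- function(frame, point) {
  span <- sum((frame@c7 - frame@origin) * frame@longitudinalW)
  sum((point - frame@origin) * frame@longitudinalW) / span
}

clampLevel <- function(t) pmin(1, pmax(0, t))

#' Torso section volumes between landmark levels
#'
#' Volumes of the torso bounded by transverse planes through (1) L2 and T8,
#' (2) XP and JN, (3) the PSIS centroid and JN.
#'
#' @inheritParams backArea
#' @return named numeric vector (L): \code{L2_T8}, \code{XP_JN}, \code{PSIS_JN}.
#' @export
sectionVolumes <- function(reg, frame) {
  lm <- frame@landmarks
  pairs <- list(L2_T8 = c("SP_L2", "SP_T8"),
                XP_JN = c("XP", "JN"),
                PSIS_JN = c(NA, "JN"))
  out <- numeric(0)
  for (nm in names(pairs)) {
    pr <- pairs[[nm]]
    lo3 <- if (is.na(pr[1])) frame@origin else landmark(lm, pr[1])
    hi3 <- landmark(lm, pr[2])
    tLo <- levelFractionOf(frame, lo3)
    tHi <- levelFractionOf(frame, hi3)
    if (tLo >= tHi)
      stop("inverted landmark order for pair ", nm)
    w <- frame@longitudinalW
    vol <- sectionVolume(reg@mesh, Plane(projOnAxis(frame, tLo), w),
                         Plane(projOnAxis(frame, tHi), w))
    out[nm] <- vol
  }
  out
}

projOnAxis <- function(frame, t) {
  span <- sum((frame@c7 - frame@origin) * frame@longitudinalW)
  frame@origin + t * span * frame@longitudinalW
}

## posterior supporting line of a 2D cross-section: the convex-hull edge on
## the posterior side that spans the lateral position of the section
## centroid (the scoliometer resting across both paraspinal prominences).
posteriorSupportLine <- function(poly) {
  cen <- polygonCentroid(poly)
  h <- grDevices::chull(poly)
  H <- poly[h, , drop = FALSE]
  if (shoelace(H) < 0) H <- H[nrow(H):1, , drop = FALSE]  # make CCW
  k <- nrow(H)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    p <- H[i, ]; q <- H[j, ]
    e <- q - p
    outward <- c(e[2], -e[1])  # outward normal of a CCW hull
    if (outward[2] >= 0) next  # not posterior-facing
    if ((p[1] - cen[1]) * (q[1] - cen[1]) <= 0 && abs(e[1]) > 1e-9)
      return(list(p = p, q = q))
  }
  stop("degenerate dorsal arc: no posterior supporting line")
}

#' Back surface rotation (angle of trunk rotation) at a level
#'
#' The signed angle between the posterior supporting line of the transverse
#' cross-section (the line a scoliometer would rest on, spanning both
#' paraspinal prominences) and the coronal reference (floor line for the
#' Adam pose). Positive when the patient's left side is more posterior.
#'
#' @inheritParams backArea
#' @param t level fraction in [0, 1].
#' @param section optional precomputed \linkS4class{CrossSection} at t.
#' @return signed angle in degrees.
#' @export
bsrAt <- function(reg, frame, t, section = NULL) {
  sec <- if (is.null(section)) trunkSlice(reg, frame, t) else section
  if (is.null(sec)) stop("empty slice at t = ", t)
  sl <- posteriorSupportLine(sec@polygon)
  e <- unname(sl$q - sl$p)
  if (e[1] < 0) e <- -e
  -atan2(e[2], e[1]) * 180 / pi
}

#' BSR profile along the trunk and its extremum
#'
#' Samples \code{\link{bsrAt}} at uniform levels over the PSIS-to-C7 span
#' and reports the signed value of maximal magnitude plus the values at
#' 25\%, 50\% and 75\%.
#'
#' @inheritParams backArea
#' @param nLevels number of uniform levels (odd; default 201).
#' @param sections optional precomputed slice list from the same levels.
#' @return list with \code{levels}, \code{angles}, \code{bsrMax},
#'   \code{bsr25}, \code{bsr50}, \code{bsr75}.
#' @export
bsrProfile <- function(reg, frame, nLevels = 201L, sections = NULL) {
  if (is.null(sections)) sections <- sliceProfile(reg, frame, nLevels)
  ts <- seq(0, 1, length.out = nLevels)
  ang <- vapply(seq_along(ts), function(i) {
    if (is.null(sections[[i]])) return(NA_real_)
    tryCatch(bsrAt(reg, frame, ts[i], section = sections[[i]]),
             error = function(e) NA_real_)
  }, numeric(1))
  sel <- function(tt) ang[which.min(abs(ts - tt))]
  iMax <- which.max(abs(ang))
  list(levels = ts, angles = ang, bsrMax = ang[iMax],
       bsr25 = sel(0.25), bsr50 = sel(0.5), bsr75 = sel(0.75))
}

#' Maximal lateral centroid deviation
#'
#' Lateral (coronal-plane) deviation of the slice centroid relative to the
#' PSIS-level slice centroid, sampled along the trunk; the signed value of
#' maximal magnitude is returned. Positive = toward the patient's left.
#'
#' @inheritParams bsrProfile
#' @return signed deviation in mm.
#' @export
centroidDeviation <- function(reg, frame, nLevels = 201L, sections = NULL) {
  if (is.null(sections)) sections <- sliceProfile(reg, frame, nLevels)
  cen <- vapply(sections, function(s)
    if (is.null(s)) NA_real_ else polygonCentroid(s@polygon)[1], numeric(1))
  if (is.na(cen[1])) stop("empty PSIS-level slice")
  dev <- cen - cen[1]
  dev[which.max(abs(dev))]
}

#' Maximal trunk axial rotation
#'
#' Angle of the principal axis of transverse slices relative to the coronal
#' reference, sampled along the trunk; the signed value of maximal magnitude
#' is returned. Positive when the patient's left side is more posterior.
#' Near-isotropic levels (undefined axis) are skipped.
#'
#' @inheritParams bsrProfile
#' @return signed angle in degrees.
#' @export
trunkAxis <- function(reg, frame, nLevels = 201L, sections = NULL) {
  if (is.null(sections)) sections <- sliceProfile(reg, frame, nLevels)
  ang <- vapply(sections, function(s) {
    if (is.null(s)) return(NA_real_)
    tryCatch(-polygonPrincipalAxis(s), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(ang))) stop("axis undefined at every level (isotropic sections)")
  ang[which.max(abs(ang))]
}

#' Back symmetry line
#'
#' The registered dorsal midline (the fixed points of the atlas symmetry
#' map), resampled to a fixed number of points uniformly in the level
#' fraction t.
#'
#' @param reg a \linkS4class{RegisteredTorso}.
#' @param nPoints number of output points (default 201).
#' @return nPoints x 3 matrix (mm).
#' @export
symmetryLine <- function(reg, nPoints = 201L) {
  chain <- reg@mesh@vertices[reg@atlas@midlineChain, , drop = FALSE]
  ## midline chain vertices are the first vertex of each ring: recover level t
  nA <- reg@atlas@gridDim[2]
  ringIdx <- (reg@atlas@midlineChain - 1L) %/% nA + 1L
  tc <- reg@atlas@levels[ringIdx]
  tt <- seq(0, 1, length.out = nPoints)
  out <- vapply(1:3, function(d)
    stats::approx(tc, chain[, d], xout = tt)$y, numeric(nPoints))
  out
}

#' Fourth-order harmonic fit of the symmetry line's lateral deviation
#'
#' Least-squares fit of the lateral (u) deviation x(t) of an ordered trunk
#' polyline to the order-4 harmonic basis on t in [0, 1].
#'
#' @param line k x 3 matrix of ordered points (k >= 9), uniformly spaced in t.
#' @param frame a \linkS4class{BodyFrame} supplying origin and lateral axis.
#' @return a \linkS4class{HarmonicFit}.
#' @export
fitHarmonic <- function(line, frame) {
  line <- as.matrix(line)
  if (nrow(line) < 9) stop("need >= 9 points for an order-4 harmonic fit")
  t <- seq(0, 1, length.out = nrow(line))
  x <- as.numeric((line - matrix(frame@origin, nrow(line), 3, byrow = TRUE)) %*%
                    frame@lateralU)
  X <- cbind(1, do.call(cbind, lapply(1:4, function(k)
    cbind(cos(2 * pi * k * t), sin(2 * pi * k * t)))))
  cf <- qr.coef(qr(X), x)
  resid <- x - X %*% cf
  new("HarmonicFit", a0 = cf[1], a = cf[c(2, 4, 6, 8)], b = cf[c(3, 5, 7, 9)],
      residRMS = sqrt(mean(resid^2)))
}

#' Qangle: topographic analogue of the Cobb angle
#'
#' From the harmonic fit of the back symmetry line, locates the apex (the
#' interior extremum of |x(t)| of largest magnitude) and the nearest slope
#' extrema flanking it (the analogue of the maximally tilted endplates);
#' Qangle is the difference of the end-tangent inclinations
#' atan(x'(t)/L), signed by the curve direction at the apex (positive =
#' apex toward the patient's left).
#'
#' @param fit a \linkS4class{HarmonicFit}.
#' @param trunkLength physical trunk length L (mm) scaling t to arclength.
#' @return signed angle in degrees; 0 with attribute \code{flag = "no curve"}
#'   when the curve is monotone with no interior apex.
#' @export
qangle <- function(fit, trunkLength) {
  if (trunkLength <= 0) stop("trunkLength must be positive")
  tg <- seq(0, 1, length.out = 2001L)
  ## lateral deviation relative to the straight chord through the endpoints
  x <- evalHarmonic(fit, tg)
  chordSlope <- x[length(x)] - x[1]
  x <- x - (x[1] + chordSlope * tg)
  s <- (evalHarmonicDeriv(fit, tg) - chordSlope) / trunkLength
  ## interior local extrema of |x|
  ax <- abs(x)
  locmax <- which(diff(sign(diff(ax))) < 0) + 1L
  locmax <- locmax[ax[locmax] > 1e-9]
  if (!length(locmax)) {
    out <- 0
    attr(out, "flag") <- "no curve"
    return(out)
  }
  apex <- locmax[which.max(ax[locmax])]
  ## slope extrema (candidate end tangents), endpoints included
  sext <- c(1L, which(diff(sign(diff(s))) != 0) + 1L, length(tg))
  below <- sext[sext < apex]
  above <- sext[sext > apex]
  if (!length(below) || !length(above)) {
    out <- 0
    attr(out, "flag") <- "no curve"
    return(out)
  }
  sBelow <- s[max(below)]
  sAbove <- s[min(above)]
  mag <- abs(atan(sAbove) - atan(sBelow)) * 180 / pi
  sign(x[apex]) * mag
}

#' Compute the full measurement suite for one registered torso
#'
#' Runs all measurements applicable to the pose. In the Adam (forward bend)
#' pose only spine length, back area and the BSR family are computed; the
#' standing-only measures are reported as NA and listed as suppressed.
#'
#' @param reg a \linkS4class{RegisteredTorso}.
#' @param landmarks optional \linkS4class{LandmarkSet}; transferred from the
#'   atlas correspondence when omitted.
#' @param pose "EOS", "A-pose" or "Adam".
#' @param floorNormal floor normal for the Adam pose.
#' @param nProfile number of profile levels (default 201).
#' @return a \linkS4class{MeasurementSuite}.
#' @export
measureAll <- function(reg, landmarks = NULL, pose = "EOS",
                       floorNormal = c(0, 0, 1), nProfile = 201L) {
  if (is.null(landmarks)) landmarks <- transferLandmarks(reg)
  frame <- buildBodyFrame(landmarks, pose = pose, floorNormal = floorNormal)
  vals <- setNames(rep(NA_real_, length(MEASURE_NAMES)), MEASURE_NAMES)
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, ": ", conditionMessage(e), call. = FALSE))
  }
  vals["spine_length_cm"] <- wrap("spine_length", spineLength(reg))
  ba <- wrap("back_area", backArea(reg, frame))
  vals["back_area_dm2"] <- ba$total
  vals["back_area_left_dm2"] <- ba$left
  vals["back_area_right_dm2"] <- ba$right
  sections <- sliceProfile(reg, frame, nProfile)
  bp <- wrap("bsr", bsrProfile(reg, frame, nProfile, sections = sections))
  vals["bsr_25_deg"] <- bp$bsr25
  vals["bsr_50_deg"] <- bp$bsr50
  vals["bsr_75_deg"] <- bp$bsr75
  vals["bsr_max_deg"] <- bp$bsrMax

  suppressed <- character(0)
  if (pose == "Adam") {
    suppressed <- setdiff(MEASURE_NAMES,
                          c("spine_length_cm", "back_area_dm2",
                            "back_area_left_dm2", "back_area_right_dm2",
                            "bsr_25_deg", "bsr_50_deg", "bsr_75_deg",
                            "bsr_max_deg"))
  } else {
    vals["xsa_L2_dm2"] <- wrap("xsa_L2", crossSectionArea(reg, frame, "L2"))
    vals["xsa_T8_dm2"] <- wrap("xsa_T8", crossSectionArea(reg, frame, "T8"))
    vals["xsa_JN_dm2"] <- wrap("xsa_JN", crossSectionArea(reg, frame, "JN"))
    xv <- wrap("xsv", sectionVolumes(reg, frame))
    vals["xsv_L2_T8_L"] <- xv["L2_T8"]
    vals["xsv_XP_JN_L"] <- xv["XP_JN"]
    vals["xsv_PSIS_JN_L"] <- xv["PSIS_JN"]
    vals["centroid_dev_mm"] <- wrap("centroid",
                                    centroidDeviation(reg, frame, nProfile, sections = sections))
    vals["axis_max_deg"] <- wrap("axis",
                                 trunkAxis(reg, frame, nProfile, sections = sections))
    line <- wrap("symmetry_line", symmetryLine(reg, nProfile))
    fit <- wrap("harmonic_fit", fitHarmonic(line, frame))
    span <- sum((frame@c7 - frame@origin) * frame@longitudinalW)
    q <- wrap("qangle", qangle(fit, span))
    vals["qangle_deg"] <- as.numeric(q)
  }
  new("MeasurementSuite", values = vals, pose = pose, suppressed = suppressed)
}

#' Serialize a measurement suite
#'
#' @param suite a \linkS4class{MeasurementSuite}.
#' @param path output path (.json or .csv).
#' @param meta named list of extra columns (subject, rater, trial, ...).
#' @export
writeSuite <- function(suite, path, meta = list()) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- c(meta, list(pose = suite@pose), as.list(suite@values))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else if (ext == "csv") {
    df <- data.frame(parameter = names(suite@values), value = unname(suite@values),
                     pose = suite@pose)
    for (nm in names(meta)) df[[nm]] <- meta[[nm]]
    write.csv(df, path, row.names = FALSE)
  } else stop("unsupported suite format: .", ext)
  invisible(path)
}
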