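## measurement tests run on generator torsos wrapped through the exact atlas
## correspondence, against the generator's quadrature ground truth

measuredTorso <- function(...) {
  spec <- torsoSpec(nLevels = 32L, nAround = 96L, ...)
  tor <- generateTorso(spec)
  key <- paste0("mt", spec@nLevels, "x", spec@nAround)
  if (!exists(key, envir = .fixtureCache))
    assign(key, templateAtlas(spec@nLevels, spec@nAround), envir = .fixtureCache)
  list(tor = tor, reg = asRegisteredTorso(tor, get(key, envir = .fixtureCache)))
}

test_that("body frame axes recover the generator's anatomy", {
  mt <- measuredTorso()
  fr <- buildBodyFrame(mt$tor$landmarks)
  ## no lateral tilt on a symmetric torso; the sagittal tilt of the
  ## PSIS-to-C7 axis relative to vertical is small but anatomically nonzero
  expect_lt(abs(fr@longitudinalW[1]), sin(0.5 * pi / 180))
  expect_lt(acos(min(1, sum(fr@longitudinalW * c(0, 0, 1)))) * 180 / pi, 5)
  expect_gt(sum(fr@lateralU * c(1, 0, 0)), 0.99)   # +u = patient left
  expect_gt(sum(fr@anteriorV * c(0, 1, 0)), 0.99)
  ## mirroring the landmark coordinates flips the lateral axis; the frame
  ## stays right-handed, so the anterior axis flips with it while the
  ## longitudinal axis is preserved
  C <- mt$tor$landmarks@coords; C[, 1] <- -C[, 1]
  fr2 <- buildBodyFrame(LandmarkSet(C))
  expect_lt(sum(fr2@lateralU * fr@lateralU), -0.99)
  expect_gt(sum(fr2@longitudinalW * fr@longitudinalW), 0.999)
  expect_error(buildBodyFrame(LandmarkSet(C[-1, , drop = FALSE])), "PSIS")
})

test_that("level planes interpolate the PSIS-to-C7 span", {
  mt <- measuredTorso()
  fr <- buildBodyFrame(mt$tor$landmarks)
  p0 <- levelPlane(fr, 0); p1 <- levelPlane(fr, 1); pm <- levelPlane(fr, 0.5)
  d0 <- sqrt(sum((pm@point - p0@point)^2))
  d1 <- sqrt(sum((pm@point - p1@point)^2))
  expect_equal(d0, d1, tolerance = 1e-9)
  expect_equal(sum((p0@point - fr@origin)^2), 0, tolerance = 1e-12)
  expect_error(levelPlane(fr, 1.2), "\\[0, 1\\]")
})

test_that("intrinsic measures match quadrature truth on a straight torso", {
  mt <- measuredTorso()
  tor <- mt$tor; reg <- mt$reg
  fr <- buildBodyFrame(tor$landmarks)
  expect_lt(abs(spineLength(reg) - tor$truth$spineLength), 0.5)  # cm
  ## measurement planes are transverse in the landmark frame (slightly
  ## oblique to the parametric sections): compare against the oblique
  ## quadrature oracle
  w <- fr@longitudinalW
  for (lv in c("L2", "T8", "JN")) {
    nm <- c(L2 = "SP_L2", T8 = "SP_T8", JN = "JN")[[lv]]
    a <- crossSectionArea(reg, fr, lv)
    tru <- tor$truth$obliqueXsa(Plane(landmark(tor$landmarks, nm), w)) / 1e4
    expect_lt(abs(a - tru) / tru, 0.005)
  }
  xv <- sectionVolumes(reg, fr)
  truL2T8 <- tor$truth$obliqueVolume(
    Plane(landmark(tor$landmarks, "SP_L2"), w),
    Plane(landmark(tor$landmarks, "SP_T8"), w))
  expect_lt(abs(xv[["L2_T8"]] - truL2T8) / truL2T8, 0.005)
  truPJ <- tor$truth$obliqueVolume(Plane(fr@origin, w),
                                   Plane(landmark(tor$landmarks, "JN"), w))
  expect_lt(abs(xv[["PSIS_JN"]] - truPJ) / truPJ, 0.005)
  ## containment and nested additivity
  expect_gt(xv[["PSIS_JN"]], xv[["L2_T8"]])
  w <- fr@longitudinalW
  vA <- sectionVolume(reg@mesh, levelPlane(fr, 0), levelPlane(fr, 0.4))
  vB <- sectionVolume(reg@mesh, levelPlane(fr, 0.4), levelPlane(fr, 0.95))
  vAll <- sectionVolume(reg@mesh, levelPlane(fr, 0), levelPlane(fr, 0.95))
  expect_equal(vA + vB, vAll, tolerance = 1e-9)
})

test_that("back area splits into equal halves on a symmetric torso", {
  mt <- measuredTorso()
  fr <- buildBodyFrame(mt$tor$landmarks)
  ba <- backArea(mt$reg, fr)
  expect_lt(abs(ba$left - ba$right) / ba$left, 0.005)
  expect_identical(ba$total, ba$left + ba$right)
})

test_that("BSR and trunk axis recover injected axial rotation", {
  prev <- -Inf
  for (Th in c(5, 15)) {
    mt <- measuredTorso(rot = Th)
    fr <- buildBodyFrame(mt$tor$landmarks)
    secs <- torsotopo:::sliceProfile(mt$reg, fr, 101L)
    bp <- bsrProfile(mt$reg, fr, 101L, sections = secs)
    expect_lt(abs(bp$bsrMax - Th), 1.5)
    expect_gt(bp$bsrMax, prev); prev <- bp$bsrMax
    expect_lt(abs(trunkAxis(mt$reg, fr, 101L, sections = secs) - Th), 1)
    ## profile consistency: bsr_at(0.25) equals the profile value there
    expect_identical(bp$bsr25, bp$angles[which(bp$levels == 0.25)])
    expect_lt(abs(bsrAt(mt$reg, fr, 0.25) - bp$bsr25), 1e-9)
  }
  ## symmetric torso floors
  mt0 <- measuredTorso()
  fr0 <- buildBodyFrame(mt0$tor$landmarks)
  bp0 <- bsrProfile(mt0$reg, fr0, 101L)
  expect_lt(max(abs(bp0$angles), na.rm = TRUE), 0.2)
})

test_that("centroid deviation recovers the injected lateral bow", {
  for (A in c(5, 40)) {
    mt <- measuredTorso(bow = A)
    fr <- buildBodyFrame(mt$tor$landmarks)
    expect_lt(abs(centroidDeviation(mt$reg, fr, 101L) - A), 1)
  }
  ## rigid translation leaves the deviation unchanged (reference subtracts)
  mt <- measuredTorso(bow = 20)
  V <- mt$tor$mesh@vertices + matrix(c(55, -20, 10), nrow(mt$tor$mesh@vertices),
                                     3, byrow = TRUE)
  C <- mt$tor$landmarks@coords + matrix(c(55, -20, 10), 9, 3, byrow = TRUE)
  rownames(C) <- rownames(mt$tor$landmarks@coords)
  regT <- new("RegisteredTorso", mesh = TriMesh(V, mt$tor$mesh@faces),
              atlas = mt$reg@atlas, residualRMS = 0)
  frT <- buildBodyFrame(LandmarkSet(C))
  expect_lt(abs(centroidDeviation(regT, frT, 101L) -
                  centroidDeviation(mt$reg, buildBodyFrame(mt$tor$landmarks), 101L)),
            1e-6)
})

test_that("the symmetry line tracks the dorsal midline and its bow", {
  mt <- measuredTorso(bow = 25)
  line <- symmetryLine(mt$reg, 201L)
  expect_identical(nrow(line), 201L)
  fr <- buildBodyFrame(mt$tor$landmarks)
  u <- as.numeric((line - matrix(fr@origin, 201, 3, byrow = TRUE)) %*% fr@lateralU)
  expect_lt(abs(max(u) - 25), 1)
  mt0 <- measuredTorso()
  line0 <- symmetryLine(mt0$reg, 201L)
  expect_lt(max(abs(line0[, 1])), 0.5)
})

test_that("harmonic fitting is exact on noiseless harmonic curves", {
  fr <- buildBodyFrame(generateTorso(torsoSpec(nLevels = 16L, nAround = 32L))$landmarks)
  t <- seq(0, 1, length.out = 201)
  xs <- fr@origin[1] + 4 - 7 * cos(2 * pi * t) + 3 * sin(8 * pi * t)
  line <- cbind(xs, fr@origin[2], fr@origin[3] + t * 450)
  fit <- fitHarmonic(line, fr)
  expect_equal(fit@a0, 4, tolerance = 1e-8)
  expect_equal(fit@a[1], -7, tolerance = 1e-8)
  expect_equal(fit@b[4], 3, tolerance = 1e-8)
  expect_lt(max(abs(c(fit@a[2:4], fit@b[1:3]))), 1e-8)
  expect_lt(fit@residRMS, 1e-8)
  ## constant line
  lineC <- cbind(fr@origin[1] + 2, fr@origin[2], fr@origin[3] + t * 450)
  fitC <- fitHarmonic(lineC, fr)
  expect_equal(fitC@a0, 2, tolerance = 1e-10)
  expect_lt(max(abs(c(fitC@a, fitC@b))), 1e-10)
  expect_error(fitHarmonic(line[1:5, ], fr), ">= 9")
})

test_that("Qangle matches its closed form and flips under mirroring", {
  fit <- new("HarmonicFit", a0 = 0, a = rep(0, 4), b = c(25, 0, 0, 0),
             residRMS = 0)
  q <- qangle(fit, 450)
  expect_lt(abs(as.numeric(q) - 2 * atan(2 * pi * 25 / 450) * 180 / pi), 0.2)
  fitM <- new("HarmonicFit", a0 = 0, a = rep(0, 4), b = c(-25, 0, 0, 0),
              residRMS = 0)
  expect_lt(abs(as.numeric(qangle(fitM, 450)) + as.numeric(q)), 1e-9)
  ## straight line: no curve
  fit0 <- new("HarmonicFit", a0 = 5, a = rep(0, 4), b = rep(0, 4), residRMS = 0)
  q0 <- qangle(fit0, 450)
  expect_identical(as.numeric(q0), 0)
  expect_identical(attr(q0, "flag"), "no curve")
  expect_error(qangle(fit, -1), "positive")
})

test_that("measureAll obeys the pose contract", {
  mt <- measuredTorso(rot = 6, bow = 10)
  s <- measureAll(mt$reg, landmarks = mt$tor$landmarks, nProfile = 61L)
  v <- measurementValues(s)
  expect_true(all(!is.na(v)))
  expect_true(all(v[c("spine_length_cm", "back_area_dm2", "xsa_L2_dm2",
                      "xsv_PSIS_JN_L")] > 0))
  ## Adam pose computes only spine length, back area and the BSR family
  specA <- torsoSpec(rot = 6, pose = "Adam", nLevels = 32L, nAround = 96L)
  torA <- generateTorso(specA)
  regA <- asRegisteredTorso(torA, mt$reg@atlas)
  sA <- measureAll(regA, landmarks = torA$landmarks, pose = "Adam",
                   nProfile = 61L)
  vA <- measurementValues(sA)
  na_ok <- c("xsa_L2_dm2", "xsa_T8_dm2", "xsa_JN_dm2", "xsv_L2_T8_L",
             "xsv_XP_JN_L", "xsv_PSIS_JN_L", "centroid_dev_mm",
             "axis_max_deg", "qangle_deg")
  expect_true(all(is.na(vA[na_ok])))
  expect_setequal(sA@suppressed, na_ok)
  expect_true(all(!is.na(vA[setdiff(names(vA), na_ok)])))
  ## flexed spine is longer than the upright one (same subject)
  expect_gt(vA[["spine_length_cm"]], v[["spine_length_cm"]])
  ## repeated measurement is bit-identical
  s2 <- measureAll(mt$reg, landmarks = mt$tor$landmarks, nProfile = 61L)
  expect_identical(measurementValues(s2), v)
})
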