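test_that("template atlas satisfies its structural invariants", {
  atlas <- cachedAtlas()
  s <- atlas@symmetryMap
  expect_identical(s[s], seq_along(s))
  V <- atlas@mesh@vertices
  Vm <- V; Vm[, 1] <- -Vm[, 1]
  expect_lt(max(abs(V[s, ] - Vm)), 1e-6)
  expect_identical(s[atlas@midlineChain], atlas@midlineChain)
  expect_true(isWatertight(atlas@mesh))
  expect_setequal(levels(atlas@faceLabels),
                  c("dorsal_left", "dorsal_right", "ventral_left",
                    "ventral_right", "cap"))
  ## dorsal and ventral halves have equal face counts
  tab <- table(atlas@faceLabels)
  expect_identical(unname(tab["dorsal_left"]), unname(tab["dorsal_right"]))
})

test_that("initial alignment recovers known similarity transforms", {
  atlas <- cachedAtlas()
  scan0 <- atlas@mesh
  tf0 <- initialRigidAlign(atlas, scan0)
  probe <- atlas@mesh@vertices[seq(1, nrow(atlas@mesh@vertices), by = 11), ]
  tf0r <- torsotopo:::rigidICPRefine(atlas@mesh@vertices, scan0, tf0)
  moved <- torsotopo:::applySimilarity(probe, tf0r)
  expect_lt(sqrt(mean(rowSums((moved - probe)^2))), 1e-6)

  tr <- rigidTransform(atlas@mesh@vertices)
  scan1 <- TriMesh(tr$V * 1.2, atlas@mesh@faces)
  tf1 <- torsotopo:::rigidICPRefine(atlas@mesh@vertices, scan1,
                                    initialRigidAlign(atlas, scan1))
  expect_equal(tf1$s, 1.2, tolerance = 0.01)
  truthP <- tr$V[seq(1, nrow(tr$V), by = 11), ] * 1.2
  expect_lt(sqrt(mean(rowSums((torsotopo:::applySimilarity(probe, tf1) - truthP)^2))),
            1e-3)
  expect_error(initialRigidAlign(atlas, TriMesh(matrix(0, 0, 3),
                                                matrix(0L, 0, 3))), "degenerate")
})

test_that("landmark-hint initialization equals similarity Procrustes", {
  atlas <- cachedAtlas()
  tr <- rigidTransform(atlas@mesh@vertices)
  hints <- LandmarkSet({
    C <- tr$V[atlas@landmarkIndex, ]
    rownames(C) <- names(atlas@landmarkIndex); C
  })
  tf <- initialRigidAlign(atlas, TriMesh(tr$V, atlas@mesh@faces), hints)
  expect_equal(tf$s, 1, tolerance = 1e-9)
  expect_equal(tf$R, tr$R, tolerance = 1e-9)
})

test_that("self-registration is idempotent", {
  atlas <- cachedAtlas()
  reg <- registerScan(atlas, atlas@mesh)
  expect_lt(residualRMS(reg), 1e-3)
  drift <- sqrt(rowSums((reg@mesh@vertices - atlas@mesh@vertices)^2))
  expect_lt(max(drift[atlas@landmarkIndex]), 0.1)
  expect_true(isWatertight(reg@mesh))
})

test_that("nonrigid ICP tracks a smooth low-frequency warp", {
  atlas <- cachedAtlas()
  V <- atlas@mesh@vertices
  r <- sqrt(V[, 1]^2 + V[, 2]^2); r[r < 1e-9] <- 1
  s <- 10 * sin(pi * V[, 3] / (470 * 1.1))
  W <- V + cbind(s * V[, 1] / r, s * V[, 2] / r, 0)
  reg <- registerScan(atlas, TriMesh(W, atlas@mesh@faces))
  expect_lt(residualRMS(reg), 1)
  lmErr <- sqrt(rowSums((transferLandmarks(reg)@coords -
                           W[atlas@landmarkIndex, ])^2))
  ## at this reduced test resolution the regularizer's tangential bias is
  ## a little larger than at the shipping resolution
  expect_lt(max(lmErr), 3)
})

test_that("registration tolerates holes in the scan", {
  atlas <- cachedAtlas()
  set.seed(4)
  keep <- sort(sample(nrow(atlas@mesh@faces),
                      round(0.8 * nrow(atlas@mesh@faces))))
  holey <- TriMesh(atlas@mesh@vertices, atlas@mesh@faces[keep, ])
  expect_false(isWatertight(holey))
  reg <- registerScan(atlas, holey)
  expect_lt(residualRMS(reg), 1)
  expect_true(isWatertight(reg@mesh))
})

test_that("landmark transfer follows rigid motion of the scan", {
  atlas <- cachedAtlas()
  tr <- rigidTransform(atlas@mesh@vertices)
  reg <- registerScan(atlas, TriMesh(tr$V, atlas@mesh@faces))
  lm0 <- atlas@mesh@vertices[atlas@landmarkIndex, ]
  truth <- lm0 %*% t(tr$R) + matrix(tr$shift, 9, 3, byrow = TRUE)
  err <- sqrt(rowSums((transferLandmarks(reg)@coords - truth)^2))
  expect_lt(max(err), 1e-3 * 100)  # sub-0.1 mm after refinement
})

test_that("mapToAtlasSpace inverts the registration on the surface", {
  atlas <- cachedAtlas()
  tr <- rigidTransform(atlas@mesh@vertices)
  reg <- registerScan(atlas, TriMesh(tr$V, atlas@mesh@faces))
  ## registered vertices map back to their template vertices
  pick <- seq(5, nrow(tr$V), by = 97)
  back <- mapToAtlasSpace(reg, reg@mesh@vertices[pick, ])
  expect_lt(max(sqrt(rowSums((back - atlas@mesh@vertices[pick, ])^2))), 1e-6)
  ## a triangle centroid maps to the template triangle centroid
  f1 <- reg@mesh@faces[10, ]
  cen <- colMeans(reg@mesh@vertices[f1, ])
  cenT <- colMeans(atlas@mesh@vertices[f1, ])
  expect_equal(as.numeric(mapToAtlasSpace(reg, cen)), cenT, tolerance = 1e-6)
  far <- cen + c(0, 0, 1e4)
  expect_error(mapToAtlasSpace(reg, far), "dMax")
})

test_that("registering a mirror-symmetric scan keeps asymmetry at the floor", {
  atlas <- cachedAtlas()
  tor <- generateTorso(torsoSpec(nLevels = 20L, nAround = 40L))
  reg <- registerScan(atlas, tor$mesh)
  fr <- buildBodyFrame(transferLandmarks(reg))
  bp <- bsrProfile(reg, fr, 41L)
  expect_lt(max(abs(bp$angles), na.rm = TRUE), 0.2)
  expect_lt(abs(centroidDeviation(reg, fr, 41L)), 0.5)
})
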