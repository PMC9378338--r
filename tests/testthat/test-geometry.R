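test_that("plane slicing of analytic solids produces the expected loops", {
  cube <- boxMesh()
  expect_true(isWatertight(cube))
  secs <- sliceMesh(cube, Plane(c(0, 0, 50), c(0, 0, 1)))
  expect_length(secs, 1)
  expect_equal(polygonArea(secs[[1]]), 10000, tolerance = 1e-12)

  cyl <- cylinderMesh(r = 100, h = 200, n = 256)
  secs <- sliceMesh(cyl, Plane(c(0, 0, 100), c(0, 0, 1)))
  expect_length(secs, 1)
  ## each of the 256 ring edges and each quad diagonal is crossed once;
  ## diagonal crossings sit on the chords, so radii span [r cos(pi/n), r]
  expect_equal(nrow(secs[[1]]@polygon), 512)
  rad <- sqrt(rowSums(secs[[1]]@polygon^2))
  expect_true(all(rad <= 100 + 1e-9 & rad >= 100 * cos(pi / 256) - 1e-9))
  expect_equal(polygonArea(secs[[1]]), pi * 100^2, tolerance = 1e-3)

  expect_identical(sliceMesh(cube, Plane(c(0, 0, 500), c(0, 0, 1))), list())
  ## non-watertight input is rejected
  open <- TriMesh(boxMesh()@vertices, boxMesh()@faces[-1, ])
  expect_false(isWatertight(open))
  expect_error(sliceMesh(open, Plane(c(0, 0, 50), c(0, 0, 1))), "watertight")
})

test_that("polygon area, centroid and principal axis match analytic values", {
  sq <- asCrossSection(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
  expect_equal(polygonArea(sq), 10000)
  expect_equal(polygonCentroid(sq), c(50, 50))

  ell <- asCrossSection(ellipsePolygon(150, 100, 512))
  expect_equal(polygonArea(ell), pi * 150 * 100, tolerance = 1e-3)
  ellOff <- asCrossSection(ellipsePolygon(150, 100, 512, cx = 20))
  expect_equal(polygonCentroid(ellOff), c(20, 0), tolerance = 1e-6)

  ## L-shaped hexagon: rectangles [0,2]x[0,1] (A=2, c=(1,1/2)) and
  ## [0,1]x[1,2] (A=1, c=(1/2,3/2)) give centroid (5/6, 5/6)
  L <- asCrossSection(rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2)))
  expect_equal(polygonCentroid(L), c(5 / 6, 5 / 6), tolerance = 1e-12)

  expect_equal(polygonPrincipalAxis(ell), 0, tolerance = 1e-6)
  rot30 <- asCrossSection(ellipsePolygon(150, 100, 512, rot = 30))
  expect_equal(polygonPrincipalAxis(rot30), 30, tolerance = 0.1)
  circ <- asCrossSection(ellipsePolygon(100, 100, 512))
  expect_error(polygonPrincipalAxis(circ), "axis undefined")
  expect_error(polygonArea(asCrossSection(rbind(c(0, 0), c(1, 0)))), ">= 3")
})

test_that("polygon metrics agree with the fan-triangulation oracle", {
  for (seed in 1:50) {
    p <- starPolygon(seed = seed)
    if (polygonArea(p) < 0) p <- p[nrow(p):1, ]
    o <- polygonOracle(p)
    expect_equal(polygonArea(p), o$area, tolerance = 1e-9)
    expect_equal(polygonCentroid(p), o$centroid, tolerance = 1e-9)
    ax <- tryCatch(polygonPrincipalAxis(p), error = function(e) NA_real_)
    if (!is.na(ax)) {
      d <- abs(ax - o$axis) %% 180
      expect_lt(min(d, 180 - d), 1e-6)
    }
  }
})

test_that("section volumes are exact for analytic solids and additive", {
  cyl <- cylinderMesh(r = 100, h = 400, n = 256)
  pz <- function(z) Plane(c(0, 0, z), c(0, 0, 1))
  v <- sectionVolume(cyl, pz(100), pz(300))
  expect_equal(v, pi * 0.1^2 * 0.2 * 1000, tolerance = 0.005)
  ## planes beyond the mesh: full volume, matching meshVolume
  expect_equal(sectionVolume(cyl, pz(-50), pz(450)), meshVolume(cyl),
               tolerance = 1e-12)
  ## additivity over an interior partition plane
  vAll <- sectionVolume(cyl, pz(50), pz(350))
  vA <- sectionVolume(cyl, pz(50), pz(170))
  vB <- sectionVolume(cyl, pz(170), pz(350))
  expect_equal(vA + vB, vAll, tolerance = 1e-9)
  expect_error(sectionVolume(cyl, pz(300), pz(100)), "below")
  expect_error(sectionVolume(cyl, Plane(c(0, 0, 0), c(0, 1, 1)), pz(10)),
               "parallel")
})

test_that("region surface area clips boundary triangles exactly", {
  n <- 128
  cyl <- cylinderMesh(r = 100, h = 200, n = n)
  side <- which(seq_len(nrow(cyl@faces)) %% 4 %in% c(1, 2))  # side quads
  pz <- function(z) Plane(c(0, 0, z), c(0, 0, 1))
  aFull <- regionSurfaceArea(cyl, side, pz(0), pz(200))
  lateral <- 2 * pi * 100 * 200 / 1e4
  expect_equal(aFull, lateral, tolerance = 0.005 * lateral)
  ## half-height slab cuts triangles mid-way: exactly half the area
  aHalf <- regionSurfaceArea(cyl, side, pz(0), pz(100))
  expect_equal(aHalf, aFull / 2, tolerance = 1e-9)
  expect_warning(a0 <- regionSurfaceArea(cyl, integer(0), pz(0), pz(200)),
                 "empty")
  expect_identical(a0, 0)
})

test_that("polyline arclength is exact and unit-correct", {
  expect_equal(polylineArclength(rbind(c(0, 0, 0), c(0, 0, 100))), 10)
  ## helix r = 30, pitch 40 mm/turn, 5 turns
  tt <- seq(0, 5 * 2 * pi, length.out = 20000)
  hel <- cbind(30 * cos(tt), 30 * sin(tt), 40 * tt / (2 * pi))
  Ltrue <- 5 * sqrt((2 * pi * 30)^2 + 40^2) / 10
  expect_lt(abs(polylineArclength(hel) - Ltrue) / Ltrue, 1e-4)
  ## duplicated points contribute nothing
  p <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 50), c(0, 0, 50))
  expect_equal(polylineArclength(p), 5)
  expect_error(polylineArclength(rbind(c(0, 0, 0))), ">= 2")
})

test_that("geometry is rigid-invariant and scales with the right powers", {
  cyl <- cylinderMesh(r = 80, h = 300, n = 128, ry = 50)
  pz <- function(z) Plane(c(0, 0, z), c(0, 0, 1))
  v0 <- sectionVolume(cyl, pz(50), pz(250))
  side <- which(seq_len(nrow(cyl@faces)) %% 4 %in% c(1, 2))
  a0 <- regionSurfaceArea(cyl, side, pz(0), pz(300))

  tr <- rigidTransform(cyl@vertices)
  cyl2 <- TriMesh(tr$V, cyl@faces)
  mv <- function(z) Plane(as.numeric(tr$R %*% c(0, 0, z)) + tr$shift,
                          as.numeric(tr$R %*% c(0, 0, 1)))
  expect_equal(sectionVolume(cyl2, mv(50), mv(250)), v0, tolerance = 1e-9)
  expect_equal(regionSurfaceArea(cyl2, side, mv(0), mv(300)), a0,
               tolerance = 1e-9)

  s <- 1.7
  cyl3 <- TriMesh(cyl@vertices * s, cyl@faces)
  expect_equal(sectionVolume(cyl3, pz(50 * s), pz(250 * s)), v0 * s^3,
               tolerance = 1e-9)
  expect_equal(regionSurfaceArea(cyl3, side, pz(0), pz(300 * s)), a0 * s^2,
               tolerance = 1e-9)
  expect_equal(meshVolume(cyl3), meshVolume(cyl) * s^3, tolerance = 1e-12)
})

test_that("analytic-shape errors shrink as angular resolution doubles", {
  errs <- vapply(c(32, 64, 128), function(n) {
    cyl <- cylinderMesh(r = 100, h = 200, n = n)
    sec <- sliceMesh(cyl, Plane(c(0, 0, 100), c(0, 0, 1)))[[1]]
    abs(polygonArea(sec) - pi * 100^2) / (pi * 100^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
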