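## Shared fixtures: analytic meshes, polygon oracles, cached atlases.

## axis-aligned box [0,sx] x [0,sy] x [0,sz], outward-oriented
boxMesh <- function(sx = 100, sy = 100, sz = 100) {
  v <- as.matrix(expand.grid(x = c(0, sx), y = c(0, sy), z = c(0, sz)))
  ## vertex order: (x fastest) 1:(0,0,0) 2:(sx,0,0) 3:(0,sy,0) 4:(sx,sy,0)
  ##               5:(0,0,sz) 6:(sx,0,sz) 7:(0,sy,sz) 8:(sx,sy,sz)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),      # bottom (z=0), outward -z
    c(5, 6, 8), c(5, 8, 7),      # top, outward +z
    c(1, 2, 6), c(1, 6, 5),      # y=0, outward -y
    c(3, 7, 8), c(3, 8, 4),      # y=sy, outward +y
    c(1, 5, 7), c(1, 7, 3),      # x=0, outward -x
    c(2, 4, 8), c(2, 8, 6))      # x=sx, outward +x
  TriMesh(v, f)
}

## closed elliptic cylinder, axis z in [0,h], n segments around
cylinderMesh <- function(r = 100, h = 200, n = 256, ry = r) {
  phi <- 2 * pi * (0:(n - 1)) / n
  ring0 <- cbind(r * cos(phi), ry * sin(phi), 0)
  ring1 <- cbind(r * cos(phi), ry * sin(phi), h)
  v <- rbind(ring0, ring1, c(0, 0, 0), c(0, 0, h))
  cb <- 2L * n + 1L; ct <- 2L * n + 2L
  f <- matrix(0L, 4L * n, 3)
  for (j in 0:(n - 1)) {
    a <- j + 1L; b <- (j + 1L) %% n + 1L
    f[4 * j + 1, ] <- c(a, b, n + b)
    f[4 * j + 2, ] <- c(a, n + b, n + a)
    f[4 * j + 3, ] <- c(cb, b, a)          # bottom cap, outward -z
    f[4 * j + 4, ] <- c(ct, n + a, n + b)  # top cap, outward +z
  }
  TriMesh(v, f)
}

ellipsePolygon <- function(a = 150, b = 100, n = 512, rot = 0, cx = 0, cy = 0) {
  phi <- 2 * pi * (0:(n - 1)) / n
  x <- a * cos(phi); y <- b * sin(phi)
  th <- rot * pi / 180
  cbind(cx + x * cos(th) - y * sin(th), cy + x * sin(th) + y * cos(th))
}

## random simple star-shaped polygon about the origin
starPolygon <- function(n = 7, seed = 1) {
  set.seed(seed)
  k <- sample(5:12, 1)
  phi <- sort(runif(k, 0, 2 * pi))
  r <- runif(k, 20, 100)
  cbind(r * cos(phi), r * sin(phi)) +
    matrix(runif(2, -30, 30), k, 2, byrow = TRUE)
}

## independent polygon-region oracle: fan triangulation from an interior
## point with exact per-triangle area/centroid/second-moment formulas
polygonOracle <- function(p, inner = colMeans(p)) {
  k <- nrow(p)
  A <- 0; Cx <- 0; Cy <- 0; Ixx <- 0; Iyy <- 0; Ixy <- 0
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    x <- c(inner[1], p[i, 1], p[j, 1])
    y <- c(inner[2], p[i, 2], p[j, 2])
    a <- ((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])) / 2
    A <- A + a
    Cx <- Cx + a * mean(x); Cy <- Cy + a * mean(y)
    Ixx <- Ixx + a / 6 * (sum(x^2) + x[1] * x[2] + x[2] * x[3] + x[1] * x[3])
    Iyy <- Iyy + a / 6 * (sum(y^2) + y[1] * y[2] + y[2] * y[3] + y[1] * y[3])
    Ixy <- Ixy + a / 12 * (2 * sum(x * y) + x[1] * y[2] + x[2] * y[1] +
                             x[2] * y[3] + x[3] * y[2] + x[1] * y[3] + x[3] * y[1])
  }
  cx <- Cx / A; cy <- Cy / A
  M <- matrix(c(Ixx - A * cx^2, Ixy - A * cx * cy,
                Ixy - A * cx * cy, Iyy - A * cy^2), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  list(area = A, centroid = c(cx, cy), axis = ang)
}

## cached small atlases / torsos (built once per test run)
.fixtureCache <- new.env(parent = emptyenv())
cachedAtlas <- function(nLevels = 20L, nAround = 40L) {
  key <- paste0("atlas", nLevels, "x", nAround)
  if (!exists(key, envir = .fixtureCache))
    assign(key, templateAtlas(nLevels = nLevels, nAround = nAround),
           envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

asCrossSection <- function(poly) {
  new("CrossSection", plane = Plane(c(0, 0, 0), c(0, 0, 1)),
      polygon = poly, levelT = NA_real_,
      basis = rbind(c(1, 0, 0), c(0, 1, 0)), origin3d = c(0, 0, 0))
}

rigidTransform <- function(V, angles = c(0.3, -0.2, 0.7), shift = c(50, -30, 80)) {
  a <- angles
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
  R <- Rz %*% Ry %*% Rx
  list(V = V %*% t(R) + matrix(shift, nrow(V), 3, byrow = TRUE), R = R, shift = shift)
}

## definitional two-way ANOVA oracle for ICC(2,1)
iccOracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   s = factor(rep(seq_len(n), k)),
                   r = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ s + r, df))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
}
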