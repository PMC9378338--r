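## Template-to-scan registration: similarity initialization (Procrustes on
## landmark hints, or markerless PCA axis alignment), stiffness-regularized
## nonrigid ICP, landmark transfer and inverse mapping into atlas space.

applySimilarity <- function(X, tf) {
  X %*% t(tf$R) * tf$s + matrix(tf$t, nrow(X), 3, byrow = TRUE)
}

composeToIdentityRMS <- function(tf, truthTf, probe) {
  ## convenience for tests: RMS discrepancy of tf vs truthTf on probe points
  sqrt(mean(rowSums((applySimilarity(probe, tf) - applySimilarity(probe, truthTf))^2)))
}

faceNormals <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  n <- crossRows(b - a, cc - a)
  n / pmax(sqrt(rowSums(n^2)), 1e-12)
}

vertexNormals <- function(v, f, incidence = NULL) {
  fn <- crossRows(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                  v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  if (is.null(incidence)) incidence <- faceVertexIncidence(nrow(v), f)
  n <- as.matrix(incidence %*% fn)
  n / pmax(sqrt(rowSums(n^2)), 1e-12)
}

## sparse vertex x face incidence (area weighting via unnormalized normals)
faceVertexIncidence <- function(nv, f) {
  Matrix::sparseMatrix(i = c(f[, 1], f[, 2], f[, 3]),
                       j = rep(seq_len(nrow(f)), 3),
                       x = 1, dims = c(nv, nrow(f)))
}

## rigid ICP refinement of a similarity initialization. The rotation and
## translation come from rigid Procrustes on closest-point pairs; the
## isotropic scale is re-estimated each iteration from the longitudinal
## extents along the current axis (a full similarity refit would let
## nonrigid shape differences leak into a spurious global stretch).
rigidICPRefine <- function(Vt, scan, tf, iters = 40L) {
  Vs <- scan@vertices; Fs <- scan@faces
  extT <- diff(range(Vt[, 3]))
  for (i in seq_len(iters)) {
    A <- Vt * tf$s
    X <- applySimilarity(A, list(s = 1, R = tf$R, t = tf$t))
    nv <- .nearestVertex(Vs, X)
    keep <- nv$dist <= stats::quantile(nv$dist, 0.95)
    upd <- procrustesRigid(A[keep, , drop = FALSE],
                           Vs[nv$index[keep], , drop = FALSE])
    sNew <- diff(range(Vs %*% upd$R[, 3])) / extT
    delta <- max(abs(applySimilarity(A, upd) - X)) + abs(sNew - tf$s) * extT
    tf <- list(s = sNew, R = upd$R, t = upd$t)
    if (delta < 1e-8) break
  }
  tf
}

## rigid Procrustes (Kabsch): R, t minimizing ||R A + t - B||, no scale
procrustesRigid <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  S <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(s = 1, R = R, t = cb - as.numeric(R %*% ca))
}

#' Initial rigid + scale alignment of the template to a scan
#'
#' With landmark hints, a similarity Procrustes fit on the landmark pairs.
#' Markerless (the default pipeline): PCA axis alignment of the two vertex
#' clouds (longitudinal = largest-variance axis), isotropic scale from the
#' extents along the longitudinal axis, and sign disambiguation by choosing
#' the candidate axis orientation with the smallest subsampled
#' cloud-to-cloud RMS distance.
#'
#' @param atlas a \linkS4class{TemplateAtlas}.
#' @param scan the raw scan \linkS4class{TriMesh}.
#' @param hintLandmarks optional \linkS4class{LandmarkSet} in scan space.
#' @return similarity transform list(s, R, t) mapping template coordinates
#'   into scan space.
#' @export
initialRigidAlign <- function(atlas, scan, hintLandmarks = NULL) {
  Vt <- atlas@mesh@vertices
  Vs <- scan@vertices
  if (nrow(Vs) < 4) stop("degenerate scan: too few vertices")
  if (!is.null(hintLandmarks)) {
    A <- Vt[atlas@landmarkIndex[CORE_LANDMARKS], , drop = FALSE]
    B <- do.call(rbind, lapply(CORE_LANDMARKS, function(nm) landmark(hintLandmarks, nm)))
    return(procrustesSimilarity(A, B))
  }
  cs <- colMeans(Vs); ct <- colMeans(Vt)
  covS <- stats::cov(Vs)
  if (qr(covS)$rank < 3) stop("degenerate scan: rank < 3 point cloud")
  es <- eigen(covS, symmetric = TRUE)

  long <- es$vectors[, 1]
  lat <- es$vectors[, 2]
  extent <- function(X, axis) diff(range(X %*% axis))
  s <- extent(sweep(Vs, 2, cs), long) / extent(sweep(Vt, 2, ct), c(0, 0, 1))

  ## template canonical axes: lateral x, anterior y, longitudinal z
  strd <- max(1L, nrow(Vt) %/% 400L)
  sub <- Vt[seq(1, nrow(Vt), by = strd), , drop = FALSE]
  strdS <- max(1L, nrow(Vs) %/% 800L)
  subS <- Vs[seq(1, nrow(Vs), by = strdS), , drop = FALSE]
  best <- NULL; bestRMS <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    a3 <- s1 * long
    a1 <- s2 * lat
    a2 <- cross3(a3, a1)
    R <- cbind(a1, a2, a3)  # maps template (x,y,z) to scan axes
    tf <- list(s = s, R = R, t = cs - as.numeric(R %*% ct) * s)
    moved <- applySimilarity(sub, tf)
    d2 <- vapply(seq_len(nrow(moved)), function(i)
      min(rowSums((subS - matrix(moved[i, ], nrow(subS), 3, byrow = TRUE))^2)),
      numeric(1))
    rms <- sqrt(mean(d2))
    if (rms < bestRMS) { bestRMS <- rms; best <- tf }
  }
  best
}

## similarity Procrustes: find s, R, t minimizing ||s R A + t - B||
procrustesSimilarity <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  S <- t(A0) %*% B0
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- sum(diag(D) * sv$d) / sum(A0^2)
  list(s = s, R = R, t = cb - as.numeric(R %*% ca) * s)
}

#' Default nonrigid ICP parameters
#'
#' Stiffness schedule in units of mean-squared-edge-length, inner iterations
#' per stage, correspondence rejection distance (mm) and maximal normal
#' disagreement (degrees).
#'
#' @export
nicpParams <- function(lambdaSchedule = c(50, 20, 8, 3, 1),
                       innerIter = 20L, dMax = 30, normalMaxAngle = 60) {
  list(lambdaSchedule = lambdaSchedule, innerIter = as.integer(innerIter),
       dMax = dMax, normalMaxAngle = normalMaxAngle)
}

#' Stiffness-regularized nonrigid ICP
#'
#' Deforms the initialized template onto the scan by iterating closest-point
#' correspondences (point to surface, rejected beyond \code{dMax} mm or at
#' normal disagreement above \code{normalMaxAngle}) with a per-vertex
#' displacement field regularized by an edge-difference stiffness term whose
#' weight steps down over a coarse-to-fine schedule. Deterministic: no
#' randomization is used anywhere.
#'
#' @param atlas a \linkS4class{TemplateAtlas}.
#' @param scan the target \linkS4class{TriMesh}.
#' @param init similarity transform from \code{\link{initialRigidAlign}}.
#' @param params list from \code{\link{nicpParams}}.
#' @return a \linkS4class{RegisteredTorso}.
#' @export
nonrigidICP <- function(atlas, scan, init, params = nicpParams()) {
  Vt <- applySimilarity(atlas@mesh@vertices, init)
  Ft <- atlas@mesh@faces
  Vs <- scan@vertices; Fs <- scan@faces
  n <- nrow(Vt)

  ## graph Laplacian of template edges
  e <- rbind(Ft[, c(1, 2)], Ft[, c(2, 3)], Ft[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  L <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = -1, dims = c(n, n))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  mel2 <- mean(rowSums((Vt[e[, 1], ] - Vt[e[, 2], ])^2))

  scanFN <- faceNormals(Vs, Fs)
  cosMax <- cos(params$normalMaxAngle * pi / 180)
  incid <- faceVertexIncidence(n, Ft)
  X <- Vt
  resid <- NA_real_
  for (lam in params$lambdaSchedule) {
    lambda <- lam  # schedule is expressed relative to mean edge length^2;
    # both energy terms are quadratic in mm, so the ratio is dimensionless.
    base <- X
    stageStart <- NA_real_
    bestResid <- Inf; bestX <- X
    for (it in seq_len(params$innerIter)) {
      cp <- .closestOnMesh(Vs, Fs, X)
      w <- as.numeric(cp$dist <= params$dMax)
      vn <- vertexNormals(X, Ft, incid)
      agree <- rowSums(vn * scanFN[cp$face, , drop = FALSE])
      w[agree < cosMax] <- 0
      if (sum(w) < 9) stop("nonrigid ICP lost all correspondences")
      resid <- sqrt(mean(cp$dist[w > 0]^2))
      if (it == 1L) stageStart <- resid
      ## correspondence rejection makes the trajectory mildly non-monotone:
      ## keep the best iterate of the stage
      if (resid < bestResid) { bestResid <- resid; bestX <- X }
      W <- Matrix::Diagonal(n, w)
      M <- W + lambda * L
      rhs <- W %*% cp$point + lambda * (L %*% base)
      Xnew <- as.matrix(Matrix::solve(M, rhs))
      step <- max(abs(Xnew - X))
      X <- Xnew
      if (step < 1e-4) break
    }
    cp <- .closestOnMesh(Vs, Fs, X)
    w <- as.numeric(cp$dist <= params$dMax)
    endResid <- sqrt(mean(cp$dist[w > 0]^2))
    if (endResid < bestResid) { bestResid <- endResid; bestX <- X }
    if (bestResid > stageStart * 1.05 + 0.05)
      stop(sprintf("nonrigid ICP diverged in stage lambda = %g (residual %.4f -> %.4f mm)",
                   lam, stageStart, bestResid))
    X <- bestX
    resid <- bestResid
  }

  ## flipped-triangle diagnostic
  fn0 <- faceNormals(Vt, Ft)
  fn1 <- faceNormals(X, Ft)
  nflip <- sum(rowSums(fn0 * fn1) < 0)
  if (nflip > 0)
    warning(sprintf("%d flipped triangles after registration", nflip))

  mesh <- TriMesh(X, Ft)
  new("RegisteredTorso", mesh = mesh, atlas = atlas, residualRMS = resid)
}

#' Register a scan to the template atlas
#'
#' Convenience wrapper: initial alignment followed by nonrigid ICP.
#'
#' @inheritParams nonrigidICP
#' @param hintLandmarks optional landmark hints for the initialization.
#' @return a \linkS4class{RegisteredTorso}.
#' @export
registerScan <- function(atlas, scan, hintLandmarks = NULL, params = nicpParams()) {
  init <- initialRigidAlign(atlas, scan, hintLandmarks)
  init <- rigidICPRefine(atlas@mesh@vertices, scan, init)
  nonrigidICP(atlas, scan, init, params)
}

#' Transfer the atlas landmarks through a registration
#'
#' Landmark positions are the registered positions of the atlas landmark
#' vertices.
#'
#' @param reg a \linkS4class{RegisteredTorso}.
#' @return a \linkS4class{LandmarkSet} in scan space.
#' @export
transferLandmarks <- function(reg) {
  idx <- reg@atlas@landmarkIndex
  coords <- reg@mesh@vertices[idx, , drop = FALSE]
  rownames(coords) <- names(idx)
  LandmarkSet(coords)
}

#' Map scan-space points into shared atlas space
#'
#' Finds the closest point on the registered surface, takes its barycentric
#' coordinates, and evaluates the same barycentric point on the template
#' triangle: the inverse of the registration at the surface.
#'
#' @param reg a \linkS4class{RegisteredTorso}.
#' @param points k x 3 matrix (or length-3 vector) of scan-space points.
#' @param dMax maximal allowed distance from the registered surface (mm).
#' @return k x 3 matrix of template-space points.
#' @export
mapToAtlasSpace <- function(reg, points, dMax = 30) {
  P <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  cp <- .closestOnMesh(reg@mesh@vertices, reg@mesh@faces, P)
  if (any(cp$dist > dMax))
    stop(sprintf("point %d is %.1f mm from the registered surface (dMax = %g)",
                 which.max(cp$dist), max(cp$dist), dMax))
  Vt <- reg@atlas@mesh@vertices
  Ft <- reg@atlas@mesh@faces
  out <- matrix(0, nrow(P), 3)
  for (i in seq_len(nrow(P))) {
    tri <- Ft[cp$face[i], ]
    out[i, ] <- as.numeric(cp$bary[i, ] %*% Vt[tri, , drop = FALSE])
  }
  out
}
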