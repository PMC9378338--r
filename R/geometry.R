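## Low-level watertight-mesh geometry: plane slicing, polygon metrics,
## clipped-and-capped section volumes, clipped region areas, arclength.
## All inputs in mm; reporting conversions happen at the call sites.

crossRows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

## Edge-manifold check: watertight iff every undirected edge appears in
## exactly two faces, once in each direction (consistent orientation).
checkWatertight <- function(vertices, faces) {
  if (nrow(faces) == 0) return(list(watertight = FALSE))
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L)) return(list(watertight = FALSE))
  ## orientation: each directed edge must appear exactly once
  dkey <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dkey)) return(list(watertight = FALSE))
  list(watertight = TRUE)
}

signedDistances <- function(vertices, plane) {
  as.numeric((vertices - matrix(plane@point, nrow(vertices), 3, byrow = TRUE)) %*%
               plane@normal)
}

#' Slice a watertight mesh with a plane
#'
#' Intersects every face with the plane and assembles the resulting segments
#' into closed loops (chained by shared mesh edges, which is exact for a
#' watertight mesh). Loops are projected into the in-plane basis and returned
#' as \linkS4class{CrossSection} objects sorted by absolute area, largest
#' first.
#'
#' @param mesh a watertight \linkS4class{TriMesh}.
#' @param plane the slicing \linkS4class{Plane}.
#' @param frameBasis optional 2 x 3 matrix with rows (u, v) giving the
#'   in-plane lateral and anteroposterior axes; defaults to an arbitrary
#'   orthonormal in-plane pair.
#' @param levelT level fraction stored on the sections (default NA).
#' @return list of \linkS4class{CrossSection}; empty list when the plane
#'   misses the mesh.
#' @export
sliceMesh <- function(mesh, plane, frameBasis = NULL, levelT = NA_real_) {
  if (!mesh@watertight)
    stop("sliceMesh requires a watertight mesh")
  v <- mesh@vertices; f <- mesh@faces
  d <- signedDistances(v, plane)
  ## nudge exact-zero vertices to avoid degenerate face/plane contacts
  z <- abs(d) < 1e-9
  if (any(z)) d[z] <- 1e-9
  lo <- min(d); hi <- max(d)
  if (lo > 0 || hi < 0) return(list())

  d1 <- d[f[, 1]]; d2 <- d[f[, 2]]; d3 <- d[f[, 3]]
  cut <- (pmin(d1, d2, d3) < 0) & (pmax(d1, d2, d3) > 0)
  if (!any(cut)) return(list())
  fc <- f[cut, , drop = FALSE]

  ## for each cut face, the two edges whose endpoints straddle the plane
  nf <- nrow(fc)
  dd1 <- d[fc[, 1]]; dd2 <- d[fc[, 2]]; dd3 <- d[fc[, 3]]
  crossFlag <- cbind(dd1 * dd2 < 0, dd2 * dd3 < 0, dd3 * dd1 < 0)
  if (!all(rowSums(crossFlag) == 2L))
    stop("inconsistent face/plane intersection")
  edgeEnds <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  slotKey <- matrix("", nf, 3)
  slotPt <- vector("list", 3)
  for (s in 1:3) {
    i <- fc[, edgeEnds[[s]][1]]; j <- fc[, edgeEnds[[s]][2]]
    slotKey[, s] <- paste(pmin(i, j), pmax(i, j))
    ti <- d[i] / (d[i] - d[j])
    slotPt[[s]] <- v[i, , drop = FALSE] + ti * (v[j, , drop = FALSE] - v[i, , drop = FALSE])
  }
  firstSlot <- max.col(crossFlag, ties.method = "first")
  lastSlot <- max.col(crossFlag, ties.method = "last")
  idx <- cbind(seq_len(nf), firstSlot)
  idx2 <- cbind(seq_len(nf), lastSlot)
  keyA <- slotKey[idx]; keyB <- slotKey[idx2]
  ptA <- matrix(0, nf, 3); ptB <- matrix(0, nf, 3)
  for (s in 1:3) {
    selA <- firstSlot == s; selB <- lastSlot == s
    ptA[selA, ] <- slotPt[[s]][selA, , drop = FALSE]
    ptB[selB, ] <- slotPt[[s]][selB, , drop = FALSE]
  }

  ## chain segments into loops: each edge key is shared by exactly two faces
  adj <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nf)) {
    for (k in c(keyA[r], keyB[r])) {
      cur <- if (exists(k, envir = adj, inherits = FALSE)) get(k, envir = adj) else integer(0)
      assign(k, c(cur, r), envir = adj)
    }
  }
  used <- logical(nf)
  loops <- list()
  for (start in seq_len(nf)) {
    if (used[start]) next
    loop_keys <- character(0)
    r <- start; enter_key <- keyA[start]
    repeat {
      used[r] <- TRUE
      exit_key <- if (identical(enter_key, keyA[r])) keyB[r] else keyA[r]
      loop_keys <- c(loop_keys, exit_key)
      nbrs <- get(exit_key, envir = adj)
      nxt <- nbrs[nbrs != r]
      if (length(nxt) != 1L)
        stop("open intersection chain at edge ", exit_key,
             " (non-watertight input?)")
      if (used[nxt]) break
      r <- nxt; enter_key <- exit_key
    }
    ## collect points along the loop (one per key, from whichever face)
    getPt <- function(k, r) if (identical(k, keyA[r])) ptA[r, ] else ptB[r, ]
    P <- matrix(0, length(loop_keys), 3)
    rr <- start; ek <- keyA[start]
    for (i in seq_along(loop_keys)) {
      xk <- if (identical(ek, keyA[rr])) keyB[rr] else keyA[rr]
      P[i, ] <- getPt(xk, rr)
      nbrs <- get(xk, envir = adj)
      rr2 <- nbrs[nbrs != rr]
      rr <- rr2[1]; ek <- xk
    }
    loops[[length(loops) + 1]] <- P
  }

  ## in-plane basis
  if (is.null(frameBasis)) {
    n <- plane@normal
    a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- normalize(a - sum(a * n) * n)
    vv <- cross3(n, u)
    frameBasis <- rbind(u, vv)
  } else {
    frameBasis <- as.matrix(frameBasis)
  }
  origin <- plane@point

  out <- list()
  for (P in loops) {
    rel <- P - matrix(origin, nrow(P), 3, byrow = TRUE)
    poly <- rel %*% t(frameBasis)
    ## merge near-duplicate consecutive points (1e-6 mm)
    keep <- c(TRUE, rowSums((poly[-1, , drop = FALSE] -
                               poly[-nrow(poly), , drop = FALSE])^2) > 1e-12)
    poly <- poly[keep, , drop = FALSE]
    if (nrow(poly) > 1 && sum((poly[1, ] - poly[nrow(poly), ])^2) <= 1e-12)
      poly <- poly[-nrow(poly), , drop = FALSE]
    if (nrow(poly) < 3) next
    if (shoelace(poly) < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
    out[[length(out) + 1]] <- new("CrossSection", plane = plane, polygon = poly,
                                  levelT = levelT, basis = frameBasis,
                                  origin3d = as.numeric(origin))
  }
  if (!length(out)) return(list())
  areas <- vapply(out, function(s) abs(polygonArea(s)), numeric(1))
  out[order(areas, decreasing = TRUE)]
}

shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

asPolygon <- function(section) {
  if (is(section, "CrossSection")) section@polygon else as.matrix(section)
}

#' Enclosed polygon area
#'
#' Shoelace formula; positive for a counter-clockwise polygon.
#'
#' @param section a \linkS4class{CrossSection} or a k x 2 coordinate matrix.
#' @return area in mm^2.
#' @export
polygonArea <- function(section) {
  p <- asPolygon(section)
  if (nrow(p) < 3) stop("polygon needs >= 3 vertices")
  shoelace(p)
}

#' Area centroid of the enclosed polygon region
#'
#' Area-weighted centroid (barycenter of the enclosed region, not the vertex
#' mean).
#'
#' @inheritParams polygonArea
#' @return length-2 centroid (mm).
#' @export
polygonCentroid <- function(section) {
  p <- asPolygon(section)
  if (nrow(p) < 3) stop("polygon needs >= 3 vertices")
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) stop("zero-area polygon: centroid undefined")
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * A)
}

## Second area moments about the centroid: returns 2x2 matrix
## [ int x^2 dA, int xy dA ; int xy dA, int y^2 dA ] (centred coordinates).
polygonMoments <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  Ixx <- sum((x^2 + x * x2 + x2^2) * cr) / 12        # int x^2 dA
  Iyy <- sum((y^2 + y * y2 + y2^2) * cr) / 12        # int y^2 dA
  Ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  M <- matrix(c(Ixx - A * cx^2, Ixy - A * cx * cy,
                Ixy - A * cx * cy, Iyy - A * cy^2), 2, 2)
  if (A < 0) M <- -M
  list(M = M, A = abs(A))
}

#' Principal-axis angle of a cross-section
#'
#' Eigen-decomposition of the area second-moment tensor of the enclosed
#' region. Returns the angle of the major axis relative to the first (u,
#' lateral) in-plane direction, wrapped to (-90, 90] degrees. The angle is
#' measured counter-clockwise in the (u, v) plane: positive when the major
#' axis is rotated toward +v for +u.
#'
#' @inheritParams polygonArea
#' @return signed angle in degrees.
#' @export
polygonPrincipalAxis <- function(section) {
  p <- asPolygon(section)
  if (nrow(p) < 3) stop("polygon needs >= 3 vertices")
  pm <- polygonMoments(p)
  ev <- eigen(pm$M, symmetric = TRUE)
  if (abs(ev$values[1] - ev$values[2]) <= 1e-9 * abs(ev$values[1]))
    stop("axis undefined: isotropic section")
  vmax <- ev$vectors[, 1]
  ang <- atan2(vmax[2], vmax[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ang
}

## --- triangle clipping --------------------------------------------------

## Sutherland-Hodgman clip of a 3D planar-ish polygon against the half-space
## dot(p - point, normal) <= 0 ... we keep the side where keepFun(d) is TRUE.
clipPolyHalfspace <- function(P, plane, keepBelow = TRUE) {
  d <- signedDistances(P, plane)
  if (!keepBelow) d <- -d
  n <- nrow(P)
  out <- matrix(0, 0, 3)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, P[i, ])
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out <- rbind(out, P[i, ] + t * (P[j, ] - P[i, ]))
    }
  }
  out
}

triArea3 <- function(a, b, cc) 0.5 * sqrt(sum(cross3(b - a, cc - a)^2))

polyArea3 <- function(P) {
  if (nrow(P) < 3) return(0)
  a <- P[1, ]; s <- 0
  for (i in 2:(nrow(P) - 1)) s <- s + triArea3(a, P[i, ], P[i + 1, ])
  s
}

## fan-triangulate a convex-ish 3D polygon, returning list of 3x3 matrices
fanTriangles <- function(P) {
  if (nrow(P) < 3) return(list())
  lapply(2:(nrow(P) - 1), function(i) rbind(P[1, ], P[i, ], P[i + 1, ]))
}

#' Volume of the mesh portion between two transverse planes
#'
#' Clips the watertight mesh to the slab between \code{planeLo} and
#' \code{planeHi} (normals are taken pointing from lo toward hi), caps the
#' cut boundaries with planar centroid fans, and evaluates the enclosed
#' volume with the divergence theorem on the capped closed surface.
#'
#' @param mesh a watertight \linkS4class{TriMesh}.
#' @param planeLo,planeHi parallel \linkS4class{Plane}s bounding the slab,
#'   \code{planeLo} below \code{planeHi} along the shared normal.
#' @return volume in litres (1 L = 1e6 mm^3).
#' @export
sectionVolume <- function(mesh, planeLo, planeHi) {
  if (!mesh@watertight) stop("sectionVolume requires a watertight mesh")
  n <- planeLo@normal
  if (sum(n * planeHi@normal) < 0) n2 <- -planeHi@normal else n2 <- planeHi@normal
  if (acos(pmin(1, sum(n * n2))) > 1e-6)
    stop("planes must be parallel")
  hLo <- sum((planeLo@point) * n)
  hHi <- sum((planeHi@point) * n)
  if (hLo > hHi) stop("planeLo must lie below planeHi along the normal")
  pl <- Plane(planeLo@point, n)
  ph <- Plane(planeHi@point, n)

  v <- mesh@vertices; f <- mesh@faces
  dLo <- signedDistances(v, pl)   # keep >= 0
  dHi <- signedDistances(v, ph)   # keep <= 0
  vol6 <- 0
  addTri <- function(a, b, cc) sum(a * cross3(b, cc))

  for (r in seq_len(nrow(f))) {
    tri <- f[r, ]
    dl <- dLo[tri]; dh <- dHi[tri]
    if (max(dl) <= 0 || min(dh) >= 0) next  # fully outside slab
    P <- v[tri, , drop = FALSE]
    if (min(dl) < 0) P <- clipPolyHalfspace(P, pl, keepBelow = FALSE)
    if (nrow(P) >= 3 && max(signedDistances(P, ph)) > 0)
      P <- clipPolyHalfspace(P, ph, keepBelow = TRUE)
    if (nrow(P) < 3) next
    for (T in fanTriangles(P)) vol6 <- vol6 + addTri(T[1, ], T[2, ], T[3, ])
  }

  ## caps at each plane that actually cuts the mesh
  dAll <- signedDistances(v, pl)
  capAt <- function(plane, outwardSign) {
    secs <- sliceMesh(mesh, plane)
    s6 <- 0
    for (sec in secs) {
      poly <- sec@polygon
      ## back to 3D
      P3 <- matrix(sec@origin3d, nrow(poly), 3, byrow = TRUE) +
        poly %*% sec@basis
      cen <- colMeans(P3)
      k <- nrow(P3)
      for (i in seq_len(k)) {
        j <- if (i == k) 1L else i + 1L
        ## loop is CCW in (u,v) basis with u x v = +normal; fan (cen, i, j)
        ## has outward normal +n. Flip order when outward is -n.
        if (outwardSign > 0) s6 <- s6 + addTri(cen, P3[i, ], P3[j, ])
        else s6 <- s6 + addTri(cen, P3[j, ], P3[i, ])
      }
    }
    s6
  }
  dmin <- min(dAll); dmax <- max(dAll)
  if (dmin < 0 && dmax > 0) vol6 <- vol6 + capAt(pl, -1)
  dAllH <- signedDistances(v, ph)
  if (min(dAllH) < 0 && max(dAllH) > 0) vol6 <- vol6 + capAt(ph, +1)

  abs(vol6 / 6) / 1e6
}

#' Surface area of a face subset clipped to a transverse slab
#'
#' Sums triangle areas over the subset, with boundary triangles exactly
#' clipped (Sutherland-Hodgman) to the slab between the two planes.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param faceSubset integer face indices (rows of \code{faces(mesh)}).
#' @param planeLo,planeHi slab-bounding planes (lo below hi along the normal).
#' @return area in dm^2 (1 dm^2 = 1e4 mm^2).
#' @export
regionSurfaceArea <- function(mesh, faceSubset, planeLo, planeHi) {
  if (length(faceSubset) == 0) {
    warning("empty face subset: area 0")
    return(0)
  }
  n <- planeLo@normal
  if (sum(n * planeHi@normal) < 0) nh <- -planeHi@normal else nh <- planeHi@normal
  pl <- Plane(planeLo@point, n)
  ph <- Plane(planeHi@point, nh)
  v <- mesh@vertices; f <- mesh@faces[faceSubset, , drop = FALSE]
  dLo <- signedDistances(v, pl); dHi <- signedDistances(v, ph)
  total <- 0
  for (r in seq_len(nrow(f))) {
    tri <- f[r, ]
    dl <- dLo[tri]; dh <- dHi[tri]
    if (max(dl) <= 0 || min(dh) >= 0) next
    P <- v[tri, , drop = FALSE]
    if (min(dl) < 0) P <- clipPolyHalfspace(P, pl, keepBelow = FALSE)
    if (nrow(P) >= 3 && max(signedDistances(P, ph)) > 0)
      P <- clipPolyHalfspace(P, ph, keepBelow = TRUE)
    if (nrow(P) >= 3) total <- total + polyArea3(P)
  }
  total / 1e4
}

#' Polyline arclength
#'
#' Sum of Euclidean segment lengths of an ordered 3D polyline.
#'
#' @param points k x 3 matrix of ordered points (mm), k >= 2.
#' @return length in cm.
#' @export
polylineArclength <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 2) stop("polyline needs >= 2 points")
  d <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  sum(sqrt(rowSums(d^2))) / 10
}

#' Total enclosed volume of a watertight mesh
#'
#' Divergence-theorem volume of the closed surface.
#'
#' @param mesh a watertight \linkS4class{TriMesh}.
#' @return volume in litres.
#' @export
meshVolume <- function(mesh) {
  if (!mesh@watertight) stop("meshVolume requires a watertight mesh")
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  abs(sum(rowSums(a * crossRows(b, cc)))) / 6 / 1e6
}
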