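## Mesh and landmark I/O: ascii OBJ / PLY / STL, JSON landmark sets,
## CSV polygon dumps.

#' Read a triangle mesh from OBJ, PLY or STL
#'
#' Format is chosen by file extension. OBJ and PLY readers are ascii; PLY
#' binary (little-endian) is also supported. Polygonal faces are fan
#' triangulated.
#'
#' @param path file path ending in .obj, .ply or .stl.
#' @return a \linkS4class{TriMesh}.
#' @export
readMesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = readOBJ(path),
         ply = readPLY(path),
         stl = readSTLAscii(path),
         stop("unsupported mesh format: .", ext))
}

#' Write a triangle mesh to OBJ, PLY or STL (ascii)
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param path output path; extension selects the format.
#' @export
writeMesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (ext == "stl") {
    writeLines("solid torsotopo", con)
    for (r in seq_len(nrow(f))) {
      a <- v[f[r, 1], ]; b <- v[f[r, 2], ]; cc <- v[f[r, 3], ]
      n <- cross3(b - a, cc - a)
      nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
                   sprintf("    vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
                   sprintf("    vertex %.9g %.9g %.9g", cc[1], cc[2], cc[3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid torsotopo", con)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

readOBJ <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "[[:space:]]+"),
                             function(x) as.numeric(x[1:3])))
  ftok <- lapply(strsplit(trimws(sub("^f", "", fl)), "[[:space:]]+"),
                 function(x) as.integer(sub("/.*", "", x)))
  f <- do.call(rbind, unlist(lapply(ftok, function(idx) {
    lapply(seq_len(length(idx) - 2), function(i) idx[c(1, i + 1, i + 2)])
  }), recursive = FALSE))
  TriMesh(v, f)
}

readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    l <- readLines(con, n = 1)
    hdr <- c(hdr, l)
    if (identical(trimws(l), "end_header")) break
    if (length(hdr) > 200) stop("malformed PLY header")
  }
  fmt <- grep("^format", hdr, value = TRUE)
  nv <- as.integer(sub(".*element vertex ", "", grep("element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub(".*element face ", "", grep("element face", hdr, value = TRUE)))
  if (grepl("ascii", fmt)) {
    body <- readLines(con)
    vp <- strsplit(trimws(body[seq_len(nv)]), "[[:space:]]+")
    v <- do.call(rbind, lapply(vp, function(x) as.numeric(x[1:3])))
    fp <- strsplit(trimws(body[nv + seq_len(nf)]), "[[:space:]]+")
    f <- do.call(rbind, unlist(lapply(fp, function(x) {
      k <- as.integer(x[1]); idx <- as.integer(x[2:(k + 1)]) + 1L
      lapply(seq_len(k - 2), function(i) idx[c(1, i + 1, i + 2)])
    }), recursive = FALSE))
  } else if (grepl("binary_little_endian", fmt)) {
    vprops <- grep("^property (float|double)", hdr, value = TRUE)
    sz <- ifelse(grepl("double", vprops), 8L, 4L)
    v <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      row <- numeric(length(sz))
      for (p in seq_along(sz))
        row[p] <- readBin(con, "double", 1, size = sz[p], endian = "little")
      v[i, ] <- row[1:3]
    }
    fl <- vector("list", nf)
    for (i in seq_len(nf)) {
      k <- readBin(con, "integer", 1, size = 1, signed = FALSE)
      idx <- readBin(con, "integer", k, size = 4, endian = "little") + 1L
      fl[[i]] <- idx
    }
    f <- do.call(rbind, unlist(lapply(fl, function(idx) {
      lapply(seq_len(length(idx) - 2), function(i) idx[c(1, i + 1, i + 2)])
    }), recursive = FALSE))
  } else stop("unsupported PLY format")
  TriMesh(v, f)
}

readSTLAscii <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  if (!length(vl)) stop("no vertices found (binary STL is not supported)")
  p <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"),
                             function(x) as.numeric(x[2:4])))
  ## weld duplicate vertices so the result can be watertight
  key <- apply(round(p, 6), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  v <- p[uk, , drop = FALSE]
  f <- matrix(map, ncol = 3, byrow = TRUE)
  TriMesh(v, f)
}

#' Read / write landmark sets as JSON
#'
#' JSON format: an object mapping landmark names to [x, y, z] in mm.
#'
#' @param path JSON file path.
#' @return a \linkS4class{LandmarkSet}.
#' @export
readLandmarks <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- do.call(rbind, lst)
  rownames(coords) <- names(lst)
  LandmarkSet(coords)
}

#' @rdname readLandmarks
#' @param lm a \linkS4class{LandmarkSet}.
#' @export
writeLandmarks <- function(lm, path) {
  lst <- lapply(seq_len(nrow(lm@coords)), function(i) as.numeric(lm@coords[i, ]))
  names(lst) <- rownames(lm@coords)
  jsonlite::write_json(lst, path, digits = NA)
  invisible(path)
}

#' Dump a cross-section polygon to CSV (x, y per row, mm)
#'
#' @param section a \linkS4class{CrossSection}.
#' @param path output CSV path.
#' @export
writeCrossSectionCSV <- function(section, path) {
  df <- data.frame(x = section@polygon[, 1], y = section@polygon[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
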