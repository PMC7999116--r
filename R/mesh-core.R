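#' Triangular surface mesh
#'
#' Container for a triangulated surface in millimetres. The coordinate
#' convention used throughout the package is +x = patient right (lateral),
#' +y = anterior (antero-posterior), +z = cranial (cranio-caudal), so the
#' antero-posterior displacement of a bone segment is its y translation,
#' positive for advancement and negative for setback.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices with
#'   counter-clockwise (outward) winding.
#' @param validate check invariants (finite coordinates, indices in range).
#' @return an object of class `ua_mesh`.
#' @export
ua_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (validate) {
    if (!all(is.finite(vertices)))
      stop("mesh vertices contain non-finite coordinates")
    if (nrow(faces) == 0L)
      stop("mesh has zero faces")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range [1, ", nrow(vertices), "]")
  }
  structure(list(vertices = vertices, faces = faces), class = "ua_mesh")
}

#' @export
print.ua_mesh <- function(x, ...) {
  cat(sprintf("<ua_mesh> %d vertices, %d faces (mm)\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Undirected edge table; attr "directed" carries the per-face directed edges.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  structure(e, key = key)
}

#' Test watertightness
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces with opposite directions (consistent orientation) and the enclosed
#' signed volume is positive.
#'
#' @param mesh a [ua_mesh].
#' @return logical; attribute `boundary_edges` gives the number of edges not
#'   shared by exactly two faces.
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges(mesh)
  tab <- table(attr(e, "key"))
  bad <- sum(tab != 2L)
  ok <- bad == 0L
  if (ok) {
    v <- signed_volume(mesh)
    ok <- v > 0
  }
  structure(ok, boundary_edges = bad)
}

signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  # sum of signed tetrahedra against the origin (divergence theorem)
  cx <- b[, 2] * c_[, 3] - b[, 3] * c_[, 2]
  cy <- b[, 3] * c_[, 1] - b[, 1] * c_[, 3]
  cz <- b[, 1] * c_[, 2] - b[, 2] * c_[, 1]
  sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

#' Enclosed volume of a watertight mesh
#'
#' Signed-tetrahedron (divergence theorem) sum; positive for outward-oriented
#' surfaces. Rigid motions leave the value unchanged.
#'
#' @param mesh a watertight [ua_mesh].
#' @return volume in cubic millimetres.
#' @export
mesh_volume <- function(mesh) {
  wt <- is_watertight(mesh)
  if (!wt)
    stop("mesh is not watertight (", attr(wt, "boundary_edges"),
         " boundary/non-manifold edges); volume is undefined")
  signed_volume(mesh)
}

# ---- rigid transforms -------------------------------------------------------

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Compose a rigid transform from Euler angles and translations
#'
#' Angles follow the intrinsic z-y-x convention: the rotation block is
#' `Rz(yaw) %*% Ry(roll) %*% Rx(pitch)` with pitch about the lateral x axis,
#' roll about the antero-posterior y axis and yaw about the cranio-caudal z
#' axis, all in degrees. Translations are in mm.
#'
#' @param pitch,roll,yaw rotation angles in degrees.
#' @param tx,ty,tz translations in mm (`ty` is the antero-posterior
#'   component: advancement positive, setback negative).
#' @return 4 x 4 homogeneous matrix.
#' @export
euler_compose <- function(pitch = 0, roll = 0, yaw = 0,
                          tx = 0, ty = 0, tz = 0) {
  a <- deg2rad(pitch); b <- deg2rad(roll); c_ <- deg2rad(yaw)
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c_), -sin(c_), 0), c(sin(c_), cos(c_), 0), c(0, 0, 1))
  M <- diag(4)
  M[1:3, 1:3] <- Rz %*% Ry %*% Rx
  M[1:3, 4] <- c(tx, ty, tz)
  M
}

#' Decompose a rigid transform into Euler angles and translations
#'
#' Inverse of [euler_compose()]. At gimbal lock (|roll| = 90 degrees) the
#' decomposition is degenerate; yaw is conventionally set to 0 and the result
#' carries `gimbal_lock = TRUE`.
#'
#' @param matrix 4 x 4 homogeneous rigid transform (orthonormal rotation
#'   block with determinant +1).
#' @return object of class `ua_transform`: a list with `pitch`, `roll`,
#'   `yaw` (degrees), `tx`, `ty`, `tz` (mm), `matrix` and `gimbal_lock`.
#' @export
euler_decompose <- function(matrix) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(4, 4)))
  R <- matrix[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("rotation block is not a proper rotation (orthonormal, det +1)")
  gl <- FALSE
  s <- -R[3, 1]
  if (abs(s) >= 1 - 1e-10) {
    gl <- TRUE
    roll <- if (s > 0) 90 else -90
    yaw <- 0
    if (s > 0) pitch <- rad2deg(atan2(R[1, 2], R[1, 3]))
    else pitch <- rad2deg(atan2(-R[1, 2], -R[1, 3]))
  } else {
    roll <- rad2deg(asin(s))
    pitch <- rad2deg(atan2(R[3, 2], R[3, 3]))
    yaw <- rad2deg(atan2(R[2, 1], R[1, 1]))
  }
  structure(list(pitch = pitch, roll = roll, yaw = yaw,
                 tx = matrix[1, 4], ty = matrix[2, 4], tz = matrix[3, 4],
                 matrix = matrix, gimbal_lock = gl),
            class = "ua_transform")
}

#' @export
print.ua_transform <- function(x, ...) {
  cat(sprintf(paste0("<ua_transform> pitch %.3f  roll %.3f  yaw %.3f deg | ",
                     "t (%.3f, %.3f, %.3f) mm%s\n"),
              x$pitch, x$roll, x$yaw, x$tx, x$ty, x$tz,
              if (isTRUE(x$gimbal_lock)) "  [gimbal lock]" else ""))
  invisible(x)
}

as_transform_matrix <- function(x) {
  if (inherits(x, "ua_transform")) x$matrix
  else if (is.matrix(x) && all(dim(x) == c(4, 4))) x
  else stop("expected a ua_transform or a 4x4 matrix")
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x a [ua_mesh] or an n x 3 point matrix.
#' @param transform a `ua_transform` or 4 x 4 homogeneous matrix.
#' @return object of the same kind as `x`, transformed.
#' @export
apply_transform <- function(x, transform) {
  M <- as_transform_matrix(transform)
  tp <- function(p) {
    out <- p %*% t(M[1:3, 1:3])
    out <- sweep(out, 2, M[1:3, 4], "+")
    dimnames(out) <- dimnames(p)
    out
  }
  if (inherits(x, "ua_mesh")) {
    x$vertices <- tp(x$vertices)
    x
  } else {
    tp(as.matrix(x))
  }
}

# ---- STL I/O ----------------------------------------------------------------

#' Read a triangular mesh from an STL file
#'
#' Accepts both the ASCII and the little-endian binary dialect. STL carries
#' no units; coordinates are taken as millimetres. Facet vertices are welded
#' by exact coordinate match so shared topology (and hence watertightness)
#' is recovered.
#'
#' @param path path to an `.stl` file.
#' @return a [ua_mesh].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  if (size < 15) stop("STL format error: file too short (", size,
                      " bytes) at byte offset 0")
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(size, 512))
  close(con)
  head_txt <- rawToChar(head[head != as.raw(0)])
  ascii <- grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
  if (ascii) read_stl_ascii(path) else read_stl_binary(path, size)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L)
    stop("STL format error: no vertex records found in ASCII file ", path)
  if (length(vl) %% 3L != 0L)
    stop("STL format error: truncated facet (vertex count ", length(vl),
         " not a multiple of 3) near line ", vl[length(vl)])
  txt <- sub("^\\s*vertex\\s+", "", lines[vl])
  nums <- suppressWarnings(
    matrix(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))),
           ncol = 3, byrow = TRUE))
  if (anyNA(nums))
    stop("STL format error: unparseable vertex coordinates near line ",
         vl[which(is.na(rowSums(nums)))[1]])
  weld_facets(nums)
}

read_stl_binary <- function(path, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (size < 84)
    stop("STL format error: binary header incomplete (", size,
         " bytes < 84) at byte offset ", size)
  invisible(readBin(con, "raw", n = 80))
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(n)
  if (n <= 0 || size < expected)
    stop("STL format error: facet count ", n, " implies ", expected,
         " bytes but file has ", size, " (truncated at byte offset ", size, ")")
  rec <- readBin(con, "raw", n = 50 * n)
  dim(rec) <- c(50, n)
  flt <- readBin(as.vector(rec[1:48, ]), "numeric", n = 12L * n,
                 size = 4, endian = "little")
  dim(flt) <- c(12, n)
  tri <- flt[4:12, , drop = FALSE]       # drop normals, keep 3 vertices
  nums <- t(matrix(as.numeric(tri), nrow = 3))
  weld_facets(nums)
}

weld_facets <- function(flat_vertices) {
  key <- paste(flat_vertices[, 1], flat_vertices[, 2], flat_vertices[, 3],
               sep = ",")
  idx <- match(key, key[!duplicated(key)])
  verts <- flat_vertices[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  ua_mesh(verts, faces)
}

#' Write a mesh to an STL file
#'
#' @param mesh a [ua_mesh].
#' @param path output path.
#' @param binary write the binary dialect (default) or ASCII.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("%-80s", "uamorph binary STL (mm)")), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    block <- rbind(t(n), t(a), t(b), t(c_))   # 12 floats per facet
    for (i in seq_len(nrow(f))) {
      writeBin(block[, i], con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
    out <- c("solid uamorph",
             paste0("  facet normal ", fmt(n), "\n",
                    "    outer loop\n",
                    "      vertex ", fmt(a), "\n",
                    "      vertex ", fmt(b), "\n",
                    "      vertex ", fmt(c_), "\n",
                    "    endloop\n",
                    "  endfacet"),
             "endsolid uamorph")
    writeLines(out, path)
  }
  invisible(path)
}
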