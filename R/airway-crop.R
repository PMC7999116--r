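# Plane clipping with cap triangulation, and the airway crop that bounds the
# pharyngeal model superiorly (skull-base plane pair) and inferiorly (C5).

#' Clip a mesh by a plane, capping the cut
#'
#' Keeps the part of the mesh on the side the plane normal points away from
#' (signed distance `(v - point) . normal <= 0`). Crossing triangles are
#' split at the plane; when `cap = TRUE` each resulting boundary loop is
#' fan-triangulated about its centroid so the output stays watertight
#' (exact for the convex / star-shaped cross-sections of tubular airway
#' models).
#'
#' @param mesh a [ua_mesh].
#' @param point,normal plane in point + normal form (mm).
#' @param cap triangulate the cut cross-section(s).
#' @return clipped [ua_mesh].
#' @export
clip_mesh_plane <- function(mesh, point, normal, cap = TRUE) {
  n <- as.numeric(normal); n <- n / sqrt(sum(n^2))
  d <- as.vector(sweep(mesh$vertices, 2, as.numeric(point)) %*% n)
  keep <- d <= 1e-12
  if (!any(keep)) stop("clipping plane removes the entire mesh")
  if (all(keep)) return(mesh)

  verts <- mesh$vertices
  new_idx <- new.env(parent = emptyenv())
  extra <- list()
  cut_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    got <- get0(key, envir = new_idx)
    if (!is.null(got)) return(got)
    t_ <- d[i] / (d[i] - d[j])
    p <- verts[i, ] + t_ * (verts[j, ] - verts[i, ])
    extra[[length(extra) + 1L]] <<- p
    id <- nrow(verts) + length(extra)
    assign(key, id, envir = new_idx)
    id
  }

  f <- mesh$faces
  kf <- matrix(keep[f], ncol = 3)
  nk <- rowSums(kf)
  faces_out <- f[nk == 3L, , drop = FALSE]
  faces_out <- split(t(faces_out), rep(seq_len(nrow(faces_out)), each = 3))
  for (r in which(nk == 1L | nk == 2L)) {
    tri <- f[r, ]
    poly <- integer(0)
    for (e in 1:3) {
      a <- tri[e]; b <- tri[if (e == 3) 1 else e + 1]
      if (keep[a]) poly <- c(poly, a)
      if (xor(keep[a], keep[b])) poly <- c(poly, cut_point(a, b))
    }
    for (k in seq_len(length(poly) - 2L))
      faces_out[[length(faces_out) + 1L]] <- poly[c(1L, k + 1L, k + 2L)]
  }
  verts <- rbind(verts, do.call(rbind, extra))
  faces <- do.call(rbind, faces_out)

  # drop unreferenced vertices
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  verts <- verts[used, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3)

  if (cap) {
    capped <- cap_boundary_loops(verts, faces)
    verts <- capped$vertices; faces <- capped$faces
  }
  ua_mesh(verts, faces)
}

# Fan-cap every open boundary loop about its centroid. Cap triangles stitch
# with reversed boundary direction so orientation stays consistent.
cap_boundary_loops <- function(verts, faces) {
  de <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  cnt <- table(key)
  boundary <- de[cnt[key] == 1L, , drop = FALSE]
  if (nrow(boundary) == 0L)
    return(list(vertices = verts, faces = faces))
  nxt <- boundary[, 2]
  names(nxt) <- boundary[, 1]
  visited <- rep(FALSE, nrow(boundary))
  starts <- boundary[, 1]
  add_faces <- list()
  while (any(!visited)) {
    s <- starts[which(!visited)[1]]
    loop <- s
    repeat {
      visited[match(loop[length(loop)], starts)] <- TRUE
      nx <- unname(nxt[as.character(loop[length(loop)])])
      if (is.na(nx) || nx == s) break
      loop <- c(loop, nx)
    }
    if (length(loop) < 3L) next
    centroid <- colMeans(verts[loop, , drop = FALSE])
    verts <- rbind(verts, centroid)
    cid <- nrow(verts)
    for (k in seq_along(loop)) {
      a <- loop[k]; b <- loop[if (k == length(loop)) 1L else k + 1L]
      add_faces[[length(add_faces) + 1L]] <- c(b, a, cid)
    }
  }
  list(vertices = verts,
       faces = rbind(faces, do.call(rbind, add_faces)))
}

#' Crop the upper-airway model to its anatomical extent
#'
#' The superior border is the intersection of two planes (tangent to the
#' occipital basion and to the most prominent point of the sphenoid sinus);
#' inferiorly the pharynx is cut at the lower edge of C5, a horizontal plane.
#' Planes are supplied in point + normal form with normals pointing away
#' from the airway (towards the removed side); all cuts are capped so the
#' result stays watertight.
#'
#' @param mesh watertight airway [ua_mesh].
#' @param superior_planes list of plane specs, each `list(point=, normal=)`.
#' @param inferior_z cranio-caudal level (mm) of the inferior cut; geometry
#'   below it is removed. `NULL` skips the cut.
#' @return cropped, capped [ua_mesh].
#' @export
crop_airway <- function(mesh, superior_planes = NULL, inferior_z = NULL) {
  out <- mesh
  for (pl in superior_planes)
    out <- clip_mesh_plane(out, pl$point, pl$normal, cap = TRUE)
  if (!is.null(inferior_z))
    out <- clip_mesh_plane(out, c(0, 0, inferior_z), c(0, 0, -1), cap = TRUE)
  if (nrow(out$faces) == 0L)
    stop("crop removed the entire airway model")
  out
}
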