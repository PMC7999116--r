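#' Per-vertex surface-distance map
#'
#' For every vertex of `mesh_a`, the unsigned distance to the nearest point
#' on the surface of `mesh_b` (nearest point on any triangle, not nearest
#' vertex). This is the quantity rendered as a colorimetric map when
#' inspecting a superimposition for misalignment.
#'
#' @param mesh_a,mesh_b [ua_mesh] objects; distances are evaluated at the
#'   vertices of `mesh_a` against the surface of `mesh_b`.
#' @return object of class `ua_distance_map`: list with `distance`
#'   (numeric, mm, one per vertex of `mesh_a`), `closest` (n x 3 matrix of
#'   footpoints on `mesh_b`) and `summary` (mean, 95th percentile, max).
#' @export
surface_distance_map <- function(mesh_a, mesh_b) {
  if (nrow(mesh_a$vertices) == 0L || nrow(mesh_b$faces) == 0L)
    stop("surface_distance_map requires two non-empty meshes")
  res <- cpp_closest_points(mesh_b$vertices, mesh_b$faces - 1L,
                            mesh_a$vertices)
  d <- res$distance
  structure(list(
    distance = d,
    closest = res$point,
    summary = c(mean = mean(d),
                p95 = unname(stats::quantile(d, 0.95, names = FALSE)),
                max = max(d))
  ), class = "ua_distance_map")
}

#' @export
print.ua_distance_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ua_distance_map> %d vertices | mean %.4f  p95 %.4f  max %.4f mm\n",
              length(x$distance), s["mean"], s["p95"], s["max"]))
  invisible(x)
}

#' Export a distance map as CSV
#'
#' Columns: `vertex_index`, `x`, `y`, `z`, `distance` (mm).
#'
#' @param map a `ua_distance_map` from [surface_distance_map()].
#' @param mesh the mesh whose vertices the map was evaluated on.
#' @param path output CSV path.
#' @export
write_distance_csv <- function(map, mesh, path) {
  df <- data.frame(vertex_index = seq_len(nrow(mesh$vertices)),
                   x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                   z = mesh$vertices[, 3], distance = map$distance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Closest surface points for arbitrary query points (used by ICP).
closest_surface_points <- function(mesh, query) {
  cpp_closest_points(mesh$vertices, mesh$faces - 1L, as.matrix(query))
}
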