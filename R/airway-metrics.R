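# 25-slab partition of the cropped airway, projected (axial silhouette)
# cross-sectional areas, and pre/post delta tables.

REGION_COUNTS <- c(nasopharynx = 5L, oropharynx = 9L, hypopharynx = 11L)

#' Partition an airway model into 25 region-labelled slabs
#'
#' The cranio-caudal (z) extent of the model is divided into 25 equal-height
#' slabs, ordered superior to inferior, and labelled by pharyngeal subregion:
#' 5 nasopharynx, 9 oropharynx, 11 hypopharynx. Because each model is divided
#' over its own extent, slab `i` of the pre- and post-operative models spans
#' the same fractional interval of its airway; this is the vertical
#' normalisation that compensates post-operative height changes. Each slab
#' also carries the minimal axis-aligned xy box of the mesh portion inside
#' its z interval.
#'
#' Slab intervals are half-open `[z_lo, z_hi)` going up, with the topmost
#' slab closed so the superior extreme belongs to slab 1.
#'
#' @param mesh cropped, watertight airway [ua_mesh].
#' @return `data.frame` of class `ua_partition` with columns `slab` (1 =
#'   most superior), `region`, `z_lo`, `z_hi`, `x_lo`, `x_hi`, `y_lo`,
#'   `y_hi`, `empty`.
#' @export
partition_airway <- function(mesh) {
  v <- mesh$vertices
  zr <- range(v[, 3])
  n <- sum(REGION_COUNTS)
  if (diff(zr) < n * 1e-6)
    stop("degenerate cranio-caudal extent (", signif(diff(zr), 3),
         " mm) cannot be divided into ", n, " slabs")
  breaks <- seq(zr[1], zr[2], length.out = n + 1L)
  # slab 1 is the most superior
  z_hi <- breaks[seq(n + 1L, 2L)]
  z_lo <- breaks[seq(n, 1L)]
  region <- rep(names(REGION_COUNTS), REGION_COUNTS)

  # xy extent per slab: vertices inside, plus edge crossings of the bounds
  e <- unique_mesh_edges(mesh)
  p1 <- v[e[, 1], , drop = FALSE]
  p2 <- v[e[, 2], , drop = FALSE]
  boxes <- vapply(seq_len(n), function(i) {
    inside <- v[, 3] >= z_lo[i] & (v[, 3] < z_hi[i] | i == 1L)
    pts <- v[inside, 1:2, drop = FALSE]
    for (zc in c(z_lo[i], z_hi[i])) {
      t_ <- (zc - p1[, 3]) / (p2[, 3] - p1[, 3])
      hit <- is.finite(t_) & t_ >= 0 & t_ <= 1
      if (any(hit)) {
        q <- p1[hit, 1:2, drop = FALSE] +
          t_[hit] * (p2[hit, 1:2, drop = FALSE] - p1[hit, 1:2, drop = FALSE])
        pts <- rbind(pts, q)
      }
    }
    if (nrow(pts) == 0L) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(range(pts[, 1]), range(pts[, 2]))
  }, numeric(4))

  out <- data.frame(slab = seq_len(n), region = region,
                    z_lo = z_lo, z_hi = z_hi,
                    x_lo = boxes[1, ], x_hi = boxes[2, ],
                    y_lo = boxes[3, ], y_hi = boxes[4, ],
                    empty = is.na(boxes[1, ]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ua_partition", "data.frame")
  out
}

unique_mesh_edges <- function(mesh) {
  e <- mesh_edges(mesh)
  e[!duplicated(attr(e, "key")), , drop = FALSE]
}

#' Projected cross-sectional area of one slab
#'
#' Area of the orthographic silhouette, along the cranio-caudal (z) axis, of
#' the solid airway portion inside the slab's z interval. The silhouette is
#' rasterised over the slab's xy box at `pixel` resolution; a pixel counts
#' when its centre falls inside the silhouette (membership along the
#' vertical line through the pixel centre comes from the winding number of
#' oriented surface crossings, so no explicit slab capping is required).
#'
#' @param mesh the airway [ua_mesh] the partition was computed from.
#' @param slab one row of a [partition_airway()] result (or the partition
#'   plus `index`).
#' @param index slab number when `slab` is a full partition.
#' @param pixel raster step in mm (default 0.1).
#' @return area in mm^2; attribute `empty` flags a slab containing no
#'   geometry (area 0, not an error).
#' @export
projected_area <- function(mesh, slab, index = NULL, pixel = 0.1) {
  if (!is.null(index)) slab <- slab[slab$slab == index, , drop = FALSE]
  stopifnot(nrow(slab) == 1L, pixel > 0)
  if (isTRUE(slab$empty))
    return(structure(0, empty = TRUE))
  pad <- pixel
  xlo <- slab$x_lo - pad; ylo <- slab$y_lo - pad
  nx <- max(1L, as.integer(ceiling((slab$x_hi + pad - xlo) / pixel)))
  ny <- max(1L, as.integer(ceiling((slab$y_hi + pad - ylo) / pixel)))
  cnt <- cpp_silhouette_count(mesh$vertices, mesh$faces - 1L,
                              xlo, ylo, nx, ny, pixel,
                              slab$z_lo, slab$z_hi)
  structure(cnt * pixel^2, empty = cnt == 0L)
}

#' Per-slab area table of one airway model
#'
#' @param mesh cropped, watertight airway [ua_mesh].
#' @param pixel raster step (mm) for [projected_area()].
#' @return `data.frame` of class `ua_area_table`: `slab`, `region`,
#'   `area_mm2`, `empty`; attribute `volume_mm3` carries the total volume.
#' @export
slice_area_table <- function(mesh, pixel = 0.1) {
  part <- partition_airway(mesh)
  # one batched sweep over a grid covering the whole model
  pad <- pixel
  xlo <- min(mesh$vertices[, 1]) - pad
  ylo <- min(mesh$vertices[, 2]) - pad
  nx <- as.integer(ceiling((max(mesh$vertices[, 1]) + pad - xlo) / pixel))
  ny <- as.integer(ceiling((max(mesh$vertices[, 2]) + pad - ylo) / pixel))
  counts <- cpp_slab_counts(mesh$vertices, mesh$faces - 1L,
                            xlo, ylo, nx, ny, pixel,
                            part$z_lo, part$z_hi)
  areas <- counts * pixel^2
  out <- data.frame(slab = part$slab, region = part$region,
                    area_mm2 = areas, empty = areas == 0,
                    stringsAsFactors = FALSE)
  attr(out, "volume_mm3") <- mesh_volume(mesh)
  attr(out, "partition") <- part
  class(out) <- c("ua_area_table", "data.frame")
  out
}

#' Pre/post delta table for one case
#'
#' Partitions the pre- and (aligned) post-operative models independently
#' into 25 slabs each, pairs slabs by index, and reports the percentage
#' area change per slab and the percentage volume change of the case:
#' `delta_area_pct = 100 * (A_post - A_pre) / A_pre`. Slabs with
#' `A_pre == 0` cannot carry a percentage and are flagged invalid (never
#' silently dropped).
#'
#' @param pre_mesh pre-operative airway [ua_mesh].
#' @param post_mesh_aligned post-operative airway already expressed in the
#'   pre frame (see [align_airway_models()]).
#' @param pixel raster step (mm).
#' @return `data.frame` of class `ua_delta`: `slab`, `region`,
#'   `area_pre_mm2`, `area_post_mm2`, `delta_area_pct`, `valid`; attributes
#'   `delta_volume_pct`, `volume_pre_mm3`, `volume_post_mm3`.
#' @export
case_metrics <- function(pre_mesh, post_mesh_aligned, pixel = 0.1) {
  pre <- slice_area_table(pre_mesh, pixel = pixel)
  post <- slice_area_table(post_mesh_aligned, pixel = pixel)
  valid <- pre$area_mm2 > 0
  if (!all(valid))
    warning(sum(!valid), " slab(s) with zero pre-operative area excluded ",
            "from the percentage delta")
  delta <- ifelse(valid,
                  100 * (post$area_mm2 - pre$area_mm2) / pre$area_mm2,
                  NA_real_)
  v_pre <- attr(pre, "volume_mm3")
  v_post <- attr(post, "volume_mm3")
  out <- data.frame(slab = pre$slab, region = pre$region,
                    area_pre_mm2 = pre$area_mm2,
                    area_post_mm2 = post$area_mm2,
                    delta_area_pct = delta, valid = valid,
                    stringsAsFactors = FALSE)
  attr(out, "delta_volume_pct") <- 100 * (v_post - v_pre) / v_pre
  attr(out, "volume_pre_mm3") <- v_pre
  attr(out, "volume_post_mm3") <- v_post
  class(out) <- c("ua_delta", "data.frame")
  out
}

#' Write per-slab tables as CSV
#'
#' @param x a `ua_area_table` or `ua_delta`.
#' @param path output path.
#' @param patient,timepoint optional identifier columns prepended to the
#'   table.
#' @export
write_slab_csv <- function(x, path, patient = NULL, timepoint = NULL) {
  df <- as.data.frame(x)
  if (inherits(x, "ua_delta"))
    df$delta_volume_pct <- attr(x, "delta_volume_pct")
  if (!is.null(timepoint)) df <- cbind(timepoint = timepoint, df)
  if (!is.null(patient)) df <- cbind(patient = patient, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
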