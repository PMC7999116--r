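# Rigid registration: landmark (Kabsch) fits, ICP refinement, and signed
# six-DOF bone-displacement extraction in the cranial-base-aligned frame.

#' Least-squares rigid fit between two landmark sets
#'
#' Finds the rotation + translation (no scaling, no reflection) that maps
#' `moving` onto `fixed` in the least-squares sense (Kabsch/Umeyama).
#' Correspondence is by label: only labels present in both sets are used.
#'
#' @param moving,fixed `ua_landmarks` (or plain labelled 3-column matrices).
#' @return a `ua_registration`: list with `transform` ([euler_decompose()]
#'   of the fitted matrix), `residuals` (per-landmark distances after
#'   alignment, mm) and `rms`.
#' @export
rigid_fit_landmarks <- function(moving, fixed) {
  common <- intersect(rownames(moving), rownames(fixed))
  if (length(common) < 3L)
    stop("degenerate configuration: need >= 3 matched landmark pairs, have ",
         length(common))
  P <- as.matrix(moving[common, , drop = FALSE])
  Q <- as.matrix(fixed[common, , drop = FALSE])
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate configuration: landmarks are collinear")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  t_ <- cq - as.vector(R %*% cp)
  M <- diag(4); M[1:3, 1:3] <- R; M[1:3, 4] <- t_
  fitted <- apply_transform(P, M)
  res <- sqrt(rowSums((fitted - Q)^2))
  names(res) <- common
  structure(list(transform = euler_decompose(M),
                 residuals = res,
                 rms = sqrt(mean(res^2))),
            class = "ua_registration")
}

#' @export
print.ua_registration <- function(x, ...) {
  cat(sprintf("<ua_registration> rms %.4f mm over %d landmarks\n",
              x$rms, length(x$residuals)))
  print(x$transform)
  invisible(x)
}

#' ICP parameter set
#'
#' @param max_iterations maximum number of ICP iterations.
#' @param tolerance stop when the RMS improvement between iterations falls
#'   below this value (mm).
#' @param rejection_distance correspondences farther than this (mm) are
#'   discarded each iteration.
#' @param samples number of moving-surface points used per iteration.
#' @param seed seed for the deterministic sampling of moving points.
#' @return list of class `ua_icp_params`.
#' @export
icp_params <- function(max_iterations = 50L, tolerance = 1e-6,
                       rejection_distance = 10, samples = 5000L,
                       seed = 1234L) {
  stopifnot(max_iterations >= 1, tolerance > 0, rejection_distance > 0,
            samples >= 3, tolerance < rejection_distance)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 rejection_distance = rejection_distance,
                 samples = as.integer(samples),
                 seed = as.integer(seed)),
            class = "ua_icp_params")
}

#' Refine a rigid alignment by iterative closest point
#'
#' Point-to-surface ICP: sampled vertices of the moving mesh are matched to
#' their nearest points on the fixed surface, a rigid least-squares update is
#' applied, and the loop repeats until the RMS stops improving. The RMS over
#' accepted iterations is non-increasing by construction (an update that
#' worsens it is rejected and iteration stops).
#'
#' @param moving,fixed [ua_mesh] objects.
#' @param init initial transform (`ua_transform` or 4 x 4 matrix) roughly
#'   aligning moving onto fixed.
#' @param params an [icp_params()] set.
#' @param mask optional logical vector over the vertices of `moving`
#'   restricting which vertices may be sampled (e.g. a posterior-wall mask).
#' @return list with `transform` (refined `ua_transform`), `rms` (final
#'   RMS, mm), `iterations`, `converged`, and `rms_trace`.
#' @export
icp_refine <- function(moving, fixed, init = diag(4),
                       params = icp_params(), mask = NULL) {
  M <- as_transform_matrix(init)
  pool <- seq_len(nrow(moving$vertices))
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(moving$vertices))
    pool <- pool[mask]
    if (length(pool) < 3L) stop("mask leaves fewer than 3 vertices")
  }
  idx <- local_seed(params$seed, {
    if (length(pool) > params$samples) sample(pool, params$samples) else pool
  })
  pts <- moving$vertices[idx, , drop = FALSE]

  current_rms <- function(M) {
    p <- apply_transform(pts, M)
    cl <- closest_surface_points(fixed, p)
    keep <- cl$distance <= params$rejection_distance
    if (!any(keep))
      stop("ICP failed to converge: no correspondences within ",
           params$rejection_distance, " mm (min distance ",
           signif(min(cl$distance), 4), " mm)")
    list(rms = sqrt(mean(cl$distance[keep]^2)), keep = keep,
         p = p, target = cl$point)
  }

  st <- current_rms(M)
  trace <- st$rms
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    src <- st$p[st$keep, , drop = FALSE]
    dst <- st$target[st$keep, , drop = FALSE]
    upd <- kabsch(src, dst)
    M_new <- upd %*% M
    st_new <- current_rms(M_new)
    if (st_new$rms > st$rms + 1e-12) break   # reject worsening update
    improved <- st$rms - st_new$rms
    M <- M_new; st <- st_new
    trace <- c(trace, st$rms)
    if (improved < params$tolerance) { converged <- TRUE; break }
  }
  list(transform = euler_decompose(M), rms = st$rms,
       iterations = iter, converged = converged, rms_trace = trace)
}

# plain Kabsch on corresponding point rows (src -> dst)
kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  sv <- svd(crossprod(sweep(src, 2, cs), sweep(dst, 2, cd)))
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- cd - as.vector(R %*% cs)
  M
}

# run expr under a temporary RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Signed six-DOF displacement of a bone segment
#'
#' Implements the registration chain used to tabulate surgical displacement:
#' (1) rigid fit of the post-operative cranial base onto the pre-operative
#' one (structures unaltered by surgery); (2) expression of the post segment
#' landmarks in the pre frame; (3) rigid fit of the pre segment landmarks
#' onto them (optionally refined by ICP when segment meshes are supplied);
#' (4) Euler decomposition into signed angles and translations. Translations
#' are reported as the motion of the segment-landmark centroid in the
#' cranial-base-aligned frame, so `ty` is the antero-posterior (AP)
#' displacement: advancement positive, setback negative.
#'
#' @param pre_case,post_case case lists with a `landmarks` element holding
#'   `cranial_base` and per-segment `ua_landmarks` (as produced by
#'   [simulate_case()]), and optionally `meshes` with per-segment meshes.
#' @param segment `"maxilla"` or `"mandible"`.
#' @param icp refine the segment fit with ICP when segment meshes exist.
#' @param params [icp_params()] used when `icp = TRUE`.
#' @return a `data.frame` of class `ua_displacement` with one row:
#'   patient, segment, tx, ty, tz (mm), pitch, roll, yaw (deg), ap (alias
#'   of ty), rms (residual RMS, mm), icp_iterations.
#' @export
compute_bone_displacement <- function(pre_case, post_case, segment,
                                      icp = FALSE, params = icp_params()) {
  segment <- match.arg(segment, c("maxilla", "mandible"))
  pre_lm <- pre_case$landmarks
  post_lm <- post_case$landmarks
  for (nm in c("cranial_base", segment)) {
    if (is.null(pre_lm[[nm]]) || is.null(post_lm[[nm]]))
      stop("case is missing landmark set '", nm, "'")
  }
  miss <- setdiff(rownames(pre_lm[[segment]]), rownames(post_lm[[segment]]))
  if (length(miss))
    stop("post-operative case lacks segment landmarks: ",
         paste(miss, collapse = ", "))

  # (1) cranial-base alignment maps post-scan coordinates into the pre frame
  cb <- rigid_fit_landmarks(post_lm$cranial_base, pre_lm$cranial_base)
  post_seg <- apply_transform(post_lm[[segment]], cb$transform)
  rownames(post_seg) <- rownames(post_lm[[segment]])

  # (3) segment fit: pre landmarks onto post-in-pre-frame landmarks
  fit <- rigid_fit_landmarks(pre_lm[[segment]], post_seg)
  M <- fit$transform$matrix
  iters <- 0L
  if (icp && !is.null(pre_case$meshes[[segment]]) &&
      !is.null(post_case$meshes[[segment]])) {
    post_mesh <- apply_transform(post_case$meshes[[segment]], cb$transform)
    ref <- icp_refine(pre_case$meshes[[segment]], post_mesh,
                      init = M, params = params)
    M <- ref$transform$matrix
    iters <- ref$iterations
  }

  # report translation as centroid motion, rotation about the centroid
  pre_c <- colMeans(pre_lm[[segment]][
    intersect(rownames(pre_lm[[segment]]), rownames(post_seg)), , drop = FALSE])
  moved_c <- as.vector(M[1:3, 1:3] %*% pre_c + M[1:3, 4])
  tr <- moved_c - pre_c
  ang <- euler_decompose(M)
  out <- data.frame(
    patient = if (!is.null(pre_case$patient)) pre_case$patient else NA_character_,
    segment = segment,
    tx = tr[1], ty = tr[2], tz = tr[3],
    pitch = ang$pitch, roll = ang$roll, yaw = ang$yaw,
    ap = tr[2], rms = fit$rms, icp_iterations = iters,
    stringsAsFactors = FALSE)
  class(out) <- c("ua_displacement", "data.frame")
  out
}

#' Align the post-operative airway model onto the pre-operative one
#'
#' Landmark alignment through the three airway landmarks (pharyngeal recess
#' bilaterally, interarytenoid notch) followed by ICP refinement. Because
#' the posterior pharyngeal wall undergoes negligible change after jaw
#' repositioning, ICP can be restricted to it via `wall_mask` (default: the
#' posterior half of the moving model, i.e. vertices whose y lies below the
#' per-slab centroid).
#'
#' @param pre_ua,post_ua pre- and post-operative airway meshes.
#' @param pre_lm,post_lm airway `ua_landmarks` of each model.
#' @param params [icp_params()] for the refinement; `NULL` skips ICP.
#' @param wall_mask logical over `post_ua` vertices, `"posterior"` (default)
#'   for the built-in posterior-wall mask, or `NULL` for no restriction.
#' @return the post model expressed in the pre model's frame; attributes
#'   `transform`, `rms` and `icp_iterations` document the alignment.
#' @export
align_airway_models <- function(pre_ua, post_ua, pre_lm, post_lm,
                                params = icp_params(),
                                wall_mask = "posterior") {
  fit <- rigid_fit_landmarks(post_lm, pre_lm)
  M <- fit$transform$matrix
  rms <- fit$rms
  iters <- 0L
  if (!is.null(params)) {
    mask <- NULL
    if (identical(wall_mask, "posterior"))
      mask <- posterior_wall_mask(post_ua)
    else if (is.logical(wall_mask))
      mask <- wall_mask
    ref <- icp_refine(post_ua, pre_ua, init = M, params = params,
                      mask = mask)
    M <- ref$transform$matrix
    rms <- ref$rms
    iters <- ref$iterations
  }
  out <- apply_transform(post_ua, M)
  attr(out, "transform") <- euler_decompose(M)
  attr(out, "rms") <- rms
  attr(out, "icp_iterations") <- iters
  out
}

#' Posterior-wall vertex mask
#'
#' Flags vertices lying behind (smaller y than) the local cross-section
#' centroid, estimated in 10 cranio-caudal bands.
#'
#' @param mesh an airway [ua_mesh].
#' @return logical vector over the mesh vertices.
#' @export
posterior_wall_mask <- function(mesh) {
  v <- mesh$vertices
  band <- cut(v[, 3], breaks = 10, labels = FALSE, include.lowest = TRUE)
  mid <- stats::ave(v[, 2], band, FUN = stats::median)
  v[, 2] < mid
}

#' Write displacement records as CSV
#'
#' Columns: patient, segment, tx, ty, tz, pitch, roll, yaw, ap, rms.
#'
#' @param records a `data.frame` of stacked [compute_bone_displacement()]
#'   rows.
#' @param path output path.
#' @export
write_displacement_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
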