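# Synthetic cohort generator: parametric pharynx meshes, landmark bundles,
# and the neutral-interval / linear-above-threshold area response that gives
# every pipeline stage a known ground truth.

#' Parametric airway profile
#'
#' Describes a tube-like pharynx: length, angular resolution, axial
#' resolution, and per-level elliptical semi-axes interpolated by a cubic
#' spline through a few control stations. The default profile is ~70 mm
#' long with a narrower oropharyngeal waist, lateral semi-axis `a` wider
#' than the antero-posterior semi-axis `b`, matching the flattened
#' cross-section of a real pharynx.
#'
#' @param length tube length in mm (cranio-caudal).
#' @param n_theta vertices per cross-section ring.
#' @param n_rings number of axial intervals.
#' @param stations data.frame with columns `frac` (0 = inferior, 1 =
#'   superior), `a`, `b` (semi-axes, mm) of the control stations.
#' @param jitter_sd multiplicative log-normal jitter applied per station
#'   and semi-axis when a mesh is generated (anatomical variation across
#'   synthetic patients).
#' @return list of class `ua_profile`.
#' @export
airway_profile <- function(length = 70, n_theta = 96L, n_rings = 56L,
                           stations = data.frame(
                             frac = c(0, 0.2, 0.45, 0.7, 0.9, 1),
                             a = c(12, 11, 9.5, 10.5, 13, 14),
                             b = c(9, 8, 6.5, 7.5, 10, 11)),
                           jitter_sd = 0.04) {
  stopifnot(length > 0, n_theta >= 8, n_rings >= 4,
            all(stations$a > 0), all(stations$b > 0))
  structure(list(length = length, n_theta = as.integer(n_theta),
                 n_rings = as.integer(n_rings), stations = stations,
                 jitter_sd = jitter_sd),
            class = "ua_profile")
}

# semi-axis functions a(z), b(z) for a (possibly jittered) profile
profile_axes <- function(profile, jitter = NULL) {
  st <- profile$stations
  a <- st$a; b <- st$b
  if (!is.null(jitter)) {
    a <- a * jitter$a
    b <- b * jitter$b
  }
  z <- st$frac * profile$length
  list(a = stats::splinefun(z, a, method = "natural"),
       b = stats::splinefun(z, b, method = "natural"))
}

#' Generate a watertight synthetic pharynx mesh
#'
#' Capped elliptical tube along z (z = 0 inferior, z = `length` superior),
#' sampled on `n_theta` x `n_rings` rings with spline-interpolated
#' semi-axes. Fully reproducible: the same seed yields an identical mesh.
#'
#' @param profile an [airway_profile()].
#' @param seed integer seed driving the per-station jitter.
#' @return a watertight [ua_mesh]; attribute `axes` carries the semi-axis
#'   spline functions used (needed by the deformation machinery).
#' @export
generate_airway <- function(profile = airway_profile(), seed = 1L) {
  jit <- local_seed(seed, list(
    a = exp(stats::rnorm(nrow(profile$stations), 0, profile$jitter_sd)),
    b = exp(stats::rnorm(nrow(profile$stations), 0, profile$jitter_sd))))
  axes <- profile_axes(profile, jit)
  nt <- profile$n_theta; nr <- profile$n_rings
  z <- seq(0, profile$length, length.out = nr + 1L)
  a <- axes$a(z); b <- axes$b(z)
  if (any(a <= 0) || any(b <= 0))
    stop("non-positive semi-axis in the interpolated profile")
  phi <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  verts <- do.call(rbind, lapply(seq_along(z), function(k) {
    cbind(a[k] * cos(phi), b[k] * sin(phi), z[k])
  }))
  ring <- function(k) (k - 1L) * nt + seq_len(nt)     # 1-based ring indices
  faces <- list()
  for (k in seq_len(nr)) {
    lo <- ring(k); hi <- ring(k + 1L)
    nxt <- c(2:nt, 1L)
    faces[[2 * k - 1]] <- cbind(lo, lo[nxt], hi[nxt])
    faces[[2 * k]] <- cbind(lo, hi[nxt], hi)
  }
  # caps: fans about the ring centroids
  c_bot <- nrow(verts) + 1L
  c_top <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, z[1]), c(0, 0, z[nr + 1L]))
  lo <- ring(1L); hi <- ring(nr + 1L)
  nxt <- c(2:nt, 1L)
  faces[[length(faces) + 1L]] <- cbind(c_bot, lo[nxt], lo)    # faces -z
  faces[[length(faces) + 1L]] <- cbind(c_top, hi, hi[nxt])    # faces +z
  mesh <- ua_mesh(verts, do.call(rbind, faces))
  attr(mesh, "axes") <- axes
  mesh
}

#' Generate a plausible skull / airway landmark bundle
#'
#' Places the landmark sets the registration chain expects at anatomically
#' plausible offsets around an airway of the given profile: four cranial
#' base points (unaltered by surgery), four maxillary and four mandibular
#' dental cusps, and three airway points (pharyngeal recess bilaterally,
#' interarytenoid notch) lying on the airway surface. Left/right pairs are
#' mirror-symmetric across the midsagittal plane when `jitter = 0`.
#'
#' @param profile an [airway_profile()] (for the airway landmark radii).
#' @param axes optional semi-axis functions of a generated mesh (attribute
#'   `axes` of [generate_airway()]); defaults to the unjittered profile.
#' @param jitter SD (mm) of Gaussian positional jitter per coordinate.
#' @param seed integer seed for the jitter.
#' @return named list of `ua_landmarks`: `cranial_base`, `maxilla`,
#'   `mandible`, `airway`.
#' @export
generate_skull_landmarks <- function(profile = airway_profile(),
                                     axes = NULL, jitter = 0.8,
                                     seed = 1L) {
  L <- profile$length
  if (is.null(axes)) axes <- profile_axes(profile)
  mirror <- function(p) c(-p[1], p[2], p[3])
  bundle <- local_seed(seed, {
    jit <- function(p) p + stats::rnorm(3, 0, jitter)
    pair <- function(base) rbind(jit(base), jit(mirror(base)))
    cb <- rbind(pair(c(45, 40, L + 30)), pair(c(50, -25, L + 8)))
    mx <- rbind(pair(c(22, 38, 0.46 * L)), pair(c(15, 48, 0.45 * L)))
    md <- rbind(pair(c(23, 36, 0.30 * L)), pair(c(16, 46, 0.28 * L)))
    # airway points on the tube surface (phi measured from +x, posterior
    # wall at phi = -90 deg)
    on_surface <- function(phi, z)
      c(axes$a(z) * cos(phi), axes$b(z) * sin(phi), z)
    aw <- rbind(on_surface(-pi / 2 + 0.45, 0.88 * L),
                on_surface(-pi / 2 - 0.45, 0.88 * L),
                on_surface(-pi / 2, 0.10 * L))
    list(cb = cb, mx = mx, md = md, aw = aw)
  })
  list(
    cranial_base = ua_landmarks(bundle$cb,
      c("frontozygomatic-L", "frontozygomatic-R",
        "zygomatic-arch-L", "zygomatic-arch-R")),
    maxilla = ua_landmarks(bundle$mx,
      c("mx-molar-cusp-L", "mx-molar-cusp-R",
        "mx-canine-cusp-L", "mx-canine-cusp-R")),
    mandible = ua_landmarks(bundle$md,
      c("md-molar-cusp-L", "md-molar-cusp-R",
        "md-canine-cusp-L", "md-canine-cusp-R")),
    airway = ua_landmarks(bundle$aw,
      c("pharyngeal-recess-L", "pharyngeal-recess-R",
        "interarytenoid-notch")))
}

#' Area response model
#'
#' Encodes the neutral-interval hypothesis: per-slab area change is pure
#' noise while the effective AP displacement lies inside `[-theta, theta]`
#' and grows linearly in the excess displacement beyond the threshold
#' (`beta` percent per mm) outside it. Each pharyngeal subregion feels an
#' effective displacement mixing the maxillary and mandibular AP via its
#' maxilla share `w`: `d_eff = w * maxilla_ap + (1 - w) * mandible_ap`,
#' with the nasopharynx maxilla-driven and the hypopharynx mandible-driven.
#'
#' @param theta displacement threshold (mm).
#' @param beta slope above threshold (delta-area percent per mm).
#' @param sigma SD of the per-slab noise (delta-area percent).
#' @param weights named maxilla-share weights in `[0, 1]` for
#'   nasopharynx / oropharynx / hypopharynx.
#' @return list of class `ua_response`.
#' @export
response_model <- function(theta = 5.5, beta = 25, sigma = 15,
                           weights = c(nasopharynx = 0.8, oropharynx = 0.5,
                                       hypopharynx = 0.2)) {
  stopifnot(theta >= 0, beta >= 0, sigma >= 0,
            all(weights >= 0 & weights <= 1),
            setequal(names(weights), names(REGION_COUNTS)))
  structure(list(theta = theta, beta = beta, sigma = sigma,
                 weights = weights),
            class = "ua_response")
}

# mean response at effective displacement d
response_mean <- function(response, d) {
  ifelse(d > response$theta, response$beta * (d - response$theta),
         ifelse(d < -response$theta, response$beta * (d + response$theta), 0))
}

#' Case noise settings
#'
#' @param landmark_sd SD (mm) of Gaussian landmark-picking noise.
#' @param scan_pose apply a random rigid scan pose (rotations up to 1
#'   degree, translations up to 3 mm) to all post-operative data,
#'   emulating a different scanner frame.
#' @param rotation_max maximum magnitude (degrees) of the small random
#'   rotations added to the true segment displacements.
#' @export
case_noise <- function(landmark_sd = 0.3, scan_pose = TRUE,
                       rotation_max = 0) {
  list(landmark_sd = landmark_sd, scan_pose = scan_pose,
       rotation_max = rotation_max)
}

# deterministic seed-splitting: sub-stream k of master seed
split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483629)
}

#' Simulate one surgical case
#'
#' Builds a paired pre/post case with full ground truth: (1) the true
#' segment displacements are pure AP translations of the landmark centroids
#' (plus optional small rotations about them); (2) post-operative landmarks
#' are the transformed pre-operative ones plus picking noise; (3) per-slab
#' true area changes are drawn from the response model; (4) the
#' post-operative airway is the pre-operative mesh with each cross-section
#' scaled about its posterior wall point by `sqrt(1 + delta/100)` (area
#' change exact by construction), smoothly interpolated between slab
#' centres; (5) when enabled, a random scan pose moves all post data into a
#' different frame.
#'
#' @param maxilla_ap,mandible_ap true AP displacements (mm), advancement
#'   positive; plausible surgical range is about -10 to +16 mm.
#' @param response a [response_model()].
#' @param noise a [case_noise()] list.
#' @param seed integer seed; identical seeds give identical cases.
#' @param profile an [airway_profile()].
#' @param patient optional patient id.
#' @param group optional group label (`"MMA"` / `"MAMS"`).
#' @return list of class `ua_case` with `pre`, `post` (each: `patient`,
#'   `landmarks`, `meshes$airway`) and `truth` (true transforms, scan pose,
#'   per-slab `delta_area` with region labels, effective displacements).
#' @export
simulate_case <- function(maxilla_ap, mandible_ap,
                          response = response_model(),
                          noise = case_noise(), seed = 1L,
                          profile = airway_profile(),
                          patient = "case", group = NA_character_) {
  pre_mesh <- generate_airway(profile, seed = split_seed(seed, 1))
  axes <- attr(pre_mesh, "axes")
  lms <- generate_skull_landmarks(profile, axes = axes,
                                  seed = split_seed(seed, 2))

  # true displacements: translation of the landmark centroid (+ optional
  # small rotation about it), so truth AP is exactly the requested value
  make_truth <- function(lm_set, ap, sub) {
    rot <- if (noise$rotation_max > 0)
      local_seed(split_seed(seed, sub),
                 stats::runif(3, -noise$rotation_max, noise$rotation_max))
    else c(0, 0, 0)
    ctr <- colMeans(lm_set)
    Mr <- euler_compose(rot[1], rot[2], rot[3])
    Tc <- diag(4); Tc[1:3, 4] <- ctr + c(0, ap, 0)
    Tn <- diag(4); Tn[1:3, 4] <- -ctr
    euler_decompose(Tc %*% Mr %*% Tn)
  }
  t_mx <- make_truth(lms$maxilla, maxilla_ap, 3)
  t_md <- make_truth(lms$mandible, mandible_ap, 4)

  # per-slab true response
  regions <- rep(names(REGION_COUNTS), REGION_COUNTS)
  d_eff <- response$weights * maxilla_ap +
    (1 - response$weights) * mandible_ap
  mu <- response_mean(response, d_eff[regions])
  delta <- local_seed(split_seed(seed, 5),
                      mu + stats::rnorm(length(mu), 0, response$sigma))
  if (any(delta <= -100)) {
    warning("true delta-area below -100% truncated at -95%")
    delta[delta <= -100] <- -95
  }
  truth_delta <- data.frame(slab = seq_along(delta), region = regions,
                            true_delta_pct = delta)

  # deform the pre mesh: slab centres superior->inferior over the z extent
  zr <- range(pre_mesh$vertices[, 3])
  n <- length(delta)
  centers <- zr[2] - (seq_len(n) - 0.5) / n * diff(zr)
  sfun <- stats::approxfun(centers, sqrt(1 + delta / 100), rule = 2)
  deform_xy <- function(pts) {
    s <- sfun(pts[, 3])
    cy <- -axes$b(pts[, 3])        # posterior wall point of the section
    out <- cbind(pts[, 1] * s, cy + s * (pts[, 2] - cy), pts[, 3])
    dimnames(out) <- dimnames(pts)
    out
  }
  post_mesh <- pre_mesh
  post_mesh$vertices <- deform_xy(pre_mesh$vertices)
  attr(post_mesh, "axes") <- NULL

  # scan pose + landmark picking noise
  scan <- if (isTRUE(noise$scan_pose)) {
    prm <- local_seed(split_seed(seed, 6),
                      c(stats::runif(3, -1, 1), stats::runif(3, -3, 3)))
    euler_decompose(euler_compose(prm[1], prm[2], prm[3],
                                  prm[4], prm[5], prm[6]))
  } else euler_decompose(diag(4))

  pick <- function(lm, sub) {
    if (noise$landmark_sd <= 0) return(lm)
    local_seed(split_seed(seed, sub), {
      out <- lm + matrix(stats::rnorm(length(lm), 0, noise$landmark_sd),
                         ncol = 3)
      ua_landmarks(out, rownames(lm))
    })
  }
  relabel <- function(m, ref) ua_landmarks(m, rownames(ref))
  post_lms <- list(
    cranial_base = pick(relabel(apply_transform(lms$cranial_base, scan),
                                lms$cranial_base), 7),
    maxilla = pick(relabel(apply_transform(
      apply_transform(lms$maxilla, t_mx), scan), lms$maxilla), 8),
    mandible = pick(relabel(apply_transform(
      apply_transform(lms$mandible, t_md), scan), lms$mandible), 9),
    airway = pick(relabel(apply_transform(deform_xy(lms$airway), scan),
                          lms$airway), 10))
  post_mesh <- apply_transform(post_mesh, scan)

  structure(list(
    pre = list(patient = patient, group = group, landmarks = lms,
               meshes = list(airway = pre_mesh)),
    post = list(patient = patient, group = group, landmarks = post_lms,
                meshes = list(airway = post_mesh)),
    truth = list(maxilla = t_mx, mandible = t_md, scan = scan,
                 maxilla_ap = maxilla_ap, mandible_ap = mandible_ap,
                 d_eff = d_eff, delta_area = truth_delta,
                 response = response)),
    class = "ua_case")
}

#' Sample cohort AP displacements
#'
#' Draws per-patient maxillary and mandibular AP displacements whose
#' distributions are calibrated to the published cohort: both jaws advance
#' in MMA (maxilla median +3.8 mm, mandible median +4.6 mm); in MAMS the
#' maxilla advances (median +3.9 mm) and the mandible is set back
#' (median -2.5 mm, never beyond -5.8 mm). Log-normal shapes reproduce the
#' medians exactly and the interquartile ranges approximately; draws are
#' clamped to the observed extremes.
#'
#' @param n_mma,n_mams group sizes.
#' @param seed integer seed.
#' @return `data.frame`: `patient`, `group`, `maxilla_ap`, `mandible_ap`.
#' @export
sample_cohort_displacements <- function(n_mma = 29L, n_mams = 16L,
                                        seed = 1L) {
  rlog <- function(n, median, sdlog, lo, hi)
    pmin(pmax(stats::rlnorm(n, log(median), sdlog), lo), hi)
  local_seed(split_seed(seed, 101), {
    mma_mx <- rlog(n_mma, 3.8, 0.66, 0.0, 15.1)
    mma_md <- rlog(n_mma, 4.6, 0.71, 0.5, 13.7)
    mams_mx <- rlog(n_mams, 3.9, 0.45, 0.9, 7.2)
    mams_md <- -rlog(n_mams, 2.5, 0.84, 0.0, 5.8)
    data.frame(
      patient = sprintf("P%03d", seq_len(n_mma + n_mams)),
      group = c(rep("MMA", n_mma), rep("MAMS", n_mams)),
      maxilla_ap = c(mma_mx, mams_mx),
      mandible_ap = c(mma_md, mams_md),
      stringsAsFactors = FALSE)
  })
}

#' Generate a full synthetic cohort
#'
#' Samples AP displacements for the two surgical groups and simulates every
#' case. All randomness flows from `seed` through a documented splitting
#' scheme, so a cohort is fully reproducible.
#'
#' @param n_mma,n_mams group sizes (defaults give the 45-patient study
#'   layout: 29 + 16).
#' @param response a [response_model()].
#' @param noise a [case_noise()].
#' @param seed integer master seed.
#' @param profile an [airway_profile()].
#' @param dir optional directory; when given, each case is written to disk
#'   (STL meshes, JSON landmarks) together with `manifest.csv` and
#'   `ground_truth.csv`.
#' @return list of class `ua_cohort`: `cases` (named list of `ua_case`),
#'   `manifest`, `response`.
#' @export
generate_cohort <- function(n_mma = 29L, n_mams = 16L,
                            response = response_model(),
                            noise = case_noise(), seed = 1L,
                            profile = airway_profile(), dir = NULL) {
  manifest <- sample_cohort_displacements(n_mma, n_mams, seed)
  cases <- lapply(seq_len(nrow(manifest)), function(i) {
    simulate_case(manifest$maxilla_ap[i], manifest$mandible_ap[i],
                  response = response, noise = noise,
                  seed = split_seed(seed, 1000 + i),
                  profile = profile,
                  patient = manifest$patient[i],
                  group = manifest$group[i])
  })
  names(cases) <- manifest$patient
  cohort <- structure(list(cases = cases, manifest = manifest,
                           response = response, seed = seed),
                      class = "ua_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.ua_cohort <- function(x, ...) {
  cat(sprintf("<ua_cohort> %d cases (%d MMA, %d MAMS), seed %d\n",
              nrow(x$manifest), sum(x$manifest$group == "MMA"),
              sum(x$manifest$group == "MAMS"), x$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One directory per case holding `airway_pre.stl`, `airway_post.stl` and
#' `landmarks_pre.json` / `landmarks_post.json` (all landmark sets merged,
#' labels prefixed by set name), plus `manifest.csv` and
#' `ground_truth.csv` at the top level.
#'
#' @param cohort a `ua_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$cases)) {
    cs <- cohort$cases[[pid]]
    cdir <- file.path(dir, pid)
    dir.create(cdir, showWarnings = FALSE)
    write_stl(cs$pre$meshes$airway, file.path(cdir, "airway_pre.stl"))
    write_stl(cs$post$meshes$airway, file.path(cdir, "airway_post.stl"))
    write_case_landmarks(cs$pre$landmarks,
                         file.path(cdir, "landmarks_pre.json"))
    write_case_landmarks(cs$post$landmarks,
                         file.path(cdir, "landmarks_post.json"))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  truth <- do.call(rbind, lapply(names(cohort$cases), function(pid) {
    d <- cohort$cases[[pid]]$truth$delta_area
    cbind(patient = pid, d)
  }))
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

write_case_landmarks <- function(lms, path) {
  merged <- do.call(rbind, lapply(names(lms), function(nm) {
    m <- lms[[nm]]
    rownames(m) <- paste(nm, rownames(m), sep = ":")
    m
  }))
  write_landmarks_json(ua_landmarks(unclass(merged)), path)
}

read_case_landmarks <- function(path) {
  merged <- read_landmarks_json(path)
  set <- sub(":.*$", "", rownames(merged))
  lab <- sub("^[^:]*:", "", rownames(merged))
  out <- lapply(split(seq_len(nrow(merged)), set), function(i)
    ua_landmarks(unclass(merged)[i, , drop = FALSE], lab[i]))
  out[unique(set)]
}
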