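# Landmark fits, ICP refinement and bone-displacement extraction.

lm4 <- function(jit = 0) {
  pts <- rbind(c(10, 0, 0), c(-10, 5, 0), c(0, -8, 6), c(3, 4, -9))
  if (jit > 0) pts <- pts + matrix(rnorm(12, 0, jit), ncol = 3)
  ua_landmarks(pts, c("a", "b", "c", "d"))
}

test_that("identical landmark sets fit to the identity", {
  fit <- rigid_fit_landmarks(lm4(), lm4())
  expect_lt(max(abs(fit$transform$matrix - diag(4))), 1e-12)
  expect_equal(max(fit$residuals), 0, tolerance = 1e-12)
})

test_that("pure translation is recovered exactly", {
  moving <- lm4()
  fixed <- ua_landmarks(moving + rep(c(1, 2, 3), each = 4),
                        rownames(moving))
  fit <- rigid_fit_landmarks(moving, fixed)
  expect_equal(c(fit$transform$tx, fit$transform$ty, fit$transform$tz),
               c(1, 2, 3), tolerance = 1e-12)
  expect_equal(abs(fit$transform$pitch) + abs(fit$transform$roll) +
                 abs(fit$transform$yaw), 0, tolerance = 1e-10)
})

test_that("degenerate landmark configurations are rejected", {
  two <- ua_landmarks(rbind(c(0, 0, 0), c(1, 0, 0)), c("a", "b"))
  expect_error(rigid_fit_landmarks(two, two), ">= 3 matched")
  line <- ua_landmarks(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                             c(3, 0, 0)), letters[1:4])
  expect_error(rigid_fit_landmarks(line, line), "collinear")
})

test_that("correspondence is by label, not order", {
  moving <- lm4()
  fixed <- ua_landmarks(moving[c(3, 1, 4, 2), ] + rep(c(0, 2, 0), each = 4),
                        rownames(moving)[c(3, 1, 4, 2)])
  fit <- rigid_fit_landmarks(moving, fixed)
  expect_equal(fit$transform$ty, 2, tolerance = 1e-12)
  expect_equal(fit$rms, 0, tolerance = 1e-10)
})

test_that("fit is equivariant under conjugation by a rotation", {
  set.seed(5)
  moving <- lm4()
  M <- random_pose()
  fixed <- ua_landmarks(apply_transform(unclass(moving), M),
                        rownames(moving))
  fit <- rigid_fit_landmarks(moving, fixed)
  Q <- euler_compose(15, -25, 40)
  mv_q <- ua_landmarks(apply_transform(unclass(moving), Q),
                       rownames(moving))
  fx_q <- ua_landmarks(apply_transform(unclass(fixed), Q),
                       rownames(moving))
  fit_q <- rigid_fit_landmarks(mv_q, fx_q)
  conj <- Q %*% fit$transform$matrix %*% solve(Q)
  expect_lt(max(abs(fit_q$transform$matrix - conj)), 1e-9)
})

test_that("noisy 4-point fits recover translation within 0.5 mm (median)", {
  set.seed(99)
  errs <- replicate(200, {
    M <- random_pose()
    moving <- lm4()
    fixed <- ua_landmarks(apply_transform(unclass(moving), M) +
                            matrix(rnorm(12, 0, 0.3), ncol = 3),
                          rownames(moving))
    fit <- rigid_fit_landmarks(moving, fixed)
    sqrt(sum((c(fit$transform$tx, fit$transform$ty, fit$transform$tz) -
                M[1:3, 4])^2))
  })
  expect_lt(median(errs), 0.5)
})

test_that("ICP on identical pre-aligned meshes stays at the identity", {
  cyl <- make_cylinder(n = 48, r = 9, h = 40)
  res <- icp_refine(cyl, cyl, init = diag(4),
                    params = icp_params(samples = 500))
  expect_lt(max(abs(res$transform$matrix - diag(4))), 1e-6)
  expect_lt(res$rms, 1e-9)
})

test_that("ICP recovers a small displacement from identity init", {
  tube <- generate_airway(airway_profile(n_theta = 48, n_rings = 30),
                          seed = 3)
  M <- euler_compose(pitch = 2, ty = 1)
  moved <- apply_transform(tube, M)
  res <- icp_refine(moved, tube, init = diag(4),
                    params = icp_params(max_iterations = 80,
                                        tolerance = 1e-9, samples = 800))
  # recovered transform should undo M
  err <- res$transform$matrix %*% M
  d <- euler_decompose(err)
  expect_lt(sqrt(d$tx^2 + d$ty^2 + d$tz^2), 0.1)
  expect_lt(max(abs(c(d$pitch, d$roll, d$yaw))), 0.1)
})

test_that("ICP RMS is non-increasing across accepted iterations", {
  tube <- generate_airway(airway_profile(n_theta = 40, n_rings = 24),
                          seed = 8)
  set.seed(42)
  for (i in 1:20) {
    M <- euler_compose(runif(1, -2, 2), runif(1, -2, 2), runif(1, -2, 2),
                       runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
    res <- icp_refine(apply_transform(tube, M), tube, init = diag(4),
                      params = icp_params(max_iterations = 15,
                                          samples = 400, seed = i))
    expect_true(all(diff(res$rms_trace) <= 1e-12))
  }
})

test_that("ICP errors out when nothing is within the rejection distance", {
  cyl <- make_cylinder(n = 24, r = 6, h = 20)
  far <- apply_transform(cyl, euler_compose(tx = 500))
  expect_error(icp_refine(far, cyl, init = diag(4),
                          params = icp_params(rejection_distance = 5,
                                              samples = 100)),
               "no correspondences")
})

test_that("no surgery yields a null displacement record", {
  cs <- simulate_case(0, 0, response = response_model(sigma = 0),
                      noise = case_noise(landmark_sd = 0,
                                         scan_pose = FALSE), seed = 2)
  for (seg in c("maxilla", "mandible")) {
    rec <- compute_bone_displacement(cs$pre, cs$post, seg)
    expect_lt(max(abs(c(rec$tx, rec$ty, rec$tz, rec$pitch, rec$roll,
                        rec$yaw))), 1e-9)
  }
})

test_that("noise-free advancement is recovered to 0.05 mm", {
  cs <- simulate_case(5, -3, response = response_model(sigma = 0),
                      noise = case_noise(landmark_sd = 0), seed = 7)
  mx <- compute_bone_displacement(cs$pre, cs$post, "maxilla")
  md <- compute_bone_displacement(cs$pre, cs$post, "mandible")
  expect_equal(mx$ap, 5, tolerance = 0.05)
  expect_equal(md$ap, -3, tolerance = 0.05)
  expect_equal(mx$ap, mx$ty)       # AP is an alias of ty
})

test_that("setback with landmark noise stays within 0.5 mm (median, 100 seeds)", {
  errs <- vapply(1:100, function(i) {
    cs <- simulate_case(0, -3, response = response_model(sigma = 0),
                        noise = case_noise(landmark_sd = 0.3), seed = i)
    compute_bone_displacement(cs$pre, cs$post, "mandible")$ap - (-3)
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.5)
})

test_that("missing landmarks are reported by name", {
  cs <- simulate_case(2, 2, seed = 4)
  cs$post$landmarks$maxilla <-
    cs$post$landmarks$maxilla[1:3, , drop = FALSE]
  expect_error(compute_bone_displacement(cs$pre, cs$post, "maxilla"),
               "mx-canine-cusp-R")
})

test_that("airway alignment recovers a rigid motion of the model", {
  tube <- generate_airway(airway_profile(n_theta = 48, n_rings = 30),
                          seed = 5)
  lm <- generate_skull_landmarks(axes = attr(tube, "axes"), seed = 5)$airway
  # identity case
  al0 <- align_airway_models(tube, tube, lm, lm, params = NULL)
  expect_lt(max(abs(attr(al0, "transform")$matrix - diag(4))), 1e-9)
  # rigidly moved case
  M <- euler_compose(1, -0.5, 0.8, 2, -1, 1.5)
  moved <- apply_transform(tube, M)
  lm_moved <- ua_landmarks(apply_transform(unclass(lm), M), rownames(lm))
  al <- align_airway_models(tube, moved, lm, lm_moved,
                            params = icp_params(samples = 800))
  expect_lt(max(abs(al$vertices - tube$vertices)), 0.1)
})

test_that("posterior-wall alignment tolerates anterior deformation", {
  tube <- generate_airway(airway_profile(n_theta = 64, n_rings = 40),
                          seed = 9)
  axes <- attr(tube, "axes")
  lm <- generate_skull_landmarks(axes = axes, seed = 9)$airway
  # bulge the anterior wall (y above the section centre), keep posterior
  v <- tube$vertices
  bulge <- pmax(v[, 2], 0) * 0.25
  deformed <- tube; deformed$vertices[, 2] <- v[, 2] + bulge
  al <- align_airway_models(tube, deformed, lm, lm,
                            params = icp_params(samples = 1000))
  post_mask <- posterior_wall_mask(al)
  post_rms <- sqrt(mean((al$vertices[post_mask, ] -
                           tube$vertices[post_mask, ])^2))
  expect_lt(post_rms, 0.2)
})
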