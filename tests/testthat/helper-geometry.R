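# Fixtures built in code: canonical meshes and independent oracles.

# Capped right cylinder (n-gon prism) along z, built directly so it is
# independent of the package's own tube generator.
make_cylinder <- function(n = 720, r = 10, h = 50, z0 = 0,
                          rx = r, ry = r) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  vb <- cbind(rx * cos(phi), ry * sin(phi), z0)
  vt <- cbind(rx * cos(phi), ry * sin(phi), z0 + h)
  verts <- rbind(vb, vt, c(0, 0, z0), c(0, 0, z0 + h))
  lo <- 1:n; hi <- n + (1:n); nxt <- c(2:n, 1)
  faces <- rbind(cbind(lo, lo[nxt], hi[nxt]), cbind(lo, hi[nxt], hi),
                 cbind(2 * n + 1, lo[nxt], lo), cbind(2 * n + 2, hi, hi[nxt]))
  ua_mesh(verts, faces)
}

# exact cross-section area of the inscribed n-gon of an ellipse rx x ry
ngon_area <- function(n, rx, ry = rx) 0.5 * n * rx * ry * sin(2 * pi / n)

make_unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),      # z = 0, faces -z
    c(5, 6, 8), c(5, 8, 7),      # z = 1, faces +z
    c(1, 2, 6), c(1, 6, 5),      # y = 0
    c(3, 7, 8), c(3, 8, 4),      # y = 1
    c(1, 5, 7), c(1, 7, 3),      # x = 0
    c(2, 4, 8), c(2, 8, 6))      # x = 1
  ua_mesh(v, f)
}

# UV sphere centred at the origin
make_sphere <- function(r = 10, n_theta = 48, n_phi = 24) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ph <- seq(0, pi, length.out = n_phi + 1)[c(-1, -(n_phi + 1))]
  verts <- rbind(c(0, 0, r),
                 do.call(rbind, lapply(ph, function(p)
                   cbind(r * sin(p) * cos(th), r * sin(p) * sin(th),
                         r * cos(p)))),
                 c(0, 0, -r))
  nb <- length(ph)
  ring <- function(k) 1 + (k - 1) * n_theta + seq_len(n_theta)
  nxt <- c(2:n_theta, 1)
  faces <- list(cbind(1, ring(1), ring(1)[nxt]))
  for (k in seq_len(nb - 1)) {
    a <- ring(k); b <- ring(k + 1)
    faces[[length(faces) + 1]] <- cbind(a, b, b[nxt])
    faces[[length(faces) + 1]] <- cbind(a, b[nxt], a[nxt])
  }
  south <- 1 + nb * n_theta + 1
  faces[[length(faces) + 1]] <- cbind(south, ring(nb)[nxt], ring(nb))
  ua_mesh(verts, do.call(rbind, faces))
}

random_pose <- function() {
  euler_compose(stats::runif(1, -170, 170), stats::runif(1, -85, 85),
                stats::runif(1, -170, 170), stats::runif(1, -20, 20),
                stats::runif(1, -20, 20), stats::runif(1, -20, 20))
}

# Independent point-to-surface distance: exhaustive scan over faces with a
# constrained least-squares formulation per triangle (normal equations +
# closed-form edge projections), distinct from the package's kernel.
brute_surface_dist <- function(mesh, pts) {
  v <- mesh$vertices; f <- mesh$faces
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t_ <- sum((p - a) * ab) / sum(ab * ab)
    t_ <- min(max(t_, 0), 1)
    sqrt(sum((a + t_ * ab - p)^2))
  }
  apply(as.matrix(pts), 1, function(p) {
    min(apply(f, 1, function(tri) {
      a <- v[tri[1], ]; b <- v[tri[2], ]; c_ <- v[tri[3], ]
      e1 <- b - a; e2 <- c_ - a
      G <- rbind(c(sum(e1 * e1), sum(e1 * e2)),
                 c(sum(e1 * e2), sum(e2 * e2)))
      rhs <- c(sum((p - a) * e1), sum((p - a) * e2))
      st <- tryCatch(solve(G, rhs), error = function(e) c(-1, -1))
      if (st[1] >= 0 && st[2] >= 0 && sum(st) <= 1) {
        sqrt(sum((a + st[1] * e1 + st[2] * e2 - p)^2))
      } else {
        min(seg_dist(p, a, b), seg_dist(p, b, c_), seg_dist(p, a, c_))
      }
    }))
  })
}

# Independent silhouette-area oracle: pixel centres sampled over the slab's
# xy box; a pixel is in when a horizontal (+x) ray test finds any sampled z
# in [zlo, zhi] inside the solid. Deliberately uses a different ray
# direction and containment rule than the package kernel.
brute_slab_area <- function(mesh, zlo, zhi, pixel = 0.4, nz = 15) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], ]; b <- v[f[, 2], ]; c_ <- v[f[, 3], ]
  inside <- function(p) {
    # ray along +x: intersect triangles in the yz projection
    den <- (b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) -
      (c_[, 2] - a[, 2]) * (b[, 3] - a[, 3])
    u <- ((p[2] - a[, 2]) * (c_[, 3] - a[, 3]) -
            (c_[, 2] - a[, 2]) * (p[3] - a[, 3])) / den
    w <- ((b[, 2] - a[, 2]) * (p[3] - a[, 3]) -
            (p[2] - a[, 2]) * (b[, 3] - a[, 3])) / den
    hit <- is.finite(u) & u >= 0 & w >= 0 & (u + w) <= 1
    if (!any(hit)) return(FALSE)
    x <- a[hit, 1] + u[hit] * (b[hit, 1] - a[hit, 1]) +
      w[hit] * (c_[hit, 1] - a[hit, 1])
    sum(x > p[1]) %% 2 == 1
  }
  xs <- seq(min(v[, 1]), max(v[, 1]), by = pixel) + pixel * 0.503
  ys <- seq(min(v[, 2]), max(v[, 2]), by = pixel) + pixel * 0.503
  zs <- seq(zlo + 1e-3, zhi - 1e-3, length.out = nz)
  count <- 0L
  for (px in xs) for (py in ys) {
    if (any(vapply(zs, function(pz) inside(c(px, py, pz)), logical(1))))
      count <- count + 1L
  }
  count * pixel^2
}
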