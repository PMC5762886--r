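# Independent brute-force oracles and fixture builders used across tests.

rand_mask <- function(dims, p = 0.3, seed = 1) {
  set.seed(seed)
  VoxelMask(array(runif(prod(dims)) < p, dims), spacing = 1)
}

rand_volume <- function(dims, seed = 1, lo = 0, hi = 100) {
  set.seed(seed)
  VoxelVolume(array(runif(prod(dims), lo, hi), dims), spacing = 1)
}

# voxel-wise 26-neighbourhood dilation by explicit loops
oracle_dilate26 <- function(arr, iterations = 1L) {
  d <- dim(arr)
  for (it in seq_len(iterations)) {
    out <- array(FALSE, d)
    for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
      ii <- max(1, i - 1):min(d[1], i + 1)
      jj <- max(1, j - 1):min(d[2], j + 1)
      kk <- max(1, k - 1):min(d[3], k + 1)
      out[i, j, k] <- any(arr[ii, jj, kk])
    }
    arr <- out
  }
  arr
}

# breadth-first search for the 26-connected component containing seed
oracle_flood26 <- function(arr, seed_ijk) {
  d <- dim(arr)
  stopifnot(arr[seed_ijk[1], seed_ijk[2], seed_ijk[3]])
  vis <- array(FALSE, d)
  queue <- matrix(seed_ijk, 1)
  vis[seed_ijk[1], seed_ijk[2], seed_ijk[3]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      n <- cur + c(di, dj, dk)
      if (any(n < 1) || any(n > d)) next
      if (arr[n[1], n[2], n[3]] && !vis[n[1], n[2], n[3]]) {
        vis[n[1], n[2], n[3]] <- TRUE
        queue <- rbind(queue, n)
      }
    }
  }
  vis
}

# synchronous geodesic growth under the same acceptance predicate,
# written independently of the compiled implementation
oracle_smart_expand <- function(vol, seed, glo, ghi, cap, max_step) {
  d <- dim(vol)
  grad <- array(0, d)
  axdiff <- function(a, axis) {
    n <- dim(a)[axis]
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    den <- ifelse(seq_len(n) == 1L | seq_len(n) == n, 1, 2)
    if (n == 1L) den[] <- 1
    g <- switch(axis,
      (a[idx_p, , , drop = FALSE] - a[idx_m, , , drop = FALSE]),
      (a[, idx_p, , drop = FALSE] - a[, idx_m, , drop = FALSE]),
      (a[, , idx_p, drop = FALSE] - a[, , idx_m, drop = FALSE]))
    if (dim(a)[axis] == 1L) g[] <- 0
    sweep_den <- array(1, d)
    if (axis == 1) sweep_den[] <- den[slice.index(sweep_den, 1)]
    if (axis == 2) sweep_den[] <- den[slice.index(sweep_den, 2)]
    if (axis == 3) sweep_den[] <- den[slice.index(sweep_den, 3)]
    g / sweep_den
  }
  grad <- sqrt(axdiff(vol, 1)^2 + axdiff(vol, 2)^2 + axdiff(vol, 3)^2)
  ok <- vol >= glo & vol <= ghi & grad <= cap
  region <- seed
  for (s in seq_len(max_step)) {
    grown <- oracle_dilate26(region, 1L)
    add <- grown & !region & ok
    if (!any(add)) break
    region <- region | add
  }
  region
}

# exact closest point on a triangle (barycentric clamping), exhaustive
# over all triangles
oracle_point_tri <- function(p, a, b, cc) {
  ab <- b - a; ac <- cc - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + d1 / (d1 - d3) * ab)
  cp <- p - cc
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(cc)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + d2 / (d2 - d6) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (d4 - d3) / ((d4 - d3) + (d5 - d6)) * (cc - b))
  den <- va + vb + vc
  a + ab * (vb / den) + ac * (vc / den)
}

oracle_mesh_distance <- function(p, mesh) {
  V <- vertices(mesh); F <- triangles(mesh)
  best <- Inf
  for (f in seq_len(nrow(F))) {
    q <- oracle_point_tri(p, V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ])
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}

# every edge shared by exactly two triangles
is_watertight <- function(mesh) {
  F <- triangles(mesh)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

# axis-aligned box surface mesh (12 triangles, outward normals)
box_mesh <- function(sizes = c(1, 1, 1), center = c(0, 0, 0)) {
  h <- sizes / 2
  V <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                             z = c(-h[3], h[3])))
  V <- sweep(V, 2, center, "+")
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z-
    c(5, 6, 7), c(6, 8, 7),   # z+
    c(1, 2, 5), c(2, 6, 5),   # y-
    c(3, 7, 4), c(4, 7, 8),   # y+
    c(1, 5, 3), c(3, 5, 7),   # x-
    c(2, 4, 6), c(4, 8, 6))   # x+
  TriangleMesh(V, F)
}

# closed cylinder mesh along +z from z0 to z0+height
cylinder_mesh <- function(radius = 3, height = 20, z0 = 0, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ring0 <- cbind(radius * cos(th), radius * sin(th), z0)
  ring1 <- cbind(radius * cos(th), radius * sin(th), z0 + height)
  V <- rbind(ring0, ring1, c(0, 0, z0), c(0, 0, z0 + height))
  c0 <- 2 * n + 1; c1 <- 2 * n + 2
  F <- NULL
  for (i in seq_len(n)) {
    j <- i %% n + 1
    F <- rbind(F,
      c(i, j, n + i), c(j, n + j, n + i),       # side
      c(j, i, c0),                               # bottom cap
      c(n + i, n + j, c1))                       # top cap
  }
  TriangleMesh(V, F)
}

# digitized solid sphere mask
sphere_mask <- function(r_vox = 10, spacing = 0.3) {
  n <- 2L * as.integer(ceiling(r_vox)) + 5L
  ctr <- (n - 1) / 2
  idx <- expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1))
  inside <- (idx$i - ctr)^2 + (idx$j - ctr)^2 + (idx$k - ctr)^2 <= r_vox^2
  VoxelMask(array(inside, c(n, n, n)), spacing = spacing)
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
rand_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# independent R implementation of the capped round-cone signed distance
# (surface oracle for the phantom ground-truth mesh)
oracle_root_sdf <- function(spec, pts) {
  sc <- pdlroot:::.phantomScene(spec)
  cones <- sc$root_cones
  one_cone <- function(p, cn) {
    A <- cn[1:3]; B <- cn[4:6]; ra <- cn[7]; rb <- cn[8]
    u <- B - A; h <- sqrt(sum(u^2)); u <- u / h
    w <- p - A
    z <- sum(w * u)
    q <- sqrt(max(0, sum(w^2) - z^2))
    bb <- (ra - rb) / h
    aa <- sqrt(max(0, 1 - bb^2))
    k <- q * (-bb) + z * aa
    if (k < 0) sqrt(q^2 + z^2) - ra
    else if (k > aa * h) sqrt(q^2 + (z - h)^2) - rb
    else q * aa + z * bb - ra
  }
  apply(as.matrix(pts), 1, function(p) {
    d <- min(vapply(seq_len(nrow(cones)), function(i) one_cone(p, cones[i, ]),
                    numeric(1)))
    max(d, p[3] - sc$z_cej)
  })
}

# analytic root solid volume by 1D quadrature of the cross-section area
oracle_root_volume <- function(spec) {
  sc <- pdlroot:::.phantomScene(spec)
  stopifnot(nrow(sc$root_cones) == 1)
  cn <- sc$root_cones[1, ]
  za <- cn[3]; zb <- cn[6]; ra <- cn[7]; rb <- cn[8]
  h <- zb - za
  bb <- (ra - rb) / h
  aa <- sqrt(1 - bb^2)
  rho <- function(z) {
    cand <- numeric(0)
    if (abs(z - za) <= ra) cand <- c(cand, sqrt(ra^2 - (z - za)^2))
    if (abs(z - zb) <= rb) cand <- c(cand, sqrt(rb^2 - (z - zb)^2))
    # lateral cone surface: q*aa + (z-za)*bb = ra, within tangent band
    q <- (ra - (z - za) * bb) / aa
    k <- q * (-bb) + (z - za) * aa
    if (q >= 0 && k >= 0 && k <= aa * h) cand <- c(cand, q)
    if (length(cand)) max(cand) else 0
  }
  f <- Vectorize(function(z) pi * rho(z)^2)
  stats::integrate(f, za - ra, sc$z_cej, subdivisions = 2000L,
                   rel.tol = 1e-8)$value
}

# ---- minimal DICOM slice writer (explicit VR little endian) --------------
# independent byte-level fixture builder for the reader tests

dcm_write_slice <- function(path, mat, spacing_xy = c(0.3, 0.3),
                            position = c(0, 0, 0), slope = 1, intercept = 0) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  w_elem <- function(group, elem, vr, payload) {
    writeBin(as.integer(c(group %% 256, group %/% 256, elem %% 256, elem %/% 256)),
             con, size = 1)
    writeBin(charToRaw(vr), con)
    if (vr %in% c("OB", "OW")) {
      writeBin(as.raw(c(0, 0)), con)
      writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(length(payload)), con, size = 2, endian = "little")
    }
    writeBin(payload, con)
  }
  str_pad <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
    r
  }
  u16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  # meta group: transfer syntax explicit VR little endian
  w_elem(0x0002, 0x0010, "UI", str_pad("1.2.840.10008.1.2.1"))
  nx <- nrow(mat); ny <- ncol(mat)   # mat is [x, y]
  w_elem(0x0008, 0x0060, "CS", str_pad("CT"))
  w_elem(0x0020, 0x0032, "DS", str_pad(paste(position, collapse = "\\")))
  w_elem(0x0028, 0x0010, "US", u16_raw(ny))             # Rows
  w_elem(0x0028, 0x0011, "US", u16_raw(nx))             # Columns
  w_elem(0x0028, 0x0030, "DS",
         str_pad(paste(c(spacing_xy[2], spacing_xy[1]), collapse = "\\")))
  w_elem(0x0028, 0x0100, "US", u16_raw(16))             # BitsAllocated
  w_elem(0x0028, 0x0103, "US", u16_raw(0))              # unsigned
  w_elem(0x0028, 0x1052, "DS", str_pad(format(intercept)))
  w_elem(0x0028, 0x1053, "DS", str_pad(format(slope)))
  # PixelData: row-major in file (row = y, column = x varies fastest);
  # mat is [x, y], so column-major order of mat is the file order
  px <- as.integer(as.vector(mat))
  w_elem(0x7FE0, 0x0010, "OW", writeBin(px, raw(), size = 2, endian = "little"))
  invisible(path)
}
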