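# Accuracy methodology: rigid registration, CEJ cutting, RMS surface
# deviation, local-frame bounding-box dimensions and errors.

#' Apply a rigid transform to a mesh
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param tf a \linkS4class{RigidTransform}.
#' @return the transformed \linkS4class{TriangleMesh}.
#' @export
applyTransform <- function(mesh, tf) {
  V <- mesh@vertices %*% t(tf@rotation)
  V <- sweep(V, 2, tf@translation, "+")
  TriangleMesh(V, mesh@triangles, dropDegenerate = FALSE)
}

#' Identity rigid transform
#' @return a \linkS4class{RigidTransform}.
#' @export
identityTransform <- function() new("RigidTransform", rotation = diag(3),
                                    translation = c(0, 0, 0))

# Kabsch: best rotation/translation mapping P onto Q (both n x 3)
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cq - R %*% cp))
}

#' Rigid ICP registration of a test mesh onto a reference mesh
#'
#' Iterative closest point with point-to-surface correspondences (closest
#' point on the reference triangles) and a Kabsch update. Initialization:
#' centroid alignment plus principal-axes alignment, with the axis-sign
#' ambiguity resolved by trying the four proper-rotation flips and keeping
#' the one with the lowest mean distance. Converged when the mean-distance
#' improvement falls below `tol` or after `maxIters` iterations.
#'
#' @param test,reference \linkS4class{TriangleMesh} objects with at least 3
#'   non-collinear vertices.
#' @param nPoints number of test vertices used as ICP samples (all if
#'   fewer; seeded uniform subsample otherwise).
#' @param maxIters,tol convergence controls (mm).
#' @param rngSeed seed for the vertex subsample.
#' @return a \linkS4class{RigidTransform} mapping test into the reference
#'   frame.
#' @export
registerICP <- function(test, reference, nPoints = 2000L, maxIters = 50L,
                        tol = 1e-7, rngSeed = 1L) {
  for (m in list(test, reference)) {
    V <- m@vertices
    if (nrow(V) < 3L) stop("mesh has fewer than 3 vertices")
    sv <- svd(sweep(V, 2, colMeans(V)))$d
    if (sv[2] < 1e-9 * max(sv[1], 1)) stop("mesh vertices are collinear")
  }
  P0 <- test@vertices
  if (nrow(P0) > nPoints) {
    keep <- .withLocalSeed(rngSeed, sample.int(nrow(P0), nPoints))
    P0 <- P0[keep, , drop = FALSE]
  }
  Vr <- reference@vertices
  cp <- colMeans(P0); cq <- colMeans(Vr)
  Et <- svd(cov(P0))$u
  Er <- svd(cov(Vr))$u
  if (det(Et) < 0) Et[, 3] <- -Et[, 3]
  if (det(Er) < 0) Er[, 3] <- -Er[, 3]
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  inits <- lapply(flips, function(fl) {
    R0 <- Er %*% diag(fl) %*% t(Et)
    list(R = R0, t = as.numeric(cq - R0 %*% cp))
  })
  # meshes already in a shared frame (the common case in this pipeline)
  # compete against the principal-axes candidates
  inits <- c(inits, list(list(R = diag(3), t = c(0, 0, 0))))
  best <- NULL
  for (ini in inits) {
    P <- sweep(P0 %*% t(ini$R), 2, ini$t, "+")
    d <- mean(.cpp_mesh_nearest(P, Vr, reference@triangles)$distance)
    if (is.null(best) || d < best$d) best <- list(R = ini$R, t = ini$t, d = d)
  }
  R <- best$R; tt <- best$t
  prev <- Inf
  for (it in seq_len(maxIters)) {
    P <- sweep(P0 %*% t(R), 2, tt, "+")
    nn <- .cpp_mesh_nearest(P, Vr, reference@triangles)
    d <- mean(nn$distance)
    if (prev - d < tol) break
    prev <- d
    k <- .kabsch(P0, nn$closest)
    R <- k$R; tt <- k$t
  }
  new("RigidTransform", rotation = R, translation = tt)
}

# clip a mesh by the plane dot(x - point, normal) >= 0, splitting
# straddling triangles at the plane
.clipMeshPlane <- function(mesh, point, normal) {
  V <- mesh@vertices
  F <- mesh@triangles
  s <- as.numeric(sweep(V, 2, point) %*% normal)
  keepV <- s >= 0
  triS <- matrix(keepV[F], ncol = 3)
  nIn <- rowSums(triS)
  newV <- list(V)
  newF <- list(F[nIn == 3L, , drop = FALSE])
  nv <- nrow(V)
  edgeCache <- new.env(hash = TRUE)
  cut_edge <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- edgeCache[[key]]
    if (!is.null(hit)) return(hit)
    t <- s[i] / (s[i] - s[j])
    p <- V[i, ] + t * (V[j, ] - V[i, ])
    nv <<- nv + 1L
    newV[[length(newV) + 1L]] <<- matrix(p, 1, 3)
    edgeCache[[key]] <- nv
    nv
  }
  for (f in which(nIn == 1L | nIn == 2L)) {
    idx <- F[f, ]
    inside <- idx[keepV[idx]]
    outside <- idx[!keepV[idx]]
    if (length(inside) == 1L) {
      # rotate so order is preserved: inside a, cut(a,b), cut(a,c)
      a <- inside
      rest <- idx[idx != a]
      # keep original winding: find position of a
      pos <- which(idx == a)
      b <- idx[pos %% 3L + 1L]
      c2 <- idx[(pos + 1L) %% 3L + 1L]
      p1 <- cut_edge(a, b)
      p2 <- cut_edge(a, c2)
      newF[[length(newF) + 1L]] <- matrix(c(a, p1, p2), 1, 3)
    } else {
      a <- outside
      pos <- which(idx == a)
      b <- idx[pos %% 3L + 1L]
      c2 <- idx[(pos + 1L) %% 3L + 1L]
      p1 <- cut_edge(a, b)   # on edge a-b
      p2 <- cut_edge(a, c2)  # on edge a-c
      newF[[length(newF) + 1L]] <- matrix(c(p1, b, c2), 1, 3)
      newF[[length(newF) + 1L]] <- matrix(c(p1, c2, p2), 1, 3)
    }
  }
  Vall <- do.call(rbind, newV)
  Fall <- do.call(rbind, newF)
  used <- sort(unique(as.vector(Fall)))
  remap <- integer(nrow(Vall))
  remap[used] <- seq_along(used)
  TriangleMesh(Vall[used, , drop = FALSE],
               matrix(remap[Fall], ncol = 3), dropDegenerate = TRUE)
}

#' Cut reference and test meshes at the CEJ
#'
#' Fits a least-squares plane to the cemento-enamel-junction curve and
#' retains, for both meshes, the sub-mesh on the apical side of that plane;
#' triangles straddling the plane are split at the plane. Using one common
#' plane for both registered models preserves comparability of the cut
#' parts.
#'
#' @param reference,test registered \linkS4class{TriangleMesh} objects.
#' @param cej k x 3 matrix (mm) of CEJ curve points, k >= 3, treated as a
#'   closed loop.
#' @param apicalDirection unit vector pointing from crown toward apex
#'   (default -z, the phantom convention).
#' @return list with elements `reference` and `test` (cut meshes), plus
#'   `plane` (list with point/normal).
#' @export
cutAtCEJ <- function(reference, test, cej, apicalDirection = c(0, 0, -1)) {
  cej <- as.matrix(cej)
  if (ncol(cej) != 3L || nrow(cej) < 3L)
    stop("cej must be a closed loop of at least 3 points (k x 3 matrix)")
  ctr <- colMeans(cej)
  normal <- svd(sweep(cej, 2, ctr))$v[, 3]
  if (sum(normal * apicalDirection) < 0) normal <- -normal
  onApical <- function(m) sweep(m@vertices, 2, ctr) %*% normal >= 0
  if (all(onApical(reference)) && all(onApical(test)))
    warning("CEJ plane does not intersect either mesh; nothing was cut")
  refCut <- .clipMeshPlane(reference, ctr, normal)
  testCut <- .clipMeshPlane(test, ctr, normal)
  list(reference = refCut, test = testCut,
       plane = list(point = ctr, normal = normal))
}

#' Nearest-point RMS surface deviation
#'
#' Samples points from the test-mesh vertices (all vertices when there are
#' at most `nSamples`, matching reference-model vertex counts of a few
#' thousand; otherwise a seeded uniform subsample), computes for each the
#' unsigned nearest distance Xi to the reference surface, and returns
#' RMS = sqrt(sum(Xi^2)/N). Signed distances (side of the reference
#' surface by the nearest-triangle normal) are included for colour-map
#' display. Note the measure is directional: swapping test and reference
#' changes the sample points.
#'
#' @param test,reference registered (and, for root evaluation, CEJ-cut)
#'   \linkS4class{TriangleMesh} objects.
#' @param nSamples target sample count (default 10000).
#' @param rngSeed subsample seed.
#' @return a \linkS4class{DeviationResult}.
#' @export
deviationRMS <- function(test, reference, nSamples = 10000L, rngSeed = 1L) {
  if (nrow(test@vertices) == 0L || nrow(reference@triangles) == 0L)
    stop("empty mesh")
  if (nSamples < 1L) stop("nSamples must be >= 1")
  P <- test@vertices
  if (nrow(P) > nSamples) {
    keep <- .withLocalSeed(rngSeed, sample.int(nrow(P), nSamples))
    P <- P[keep, , drop = FALSE]
  }
  nn <- .cpp_mesh_nearest(P, reference@vertices, reference@triangles)
  Fr <- reference@triangles
  Vr <- reference@vertices
  tri <- nn$triangle
  a <- Vr[Fr[tri, 1], , drop = FALSE]
  b <- Vr[Fr[tri, 2], , drop = FALSE]
  cc <- Vr[Fr[tri, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sgn <- sign(rowSums((P - nn$closest) * nrm))
  sgn[sgn == 0] <- 1
  d <- nn$distance
  new("DeviationResult", distances = d, signed = sgn * d,
      rms = sqrt(mean(d^2)))
}

#' Build the per-tooth local coordinate frame
#'
#' Z is the principal component of the vertex covariance with the largest
#' variance (the root-length direction), oriented so that the vertex
#' centroid — which sits toward the bulky coronal end — lies on the
#' positive side (apex negative, crown positive). X (bucco-lingual) is the
#' component of `buccalHint` orthogonal to Z, or the second principal
#' component when no hint is given; Y = Z x X completes a right-handed
#' orthonormal triad. The origin is the vertex centroid.
#'
#' @param mesh a non-degenerate \linkS4class{TriangleMesh}.
#' @param buccalHint optional approximate bucco-lingual direction.
#' @param axisOverride optional \linkS4class{LocalFrame} returned verbatim.
#' @return a \linkS4class{LocalFrame}.
#' @export
buildLocalFrame <- function(mesh, buccalHint = NULL, axisOverride = NULL) {
  if (!is.null(axisOverride)) {
    stopifnot(is(axisOverride, "LocalFrame"))
    return(axisOverride)
  }
  V <- mesh@vertices
  if (nrow(V) < 3L) stop("mesh is degenerate (fewer than 3 vertices)")
  ctr <- colMeans(V)
  C <- sweep(V, 2, ctr)
  sv <- svd(cov(C))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("mesh vertices are collinear; cannot build a frame")
  z <- sv$u[, 1]
  proj <- as.numeric(C %*% z)
  if (mean(proj) < (max(proj) + min(proj)) / 2) z <- -z
  if (!is.null(buccalHint)) {
    x <- buccalHint - sum(buccalHint * z) * z
    if (sqrt(sum(x^2)) < 1e-9) stop("buccalHint is parallel to the long axis")
    x <- x / sqrt(sum(x^2))
  } else {
    x <- sv$u[, 2]
    # deterministic sign: largest-magnitude component positive
    if (x[which.max(abs(x))] < 0) x <- -x
  }
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  new("LocalFrame", axes = cbind(x, y, z, deparse.level = 0), origin = ctr)
}

#' Maximum bounding-box dimensions in a local frame
#'
#' Extent (max minus min) of the vertex projections onto the frame's X
#' (bucco-lingual), Y (mesio-distal) and Z (root length) axes.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param frame a \linkS4class{LocalFrame}.
#' @return named numeric vector `c(bl=, md=, rl=)` in mm.
#' @export
boundingBoxDims <- function(mesh, frame) {
  P <- mesh@vertices %*% frame@axes
  ext <- apply(P, 2, function(x) max(x) - min(x))
  c(bl = ext[1], md = ext[2], rl = ext[3])
}

#' Dimensional errors between reference and test measurements
#'
#' Error = reference minus test per axis, so a negative error means the
#' test model is larger than the reference.
#'
#' @param ref,test named vectors as returned by [boundingBoxDims()].
#' @return one-row data.frame with columns bl_1, bl_2, bl_error, md_1,
#'   md_2, md_error, rl_1, rl_2, rl_error (mm).
#' @export
sizeErrors <- function(ref, test) {
  data.frame(bl_1 = ref[["bl"]], bl_2 = test[["bl"]],
             bl_error = ref[["bl"]] - test[["bl"]],
             md_1 = ref[["md"]], md_2 = test[["md"]],
             md_error = ref[["md"]] - test[["md"]],
             rl_1 = ref[["rl"]], rl_2 = test[["rl"]],
             rl_error = ref[["rl"]] - test[["rl"]])
}
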