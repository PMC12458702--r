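# Minimal 3-D convex hull (incremental construction) used to bound the
# pocket-volume grid. Input points must span 3-D space; degenerate
# (coplanar) inputs raise an error. Facet normals are unit length and
# outward-oriented: a point x is inside iff normal . x <= offset for all
# facets (within tolerance).

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

hull3d <- function(P, tol = 1e-9) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (n < 4L) stop("convex hull needs >= 4 points")
  # initial tetrahedron from extreme points
  i1 <- which.min(P[, 1])
  d1 <- rowSums(sweep(P, 2L, P[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] < tol) stop("degenerate point set (all coincident)")
  e <- P[i2, ] - P[i1, ]
  w <- sweep(P, 2L, P[i1, ])
  cr <- t(apply(w, 1L, function(x) cross3(e, x)))
  d2 <- rowSums(cr^2)
  i3 <- which.max(d2)
  if (d2[i3] < tol) stop("degenerate point set (collinear)")
  nrm <- cross3(e, P[i3, ] - P[i1, ])
  d3 <- abs(w %*% nrm)
  i4 <- which.max(d3)
  if (d3[i4] < tol) stop("degenerate point set (coplanar)")
  interior <- colMeans(P[c(i1, i2, i3, i4), ])
  make_facet <- function(a, b, c) {
    nn <- cross3(P[b, ] - P[a, ], P[c, ] - P[a, ])
    nn <- nn / sqrt(sum(nn^2))
    if (sum(nn * (interior - P[a, ])) > 0) nn <- -nn
    list(v = c(a, b, c), normal = nn, offset = sum(nn * P[a, ]))
  }
  facets <- list(make_facet(i1, i2, i3), make_facet(i1, i2, i4),
                 make_facet(i1, i3, i4), make_facet(i2, i3, i4))
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    sig <- vapply(facets, function(f) sum(f$normal * P[p, ]) - f$offset, 1.0)
    vis <- which(sig > tol)
    if (length(vis) == 0L) next
    edges <- do.call(rbind, lapply(facets[vis], function(f) {
      rbind(sort(f$v[1:2]), sort(f$v[2:3]), sort(f$v[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    facets <- facets[-vis]
    for (r in seq_len(nrow(horizon))) {
      facets[[length(facets) + 1L]] <-
        make_facet(horizon[r, 1], horizon[r, 2], p)
    }
  }
  list(normals = do.call(rbind, lapply(facets, `[[`, "normal")),
       offsets = vapply(facets, `[[`, 1.0, "offset"),
       vertices = sort(unique(unlist(lapply(facets, `[[`, "v")))))
}

# logical vector: which rows of `points` lie inside the hull
# (chunked so the points x facets matrix stays small)
in_hull3d <- function(points, hull, tol = 1e-9, chunk = 20000L) {
  n <- nrow(points)
  out <- logical(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    S <- points[lo:hi, , drop = FALSE] %*% t(hull$normals)
    out[lo:hi] <- rowSums(sweep(S, 2L, hull$offsets) > tol) == 0L
  }
  out
}
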