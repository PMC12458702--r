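#' @name superpose
#' @rdname superpose
NULL

# Kabsch least-squares fit: returns the proper rotation R (det +1) and
# translation mapping P onto Q after centering. Internal workhorse for all
# superposition-based metrics.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, center_p = cp, center_q = cq)
}

apply_fit <- function(P, fit) {
  sweep(sweep(P, 2L, fit$center_p) %*% t(fit$R), 2L, fit$center_q, `+`)
}

#' Rigid-body superposition of one frame onto another
#'
#' Least-squares (Kabsch) superposition over a residue selection, the
#' operator implied by C-alpha RMSD comparisons of conformations. The
#' rotation is always proper (determinant +1).
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices of the same
#'   ensemble (or compatible atom order).
#' @param sel integer atom indices used for the fit (default: all rows).
#'   At least 3 non-collinear atoms are required.
#' @return list with `coords` (the whole mobile frame after the fitted rigid
#'   motion) and `rmsd` (Angstrom, over `sel`).
#' @export
superpose <- function(mobile, reference, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(nrow(mobile))
  if (length(sel) < 3L) stop("superposition needs >= 3 selected atoms")
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selection size mismatch between frames")
  Pc <- sweep(P, 2L, colMeans(P))
  if (qr(Pc)$rank < 2L) stop("degenerate (collinear) selection geometry")
  fit <- kabsch(P, Q)
  moved <- apply_fit(mobile, fit)
  dd <- moved[sel, , drop = FALSE] - Q
  list(coords = moved, rmsd = sqrt(mean(rowSums(dd * dd))))
}

#' Pairwise C-alpha RMSD between two frames
#' @inheritParams superpose
#' @param fit superpose before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
frame_rmsd <- function(mobile, reference, sel = NULL, fit = TRUE) {
  if (is.null(sel)) sel <- seq_len(nrow(mobile))
  if (fit) return(superpose(mobile, reference, sel)$rmsd)
  dd <- mobile[sel, , drop = FALSE] - reference[sel, , drop = FALSE]
  sqrt(mean(rowSums(dd * dd)))
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2), optionally after iteratively
#' superposing every frame onto the mean structure of the selection.
#'
#' @param ens an [ensemble()] with >= 2 frames.
#' @param residues 0-based residue indices (default: all CA residues).
#' @param fit superpose frames onto the mean structure first (default TRUE).
#' @return named numeric vector, Angstrom, one value per selected residue.
#' @export
rmsf <- function(ens, residues = NULL, fit = TRUE) {
  nfr <- n_frames(ens)
  if (nfr < 2L) stop("RMSF needs >= 2 frames")
  sel <- ca_indices(ens, residues)
  if (length(sel) == 0L) stop("empty selection")
  X <- ens$coords[sel, , , drop = FALSE]
  if (fit) {
    ref <- X[, , 1L, drop = TRUE]
    for (pass in 1:2) {
      fitted <- X
      for (k in seq_len(nfr)) {
        f <- kabsch(X[, , k, drop = TRUE], ref)
        fitted[, , k] <- apply_fit(X[, , k, drop = TRUE], f)
      }
      ref <- apply(fitted, c(1L, 2L), mean)
      X <- fitted
    }
  }
  mean_xyz <- apply(X, c(1L, 2L), mean)
  dev2 <- sweep(X, c(1L, 2L), mean_xyz)^2
  vals <- sqrt(apply(dev2, 1L, sum) / nfr)
  names(vals) <- ens$atoms$residue_index[sel]
  vals
}

#' Radius of gyration of a frame
#'
#' Mass-weighted Rg; unit masses are used when no masses are supplied, and
#' the choice is recorded in the result's `"weighting"` attribute.
#'
#' @param frame `n x 3` coordinate matrix (or an [ensemble()], in which case
#'   `frame_index` picks the frame).
#' @param sel integer atom indices (default all).
#' @param masses optional atomic masses.
#' @param frame_index frame to use when `frame` is an ensemble.
#' @return Rg in Angstrom with attribute `weighting`.
#' @export
radius_of_gyration <- function(frame, sel = NULL, masses = NULL,
                               frame_index = 1L) {
  if (inherits(frame, "ensemble")) frame <- get_frame(frame, frame_index)
  if (is.null(sel)) sel <- seq_len(nrow(frame))
  if (length(sel) == 0L) stop("empty selection")
  X <- frame[sel, , drop = FALSE]
  m <- if (is.null(masses)) rep(1, nrow(X)) else masses[sel]
  com <- colSums(X * m) / sum(m)
  d2 <- rowSums(sweep(X, 2L, com)^2)
  rg <- sqrt(sum(m * d2) / sum(m))
  attr(rg, "weighting") <- if (is.null(masses)) "unit" else "mass"
  rg
}

#' Agglomerative clustering of frames on superposed C-alpha RMSD
#'
#' Average-linkage hierarchical clustering of all frames on the pairwise
#' superposed C-alpha RMSD matrix; merging stops once the smallest
#' average-linkage distance exceeds `epsilon`. Each cluster's representative
#' is the frame minimising the sum of within-cluster distances (ties broken
#' by lowest frame index); clusters are reported by population, descending.
#'
#' @param ens an [ensemble()] with >= 2 frames.
#' @param residues optional 0-based residue restriction for the RMSD metric.
#' @param epsilon merge cutoff in Angstrom (default 3.0).
#' @param linkage only `"average"` is supported.
#' @return object of class `cluster_result`: `assignments` (per frame),
#'   `representatives` data.frame (`frame`, `cluster`, `population`), and
#'   the pairwise `dist` matrix used.
#' @export
cluster_frames <- function(ens, residues = NULL, epsilon = 3.0,
                           linkage = c("average")) {
  linkage <- match.arg(linkage)
  if (epsilon <= 0) stop("epsilon must be > 0")
  nfr <- n_frames(ens)
  if (nfr < 2L) stop("clustering needs >= 2 frames")
  sel <- ca_indices(ens, residues)
  if (length(sel) < 3L) stop("need >= 3 CA atoms for the RMSD metric")
  D <- matrix(0, nfr, nfr)
  for (i in seq_len(nfr - 1L)) {
    Fi <- ens$coords[sel, , i, drop = TRUE]
    for (j in (i + 1L):nfr) {
      D[i, j] <- D[j, i] <- superpose(ens$coords[sel, , j, drop = TRUE], Fi)$rmsd
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  assign_raw <- stats::cutree(hc, h = epsilon)
  # order clusters by population (descending), ties by first occurrence
  tab <- sort(table(assign_raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(tab), names(tab))
  assignments <- as.integer(relabel[as.character(assign_raw)])
  reps <- lapply(seq_along(tab), function(cl) {
    members <- which(assignments == cl)
    score <- rowSums(D[members, members, drop = FALSE])
    members[which.min(score)]   # which.min returns first minimum: lowest index
  })
  representatives <- data.frame(
    frame = unlist(reps),
    cluster = seq_along(tab),
    population = as.numeric(tab) / nfr)
  structure(list(assignments = assignments,
                 representatives = representatives,
                 dist = D, epsilon = epsilon, linkage = linkage),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", nrow(x$representatives), "cluster(s) at epsilon",
      x$epsilon, "A (", x$linkage, "linkage )\n")
  print(x$representatives, row.names = FALSE)
  invisible(x)
}
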