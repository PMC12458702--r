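#' Canonical geometric descriptor names
#'
#' Thirteen descriptors of the multi-domain architecture: eight distances
#' between domain centres of mass (including the composite lobes N+PAZ and
#' MID+PIWI and the helix-7 sub-selection) and five angles subtended at the
#' whole-molecule centre of mass.
#'
#' @return character vector of length 13, in fixed column order.
#' @export
descriptor_names <- function() {
  c("d_PAZ_PIWI", "d_PAZ_N", "d_PIWI_N", "d_PAZ_MID", "d_NPAZ_MIDPIWI",
    "d_PIWI_L2", "d_PAZ_helix7", "d_L1_L2",
    "a_PAZ_PIWI", "a_PAZ_N", "a_PIWI_N", "a_PAZ_MID", "a_NPAZ_MIDPIWI")
}

#' Default descriptor specification for the canonical domain names
#' @return list of `list(name, type, groups)`, one per descriptor.
#' @export
default_pair_spec <- function() {
  d <- function(a, b) list(name = paste("d", a, b, sep = "_"),
                           type = "distance", groups = c(a, b))
  a <- function(x, y) list(name = paste("a", x, y, sep = "_"),
                           type = "angle", groups = c(x, y))
  list(d("PAZ", "PIWI"), d("PAZ", "N"), d("PIWI", "N"), d("PAZ", "MID"),
       d("NPAZ", "MIDPIWI"), d("PIWI", "L2"), d("PAZ", "helix7"),
       d("L1", "L2"),
       a("PAZ", "PIWI"), a("PAZ", "N"), a("PIWI", "N"), a("PAZ", "MID"),
       a("NPAZ", "MIDPIWI"))
}

# Resolve a group name (domain, composite lobe NPAZ / MIDPIWI, or helix7)
# to 0-based residue indices.
composite_selection <- function(name, ens, helix7 = NULL) {
  doms <- ens$partition$domains
  if (name %in% names(doms)) return(doms[[name]])
  if (name == "NPAZ") return(sort(c(doms[["N"]], doms[["PAZ"]])))
  if (name == "MIDPIWI") return(sort(c(doms[["MID"]], doms[["PIWI"]])))
  if (name == "helix7") {
    h <- if (!is.null(helix7)) helix7 else ens$metadata$helix7
    if (is.null(h)) stop("helix7 selection not defined; supply residue indices")
    return(h)
  }
  stop("unknown group '", name, "' (not a domain of the partition)")
}

#' Per-frame geometric descriptors of a multi-domain ensemble
#'
#' Computes, for every frame, centre-of-mass (unweighted C-alpha centroid)
#' distances and angles between domains. Angles are measured at the
#' whole-selection centre of mass: the angle subtended there by the two
#' domain centroids, in degrees.
#'
#' @param ens an [ensemble()] with a [domain_partition()].
#' @param pair_spec descriptor specification (default [default_pair_spec()]).
#' @param helix7 optional 0-based residue indices of the helix-7
#'   sub-selection (default: `ens$metadata$helix7`).
#' @return object of class `descriptor_matrix`: `values` (frames x
#'   descriptors), `labels` (per-frame ensemble label), `descriptor_names`.
#' @export
compute_descriptors <- function(ens, pair_spec = default_pair_spec(),
                                helix7 = NULL) {
  if (is.null(ens$partition)) stop("ensemble has no domain partition")
  groups <- unique(unlist(lapply(pair_spec, `[[`, "groups")))
  sel_list <- lapply(groups, function(g) {
    res <- composite_selection(g, ens, helix7)
    idx <- ca_indices(ens, res)
    if (length(idx) == 0L) stop("group '", g, "' selects no CA atoms")
    idx
  })
  names(sel_list) <- groups
  all_ca <- ca_indices(ens)
  nfr <- n_frames(ens)
  vals <- matrix(NA_real_, nfr, length(pair_spec))
  colnames(vals) <- vapply(pair_spec, `[[`, "", "name")
  for (k in seq_len(nfr)) {
    fr <- ens$coords[, , k, drop = TRUE]
    com <- lapply(sel_list, function(ix) colMeans(fr[ix, , drop = FALSE]))
    gcom <- colMeans(fr[all_ca, , drop = FALSE])
    for (j in seq_along(pair_spec)) {
      ps <- pair_spec[[j]]
      A <- com[[ps$groups[1]]]; B <- com[[ps$groups[2]]]
      if (ps$type == "distance") {
        vals[k, j] <- sqrt(sum((A - B)^2))
      } else {
        u <- A - gcom; v <- B - gcom
        nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
        if (nu < 1e-9 || nv < 1e-9) {
          stop("degenerate geometry: domain COM coincides with the vertex")
        }
        vals[k, j] <- acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
      }
    }
  }
  structure(list(values = vals,
                 labels = rep(ens$label, nfr),
                 descriptor_names = colnames(vals)),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("descriptor_matrix:", nrow(x$values), "frames x",
      ncol(x$values), "descriptors; labels:",
      paste(unique(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Standardised PCA of pooled descriptor matrices
#'
#' Pools the per-frame descriptors of all supplied ensembles, mean-centres
#' and scales each column to unit variance over the pooled data, and
#' performs PCA (correlation-matrix PCA). Component signs are fixed so the
#' largest-magnitude loading of every PC is positive.
#'
#' @param matrices list of [compute_descriptors()] results (>= 2 ensembles).
#' @return object of class `pca_selection`: `explained_variance` (fractions
#'   summing to 1), `coefficients` (descriptors x PCs loading matrix),
#'   `scores` (pooled frames x PCs), `labels`, `descriptor_names`. The
#'   discrimination fields (`candidate_pairs`, `top_pair`,
#'   `top_descriptors`) are filled in by [select_discriminative()].
#' @export
fit_pca <- function(matrices) {
  if (inherits(matrices, "descriptor_matrix")) matrices <- list(matrices)
  if (length(matrices) < 2L) stop("pool at least 2 ensembles for PCA")
  X <- do.call(rbind, lapply(matrices, `[[`, "values"))
  labels <- unlist(lapply(matrices, `[[`, "labels"))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) stop("zero-variance descriptor(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  # deterministic sign convention
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(explained_variance = ev,
                 coefficients = pc$rotation,
                 scores = pc$x,
                 labels = labels,
                 descriptor_names = colnames(X),
                 candidate_pairs = NULL, top_pair = NULL,
                 top_descriptors = NULL),
            class = "pca_selection")
}

#' @export
print.pca_selection <- function(x, ...) {
  cat("pca_selection:", length(x$explained_variance), "PCs; PC1-3 variance",
      paste(sprintf("%.1f%%", 100 * x$explained_variance[1:3]),
            collapse = ", "), "\n")
  if (!is.null(x$top_pair)) {
    cat("  top pair: PC", x$top_pair[1], "-PC", x$top_pair[2],
        " (CH = ", signif(x$top_ch, 4), ")\n", sep = "")
    cat("  top descriptors:",
        paste(utils::head(x$top_descriptors$descriptor, 3), collapse = ", "),
        "\n")
  } else if (isTRUE(x$no_qualifying_pair)) {
    cat("  no PC pair beyond PC2 reaches the variance threshold\n")
  }
  invisible(x)
}

#' Calinski-Harabasz score of a labelled projection
#'
#' CH = (B / (k - 1)) / (W / (n - k)) with B the between-group and W the
#' within-group sum of squared distances to the respective means. A perfect
#' separation (W = 0) returns `Inf`.
#'
#' @param points numeric matrix (rows = observations), typically a 2-D PC
#'   projection.
#' @param labels group label per row (>= 2 distinct).
#' @return numeric score.
#' @export
calinski_harabasz <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  groups <- unique(labels)
  k <- length(groups); n <- nrow(points)
  if (k < 2L) stop("need >= 2 distinct labels")
  m <- colMeans(points)
  B <- 0; W <- 0
  for (g in groups) {
    pg <- points[labels == g, , drop = FALSE]
    mg <- colMeans(pg)
    B <- B + nrow(pg) * sum((mg - m)^2)
    W <- W + sum(sweep(pg, 2L, mg)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the discriminative PC pair and descriptors
#'
#' Excludes PC1 and PC2 (which absorb the dominant shared conformational
#' modes), enumerates unordered pairs among the remaining PCs whose combined
#' explained-variance fraction reaches `min_variance`, ranks them by the
#' Calinski-Harabasz score of their 2-D labelled projection, and ranks
#' descriptors by their largest absolute loading on the winning pair.
#'
#' @param pca a [fit_pca()] result.
#' @param labels per-frame labels (default: those stored in `pca`).
#' @param min_variance combined variance-fraction threshold (default 0.15).
#' @return the completed `pca_selection`: `candidate_pairs` (data.frame
#'   `pc_a`, `pc_b`, `variance`, `ch`), `top_pair`, `top_ch`,
#'   `top_descriptors` (data.frame `descriptor`, `coefficient`, ranked).
#'   When no pair qualifies, `no_qualifying_pair = TRUE` and `top_pair`
#'   stays `NULL` (explicit, never a silent fallback).
#' @export
select_discriminative <- function(pca, labels = pca$labels,
                                  min_variance = 0.15) {
  np <- length(pca$explained_variance)
  if (np < 4L) stop("need at least 4 PCs to search beyond PC1-2")
  cand <- utils::combn(3:np, 2L)
  varsum <- pca$explained_variance[cand[1, ]] + pca$explained_variance[cand[2, ]]
  keep <- varsum >= min_variance
  if (!any(keep)) {
    pca$candidate_pairs <- data.frame(pc_a = integer(), pc_b = integer(),
                                      variance = numeric(), ch = numeric())
    pca$no_qualifying_pair <- TRUE
    return(pca)
  }
  cand <- cand[, keep, drop = FALSE]
  varsum <- varsum[keep]
  ch <- vapply(seq_len(ncol(cand)), function(j) {
    calinski_harabasz(pca$scores[, cand[, j], drop = FALSE], labels)
  }, 1.0)
  ord <- order(-ch, cand[1, ], cand[2, ])
  pairs <- data.frame(pc_a = cand[1, ord], pc_b = cand[2, ord],
                      variance = varsum[ord], ch = ch[ord])
  top <- c(pairs$pc_a[1], pairs$pc_b[1])
  coef2 <- pmax(abs(pca$coefficients[, top[1]]), abs(pca$coefficients[, top[2]]))
  rk <- order(-coef2)
  pca$candidate_pairs <- pairs
  pca$top_pair <- top
  pca$top_ch <- pairs$ch[1]
  pca$top_descriptors <- data.frame(descriptor = pca$descriptor_names[rk],
                                    coefficient = coef2[rk],
                                    row.names = NULL)
  pca$no_qualifying_pair <- FALSE
  pca
}

#' @export
plot.pca_selection <- function(x, ...) {
  if (is.null(x$top_pair)) stop("run select_discriminative() first")
  pr <- x$scores[, x$top_pair]
  labs <- factor(x$labels)
  graphics::plot(pr, col = as.integer(labs), pch = 16, cex = 0.5,
                 xlab = paste0("PC", x$top_pair[1]),
                 ylab = paste0("PC", x$top_pair[2]), ...)
  graphics::legend("topright", legend = levels(labs),
                   col = seq_along(levels(labs)), pch = 16, cex = 0.8)
  invisible(x)
}
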