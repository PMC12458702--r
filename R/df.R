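#' Distance-fluctuation matrix of a trajectory
#'
#' For every pair of selected C-alpha atoms, the time-averaged mean-square
#' fluctuation of their distance, DF_ij = <(r_ij - <r_ij>)^2>, accumulated
#' in one streaming pass (compensated summation of r and r^2; the identity
#' <r^2> - <r>^2 is used). Low values flag dynamically coordinated pairs;
#' no superposition is applied since pairwise distances are invariant under
#' rigid motion.
#'
#' @param ens an [ensemble()] with >= 2 frames.
#' @param residues optional 0-based residue indices (default: all CA).
#' @param skip number of leading equilibration frames to discard (default 0).
#' @return object of class `dfmat`: `values` (symmetric residue x residue
#'   matrix, Angstrom^2, zero diagonal, dimnames = residue indices),
#'   `selection`, `n_frames`.
#' @export
compute_df <- function(ens, residues = NULL, skip = 0L) {
  sel <- ca_indices(ens, residues)
  if (length(sel) < 2L) stop("need >= 2 selected residues")
  frames <- seq_len(n_frames(ens))
  if (skip > 0L) frames <- frames[-seq_len(skip)]
  if (length(frames) < 2L) stop("distance fluctuation needs >= 2 frames")
  n <- length(sel)
  npair <- n * (n - 1L) / 2L
  s1 <- numeric(npair); c1 <- numeric(npair)   # Kahan accumulators
  s2 <- numeric(npair); c2 <- numeric(npair)
  for (k in frames) {
    r <- as.numeric(stats::dist(ens$coords[sel, , k, drop = TRUE]))
    y <- r - c1; t1 <- s1 + y; c1 <- (t1 - s1) - y; s1 <- t1
    y <- r * r - c2; t2 <- s2 + y; c2 <- (t2 - s2) - y; s2 <- t2
  }
  nf <- length(frames)
  dfv <- pmax(s2 / nf - (s1 / nf)^2, 0)
  M <- matrix(0, n, n)
  M[lower.tri(M)] <- dfv
  M <- M + t(M)
  res_ids <- ens$atoms$residue_index[sel]
  dimnames(M) <- list(res_ids, res_ids)
  structure(list(values = M, selection = res_ids, n_frames = nf),
            class = "dfmat")
}

#' @export
print.dfmat <- function(x, ...) {
  cat("dfmat:", nrow(x$values), "residues,", x$n_frames, "frames; mean DF",
      signif(mean(x$values[upper.tri(x$values)]), 4), "A^2\n")
  invisible(x)
}

#' @export
plot.dfmat <- function(x, main = "distance fluctuations (A^2)", ...) {
  n <- nrow(x$values)
  graphics::image(seq_len(n), seq_len(n), x$values,
                  xlab = "residue", ylab = "residue", main = main,
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Domain-block summary of a distance-fluctuation matrix
#'
#' Mean DF over all residue pairs (i in A, j in B, i != j) for every ordered
#' domain pair; diagonal blocks summarise within-domain coordination,
#' off-diagonal blocks inter-domain flexibility.
#'
#' @param df a [compute_df()] result.
#' @param partition a [domain_partition()] covering the DF selection.
#' @return symmetric domain x domain matrix of mean DF (Angstrom^2).
#' @export
df_block_summary <- function(df, partition) {
  doms <- partition$domains
  idx <- lapply(doms, function(r) which(df$selection %in% r))
  empty <- vapply(idx, length, 1L) < 1L
  if (any(empty)) stop("domain(s) with no selected residue: ",
                       paste(names(doms)[empty], collapse = ", "))
  k <- length(doms)
  out <- matrix(NA_real_, k, k, dimnames = list(names(doms), names(doms)))
  for (a in seq_len(k)) for (b in a:k) {
    block <- df$values[idx[[a]], idx[[b]], drop = FALSE]
    if (a == b) {
      if (length(idx[[a]]) < 2L) { out[a, b] <- 0; next }
      vals <- block[row(block) != col(block)]
    } else vals <- as.numeric(block)
    out[a, b] <- out[b, a] <- mean(vals)
  }
  out
}

#' Difference of two distance-fluctuation matrices (e.g. bound minus apo)
#'
#' @param df_a,df_b [compute_df()] results over identical selections.
#' @return signed residue x residue matrix, `df_a$values - df_b$values`.
#' @export
df_difference <- function(df_a, df_b) {
  if (!identical(dim(df_a$values), dim(df_b$values)) ||
      !identical(df_a$selection, df_b$selection)) {
    stop("DF matrices have mismatched selections/shapes")
  }
  df_a$values - df_b$values
}
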