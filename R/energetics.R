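#' @name energetics
#' @rdname energetics
NULL

KE_COULOMB <- 332.0637   # kcal A / (mol e^2), Amber convention

#' Read a plain nonbonded parameter table
#'
#' CSV with columns `atom_id`, `charge` (e), `sigma` (Angstrom), `epsilon`
#' (kcal/mol).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_parameters <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("atom_id", "charge", "sigma", "epsilon")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("parameter table lacks column(s): ",
                         paste(miss, collapse = ", "))
  p
}

#' Attach nonbonded parameters to an ensemble's atoms
#' @param ens an [ensemble()].
#' @param params data.frame from [read_parameters()] (matched on `atom_id`).
#' @return the ensemble with `charge`, `sigma`, `epsilon` atom columns.
#' @export
attach_parameters <- function(ens, params) {
  m <- match(ens$atoms$atom_id, params$atom_id)
  if (anyNA(m)) stop("parameters missing for atom id(s): ",
                     paste(utils::head(ens$atoms$atom_id[is.na(m)], 5),
                           collapse = ", "))
  ens$atoms$charge <- params$charge[m]
  ens$atoms$sigma <- params$sigma[m]
  ens$atoms$epsilon <- params$epsilon[m]
  ens
}

check_parameters <- function(atoms, idx) {
  need <- c("charge", "sigma", "epsilon")
  miss_col <- setdiff(need, names(atoms))
  if (length(miss_col)) stop("atoms carry no nonbonded parameters (missing ",
                             paste(miss_col, collapse = ", "),
                             "); see attach_parameters()")
  bad <- idx[!stats::complete.cases(atoms[idx, need])]
  if (length(bad)) stop("incomplete nonbonded parameters for atom id(s): ",
                        paste(utils::head(atoms$atom_id[bad], 8),
                              collapse = ", "))
  invisible(TRUE)
}

# Electrostatic + Lennard-Jones energies for explicit atom index pairs,
# summed per residue pair. Lorentz-Berthelot mixing; epsilon(r) = 1 for
# mode "none", = r (in Angstrom) for mode "ddd".
nb_pair_energies <- function(fr, atoms, ai, bi, cutoff, mode) {
  r2 <- rowSums((fr[ai, , drop = FALSE] - fr[bi, , drop = FALSE])^2)
  keep <- r2 <= cutoff^2 & r2 > 0
  if (!any(keep)) {
    return(data.frame(res_i = integer(), res_j = integer(),
                      el = numeric(), vdw = numeric()))
  }
  ai <- ai[keep]; bi <- bi[keep]; r <- sqrt(r2[keep])
  qq <- atoms$charge[ai] * atoms$charge[bi]
  el <- if (mode == "ddd") KE_COULOMB * qq / (r * r) else KE_COULOMB * qq / r
  sab <- (atoms$sigma[ai] + atoms$sigma[bi]) / 2
  eab <- sqrt(atoms$epsilon[ai] * atoms$epsilon[bi])
  sr6 <- (sab / r)^6
  vdw <- 4 * eab * (sr6^2 - sr6)
  key <- paste(atoms$residue_index[ai], atoms$residue_index[bi])
  agg_el <- rowsum(el, key)
  agg_vdw <- rowsum(vdw, key)
  ij <- do.call(rbind, strsplit(rownames(agg_el), " "))
  data.frame(res_i = as.integer(ij[, 1]), res_j = as.integer(ij[, 2]),
             el = as.numeric(agg_el), vdw = as.numeric(agg_vdw))
}

#' Residue-pair nonbonded energy matrix (EDM) of one frame
#'
#' E_ij = E^el_ij + E^vdW_ij (+ G^solv_ij) summed over all atom pairs of
#' residues i, j within the cutoff. Electrostatics use the Amber Coulomb
#' constant 332.0637 kcal A/(mol e^2); Lennard-Jones parameters combine by
#' Lorentz-Berthelot rules. Sequence-adjacent residue pairs (|i - j| < 2)
#' are excluded: their energies are dominated by covalent terms this model
#' omits. `solvation = "ddd"` screens the Coulomb term with a
#' distance-dependent dielectric eps(r) = r; `"none"` sets G^solv = 0.
#'
#' @param ens an [ensemble()] whose atoms carry `charge`, `sigma`, `epsilon`.
#' @param frame_index frame to evaluate (default 1; typically a cluster
#'   representative).
#' @param cutoff atom-pair distance cutoff in Angstrom (default 10).
#' @param solvation `"none"` or `"ddd"`.
#' @param min_seq_sep minimum residue-sequence separation (default 2).
#' @return list of symmetric residue x residue matrices `total`,
#'   `electrostatic`, `vdw` (kcal/mol; dimnames = residue indices), plus the
#'   evaluation settings.
#' @export
pairwise_energy <- function(ens, frame_index = 1L, cutoff = 10,
                            solvation = c("none", "ddd"),
                            min_seq_sep = 2L) {
  solvation <- match.arg(solvation)
  if (cutoff <= 0) stop("cutoff must be > 0")
  atoms <- ens$atoms
  check_parameters(atoms, seq_len(nrow(atoms)))
  fr <- get_frame(ens, frame_index)
  res <- sort(unique(atoms$residue_index))
  n <- length(res)
  # candidate atom pairs: all i<j with residue separation >= min_seq_sep
  cp <- utils::combn(nrow(atoms), 2L)
  sep <- abs(atoms$residue_index[cp[1, ]] - atoms$residue_index[cp[2, ]])
  cp <- cp[, sep >= min_seq_sep, drop = FALSE]
  pe <- nb_pair_energies(fr, atoms, cp[1, ], cp[2, ], cutoff, solvation)
  mk <- function(v) {
    M <- matrix(0, n, n, dimnames = list(res, res))
    if (nrow(pe)) {
      i <- match(pe$res_i, res); j <- match(pe$res_j, res)
      M[cbind(i, j)] <- M[cbind(i, j)] + v
      M[cbind(j, i)] <- M[cbind(i, j)]
    }
    M
  }
  el <- mk(pe$el); vdw <- mk(pe$vdw)
  list(total = el + vdw, electrostatic = el, vdw = vdw,
       cutoff = cutoff, solvation = solvation, min_seq_sep = min_seq_sep,
       frame_index = frame_index)
}

#' Eigen-decomposition and stability profile of an energy matrix
#'
#' Diagonalises the symmetric residue-pair energy matrix; the first
#' eigenvector is the one whose eigenvalue has the largest magnitude (it
#' recapitulates most of the nonbonded energy) with its sign fixed so the
#' component sum is non-negative. The per-residue stabilisation profile is
#' the energy-weighted participation `|lambda_1| * v_i^2` (non-negative);
#' `profile = "loading"` reports `|v_i|` instead.
#'
#' @param M symmetric residue x residue energy matrix (kcal/mol), e.g.
#'   `pairwise_energy(...)$total` or a [make_energy_matrix()] fixture.
#' @param profile `"weighted"` (default) or `"loading"`.
#' @return object of class `edm`: `matrix`, `eigenvalues` (sorted by
#'   descending magnitude), `first_eigenvector` (unit norm), `profile`
#'   (named by residue), `degenerate` (TRUE when |lambda_1| and |lambda_2|
#'   coincide within 1e-9, recorded as a warning in the object).
#' @export
edm_eigen <- function(M, profile = c("weighted", "loading")) {
  profile <- match.arg(profile)
  if (!isSymmetric(unname(M), tol = 1e-9)) stop("matrix must be symmetric")
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(-abs(eg$values))
  vals <- eg$values[ord]
  v1 <- eg$vectors[, ord[1]]
  if (sum(v1) < 0) v1 <- -v1
  degenerate <- length(vals) > 1L && abs(abs(vals[1]) - abs(vals[2])) < 1e-9
  prof <- if (profile == "weighted") abs(vals[1]) * v1^2 else abs(v1)
  names(prof) <- rownames(M) %||% as.character(seq_along(prof) - 1L)
  structure(list(matrix = M, eigenvalues = vals, first_eigenvector = v1,
                 profile = prof, profile_kind = profile,
                 degenerate = degenerate),
            class = "edm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.edm <- function(x, ...) {
  cat("edm:", nrow(x$matrix), "residues; |lambda1| =",
      signif(abs(x$eigenvalues[1]), 5),
      if (x$degenerate) "(degenerate leading eigenvalue)" else "", "\n")
  invisible(x)
}

#' @export
plot.edm <- function(x, ...) {
  graphics::plot(as.integer(names(x$profile)), x$profile, type = "h",
                 xlab = "residue", ylab = "stability profile", ...)
  invisible(x)
}

#' Electrostatic stability nuclei from an EDM profile
#'
#' Retains residues whose stability-profile value is at least `threshold`
#' (inclusive) and counts, per domain, the retained-residue pairs that
#' interact (|E_ij| > 0) within the same domain. `use = "matrix"` applies
#' the threshold to the strongest raw |E_ij| of each residue instead of the
#' eigenvector-weighted profile.
#'
#' @param edm an [edm_eigen()] result.
#' @param partition a [domain_partition()].
#' @param threshold kcal/mol (default 0.005).
#' @param use `"profile"` (default) or `"matrix"`.
#' @return object of class `nuclei_set`: `residues` (0-based ids),
#'   `threshold`, `intradomain_counts` (named integer vector).
#' @export
electrostatic_nuclei <- function(edm, partition, threshold = 0.005,
                                 use = c("profile", "matrix")) {
  use <- match.arg(use)
  if (threshold < 0) stop("threshold must be >= 0")
  res_ids <- as.integer(names(edm$profile))
  score <- if (use == "profile") edm$profile else apply(abs(edm$matrix), 1L, max)
  keep <- res_ids[score >= threshold]
  counts <- vapply(partition$domains, function(dres) {
    members <- intersect(keep, dres)
    if (length(members) < 2L) return(0L)
    ii <- match(members, res_ids)
    sub <- abs(edm$matrix[ii, ii, drop = FALSE])
    as.integer(sum(sub[upper.tri(sub)] > 0))
  }, 1L)
  structure(list(residues = keep, threshold = threshold, use = use,
                 intradomain_counts = counts),
            class = "nuclei_set")
}

#' @export
print.nuclei_set <- function(x, ...) {
  cat("nuclei_set:", length(x$residues), "residues at threshold >=",
      x$threshold, "kcal/mol (", x$use, ")\n")
  print(x$intradomain_counts)
  invisible(x)
}

#' Domain-pair nonbonded interaction energies averaged over frames
#'
#' Evaluates [pairwise_energy()] per frame and aggregates residue-pair
#' energies by domain pair, averaging across frames.
#'
#' @param ens an [ensemble()] with parameters and a partition.
#' @param cutoff Angstrom (default 10).
#' @param solvation as in [pairwise_energy()].
#' @param frames frame indices to average (default all).
#' @return data.frame (`group_a`, `group_b`, `electrostatic`, `vdw`,
#'   `total`, `n_frames`), domain pairs with zero energy omitted.
#' @export
interdomain_energy <- function(ens, cutoff = 10,
                               solvation = c("none", "ddd"),
                               frames = seq_len(n_frames(ens))) {
  solvation <- match.arg(solvation)
  if (is.null(ens$partition)) stop("ensemble has no domain partition")
  doms <- ens$partition$domains
  dom_of <- rep(NA_character_, max(unlist(doms)) + 1L)
  for (d in names(doms)) dom_of[doms[[d]] + 1L] <- d
  acc <- NULL
  for (k in frames) {
    pe <- pairwise_energy(ens, k, cutoff, solvation)
    res <- as.integer(rownames(pe$total))
    da <- dom_of[res + 1L]
    M_el <- pe$electrostatic; M_vdw <- pe$vdw
    ut <- upper.tri(M_el)
    ii <- which(ut, arr.ind = TRUE)
    key <- paste(pmin(da[ii[, 1]], da[ii[, 2]]),
                 pmax(da[ii[, 1]], da[ii[, 2]]), sep = "|")
    el <- rowsum(M_el[ut], key); vdw <- rowsum(M_vdw[ut], key)
    fr_tab <- data.frame(key = rownames(el), el = as.numeric(el),
                         vdw = as.numeric(vdw))
    acc <- if (is.null(acc)) fr_tab else {
      m <- merge(acc, fr_tab, by = "key", all = TRUE)
      m[is.na(m)] <- 0
      data.frame(key = m$key, el = m$el.x + m$el.y, vdw = m$vdw.x + m$vdw.y)
    }
  }
  nf <- length(frames)
  ab <- do.call(rbind, strsplit(acc$key, "|", fixed = TRUE))
  out <- data.frame(group_a = ab[, 1], group_b = ab[, 2],
                    electrostatic = acc$el / nf, vdw = acc$vdw / nf,
                    total = (acc$el + acc$vdw) / nf, n_frames = nf,
                    stringsAsFactors = FALSE)
  out[out$total != 0 | out$electrostatic != 0 | out$vdw != 0, , drop = FALSE]
}

#' Protein-RNA interface energies and contact counts
#'
#' Nonbonded energies between every protein domain and the RNA chain,
#' averaged over frames, plus per-frame heavy-atom contact counts within
#' `contact_cutoff`.
#'
#' @param ens an [ensemble()] with parameters, partition, and an RNA chain.
#' @param rna_chain chain id (default `ens$rna_chain`).
#' @param contact_cutoff heavy-atom contact distance, Angstrom (default 4.5).
#' @param cutoff energy cutoff, Angstrom (default 10).
#' @param solvation as in [pairwise_energy()].
#' @param frames frame indices (default all).
#' @return list: `energies` data.frame (`group_a` = domain, `group_b` =
#'   "RNA", `electrostatic`, `vdw`, `total`, `n_frames`), `contacts`
#'   integer vector of per-frame contact counts.
#' @export
protein_rna_interface <- function(ens, rna_chain = ens$rna_chain,
                                  contact_cutoff = 4.5, cutoff = 10,
                                  solvation = c("none", "ddd"),
                                  frames = seq_len(n_frames(ens))) {
  solvation <- match.arg(solvation)
  if (is.null(rna_chain)) stop("no RNA chain defined")
  atoms <- ens$atoms
  rna_idx <- which(atoms$chain_id == rna_chain & atoms$element != "H")
  prot_idx <- which(atoms$chain_id != rna_chain & atoms$element != "H")
  if (length(rna_idx) == 0L) stop("chain '", rna_chain, "' has no atoms")
  doms <- ens$partition$domains
  dom_of <- rep(NA_character_, max(atoms$residue_index) + 1L)
  for (d in names(doms)) dom_of[doms[[d]] + 1L] <- d
  pairs <- expand.grid(a = prot_idx, b = rna_idx)
  check_parameters(atoms, c(prot_idx, rna_idx))
  acc <- NULL; contacts <- integer(length(frames))
  for (w in seq_along(frames)) {
    k <- frames[w]
    fr <- get_frame(ens, k)
    d2 <- rowSums((fr[pairs$a, , drop = FALSE] - fr[pairs$b, , drop = FALSE])^2)
    contacts[w] <- sum(d2 <= contact_cutoff^2)
    pe <- nb_pair_energies(fr, atoms, pairs$a, pairs$b, cutoff, solvation)
    if (nrow(pe)) {
      key <- dom_of[pe$res_i + 1L]
      el <- rowsum(pe$el, key); vdw <- rowsum(pe$vdw, key)
      fr_tab <- data.frame(key = rownames(el), el = as.numeric(el),
                           vdw = as.numeric(vdw))
      acc <- if (is.null(acc)) fr_tab else {
        m <- merge(acc, fr_tab, by = "key", all = TRUE)
        m[is.na(m)] <- 0
        data.frame(key = m$key, el = m$el.x + m$el.y, vdw = m$vdw.x + m$vdw.y)
      }
    }
  }
  nf <- length(frames)
  energies <- if (is.null(acc)) {
    data.frame(group_a = character(), group_b = character(),
               electrostatic = numeric(), vdw = numeric(),
               total = numeric(), n_frames = integer())
  } else {
    data.frame(group_a = acc$key, group_b = "RNA",
               electrostatic = acc$el / nf, vdw = acc$vdw / nf,
               total = (acc$el + acc$vdw) / nf, n_frames = nf,
               stringsAsFactors = FALSE)
  }
  list(energies = energies, contacts = contacts)
}
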