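#' @name pocket
#' @rdname pocket
NULL

VDW_RADII <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Define the RNA-binding pocket by distance to the bound RNA
#'
#' A protein residue belongs to the pocket iff any of its heavy atoms lies
#' within `cutoff` of any RNA heavy atom in the chosen frame. An empty
#' result (RNA too far, or cutoff 0) is returned with a warning and the
#' `empty` flag set.
#'
#' @param ens an [ensemble()] with an RNA chain.
#' @param cutoff Angstrom (default 6).
#' @param rna_chain chain id (default `ens$rna_chain`).
#' @param frame_index frame used (default 1, typically a crystal structure).
#' @return object of class `pocket_definition`: `residues` (0-based),
#'   `source`, `cutoff`, `empty`.
#' @export
define_pocket <- function(ens, cutoff = 6.0, rna_chain = ens$rna_chain,
                          frame_index = 1L) {
  if (is.null(rna_chain)) stop("no RNA chain defined")
  atoms <- ens$atoms
  fr <- get_frame(ens, frame_index)
  rna <- which(atoms$chain_id == rna_chain & atoms$element != "H")
  prot <- which(atoms$chain_id != rna_chain & atoms$element != "H")
  if (length(rna) == 0L) stop("chain '", rna_chain, "' has no atoms")
  near <- rep(FALSE, length(prot))
  if (cutoff > 0) {
    for (r in rna) {
      d2 <- rowSums(sweep(fr[prot, , drop = FALSE], 2L, fr[r, ])^2)
      near <- near | d2 <= cutoff^2
    }
  }
  residues <- sort(unique(atoms$residue_index[prot[near]]))
  empty <- length(residues) == 0L
  if (empty) warning("pocket is empty at cutoff ", cutoff, " A")
  structure(list(residues = residues, source = "distance-to-RNA",
                 cutoff = cutoff, empty = empty),
            class = "pocket_definition")
}

#' User-supplied pocket definition
#' @param residues 0-based residue indices.
#' @return `pocket_definition` with source `"user"`.
#' @export
user_pocket <- function(residues) {
  structure(list(residues = sort(unique(as.integer(residues))),
                 source = "user", cutoff = NA_real_,
                 empty = length(residues) == 0L),
            class = "pocket_definition")
}

#' @export
print.pocket_definition <- function(x, ...) {
  cat("pocket_definition (", x$source, "): ", length(x$residues),
      " residues\n", sep = "")
  invisible(x)
}

#' Minimal pocket conserved across ensembles
#'
#' Maps every ensemble's pocket residues into a common index space via the
#' supplied correspondence tables, intersects them, and maps the conserved
#' core back into each ensemble's own numbering. Unmapped pocket residues
#' are excluded with a warning.
#'
#' @param pockets named list of [define_pocket()] results.
#' @param correspondence named list (same names) of data.frames with
#'   columns `residue` (the ensemble's 0-based index) and `common`.
#' @return named list of `pocket_definition`s (source `"minimal"`); the
#'   attribute `"common"` holds the conserved common-space ids.
#' @export
minimal_pocket <- function(pockets, correspondence) {
  if (!identical(sort(names(pockets)), sort(names(correspondence)))) {
    stop("pockets and correspondence tables must share names")
  }
  common_sets <- lapply(names(pockets), function(nm) {
    corr <- correspondence[[nm]]
    m <- match(pockets[[nm]]$residues, corr$residue)
    if (anyNA(m)) {
      warning("pocket '", nm, "': excluding unmapped residue(s) ",
              paste(pockets[[nm]]$residues[is.na(m)], collapse = ", "))
      m <- m[!is.na(m)]
    }
    sort(corr$common[m])
  })
  core <- Reduce(intersect, common_sets)
  if (length(core) == 0L) warning("conserved minimal pocket is empty")
  out <- lapply(names(pockets), function(nm) {
    corr <- correspondence[[nm]]
    res <- sort(corr$residue[match(core, corr$common)])
    structure(list(residues = res, source = "minimal", cutoff = NA_real_,
                   empty = length(res) == 0L),
              class = "pocket_definition")
  })
  names(out) <- names(pockets)
  attr(out, "common") <- core
  out
}

# probe-accessible grid count bounded by the convex hull of the pocket's
# heavy atoms
volume_one_frame <- function(fr, atoms, pocket_res, grid, probe) {
  heavy <- which(atoms$element != "H")
  pk <- heavy[atoms$residue_index[heavy] %in% pocket_res]
  if (length(pk) < 4L) stop("pocket has fewer than 4 heavy atoms")
  hull <- hull3d(fr[pk, , drop = FALSE])
  hp <- fr[pk, , drop = FALSE]
  ax <- lapply(1:3, function(d) {
    seq(min(hp[, d]) + grid / 2, max(hp[, d]), by = grid)
  })
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  pts <- pts[in_hull3d(pts, hull), , drop = FALSE]
  if (nrow(pts) == 0L) return(0)
  rad <- probe + vdw_radius(atoms$element[heavy])
  blocked <- rep(FALSE, nrow(pts))
  for (a in seq_along(heavy)) {
    idx <- which(!blocked)
    if (length(idx) == 0L) break
    d2 <- rowSums(sweep(pts[idx, , drop = FALSE], 2L, fr[heavy[a], ])^2)
    blocked[idx[d2 <= rad[a]^2]] <- TRUE
  }
  sum(!blocked) * grid^3
}

#' Channel volume as a population-weighted average over representatives
#'
#' For each representative frame, counts the grid points that lie inside
#' the convex hull of the pocket residues' heavy atoms and farther than
#' `probe` + vdW radius from every protein heavy atom, times the grid-cell
#' volume; the reported volume is the cluster-population-weighted mean.
#'
#' @param ens an [ensemble()].
#' @param pocket a [pocket_definition()].
#' @param representatives data.frame with columns `frame` and `population`
#'   (e.g. `cluster_frames(...)$representatives`), or NULL for frame 1 with
#'   weight 1. Populations are renormalised over the supplied frames.
#' @param grid grid spacing, Angstrom (default 0.5).
#' @param probe probe radius, Angstrom (default 1.4).
#' @return object of class `volume_result`: `volumes` (per representative,
#'   Angstrom^3), `weights`, `weighted_mean`, `grid_spacing`,
#'   `probe_radius`, `algorithm`.
#' @export
channel_volume <- function(ens, pocket, representatives = NULL,
                           grid = 0.5, probe = 1.4) {
  if (grid <= 0) stop("grid spacing must be > 0")
  if (probe < 0) stop("probe radius must be >= 0")
  if (pocket$empty || length(pocket$residues) == 0L) stop("pocket is empty")
  if (is.null(representatives)) {
    representatives <- data.frame(frame = 1L, population = 1)
  }
  w <- representatives$population / sum(representatives$population)
  vols <- vapply(seq_len(nrow(representatives)), function(i) {
    volume_one_frame(get_frame(ens, representatives$frame[i]),
                     ens$atoms, pocket$residues, grid, probe)
  }, 1.0)
  structure(list(volumes = vols, weights = w,
                 weighted_mean = sum(w * vols),
                 grid_spacing = grid, probe_radius = probe,
                 frames = representatives$frame,
                 algorithm = "convex-hull-bounded probe-accessible grid count"),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat("volume_result:", signif(x$weighted_mean, 6), "A^3 (weighted over",
      length(x$volumes), "representative(s); grid", x$grid_spacing,
      "A, probe", x$probe_radius, "A)\n")
  invisible(x)
}
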