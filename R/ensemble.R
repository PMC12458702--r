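#' Conformational ensemble container
#'
#' An `ensemble` bundles an atom table, one or more coordinate frames, and
#' optional annotations (domain partition, RNA chain, per-atom nonbonded
#' parameters). It is the substrate of every analysis stage in the package.
#'
#' @param atoms data.frame with at least the columns `atom_id`, `name`,
#'   `element`, `residue_index` (0-based, contiguous within the structure),
#'   `residue_name`, `chain_id`. Optional columns: `resno` (author/PDB
#'   residue numbering, display metadata only), `insert` (insertion code),
#'   `charge` (e), `sigma` (Angstrom), `epsilon` (kcal/mol).
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`, in
#'   Angstrom. A single `n_atoms x 3` matrix is promoted to one frame.
#' @param frame_interval time per frame in arbitrary declared units
#'   (default 1).
#' @param label free-text condition/isoform tag.
#' @param partition optional [domain_partition()].
#' @param rna_chain optional chain identifier of a bound nucleic acid.
#' @param metadata optional named list carried along unchanged (the synthetic
#'   generators record their planted parameters here).
#'
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(atoms, coords, frame_interval = 1, label = "",
                     partition = NULL, rna_chain = NULL, metadata = list()) {
  required <- c("atom_id", "name", "element", "residue_index",
                "residue_name", "chain_id")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(atoms)) {
    stop("coords first dimension (", dim(coords)[1],
         ") does not match atom count (", nrow(atoms), ")")
  }
  if (dim(coords)[3] < 1L) stop("ensemble needs at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (any(atoms$residue_index < 0L)) stop("residue_index must be >= 0")
  if (!is.null(partition)) validate_partition(partition, atoms)
  structure(
    list(atoms = atoms, coords = coords,
         frame_interval = frame_interval, label = label,
         partition = partition, rna_chain = rna_chain, metadata = metadata),
    class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "\n  atoms:   ", nrow(x$atoms),
      "\n  residues:", length(unique(x$atoms$residue_index)),
      "\n  frames:  ", n_frames(x),
      " (interval ", x$frame_interval, ")\n", sep = "")
  if (!is.null(x$partition)) {
    cat("  domains: ", paste(names(x$partition$domains), collapse = ", "), "\n")
  }
  if (!is.null(x$rna_chain)) cat("  RNA chain:", x$rna_chain, "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an [ensemble()].
#' @return integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[3]

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param ens an [ensemble()].
#' @param i frame index (1-based).
#' @return numeric matrix.
#' @export
get_frame <- function(ens, i = 1L) {
  if (i < 1L || i > n_frames(ens)) stop("frame index out of range")
  ens$coords[, , i, drop = TRUE]
}

#' Domain partition of a multi-domain structure
#'
#' Groups residues (0-based internal indices) into named, non-overlapping
#' domains, e.g. the N/L1/PAZ/L2/MID/PIWI architecture of Argonaute.
#'
#' @param ... named integer vectors of residue indices, or a single named
#'   list of such vectors.
#' @return object of class `domain_partition` with element `domains`.
#' @export
domain_partition <- function(...) {
  doms <- list(...)
  if (length(doms) == 1L && is.list(doms[[1]]) && is.null(names(doms)[1])) {
    doms <- doms[[1]]
  }
  if (is.null(names(doms)) || any(!nzchar(names(doms)))) {
    stop("every domain must be named")
  }
  if (anyDuplicated(names(doms))) stop("domain names must be unique")
  doms <- lapply(doms, function(v) sort(unique(as.integer(v))))
  all_res <- unlist(doms, use.names = FALSE)
  if (anyDuplicated(all_res)) stop("domains overlap: residue(s) ",
    paste(unique(all_res[duplicated(all_res)]), collapse = ", "))
  if (length(all_res) && any(all_res < 0L)) stop("residue indices must be >= 0")
  structure(list(domains = doms), class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("domain_partition:",
      paste(sprintf("%s (%d)", names(x$domains),
                    vapply(x$domains, length, 1L)), collapse = ", "), "\n")
  invisible(x)
}

validate_partition <- function(partition, atoms) {
  if (!inherits(partition, "domain_partition")) {
    stop("partition must be a domain_partition")
  }
  known <- unique(atoms$residue_index)
  bad <- setdiff(unlist(partition$domains, use.names = FALSE), known)
  if (length(bad) > 0L) {
    stop("partition names residue(s) absent from structure: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Atom indices of the C-alpha trace
#'
#' @param ens an [ensemble()].
#' @param residues optional 0-based residue indices to restrict to; `NULL`
#'   selects every protein residue with a CA atom.
#' @return integer atom row indices, ordered by residue index.
#' @export
ca_indices <- function(ens, residues = NULL) {
  at <- ens$atoms
  idx <- which(at$name == "CA")
  if (!is.null(residues)) idx <- idx[at$residue_index[idx] %in% residues]
  idx[order(at$residue_index[idx])]
}

#' Atom indices for a residue selection (all atoms)
#' @param ens an [ensemble()].
#' @param residues 0-based residue indices.
#' @return integer atom row indices.
#' @export
atom_indices <- function(ens, residues) {
  which(ens$atoms$residue_index %in% residues)
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' Parsing is delegated to [bio3d::read.pdb()]; each MODEL becomes one frame.
#' Author residue numbers and insertion codes are kept as display metadata
#' (`resno`, `insert`); internal `residue_index` is 0-based and contiguous in
#' file order.
#'
#' @param path PDB file path.
#' @param format currently only `"pdb"`.
#' @return an [ensemble()] (single- or multi-frame).
#' @export
read_structure <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE)),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("PDB contains no atoms: ", path)
  # one residue per unique (chain, resno, insert) in order of appearance
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  ridx <- match(key, unique(key)) - 1L
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(!nzchar(trimws(element)))) {
    element <- substr(trimws(at$elety), 1L, 1L)
  }
  atoms <- data.frame(
    atom_id = at$eleno, name = trimws(at$elety),
    element = trimws(element), residue_index = ridx,
    residue_name = trimws(at$resid), chain_id = at$chain,
    resno = at$resno, insert = ifelse(is.na(at$insert), "", at$insert),
    stringsAsFactors = FALSE)
  nfr <- nrow(pdb$xyz)
  if (ncol(pdb$xyz) != 3L * nrow(atoms)) {
    stop("models in '", path, "' have mismatched atom counts (",
         ncol(pdb$xyz) / 3, " coordinates per model vs ", nrow(atoms),
         " atoms)")
  }
  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, nfr))
  for (k in seq_len(nfr)) {
    coords[, , k] <- matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE)
  }
  if (!all(is.finite(coords))) {
    stop("models in '", path, "' have mismatched or incomplete coordinates")
  }
  ensemble(atoms, coords, label = basename(path))
}

#' Write an ensemble as a (multi-model) PDB file
#'
#' @param ens an [ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(ens, path) {
  at <- ens$atoms
  nfr <- n_frames(ens)
  xyz <- t(apply(ens$coords, 3L, function(m) as.numeric(t(m))))
  if (nfr == 1L) xyz <- matrix(xyz, nrow = 1L)
  resno <- if ("resno" %in% names(at)) at$resno else at$residue_index + 1L
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno,
                   resid = at$residue_name, eleno = at$atom_id,
                   elety = at$name, chain = at$chain_id)
  invisible(path)
}
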