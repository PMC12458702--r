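#' Specification of a synthetic multi-domain ensemble
#'
#' Collects every knob of the synthetic-trajectory generators in one
#' validated object. All generators are pure functions of (spec, seed):
#' the same spec reproduces byte-identical output.
#'
#' @param seed integer; fixes all randomness.
#' @param n_frames number of trajectory frames.
#' @param domain_sizes integer vector of residues per domain. If unnamed and
#'   of length 6 the canonical Argonaute names N, L1, PAZ, L2, MID, PIWI are
#'   used; otherwise D1..Dk.
#' @param domain_sigma per-domain rigid-jitter scale (per-axis SD of the
#'   Gaussian domain displacement, Angstrom). Recycled to the domain count.
#' @param breathing optional list of planted collective modes, each
#'   `list(pair = c("A","B"), amplitude = , period = )`: domain B is
#'   displaced along the A-B centroid axis by `amplitude * sin(2*pi*k/period)`.
#' @param label_effects named list: label -> named numeric vector of mean
#'   shifts (Angstrom) on distance descriptors (e.g. `c(d_PAZ_PIWI = 4)`).
#' @param bond_traces list of planted bond occupancies,
#'   `list(occupancy = f)`, one donor/acceptor residue pair per entry.
#' @param water_spec `list(n_waters = , exchange_rate = , region_radius = )`;
#'   memoryless per-frame exchange with probability `exchange_rate`.
#' @param energy_blocks list of `list(residues = , depth = )` planted blocks
#'   for the synthetic residue-pair energy matrix.
#' @param energy_noise SD of the symmetric Gaussian noise added to the
#'   energy matrix (kcal/mol, default 0).
#' @param spacing domain-layout scale in Angstrom (default 40): domain
#'   centroids sit on octahedron vertices of radius `spacing`.
#' @param domain_radius radius of each domain's residue shell (default 5).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_frames = 100L,
                           domain_sizes = c(30, 15, 30, 15, 30, 40),
                           domain_sigma = 0.5,
                           breathing = NULL,
                           label_effects = NULL,
                           bond_traces = NULL,
                           water_spec = list(n_waters = 100L,
                                             exchange_rate = 0.1,
                                             region_radius = 8),
                           energy_blocks = NULL,
                           energy_noise = 0,
                           spacing = 40,
                           domain_radius = 5) {
  if (any(domain_sizes < 1L)) stop("domain sizes must be >= 1")
  if (is.null(names(domain_sizes))) {
    names(domain_sizes) <- if (length(domain_sizes) == 6L) {
      c("N", "L1", "PAZ", "L2", "MID", "PIWI")
    } else paste0("D", seq_along(domain_sizes))
  }
  domain_sigma <- rep_len(domain_sigma, length(domain_sizes))
  names(domain_sigma) <- names(domain_sizes)
  if (!is.null(water_spec)) {
    p <- water_spec$exchange_rate
    if (p < 0 || p > 1) stop("exchange_rate must lie in [0, 1]")
  }
  if (!is.null(bond_traces)) {
    occ <- vapply(bond_traces, function(b) b$occupancy, 1.0)
    if (any(occ < 0 | occ > 1)) stop("occupancies must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 domain_sizes = domain_sizes, domain_sigma = domain_sigma,
                 breathing = breathing, label_effects = label_effects,
                 bond_traces = bond_traces, water_spec = water_spec,
                 energy_blocks = energy_blocks, energy_noise = energy_noise,
                 spacing = spacing, domain_radius = domain_radius),
            class = "synthetic_spec")
}

# Deterministic domain centroid layout: octahedron vertices (then cube
# corners for domains 7-14), scaled by `spacing`.
layout_centers <- function(k, spacing) {
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  centers <- rbind(octa, cube)
  if (k > nrow(centers)) stop("at most ", nrow(centers), " domains supported")
  centers[seq_len(k), , drop = FALSE] * spacing
}

# Evenly spread points on a sphere (Fibonacci lattice), re-centred so the
# centroid is exactly the origin.
fibonacci_shell <- function(n, radius) {
  if (n == 1L) return(matrix(0, 1L, 3L))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  sweep(pts, 2L, colMeans(pts))
}

#' Build the reference C-alpha bead structure for a synthetic spec
#'
#' Domains are compact residue shells placed on a deterministic octahedral
#' layout; the domain centroid positions and pairwise separations are
#' recorded in the ensemble metadata so tests never re-derive them.
#'
#' @param spec a [synthetic_spec()].
#' @return single-frame [ensemble()] with its [domain_partition()] attached.
#'   `metadata$centers` holds the exact domain centroids; `metadata$helix7`
#'   a 12-residue sub-selection inside L2 (when an L2 domain exists).
#' @export
make_toy_protein <- function(spec) {
  sizes <- spec$domain_sizes
  k <- length(sizes)
  centers <- layout_centers(k, spec$spacing)
  rownames(centers) <- names(sizes)
  coords <- NULL
  res0 <- cumsum(c(0L, sizes))[seq_len(k)]
  doms <- list()
  for (d in seq_len(k)) {
    shell <- fibonacci_shell(sizes[d], spec$domain_radius)
    coords <- rbind(coords, sweep(shell, 2L, centers[d, ], `+`))
    doms[[names(sizes)[d]]] <- res0[d] + seq_len(sizes[d]) - 1L
  }
  n <- sum(sizes)
  atoms <- data.frame(
    atom_id = seq_len(n), name = "CA", element = "C",
    residue_index = 0:(n - 1L), residue_name = "ALA", chain_id = "A",
    resno = seq_len(n), insert = "", stringsAsFactors = FALSE)
  part <- domain_partition(doms)
  helix7 <- NULL
  if ("L2" %in% names(doms) && length(doms$L2) >= 12L) {
    mid <- floor((length(doms$L2) - 12L) / 2)
    helix7 <- doms$L2[mid + seq_len(12L)]
  }
  ensemble(atoms, coords, label = "toy", partition = part,
           metadata = list(centers = centers,
                           separations = as.matrix(stats::dist(centers)),
                           helix7 = helix7, spec_seed = spec$seed))
}

#' Generate a synthetic trajectory with planted domain dynamics
#'
#' Each frame is the reference plus (i) an independent Gaussian rigid
#' translation of every domain (per-axis SD `domain_sigma`) and (ii) any
#' planted breathing modes, which move one domain sinusoidally along its
#' centroid-centroid axis to the partner domain. All planted parameters are
#' recorded in `metadata$planted`.
#'
#' @param spec a [synthetic_spec()].
#' @param reference optional reference [ensemble()] (default
#'   `make_toy_protein(spec)`).
#' @param seed optional override of `spec$seed`.
#' @param label label for the resulting ensemble.
#' @return multi-frame [ensemble()].
#' @export
make_ensemble <- function(spec, reference = NULL, seed = spec$seed,
                          label = "synthetic") {
  if (is.null(reference)) reference <- make_toy_protein(spec)
  ref <- get_frame(reference, 1L)
  part <- reference$partition
  nfr <- spec$n_frames
  doms <- part$domains
  centers <- t(vapply(doms, function(r) {
    colMeans(ref[ca_indices(reference, r), , drop = FALSE])
  }, numeric(3)))
  coords <- array(0, dim = c(nrow(ref), 3L, nfr))
  rng <- local({ set.seed(seed); lapply(seq_along(doms), function(d)
    matrix(stats::rnorm(3L * nfr, sd = spec$domain_sigma[[d]]), nfr, 3L)) })
  for (k in seq_len(nfr)) {
    fr <- ref
    for (d in seq_along(doms)) {
      ai <- atom_indices(reference, doms[[d]])
      fr[ai, ] <- sweep(fr[ai, , drop = FALSE], 2L, rng[[d]][k, ], `+`)
    }
    if (!is.null(spec$breathing)) {
      for (b in spec$breathing) {
        a <- b$pair[1]; bb <- b$pair[2]
        axis <- centers[bb, ] - centers[a, ]
        axis <- axis / sqrt(sum(axis^2))
        disp <- b$amplitude * sin(2 * pi * k / b$period)
        ai <- atom_indices(reference, doms[[bb]])
        fr[ai, ] <- sweep(fr[ai, , drop = FALSE], 2L, disp * axis, `+`)
      }
    }
    coords[, , k] <- fr
  }
  ensemble(reference$atoms, coords, frame_interval = 1, label = label,
           partition = part, metadata = c(reference$metadata,
             list(planted = list(domain_sigma = spec$domain_sigma,
                                 breathing = spec$breathing, seed = seed))))
}

#' Generate one labelled ensemble per condition with planted separations
#'
#' Every label shares the same common-mode collective dynamics (the
#' `breathing` modes of the spec, intended to dominate PC1-2 downstream);
#' each label additionally shifts the mean of the distance descriptors named
#' in `spec$label_effects[[label]]` by displacing the first-named domain
#' away from the second along their centroid axis.
#'
#' @param spec a [synthetic_spec()] with `label_effects` defined for each
#'   label.
#' @param labels character vector of condition labels.
#' @return named list of [ensemble()] objects.
#' @export
make_labeled_set <- function(spec, labels) {
  if (is.null(spec$label_effects)) stop("spec$label_effects is not defined")
  missing <- setdiff(labels, names(spec$label_effects))
  if (length(missing)) stop("label_effects missing for: ",
                            paste(missing, collapse = ", "))
  base <- make_toy_protein(spec)
  out <- list()
  for (li in seq_along(labels)) {
    lab <- labels[li]
    ref <- base
    effects <- spec$label_effects[[lab]]
    if (length(effects)) {
      valid <- descriptor_names()
      bad <- setdiff(names(effects), valid)
      if (length(bad)) stop("unknown descriptor name(s): ",
                            paste(bad, collapse = ", "))
      nondist <- names(effects)[!startsWith(names(effects), "d_")]
      if (length(nondist)) stop("label effects are supported for distance ",
                                "descriptors only: ",
                                paste(nondist, collapse = ", "))
      fr <- get_frame(ref, 1L)
      for (nm in names(effects)) {
        parts <- strsplit(sub("^d_", "", nm), "_")[[1]]
        grpA <- composite_selection(parts[1], ref)
        grpB <- composite_selection(parts[2], ref)
        axis <- colMeans(fr[ca_indices(ref, grpA), , drop = FALSE]) -
                colMeans(fr[ca_indices(ref, grpB), , drop = FALSE])
        axis <- axis / sqrt(sum(axis^2))
        ai <- atom_indices(ref, grpA)
        fr[ai, ] <- sweep(fr[ai, , drop = FALSE], 2L, effects[[nm]] * axis, `+`)
      }
      ref <- ensemble(ref$atoms, fr, partition = ref$partition,
                      metadata = ref$metadata)
    }
    out[[lab]] <- make_ensemble(spec, reference = ref,
                                seed = spec$seed + 7919L * li, label = lab)
  }
  out
}

#' Generate a water ensemble with memoryless region exchange
#'
#' A spherical region of radius `region_radius` around a single anchor atom
#' holds `n_waters` oxygens. Each frame, every resident water independently
#' leaves with probability `exchange_rate` (its id is retired and it is
#' teleported far away) and is replaced in-region by a fresh id, so the
#' occupancy stays constant while residence times are geometric:
#' P(survive tau frames) = (1 - p)^tau.
#'
#' @param spec a [synthetic_spec()] with `water_spec` set.
#' @param seed optional override of `spec$seed`.
#' @return list: `ensemble` (anchor + water oxygens; `metadata$water_ids` is
#'   the slot x frame id matrix), `region` (a [region_definition()]), and
#'   `p` the planted exchange probability.
#' @export
make_water_region <- function(spec, seed = spec$seed) {
  ws <- spec$water_spec
  nw <- ws$n_waters; p <- ws$exchange_rate; R <- ws$region_radius
  nfr <- spec$n_frames
  set.seed(seed)
  n_atoms <- 1L + nw
  atoms <- data.frame(
    atom_id = seq_len(n_atoms),
    name = c("ANC", rep("O", nw)), element = c("C", rep("O", nw)),
    residue_index = 0:(n_atoms - 1L),
    residue_name = c("ANC", rep("HOH", nw)), chain_id = c("A", rep("W", nw)),
    resno = seq_len(n_atoms), insert = "", stringsAsFactors = FALSE)
  rand_in_sphere <- function(n, radius) {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    u * radius * stats::runif(n)^(1 / 3)
  }
  coords <- array(0, dim = c(n_atoms, 3L, nfr))
  ids <- matrix(0L, nw, nfr)
  cur_ids <- seq_len(nw); next_id <- nw + 1L
  pos <- rand_in_sphere(nw, 0.98 * R)
  for (k in seq_len(nfr)) {
    if (k > 1L) {
      leave <- stats::runif(nw) < p
      n_leave <- sum(leave)
      if (n_leave > 0L) {
        cur_ids[leave] <- next_id + seq_len(n_leave) - 1L
        next_id <- next_id + n_leave
        pos[leave, ] <- rand_in_sphere(n_leave, 0.98 * R)
      }
      stay <- !leave
      if (any(stay)) {   # small in-region diffusion, reflected at the wall
        step <- matrix(stats::rnorm(3 * sum(stay), sd = 0.2), ncol = 3)
        cand <- pos[stay, , drop = FALSE] + step
        r <- sqrt(rowSums(cand^2))
        too_far <- r > 0.98 * R
        cand[too_far, ] <- cand[too_far, , drop = FALSE] *
          (0.98 * R / r[too_far])
        pos[stay, ] <- cand
      }
    }
    ids[, k] <- cur_ids
    coords[1L, , k] <- 0
    coords[-1L, , k] <- pos
  }
  ens <- ensemble(atoms, coords, label = "water",
                  metadata = list(water_ids = ids, exchange_rate = p,
                                  region_radius = R, seed = seed))
  region <- region_definition("synthetic-lake", anchor_atoms = 1L,
                              inclusion_radius = R)
  list(ensemble = ens, region = region, p = p)
}

#' Generate a synthetic residue-pair energy matrix with planted blocks
#'
#' The matrix is a sum of block terms `depth * (indicator outer product)`
#' over the planted residue sets, plus optional small symmetric Gaussian
#' noise, with a zero diagonal. The planted dominant (deepest) block is
#' recorded in the `"planted"` attribute.
#'
#' @param spec a [synthetic_spec()] with `energy_blocks` set.
#' @param n matrix dimension (default: total residues of the spec).
#' @param seed optional override of `spec$seed`.
#' @return symmetric `n x n` matrix (kcal/mol) with attribute `planted`.
#' @export
make_energy_matrix <- function(spec, n = sum(spec$domain_sizes),
                               seed = spec$seed) {
  blocks <- spec$energy_blocks
  M <- matrix(0, n, n)
  if (!is.null(blocks)) {
    all_res <- unlist(lapply(blocks, `[[`, "residues"))
    if (anyDuplicated(all_res)) stop("energy blocks overlap")
    for (b in blocks) {
      v <- rep(0, n); v[b$residues + 1L] <- 1
      M <- M + b$depth * tcrossprod(v)
    }
  }
  if (spec$energy_noise > 0) {
    set.seed(seed)
    E <- matrix(stats::rnorm(n * n, sd = spec$energy_noise), n, n)
    M <- M + (E + t(E)) / 2
  }
  diag(M) <- 0
  dominant <- NULL
  if (!is.null(blocks)) {
    dominant <- blocks[[which.max(vapply(blocks, function(b) abs(b$depth), 1.0))]]
  }
  attr(M, "planted") <- list(blocks = blocks, dominant = dominant,
                             noise = spec$energy_noise)
  M
}

#' Generate an all-atom micro-system with planted bond occupancy traces
#'
#' Each planted trace gets its own isolated donor/acceptor residue pair
#' (backbone amide N-H donating to a carbonyl O). In "on" frames the pair
#' sits in ideal linear hydrogen-bond geometry (N...O 2.9 A, angle 180
#' degrees, which also satisfies the salt-bridge distance criterion for
#' charged residue types); in "off" frames the acceptor is retracted to 6 A.
#' The on-frames are the first `round(occupancy * n_frames)` frames, so the
#' realised occupancy is exact and recorded in `metadata$planted_occupancy`.
#'
#' @param spec a [synthetic_spec()] with `bond_traces` set.
#' @param residue_names optional 2-column character matrix of donor/acceptor
#'   residue names per trace (default GLY/GLY).
#' @return multi-frame all-atom [ensemble()]; donor residue of trace i has
#'   residue_index `2*(i-1)`, acceptor `2*(i-1)+1`.
#' @export
make_bonded_system <- function(spec, residue_names = NULL) {
  traces <- spec$bond_traces
  if (is.null(traces)) stop("spec$bond_traces is not defined")
  nt <- length(traces); nfr <- spec$n_frames
  if (is.null(residue_names)) {
    residue_names <- matrix("GLY", nt, 2L)
  }
  # donor residue: N, H, CA ; acceptor residue: C, O, CA
  atoms <- NULL; base <- NULL
  for (i in seq_len(nt)) {
    off <- c(60 * (i - 1), 0, 0)
    don <- rbind(N = c(0, 0, 0), H = c(1.0, 0, 0), CA = c(-1.2, 0.8, 0))
    acc <- rbind(C = c(4.1, 0, 0), O = c(2.9, 0, 0), CA = c(5.0, 1.0, 0))
    base <- rbind(base, sweep(don, 2L, off, `+`), sweep(acc, 2L, off, `+`))
    atoms <- rbind(atoms, data.frame(
      name = c(rownames(don), rownames(acc)),
      element = c("N", "H", "C", "C", "O", "C"),
      residue_index = rep(c(2L * (i - 1L), 2L * i - 1L), each = 3L),
      residue_name = rep(residue_names[i, ], each = 3L),
      stringsAsFactors = FALSE))
  }
  atoms <- data.frame(atom_id = seq_len(nrow(atoms)), atoms,
                      chain_id = "A", resno = atoms$residue_index + 1L,
                      insert = "", stringsAsFactors = FALSE)
  coords <- array(0, dim = c(nrow(atoms), 3L, nfr))
  n_on <- vapply(traces, function(b) as.integer(round(b$occupancy * nfr)), 1L)
  for (k in seq_len(nfr)) {
    fr <- base
    for (i in seq_len(nt)) {
      if (k > n_on[i]) {   # retract acceptor residue: bond off
        ai <- 6L * (i - 1L) + 4:6
        fr[ai, 1] <- fr[ai, 1] + 3.1
      }
    }
    coords[, , k] <- fr
  }
  ensemble(atoms, coords, label = "bonded-system",
           metadata = list(planted_occupancy = n_on / nfr,
                           n_on = n_on))
}
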