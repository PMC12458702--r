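# Shared fixture builders: every fixture is constructed in code so tests
# control all planted quantities exactly.

# minimal CA-only ensemble from a list of n x 3 frames
ca_ensemble <- function(frames, label = "fixture", partition = NULL,
                        metadata = list()) {
  if (is.matrix(frames)) frames <- list(frames)
  n <- nrow(frames[[1]])
  atoms <- data.frame(
    atom_id = seq_len(n), name = "CA", element = "C",
    residue_index = 0:(n - 1L), residue_name = "ALA", chain_id = "A",
    resno = seq_len(n), insert = "", stringsAsFactors = FALSE)
  coords <- array(0, dim = c(n, 3L, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  ensemble(atoms, coords, label = label, partition = partition,
           metadata = metadata)
}

# all-atom micro-ensemble from an atom table (name, element, residue_index,
# residue_name) and frames
atom_ensemble <- function(tab, frames, rna_chain = NULL, chain = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  n <- nrow(tab)
  atoms <- data.frame(
    atom_id = seq_len(n), name = tab$name, element = tab$element,
    residue_index = tab$residue_index, residue_name = tab$residue_name,
    chain_id = if (is.null(chain)) "A" else chain,
    resno = tab$residue_index + 1L, insert = "", stringsAsFactors = FALSE)
  coords <- array(0, dim = c(n, 3L, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  ensemble(atoms, coords, rna_chain = rna_chain)
}

# deterministic random proper rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(X, R, t = c(0, 0, 0)) {
  sweep(X %*% t(R), 2L, t, `+`)
}

# points evenly spread on a sphere (independent of the package's internal
# layout helper)
sphere_points <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
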