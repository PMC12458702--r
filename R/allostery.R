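#' Gaussian-network contact topology of a conformation
#'
#' Builds the Kirchhoff (graph Laplacian) matrix of C-alpha contacts:
#' Gamma_ij = -1 for residue pairs within `cutoff`, diagonal = degree.
#' The network must be connected for the random-walk stage; a disconnected
#' graph raises an error naming the components.
#'
#' @param ens an [ensemble()] (or `n x 3` CA coordinate matrix).
#' @param residues optional 0-based residue restriction.
#' @param cutoff contact distance, Angstrom (default 10).
#' @param frame_index frame used when `ens` is an ensemble (default 1,
#'   typically a cluster representative).
#' @return object of class `contact_network`: `kirchhoff`, `adjacency`,
#'   `cutoff`, `nodes` (residue ids).
#' @export
build_network <- function(ens, residues = NULL, cutoff = 10,
                          frame_index = 1L) {
  if (inherits(ens, "ensemble")) {
    sel <- ca_indices(ens, residues)
    xyz <- ens$coords[sel, , frame_index, drop = TRUE]
    nodes <- ens$atoms$residue_index[sel]
  } else {
    xyz <- as.matrix(ens)
    nodes <- seq_len(nrow(xyz)) - 1L
  }
  n <- nrow(xyz)
  if (n < 2L) stop("need >= 2 residues")
  A <- as.matrix(stats::dist(xyz)) <= cutoff
  diag(A) <- FALSE
  A <- A * 1
  dimnames(A) <- list(nodes, nodes)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    sizes <- sort(comp$csize, decreasing = TRUE)
    stop("contact network is disconnected at cutoff ", cutoff, " A: ",
         comp$no, " components of sizes ",
         paste(sizes, collapse = ", "))
  }
  K <- diag(rowSums(A)) - A
  dimnames(K) <- dimnames(A)
  structure(list(kirchhoff = K, adjacency = A, cutoff = cutoff,
                 nodes = nodes),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat("contact_network:", length(x$nodes), "nodes,",
      sum(x$adjacency) / 2, "contacts at cutoff", x$cutoff, "A\n")
  invisible(x)
}

#' Markov hit and commute times on a contact network
#'
#' Random walk with transition matrix P = D^-1 A over the binary contact
#' adjacency. H(i -> j), the expected number of steps to first reach j from
#' i, solves the first-passage linear system (I - P_{-j}) h = 1 for every
#' target j; the commute time C(i, j) = H(i -> j) + H(j -> i) is symmetric
#' and serves as the allosteric communication distance. Contact edges are
#' re-weighted by C for the pathway search.
#'
#' @param network a [build_network()] result (connected).
#' @return object of class `commute_graph`: `hit` (H(i -> j) in steps,
#'   rows = i), `commute`, `graph` (igraph object with commute-time edge
#'   weights), `nodes`.
#' @export
markov_times <- function(network) {
  A <- network$adjacency
  n <- nrow(A)
  d <- rowSums(A)
  P <- A / d
  H <- matrix(0, n, n, dimnames = dimnames(A))
  I <- diag(n - 1L)
  for (j in seq_len(n)) {
    M <- I - P[-j, -j, drop = FALSE]
    h <- tryCatch(solve(M, rep(1, n - 1L)),
                  error = function(e) stop("first-passage system singular ",
                    "for target ", j, ": ", conditionMessage(e)))
    H[-j, j] <- h
  }
  C <- H + t(H)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- C[el]
  igraph::V(g)$name <- as.character(network$nodes)
  structure(list(hit = H, commute = C, graph = g, nodes = network$nodes),
            class = "commute_graph")
}

#' @export
print.commute_graph <- function(x, ...) {
  cat("commute_graph:", length(x$nodes), "nodes; mean commute time",
      signif(mean(x$commute[upper.tri(x$commute)]), 5), "steps\n")
  invisible(x)
}

#' k shortest commute-weighted communication pathways
#'
#' Loopless (Yen) enumeration of the k globally shortest paths from any
#' source residue to any target residue over the contact graph with
#' commute-time edge weights; realised set-to-set via zero-weight
#' super-source/super-target edges. Path score = sum of edge commute times.
#' Equal-weight ties are broken lexicographically on the node sequence.
#'
#' @param cg a [markov_times()] result.
#' @param source_set,target_set disjoint non-empty residue id vectors.
#' @param k number of pathways (default 15); fewer are returned when fewer
#'   simple paths exist.
#' @return object of class `pathway_set`: `paths` (list of residue-id
#'   vectors), `weights` (ascending), `source_set`, `target_set`, `k`.
#' @export
shortest_pathways <- function(cg, source_set, target_set, k = 15L) {
  if (length(source_set) == 0L || length(target_set) == 0L) {
    stop("source and target sets must be non-empty")
  }
  if (length(intersect(source_set, target_set))) {
    stop("source and target sets overlap")
  }
  miss <- setdiff(c(source_set, target_set), cg$nodes)
  if (length(miss)) stop("unknown residue id(s): ",
                         paste(miss, collapse = ", "))
  g <- cg$graph
  g <- igraph::add_vertices(g, 2L, name = c(".SRC", ".TGT"))
  src_v <- match(as.character(source_set), igraph::V(g)$name)
  tgt_v <- match(as.character(target_set), igraph::V(g)$name)
  s_id <- match(".SRC", igraph::V(g)$name)
  t_id <- match(".TGT", igraph::V(g)$name)
  g <- igraph::add_edges(g, rbind(s_id, src_v), weight = 0)
  g <- igraph::add_edges(g, rbind(tgt_v, t_id), weight = 0)
  ks <- igraph::k_shortest_paths(g, from = s_id, to = t_id, k = k,
                                 weights = igraph::E(g)$weight)
  paths <- lapply(ks$vpaths, function(vp) {
    ids <- as.integer(igraph::V(g)$name[as.integer(vp)][-c(1, length(vp))])
    ids
  })
  weights <- vapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (length(p) < 2L) return(0)
    idx <- match(as.character(p), as.character(cg$nodes))
    sum(cg$commute[cbind(idx[-length(idx)], idx[-1])])
  }, 1.0)
  lex <- vapply(paths, function(p) paste(sprintf("%08d", p), collapse = ","), "")
  ord <- order(weights, lex)
  structure(list(paths = paths[ord], weights = weights[ord],
                 source_set = source_set, target_set = target_set, k = k),
            class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat("pathway_set:", length(x$paths), "pathway(s)\n")
  for (i in utils::head(seq_along(x$paths), 5)) {
    cat(sprintf("  %2d. [%s]  weight %.3f\n", i,
                paste(x$paths[[i]], collapse = "-"), x$weights[i]))
  }
  invisible(x)
}

#' Hotspot conservation across representatives and conditions
#'
#' Scores every residue by the number of top-k pathways (pooled across a
#' condition's cluster representatives) that pass through it, excluding
#' source/target endpoints; reports the `top_n` hotspots per condition,
#' the pairwise overlap of those hotspot sets between conditions, and each
#' condition's communication efficiency (mean total commute time of its
#' pathways, shorter = more efficient).
#'
#' @param pathway_sets named list (one entry per condition) of lists of
#'   [shortest_pathways()] results (one per cluster representative).
#' @param top_n hotspots per condition (default 15).
#' @return list: `scores` (named list of sorted residue scores), `top`
#'   (named list of hotspot residue ids), `overlap` (condition x condition
#'   matrix of intersection sizes), `efficiency` (named mean path commute
#'   time).
#' @export
hotspot_conservation <- function(pathway_sets, top_n = 15L) {
  if (length(pathway_sets) == 0L) stop("no pathway sets supplied")
  conds <- names(pathway_sets)
  scores <- list(); top <- list(); eff <- numeric(0)
  for (cn in conds) {
    psets <- pathway_sets[[cn]]
    if (inherits(psets, "pathway_set")) psets <- list(psets)
    if (length(psets) == 0L) stop("condition '", cn, "' has no pathways")
    tally <- integer(0)
    all_w <- numeric(0)
    for (ps in psets) {
      ends <- c(ps$source_set, ps$target_set)
      for (p in ps$paths) {
        inner <- setdiff(p, ends)
        for (r in inner) {
          key <- as.character(r)
          tally[key] <- if (key %in% names(tally)) tally[key] + 1L else 1L
        }
      }
      all_w <- c(all_w, ps$weights)
    }
    if (length(tally)) {
      ord <- order(-tally, as.integer(names(tally)))
      tally <- tally[ord]
    }
    scores[[cn]] <- tally
    top[[cn]] <- as.integer(names(utils::head(tally, top_n)))
    eff[cn] <- if (length(all_w)) mean(all_w) else NA_real_
  }
  overlap <- matrix(NA_integer_, length(conds), length(conds),
                    dimnames = list(conds, conds))
  for (a in conds) for (b in conds) {
    overlap[a, b] <- length(intersect(top[[a]], top[[b]]))
  }
  list(scores = scores, top = top, overlap = overlap, efficiency = eff)
}
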