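#' @name interactions
#' @rdname interactions
NULL

read_chem_table <- function(name) {
  utils::read.csv(system.file("extdata", name, package = "confdyn",
                              mustWork = TRUE),
                  stringsAsFactors = FALSE, comment.char = "#")
}

match_chem <- function(atoms, tab) {
  hit <- rep(FALSE, nrow(atoms))
  for (r in seq_len(nrow(tab))) {
    res_ok <- if (tab$residue_name[r] == "*") TRUE else
      atoms$residue_name == tab$residue_name[r]
    hit <- hit | (res_ok & atoms$name == tab$atom_name[r])
  }
  which(hit)
}

# hydrogens covalently attached to each donor heavy atom, inferred from the
# first frame (bond length <= 1.25 A)
attached_hydrogens <- function(ens, donor_idx) {
  fr <- get_frame(ens, 1L)
  h_idx <- which(ens$atoms$element == "H" | startsWith(ens$atoms$name, "H"))
  out <- vector("list", length(donor_idx))
  for (i in seq_along(donor_idx)) {
    d <- donor_idx[i]
    same_res <- h_idx[ens$atoms$residue_index[h_idx] ==
                      ens$atoms$residue_index[d]]
    if (length(same_res)) {
      dd <- sqrt(rowSums((fr[same_res, , drop = FALSE] -
                          matrix(fr[d, ], length(same_res), 3L,
                                 byrow = TRUE))^2))
      out[[i]] <- same_res[dd <= 1.25]
    } else out[[i]] <- integer()
  }
  out
}

new_bond_event <- function(kind, res_a, atom_a, res_b, atom_b, trace) {
  list(kind = kind, res_a = res_a, atom_a = atom_a,
       res_b = res_b, atom_b = atom_b,
       trace = trace, persistence = mean(trace))
}

#' Detect hydrogen bonds over a trajectory
#'
#' A bond is present in a frame iff the donor-acceptor heavy-atom distance
#' is at most `d_cut` and some hydrogen attached to the donor makes a
#' D-H...A angle of at least `angle_cut` degrees. Donor and acceptor atoms
#' come from the bundled chemistry tables (backbone amide N / carbonyl O
#' plus the polar side chains); hydrogens must be explicit in the structure.
#'
#' @param ens an all-atom [ensemble()] with explicit hydrogens.
#' @param d_cut donor-acceptor distance cutoff, Angstrom (default 3.0).
#' @param angle_cut D-H...A angle cutoff, degrees (default 160).
#' @return list of bond events (kind `"hbond"`), each with the per-frame
#'   occupancy trace and its persistence.
#' @export
detect_hbonds <- function(ens, d_cut = 3.0, angle_cut = 160) {
  atoms <- ens$atoms
  donors <- match_chem(atoms, read_chem_table("hbond_donors.csv"))
  acceptors <- match_chem(atoms, read_chem_table("hbond_acceptors.csv"))
  if (length(donors) == 0L || length(acceptors) == 0L) return(list())
  hyd <- attached_hydrogens(ens, donors)
  has_h <- lengths(hyd) > 0L
  if (!any(has_h)) {
    stop("no hydrogens attached to any donor: supply a structure with ",
         "explicit hydrogens (H atoms within 1.25 A of their donor heavy ",
         "atom in frame 1)")
  }
  donors <- donors[has_h]; hyd <- hyd[has_h]
  nfr <- n_frames(ens)
  cosmin <- cos(angle_cut * pi / 180)
  events <- list()
  for (k in seq_len(nfr)) {
    fr <- ens$coords[, , k, drop = TRUE]
    for (di in seq_along(donors)) {
      d <- donors[di]
      acc <- acceptors[atoms$residue_index[acceptors] != atoms$residue_index[d]]
      if (length(acc) == 0L) next
      dd <- sqrt(rowSums((fr[acc, , drop = FALSE] -
                          matrix(fr[d, ], length(acc), 3L, byrow = TRUE))^2))
      close <- acc[dd <= d_cut]
      for (a in close) {
        ok <- FALSE
        for (h in hyd[[di]]) {
          u <- fr[d, ] - fr[h, ]; v <- fr[a, ] - fr[h, ]
          ca <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
          if (ca <= cosmin) { ok <- TRUE; break }   # angle >= angle_cut
        }
        if (ok) {
          key <- paste(atoms$residue_index[d], atoms$name[d],
                       atoms$residue_index[a], atoms$name[a], sep = "|")
          if (is.null(events[[key]])) {
            events[[key]] <- new_bond_event(
              "hbond", atoms$residue_index[d], atoms$name[d],
              atoms$residue_index[a], atoms$name[a], rep(FALSE, nfr))
          }
          events[[key]]$trace[k] <- TRUE
        }
      }
    }
  }
  events <- lapply(events, function(e) {
    e$persistence <- mean(e$trace); e
  })
  unname(events)
}

#' Detect salt bridges over a trajectory
#'
#' Present in a frame iff any basic nitrogen (Lys NZ, Arg NH1/NH2/NE, His
#' ND1/NE2) lies within `d_cut` (inclusive) of any acidic oxygen (Asp
#' OD1/OD2, Glu OE1/OE2, C-terminal OXT) of a different residue.
#'
#' @param ens an [ensemble()].
#' @param d_cut N-O distance cutoff, Angstrom (default 4.0).
#' @return list of bond events (kind `"saltbridge"`).
#' @export
detect_saltbridges <- function(ens, d_cut = 4.0) {
  atoms <- ens$atoms
  basic <- match_chem(atoms, read_chem_table("saltbridge_basic.csv"))
  acidic <- match_chem(atoms, read_chem_table("saltbridge_acidic.csv"))
  if (length(basic) == 0L || length(acidic) == 0L) return(list())
  nfr <- n_frames(ens)
  events <- list()
  for (k in seq_len(nfr)) {
    fr <- ens$coords[, , k, drop = TRUE]
    for (b in basic) {
      acc <- acidic[atoms$residue_index[acidic] != atoms$residue_index[b]]
      if (length(acc) == 0L) next
      dd <- sqrt(rowSums((fr[acc, , drop = FALSE] -
                          matrix(fr[b, ], length(acc), 3L, byrow = TRUE))^2))
      for (a in acc[dd <= d_cut]) {
        key <- paste(atoms$residue_index[b], atoms$name[b],
                     atoms$residue_index[a], atoms$name[a], sep = "|")
        if (is.null(events[[key]])) {
          events[[key]] <- new_bond_event(
            "saltbridge", atoms$residue_index[b], atoms$name[b],
            atoms$residue_index[a], atoms$name[a], rep(FALSE, nfr))
        }
        events[[key]]$trace[k] <- TRUE
      }
    }
  }
  events <- lapply(events, function(e) { e$persistence <- mean(e$trace); e })
  unname(events)
}

equivalence_class <- function(res_name, atom_name, tab) {
  hit <- tab$residue_name == res_name & tab$atom_name == atom_name
  if (any(hit)) tab$class_name[which(hit)[1]] else atom_name
}

#' Merge bonds mediated by chemically equivalent atoms
#'
#' Events identical up to a within-class atom swap (Asp OD1/OD2, Glu
#' OE1/OE2, Arg NH1/NH2, Phe/Tyr ring carbon pairs) are merged into one
#' event whose persistence is the arithmetic mean of the merged
#' persistences; the merged trace is the frame-wise OR, kept for
#' classification only. Idempotent.
#'
#' @param events bond-event list from the `detect_*` functions.
#' @param ens the ensemble the events came from (for residue names).
#' @return merged bond-event list; merged events carry the class label as
#'   atom name.
#' @export
average_equivalent <- function(events, ens) {
  if (length(events) == 0L) return(events)
  tab <- read_chem_table("equivalence_classes.csv")
  res_name_of <- function(res) ens$atoms$residue_name[
    match(res, ens$atoms$residue_index)]
  keys <- vapply(events, function(e) {
    ca <- equivalence_class(res_name_of(e$res_a), e$atom_a, tab)
    cb <- equivalence_class(res_name_of(e$res_b), e$atom_b, tab)
    paste(e$kind, e$res_a, ca, e$res_b, cb, sep = "|")
  }, "")
  out <- list()
  for (g in unique(keys)) {
    members <- events[keys == g]
    e <- members[[1]]
    ka <- strsplit(g, "|", fixed = TRUE)[[1]]
    e$atom_a <- ka[3]; e$atom_b <- ka[5]
    e$persistence <- mean(vapply(members, `[[`, 1.0, "persistence"))
    tr <- Reduce(`|`, lapply(members, `[[`, "trace"))
    e$trace <- tr
    out[[length(out) + 1L]] <- e
  }
  out
}

domain_of_residue <- function(res, partition) {
  for (d in names(partition$domains)) {
    if (res %in% partition$domains[[d]]) return(d)
  }
  NA_character_
}

#' Persistence-filter bond events into a classified table
#'
#' Applies equivalence-averaging (when `ens` is given), drops events with
#' persistence below `retain` (inclusive threshold: >= retain is kept) and
#' flags events with persistence strictly above `flag` as "meaningful".
#' When a partition is supplied, each bond is classified intra- or
#' inter-domain.
#'
#' @param events bond-event list.
#' @param retain retention threshold (default 0.05).
#' @param flag flagging threshold (default 0.20, strict).
#' @param ens optional ensemble enabling equivalence-averaging.
#' @param partition optional [domain_partition()] for classification.
#' @return object of class `persistence_table`: data.frame `bonds` (kind,
#'   res_a, atom_a, domain_a, res_b, atom_b, domain_b, persistence,
#'   classification, flagged) plus the thresholds and retained traces.
#' @export
persistence_filter <- function(events, retain = 0.05, flag = 0.20,
                               ens = NULL, partition = NULL) {
  if (length(events) > 0L &&
      any(vapply(events, function(e) length(e$trace), 1L) == 0L)) {
    stop("empty occupancy trace")
  }
  if (!is.null(ens)) events <- average_equivalent(events, ens)
  pers <- vapply(events, `[[`, 1.0, "persistence")
  keep <- which(pers >= retain)
  events <- events[keep]; pers <- pers[keep]
  dom <- function(res) if (is.null(partition)) NA_character_ else
    domain_of_residue(res, partition)
  bonds <- if (length(events) == 0L) {
    data.frame(kind = character(), res_a = integer(), atom_a = character(),
               domain_a = character(), res_b = integer(),
               atom_b = character(), domain_b = character(),
               persistence = numeric(), classification = character(),
               flagged = logical(), stringsAsFactors = FALSE)
  } else {
    da <- vapply(events, function(e) dom(e$res_a), "")
    db <- vapply(events, function(e) dom(e$res_b), "")
    data.frame(
      kind = vapply(events, `[[`, "", "kind"),
      res_a = vapply(events, `[[`, 1L, "res_a"),
      atom_a = vapply(events, `[[`, "", "atom_a"),
      domain_a = da,
      res_b = vapply(events, `[[`, 1L, "res_b"),
      atom_b = vapply(events, `[[`, "", "atom_b"),
      domain_b = db,
      persistence = pers,
      classification = ifelse(is.na(da) | is.na(db), NA_character_,
                              ifelse(da == db, "intra", "inter")),
      flagged = pers > flag,
      stringsAsFactors = FALSE)
  }
  structure(list(bonds = bonds[order(-bonds$persistence), , drop = FALSE],
                 retain = retain, flag = flag,
                 traces = lapply(events, `[[`, "trace")),
            class = "persistence_table")
}

#' @export
print.persistence_table <- function(x, ...) {
  cat("persistence_table:", nrow(x$bonds), "bond(s) retained (>=",
      x$retain, "), ", sum(x$bonds$flagged), "flagged (>", x$flag, ")\n")
  print(utils::head(x$bonds, 10), row.names = FALSE)
  invisible(x)
}

#' Per-domain intradomain hydrogen-bond statistics
#'
#' Counts, per frame, the hydrogen bonds whose donor and acceptor residues
#' belong to the same domain, and reports the per-domain mean and standard
#' deviation across frames.
#'
#' @param ens an all-atom [ensemble()].
#' @param partition a [domain_partition()].
#' @param ... passed to [detect_hbonds()].
#' @return data.frame (`domain`, `mean`, `sd`).
#' @export
count_intradomain_hbonds <- function(ens, partition, ...) {
  events <- detect_hbonds(ens, ...)
  nfr <- n_frames(ens)
  doms <- names(partition$domains)
  counts <- matrix(0L, nfr, length(doms), dimnames = list(NULL, doms))
  for (e in events) {
    da <- domain_of_residue(e$res_a, partition)
    db <- domain_of_residue(e$res_b, partition)
    if (!is.na(da) && identical(da, db)) {
      counts[, da] <- counts[, da] + e$trace
    }
  }
  data.frame(domain = doms,
             mean = colMeans(counts),
             sd = apply(counts, 2L, function(v) sqrt(mean((v - mean(v))^2))),
             row.names = NULL)
}
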