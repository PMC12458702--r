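#' Definition of an internal hydration region
#'
#' A named spatial region: a water resides inside when its oxygen lies
#' within `inclusion_radius` of any anchor atom (the side-chain, backbone
#' or C-beta selections that delimit internal "lake" cavities).
#'
#' @param name region name.
#' @param anchor_atoms integer atom indices of the anchor selection.
#' @param inclusion_radius Angstrom (default 4).
#' @return object of class `region_definition`.
#' @export
region_definition <- function(name, anchor_atoms, inclusion_radius = 4) {
  if (length(anchor_atoms) == 0L) stop("region needs at least one anchor atom")
  if (inclusion_radius <= 0) stop("inclusion_radius must be > 0")
  structure(list(name = name, anchor_atoms = as.integer(anchor_atoms),
                 inclusion_radius = inclusion_radius),
            class = "region_definition")
}

#' Per-frame occupancy of a hydration region
#'
#' A water is inside the region at frame t iff its oxygen atom is within
#' the inclusion radius (inclusive) of any anchor atom at t. Water ids come
#' from `ens$metadata$water_ids` (slot x frame matrix, as written by
#' [make_water_region()]) when present, else from the residue index.
#'
#' @param ens an [ensemble()] containing water molecules.
#' @param region a [region_definition()].
#' @param water_names residue names recognised as water.
#' @return object of class `occupancy_trace`: a list of per-frame integer
#'   id vectors, with attribute `n_frames`.
#' @export
occupancy_trace <- function(ens, region,
                            water_names = c("HOH", "WAT", "TIP3")) {
  atoms <- ens$atoms
  wat <- which(atoms$residue_name %in% water_names &
               (atoms$element == "O" | startsWith(atoms$name, "O")))
  if (length(wat) == 0L) stop("no water oxygens found (residue names ",
                              paste(water_names, collapse = "/"), ")")
  anchors <- region$anchor_atoms
  ids_matrix <- ens$metadata$water_ids
  nfr <- n_frames(ens)
  out <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    fr <- ens$coords[, , k, drop = TRUE]
    W <- fr[wat, , drop = FALSE]
    inside <- rep(FALSE, nrow(W))
    for (a in anchors) {
      d2 <- rowSums(sweep(W, 2L, fr[a, ])^2)
      inside <- inside | d2 <= region$inclusion_radius^2
    }
    ids <- if (!is.null(ids_matrix)) ids_matrix[, k] else
      atoms$residue_index[wat]
    out[[k]] <- sort(ids[inside])
  }
  structure(out, class = "occupancy_trace", n_frames = nfr)
}

# runs of continuous presence per id -> data.frame(start, end)
presence_runs <- function(traces) {
  nfr <- length(traces)
  frame <- rep.int(seq_len(nfr), lengths(traces))
  id <- unlist(traces, use.names = FALSE)
  if (length(id) == 0L) return(data.frame(start = integer(), end = integer()))
  o <- order(id, frame)
  id <- id[o]; frame <- frame[o]
  new_run <- c(TRUE, id[-1] != id[-length(id)] | diff(frame) != 1L)
  run_id <- cumsum(new_run)
  data.frame(start = frame[new_run],
             end = frame[c(new_run[-1], TRUE)])
}

#' Survival probability of waters in a region
#'
#' P(tau) = (1/T_n) * sum_t N(t,tau) / N(t): the fraction of waters present
#' at origin t that remain continuously in the region through t + tau,
#' averaged over all valid origins and across time windows. The trajectory
#' (after discarding `skip` equilibration frames) is divided into
#' consecutive windows of `window_length` frames; within each window every
#' origin t with N(t) > 0 and t + max(tau) still inside the window
#' contributes (a common origin set across lags keeps P monotone).
#'
#' @param traces an [occupancy_trace()] (or plain list of per-frame id
#'   vectors).
#' @param taus integer lags in frames (0 is allowed; P(0) = 1).
#' @param window_length frames per window (default: one window spanning
#'   everything after `skip`).
#' @param skip equilibration frames discarded from the start (default 0).
#' @return object of class `survival_curve`: `taus`, `values`, `stderr`
#'   (across windows), `n_windows`, `skip`.
#' @export
survival_probability <- function(traces, taus, window_length = NULL,
                                 skip = 0L) {
  nfr <- length(traces)
  traces <- traces[seq_len(nfr) > skip]
  nfr <- length(traces)
  if (is.null(window_length)) window_length <- nfr
  taus <- sort(unique(as.integer(taus)))
  if (any(taus < 0L)) stop("taus must be >= 0")
  if (max(taus) > window_length) stop("tau exceeds the window length")
  if (window_length > nfr) stop("window longer than the available trajectory")
  runs <- presence_runs(traces)
  # N(t) and, per tau, N(t, tau) via difference-array accumulation over runs
  diffcount <- function(lo, hi) {   # counts over [lo, hi] intervals
    d <- numeric(nfr + 1L)
    ok <- hi >= lo
    if (any(ok)) {
      ag <- rowsum(rep(1, sum(ok)), lo[ok]); d[as.integer(rownames(ag))] <-
        d[as.integer(rownames(ag))] + ag
      ag <- rowsum(rep(1, sum(ok)), hi[ok] + 1L)
      d[as.integer(rownames(ag))] <- d[as.integer(rownames(ag))] - ag
    }
    cumsum(d)[seq_len(nfr)]
  }
  Nt <- diffcount(runs$start, runs$end)
  n_win <- nfr %/% window_length
  win_start <- (seq_len(n_win) - 1L) * window_length + 1L
  tmax <- max(taus)
  vals <- matrix(NA_real_, n_win, length(taus))
  for (ti in seq_along(taus)) {
    tau <- taus[ti]
    Ntau <- if (tau == 0L) Nt else diffcount(runs$start, runs$end - tau)
    for (w in seq_len(n_win)) {
      hi <- win_start[w] + window_length - 1L - tmax
      if (hi < win_start[w]) next
      origins <- win_start[w]:hi
      origins <- origins[Nt[origins] > 0]
      if (length(origins)) vals[w, ti] <- mean(Ntau[origins] / Nt[origins])
    }
  }
  P <- colMeans(vals, na.rm = TRUE)
  se <- apply(vals, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  stopifnot(all(P >= -1e-12 & P <= 1 + 1e-12), all(diff(P) <= 1e-12))
  structure(list(taus = taus, values = pmin(pmax(P, 0), 1), stderr = se,
                 n_windows = n_win, skip = skip,
                 window_length = window_length),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("survival_curve over", length(x$taus), "lags,", x$n_windows,
      "window(s) of", x$window_length, "frames (skip", x$skip, ")\n")
  print(data.frame(tau = x$taus, P = signif(x$values, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, ...) {
  graphics::plot(x$taus, x$values, type = "b", ylim = c(0, 1),
                 xlab = "tau (frames)", ylab = "P(tau)", ...)
  invisible(x)
}

#' Compare survival curves across conditions
#'
#' @param curves named list of [survival_probability()] results on matching
#'   tau grids.
#' @return list: `auc` (named trapezoid area under P(tau) per condition)
#'   and `differences` (data.frame of per-tau differences for every
#'   condition pair, columns `"A-B"`).
#' @export
compare_conditions <- function(curves) {
  if (length(curves) < 2L) stop("need >= 2 conditions")
  taus <- curves[[1]]$taus
  for (cv in curves) if (!identical(cv$taus, taus)) stop("tau grids differ")
  trap <- function(v) {
    if (length(taus) == 1L) return(v[1])
    sum(diff(taus) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  }
  auc <- vapply(curves, function(cv) trap(cv$values), 1.0)
  nm <- names(curves)
  diffs <- data.frame(tau = taus)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i < j) diffs[[paste(nm[i], nm[j], sep = "-")]] <-
      curves[[i]]$values - curves[[j]]$values
  }
  list(auc = auc, differences = diffs)
}
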