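#' Default configuration of the synthetic end-to-end demo
#'
#' Every stage parameter named by the analysis modules, with the bundled
#' demo scale: a 6-domain toy protein (105 residues), 150-frame ensembles,
#' two planted common-mode breathing motions, one label-separating
#' descriptor shift, geometric water exchange at two rates, a planted
#' two-block energy matrix, and planted bond occupancies.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_frames = 150L,
    stages = c("simulate", "df", "descriptors", "edm", "networks",
               "pocket", "water", "allostery", "report"),
    simulate = list(domain_sizes = c(N = 20L, L1 = 10L, PAZ = 20L,
                                     L2 = 14L, MID = 20L, PIWI = 21L),
                    domain_sigma = 0.5, spacing = 40,
                    breathing_amplitudes = c(6, 4),
                    breathing_periods = c(37, 23),
                    effect_descriptor = "d_L1_L2",
                    effect_shift = 3.5,
                    labels = c("hAgo1", "hAgo2", "hAgo3", "hAgo4"),
                    effect_label = "hAgo2"),
    df = list(skip = 0L),
    descriptors = list(min_variance = 0.15),
    edm = list(threshold = 0.005, block_depths = c(-5, -1),
               block_size = 8L, noise = 0.02),
    networks = list(d_cut = 3.0, angle_cut = 160, sb_cut = 4.0,
                    retain = 0.05, flag = 0.20,
                    occupancies = c(0.30, 0.05, 0.50)),
    pocket = list(cutoff = 6.0, grid = 1.0, probe = 1.4,
                  n_cluster_frames = 8L, epsilon = 3.0),
    water = list(exchange_rates = c(slow = 0.05, fast = 0.2),
                 n_waters = 120L, taus = 0:10,
                 window_length = 50L, skip = 10L),
    allostery = list(cutoff = 10, k = 10L, spacing = 9,
                     domain_sizes = c(N = 12L, L1 = 8L, PAZ = 12L,
                                      L2 = 8L, MID = 12L, PIWI = 14L),
                     top_n = 10L))
}

merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

write_csv_out <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  path
}

write_json_out <- function(x, dir, name) {
  path <- file.path(dir, name)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  path
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Orchestrates all analysis stages on generated data with planted
#' structure: simulate, df, descriptors, edm, networks, pocket, water,
#' allostery, report. Every output is a CSV/JSON file under `out_dir`;
#' the run is a pure function of the configuration and seed (re-running
#' writes byte-identical files). The `report` stage writes a manifest with
#' the echoed configuration, per-file md5 checksums, and the headline
#' numbers of each stage.
#'
#' @param config NULL (defaults), a named list overriding parts of
#'   [default_config()], or the path of a YAML file with the same layout.
#'   Unknown keys are rejected.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @param stages optional override of the stage list.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("confdyn_run_"),
                         seed = NULL, stages = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, default_config())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(stages)) cfg$stages <- stages
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  summary <- list()
  sim <- cfg$simulate

  base_spec <- synthetic_spec(
    seed = cfg$seed, n_frames = cfg$n_frames,
    domain_sizes = sim$domain_sizes, domain_sigma = sim$domain_sigma,
    spacing = sim$spacing,
    breathing = list(
      list(pair = c("PAZ", "MID"), amplitude = sim$breathing_amplitudes[1],
           period = sim$breathing_periods[1]),
      list(pair = c("N", "PIWI"), amplitude = sim$breathing_amplitudes[2],
           period = sim$breathing_periods[2])))
  toy <- make_toy_protein(base_spec)

  if ("simulate" %in% cfg$stages) {
    files <- c(files, write_structure(toy, file.path(out_dir, "reference.pdb")))
    doms <- toy$partition$domains
    files <- c(files, write_csv_out(
      data.frame(domain = rep(names(doms), lengths(doms)),
                 residue = unlist(doms, use.names = FALSE)),
      out_dir, "domains.csv"))
  }

  apo <- make_ensemble(base_spec, reference = toy, label = "apo")
  nobreath_spec <- base_spec; nobreath_spec$breathing <- NULL
  bound <- make_ensemble(nobreath_spec, reference = toy,
                         seed = cfg$seed + 1L, label = "bound")

  if ("df" %in% cfg$stages) {
    df_apo <- compute_df(apo, skip = cfg$df$skip)
    df_bound <- compute_df(bound, skip = cfg$df$skip)
    blocks <- df_block_summary(df_apo, toy$partition)
    delta <- df_difference(df_bound, df_apo)
    files <- c(files,
      write_csv_out(as.data.frame(df_apo$values), out_dir, "df_apo.csv"),
      write_csv_out(as.data.frame(df_bound$values), out_dir, "df_bound.csv"),
      write_csv_out(as.data.frame(blocks), out_dir, "df_blocks_apo.csv"),
      write_csv_out(as.data.frame(delta), out_dir, "df_bound_minus_apo.csv"))
    summary$df <- list(
      mean_df_apo = mean(df_apo$values[upper.tri(df_apo$values)]),
      mean_df_bound = mean(df_bound$values[upper.tri(df_bound$values)]),
      max_block_pair = paste(
        rownames(blocks)[which(blocks == max(blocks), arr.ind = TRUE)[1, ]],
        collapse = "-"))
  }

  if ("descriptors" %in% cfg$stages) {
    effects <- stats::setNames(
      rep(list(stats::setNames(numeric(0), character(0))), length(sim$labels)),
      sim$labels)
    effects[[sim$effect_label]] <-
      stats::setNames(sim$effect_shift, sim$effect_descriptor)
    lab_spec <- base_spec; lab_spec$label_effects <- effects
    ens_set <- make_labeled_set(lab_spec, sim$labels)
    dmats <- lapply(ens_set, compute_descriptors)
    pca <- fit_pca(dmats)
    seld <- select_discriminative(pca, min_variance = cfg$descriptors$min_variance)
    pooled <- do.call(rbind, lapply(dmats, function(m)
      data.frame(label = m$labels, m$values, check.names = FALSE)))
    files <- c(files, write_csv_out(pooled, out_dir, "descriptors.csv"))
    files <- c(files, write_json_out(list(
      explained_variance = seld$explained_variance,
      top_pair = seld$top_pair, top_ch = seld$top_ch,
      no_qualifying_pair = isTRUE(seld$no_qualifying_pair),
      top_descriptors = utils::head(seld$top_descriptors, 5)),
      out_dir, "pca_selection.json"))
    summary$descriptors <- list(
      planted = sim$effect_descriptor,
      top_descriptor = if (!is.null(seld$top_descriptors))
        seld$top_descriptors$descriptor[1] else NA,
      top_pair = seld$top_pair, top_ch = seld$top_ch)
  }

  if ("edm" %in% cfg$stages) {
    n_res <- sum(sim$domain_sizes)
    bs <- cfg$edm$block_size
    e_spec <- base_spec
    e_spec$energy_blocks <- list(
      list(residues = toy$partition$domains$PIWI[seq_len(bs)],
           depth = cfg$edm$block_depths[1]),
      list(residues = toy$partition$domains$MID[seq_len(bs)],
           depth = cfg$edm$block_depths[2]))
    e_spec$energy_noise <- cfg$edm$noise
    M <- make_energy_matrix(e_spec, n = n_res)
    dimnames(M) <- list(0:(n_res - 1L), 0:(n_res - 1L))
    ed <- edm_eigen(M)
    nuc <- electrostatic_nuclei(ed, toy$partition,
                                threshold = cfg$edm$threshold)
    files <- c(files, write_csv_out(
      data.frame(residue = as.integer(names(ed$profile)),
                 profile = ed$profile), out_dir, "edm_profile.csv"))
    files <- c(files, write_json_out(list(
      leading_eigenvalue = ed$eigenvalues[1],
      degenerate = ed$degenerate,
      nuclei_residues = nuc$residues,
      intradomain_counts = as.list(nuc$intradomain_counts)),
      out_dir, "edm_nuclei.json"))
    summary$edm <- list(leading_eigenvalue = ed$eigenvalues[1],
                        n_nuclei = length(nuc$residues))
  }

  if ("networks" %in% cfg$stages) {
    b_spec <- synthetic_spec(seed = cfg$seed, n_frames = cfg$n_frames,
      bond_traces = lapply(cfg$networks$occupancies,
                           function(f) list(occupancy = f)))
    bsys <- make_bonded_system(b_spec)
    hb <- detect_hbonds(bsys, d_cut = cfg$networks$d_cut,
                        angle_cut = cfg$networks$angle_cut)
    sb <- detect_saltbridges(bsys, d_cut = cfg$networks$sb_cut)
    half <- max(bsys$atoms$residue_index) %/% 2
    part2 <- domain_partition(
      lobeA = 0:half,
      lobeB = (half + 1L):max(bsys$atoms$residue_index))
    pt <- persistence_filter(c(hb, sb), retain = cfg$networks$retain,
                             flag = cfg$networks$flag, ens = bsys,
                             partition = part2)
    files <- c(files, write_csv_out(pt$bonds, out_dir, "bond_persistence.csv"))
    summary$networks <- list(planted = bsys$metadata$planted_occupancy,
                             retained = nrow(pt$bonds),
                             flagged = sum(pt$bonds$flagged))
  }

  if ("pocket" %in% cfg$stages) {
    rna_n <- 6L
    piwi_c <- toy$metadata$centers["PIWI", ]
    n_prot <- nrow(toy$atoms)
    rna_atoms <- data.frame(
      atom_id = n_prot + seq_len(rna_n), name = "P", element = "P",
      residue_index = max(toy$atoms$residue_index) + seq_len(rna_n),
      residue_name = "U", chain_id = "R",
      resno = seq_len(rna_n), insert = "", stringsAsFactors = FALSE)
    rna_xyz <- matrix(rep(piwi_c, each = rna_n), rna_n, 3L) +
      cbind(seq(-2, 2, length.out = rna_n), 0, 0)
    nf_sub <- cfg$pocket$n_cluster_frames
    sub_idx <- round(seq(1L, n_frames(apo), length.out = nf_sub))
    coords <- array(0, dim = c(n_prot + rna_n, 3L, nf_sub))
    for (w in seq_len(nf_sub)) {
      coords[seq_len(n_prot), , w] <- apo$coords[, , sub_idx[w]]
      coords[n_prot + seq_len(rna_n), , w] <- rna_xyz
    }
    holo <- ensemble(rbind(toy$atoms, rna_atoms), coords,
                     label = "holo", partition = toy$partition,
                     rna_chain = "R")
    pk <- define_pocket(holo, cutoff = cfg$pocket$cutoff)
    cl <- cluster_frames(holo, residues = 0:(max(toy$atoms$residue_index)),
                         epsilon = cfg$pocket$epsilon)
    # the channel volume is a property of the protein: strip the RNA so its
    # atoms do not block the grid
    prot_only <- ensemble(toy$atoms, coords[seq_len(n_prot), , , drop = FALSE],
                          partition = toy$partition)
    vol <- channel_volume(prot_only, pk, cl$representatives,
                          grid = cfg$pocket$grid, probe = cfg$pocket$probe)
    files <- c(files, write_csv_out(
      data.frame(residue = pk$residues), out_dir, "pocket_residues.csv"))
    files <- c(files, write_json_out(list(
      weighted_volume = vol$weighted_mean, volumes = vol$volumes,
      weights = vol$weights, grid = vol$grid_spacing,
      probe = vol$probe_radius, algorithm = vol$algorithm),
      out_dir, "pocket_volume.json"))
    summary$pocket <- list(n_residues = length(pk$residues),
                           weighted_volume = vol$weighted_mean)
  }

  if ("water" %in% cfg$stages) {
    wcfg <- cfg$water
    curves <- list()
    for (nm in names(wcfg$exchange_rates)) {
      w_spec <- synthetic_spec(seed = cfg$seed, n_frames = cfg$n_frames,
        water_spec = list(n_waters = wcfg$n_waters,
                          exchange_rate = wcfg$exchange_rates[[nm]],
                          region_radius = 8))
      wr <- make_water_region(w_spec)
      tr <- occupancy_trace(wr$ensemble, wr$region)
      curves[[nm]] <- survival_probability(tr, taus = wcfg$taus,
                                           window_length = wcfg$window_length,
                                           skip = wcfg$skip)
    }
    cmp <- compare_conditions(curves)
    curve_df <- data.frame(tau = curves[[1]]$taus)
    for (nm in names(curves)) curve_df[[nm]] <- curves[[nm]]$values
    files <- c(files, write_csv_out(curve_df, out_dir, "survival_curves.csv"))
    files <- c(files, write_json_out(list(auc = as.list(cmp$auc)),
                                     out_dir, "survival_auc.json"))
    summary$water <- list(auc = as.list(cmp$auc))
  }

  if ("allostery" %in% cfg$stages) {
    acfg <- cfg$allostery
    a_spec <- synthetic_spec(seed = cfg$seed, n_frames = 4L,
                             domain_sizes = acfg$domain_sizes,
                             domain_sigma = 0.4, spacing = acfg$spacing)
    a_ens <- make_ensemble(a_spec)
    doms <- a_ens$partition$domains
    psets <- list(apo = list(), bound = list())
    for (w in 1:2) {
      net <- build_network(a_ens, cutoff = acfg$cutoff, frame_index = w)
      cg <- markov_times(net)
      psets$apo[[w]] <- shortest_pathways(cg, doms$N, doms$L1, k = acfg$k)
      net2 <- build_network(a_ens, cutoff = acfg$cutoff, frame_index = 2L + w)
      cg2 <- markov_times(net2)
      psets$bound[[w]] <- shortest_pathways(cg2, doms$N, doms$L1, k = acfg$k)
    }
    hot <- hotspot_conservation(psets, top_n = acfg$top_n)
    files <- c(files, write_json_out(list(
      top_apo = hot$top$apo, top_bound = hot$top$bound,
      overlap = hot$overlap["apo", "bound"],
      efficiency = as.list(hot$efficiency)),
      out_dir, "allostery_hotspots.json"))
    summary$allostery <- list(
      overlap = hot$overlap["apo", "bound"],
      efficiency = as.list(hot$efficiency))
  }

  manifest <- list(package = "confdyn",
                   version = as.character(utils::packageVersion("confdyn")),
                   seed = cfg$seed, stages = cfg$stages,
                   config = cfg, summary = summary,
                   outputs = lapply(stats::setNames(files, basename(files)),
                                    function(f) unname(tools::md5sum(f))))
  if ("report" %in% cfg$stages) {
    write_json_out(manifest, out_dir, "manifest.json")
  }
  invisible(manifest)
}
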