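#' Run the full ensemble analysis pipeline from one config
#'
#' Executes the enabled stages in dependency order on one conformational
#' ensemble, writing TSV outputs and a JSON run manifest into the output
#' directory.  Stage defaults pin the standard parameters of the method:
#' contact cutoff 4.5 A, I_min 2.5 percent, hub degree 4, clique sizes 3 and
#' 4, stability threshold 0.75, at most 1000 network snapshots, T = 300 K,
#' sigma = 0.0072 kcal/(mol A^2), probe 1.4 A.
#'
#' Config (a named list or YAML file path):
#' \describe{
#'   \item{input}{`ensemble` path (PDB), or `simulate = list(n_residues,
#'     geometry, sidechain_atoms, n_frames, cutoff)` for a seeded ANM toy}
#'   \item{stages}{character vector from bfactors, pca, dccm, dos,
#'     forceconst, network, centrality, communities, depth, mmgbsa, alascan}
#'   \item{parameters}{overrides: I_min, contact_cutoff, c_min, hub_degree,
#'     stability_threshold, max_snapshots, temperature, sigma_np, probe,
#'     points_per_atom, peak_window, peak_prominence, receptor, ligand,
#'     scan_residues, energy_series (path), depth_stride}
#'   \item{seed}{top-level seed, fanned out per stage}
#'   \item{output_dir}{where outputs and the manifest go}
#' }
#'
#' Stages that fail stop their dependents but independent stages still run.
#'
#' @param config named list or YAML path
#' @param output_dir overrides config$output_dir
#' @return object of class `run_manifest` (also written as manifest.json)
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- output_dir %||% config$output_dir %||%
    stop_allonet("output_dir required", "allonet_config_error")
  stages <- config$stages %||% c("bfactors", "pca", "dccm", "forceconst",
                                 "network", "centrality", "communities")
  deps_map <- list(centrality = c("dccm", "network"), communities = "network",
                   alascan = "mmgbsa")
  for (i in 1:2) stages <- union(stages, unlist(deps_map[intersect(stages, names(deps_map))]))
  seed <- config$seed %||% 1L
  p <- config$parameters %||% list()
  def <- list(I_min = 2.5, contact_cutoff = 4.5, c_min = 0.5, hub_degree = 4L,
              stability_threshold = 0.75, max_snapshots = 1000L,
              temperature = 300, sigma_np = 0.0072, probe = 1.4,
              points_per_atom = 64L, peak_window = 3L, peak_prominence = 0.5,
              anm_cutoff = 13, n_modes = 3L, depth_stride = 10L,
              denominator = "product")
  unset <- setdiff(names(def), names(p))
  p <- utils::modifyList(def, p)
  if (length(unset))
    message("defaulted parameters: ",
            paste(sprintf("%s=%s", unset, vapply(def[unset], format, "")), collapse = ", "))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- list(); outputs <- character(); inputs <- character()
  done <- new.env(parent = emptyenv())
  record <- function(stage, ok, msg = "") status[[stage]] <<- list(ok = ok, message = msg)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  run_stage <- function(stage, deps = character(), expr) {
    if (!stage %in% stages && !stage %in% deps) return(invisible())
    missing_dep <- deps[!vapply(deps, function(d) isTRUE(done[[d]]), logical(1))]
    if (length(missing_dep)) {
      record(stage, FALSE, paste("skipped: failed dependency", missing_dep[1]))
      return(invisible())
    }
    res <- tryCatch({ force(expr); done[[stage]] <- TRUE; record(stage, TRUE) },
                    error = function(e) record(stage, FALSE, conditionMessage(e)))
    invisible(res)
  }

  # --- input -----------------------------------------------------------
  env <- new.env(parent = emptyenv())
  ok_input <- tryCatch({
    if (!is.null(config$input$ensemble)) {
      if (!file.exists(config$input$ensemble))
        stop_allonet(paste("missing input:", config$input$ensemble), "allonet_config_error")
      inputs <- c(inputs, config$input$ensemble)
      env$ens <- read_ensemble(config$input$ensemble)
    } else if (!is.null(config$input$simulate)) {
      s <- config$input$simulate
      toy <- build_toy_protein(s$n_residues %||% 20L, s$geometry %||% "helix",
                               s$sidechain_atoms %||% 3L, seed = seed)
      model <- anm_covariance(toy, cutoff = p$anm_cutoff,
                              temperature = p$temperature)
      ca <- sample_gaussian_ensemble(model, s$n_frames %||% 200L, seed = seed)
      # re-dress CA displacements onto the full-atom toy so side-chain
      # contacts fluctuate with the backbone
      full <- as_ensemble(toy)
      F <- n_frames(ca)
      nat <- nrow(toy$atoms)
      xyz <- matrix(0, F, 3 * nat)
      ca_idx <- match(toy$atoms$res_index, seq_len(n_residues(toy)))
      mean_ca <- flat_xyz(model$mean_xyz)
      for (f in seq_len(F)) {
        disp <- matrix(ca$xyz[f, ] - mean_ca, ncol = 3, byrow = TRUE)
        xyz[f, ] <- flat_xyz(toy$xyz + disp[toy$atoms$res_index, , drop = FALSE])
      }
      env$ens <- new_ensemble(toy$atoms, xyz)
      env$model <- model
      emit("simulated_ensemble.pdb", function(pp) write_ensemble_pdb(env$ens, pp))
    } else stop_allonet("config$input must give `ensemble` or `simulate`",
                        "allonet_config_error")
    TRUE
  }, error = function(e) { record("input", FALSE, conditionMessage(e)); FALSE })
  if (!ok_input) {
    manifest <- structure(list(config = config, parameters = p, status = status,
                               outputs = outputs, ok = FALSE),
                          class = "run_manifest")
    return(manifest)
  }
  done[["input"]] <- TRUE
  record("input", TRUE)
  env$fitted <- superpose_ensemble(env$ens)

  # --- stages ----------------------------------------------------------
  run_stage("bfactors", "input", {
    env$b <- bfactor_profile(env$fitted, "CA")
    emit("bfactors.tsv", function(pp) write_profile(env$b, pp))
  })
  run_stage("pca", "input", {
    env$pca <- pca_modes(env$fitted, "CA")
    env$mob <- mode_mobility_profile(env$pca, p$n_modes)
    emit("mode_mobility.tsv", function(pp) write_profile(env$mob, pp))
    emit("pca_eigenvalues.tsv", function(pp)
      utils::write.table(data.frame(mode = seq_along(env$pca$values),
                                    eigenvalue = env$pca$values,
                                    var_frac = env$pca$var_frac),
                         pp, sep = "\t", quote = FALSE, row.names = FALSE))
  })
  run_stage("dccm", "input", {
    env$C <- cross_correlation(env$fitted)
    emit("dccm.tsv", function(pp)
      utils::write.table(format(unclass(env$C), digits = 8), pp, sep = "\t",
                         quote = FALSE))
  })
  run_stage("dos", "input", {
    es <- p$energy_series
    energy <- if (!is.null(es) && file.exists(as.character(es)))
      utils::read.table(es, header = TRUE)[[1]]
    else stop_allonet("dos stage needs parameters$energy_series", "allonet_config_error")
    rb <- rigid_body_decomposition(env$fitted, NULL,
                                   p$probe_selection %||% NULL, reference = 1L)
    env$dos <- density_of_states(energy, rb$rmsd)
    emit("density_of_states.tsv", function(pp)
      utils::write.table(env$dos$peaks, pp, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })
  run_stage("forceconst", "input", {
    env$k <- force_constant_profile(env$fitted, "all-atom", p$temperature)
    env$k_peaks <- detect_profile_peaks(env$k, p$peak_window, p$peak_prominence)
    emit("force_constants.tsv", function(pp) write_profile(env$k, pp))
    emit("force_constant_peaks.tsv", function(pp)
      utils::write.table(env$k_peaks, pp, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })
  run_stage("network", "input", {
    first <- frame_structure(env$ens, 1L)
    env$norm <- derive_normalization_table(first, p$contact_cutoff)
    env$im <- interaction_strengths(first, env$norm, p$denominator,
                                    p$contact_cutoff)
    env$scan <- lcc_transition_scan(env$im)
    env$graph <- build_graph(env$im, p$I_min)
    env$egs <- ensemble_graphs(env$ens, env$norm, p$I_min, p$max_snapshots,
                               denominator = p$denominator,
                               cutoff = p$contact_cutoff)
    emit("edges.tsv", function(pp) write_edge_list(env$im, pp, p$I_min))
    emit("lcc_scan.tsv", function(pp)
      utils::write.table(env$scan$scan, pp, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    emit("normalization.tsv", function(pp)
      utils::write.table(data.frame(restype = names(env$norm),
                                    N = as.numeric(env$norm)),
                         pp, sep = "\t", quote = FALSE, row.names = FALSE))
  })
  run_stage("centrality", c("input", "dccm", "network"), {
    env$cent <- ensemble_centrality(env$egs, env$C, c_min = p$c_min)
    env$cent_peaks <- detect_profile_peaks(env$cent$betweenness,
                                           p$peak_window, p$peak_prominence)
    env$dist <- centrality_distribution(env$cent)
    emit("centrality.tsv", function(pp)
      utils::write.table(env$cent, pp, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    emit("centrality_distribution.tsv", function(pp)
      utils::write.table(env$dist, pp, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    if (!is.null(p$clusters)) {
      env$clus <- cluster_average_centrality(env$cent, p$clusters)
      emit("cluster_centrality.tsv", function(pp)
        utils::write.table(env$clus, pp, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    }
  })
  run_stage("communities", c("input", "network"), {
    env$hubs <- find_hubs(env$graph, p$hub_degree)
    env$comms <- list()
    for (k in c(3L, 4L)) {
      cs <- clique_percolation_communities(enumerate_k_cliques(env$graph, k))
      env$comms[[as.character(k)]] <-
        community_stability_filter(cs, env$egs, p$stability_threshold)
    }
    emit("hubs.tsv", function(pp) writeLines(c("node", env$hubs), pp))
    emit("communities_k3.tsv", function(pp) write_communities(env$comms[["3"]], pp))
    emit("communities_k4.tsv", function(pp) write_communities(env$comms[["4"]], pp))
  })
  run_stage("depth", "input", {
    sel <- seq(1L, n_frames(env$ens), by = p$depth_stride)
    sub <- new_ensemble(env$ens$atoms, env$ens$xyz[sel, , drop = FALSE])
    env$depth <- residue_depth_profile(sub, p$probe, p$points_per_atom)
    emit("residue_depth.tsv", function(pp) write_profile(env$depth, pp))
  })
  run_stage("mmgbsa", "input", {
    if (is.null(p$receptor) || is.null(p$ligand))
      stop_allonet("mmgbsa needs parameters$receptor and parameters$ligand",
                   "allonet_config_error")
    env$etab <- snapshot_energy_table(env$ens, p$receptor, p$ligand,
                                      sigma_np = p$sigma_np, probe = p$probe,
                                      points_per_atom = p$points_per_atom)
    env$dg <- mmgbsa_aggregate(env$etab, p$TdS %||% 0)
    emit("energy_table.tsv", function(pp)
      utils::write.table(env$etab, pp, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })
  run_stage("alascan", c("input", "mmgbsa"), {
    res <- p$scan_residues %||%
      stop_allonet("alascan needs parameters$scan_residues", "allonet_config_error")
    env$scan_res <- alanine_scan(env$ens, res, p$receptor, p$ligand,
                                 sigma_np = p$sigma_np, probe = p$probe,
                                 points_per_atom = p$points_per_atom)
    emit("alanine_scan.tsv", function(pp)
      utils::write.table(env$scan_res, pp, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })

  manifest <- structure(list(
    config = config, parameters = p, seed = seed,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(outputs)),
    status = status,
    version = as.character(utils::packageVersion("allonet")),
    ok = all(vapply(status, `[[`, logical(1), "ok")),
    summary = list(
      hubs = env$hubs,
      top_centrality = if (!is.null(env$cent))
        utils::head(env$cent[order(-env$cent$betweenness), ], 10),
      k_peaks = env$k_peaks,
      transition_I_min = env$scan$transition,
      dG = if (!is.null(env$dg)) unclass(env$dg))),
    class = "run_manifest")
  json <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest_json(manifest), json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null", force = TRUE)
  manifest$path <- json
  manifest
}

manifest_json <- function(m) {
  m$summary$top_centrality <- NULL   # tabular; kept in TSV outputs
  m$summary$k_peaks <- NULL
  unclass(m)
}

#' Human-readable report from a run manifest
#'
#' @param manifest a `run_manifest` (or path to manifest.json)
#' @param path output text file
#' @return the path, invisibly
#' @export
generate_report <- function(manifest, path) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  missing <- names(manifest$outputs)[!file.exists(names(manifest$outputs))]
  if (length(missing))
    stop_allonet(paste("manifest references missing outputs:",
                       paste(missing, collapse = ", ")), "allonet_report_error")
  ln <- c("allonet run report", strrep("=", 60))
  for (st in names(manifest$status)) {
    s <- manifest$status[[st]]
    ln <- c(ln, sprintf("stage %-12s %s%s", st, if (isTRUE(s$ok)) "ok" else "FAILED",
                        if (nzchar(s$message %||% "")) paste0(" (", s$message, ")") else ""))
  }
  sm <- manifest$summary
  ln <- c(ln, "")
  ln <- c(ln, if (length(sm$hubs)) paste("hubs:", paste(unlist(sm$hubs), collapse = " "))
              else "hubs: none detected")
  if (!is.null(sm$transition_I_min) && !is.na(sm$transition_I_min))
    ln <- c(ln, sprintf("I_min transition: %s%%", sm$transition_I_min))
  if (!is.null(sm$top_centrality)) {
    ln <- c(ln, "top centrality residues:")
    tc <- sm$top_centrality
    ln <- c(ln, sprintf("  %-12s %.5f", tc$node, tc$betweenness))
  }
  if (!is.null(sm$dG))
    ln <- c(ln, sprintf("dG_bind = %.4f kcal/mol", sm$dG$dG_bind))
  ln <- c(ln, "", "outputs:", paste(" ", names(manifest$outputs)))
  writeLines(ln, path)
  invisible(path)
}
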