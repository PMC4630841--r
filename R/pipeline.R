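#' Default run configuration
#'
#' Builds the configuration list consumed by [run_study()], optionally
#' overridden by a YAML file (top-level keys with the same names). Input data
#' come either from a packaged simulation scenario (`scenario` + `seed`) or
#' from landmark files (`inputs`: a list of per-structure entries with `path`,
#' `format`, `template`).
#'
#' @param scenario `"bear_like"` or `"global_null"` (ignored when `inputs`
#'   is supplied).
#' @param structures Character vector of structures to analyze.
#' @param n_permutations Resamples for every permutation test (>= 99).
#' @param angle_dimension Dimension for the trajectory-angle null; `NULL` uses
#'   the rank of the pooled shape data.
#' @param tracks Distance-table tracks to compute.
#' @param tree_file Newick file for the phylogenetic-signal stage; `NULL` uses
#'   the packaged example tree.
#' @param branch_modes Branch-length schemes for the signal test.
#' @param diet_map Named list mapping species to dietary categories for the
#'   rank-test stage.
#' @param diet_pc Which PC of the raw-track morphospace feeds the rank test.
#' @param out_dir Output directory (`NULL`: return results only, write
#'   nothing).
#' @param make_plots Write morphospace SVG plots?
#' @param seed Master seed; all stage streams derive from it.
#' @param inputs Optional list of per-structure input files (see above).
#' @return A named configuration list.
#' @export
default_config <- function(scenario = "bear_like",
                           structures = c("cranium", "mandible"),
                           n_permutations = 10000L,
                           angle_dimension = NULL,
                           tracks = c("raw", "nonallometric"),
                           tree_file = NULL,
                           branch_modes = c("given_lengths", "unit_lengths"),
                           diet_map = list(spelaeus = "herbivore",
                                           arctos = "omnivore",
                                           americanus = "omnivore",
                                           maritimus = "carnivore"),
                           diet_pc = 2L,
                           out_dir = NULL,
                           make_plots = FALSE,
                           seed = 1L,
                           inputs = NULL) {
  cfg <- list(scenario = scenario, structures = structures,
              n_permutations = as.integer(n_permutations),
              angle_dimension = angle_dimension, tracks = tracks,
              tree_file = tree_file, branch_modes = branch_modes,
              diet_map = diet_map, diet_pc = as.integer(diet_pc),
              out_dir = out_dir, make_plots = make_plots,
              seed = as.integer(seed), inputs = inputs)
  validate_config(cfg)
}

#' Read a YAML run configuration
#'
#' Reads a YAML file whose top-level keys override the [default_config()]
#' values.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (key in names(user)) cfg[[key]] <- user[[key]]
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$n_permutations < 99L)
    stop("n_permutations must be >= 99", call. = FALSE)
  if (is.null(cfg$inputs) &&
      !cfg$scenario %in% c("bear_like", "global_null"))
    stop("unknown scenario: ", cfg$scenario, call. = FALSE)
  if (!is.null(cfg$tree_file) && !file.exists(cfg$tree_file))
    stop("tree file not found: ", cfg$tree_file, call. = FALSE)
  if (!is.null(cfg$inputs))
    for (inp in cfg$inputs)
      if (!file.exists(inp$path))
        stop("input file not found: ", inp$path, call. = FALSE)
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the complete inference chain for each configured structure:
#' validation, missing-landmark estimation, generalized Procrustes analysis
#' (with object symmetry for paired templates), PCA morphospace, pooled and
#' per-species allometric regression with pairwise trajectory-angle tests,
#' group Procrustes-distance permutation tests on the raw and non-allometric
#' tracks, a rank test of a morphospace axis across dietary categories, and
#' the squared-change permutation test of phylogenetic signal on per-species
#' adult mean size-corrected PC scores. Every stage derives its random stream
#' from the master seed, and the result carries a manifest with every seed
#' and parameter needed to reproduce any number in the bundle.
#'
#' @param config A configuration list from [default_config()] /
#'   [read_config()], or a path to a YAML file.
#' @return A list with one entry per structure (each containing the stage
#'   results) plus `manifest`; when `out_dir` is set, CSV/JSON/SVG artifacts
#'   are written there.
#' @export
run_study <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  results <- list()
  for (structure in config$structures)
    results[[structure]] <- run_structure(structure, config)
  tree <- if (is.null(config$tree_file)) ursus_tree()
          else read_newick(path = config$tree_file)
  for (structure in config$structures) {
    res <- results[[structure]]
    tips <- res$adult_species_scores
    if (!is.null(tips) && nrow(tips) >= 3L) {
      res$phylo_signal <- lapply(
        stats::setNames(config$branch_modes, config$branch_modes),
        function(bm) phylo_signal_permutation(
          tree, tips, n_permutations = config$n_permutations,
          seed = derive_seed(config$seed, paste0("phylo_", structure, bm)),
          branch_mode = bm))
    }
    results[[structure]] <- res
  }
  results$manifest <- build_manifest(config, results)
  if (!is.null(config$out_dir)) write_bundle(results, config)
  results
}

run_structure <- function(structure, config) {
  message("[", structure, "] loading data")
  ds <- load_stage(structure, config)
  message("[", structure, "] validating ", n_specimens(ds), " specimens")
  validate_dataset(ds)
  if (any(ds$missing)) {
    message("[", structure, "] estimating missing landmarks")
    ds <- estimate_missing(ds)
  }
  symmetric <- has_symmetry(ds$template)
  message("[", structure, "] GPA (object symmetry: ", symmetric, ")")
  if (symmetric) {
    g <- gpa_with_object_symmetry(ds)
    x <- flatten_shapes(g$symmetric)
    log_cs <- g$gpa$log_centroid_sizes
  } else {
    g <- gpa(ds)
    x <- flatten_shapes(g$aligned)
    log_cs <- g$log_centroid_sizes
  }
  message("[", structure, "] PCA morphospace")
  pca <- shape_pca(x)
  message("[", structure, "] allometry")
  pooled <- regress_shape_on_size(
    x, log_cs, n_permutations = config$n_permutations,
    seed = derive_seed(config$seed, paste0("pooled_", structure)))
  resid_x <- nonallometric_coordinates(pooled)
  pca_resid <- shape_pca(resid_x)
  traj_species <- names(which(table(ds$meta$species) >= 3L))
  traj <- ontogenetic_trajectories(
    x[ds$meta$species %in% traj_species, , drop = FALSE],
    log_cs[ds$meta$species %in% traj_species],
    ds$meta$species[ds$meta$species %in% traj_species],
    dimension = config$angle_dimension,
    n_permutations = config$n_permutations,
    seed = derive_seed(config$seed, paste0("traj_", structure)))
  message("[", structure, "] group distances")
  glab <- interaction(ds$meta$species, ds$meta$age_class, drop = TRUE,
                      sep = "_")
  dist_tables <- list()
  if ("raw" %in% config$tracks)
    dist_tables$raw <- group_distance_permutation(
      x, glab, n_permutations = config$n_permutations,
      seed = derive_seed(config$seed, paste0("dist_raw_", structure)),
      track = "raw")
  if ("nonallometric" %in% config$tracks)
    dist_tables$nonallometric <- group_distance_permutation(
      resid_x, glab, n_permutations = config$n_permutations,
      seed = derive_seed(config$seed, paste0("dist_res_", structure)),
      track = "nonallometric")
  message("[", structure, "] rank tests by diet")
  diet <- unlist(config$diet_map[ds$meta$species])
  rank_res <- NULL
  if (length(unique(diet)) >= 2L) {
    pc_vals <- pca$scores[, min(config$diet_pc, ncol(pca$scores))]
    rank_res <- list(test = kruskal_wallis(pc_vals, diet),
                     posthoc = kruskal_posthoc(pc_vals, diet))
  }
  adults <- ds$meta$age_class == "adult"
  sp_adult <- sort(unique(ds$meta$species[adults]))
  adult_scores <- NULL
  if (length(sp_adult) >= 3L) {
    adult_scores <- t(vapply(sp_adult, function(s) {
      colMeans(pca_resid$scores[adults & ds$meta$species == s, ,
                                drop = FALSE])
    }, numeric(ncol(pca_resid$scores))))
  }
  list(dataset = ds, gpa = g, coordinates = x, log_sizes = log_cs,
       pca = pca, pooled_regression = pooled,
       nonallometric = resid_x, pca_nonallometric = pca_resid,
       trajectories = traj, distances = dist_tables, rank_tests = rank_res,
       adult_species_scores = adult_scores, symmetric = symmetric)
}

load_stage <- function(structure, config) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs[[structure]]
    if (is.null(inp)) stop("no input configured for structure ", structure,
                           call. = FALSE)
    return(read_landmarks(inp$path, inp$format %||% "tps",
                          load_template(inp$template)))
  }
  simulate_ontogeny(scenario_params(
    config$scenario, structure,
    seed = derive_seed(config$seed, paste0("simulate_", structure))))
}

build_manifest <- function(config, results) {
  per_structure <- lapply(
    results[setdiff(names(results), "manifest")], function(res) {
      list(
        n_specimens = n_specimens(res$dataset),
        gpa_iterations = if (res$symmetric) res$gpa$gpa$iterations
                         else res$gpa$iterations,
        pc_percent_variance = round(res$pca$percent_variance, 4),
        pooled_percent_predicted = res$pooled_regression$percent_predicted,
        pooled_permutation_p = res$pooled_regression$permutation_p,
        trajectory_angles = res$trajectories$angles,
        angle_dimension = res$trajectories$dimension,
        distance_tracks = lapply(res$distances, function(d)
          list(distances = d$distances, p_values = d$p_values)),
        kruskal = if (!is.null(res$rank_tests))
          list(chi_square = res$rank_tests$test$chi_square,
               p = res$rank_tests$test$p_value),
        phylo_signal = lapply(res$phylo_signal, function(ps)
          list(tree_length = ps$observed_tree_length,
               p = ps$permutation_p, method = ps$method)))
    })
  list(config = config[c("scenario", "structures", "n_permutations",
                         "tracks", "branch_modes", "diet_pc", "seed")],
       results = per_structure)
}

write_bundle <- function(results, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(results$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(study_design_table(),
                   file.path(config$out_dir, "study_design.csv"),
                   row.names = FALSE)
  for (structure in config$structures) {
    res <- results[[structure]]
    prefix <- file.path(config$out_dir, structure)
    scores <- data.frame(res$dataset$meta[, c("specimen_id", "species",
                                              "age_class")],
                         res$pca$scores[, seq_len(min(10L,
                                                      ncol(res$pca$scores)))])
    utils::write.csv(scores, paste0(prefix, "_pc_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(res$trajectories$angles,
                     paste0(prefix, "_trajectory_angles.csv"),
                     row.names = FALSE)
    for (track in names(res$distances)) {
      d <- res$distances[[track]]
      m <- length(d$labels)
      tab <- matrix("", m, m, dimnames = list(d$labels, d$labels))
      for (i in seq_len(m)) for (j in seq_len(m))
        if (i > j) tab[i, j] <- sprintf("%.4f (%.4g)", d$distances[i, j],
                                        d$p_values[i, j])
      utils::write.csv(tab, paste0(prefix, "_distances_", track, ".csv"))
    }
    # extreme-shape wireframe models at the observed PC1/PC2 score ranges
    for (pc in 1:2) {
      rng <- range(res$pca$scores[, pc])
      lo <- shape_along_pc(res$pca, pc, rng[1L])
      hi <- shape_along_pc(res$pca, pc, rng[2L])
      utils::write.csv(
        data.frame(landmark = res$dataset$template$landmark_names,
                   low_x = lo[, 1], low_y = lo[, 2], low_z = lo[, 3],
                   high_x = hi[, 1], high_y = hi[, 2], high_z = hi[, 3]),
        paste0(prefix, "_pc", pc, "_extremes.csv"), row.names = FALSE)
    }
    if (isTRUE(config$make_plots)) {
      glab <- paste(res$dataset$meta$species, res$dataset$meta$age_class,
                    sep = "_")
      for (pcs in list(c(1L, 2L), c(1L, 3L))) {
        if (max(pcs) > ncol(res$pca$scores)) next
        grDevices::svg(paste0(prefix, "_morphospace_pc",
                              pcs[1L], pcs[2L], ".svg"), width = 7,
                       height = 6)
        plot_morphospace(res$pca, glab, pcs,
                         main = paste("Morphospace:", structure))
        grDevices::dev.off()
      }
    }
  }
  invisible(config$out_dir)
}
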