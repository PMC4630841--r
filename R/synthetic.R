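#' Seeded symmetric mean shape
#'
#' Draws a smooth, non-degenerate base configuration for a template: centered,
#' scaled to unit centroid size and — when the template defines left/right
#' pairs — exactly symmetric under reflect-and-relabel (paired landmarks
#' mirror across the x = 0 midsagittal plane, midline landmarks lie on it).
#' Landmarks are spread along an elongate skull-like ellipsoid so
#' configurations are full-rank and well conditioned.
#'
#' @param template A [load_template()] object.
#' @param seed Integer seed; the same seed always returns the same shape.
#' @return `k x 3` matrix with centroid 0 and centroid size 1.
#' @export
make_symmetric_mean <- function(template, seed = 1L) {
  k <- length(template$landmark_names)
  withr_seed(derive_seed(seed, "mean_shape"), {
    cfg <- matrix(0, k, 3L)
    if (has_symmetry(template)) {
      np <- nrow(template$pairs)
      # left-side positions; x strictly negative, y spread along the long axis
      left <- cbind(-stats::runif(np, 0.15, 0.6),
                    stats::runif(np, -1, 1),
                    stats::runif(np, -0.4, 0.4))
      cfg[template$pairs[, 1L], ] <- left
      cfg[template$pairs[, 2L], ] <- left %*% diag(c(-1, 1, 1))
      nm <- length(template$midline)
      cfg[template$midline, ] <- cbind(0,
                                       stats::runif(nm, -1, 1),
                                       stats::runif(nm, -0.4, 0.4))
    } else {
      cfg <- cbind(stats::runif(k, -0.3, 0.3),
                   stats::runif(k, -1, 1),
                   stats::runif(k, -0.4, 0.4))
    }
    cfg <- center_config(cfg)
    if (has_symmetry(template)) cfg[template$midline, 1L] <- 0
    cfg / sqrt(sum(cfg^2))
  })
}

# Orthonormal basis directions of the similarity transformations at shape m
# (3 translations, 3 infinitesimal rotations, 1 scaling), as flattened 3k
# vectors. Used to build tangent-space effect directions.
similarity_directions <- function(m) {
  k <- nrow(m)
  gens <- list(
    matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE),  # about z
    matrix(c(0, 0, 1, 0, 0, 0, -1, 0, 0), 3, 3, byrow = TRUE),  # about y
    matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE))  # about x
  dirs <- cbind(
    flatten_config(matrix(rep(c(1, 0, 0), k), k, byrow = TRUE)),
    flatten_config(matrix(rep(c(0, 1, 0), k), k, byrow = TRUE)),
    flatten_config(matrix(rep(c(0, 0, 1), k), k, byrow = TRUE)),
    vapply(gens, function(g) flatten_config(m %*% t(g)), numeric(3L * k)),
    flatten_config(m))
  qr.Q(qr(dirs))
}

#' Project a perturbation into the shape tangent space
#'
#' Removes from a flattened perturbation vector its components along the
#' similarity transformations at the given mean shape (translations,
#' rotations, scaling) and optionally symmetrizes it first (averaging with
#' its reflect-and-relabeled copy), yielding a direction along which shapes
#' actually change — the space allometric and species-effect directions live
#' in.
#'
#' @param v Flattened length-`3k` perturbation.
#' @param mean_shape `k x 3` shape the tangent space is anchored at.
#' @param template Template; needed when `symmetric = TRUE`.
#' @param symmetric Constrain the direction to the symmetric subspace?
#' @param unit Rescale the result to unit norm?
#' @return Flattened length-`3k` tangent vector.
#' @export
tangent_direction <- function(v, mean_shape, template = NULL,
                              symmetric = FALSE, unit = TRUE) {
  k <- nrow(mean_shape)
  if (symmetric) {
    if (is.null(template) || !has_symmetry(template))
      stop("symmetric projection needs a paired template", call. = FALSE)
    v <- (v + flatten_config(
      reflect_relabel(unflatten_config(v, k), template))) / 2
  }
  q <- similarity_directions(mean_shape)
  v <- v - q %*% crossprod(q, v)
  v <- drop(v)
  if (unit) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("perturbation vanished under projection", call. = FALSE)
    v <- v / nv
  }
  v
}

#' Ontogenetic simulation parameters
#'
#' Assembles and validates the parameter set for [simulate_ontogeny()]. The
#' latent model for a specimen of species s with drawn centroid size CS is
#'
#' `shape = mean_s + strength * v_s * (log CS - log CS_ref,s) + noise`,
#'
#' built in the unit-size shape space; the configuration is then rigidly
#' rotated and translated at random and scaled to CS. Species means are the
#' base shape plus tangent-space offsets; allometric directions `v_s` are
#' unit tangent vectors; `CS_ref,s` is the geometric mid-size of the species.
#' Age classes follow the generating (species, age class) group, whose size
#' ranges define the size threshold between juveniles and adults.
#'
#' @param template A [load_template()] object.
#' @param groups Data frame with columns `species`, `age_class`, `n`,
#'   `size_min`, `size_max` (centroid sizes, mm).
#' @param species_means Named list of `k x 3` mean shapes (unit centroid
#'   size); defaults to a common [make_symmetric_mean()] for all species.
#' @param allometric_vectors Named list of flattened unit tangent vectors;
#'   defaults to one shared random tangent direction.
#' @param allometry_strength Shape change (in Procrustes units) per unit log
#'   centroid size; 0 disables allometry.
#' @param noise_sd Isotropic per-coordinate landmark noise in the unit-size
#'   shape space, applied before the rigid motion.
#' @param asymmetry_sd Optional extra noise added only to the left side of
#'   paired templates (fluctuating-asymmetry style); 0 disables.
#' @param post_rigid_noise_sd Optional noise applied after the rigid motion
#'   (in mm); stresses the Procrustes small-variation assumptions.
#' @param missing_fraction Proportion of landmarks masked in
#'   `missing_species` specimens.
#' @param missing_species Species whose specimens lose landmarks.
#' @param size_mode `"log_uniform"` (default) draws each specimen's size
#'   log-uniformly over its group range; `"balanced"` draws antithetic pairs
#'   of log-size offsets around the group midpoint, giving a size design that
#'   is exactly centered (useful for exactness checks and variance
#'   reduction).
#' @param seed Integer master seed.
#' @return Object of class `ontogeny_params`.
#' @export
ontogeny_params <- function(template, groups,
                            species_means = NULL,
                            allometric_vectors = NULL,
                            allometry_strength = 0.08,
                            noise_sd = 0.01,
                            asymmetry_sd = 0,
                            post_rigid_noise_sd = 0,
                            missing_fraction = 0,
                            missing_species = NULL,
                            size_mode = c("log_uniform", "balanced"),
                            seed = 1L) {
  size_mode <- match.arg(size_mode)
  stopifnot(noise_sd >= 0, asymmetry_sd >= 0, post_rigid_noise_sd >= 0,
            missing_fraction >= 0, missing_fraction < 1)
  if (any(groups$size_min >= groups$size_max))
    stop("degenerate size range: size_min must be < size_max", call. = FALSE)
  if (any(groups$n < 0)) stop("negative group size", call. = FALSE)
  species <- unique(groups$species)
  k <- length(template$landmark_names)
  sym <- has_symmetry(template)
  base <- make_symmetric_mean(template, seed)
  if (is.null(species_means))
    species_means <- stats::setNames(rep(list(base), length(species)), species)
  if (is.null(allometric_vectors)) {
    v0 <- withr_seed(derive_seed(seed, "allometric_direction"),
                     stats::rnorm(3L * k))
    v0 <- tangent_direction(v0, base, template, symmetric = sym)
    allometric_vectors <- stats::setNames(rep(list(v0), length(species)),
                                          species)
  }
  for (s in species) {
    if (!s %in% names(species_means)) stop("no mean shape for ", s, call. = FALSE)
    if (!s %in% names(allometric_vectors))
      stop("no allometric vector for ", s, call. = FALSE)
    nv <- sqrt(sum(allometric_vectors[[s]]^2))
    if (abs(nv - 1) > 1e-8)
      stop("allometric vector for ", s, " is not unit norm", call. = FALSE)
  }
  structure(
    list(template = template, groups = groups, species_means = species_means,
         allometric_vectors = allometric_vectors,
         allometry_strength = allometry_strength, noise_sd = noise_sd,
         asymmetry_sd = asymmetry_sd,
         post_rigid_noise_sd = post_rigid_noise_sd,
         missing_fraction = missing_fraction,
         missing_species = missing_species, size_mode = size_mode,
         seed = seed),
    class = "ontogeny_params")
}

#' Simulate an ontogenetic landmark dataset
#'
#' Generates specimens under the latent allometric model of
#' [ontogeny_params()], applies a random rigid motion and the drawn centroid
#' size to each, and masks landmarks of the designated species at the
#' requested rate (leaving at least 8 observed). The returned dataset carries
#' the generating ground truth in `attr(, "truth")`: the latent unit-size
#' shapes, species means, allometric directions, strength and the per-specimen
#' log-size offsets.
#'
#' @param params An [ontogeny_params()] object.
#' @return A [landmark_dataset()]; bit-reproducible for a fixed seed.
#' @export
simulate_ontogeny <- function(params) {
  tpl <- params$template
  k <- length(tpl$landmark_names)
  g <- params$groups
  n_tot <- sum(g$n)
  coords <- array(NA_real_, dim = c(k, 3L, n_tot))
  missing <- matrix(FALSE, k, n_tot)
  meta <- data.frame(specimen_id = character(n_tot),
                     species = character(n_tot),
                     age_class = character(n_tot),
                     structure = tpl$structure_name,
                     idas_stage = NA_integer_, site = "synthetic",
                     stringsAsFactors = FALSE)
  latent <- matrix(0, n_tot, 3L * k)
  t_offsets <- numeric(n_tot)
  # species reference size: geometric mid of that species' full size span
  ref_log <- vapply(unique(g$species), function(s) {
    rows <- g$species == s
    mean(c(log(min(g$size_min[rows])), log(max(g$size_max[rows]))))
  }, numeric(1))
  names(ref_log) <- unique(g$species)
  idx <- 0L
  withr_seed(derive_seed(params$seed, "ontogeny"), {
    for (r in seq_len(nrow(g))) {
      lo <- log(g$size_min[r]); hi <- log(g$size_max[r])
      log_sizes <- if (params$size_mode == "balanced") {
        mid <- (lo + hi) / 2
        d <- stats::runif(ceiling(g$n[r] / 2), 0, (hi - lo) / 2)
        utils::head(mid + c(rbind(d, -d)), g$n[r])
      } else stats::runif(g$n[r], lo, hi)
      for (j in seq_len(g$n[r])) {
        idx <- idx + 1L
        s <- g$species[r]
        cs <- exp(log_sizes[j])
        t_i <- log(cs) - ref_log[[s]]
        shape <- flatten_config(params$species_means[[s]]) +
          params$allometry_strength * params$allometric_vectors[[s]] * t_i
        if (params$noise_sd > 0)
          shape <- shape + stats::rnorm(3L * k, 0, params$noise_sd)
        cfg <- unflatten_config(shape, k)
        if (params$asymmetry_sd > 0 && has_symmetry(tpl)) {
          left <- tpl$pairs[, 1L]
          cfg[left, ] <- cfg[left, ] +
            matrix(stats::rnorm(3L * length(left), 0, params$asymmetry_sd),
                   ncol = 3L)
        }
        latent[idx, ] <- flatten_config(cfg)
        raw <- to_preshape(cfg) * cs
        raw <- raw %*% random_rotation()
        raw <- sweep(raw, 2L, stats::runif(3, -100, 100), `+`)
        if (params$post_rigid_noise_sd > 0)
          raw <- raw + matrix(stats::rnorm(3L * k, 0,
                                           params$post_rigid_noise_sd),
                              ncol = 3L)
        if (!is.null(params$missing_species) &&
            s %in% params$missing_species && params$missing_fraction > 0) {
          mask <- stats::runif(k) < params$missing_fraction
          if (sum(!mask) < 8L)
            mask[sample(which(mask), sum(mask) - (k - 8L))] <- FALSE
          raw[mask, ] <- NA_real_
          missing[, idx] <- mask
        }
        coords[, , idx] <- raw
        meta$specimen_id[idx] <- sprintf("%s_%s_%03d", s, g$age_class[r], j)
        meta$species[idx] <- s
        meta$age_class[idx] <- g$age_class[r]
        meta$idas_stage[idx] <- if (g$age_class[r] == "juvenile")
          sample(1:2, 1) else sample(3:5, 1)
        t_offsets[idx] <- t_i
      }
    }
  })
  ds <- landmark_dataset(tpl, coords, meta, missing = missing,
                         provenance = sprintf(
                           "simulated %d specimens (seed %d)", n_tot,
                           params$seed))
  attr(ds, "truth") <- list(
    latent = latent, species_means = params$species_means,
    allometric_vectors = params$allometric_vectors,
    allometry_strength = params$allometry_strength,
    t_offsets = t_offsets, ref_log = ref_log)
  ds
}

#' Simulate multivariate Brownian motion on a tree
#'
#' Independent Brownian traits along every branch: each child node value is
#' its parent's plus Gaussian increments with variance `rate x branch length`
#' per dimension.
#'
#' @param tree An [ape] `phylo` object with branch lengths.
#' @param rate Brownian variance per unit branch length (>= 0).
#' @param root_state Numeric vector; the trait value at the root.
#' @param seed Integer seed.
#' @return Matrix of tip values (rows named by tip label).
#' @export
simulate_bm_tips <- function(tree, rate, root_state, seed = 1L) {
  stopifnot(rate >= 0)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  p <- length(root_state)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  vals <- matrix(NA_real_, n_all, p)
  root <- n_tip + 1L
  vals[root, ] <- root_state
  # preorder: parents before children
  ord <- order(tree$edge[, 1L])
  edges <- tree$edge[ord, , drop = FALSE]
  lens <- tree$edge.length[ord]
  withr_seed(derive_seed(seed, "bm_tips"), {
    repeat {
      todo <- which(is.na(vals[edges[, 2L], 1L]) &
                    !is.na(vals[edges[, 1L], 1L]))
      if (!length(todo)) break
      for (e in todo)
        vals[edges[e, 2L], ] <- vals[edges[e, 1L], ] +
          stats::rnorm(p, 0, sqrt(rate * lens[e]))
    }
  })
  tips <- vals[seq_len(n_tip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  tips
}

#' Study-shaped simulation scenarios
#'
#' Two packaged scenarios, both on the four-species, two-age-class bear study
#' design (group sizes from [study_design_table()]):
#'
#' * `"bear_like"` — species mean shapes evolve by Brownian motion on the
#'   packaged phylogeny ([ursus_tree()]), all species share an ontogenetic
#'   allometry of realistic magnitude with a controllable spread of
#'   trajectory directions, and a fraction of landmarks is missing in the
#'   fossil species (*spelaeus*) crania.
#' * `"global_null"` — identical design but no species differences, no
#'   allometry and no missing data: every downstream test's null is true.
#'
#' Sizes are drawn per age class from non-overlapping log-uniform ranges
#' (cranium: juveniles 150-300 mm, adults 300-450 mm centroid size; mandible:
#' 80-150 / 150-250 mm). Defaults: landmark noise 0.01 Procrustes units,
#' allometry 0.08 shape units per log size, trajectory spread 29 degrees
#' about the common direction (about 40 degrees between species pairs),
#' Brownian rate 1e-5 per million years, 5% missing landmarks in spelaeus
#' crania.
#'
#' @param scenario `"bear_like"` or `"global_null"`.
#' @param structure `"cranium"` or `"mandible"`.
#' @param seed Integer master seed.
#' @param noise_sd,allometry_strength,missing_fraction Override defaults.
#' @param trajectory_spread_deg Angle of each species' allometric direction
#'   from the shared direction (0 = identical trajectories).
#' @param bm_rate Brownian variance (per unit branch length) of the
#'   species-mean evolution.
#' @return An [ontogeny_params()] object; pass to [simulate_ontogeny()].
#' @export
scenario_params <- function(scenario = c("bear_like", "global_null"),
                            structure = c("cranium", "mandible"),
                            seed = 1L,
                            noise_sd = 0.01,
                            allometry_strength = 0.08,
                            missing_fraction = 0.05,
                            trajectory_spread_deg = 29,
                            bm_rate = 1e-5) {
  scenario <- match.arg(scenario)
  structure <- match.arg(structure)
  tpl <- load_template(if (structure == "cranium") "cranium36" else "mandible9")
  des <- study_design_table()
  des <- des[des$structure == structure & des$n > 0L, ]
  size_ranges <- if (structure == "cranium")
    list(juvenile = c(150, 300), adult = c(300, 450))
  else list(juvenile = c(80, 150), adult = c(150, 250))
  groups <- data.frame(
    species = des$species, age_class = des$age_class, n = des$n,
    size_min = vapply(des$age_class, function(a) size_ranges[[a]][1L], 0),
    size_max = vapply(des$age_class, function(a) size_ranges[[a]][2L], 0),
    stringsAsFactors = FALSE)
  species <- unique(groups$species)
  sym <- has_symmetry(tpl)
  base <- make_symmetric_mean(tpl, seed)
  k <- length(tpl$landmark_names)
  if (scenario == "global_null") {
    means <- stats::setNames(rep(list(base), length(species)), species)
    v0 <- withr_seed(derive_seed(seed, "allometric_direction"),
                     stats::rnorm(3L * k))
    v0 <- tangent_direction(v0, base, tpl, symmetric = sym)
    vecs <- stats::setNames(rep(list(v0), length(species)), species)
    return(ontogeny_params(tpl, groups, species_means = means,
                           allometric_vectors = vecs,
                           allometry_strength = 0, noise_sd = noise_sd,
                           missing_fraction = 0, seed = seed))
  }
  # species means: Brownian offsets on the packaged tree, tangent-projected
  tree <- ursus_tree()
  bm <- simulate_bm_tips(tree, bm_rate, rep(0, 3L * k),
                         seed = derive_seed(seed, "species_means"))
  means <- list()
  for (s in species) {
    off <- tangent_direction(bm[s, ], base, tpl, symmetric = sym, unit = FALSE)
    m <- base + unflatten_config(off, k)
    if (sym) m[tpl$midline, 1L] <- 0
    means[[s]] <- to_preshape(m)
  }
  # shared allometric direction with a per-species angular spread
  v0 <- withr_seed(derive_seed(seed, "allometric_direction"),
                   stats::rnorm(3L * k))
  v0 <- tangent_direction(v0, base, tpl, symmetric = sym)
  th <- trajectory_spread_deg * pi / 180
  vecs <- list()
  for (i in seq_along(species)) {
    u <- withr_seed(derive_seed(seed, paste0("traj_", species[i])),
                    stats::rnorm(3L * k))
    u <- tangent_direction(u, base, tpl, symmetric = sym)
    u <- u - sum(u * v0) * v0
    u <- u / sqrt(sum(u^2))
    v <- cos(th) * v0 + sin(th) * u
    vecs[[species[i]]] <- v / sqrt(sum(v^2))
  }
  ontogeny_params(tpl, groups, species_means = means,
                  allometric_vectors = vecs,
                  allometry_strength = allometry_strength,
                  noise_sd = noise_sd,
                  missing_fraction = if (structure == "cranium")
                    missing_fraction else 0,
                  missing_species = "spelaeus", seed = seed)
}
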