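# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (grid search, generic optimizers, hand formulas) and
# never reuse the code paths they check.

# random non-degenerate configuration
random_config <- function(k, scale = 1) {
  matrix(stats::runif(k * 3, -1, 1), k, 3) * scale
}

apply_rigid <- function(config, rot = NULL, trans = c(0, 0, 0), scale = 1) {
  if (is.null(rot)) rot <- morphotraj:::random_rotation()
  sweep(config %*% rot * scale, 2, trans, `+`)
}

# tiny complete dataset on a template, with metadata
toy_dataset <- function(template, n = 4, seed = 42, noise = 0.05) {
  set.seed(seed)
  base <- make_symmetric_mean(template, seed)
  k <- nrow(base)
  arr <- array(0, dim = c(k, 3, n))
  for (i in seq_len(n))
    arr[, , i] <- apply_rigid(base + matrix(rnorm(k * 3, 0, noise), k),
                              trans = runif(3, -5, 5),
                              scale = runif(1, 50, 150))
  meta <- data.frame(
    specimen_id = sprintf("s%02d", seq_len(n)),
    species = rep_len(c("arctos", "spelaeus"), n),
    age_class = rep_len(c("adult", "juvenile"), n),
    structure = template$structure_name,
    stringsAsFactors = FALSE)
  landmark_dataset(template, arr, meta)
}

# Brute-force partial Procrustes distance: coarse Euler-angle grid followed
# by Nelder-Mead refinement of the residual over rotations.
oracle_procrustes_distance <- function(a, b) {
  pre <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    x / sqrt(sum(x^2))
  }
  a <- pre(a); b <- pre(b)
  obj <- function(p) sum((a %*% morphotraj:::rotation_from_euler(
    p[1], p[2], p[3]) - b)^2)
  grid <- seq(0, 2 * pi, length.out = 9)[-9]
  best <- NULL; best_val <- Inf
  for (p1 in grid) for (p2 in grid) for (p3 in grid) {
    v <- obj(c(p1, p2, p3))
    if (v < best_val) { best_val <- v; best <- c(p1, p2, p3) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  sqrt(opt$value)
}

# Brute-force two-shape GPA total sum of squares: optimize the rotation of
# the second unit-size shape; the consensus of two shapes is their mean.
oracle_gpa2_ss <- function(a, b) {
  pre <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    x / sqrt(sum(x^2))
  }
  a <- pre(a); b <- pre(b)
  obj <- function(p) {
    br <- b %*% morphotraj:::rotation_from_euler(p[1], p[2], p[3])
    m <- (a + br) / 2
    sum((a - m)^2) + sum((br - m)^2)
  }
  grid <- seq(0, 2 * pi, length.out = 7)[-7]
  best <- NULL; best_val <- Inf
  for (p1 in grid) for (p2 in grid) for (p3 in grid) {
    v <- obj(c(p1, p2, p3))
    if (v < best_val) { best_val <- v; best <- c(p1, p2, p3) }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# Quadratic-programming oracle for squared-change parsimony: numerical
# minimization over all internal-node values.
oracle_squared_change <- function(tree, tip_values, weights) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  p <- ncol(tip_values)
  obj <- function(theta) {
    nodevals <- matrix(theta, n_node, p)
    allvals <- rbind(tip_values, nodevals)
    tot <- 0
    for (e in seq_len(nrow(tree$edge)))
      tot <- tot + sum((allvals[tree$edge[e, 1], ] -
                        allvals[tree$edge[e, 2], ])^2) / weights[e]
    tot
  }
  start <- rep(colMeans(tip_values), each = n_node)
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 10000))
  opt$value
}

# flatten helper mirroring the package layout, for hand-built expectations
flat <- function(m) as.vector(t(m))
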