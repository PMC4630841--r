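#' Principal component analysis of shape coordinates
#'
#' Eigen-decomposition of the sample covariance matrix (divisor n - 1) of
#' flattened shape coordinates — Procrustes coordinates, symmetric components
#' or regression residuals. Components with eigenvalues below
#' `1e-12 x` the leading eigenvalue are dropped (they are numerical zeros:
#' superimposition removes position, scale and orientation, and the symmetric
#' decomposition removes further dimensions). Axis signs are fixed by making
#' the largest-magnitude loading of each axis positive, so results are
#' deterministic across platforms; PC signs carry no meaning.
#'
#' @param coordinates `n x p` matrix of flattened shapes (see
#'   [flatten_shapes()]), or a `k x 3 x n` array.
#' @return Object of class `shape_pca`: list with `mean_vector`,
#'   `eigenvalues`, `percent_variance`, `axes` (`p x n_components`,
#'   orthonormal columns), `scores` (`n x n_components`, zero column means)
#'   and `k` (landmark count).
#' @export
shape_pca <- function(coordinates) {
  x <- as_shape_matrix(coordinates)
  n <- nrow(x)
  if (n < 2L) stop("PCA needs at least two specimens", call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  eig <- sv$d^2 / (n - 1L)
  keep <- eig > 1e-12 * max(eig)
  eig <- eig[keep]
  axes <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| positive per axis
  for (j in seq_len(ncol(axes))) {
    i_max <- which.max(abs(axes[, j]))
    if (axes[i_max, j] < 0) axes[, j] <- -axes[, j]
  }
  scores <- xc %*% axes
  structure(
    list(mean_vector = mu, eigenvalues = eig,
         percent_variance = 100 * eig / sum(eig),
         axes = axes, scores = scores, k = ncol(x) / 3L),
    class = "shape_pca")
}

as_shape_matrix <- function(coordinates) {
  if (length(dim(coordinates)) == 3L) flatten_array(coordinates)
  else as.matrix(coordinates)
}

#' Flatten shape arrays for linear analyses
#'
#' @param coords `k x 3 x n` array of configurations.
#' @return `n x 3k` matrix, one flattened configuration
#'   (`x1 y1 z1 x2 ...`) per row.
#' @export
flatten_shapes <- function(coords) flatten_array(coords)

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA:", nrow(x$scores), "specimens,", length(x$eigenvalues),
      "non-zero components\n")
  pv <- utils::head(x$percent_variance, 5L)
  cat("  % variance (PC1..):", paste(sprintf("%.2f", pv), collapse = ", "),
      "\n")
  invisible(x)
}

#' Equal-frequency confidence ellipse of 2D scores
#'
#' Ellipse containing the stated probability mass of a bivariate normal fitted
#' to the scores: centered at the group mean, axes along the eigenvectors of
#' the 2x2 covariance matrix, semi-axes scaled by the square root of the
#' chi-square quantile with 2 degrees of freedom. This is a data (scatter)
#' ellipse, not a standard-error-of-the-mean ellipse.
#'
#' @param scores_2d `n x 2` matrix, `n >= 3`.
#' @param level Coverage probability (default 0.95).
#' @return List with `center` (length 2), `semi_axes` (length 2,
#'   non-increasing), `orientation` (radians, direction of the major axis) and
#'   `level`.
#' @export
confidence_ellipse <- function(scores_2d, level = 0.95) {
  scores_2d <- as.matrix(scores_2d)
  if (nrow(scores_2d) < 3L)
    stop("confidence ellipse needs at least 3 points", call. = FALSE)
  ctr <- colMeans(scores_2d)
  e <- eigen(stats::cov(scores_2d), symmetric = TRUE)
  q <- stats::qchisq(level, df = 2L)
  list(center = ctr,
       semi_axes = sqrt(pmax(e$values, 0) * q),
       orientation = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
       level = level)
}

ellipse_outline <- function(ell, n = 100L) {
  th <- seq(0, 2 * pi, length.out = n)
  pts <- cbind(ell$semi_axes[1L] * cos(th), ell$semi_axes[2L] * sin(th))
  rot <- matrix(c(cos(ell$orientation), sin(ell$orientation),
                  -sin(ell$orientation), cos(ell$orientation)), 2L, 2L)
  sweep(pts %*% t(rot), 2L, ell$center, `+`)
}

#' Model shape along a principal component
#'
#' Reconstructs the configuration at a given score on one PC:
#' `mean + score x axis`, refolded to `k x 3`. Used to render extreme-shape
#' wireframe models at the ends of the observed score range.
#'
#' @param pca A [shape_pca()] object.
#' @param component PC index.
#' @param score Score value along that component.
#' @return `k x 3` configuration matrix.
#' @export
shape_along_pc <- function(pca, component, score) {
  if (component < 1L || component > ncol(pca$axes))
    stop("component out of range (1..", ncol(pca$axes), ")", call. = FALSE)
  unflatten_config(pca$mean_vector + score * pca$axes[, component], pca$k)
}

#' Morphospace scatter plot with group ellipses
#'
#' PC-versus-PC scatter with one symbol and one equal-frequency
#' ellipse per group, after the usual two-panel morphospace layout
#' (PC1 x PC2, PC1 x PC3).
#'
#' @param pca A [shape_pca()] object.
#' @param groups Factor/character vector of group labels (one per specimen).
#' @param pcs Length-2 integer vector of components to plot.
#' @param level Ellipse coverage probability.
#' @param main Plot title.
#' @return Invisibly, the list of per-group ellipses.
#' @export
plot_morphospace <- function(pca, groups, pcs = c(1L, 2L), level = 0.95,
                             main = "Morphospace") {
  groups <- factor(groups)
  sc <- pca$scores[, pcs, drop = FALSE]
  cols <- grDevices::hcl.colors(nlevels(groups), "Dark 3")
  graphics::plot(sc, col = cols[groups], pch = as.integer(groups) %% 25L,
                 xlab = sprintf("PC%d (%.1f%%)", pcs[1L],
                                pca$percent_variance[pcs[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", pcs[2L],
                                pca$percent_variance[pcs[2L]]),
                 main = main, asp = 1)
  ells <- list()
  for (g in levels(groups)) {
    idx <- groups == g
    if (sum(idx) >= 3L) {
      ell <- confidence_ellipse(sc[idx, , drop = FALSE], level)
      graphics::lines(ellipse_outline(ell), col = cols[match(g, levels(groups))])
      ells[[g]] <- ell
    }
  }
  graphics::legend("topright", legend = levels(groups), col = cols,
                   pch = seq_len(nlevels(groups)) %% 25L, cex = 0.7, bty = "n")
  invisible(ells)
}
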