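#' Multivariate regression of shape on log centroid size
#'
#' Ordinary least squares of every flattened shape coordinate on the common
#' predictor log centroid size. The fitted coefficient vector (per unit log
#' size) is the allometric / ontogenetic trajectory direction; the percentage
#' of total shape variation it predicts and a permutation test of the
#' association (statistic: predicted sum of squares; sizes permuted among
#' specimens) are returned alongside the residual coordinates.
#'
#' The permutation p-value uses the add-one convention
#' `p = (b + 1) / (n_permutations + 1)`, so it is never zero; a zero
#' exceedance count is reported as `p <= 1/(n_permutations + 1)`.
#' Percent predicted and the direction are invariant to the logarithm base of
#' the size variable (a base change rescales the predictor only).
#'
#' @param coordinates `n x p` matrix of flattened shapes or `k x 3 x n` array.
#' @param log_sizes Numeric vector of log centroid sizes, not all equal.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `shape_regression`: list with `allometric_vector`
#'   (length p), `intercept_shape`, `mean_shape`, `percent_predicted`,
#'   `permutation_p`, `residuals` (`n x p`, per-coordinate zero mean,
#'   orthogonal to the predictor), `log_sizes`, `n_permutations`, `seed`.
#' @export
regress_shape_on_size <- function(coordinates, log_sizes,
                                  n_permutations = 999L, seed = 1L) {
  x <- as_shape_matrix(coordinates)
  n <- nrow(x)
  if (n < 3L) stop("regression needs at least 3 specimens", call. = FALSE)
  if (length(log_sizes) != n)
    stop("length of log_sizes does not match specimen count", call. = FALSE)
  z <- log_sizes - mean(log_sizes)
  szz <- sum(z^2)
  if (szz == 0) stop("log centroid size is constant across specimens",
                     call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  b <- drop(crossprod(xc, z)) / szz
  fitted <- outer(z, b)
  resid <- xc - fitted
  pred_ss <- sum(b^2) * szz
  tot_ss <- sum(xc^2)
  # permutation: predicted SS = |Xc' z_perm|^2 / szz (szz is permutation
  # invariant), computed without refitting
  perm_p <- NA_real_
  if (n_permutations > 0L) {
    xtz_obs <- pred_ss
    count <- 0L
    withr_seed(seed, {
      for (i in seq_len(n_permutations)) {
        zp <- z[sample.int(n)]
        if (sum(drop(crossprod(xc, zp))^2) / szz >= xtz_obs - 1e-12)
          count <- count + 1L
      }
    })
    perm_p <- (count + 1) / (n_permutations + 1)
  }
  structure(
    list(allometric_vector = b,
         intercept_shape = mu - mean(log_sizes) * b,
         mean_shape = mu,
         percent_predicted = 100 * pred_ss / tot_ss,
         permutation_p = perm_p,
         residuals = resid,
         log_sizes = log_sizes,
         n_permutations = n_permutations, seed = seed),
    class = "shape_regression")
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' @export
print.shape_regression <- function(x, ...) {
  cat(sprintf(
    "Shape ~ log(CS): %.2f%% of variation predicted, permutation p = %s (%d rounds)\n",
    x$percent_predicted,
    if (is.na(x$permutation_p)) "NA" else format(x$permutation_p, digits = 4),
    x$n_permutations))
  invisible(x)
}

#' Non-allometric (size-corrected) shape coordinates
#'
#' Adds the consensus back onto the regression residuals, yielding
#' shape coordinates with the size effect removed — the "non-allometric"
#' track used for residual PCA and size-corrected group distances.
#' Regressing the result on the same sizes again predicts 0%.
#'
#' @param result A [regress_shape_on_size()] object.
#' @return `n x p` matrix of residual shape coordinates.
#' @export
nonallometric_coordinates <- function(result) {
  sweep(result$residuals, 2L, result$mean_shape, `+`)
}

#' Angle between two trajectory vectors
#'
#' @param vector_a,vector_b Non-zero numeric vectors of equal length.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
trajectory_angle <- function(vector_a, vector_b) {
  na <- sqrt(sum(vector_a^2)); nb <- sqrt(sum(vector_b^2))
  if (na == 0 || nb == 0) stop("zero-length trajectory vector", call. = FALSE)
  if (length(vector_a) != length(vector_b))
    stop("trajectory vectors differ in length", call. = FALSE)
  acos(clamp(sum(vector_a * vector_b) / (na * nb), -1, 1)) * 180 / pi
}

#' Test the similarity of two trajectory directions
#'
#' Tests the observed angle between two vectors against the null that both
#' directions are drawn independently and uniformly on the unit sphere in
#' `dimension`-dimensional space, one-sided toward similarity:
#' `p = P(null angle <= observed)`. Under this null the cosine of the angle
#' `t` satisfies `(t+1)/2 ~ Beta((d-1)/2, (d-1)/2)` — the closed form of the
#' integrated `sin^(d-2)` angle density — which the analytic method evaluates;
#' the Monte-Carlo method samples random direction pairs and applies the
#' add-one convention, so its smallest attainable p is `1/(n_samples+1)`.
#'
#' The choice of `dimension` matters: for shape data it should be the
#' effective dimension of the shape space the vectors live in (e.g. the rank
#' of the pooled superimposed data), not the raw coordinate count.
#'
#' @param vector_a,vector_b The two trajectory vectors.
#' @param dimension Effective dimension of the null direction space (>= 2).
#' @param method `"analytic"` or `"monte_carlo"`.
#' @param n_samples Monte-Carlo sample count.
#' @param seed Integer seed for the Monte-Carlo stream.
#' @return Object of class `angle_test`: list with `angle_degrees`,
#'   `dimension`, `p_value`, `method`, `n_samples`, `seed`.
#' @export
angle_similarity_test <- function(vector_a, vector_b, dimension,
                                  method = c("analytic", "monte_carlo"),
                                  n_samples = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (dimension < 2L) stop("dimension must be >= 2", call. = FALSE)
  ang <- trajectory_angle(vector_a, vector_b)
  p <- if (method == "analytic") {
    angle_null_cdf(ang, dimension)
  } else {
    withr_seed(seed, {
      u <- matrix(stats::rnorm(n_samples * dimension), n_samples)
      v <- matrix(stats::rnorm(n_samples * dimension), n_samples)
      cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
      angs <- acos(clamp(cosang, -1, 1)) * 180 / pi
      (sum(angs <= ang) + 1) / (n_samples + 1)
    })
  }
  structure(
    list(angle_degrees = ang, dimension = as.integer(dimension), p_value = p,
         method = method,
         n_samples = if (method == "monte_carlo") n_samples else NA_integer_,
         seed = if (method == "monte_carlo") seed else NA_integer_),
    class = "angle_test")
}

# P(angle <= a degrees) for two independent uniform directions in d dims.
angle_null_cdf <- function(a_deg, d) {
  t <- cos(a_deg * pi / 180)
  stats::pbeta((t + 1) / 2, (d - 1) / 2, (d - 1) / 2, lower.tail = FALSE)
}

#' @export
print.angle_test <- function(x, ...) {
  cat(sprintf(
    "Trajectory angle %.2f deg in %d-D shape space: p = %s (%s null)\n",
    x$angle_degrees, x$dimension, format(x$p_value, digits = 4), x$method))
  invisible(x)
}

#' Effective dimension of a shape data matrix
#'
#' Numerical rank of the centered coordinate matrix (eigenvalues above
#' `1e-10 x` the largest), the default dimension for the trajectory-angle
#' null: superimposition and the symmetry decomposition leave shape variation
#' in a proper subspace of the raw coordinate space.
#'
#' @param coordinates `n x p` matrix or `k x 3 x n` array.
#' @return Integer rank.
#' @export
shape_space_dimension <- function(coordinates) {
  x <- as_shape_matrix(coordinates)
  d <- svd(sweep(x, 2L, colMeans(x)), nu = 0, nv = 0)$d
  sum(d^2 > 1e-10 * max(d^2))
}

#' Per-group ontogenetic trajectories and their pairwise comparison
#'
#' Fits the shape-on-log-size regression within each group on a common
#' superimposition, then compares every pair of groups by the angle between
#' their allometric vectors and the direction-similarity test.
#'
#' @param coordinates `n x p` matrix of flattened superimposed shapes or
#'   `k x 3 x n` array.
#' @param log_sizes Numeric vector of log centroid sizes.
#' @param groups Factor/character vector of group labels.
#' @param dimension Dimension for the angle null; default the rank of the
#'   pooled coordinates ([shape_space_dimension()]).
#' @param n_permutations Permutations for each within-group regression test.
#' @param method,n_samples Passed to [angle_similarity_test()].
#' @param seed Master seed; per-group and per-pair streams are derived.
#' @return List with `regressions` (named per group), `angles` (data frame of
#'   pairwise angles and p-values) and `dimension`.
#' @export
ontogenetic_trajectories <- function(coordinates, log_sizes, groups,
                                     dimension = NULL,
                                     n_permutations = 999L,
                                     method = "analytic",
                                     n_samples = 10000L, seed = 1L) {
  x <- as_shape_matrix(coordinates)
  groups <- factor(groups)
  if (is.null(dimension)) dimension <- shape_space_dimension(x)
  regs <- list()
  for (g in levels(groups)) {
    idx <- groups == g
    if (sum(idx) < 3L)
      stop("group '", g, "' has fewer than 3 specimens", call. = FALSE)
    regs[[g]] <- regress_shape_on_size(
      x[idx, , drop = FALSE], log_sizes[idx],
      n_permutations = n_permutations,
      seed = derive_seed(seed, paste0("regression_", g)))
  }
  pairs <- utils::combn(levels(groups), 2L)
  angles <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                       angle_degrees = NA_real_, p_value = NA_real_,
                       stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    at <- angle_similarity_test(
      regs[[pairs[1L, i]]]$allometric_vector,
      regs[[pairs[2L, i]]]$allometric_vector,
      dimension = dimension, method = method, n_samples = n_samples,
      seed = derive_seed(seed, paste0("angle_", i)))
    angles$angle_degrees[i] <- at$angle_degrees
    angles$p_value[i] <- at$p_value
  }
  list(regressions = regs, angles = angles, dimension = dimension)
}
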