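#' Centroid size
#'
#' The standard geometric size measure of a landmark configuration: the square
#' root of the summed squared distances of all landmarks from their centroid.
#'
#' @param config Numeric `k x 3` coordinate matrix without missing values.
#' @return Non-negative scalar, in the units of the input coordinates.
#' @examples
#' centroid_size(cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 0))  # sqrt(8)
#' @export
centroid_size <- function(config) {
  if (anyNA(config))
    stop("configuration has missing landmarks; run estimate_missing() first",
         call. = FALSE)
  ctr <- colMeans(config)
  sqrt(sum(sweep(config, 2L, ctr)^2))
}

center_config <- function(config) sweep(config, 2L, colMeans(config))

# Center and scale to unit centroid size.
to_preshape <- function(config) {
  x <- center_config(config)
  cs <- sqrt(sum(x^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincident",
                    call. = FALSE)
  x / cs
}

# Optimal rotation of (centered) x onto (centered) ref by SVD;
# det constrained to +1 unless reflections are allowed.
optimal_rotation <- function(x, ref, allow_reflection = FALSE) {
  s <- svd(crossprod(x, ref))
  r <- s$u %*% t(s$v)
  if (!allow_reflection && det(r) < 0) {
    u <- s$u
    u[, 3L] <- -u[, 3L]
    r <- u %*% t(s$v)
  }
  r
}

#' Ordinary Procrustes alignment of one configuration onto a reference
#'
#' Centers the configuration, scales it to unit centroid size and rotates it
#' (SVD-based orthogonal Procrustes) to minimize the summed squared distance
#' to the reference. The rotation is a proper rotation (determinant +1)
#' unless `allow_reflection = TRUE`.
#'
#' @param config Numeric `k x 3` matrix.
#' @param reference Numeric `k x 3` matrix (centered internally; its scale is
#'   kept as given).
#' @param allow_reflection Permit an improper rotation (reflection)?
#' @return List with `aligned` (the transformed configuration), `rotation`,
#'   and `rss` (the residual sum of squares against the centered reference).
#' @export
align_to <- function(config, reference, allow_reflection = FALSE) {
  if (!all(dim(config) == dim(reference)))
    stop("landmark counts differ between configuration and reference",
         call. = FALSE)
  x <- to_preshape(config)
  ref <- center_config(reference)
  if (qr(x)$rank < 2L)
    stop("alignment undefined: configuration of rank < 2", call. = FALSE)
  r <- optimal_rotation(x, ref, allow_reflection)
  aligned <- x %*% r
  list(aligned = aligned, rotation = r, rss = sum((aligned - ref)^2))
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of all configurations: each is centered and
#' scaled to unit centroid size, rotated onto a provisional consensus, and the
#' consensus (the arithmetic mean, rescaled to unit centroid size) is updated
#' until the total Procrustes sum of squares stabilizes. The total sum of
#' squares is non-increasing across iterations.
#'
#' Optionally the aligned coordinates are projected into the tangent space at
#' the consensus: `"orthogonal"` subtracts the component along the consensus
#' (Rohlf's orthogonal projection), `"central"` rescales each configuration by
#' the inverse of its inner product with the consensus (gnomonic projection,
#' which maps shapes lying on a straight line through configuration space back
#' onto that line exactly). The default uses the unit-size Procrustes
#' coordinates directly, the usual small-variation treatment.
#'
#' @param dataset A complete [landmark_dataset()] (estimate missing landmarks
#'   first), or a `k x 3 x n` array.
#' @param tol Convergence tolerance on the relative change in total sum of
#'   squares.
#' @param max_iter Iteration cap; non-convergence flags the result and warns.
#' @param tangent One of `"none"`, `"orthogonal"`, `"central"`.
#' @return An object of class `gpa_result`: list with `consensus` (`k x 3`,
#'   unit centroid size), `aligned` (`k x 3 x n`), `centroid_sizes`,
#'   `log_centroid_sizes`, `iterations`, `converged`, `ss_trace` (total sum of
#'   squares after each iteration) and `tangent`.
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L,
                tangent = c("none", "orthogonal", "central")) {
  tangent <- match.arg(tangent)
  coords <- if (inherits(dataset, "landmark_dataset")) dataset$coords else dataset
  if (anyNA(coords))
    stop("dataset has missing landmarks; run estimate_missing() first",
         call. = FALSE)
  n <- dim(coords)[3L]
  if (n < 2L) stop("GPA needs at least two specimens", call. = FALSE)
  sizes <- apply(coords, 3L, centroid_size)
  aligned <- array(0, dim = dim(coords))
  for (i in seq_len(n)) aligned[, , i] <- to_preshape(coords[, , i])
  consensus <- to_preshape(aligned[, , 1L])
  total_ss <- function() {
    mean_shape <- apply(aligned, c(1L, 2L), mean)
    sum(sweep(aligned, c(1L, 2L), mean_shape)^2)
  }
  ss_prev <- Inf
  ss_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      r <- optimal_rotation(aligned[, , i], consensus)
      aligned[, , i] <- aligned[, , i] %*% r
    }
    consensus <- to_preshape(apply(aligned, c(1L, 2L), mean))
    ss <- total_ss()
    ss_trace <- c(ss_trace, ss)
    if (is.finite(ss_prev) &&
        abs(ss_prev - ss) <= tol * max(ss_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ss_prev <- ss
  }
  if (!converged) warning("GPA did not converge in ", max_iter, " iterations")
  if (tangent != "none") {
    c_vec <- flatten_config(consensus)
    for (i in seq_len(n)) {
      y <- flatten_config(aligned[, , i])
      proj <- sum(y * c_vec)
      y <- if (tangent == "central") y / proj else y - (proj - 1) * c_vec
      aligned[, , i] <- unflatten_config(y, nrow(consensus))
    }
  }
  structure(
    list(consensus = consensus, aligned = aligned,
         centroid_sizes = sizes, log_centroid_sizes = log(sizes),
         iterations = iter, converged = converged, ss_trace = ss_trace,
         tangent = tangent),
    class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat("GPA of ", dim(x$aligned)[3L], " configurations (",
      dim(x$aligned)[1L], " landmarks): ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged",
      ", final SS = ", format(x$ss_trace[length(x$ss_trace)], digits = 6),
      "\n", sep = "")
  invisible(x)
}

# Reflect a configuration across the template's left-right axis (x) and swap
# paired landmarks, yielding the mirrored-and-relabeled copy used by the
# object-symmetry decomposition.
reflect_relabel <- function(config, template, axis = 1L) {
  out <- config
  out[, axis] <- -out[, axis]
  pr <- template$pairs
  if (nrow(pr)) {
    tmp <- out[pr[, 1L], , drop = FALSE]
    out[pr[, 1L], ] <- out[pr[, 2L], , drop = FALSE]
    out[pr[, 2L], ] <- tmp
  }
  out
}

#' Generalized Procrustes analysis with object symmetry
#'
#' For structures with internal bilateral symmetry, each configuration is
#' superimposed together with its reflected-and-relabeled copy (reflection of
#' the left-right axis with paired landmarks swapped). The symmetric component
#' of a specimen is the average of its two aligned copies — an exact fixed
#' point of reflect-and-relabel — and the asymmetric component is the
#' half-difference, so `symmetric + asymmetric` reproduces the aligned
#' original. Downstream covariance analyses of symmetric structures use the
#' symmetric components only.
#'
#' @param dataset A complete [landmark_dataset()] whose template defines
#'   pairs/midline, or a `k x 3 x n` array plus an explicit `template`.
#' @param template Optional [load_template()] when `dataset` is an array.
#' @param tol,max_iter Passed to [gpa()].
#' @return A list with `gpa` (the `gpa_result` over all `2n` copies; sizes
#'   refer to the n original specimens), `symmetric` and `asymmetric`
#'   (`k x 3 x n` arrays), `consensus` (symmetric mean, an exact fixed point
#'   of reflect-and-relabel) and `reflection_axis` (always 1, the x axis).
#' @export
gpa_with_object_symmetry <- function(dataset, template = NULL,
                                     tol = 1e-10, max_iter = 100L) {
  if (inherits(dataset, "landmark_dataset")) {
    template <- dataset$template
    coords <- dataset$coords
  } else coords <- dataset
  if (is.null(template) || !has_symmetry(template))
    stop("object symmetry requires a template with left/right pairs",
         call. = FALSE)
  if (anyNA(coords))
    stop("dataset has missing landmarks; run estimate_missing() first",
         call. = FALSE)
  k <- dim(coords)[1L]; n <- dim(coords)[3L]
  doubled <- array(0, dim = c(k, 3L, 2L * n))
  doubled[, , seq_len(n)] <- coords
  for (i in seq_len(n))
    doubled[, , n + i] <- reflect_relabel(coords[, , i], template)
  g <- gpa(doubled, tol = tol, max_iter = max_iter)
  # symmetrize the consensus exactly and realign every copy to it once, so
  # mirror pairs are aligned mutually consistently and the half-sum /
  # half-difference decomposition is orthogonal by construction
  consensus <- (g$consensus + reflect_relabel(g$consensus, template)) / 2
  consensus <- consensus / sqrt(sum(center_config(consensus)^2))
  for (i in seq_len(2L * n)) {
    r <- optimal_rotation(g$aligned[, , i], consensus)
    g$aligned[, , i] <- g$aligned[, , i] %*% r
  }
  g$consensus <- consensus
  sym <- (g$aligned[, , seq_len(n), drop = FALSE] +
          g$aligned[, , n + seq_len(n), drop = FALSE]) / 2
  asym <- (g$aligned[, , seq_len(n), drop = FALSE] -
           g$aligned[, , n + seq_len(n), drop = FALSE]) / 2
  g$centroid_sizes <- g$centroid_sizes[seq_len(n)]
  g$log_centroid_sizes <- g$log_centroid_sizes[seq_len(n)]
  list(gpa = g, symmetric = sym, asymmetric = asym,
       consensus = consensus, reflection_axis = 1L)
}

#' Procrustes distance between two shapes
#'
#' Partial Procrustes distance: both configurations are centered and scaled to
#' unit centroid size, one is optimally rotated onto the other, and the square
#' root of the residual sum of squares is returned. This is the shape-space
#' metric used for all group comparisons.
#'
#' @param shape_a,shape_b Numeric `k x 3` matrices over the same landmarks.
#' @return Non-negative scalar; 0 iff the shapes are identical up to
#'   translation, scaling and rotation.
#' @export
procrustes_distance <- function(shape_a, shape_b) {
  a <- to_preshape(shape_a)
  b <- to_preshape(shape_b)
  r <- optimal_rotation(a, b)
  sqrt(sum((a %*% r - b)^2))
}

#' Transfer a shape or trajectory vector between superimposition frames
#'
#' Two superimpositions of the same landmarks generally differ by a global
#' rotation. This rotates a configuration (or a flattened trajectory vector)
#' by the proper rotation that optimally aligns `from_consensus` onto
#' `to_reference`, so directions estimated in one frame can be compared with
#' directions expressed in another (e.g. an estimated allometric vector with
#' a generating one).
#'
#' @param x `k x 3` configuration or flattened length-`3k` vector.
#' @param from_consensus Consensus shape of the frame `x` lives in.
#' @param to_reference Shape defining the target frame.
#' @return `x` rotated into the target frame (same form as the input).
#' @export
transfer_frame <- function(x, from_consensus, to_reference) {
  r <- optimal_rotation(center_config(from_consensus),
                        center_config(to_reference))
  if (is.null(dim(x)))
    flatten_config(unflatten_config(x, nrow(from_consensus)) %*% r)
  else x %*% r
}
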