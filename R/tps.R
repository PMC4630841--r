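#' Fit a 3D thin-plate-spline interpolation
#'
#' Fits the interpolating spline from `source` to `target` using the 3D
#' biharmonic radial kernel U(r) = r together with a full affine term. The
#' spline reproduces the target exactly at the source points, minimizes
#' bending energy among all such interpolants, and its non-affine weights
#' satisfy the side conditions (orthogonality to constants and to the source
#' coordinates), so an affine target is reproduced with zero bending.
#'
#' A near-singular system (e.g. nearly coplanar sources) is re-solved with a
#' small ridge (1e-10 x trace) on the kernel block and a note is recorded on
#' the returned object; exactly degenerate systems error.
#'
#' @param source Numeric `m x 3` matrix, `m >= 5`, not all coplanar.
#' @param target Numeric `m x 3` matrix.
#' @return Object of class `tps_mapping`: list with `source_points`,
#'   `target_points`, `affine_part` (4 x 3: intercept row + linear map),
#'   `nonaffine_weights` (`m x 3`), `kernel = "r"` and `ridge_used`.
#' @export
fit_tps <- function(source, target) {
  m <- nrow(source)
  if (m < 5L) stop("TPS needs at least 5 source landmarks", call. = FALSE)
  if (!all(dim(source) == dim(target)))
    stop("source and target dimensions differ", call. = FALSE)
  K <- as.matrix(stats::dist(source))          # U(r) = r
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(target, matrix(0, 4L, 3L))
  ridge_used <- FALSE
  sol <- tryCatch(solve(L, rhs), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol)) || rcond(L) < 1e-14) {
    Lr <- L
    diag(Lr)[seq_len(m)] <- diag(Lr)[seq_len(m)] + 1e-10 * sum(diag(K))
    sol <- tryCatch(solve(Lr, rhs), error = function(e) NULL)
    if (is.null(sol) || !all(is.finite(sol)))
      stop("TPS system singular: source landmarks degenerate (coplanar or ",
           "coincident)", call. = FALSE)
    ridge_used <- TRUE
  }
  structure(
    list(source_points = source, target_points = target,
         affine_part = sol[m + 1:4, , drop = FALSE],
         nonaffine_weights = sol[seq_len(m), , drop = FALSE],
         kernel = "r", ridge_used = ridge_used),
    class = "tps_mapping")
}

#' Evaluate a thin-plate-spline mapping
#'
#' @param mapping A [fit_tps()] object.
#' @param query Numeric `q x 3` matrix of points to warp.
#' @return Numeric `q x 3` matrix of warped points.
#' @export
warp_points <- function(mapping, query) {
  if (is.null(dim(query))) query <- matrix(query, ncol = 3L)
  affine <- cbind(1, query) %*% mapping$affine_part
  # pairwise distances query x source
  d2 <- outer(rowSums(query^2), rep(1, nrow(mapping$source_points))) +
    outer(rep(1, nrow(query)), rowSums(mapping$source_points^2)) -
    2 * query %*% t(mapping$source_points)
  U <- sqrt(pmax(d2, 0))
  affine + U %*% mapping$nonaffine_weights
}

#' Estimate missing landmarks by thin-plate-spline warping
#'
#' For each incomplete specimen, a reference shape (by default the Procrustes
#' consensus of all complete specimens) is warped onto the specimen's observed
#' landmarks and the missing landmarks are read off the warped reference.
#' The specimen is first aligned to the reference by partial Procrustes on its
#' observed landmarks, the spline is fitted from the reference's observed
#' subset to the aligned specimen, and the estimated positions are mapped back
#' into the specimen's original digitizing frame, so estimation is equivariant
#' under rigid motion of the incomplete specimen.
#'
#' Complete specimens are returned untouched; running the procedure on a
#' complete dataset is the identity.
#'
#' @param dataset A [landmark_dataset()].
#' @param reference Either `"grand_mean_complete"` (default; requires at least
#'   one complete specimen) or an explicit `k x 3` reference shape.
#' @param min_observed Minimum observed landmarks required per specimen.
#' @return A [landmark_dataset()] with all missing landmarks filled in,
#'   missing mask cleared, and completion noted in the provenance log.
#' @export
estimate_missing <- function(dataset, reference = "grand_mean_complete",
                             min_observed = 5L) {
  n <- n_specimens(dataset)
  incomplete <- which(colSums(dataset$missing) > 0L)
  if (!length(incomplete)) return(dataset)
  if (is.character(reference)) {
    reference <- match.arg(reference, "grand_mean_complete")
    complete <- setdiff(seq_len(n), incomplete)
    if (!length(complete))
      stop("no complete specimens to build the grand-mean reference; ",
           "supply an explicit reference shape", call. = FALSE)
    ref <- if (length(complete) == 1L) {
      to_preshape(dataset$coords[, , complete])
    } else {
      gpa(dataset$coords[, , complete, drop = FALSE])$consensus
    }
  } else ref <- reference
  coords <- dataset$coords
  for (i in incomplete) {
    obs <- !dataset$missing[, i]
    if (sum(obs) < min_observed)
      stop("specimen ", dataset$meta$specimen_id[i], " retains only ",
           sum(obs), " observed landmarks; need >= ", min_observed,
           call. = FALSE)
    spec_obs <- coords[, , i][obs, , drop = FALSE]
    ref_obs <- ref[obs, , drop = FALSE]
    # align the specimen's observed landmarks onto the reference subset
    ctr <- colMeans(spec_obs)
    x <- sweep(spec_obs, 2L, ctr)
    cs <- sqrt(sum(x^2))
    ref_ctr <- colMeans(ref_obs)
    refc <- sweep(ref_obs, 2L, ref_ctr)
    r <- optimal_rotation(x / cs, refc)
    spec_aligned <- sweep((x / cs) %*% r, 2L, ref_ctr, `+`)
    map <- fit_tps(ref_obs, spec_aligned)
    est_aligned <- warp_points(map, ref[!obs, , drop = FALSE])
    # map estimates back into the original digitizing frame
    est <- sweep(est_aligned, 2L, ref_ctr) %*% t(r) * cs
    coords[!obs, , i] <- sweep(est, 2L, ctr, `+`)
  }
  mm <- matrix(FALSE, dim(coords)[1L], n)
  landmark_dataset(dataset$template, coords, dataset$meta, missing = mm,
                   provenance = c(dataset$provenance,
                                  paste0("estimated missing landmarks for ",
                                         length(incomplete),
                                         " specimen(s) by TPS warping")))
}
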