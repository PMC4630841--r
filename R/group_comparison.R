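#' Pairwise group Procrustes distances with permutation tests
#'
#' For every pair of groups the statistic is the Procrustes distance between
#' the two group mean shapes (arithmetic means of the superimposed
#' coordinates, re-standardized to unit centroid size before the distance).
#' Significance comes from reshuffling the two groups' specimen labels; the
#' p-value uses the add-one convention so it is never zero. Run once on raw
#' Procrustes coordinates and once on non-allometric residual coordinates to
#' obtain the size-uncorrected and size-corrected panels of a distance table.
#'
#' @param coordinates `n x p` matrix of flattened shapes or `k x 3 x n` array.
#' @param groups Factor/character vector of group labels (>= 2 groups, each
#'   with >= 2 specimens).
#' @param n_permutations Permutations per pair (default 999).
#' @param seed Integer master seed; each pair gets a derived stream.
#' @param track Label stored on the result (`"raw"` or `"nonallometric"`).
#' @return Object of class `distance_table`: list with `labels`, `distances`
#'   and `p_values` (symmetric matrices, zero/unit diagonal), `n_permutations`,
#'   `seed`, `track`.
#' @export
group_distance_permutation <- function(coordinates, groups,
                                       n_permutations = 999L, seed = 1L,
                                       track = "raw") {
  x <- as_shape_matrix(coordinates)
  groups <- factor(groups)
  labs <- levels(groups)
  if (length(labs) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("group '", names(sizes)[which(sizes < 2L)[1L]],
         "' has fewer than 2 specimens", call. = FALSE)
  k <- ncol(x) / 3L
  g_dist <- function(rows_a, rows_b) {
    ma <- unflatten_config(colMeans(x[rows_a, , drop = FALSE]), k)
    mb <- unflatten_config(colMeans(x[rows_b, , drop = FALSE]), k)
    procrustes_distance(ma, mb)
  }
  m <- length(labs)
  D <- matrix(0, m, m, dimnames = list(labs, labs))
  P <- matrix(1, m, m, dimnames = list(labs, labs))
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    rows_i <- which(groups == labs[i]); rows_j <- which(groups == labs[j])
    obs <- g_dist(rows_i, rows_j)
    pool <- c(rows_i, rows_j)
    na <- length(rows_i)
    count <- 0L
    withr_seed(derive_seed(seed, paste0("dist_", labs[i], "_", labs[j])), {
      for (b in seq_len(n_permutations)) {
        perm <- sample(pool)
        if (g_dist(perm[seq_len(na)], perm[-seq_len(na)]) >= obs - 1e-12)
          count <- count + 1L
      }
    })
    D[i, j] <- D[j, i] <- obs
    P[i, j] <- P[j, i] <- (count + 1) / (n_permutations + 1)
  }
  structure(list(labels = labs, distances = D, p_values = P,
                 n_permutations = n_permutations, seed = seed, track = track),
            class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat("Group Procrustes distances (", x$track, " track, ",
      x$n_permutations, " permutations); p-values in brackets\n", sep = "")
  m <- length(x$labels)
  out <- matrix("", m, m, dimnames = list(x$labels, x$labels))
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i > j) out[i, j] <- sprintf("%.4f (%.4g)", x$distances[i, j],
                                    x$p_values[i, j])
  print(out[-1L, -m, drop = FALSE], quote = FALSE)
  invisible(x)
}

#' Canonical variates analysis on retained principal components
#'
#' Ordination maximizing between-group relative to within-group variation.
#' The shape data are first reduced to leading PCs so the pooled within-group
#' covariance is invertible (default: PCs explaining 95% of variance, capped
#' at `n - groups - 1`), then the canonical axes are the eigenvectors of
#' `W^{-1} B`. Group Mahalanobis distances (in the retained-PC metric) are
#' invariant to any invertible linear transformation of the retained scores.
#'
#' @param coordinates `n x p` flattened shapes or `k x 3 x n` array.
#' @param groups Factor/character group labels.
#' @param n_retained_pcs Number of PCs retained; `NULL` for the default rule.
#' @return List with `scores` (`n x n_cv`), `eigenvalues`,
#'   `mahalanobis` (symmetric group-distance matrix), `n_retained_pcs`,
#'   `group_means` (CV-space means).
#' @export
cva_scores <- function(coordinates, groups, n_retained_pcs = NULL) {
  x <- as_shape_matrix(coordinates)
  groups <- factor(groups)
  n <- nrow(x); g <- nlevels(groups)
  pca <- shape_pca(x)
  if (is.null(n_retained_pcs)) {
    cum <- cumsum(pca$percent_variance)
    n_retained_pcs <- min(which(cum >= 95), n - g - 1L,
                          length(pca$eigenvalues))
  }
  if (n - g <= n_retained_pcs)
    stop("too few specimens (", n, ") for ", n_retained_pcs,
         " retained PCs with ", g, " groups", call. = FALSE)
  y <- pca$scores[, seq_len(n_retained_pcs), drop = FALSE]
  out <- cva_core(y, groups)
  out$n_retained_pcs <- n_retained_pcs
  out
}

# CVA on an already-reduced score matrix y (n x q, q < n - g).
cva_core <- function(y, groups) {
  groups <- factor(groups)
  n <- nrow(y); g <- nlevels(groups); q <- ncol(y)
  counts <- as.vector(table(groups))
  gm <- rowsum(y, groups) / counts
  centered_within <- y - gm[as.integer(groups), , drop = FALSE]
  W <- crossprod(centered_within) / (n - g)
  grand <- colSums(gm * counts) / n
  B <- crossprod(sweep(gm, 2L, grand) * sqrt(counts)) / (g - 1L)
  # eigen of W^-1 B via symmetric whitening
  ew <- eigen(W, symmetric = TRUE)
  w_half_inv <- ew$vectors %*% diag(1 / sqrt(pmax(ew$values, 1e-300)), q) %*%
    t(ew$vectors)
  eb <- eigen(w_half_inv %*% B %*% w_half_inv, symmetric = TRUE)
  n_cv <- min(g - 1L, q)
  axes <- w_half_inv %*% eb$vectors[, seq_len(n_cv), drop = FALSE]
  scores <- sweep(y, 2L, grand) %*% axes
  # Mahalanobis distances between group means under pooled W
  md <- matrix(0, g, g, dimnames = list(levels(groups), levels(groups)))
  w_inv <- ew$vectors %*% diag(1 / pmax(ew$values, 1e-300), q) %*%
    t(ew$vectors)
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    d <- gm[i, ] - gm[j, ]
    md[i, j] <- md[j, i] <- sqrt(drop(t(d) %*% w_inv %*% d))
  }
  list(scores = scores, eigenvalues = pmax(eb$values[seq_len(n_cv)], 0),
       mahalanobis = md,
       group_means = sweep(gm, 2L, grand) %*% axes)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected rank-based H test that several groups share a distribution,
#' referred to a chi-square distribution with `groups - 1` degrees of freedom
#' (computed via [stats::kruskal.test()]).
#'
#' @param values Numeric response (e.g. PC scores).
#' @param groups Factor/character group labels.
#' @return Object of class `rank_test`: list with `chi_square`, `df`,
#'   `p_value`, `group_sizes`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (length(unique(values)) == 1L) {
    # fully tied response: no evidence of any difference (H = 0), which the
    # tie-corrected formula leaves indeterminate (0/0)
    return(structure(list(chi_square = 0, df = nlevels(groups) - 1L,
                          p_value = 1, group_sizes = table(groups)),
                     class = "rank_test"))
  }
  kt <- stats::kruskal.test(values, groups)
  structure(list(chi_square = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, group_sizes = table(groups)),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi2 = %.4g, df = %d, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Post-hoc multiple comparison of mean ranks
#'
#' Pairwise follow-up to the Kruskal-Wallis test: two groups differ when the
#' absolute difference of their mean ranks (ranks over the pooled sample)
#' exceeds the normal-approximation critical difference
#' `z_{1 - alpha / (g(g-1))} * sqrt(N(N+1)/12 * (1/n_i + 1/n_j))`
#' (the Siegel-Castellan rule, with the Bonferroni-style adjustment for all
#' `g(g-1)/2` two-sided comparisons built into the quantile).
#'
#' @param values Numeric response.
#' @param groups Factor/character group labels.
#' @param alpha Familywise significance level (default 0.05).
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `obs_diff` (absolute mean-rank difference), `critical_diff`,
#'   `significant`.
#' @export
kruskal_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  g <- nlevels(groups)
  if (g < 2L) stop("post-hoc comparison needs at least two groups",
                   call. = FALSE)
  n_tot <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  sizes <- table(groups)
  z <- stats::qnorm(1 - alpha / (g * (g - 1L)))
  pairs <- utils::combn(levels(groups), 2L)
  out <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                    obs_diff = NA_real_, critical_diff = NA_real_,
                    significant = NA, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    crit <- z * sqrt(n_tot * (n_tot + 1) / 12 *
                       (1 / sizes[[a]] + 1 / sizes[[b]]))
    out$obs_diff[i] <- abs(mean_ranks[[a]] - mean_ranks[[b]])
    out$critical_diff[i] <- crit
    out$significant[i] <- out$obs_diff[i] > crit
  }
  out
}
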