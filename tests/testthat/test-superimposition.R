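test_that("centroid size has its analytic values and scaling behaviour", {
  sq <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 0)
  expect_equal(centroid_size(sq), sqrt(8))
  expect_equal(centroid_size(matrix(5, 4, 3)), 0)  # coincident landmarks
  set.seed(1)
  cfg <- random_config(10)
  for (c_scale in c(0.5, 3, -2))
    expect_equal(centroid_size(cfg * c_scale),
                 abs(c_scale) * centroid_size(cfg))
  cfg[3, 1] <- NA
  expect_error(centroid_size(cfg), "estimate_missing")
})

test_that("ordinary Procrustes alignment recovers rigid motions and mirrors", {
  set.seed(7)
  ref <- random_config(8)
  ref <- ref / centroid_size(ref)
  moved <- apply_rigid(ref, trans = c(3, -2, 9), scale = 12)
  fit <- align_to(moved, ref)
  expect_lt(fit$rss, 1e-20)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  # a chiral configuration's mirror image cannot be rotated back...
  mirrored <- ref %*% diag(c(-1, 1, 1))
  expect_gt(align_to(mirrored, ref)$rss, 1e-3)
  # ...unless reflections are allowed
  expect_lt(align_to(mirrored, ref, allow_reflection = TRUE)$rss, 1e-20)
  expect_error(align_to(matrix(0, 8, 3), ref), "degenerate|rank")
})

test_that("Procrustes distance matches the rotation-search oracle", {
  set.seed(11)
  for (rep in 1:6) {
    a <- random_config(3)          # random triangles
    b <- random_config(3)
    expect_equal(procrustes_distance(a, b), oracle_procrustes_distance(a, b),
                 tolerance = 1e-4)
  }
  # larger random configurations too
  a <- random_config(12); b <- random_config(12)
  expect_equal(procrustes_distance(a, b), oracle_procrustes_distance(a, b),
               tolerance = 1e-4)
  # metric sanity
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
               tolerance = 1e-10)
})

test_that("Procrustes distance agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(3)
  # planar configurations: vegan's least-squares rotation may reflect, which
  # for planar shapes is reachable by a proper 3D rotation
  a <- cbind(random_config(6)[, 1:2], 0)
  b <- cbind(random_config(6)[, 1:2], 0)
  v <- vegan::procrustes(
    sweep(b, 2, colMeans(b)) / centroid_size(b),
    sweep(a, 2, colMeans(a)) / centroid_size(a),
    scale = FALSE)
  expect_equal(procrustes_distance(a, b), sqrt(sum((v$Yrot - v$X)^2)),
               tolerance = 1e-8)
})

test_that("GPA collapses identical shapes and matches a two-shape oracle", {
  set.seed(5)
  base <- random_config(9)
  arr <- array(0, dim = c(9, 3, 6))
  for (i in 1:6)
    arr[, , i] <- apply_rigid(base, trans = runif(3, -10, 10),
                              scale = runif(1, 0.2, 8))
  g <- gpa(arr)
  expect_lt(g$ss_trace[length(g$ss_trace)], 1e-20)
  for (i in 2:6)
    expect_equal(g$aligned[, , i], g$aligned[, , 1], tolerance = 1e-9)

  a <- random_config(7); b <- random_config(7)
  arr2 <- array(0, dim = c(7, 3, 2)); arr2[, , 1] <- a; arr2[, , 2] <- b
  g2 <- gpa(arr2)
  expect_equal(g2$ss_trace[length(g2$ss_trace)], oracle_gpa2_ss(a, b),
               tolerance = 1e-8)
})

test_that("GPA descends monotonically and is invariant to input nuisance", {
  set.seed(13)
  tpl <- load_template("cranium36")
  ds <- toy_dataset(tpl, n = 12, seed = 13)
  g <- gpa(ds)
  expect_true(all(diff(g$ss_trace) <= 1e-12))
  expect_lt(g$iterations, 20)
  expect_true(g$converged)
  # unit size and zero centroid for every aligned configuration
  for (i in 1:12) {
    expect_equal(centroid_size(g$aligned[, , i]), 1, tolerance = 1e-10)
    expect_equal(colMeans(g$aligned[, , i]), rep(0, 3), tolerance = 1e-10)
  }
  # consensus is the normalized mean of the aligned configurations
  expect_equal(g$consensus,
               apply(g$aligned, c(1, 2), mean) /
                 centroid_size(apply(g$aligned, c(1, 2), mean)),
               tolerance = 1e-8)
  # per-specimen rigid motion + scaling of the inputs changes nothing
  perturbed <- ds$coords
  for (i in 1:12)
    perturbed[, , i] <- apply_rigid(perturbed[, , i],
                                    trans = runif(3, -50, 50),
                                    scale = runif(1, 0.1, 10))
  g2 <- gpa(perturbed)
  expect_equal(procrustes_distance(g$consensus, g2$consensus), 0,
               tolerance = 1e-8)
  d1 <- procrustes_distance(g$aligned[, , 1], g$aligned[, , 2])
  d2 <- procrustes_distance(g2$aligned[, , 1], g2$aligned[, , 2])
  expect_equal(d1, d2, tolerance = 1e-8)
  # specimen order is immaterial
  g3 <- gpa(ds$coords[, , 12:1])
  expect_equal(procrustes_distance(g$consensus, g3$consensus), 0,
               tolerance = 1e-6)
})

test_that("object-symmetry decomposition is exact and orthogonal", {
  tpl <- load_template("cranium36")
  set.seed(23)
  base <- make_symmetric_mean(tpl, 23)
  n <- 10
  arr <- array(0, dim = c(36, 3, n))
  for (i in 1:n)
    arr[, , i] <- apply_rigid(base + matrix(rnorm(108, 0, 0.03), 36),
                              trans = runif(3, -5, 5),
                              scale = runif(1, 80, 120))
  res <- gpa_with_object_symmetry(arr, tpl)
  # symmetric + asymmetric reproduces the aligned originals exactly
  expect_equal(res$symmetric + res$asymmetric,
               res$gpa$aligned[, , 1:n], tolerance = 1e-12)
  # each symmetric component is a fixed point of reflect-and-relabel
  for (i in 1:n)
    expect_lt(max(abs(res$symmetric[, , i] -
                        morphotraj:::reflect_relabel(res$symmetric[, , i],
                                                     tpl))), 1e-9)
  # consensus itself symmetric
  expect_equal(res$consensus,
               morphotraj:::reflect_relabel(res$consensus, tpl),
               tolerance = 1e-12)
  # orthogonality: total SS over the 2n copies splits into the two parts
  al <- res$gpa$aligned
  grand <- apply(al, c(1, 2), mean)
  total <- sum(sweep(al, c(1, 2), grand)^2)
  sym_ss <- 2 * sum(sweep(res$symmetric, c(1, 2), grand)^2)
  asym_ss <- 2 * sum(res$asymmetric^2)
  expect_equal(total, sym_ss + asym_ss, tolerance = 1e-8 * total)

  # perfectly symmetric specimens have vanishing asymmetric components
  arr_sym <- array(0, dim = c(36, 3, 4))
  for (i in 1:4) {
    d <- matrix(rnorm(108, 0, 0.05), 36)
    cfg <- base + (d + morphotraj:::reflect_relabel(
      morphotraj:::unflatten_config(flat(d), 36), tpl)) / 2
    cfg[tpl$midline, 1] <- 0
    arr_sym[, , i] <- apply_rigid(cfg, scale = runif(1, 0.5, 2))
  }
  res_sym <- gpa_with_object_symmetry(arr_sym, tpl)
  expect_lt(max(abs(res_sym$asymmetric)), 1e-8)

  # a specimen and its mirror twin share a symmetric component
  twin <- array(0, dim = c(36, 3, 4))
  cfg <- base + matrix(rnorm(108, 0, 0.05), 36)
  twin[, , 1] <- cfg
  twin[, , 2] <- morphotraj:::reflect_relabel(cfg, tpl)
  twin[, , 3] <- apply_rigid(base + matrix(rnorm(108, 0, 0.05), 36))
  twin[, , 4] <- apply_rigid(base + matrix(rnorm(108, 0, 0.05), 36))
  res_tw <- gpa_with_object_symmetry(twin, tpl)
  expect_equal(res_tw$symmetric[, , 1], res_tw$symmetric[, , 2],
               tolerance = 1e-9)

  # one-sided templates refuse the symmetry pathway
  expect_error(gpa_with_object_symmetry(arr[1:9, , ],
                                        load_template("mandible9")),
               "pairs")
})

test_that("symmetric-component covariance rank equals the projected
           symmetric-subspace dimension", {
  tpl <- load_template("cranium36")
  set.seed(31)
  base <- make_symmetric_mean(tpl, 31)
  n <- 80
  arr <- array(0, dim = c(36, 3, n))
  # small noise keeps second-order (sphere-curvature) eigenvalues far below
  # the genuine symmetric-subspace ones, so the rank cutoff is unambiguous
  for (i in 1:n)
    arr[, , i] <- apply_rigid(base + matrix(rnorm(108, 0, 0.005), 36))
  res <- gpa_with_object_symmetry(arr, tpl)
  ev <- shape_pca(flatten_shapes(res$symmetric))$eigenvalues
  rank_data <- sum(ev > 1e-3 * ev[1])
  # oracle: rank of random tangent vectors after brute-force symmetrization
  # and projection off the similarity directions at the consensus
  q <- morphotraj:::similarity_directions(res$consensus)
  vs <- sapply(1:70, function(i) {
    v <- rnorm(108)
    v <- (v + flat(morphotraj:::reflect_relabel(
      morphotraj:::unflatten_config(v, 36), tpl))) / 2
    v - q %*% crossprod(q, v)
  })
  sv <- svd(vs, nu = 0, nv = 0)$d
  rank_oracle <- sum(sv > 1e-8 * sv[1])
  expect_equal(rank_data, min(rank_oracle, n - 1))
  # 14 pairs x 3 + 8 midline x 2 minus 2 translations, 1 rotation, 1 scale
  expect_equal(rank_oracle, 14 * 3 + 8 * 2 - 4)
})
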