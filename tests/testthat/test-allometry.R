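test_that("noiseless simulated allometry is recovered exactly", {
  tpl <- load_template("cranium36")
  groups <- data.frame(species = "arctos", age_class = "adult", n = 20L,
                       size_min = 300, size_max = 450)
  p <- ontogeny_params(tpl, groups, noise_sd = 0, allometry_strength = 0.08,
                       size_mode = "balanced", seed = 7)
  ds <- simulate_ontogeny(p)
  g <- gpa(ds, tangent = "central")
  reg <- regress_shape_on_size(flatten_shapes(g$aligned),
                               g$log_centroid_sizes, n_permutations = 0)
  expect_equal(reg$percent_predicted, 100, tolerance = 1e-8)
  # compare the estimate with the generating direction: rotate it into the
  # latent frame and express the truth within the fitted tangent space
  truth <- attr(ds, "truth")$allometric_vectors$arctos
  est <- transfer_frame(reg$allometric_vector, g$consensus,
                        p$species_means$arctos)
  cons <- flat(transfer_frame(g$consensus, g$consensus,
                              p$species_means$arctos))
  truth_t <- truth - sum(truth * cons) * cons / sum(cons^2)
  angle_rad <- trajectory_angle(est, truth_t) * pi / 180
  expect_lt(angle_rad, 1e-6)

  # with landmark noise the recovery degrades gracefully: average angular
  # error decreases with sample size (checked over seeds)
  angle_for <- function(n, seed) {
    gr <- data.frame(species = "arctos", age_class = "adult", n = n,
                     size_min = 150, size_max = 450)
    pp <- ontogeny_params(tpl, gr, noise_sd = 0.01,
                          allometry_strength = 0.08, seed = seed)
    dd <- simulate_ontogeny(pp)
    gg <- gpa(dd, tangent = "central")
    rr <- regress_shape_on_size(flatten_shapes(gg$aligned),
                                gg$log_centroid_sizes, n_permutations = 0)
    ee <- transfer_frame(rr$allometric_vector, gg$consensus,
                         pp$species_means$arctos)
    cc <- flat(pp$species_means$arctos)
    tt <- attr(dd, "truth")$allometric_vectors$arctos
    tt <- tt - sum(tt * cc) * cc / sum(cc^2)
    trajectory_angle(ee, tt)
  }
  err_small_n <- mean(vapply(1:4, function(s) angle_for(10, s), numeric(1)))
  err_large_n <- mean(vapply(1:4, function(s) angle_for(80, s), numeric(1)))
  expect_lt(err_large_n, err_small_n)
})

test_that("shape-size regression has exact least-squares structure", {
  set.seed(21)
  x <- matrix(rnorm(25 * 12), 25, 12)
  z <- runif(25, 5, 6)
  reg <- regress_shape_on_size(x, z, n_permutations = 199, seed = 2)
  expect_equal(colMeans(reg$residuals), rep(0, 12), tolerance = 1e-12)
  expect_lt(max(abs(crossprod(reg$residuals, z - mean(z)))), 1e-10)
  expect_gte(reg$percent_predicted, 0)
  expect_lte(reg$percent_predicted, 100)
  # logarithm-base invariance: log10 sizes rescale the predictor only
  reg10 <- regress_shape_on_size(x, z / log(10), n_permutations = 199,
                                 seed = 2)
  expect_equal(reg10$percent_predicted, reg$percent_predicted,
               tolerance = 1e-10)
  expect_equal(trajectory_angle(reg$allometric_vector,
                                reg10$allometric_vector), 0,
               tolerance = 1e-6)
  expect_equal(reg10$permutation_p, reg$permutation_p)
  expect_error(regress_shape_on_size(x, rep(1, 25)), "constant")
})

test_that("non-allometric coordinates remove exactly the size effect", {
  set.seed(22)
  n <- 30
  z <- runif(n, 1, 3)
  b_true <- rnorm(10)
  x <- outer(z, b_true) + matrix(rnorm(n * 10, 0, 0.3), n)
  reg <- regress_shape_on_size(x, z, n_permutations = 0)
  resid_x <- nonallometric_coordinates(reg)
  # regressing the residual track on size again predicts nothing
  reg2 <- regress_shape_on_size(resid_x, z, n_permutations = 0)
  expect_equal(reg2$percent_predicted, 0, tolerance = 1e-8)
  # adding the fitted allometric term back reconstructs the data
  rebuilt <- resid_x + outer(z - mean(z), reg$allometric_vector)
  expect_equal(rebuilt, x, tolerance = 1e-10)
  # groups differing in size only: raw means differ, residual means align
  grp <- rep(c("small", "large"), each = 15)
  z2 <- ifelse(grp == "small", 1, 3) + runif(n, -0.1, 0.1)
  x2 <- outer(z2, b_true) + matrix(rnorm(n * 10, 0, 0.1), n)
  r2 <- regress_shape_on_size(x2, z2, n_permutations = 0)
  res2 <- nonallometric_coordinates(r2)
  raw_gap <- sqrt(sum((colMeans(x2[grp == "small", ]) -
                         colMeans(x2[grp == "large", ]))^2))
  res_gap <- sqrt(sum((colMeans(res2[grp == "small", ]) -
                         colMeans(res2[grp == "large", ]))^2))
  expect_lt(res_gap, raw_gap / 5)
})

test_that("permutation test is calibrated under the size-independence null", {
  set.seed(33)
  n_rep <- 500
  pvals <- vapply(seq_len(n_rep), function(r) {
    x <- matrix(rnorm(20 * 9), 20, 9)
    z <- rnorm(20)
    regress_shape_on_size(x, z, n_permutations = 99,
                          seed = r)$permutation_p
  }, numeric(1))
  rej <- sum(pvals <= 0.05)
  ci <- qbinom(c(0.0005, 0.9995), n_rep, 0.05)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
  # approximate uniformity over the unit interval
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("trajectory angles and their null distribution behave analytically", {
  v <- c(1, 0, 0, 0)
  expect_equal(trajectory_angle(v, v), 0)
  expect_equal(trajectory_angle(v, c(0, 1, 0, 0)), 90)
  expect_equal(trajectory_angle(v, -v), 180)
  expect_error(trajectory_angle(v, rep(0, 4)), "zero")

  # hemisphere symmetry: 90 degrees is the null median in any dimension
  for (d in c(3, 10, 50))
    expect_equal(angle_similarity_test(c(1, rep(0, d - 1)),
                                       c(0, 1, rep(0, d - 2)),
                                       dimension = d)$p_value, 0.5)
  # the smallest attainable Monte-Carlo p
  mc0 <- angle_similarity_test(v, v, dimension = 4, method = "monte_carlo",
                               n_samples = 999, seed = 5)
  expect_equal(mc0$p_value, 1 / 1000)

  # analytic null against Monte-Carlo across dimensions and angles
  for (d in c(3, 10, 50, 101)) {
    for (ang in c(30, 60, 80, 90, 110)) {
      u1 <- c(1, rep(0, d - 1))
      u2 <- c(cos(ang * pi / 180), sin(ang * pi / 180), rep(0, d - 2))
      pa <- angle_similarity_test(u1, u2, dimension = d)$p_value
      pm <- angle_similarity_test(u1, u2, dimension = d,
                                  method = "monte_carlo",
                                  n_samples = 1e5,
                                  seed = d + ang)$p_value
      se <- sqrt(max(pa * (1 - pa), 1e-9) / 1e5)
      expect_lt(abs(pa - pm), 3 * se + 2e-5)
    }
  }
  expect_error(angle_similarity_test(v, v, dimension = 1), "dimension")
})

test_that("per-group trajectories detect shared and unrelated ontogenies", {
  tpl <- load_template("cranium36")
  groups <- data.frame(
    species = c("arctos", "spelaeus"), age_class = "adult",
    n = c(40L, 40L), size_min = c(150, 150), size_max = c(450, 450))
  # identical generating trajectories: small angle, significant similarity
  p_same <- ontogeny_params(tpl, groups, noise_sd = 0.01,
                            allometry_strength = 0.08, seed = 13)
  ds <- simulate_ontogeny(p_same)
  g <- gpa(ds)
  tr <- ontogenetic_trajectories(flatten_shapes(g$aligned),
                                 g$log_centroid_sizes, ds$meta$species,
                                 n_permutations = 99, seed = 1)
  # estimation noise inflates the angle well above zero (each group vector
  # carries independent error), but far below the ~90-degree null centre,
  # and the similarity is overwhelmingly significant
  expect_lt(tr$angles$angle_degrees[1], 70)
  expect_lt(tr$angles$p_value[1], 0.001)
  # a trajectory compared with itself has angle zero
  va <- tr$regressions$arctos$allometric_vector
  expect_equal(trajectory_angle(va, va), 0)

  # orthogonal generating trajectories: p near the null median
  base <- make_symmetric_mean(tpl, 13)
  v1 <- tangent_direction(withr::with_seed(3, rnorm(108)), base, tpl,
                          symmetric = TRUE)
  v2 <- tangent_direction(withr::with_seed(4, rnorm(108)), base, tpl,
                          symmetric = TRUE)
  v2 <- v2 - sum(v1 * v2) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  p_orth <- ontogeny_params(
    tpl, groups, allometric_vectors = list(arctos = v1, spelaeus = v2),
    noise_sd = 0.01, allometry_strength = 0.08, seed = 14)
  ds2 <- simulate_ontogeny(p_orth)
  g2 <- gpa(ds2)
  tr2 <- ontogenetic_trajectories(flatten_shapes(g2$aligned),
                                  g2$log_centroid_sizes, ds2$meta$species,
                                  n_permutations = 99, seed = 1)
  expect_gt(tr2$angles$angle_degrees[1], 60)
  expect_gt(tr2$angles$p_value[1], 0.05)
  expect_lt(tr2$angles$p_value[1], 0.95)

  expect_error(
    ontogenetic_trajectories(matrix(rnorm(12), 4), rnorm(4),
                             c("a", "a", "a", "b")),
    "fewer than 3")
})
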