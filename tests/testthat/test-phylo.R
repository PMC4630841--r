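test_that("Newick reading validates and round-trips", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))
  # round-trip through the writer preserves topology and lengths
  tr4 <- read_newick("(a:5,(b:2.5,(c:1,d:1):1.5):2.5);")
  txt <- ape::write.tree(tr4)
  back <- read_newick(txt)
  expect_true(ape::all.equal.phylo(tr4, back))
  expect_error(read_newick("(A:1,B:1;"), "parse")
  expect_error(read_newick("(A:1,A:1);"), "unique")
  expect_error(read_newick("(A:1,B:-2);"), "negative")

  u <- ursus_tree()
  expect_setequal(u$tip.label,
                  c("americanus", "spelaeus", "arctos", "maritimus"))
  expect_true(ape::is.rooted(u))
})

test_that("squared-change length matches calculus and optimization oracles", {
  # two tips, unit branches: root at the midpoint, length (a - b)^2 / 2
  tr2 <- read_newick("(A:1,B:1);")
  for (ab in list(c(0, 1), c(-3, 5), c(2.2, 2.2))) {
    res <- squared_change_length(tr2, c(A = ab[1], B = ab[2]),
                                 "unit_lengths")
    expect_equal(res$tree_length, (ab[1] - ab[2])^2 / 2, tolerance = 1e-12)
    expect_equal(unname(res$node_values[1, 1]), mean(ab), tolerance = 1e-12)
  }
  # identical tips collapse to zero change everywhere
  tr4 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  resid <- squared_change_length(tr4, c(A = 7, B = 7, C = 7, D = 7),
                                 "unit_lengths")
  expect_equal(resid$tree_length, 0, tolerance = 1e-12)
  expect_equal(unname(resid$node_values),
               matrix(7, nrow(resid$node_values), 1), tolerance = 1e-12)

  # balanced 4-tip tree with random scalars against numerical minimization
  set.seed(71)
  for (rep in 1:3) {
    tips <- matrix(rnorm(4), 4, 1,
                   dimnames = list(c("A", "B", "C", "D"), NULL))
    got <- squared_change_length(tr4, tips, "unit_lengths")$tree_length
    expect_equal(got, oracle_squared_change(tr4, tips, rep(1, 6)),
                 tolerance = 1e-6)
  }
  # weighted (given branch lengths) mode against the same oracle
  trw <- read_newick("((A:2,B:0.5):1,(C:3,D:1):0.5);")
  tips <- matrix(rnorm(8), 4, 2,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  got_w <- squared_change_length(trw, tips, "given_lengths")$tree_length
  expect_equal(got_w, oracle_squared_change(trw, tips, trw$edge.length),
               tolerance = 1e-6)

  expect_error(squared_change_length(tr4, c(A = 1, B = 2, C = 3)), "missing")
})

test_that("weighted ancestral values agree with an independent BM fit", {
  set.seed(72)
  tr <- read_newick("((A:2,B:1):1,(C:1.5,D:2.5):2);")
  tips <- c(A = 1.2, B = -0.4, C = 2.5, D = 0.3)
  got <- squared_change_length(tr, tips, "given_lengths")
  # maximum-likelihood Brownian ancestral states minimize the same
  # branch-length-weighted criterion
  a <- ape::ace(tips[tr$tip.label], tr, method = "ML", model = "BM")
  expect_equal(unname(got$node_values[, 1]), unname(a$ace), tolerance = 1e-4)
})

test_that("tree length is rotation-invariant and additive across traits", {
  set.seed(73)
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  tips <- matrix(rnorm(12), 4, 3,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  base_len <- squared_change_length(tr, tips, "unit_lengths")$tree_length
  rot <- morphotraj:::random_rotation()
  expect_equal(squared_change_length(tr, tips %*% rot,
                                     "unit_lengths")$tree_length,
               base_len, tolerance = 1e-10)
  per_dim <- sum(vapply(1:3, function(j)
    squared_change_length(tr, tips[, j, drop = FALSE],
                          "unit_lengths")$tree_length, numeric(1)))
  expect_equal(per_dim, base_len, tolerance = 1e-10)
})

test_that("zero-length branches act as hard equality constraints", {
  tr <- read_newick("((A:0,B:1):1,C:1);")
  tips <- c(A = 1, B = 4, C = 7)
  res <- squared_change_length(tr, tips, "given_lengths")
  # the zero branch pins the cherry node at A's value; the root balances
  # between it and C: total = (B - A)^2 + (C - A)^2 / 2
  expect_equal(res$tree_length, (4 - 1)^2 + (7 - 1)^2 / 2, tolerance = 1e-10)
})

test_that("four-tip signal test enumerates exactly and sampling agrees", {
  tree <- ursus_tree()
  set.seed(81)
  tips <- matrix(rnorm(8), 4, 2,
                 dimnames = list(tree$tip.label, NULL))
  exact <- phylo_signal_permutation(tree, tips, branch_mode = "unit_lengths")
  expect_equal(exact$method, "exhaustive")
  expect_equal(exact$n_permutations, 24)
  expect_gte(exact$permutation_p, 1 / 24)     # identity always included
  # sampled mode converges on the enumerated probability
  sampled <- phylo_signal_permutation(tree, tips, n_permutations = 4000,
                                      seed = 3, branch_mode = "unit_lengths",
                                      enumerate_below = 2)
  se <- sqrt(exact$permutation_p * (1 - exact$permutation_p) / 4000)
  expect_lt(abs(sampled$permutation_p - exact$permutation_p), 3 * se + 1e-3)

  # strong Brownian-like signal sits at the attainable minimum: identity and
  # the left-right swap of the shortest cherry tie at 2/24
  strong <- matrix(c(0, 0.1, 5, 5.1, 0, 0.1, 5, 5.1), 4, 2,
                   dimnames = list(c("americanus", "spelaeus", "arctos",
                                     "maritimus"), NULL))
  strong["americanus", ] <- c(-5, -5)
  strong["spelaeus", ] <- c(0, 0)
  p_strong <- phylo_signal_permutation(tree, strong,
                                       branch_mode = "given_lengths")
  expect_lte(p_strong$permutation_p, 2 / 24 + 1e-12)
})

test_that("signal test is calibrated without signal and powerless on stars", {
  tree <- ursus_tree()
  set.seed(91)
  pvals <- vapply(1:150, function(r) {
    tips <- matrix(rnorm(12), 4, 3, dimnames = list(tree$tip.label, NULL))
    phylo_signal_permutation(tree, tips,
                             branch_mode = "unit_lengths")$permutation_p
  }, numeric(1))
  # exchangeable tips: enumerated p is (super)uniform; its mean sits at 1/2
  # plus half the tie-induced granularity
  expect_gt(mean(pvals), 0.40)
  expect_lt(mean(pvals), 0.65)
  expect_gte(min(pvals), 1 / 24)
  # rejection at the finest attainable level matches its nominal rate
  # (arctos/maritimus share a branch length, so levels come in steps of 2/24)
  rej <- sum(pvals <= 2 / 24 + 1e-12)
  ci <- qbinom(c(0.0005, 0.9995), 150, 2 / 24)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])

  # star phylogeny: every assignment yields the same length, p = 1
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  tips <- matrix(rnorm(4), 4, 1,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  p_star <- phylo_signal_permutation(star, tips, branch_mode = "unit_lengths")
  expect_equal(p_star$permutation_p, 1)
})
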