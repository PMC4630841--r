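#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that validates the result for use in
#' the squared-change analyses: a rooted topology with unique tip labels and
#' non-negative branch lengths (absent lengths are allowed; use
#' `branch_mode = "unit_lengths"` downstream).
#'
#' @param text Newick string, or `NULL` when `path` is given.
#' @param path Path to a Newick file.
#' @return An [ape] `phylo` object.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  tr <- if (!is.null(text)) {
    tryCatch(ape::read.tree(text = text),
             error = function(e) NULL, warning = function(w) NULL)
  } else ape::read.tree(path)
  if (is.null(tr))
    stop("Newick parse error in: ", substr(text %||% path, 1, 60), call. = FALSE)
  if (length(tr$tip.label) < 2L)
    stop("tree must have at least 2 tips", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("tree tip labels are not unique", call. = FALSE)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  tr
}

#' Packaged example phylogeny of the four bear species
#'
#' Topology `(americanus, (spelaeus, (arctos, maritimus)))` with approximate
#' divergence-time branch lengths (millions of years; synthetic example
#' values, not estimates from any particular study). Use
#' `branch_mode = "unit_lengths"` to ignore the lengths.
#'
#' @return An [ape] `phylo` object with 4 tips.
#' @export
ursus_tree <- function() {
  path <- system.file("extdata", "ursus_divtimes.nwk", package = "morphotraj")
  read_newick(path = path)
}

#' Squared-change parsimony tree length
#'
#' Assigns values to the internal nodes of a rooted tree so as to minimize
#' the total squared change summed over all branches,
#' `sum_b ||child_b - parent_b||^2 / w_b`, where the branch weight `w_b` is
#' the branch length (`"given_lengths"`) or 1 (`"unit_lengths"`), and returns
#' the minimized total together with the minimizing node values. Trait
#' dimensions are independent, so the total is additive across dimensions and
#' invariant under rotation of the multivariate tip data. Zero-length
#' branches under `"given_lengths"` are treated as hard equality constraints
#' (child and parent share a value).
#'
#' @param tree An [ape] `phylo` object.
#' @param tip_values Numeric matrix with one row per tip (rownames must match
#'   the tip labels) or a named vector for a single trait.
#' @param branch_mode `"unit_lengths"` or `"given_lengths"`.
#' @return List with `tree_length` (the minimized total), `node_values`
#'   (matrix over internal nodes, rows named by node number) and
#'   `branch_mode`.
#' @export
squared_change_length <- function(tree, tip_values,
                                  branch_mode = c("unit_lengths",
                                                  "given_lengths")) {
  branch_mode <- match.arg(branch_mode)
  if (is.null(dim(tip_values)))
    tip_values <- matrix(tip_values, ncol = 1L,
                         dimnames = list(names(tip_values), NULL))
  if (is.null(rownames(tip_values)))
    stop("tip_values must be named by tip label", call. = FALSE)
  if (!all(tree$tip.label %in% rownames(tip_values)))
    stop("missing tip values for: ",
         paste(setdiff(tree$tip.label, rownames(tip_values)), collapse = ", "),
         call. = FALSE)
  tip_values <- tip_values[tree$tip.label, , drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  n_all <- n_tip + n_node
  w <- if (branch_mode == "unit_lengths" || is.null(tree$edge.length))
    rep(1, nrow(tree$edge)) else tree$edge.length
  # collapse zero-length branches into shared value groups (union-find)
  group <- seq_len(n_all)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  zero <- w <= 0
  for (e in which(zero)) {
    a <- find(tree$edge[e, 1L]); b <- find(tree$edge[e, 2L])
    if (a != b) group[max(a, b)] <- min(a, b)
  }
  grp <- vapply(seq_len(n_all), find, integer(1))
  ids <- sort(unique(grp))
  gid <- match(grp, ids)             # 1..m contracted node ids
  m <- length(ids)
  is_tip_grp <- logical(m)
  tip_vals_grp <- matrix(0, m, ncol(tip_values))
  for (i in seq_len(n_tip)) {
    g <- gid[i]
    if (is_tip_grp[g] && any(tip_vals_grp[g, ] != tip_values[i, ]))
      stop("zero-length branches force unequal tips to one value",
           call. = FALSE)
    is_tip_grp[g] <- TRUE
    tip_vals_grp[g, ] <- tip_values[i, ]
  }
  free <- which(!is_tip_grp)         # contracted internal nodes to solve for
  # weighted graph Laplacian over contracted nodes, positive edges only
  L <- matrix(0, m, m)
  for (e in which(!zero)) {
    a <- gid[tree$edge[e, 1L]]; b <- gid[tree$edge[e, 2L]]
    iw <- 1 / w[e]
    L[a, a] <- L[a, a] + iw; L[b, b] <- L[b, b] + iw
    L[a, b] <- L[a, b] - iw; L[b, a] <- L[b, a] - iw
  }
  vals <- tip_vals_grp
  if (length(free)) {
    rhs <- -L[free, -free, drop = FALSE] %*%
      tip_vals_grp[-free, , drop = FALSE]
    vals[free, ] <- solve(L[free, free, drop = FALSE], rhs)
  }
  total <- 0
  for (e in which(!zero)) {
    a <- gid[tree$edge[e, 1L]]; b <- gid[tree$edge[e, 2L]]
    total <- total + sum((vals[a, ] - vals[b, ])^2) / w[e]
  }
  node_values <- vals[gid[n_tip + seq_len(n_node)], , drop = FALSE]
  rownames(node_values) <- as.character(n_tip + seq_len(n_node))
  list(tree_length = total, node_values = node_values,
       branch_mode = branch_mode)
}

#' Permutation test of phylogenetic signal
#'
#' Compares the observed squared-change tree length against its distribution
#' under random reassignment of the tip value vectors to the tips (vectors
#' permuted jointly, preserving trait covariance); a short observed length
#' relative to the permutation null indicates that similar values cluster on
#' the tree. For trees with at most `enumerate_below` tips all distinct tip
#' permutations are enumerated, making the test exact (with 4 tips only 24
#' assignments exist); otherwise `n_permutations` random permutations are
#' drawn and the identity assignment is always included, so
#' `p = (count of lengths <= observed + 1) / (n_permutations + 1)` is never 0.
#'
#' @param tree An [ape] `phylo` object with >= 3 tips.
#' @param tip_values Matrix with rownames matching the tip labels, or a named
#'   vector.
#' @param n_permutations Random permutations when not enumerating.
#' @param seed Integer seed for the sampled mode.
#' @param branch_mode `"unit_lengths"` or `"given_lengths"`.
#' @param enumerate_below Enumerate exhaustively when tips <= this (default 8).
#' @return Object of class `phylo_signal_test`: list with
#'   `observed_tree_length`, `permutation_p`, `n_permutations` (number of
#'   assignments actually evaluated), `method` (`"exhaustive"` or
#'   `"sampled"`), `seed`, `branch_mode`, `null_lengths`.
#' @export
phylo_signal_permutation <- function(tree, tip_values,
                                     n_permutations = 9999L, seed = 1L,
                                     branch_mode = c("unit_lengths",
                                                     "given_lengths"),
                                     enumerate_below = 8L) {
  branch_mode <- match.arg(branch_mode)
  if (is.null(dim(tip_values)))
    tip_values <- matrix(tip_values, ncol = 1L,
                         dimnames = list(names(tip_values), NULL))
  tip_values <- tip_values[tree$tip.label, , drop = FALSE]
  n_tip <- nrow(tip_values)
  if (n_tip < 3L) stop("signal test needs at least 3 tips", call. = FALSE)
  scl <- function(vals) {
    rownames(vals) <- tree$tip.label
    squared_change_length(tree, vals, branch_mode)$tree_length
  }
  observed <- scl(tip_values)
  if (n_tip <= enumerate_below) {
    perms <- all_permutations(n_tip)
    lens <- apply(perms, 1L, function(p) scl(tip_values[p, , drop = FALSE]))
    p <- mean(lens <= observed + 1e-12)   # identity permutation included
    method <- "exhaustive"; n_eval <- nrow(perms); seed_used <- NA_integer_
  } else {
    lens <- numeric(n_permutations)
    withr_seed(seed, {
      for (b in seq_len(n_permutations))
        lens[b] <- scl(tip_values[sample.int(n_tip), , drop = FALSE])
    })
    p <- (sum(lens <= observed + 1e-12) + 1) / (n_permutations + 1)
    method <- "sampled"; n_eval <- n_permutations; seed_used <- seed
  }
  structure(
    list(observed_tree_length = observed, permutation_p = p,
         n_permutations = n_eval, method = method, seed = seed_used,
         branch_mode = branch_mode, null_lengths = lens),
    class = "phylo_signal_test")
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(i, rest[sub[j, ]])
    }
  }
  out
}

#' @export
print.phylo_signal_test <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic signal (%s branches): tree length = %.6g, p = %.4g (%s, %d assignments)\n",
    x$branch_mode, x$observed_tree_length, x$permutation_p, x$method,
    x$n_permutations))
  invisible(x)
}
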