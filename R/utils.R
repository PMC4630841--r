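#' @keywords internal
"_PACKAGE"

# Flatten a k x 3 configuration to a length-3k vector (landmark-major:
# x1 y1 z1 x2 y2 z2 ...) and back. All linear analyses operate on this layout.
flatten_config <- function(x) as.vector(t(x))

unflatten_config <- function(v, k = length(v) / 3L) {
  matrix(v, nrow = k, ncol = 3L, byrow = TRUE)
}

# Flatten an k x 3 x n array into an n x 3k matrix of row vectors.
flatten_array <- function(a) {
  n <- dim(a)[3L]
  t(vapply(seq_len(n), function(i) flatten_config(a[, , i]),
           numeric(dim(a)[1L] * 3L)))
}

unflatten_matrix <- function(m, k = ncol(m) / 3L) {
  n <- nrow(m)
  a <- array(0, dim = c(k, 3L, n))
  for (i in seq_len(n)) a[, , i] <- unflatten_config(m[i, ], k)
  a
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic per-stage seed derived from a master seed, kept < 2^31.
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729 + 17) %% 2147483629)
}

# Uniform random 3D rotation matrix (det +1) via QR of a Gaussian matrix.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Rotation from Euler angles (z-y-x convention); used by the grid-search
# oracle in the tests as well as by alignment utilities.
rotation_from_euler <- function(a, b, c) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
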