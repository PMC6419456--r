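# Independent brute-force oracles; these never call the implementation
# paths they are used to check.

# Minimum RMSD of a onto b over an Euler-angle rotation grid plus local
# refinement (translation handled by centering). Reflection searched by
# also flipping a.
grid_rmsd_oracle <- function(a, b, steps = 24) {
  rot_z <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  rot_x <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3)
  euler <- function(p) rot_z(p[1]) %*% rot_x(p[2]) %*% rot_z(p[3])
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  obj <- function(p, A) sqrt(mean(rowSums((A %*% euler(p) - bc)^2)))
  best <- Inf
  for (A in list(ac, ac %*% diag(c(1, 1, -1)))) {  # proper + mirrored
    grid <- as.matrix(expand.grid(
      seq(0, 2 * pi, length.out = steps),
      seq(0, pi, length.out = steps %/% 2),
      seq(0, 2 * pi, length.out = steps)
    ))
    vals <- apply(grid, 1, obj, A = A)
    start <- grid[which.min(vals), ]
    opt <- optim(start, obj, A = A, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, opt$value)
  }
  best
}

# Kabsch on given index pairs only, reused by the TM oracle (plain SVD
# superposition written out here, independent of the package's version).
oracle_superpose <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(crossprod(Ac, Bc))
  R <- sv$u %*% t(sv$v)          # reflection allowed
  list(R = R, d = sqrt(rowSums((Ac %*% R - Bc)^2)))
}

# Exhaustive TM-score: maximum over all order-preserving correspondences
# (pairs of equal-size index subsets, matched in order) of the TM sum
# under the per-correspondence least-RMSD superposition. Enumerates sizes
# from largest down and prunes sizes whose ceiling k/Lmin cannot beat the
# best score found (each term is <= 1, so a size-k correspondence scores
# <= k/Lmin); the pruning is exact.
brute_tm_oracle <- function(a, b, target_bond = 3.8) {
  A <- if (inherits(a, "structure3d")) a$coords else as.matrix(a)
  B <- if (inherits(b, "structure3d")) b$coords else as.matrix(b)
  scale_chain <- function(X) {
    bl <- mean(sqrt(rowSums(diff(X)^2)))
    X * (target_bond / bl)
  }
  A <- scale_chain(A); B <- scale_chain(B)
  La <- nrow(A); Lb <- nrow(B); Lmin <- min(La, Lb)
  d0 <- max(0.5, 1.24 * sign(Lmin - 15) * abs(Lmin - 15)^(1/3) - 1.8)
  best <- 0
  for (k in seq(Lmin, 3)) {
    if (k / Lmin <= best) break
    subs_a <- utils::combn(La, k)
    subs_b <- utils::combn(Lb, k)
    for (ia in seq_len(ncol(subs_a))) {
      Ai <- A[subs_a[, ia], , drop = FALSE]
      for (ib in seq_len(ncol(subs_b))) {
        d <- oracle_superpose(Ai, B[subs_b[, ib], , drop = FALSE])$d
        best <- max(best, sum(1 / (1 + (d / d0)^2)) / Lmin)
      }
    }
  }
  best
}

# Random cluster assignment over given ids (each cluster guaranteed
# non-empty).
random_assignment <- function(ids, k, kind = "structural") {
  labels <- c(seq_len(k), sample.int(k, length(ids) - k, replace = TRUE))
  labels <- sample(labels)
  names(labels) <- ids
  structure(list(labels = labels, k = as.integer(k), kind = kind),
            class = "cluster_assignment")
}

ari <- function(x, y) mclust::adjustedRandIndex(x, y)

# Jittered copy of a structure (per-coordinate gaussian noise).
jitter_structure <- function(s, sd, seed) {
  withr::with_seed(seed, {
    structure3d(s$coords + matrix(rnorm(length(s$coords), sd = sd),
                                  ncol = 3),
                source = s$source)
  })
}
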