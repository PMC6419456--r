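#' Optimal rigid superposition of two bead chains (Kabsch)
#'
#' Least-RMSD rigid transform of `a` onto `b` via the SVD of the
#' cross-covariance of the centered coordinates. With
#' `allow_reflection = TRUE` the optimal orthogonal map is used
#' (determinant may be -1); otherwise it is constrained to a proper
#' rotation.
#'
#' @param a,b n x 3 coordinate matrices (or [structure3d()]), equal n >= 3,
#'   with bead `i` of `a` corresponding to bead `i` of `b`.
#' @param allow_reflection Allow an improper (mirror) transform.
#' @return List with `rotation` (3 x 3, applied as `a %*% rotation`),
#'   `translation` (length 3), `rmsd`, `aligned` (transformed `a`),
#'   `reflected` (logical), and `correspondence` (n x 2 index pairs).
#' @export
kabsch_superpose <- function(a, b, allow_reflection = FALSE) {
  A <- if (inherits(a, "structure3d")) a$coords else as.matrix(a)
  B <- if (inherits(b, "structure3d")) b$coords else as.matrix(b)
  if (nrow(A) != nrow(B)) tf_stop("tf_argument_error", "bead counts differ")
  if (nrow(A) < 3) tf_stop("tf_argument_error", "need >= 3 beads")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  }
  aligned_c <- Ac %*% R
  rmsd <- sqrt(mean(rowSums((aligned_c - Bc)^2)))
  translation <- cb - as.vector(ca %*% R)
  list(rotation = R, translation = translation, rmsd = rmsd,
       aligned = sweep(A %*% R, 2, translation, `+`),
       reflected = det(R) < 0,
       correspondence = cbind(seq_len(nrow(A)), seq_len(nrow(B))))
}

# Best monotone (order-preserving) pairing of two chains given a
# cross-score matrix: Needleman-Wunsch with free gaps, maximizing the sum
# of matched scores. Returns an m x 2 index matrix, strictly increasing in
# both columns.
monotone_align <- function(S) {
  n <- nrow(S); m <- ncol(S)
  F <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      F[i + 1, j + 1] <- max(F[i, j] + S[i, j], F[i, j + 1], F[i + 1, j])
    }
  }
  pairs <- matrix(0L, 0, 2)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    if (abs(F[i + 1, j + 1] - (F[i, j] + S[i, j])) < 1e-12) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (F[i + 1, j + 1] == F[i, j + 1]) i <- i - 1
    else j <- j - 1
  }
  pairs
}

tm_d0 <- function(L) max(0.5, 1.24 * cbrt(L - 15) - 1.8)

# Rescale a chain so its mean consecutive-bead distance is `target`
# (protein CA-CA convention), making the protein-calibrated d0 commensurate
# with arbitrary-unit chromatin beads.
normalize_bond_length <- function(X, target = 3.8) {
  bl <- mean(sqrt(rowSums(diff(X)^2)))
  if (bl > 0) X * (target / bl) else X
}

tm_pair_scores <- function(dists, d0) 1 / (1 + (dists / d0)^2)

#' TM-score between two reconstructed TAD structures
#'
#' Length-normalized structural similarity in (0, 1]:
#' `max (1 / L_min) * sum_i 1 / (1 + (d_i / d0(L_min))^2)` over
#' sequence-order-preserving bead correspondences and rigid superpositions
#' (reflection allowed, no scaling), where `L_min` is the smaller bead
#' count and `d_i` the distance of matched pair `i` after superposition.
#' `d0(L) = max(0.5, 1.24 (L - 15)^(1/3) - 1.8)`, applied to bead counts
#' after both chains are rescaled to mean consecutive-bead distance 3.8.
#'
#' The search seeds superpositions from corresponding fragments, then
#' alternates rigid superposition on the matched set with dynamic-
#' programming correspondence refinement until the matched set is stable,
#' followed by superposition polishing on the close-pair subset.
#'
#' @param a,b [structure3d()] objects (or coordinate matrices), each with
#'   >= 5 beads.
#' @return TM-score in (0, 1], normalized by the smaller structure.
#' @export
tm_score <- function(a, b) {
  A <- if (inherits(a, "structure3d")) a$coords else as.matrix(a)
  B <- if (inherits(b, "structure3d")) b$coords else as.matrix(b)
  if (nrow(A) < 5 || nrow(B) < 5) tf_stop("tf_argument_error", "need >= 5 beads")
  swapped <- nrow(A) > nrow(B)
  X <- if (swapped) B else A   # shorter chain
  Y <- if (swapped) A else B
  X <- normalize_bond_length(X)
  Y <- normalize_bond_length(Y)
  Lx <- nrow(X); Ly <- nrow(Y)
  d0 <- tm_d0(Lx)

  cross_dists <- function(Xt) {
    # |Xt_i - Y_j| for all i, j
    d2 <- outer(rowSums(Xt^2), rowSums(Y^2), `+`) - 2 * Xt %*% t(Y)
    d2[d2 < 0] <- 0
    sqrt(d2)
  }
  best <- 0
  # Evaluate one rigid transform: superpose the matched subset, score the
  # best monotone matching of the whole chains under that transform. The
  # running maximum over every transform visited is the returned score.
  eval_transform <- function(pairs) {
    fit <- kabsch_superpose(X[pairs[, 1], , drop = FALSE],
                            Y[pairs[, 2], , drop = FALSE],
                            allow_reflection = TRUE)
    Xt <- sweep(X %*% fit$rotation, 2, fit$translation, `+`)
    S <- tm_pair_scores(cross_dists(Xt), d0)
    new_pairs <- monotone_align(S)
    tm <- sum(S[new_pairs]) / Lx
    if (tm > best) best <<- tm
    list(pairs = new_pairs, S = S)
  }

  frag <- max(5L, Lx %/% 2L)
  stride <- max(1L, Lx %/% 10L)
  starts <- unique(c(seq(1L, Lx - frag + 1L, by = stride), Lx - frag + 1L))
  offsets <- if (Ly > Lx) unique(round(seq(0, Ly - Lx, length.out = 3))) else 0L
  seeds <- list(cbind(seq_len(Lx), seq_len(Lx)))  # full diagonal
  for (s in starts) {
    for (o in offsets) {
      idx <- s:(s + frag - 1L)
      seeds[[length(seeds) + 1L]] <- cbind(idx, idx + o)
    }
  }

  for (seed_pairs in seeds) {
    pairs <- seed_pairs
    for (it in 1:20) {
      st <- eval_transform(pairs)
      if (nrow(st$pairs) == nrow(pairs) && all(st$pairs == pairs)) break
      pairs <- st$pairs
    }
    # polish: seed further transforms from the close-pair subsets of the
    # converged matching (distance cutoffs sweeping below d0 catch optima
    # whose superposition is carried by a tight core of pairs)
    S <- st$S
    d <- sqrt(pmax(0, 1 / S[pairs] - 1)) * d0
    for (cut in c(2.5, 1.5, 1, 0.6) * d0) {
      close <- which(d < cut)
      if (length(close) >= 3 && length(close) < nrow(pairs)) {
        eval_transform(pairs[close, , drop = FALSE])
      }
    }
  }
  min(best, 1)
}

#' Pairwise TM-score matrix over a set of structures
#'
#' @param structs Named list of [structure3d()] (names are TAD ids; ids
#'   fall back to `origin$id` or positional names).
#' @return A [similarity_matrix()] of kind `"structural"`: symmetric,
#'   unit diagonal, one TM-score evaluation per unordered pair.
#' @export
structural_similarity_matrix <- function(structs) {
  m <- length(structs)
  if (m < 2) tf_stop("tf_argument_error", "need >= 2 structures")
  ids <- names(structs)
  if (is.null(ids)) {
    ids <- vapply(seq_len(m), function(i) {
      o <- structs[[i]]$origin
      if (!is.null(o)) o$id else paste0("tad", i)
    }, "")
  }
  for (i in seq_len(m)) {
    if (n_beads(structs[[i]]) < 5) {
      tf_stop("tf_argument_error", "structure '%s' has fewer than 5 beads", ids[i])
    }
  }
  values <- diag(m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      values[i, j] <- values[j, i] <- tm_score(structs[[i]], structs[[j]])
    }
  }
  similarity_matrix(values, kind = "structural", tad_ids = ids)
}
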