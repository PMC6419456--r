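#' Rescale the contacts of a TAD to a fixed range
#'
#' Hi-C contact scales vary widely between experiments and the cube-root
#' contact-to-distance conversion is sensitive to that scale, so the
#' observed off-diagonal contacts of each TAD are first mapped linearly
#' onto `[lo, hi]` (default `[1, 30]`), ignoring missing entries. The
#' diagonal is masked here: self-distance is 0 by definition and never
#' derived from a contact value.
#'
#' @param m A [contact_matrix()].
#' @param lo,hi Target range, `lo < hi`; the default lower bound of 1
#'   guarantees positive contacts, as the wish-distance formula requires.
#' @return A rescaled [contact_matrix()] with observed off-diagonal range
#'   exactly `[lo, hi]`.
#' @export
rescale_contacts <- function(m, lo = 1, hi = 30) {
  stopifnot(inherits(m, "contact_matrix"), lo < hi)
  n <- n_bins(m)
  mask <- m$mask | (diag(n) == 1)
  obs <- m$values[!mask]
  if (length(obs) == 0) tf_stop("tf_empty_input_error", "all entries missing")
  if (length(obs) < 2) tf_stop("tf_empty_input_error", "need >= 2 observed off-diagonal entries")
  rng <- range(obs)
  if (rng[2] - rng[1] <= 0) {
    tf_stop("tf_degenerate_input_error",
            "constant contact matrix carries no distance information")
  }
  values <- m$values
  values[!mask] <- lo + (values[!mask] - rng[1]) * (hi - lo) / (rng[2] - rng[1])
  values[mask] <- NA_real_
  contact_matrix(values, bin_size = m$bin_size, origin = m$origin, mask = mask)
}

#' Convert contacts to wish distances
#'
#' Applies `d = (1/c)^(1/3)` elementwise to observed entries: more
#' contacts mean a shorter target spatial distance. Missing entries stay
#' missing; the diagonal is 0.
#'
#' @param m A [contact_matrix()], typically after [rescale_contacts()] so
#'   all observed off-diagonal contacts are >= 1.
#' @return A `wish_distance` object: list with `values` (n x n, diagonal
#'   0), and `mask`.
#' @export
contacts_to_wish_distances <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- n_bins(m)
  mask <- m$mask | (diag(n) == 1)
  obs <- m$values[!mask]
  if (any(obs <= 0)) {
    tf_stop("tf_domain_error", "wish distance requires contacts > 0; rescale first")
  }
  values <- matrix(NA_real_, n, n)
  values[!mask] <- (1 / m$values[!mask])^(1 / 3)
  diag(values) <- 0
  mask <- mask & !(diag(n) == 1)
  structure(list(values = values, mask = mask), class = "wish_distance")
}

# Connectivity of the observation graph (beads joined where a distance is
# observed); plain BFS over the weight pattern.
observation_connected <- function(W) {
  n <- nrow(W)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(W[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Embed wish distances in 3D by metric MDS (stress majorization)
#'
#' Weighted SMACOF: minimizes the stress
#' `sum_ij w_ij (d_ij - |x_i - x_j|)^2` by iterated Guttman transforms,
#' with zero weight on missing pairs. The first start is the classical-MDS
#' (Torgerson) configuration (missing entries imputed with the largest
#' observed distance); any further starts are seeded random configurations
#' and the restart with lowest final stress wins.
#'
#' Frustrated distance sets (not embeddable in 3D) have several
#' near-equal stress minima, so embeddings compared downstream should be
#' produced with one shared seed: the result is then a pure function of
#' (distances, seed) and identical matrices always yield identical
#' structures, while the seeded restarts still escape poor local minima
#' on noisy input.
#'
#' @param w A `wish_distance` from [contacts_to_wish_distances()], or any
#'   symmetric distance matrix.
#' @param seed Integer seed; results are a pure function of inputs + seed.
#' @param n_init Number of restarts (first start is always the
#'   deterministic Torgerson configuration).
#' @param max_iter Majorization iterations per restart.
#' @param tol Relative stress-decrease convergence threshold.
#' @param origin Optional interval carried onto the structure.
#' @return A [structure3d()] with `source = "mds"` and attribute `stress`.
#' @export
embed_mds <- function(w, seed = 1L, n_init = 4L, max_iter = 300L,
                      tol = 1e-9, origin = NULL) {
  if (inherits(w, "wish_distance")) {
    d <- w$values; mask <- w$mask
  } else {
    d <- as.matrix(w); mask <- is.na(d)
  }
  n <- nrow(d)
  if (n < 3) tf_stop("tf_argument_error", "need >= 3 beads")
  W <- matrix(1, n, n)
  W[mask] <- 0
  diag(W) <- 0
  if (!observation_connected(W)) {
    tf_stop("tf_connectivity_error",
            "observation graph is disconnected; beads cannot be placed relative to each other")
  }
  d0 <- d
  d0[mask] <- max(d[!mask & row(d) != col(d)])
  diag(d0) <- 0
  V <- diag(rowSums(W)) - W
  Vinv <- MASS::ginv(V)

  run_smacof <- function(X) {
    s_prev <- Inf
    for (it in seq_len(max_iter)) {
      D <- as.matrix(dist(X))
      s <- sum(W * (d0 * (W > 0) - D * (W > 0))^2) / 2
      if (is.finite(s_prev) && (s_prev - s) < tol * max(s_prev, 1e-300)) break
      s_prev <- s
      ratio <- matrix(0, n, n)
      pos <- D > 0 & W > 0
      ratio[pos] <- d0[pos] / D[pos]
      B <- -W * ratio
      diag(B) <- -rowSums(B)
      X <- Vinv %*% (B %*% X)
    }
    list(X = X, stress = s_prev)
  }

  best <- withr::with_seed(seed, {
    inits <- vector("list", n_init)
    inits[[1]] <- suppressWarnings(cmdscale(d0, k = 3))
    if (ncol(inits[[1]]) < 3) {  # degenerate spectra (e.g. collinear beads)
      inits[[1]] <- cbind(inits[[1]],
                          matrix(rnorm(n * (3 - ncol(inits[[1]])), sd = 1e-4),
                                 n))
    }
    if (n_init > 1) {
      for (k in 2:n_init) inits[[k]] <- matrix(rnorm(n * 3), n, 3)
    }
    fits <- lapply(inits, run_smacof)
    fits[[which.min(vapply(fits, `[[`, 0, "stress"))]]
  })
  s3d <- structure3d(best$X, source = "mds", origin = origin)
  attr(s3d, "stress") <- best$stress
  s3d
}

#' Radius of gyration of a structure
#'
#' Root-mean-square distance of beads from their centroid; the standard
#' compactness measure for reconstructed chromatin.
#'
#' @param s A [structure3d()] (or bare n x 3 coordinate matrix), n >= 2.
#' @return Non-negative scalar in coordinate units.
#' @export
radius_of_gyration <- function(s) {
  coords <- if (inherits(s, "structure3d")) s$coords else as.matrix(s)
  if (nrow(coords) < 2) tf_stop("tf_argument_error", "need >= 2 beads")
  centered <- sweep(coords, 2, colMeans(coords))
  sqrt(mean(rowSums(centered^2)))
}

#' Contact-decay exponent of a contact matrix
#'
#' The mean observed contact `P(s)` is computed at every genomic bin
#' separation `s = 1 .. n-1` with data; the returned exponent is the
#' unweighted least-squares slope of `log P(s)` versus `log s` over
#' separations with `P(s) > 0`. More negative means steeper contact decay
#' with genomic distance.
#'
#' @param m A [contact_matrix()] with n >= 5.
#' @return The fitted slope (dimensionless).
#' @export
exponent_parameter <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- n_bins(m)
  if (n < 5) tf_stop("tf_argument_error", "need >= 5 bins")
  sep <- abs(row(m$values) - col(m$values))
  ok <- !m$mask & sep > 0
  P <- vapply(seq_len(n - 1), function(s) {
    v <- m$values[ok & sep == s]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  s_grid <- seq_len(n - 1)
  use <- !is.na(P) & P > 0
  if (sum(use) < 3) {
    tf_stop("tf_insufficient_data_error",
            "fewer than 3 usable genomic distances")
  }
  unname(coef(lm(log(P[use]) ~ log(s_grid[use])))[2])
}

#' Consistency between 2D decay and 3D compactness
#'
#' Correlates fitted contact-decay exponents with radii of gyration across
#' a set of TADs. A good reconstruction shows a negative association:
#' steeper decay (fewer long-range contacts) should produce more extended
#' structures.
#'
#' @param exponents Numeric vector of per-TAD decay exponents.
#' @param rgs Numeric vector of per-TAD radii of gyration (same order).
#' @return List with `pearson` and `spearman` correlation coefficients.
#' @export
evaluate_consistency <- function(exponents, rgs) {
  stopifnot(length(exponents) == length(rgs))
  if (length(exponents) < 3) tf_stop("tf_argument_error", "need >= 3 TADs")
  if (sd(exponents) == 0 || sd(rgs) == 0) {
    tf_stop("tf_undefined_correlation_error", "zero variance in a statistic")
  }
  list(pearson = cor(exponents, rgs, method = "pearson"),
       spearman = cor(exponents, rgs, method = "spearman"))
}

# Content fingerprint of a contact matrix, folded into the embedding seed
# so that reconstruction is a pure function of (matrix, seed): identical
# matrices always embed identically, while distinct matrices draw
# decoupled restart streams.
matrix_fingerprint <- function(m) {
  v <- m$values[!m$mask]
  sprintf("%.10e|%.10e|%d", sum(v), sum(v * seq_along(v)), length(v))
}

#' Reconstruct one TAD end to end
#'
#' Convenience wrapper: rescale contacts, convert to wish distances, embed
#' with MDS, and attach statistics. The embedding seed is derived from
#' `seed` and a content fingerprint of the matrix, so with one shared
#' `seed` across a cohort, identical contact matrices always yield
#' identical structures (required for TM-scores to compare them) while
#' different matrices use independent restarts.
#'
#' @param m A [contact_matrix()].
#' @param seed Base seed for the embedding.
#' @param lo,hi Rescale range.
#' @param ... Passed to [embed_mds()].
#' @return A [structure3d()] with attributes `exponent` and `rg`.
#' @export
reconstruct_tad <- function(m, seed = 1L, lo = 1, hi = 30, ...) {
  w <- contacts_to_wish_distances(rescale_contacts(m, lo, hi))
  s <- embed_mds(w, seed = derive_seed(seed, matrix_fingerprint(m)),
                 origin = m$origin, ...)
  attr(s, "exponent") <- exponent_parameter(m)
  attr(s, "rg") <- radius_of_gyration(s)
  s
}
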