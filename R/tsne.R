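# Minimal t-SNE on a precomputed distance matrix, 3 output components.
# Standard formulation: per-point Gaussian bandwidths found by binary search
# to match the target perplexity, symmetrized input affinities, Student-t
# output kernel, gradient descent with momentum and early exaggeration.
tsne_embed <- function(d, perplexity, learning_rate, seed,
                       n_iter = 500L, momentum = c(0.5, 0.8),
                       exaggeration = 4, exaggeration_iter = 100L) {
  n <- nrow(d)
  if (perplexity >= n) tf_stop("tf_argument_error", "perplexity must be < n")
  if (perplexity < 2) tf_stop("tf_argument_error", "perplexity must be >= 2")
  d2 <- d^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (tries in 1:50) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP <= 0) { H <- 0; p[] <- 0 } else {
        H <- log(sumP) + beta * sum(di * p) / sumP
        p <- p / sumP
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withr::with_seed(seed, {
    Y <- matrix(rnorm(n * 3, sd = 1e-4), n, 3)
    gain <- matrix(1, n, 3)
    inc <- matrix(0, n, 3)
    for (it in seq_len(n_iter)) {
      Pit <- if (it <= exaggeration_iter) P * exaggeration else P
      num <- 1 / (1 + as.matrix(dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pit - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (it <= exaggeration_iter) momentum[1] else momentum[2]
      gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
      gain <- pmax(gain, 0.01)
      inc <- mom * inc - learning_rate * gain * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' t-SNE reconstruction with RMSD-based selection against a reference
#'
#' t-SNE embeddings of wish distances are highly sensitive to perplexity
#' and learning rate, so one candidate structure is produced per grid
#' configuration, each is rigidly superposed onto the reference structure
#' (rotation + translation, reflection allowed, no scaling), and the
#' candidate with minimum RMSD is selected.
#'
#' @param w A `wish_distance` (or symmetric distance matrix); missing
#'   entries are imputed with the largest observed distance.
#' @param reference A [structure3d()] with the same bead count (typically
#'   the MDS embedding).
#' @param perplexities,learning_rates Numeric grids; defaults
#'   `{5, 10, 30, 50}` intersected with `[2, n - 1]` and
#'   `{10, 100, 200, 1000}`.
#' @param seed Integer seed.
#' @return List with `structure` (a [structure3d()], `source = "tsne"`)
#'   and `report` (data frame: perplexity, learning_rate, rmsd).
#' @export
embed_tsne_selected <- function(w, reference,
                                perplexities = c(5, 10, 30, 50),
                                learning_rates = c(10, 100, 200, 1000),
                                seed = 1L) {
  if (inherits(w, "wish_distance")) {
    d <- w$values
    d[w$mask] <- NA
  } else d <- as.matrix(w)
  n <- nrow(d)
  offdiag <- d[row(d) != col(d)]
  d[is.na(d)] <- max(offdiag, na.rm = TRUE)
  diag(d) <- 0
  if (!inherits(reference, "structure3d") || n_beads(reference) != n) {
    tf_stop("tf_argument_error", "reference must be a structure3d with %d beads", n)
  }
  perplexities <- perplexities[perplexities >= 2 & perplexities <= n - 1]
  if (!length(perplexities) || !length(learning_rates)) {
    tf_stop("tf_argument_error", "empty t-SNE parameter grid")
  }
  grid <- expand.grid(perplexity = perplexities, learning_rate = learning_rates)
  rmsds <- numeric(nrow(grid))
  candidates <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    Y <- tsne_embed(d, grid$perplexity[g], grid$learning_rate[g],
                    seed = derive_seed(seed, paste0("tsne", g)))
    fit <- kabsch_superpose(Y, reference$coords, allow_reflection = TRUE)
    candidates[[g]] <- fit$aligned
    rmsds[g] <- fit$rmsd
  }
  grid$rmsd <- rmsds
  best <- which.min(rmsds)
  s <- structure3d(candidates[[best]], source = "tsne",
                   origin = reference$origin)
  list(structure = s, report = grid)
}
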