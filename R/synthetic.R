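#' Specification of a synthetic TAD cohort
#'
#' Describes a cohort with planted ground truth: each TAD carries one
#' structural class (a contact-decay exponent alpha) and one chromatin-state
#' class (a per-state probability profile), assigned round-robin so that
#' small cohorts stay balanced.
#'
#' @param n_tads Number of TADs (>= 1).
#' @param bins_range Length-2 integer vector `(min, max)` bins per TAD;
#'   `min >= 5`.
#' @param struct_classes Numeric vector of decay exponents alpha (<= 0),
#'   one per structural class.
#' @param state_classes List of state-profile probability vectors, one per
#'   chromatin-state class; each of length `length(state_labels)` and
#'   summing to 1.
#' @param noise_sd Standard deviation of the multiplicative log-normal
#'   contact noise (sd of the log-multiplier).
#' @param seed Integer seed; every generated cohort is a pure function of
#'   this spec.
#' @param bin_size Base pairs per Hi-C bin (default 40 kb, the resolution
#'   at which TAD structures are typically reconstructed).
#' @param resolution Segmentation tile size in bp (default 200, the
#'   ChromHMM convention).
#' @param scale Contact scale factor (expected contact at distance 1).
#' @param state_labels State universe (default [roadmap25_labels()]).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_tads, bins_range = c(10L, 25L),
                        struct_classes = c(-0.5, -1.0, -1.5),
                        state_classes = NULL,
                        noise_sd = 0.1, seed = 1L,
                        bin_size = 40000L, resolution = 200L, scale = 1,
                        state_labels = roadmap25_labels()) {
  S <- length(state_labels)
  if (is.null(state_classes)) {
    # Three default classes on disjoint state blocks: promoter/TSS-heavy
    # (1-8), transcription/enhancer (9-17), heterochromatin/quiescent
    # (18-25). At least three classes are required for the functional
    # side to be recoverable: with exactly two classes the per-TAD
    # enrichment deviations from the genome mixture are exact mirror
    # images of each other, so the absolute-correlation similarity is ~1
    # for every pair of TADs and carries no class signal.
    mk <- function(idx) {
      p <- rep(0.15 / (S - length(idx)), S)
      p[idx] <- 0.85 / length(idx)
      p
    }
    state_classes <- list(mk(1:8), mk(9:17), mk(18:25))
  }
  stopifnot(n_tads >= 1, length(bins_range) == 2, bins_range[1] >= 5,
            bins_range[1] <= bins_range[2], noise_sd >= 0)
  if (any(struct_classes > 0)) {
    tf_stop("tf_domain_error", "decay exponents must be <= 0")
  }
  for (p in state_classes) {
    if (length(p) != S) {
      tf_stop("tf_argument_error", "state profile length %d != %d states",
              length(p), S)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      tf_stop("tf_domain_error", "state profile does not sum to 1")
    }
  }
  structure(
    list(n_tads = as.integer(n_tads), bins_range = as.integer(bins_range),
         struct_classes = struct_classes, state_classes = state_classes,
         noise_sd = noise_sd, seed = as.integer(seed),
         bin_size = as.integer(bin_size), resolution = as.integer(resolution),
         scale = scale, state_labels = state_labels),
    class = "cohort_spec"
  )
}

#' Generate a synthetic Hi-C contact matrix with power-law decay
#'
#' Off-diagonal entry `(i, j)` has expectation `scale * |i - j|^alpha`;
#' multiplicative log-normal noise (sd of the log equals `noise_sd`, mean
#' corrected so the expectation is exact) is applied symmetrically. The
#' diagonal is masked: distance-0 contacts are never generated.
#'
#' @param n_bins Number of bins (>= 5).
#' @param alpha Decay exponent (<= 0).
#' @param scale Expected contact at bin distance 1 (> 0).
#' @param noise_sd Log-normal noise sd; 0 gives the exact power law.
#' @param seed Integer seed; the matrix is a pure function of its arguments.
#' @param bin_size,origin Passed to [contact_matrix()].
#' @return A [contact_matrix()].
#' @examples
#' m <- gen_contact_matrix(10, alpha = -1, seed = 1)
#' m$values[1, 3]  # 2^-1 = 0.5 under the exact power law (noise_sd = 0)
#' @export
gen_contact_matrix <- function(n_bins, alpha, scale = 1, noise_sd = 0,
                               seed = 1L, bin_size = 1L, origin = NULL) {
  if (n_bins < 5) tf_stop("tf_argument_error", "n_bins must be >= 5")
  if (alpha > 0) tf_stop("tf_domain_error", "alpha must be <= 0")
  if (scale <= 0) tf_stop("tf_argument_error", "scale must be > 0")
  sep <- abs(row(diag(n_bins)) - col(diag(n_bins)))
  sep[sep == 0] <- 1L  # diagonal is masked below; floor |i-j| at 1
  values <- scale * sep^alpha
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, {
      z <- matrix(rnorm(n_bins^2, mean = -noise_sd^2 / 2, sd = noise_sd),
                  n_bins, n_bins)
      z[lower.tri(z)] <- t(z)[lower.tri(z)]
      exp(z)
    })
    values <- values * noise
  }
  mask <- diag(n_bins) == 1
  values[mask] <- NA_real_
  contact_matrix(values, bin_size = bin_size, origin = origin, mask = mask)
}

#' Generate oracle 3D geometries
#'
#' Deterministic reference shapes for embedding and superposition tests:
#' a unit-radius helix with pitch 0.5 (rise per turn, 10 beads per turn),
#' a collinear segment with unit bead spacing, or a unit-step random walk.
#'
#' @param kind `"helix"`, `"segment"`, or `"random_walk"`.
#' @param n_beads Number of beads (>= 3).
#' @param seed Seed (used by `random_walk` only).
#' @return A [structure3d()].
#' @export
gen_structure <- function(kind = c("helix", "segment", "random_walk"),
                          n_beads, seed = 1L) {
  kind <- match.arg(kind)
  if (n_beads < 3) tf_stop("tf_domain_error", "n_beads must be >= 3")
  i <- seq_len(n_beads) - 1
  coords <- switch(kind,
    helix = {
      theta <- 2 * pi * i / 10
      cbind(cos(theta), sin(theta), 0.5 * i / 10)
    },
    segment = cbind(i * 1.0, 0 * i, 0 * i),
    random_walk = withr::with_seed(seed, {
      steps <- matrix(rnorm(3 * (n_beads - 1)), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2))
      rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    })
  )
  structure3d(coords, source = kind)
}

#' Generate a chromatin-state segmentation with planted profiles
#'
#' Tiles `[0, chrom_length)` at the given resolution; the state of each
#' tile is drawn from the profile of the region containing its midpoint,
#' or from the background profile elsewhere.
#'
#' @param chrom_length Chromosome length in bp.
#' @param state_labels Legal state labels.
#' @param region_profiles List of `list(interval =, profile =)` pairs; each
#'   profile is a probability vector over states.
#' @param background Background probability profile.
#' @param resolution Tile size in bp.
#' @param seed Integer seed.
#' @param chrom Chromosome name for the records.
#' @return A [segmentation()].
#' @export
gen_segmentation <- function(chrom_length, state_labels, region_profiles = list(),
                             background, resolution = 200L, seed = 1L,
                             chrom = "chr1") {
  S <- length(state_labels)
  check_profile <- function(p) {
    if (length(p) != S || abs(sum(p) - 1) > 1e-9) {
      tf_stop("tf_domain_error", "profile must be a length-%d vector summing to 1", S)
    }
  }
  check_profile(background)
  for (rp in region_profiles) check_profile(rp$profile)
  starts <- seq(0, chrom_length - 1, by = resolution)
  ends <- pmin(starts + resolution, chrom_length)
  mid <- (starts + ends) / 2
  prof_idx <- rep(0L, length(starts))  # 0 = background
  for (k in seq_along(region_profiles)) {
    iv <- region_profiles[[k]]$interval
    inside <- iv$chrom == chrom & mid >= iv$start & mid < iv$end
    prof_idx[inside] <- k
  }
  states <- withr::with_seed(seed, {
    vapply(prof_idx, function(k) {
      p <- if (k == 0L) background else region_profiles[[k]]$profile
      sample.int(S, 1, prob = p)
    }, integer(1))
  })
  segmentation(
    data.frame(chrom = chrom, start = starts, end = ends,
               state = state_labels[states], stringsAsFactors = FALSE),
    state_labels
  )
}

#' Generate a full synthetic cohort with planted classes
#'
#' Lays `n_tads` TADs end to end on one chromosome. TAD `i` receives
#' structural class `((i - 1) mod n_struct) + 1` and chromatin-state class
#' `((i - 1) mod n_state) + 1` (round-robin); when the class counts are
#' coprime the cohort cycles through every (structural, state) pair.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `matrices` (named list of
#'   [contact_matrix()]), `tads` (interval data frame), `segmentation`,
#'   `true_struct` and `true_state` (named integer class labels),
#'   `chrom_matrix` (the TAD matrices placed into one chromosome-wide
#'   contact matrix, background masked), and `spec`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_tads
  ns <- length(spec$struct_classes)
  nf <- length(spec$state_classes)
  true_struct <- ((seq_len(n) - 1L) %% ns) + 1L
  true_state <- ((seq_len(n) - 1L) %% nf) + 1L
  bins <- withr::with_seed(spec$seed, {
    if (spec$bins_range[1] == spec$bins_range[2]) rep(spec$bins_range[1], n)
    else sample(seq(spec$bins_range[1], spec$bins_range[2]), n, replace = TRUE)
  })
  ends <- cumsum(bins) * spec$bin_size
  starts <- c(0, head(ends, -1))
  ids <- sprintf("TAD%03d", seq_len(n))
  tads <- data.frame(chrom = "chr1", start = starts, end = ends, id = ids,
                     strand = ".", stringsAsFactors = FALSE)
  matrices <- lapply(seq_len(n), function(i) {
    gen_contact_matrix(
      bins[i], alpha = spec$struct_classes[true_struct[i]],
      scale = spec$scale, noise_sd = spec$noise_sd,
      seed = derive_seed(spec$seed, paste0("matrix", i)),
      bin_size = spec$bin_size,
      origin = genomic_interval("chr1", starts[i], ends[i], ids[i])
    )
  })
  names(matrices) <- ids
  chrom_length <- ends[n]
  S <- length(spec$state_labels)
  region_profiles <- lapply(seq_len(n), function(i) {
    list(interval = tads[i, ], profile = spec$state_classes[[true_state[i]]])
  })
  seg <- gen_segmentation(
    chrom_length, spec$state_labels, region_profiles,
    background = rep(1 / S, S), resolution = spec$resolution,
    seed = derive_seed(spec$seed, "segmentation")
  )
  # chromosome-wide matrix: per-TAD blocks on the diagonal, inter-TAD masked
  total_bins <- sum(bins)
  chrom_values <- matrix(NA_real_, total_bins, total_bins)
  off <- 0L
  for (i in seq_len(n)) {
    idx <- off + seq_len(bins[i])
    chrom_values[idx, idx] <- matrices[[i]]$values
    off <- off + bins[i]
  }
  chrom_matrix <- contact_matrix(
    chrom_values, bin_size = spec$bin_size,
    origin = genomic_interval("chr1", 0, chrom_length, "chr1")
  )
  names(true_struct) <- ids
  names(true_state) <- ids
  list(matrices = matrices, tads = tads, segmentation = seg,
       true_struct = true_struct, true_state = true_state,
       chrom_matrix = chrom_matrix, spec = spec)
}
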