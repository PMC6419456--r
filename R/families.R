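#' Spectral clustering of a TAD similarity matrix
#'
#' Normalized-Laplacian spectral embedding (Ng-Jordan-Weiss): the affinity
#' matrix is the similarity matrix itself, rows of the top-k eigenvector
#' matrix of `D^-1/2 A D^-1/2` are unit-normalized and partitioned with
#' seeded k-means. Cluster indices are relabeled by decreasing cluster
#' size (largest = 1, ties by first occurrence) so labels are reproducible
#' across runs.
#'
#' @param sim A [similarity_matrix()].
#' @param k Number of clusters, `2 <= k <= m`.
#' @param seed Integer seed for k-means.
#' @return A `cluster_assignment`: list with `labels` (named integer
#'   vector, values in `1..k`), `k`, `kind`.
#' @export
spectral_cluster <- function(sim, k, seed = 1L) {
  if (!inherits(sim, "similarity_matrix")) {
    sim <- similarity_matrix(sim, kind = "structural")
  }
  A <- unclass(sim)
  m <- nrow(A)
  if (k < 2) tf_stop("tf_argument_error", "k must be >= 2")
  if (k > m) tf_stop("tf_argument_error", "k = %d exceeds %d TADs", k, m)
  deg <- rowSums(A)
  if (any(deg <= 0)) tf_stop("tf_domain_error", "isolated TAD with zero affinity")
  Dm <- 1 / sqrt(deg)
  L <- A * outer(Dm, Dm)
  eig <- eigen(L, symmetric = TRUE)
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  U <- U / pmax(norms, 1e-12)
  km <- withr::with_seed(seed, kmeans(U, centers = k, nstart = 20, iter.max = 100))
  raw <- km$cluster
  # relabel by decreasing size; ties broken by first appearance
  sizes <- table(raw)
  order_idx <- order(-as.integer(sizes), match(names(sizes), unique(as.character(raw))))
  relabel <- setNames(seq_len(k), names(sizes)[order_idx])
  labels <- unname(relabel[as.character(raw)])
  names(labels) <- rownames(A)
  structure(list(labels = labels, k = as.integer(k), kind = attr(sim, "kind")),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("%s clustering of %d TADs into %d clusters (sizes: %s)\n",
              x$kind, length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

cluster_sizes <- function(a) tabulate(a$labels, a$k)

check_same_ids <- function(a, b) {
  diff <- c(setdiff(names(a$labels), names(b$labels)),
            setdiff(names(b$labels), names(a$labels)))
  if (length(diff)) {
    tf_stop("tf_argument_error", "TAD id sets differ: %s",
            paste(diff, collapse = ", "))
  }
}

#' Contingency counts between two clusterings
#'
#' Entry `(i, j)` is the number of TADs in cluster `i` of `b` and cluster
#' `j` of `a` (by convention `b` = chromatin-state clustering on rows,
#' `a` = structural clustering on columns). Row sums are `b` cluster
#' sizes, column sums `a` cluster sizes, the total is the TAD count.
#'
#' @param a,b `cluster_assignment` objects over the same TAD ids.
#' @return Integer matrix, `b$k` rows x `a$k` columns.
#' @export
overlap_counts <- function(a, b) {
  check_same_ids(a, b)
  ids <- names(a$labels)
  counts <- table(factor(b$labels[ids], levels = seq_len(b$k)),
                  factor(a$labels[ids], levels = seq_len(a$k)))
  m <- matrix(as.integer(counts), b$k, a$k)
  dimnames(m) <- list(paste0(substr(b$kind, 1, 4), seq_len(b$k)),
                      paste0(substr(a$kind, 1, 4), seq_len(a$k)))
  m
}

#' Normalized overlapping-TAD enrichment
#'
#' Each overlap count is divided by both cluster sizes and multiplied by
#' `scale` (default 1000 for readable display), making the value
#' insensitive to cluster size. Computation keeps full precision; use
#' `round(x, 1)` for the 1-decimal display convention.
#'
#' @param counts Integer matrix from [overlap_counts()] (rows = `b`,
#'   columns = `a`), or a single count.
#' @param sizes_a Column-cluster sizes (structural).
#' @param sizes_b Row-cluster sizes (chromatin-state).
#' @param scale Display scale factor.
#' @return Numeric matrix (or scalar) of enrichments at full precision.
#' @examples
#' # 18 shared TADs between a 167-TAD state cluster and a 338-TAD
#' # structural cluster:
#' round(overlap_enrichment(18, 338, 167), 1)  # 0.3
#' @export
overlap_enrichment <- function(counts, sizes_a, sizes_b, scale = 1000) {
  counts <- as.matrix(counts)
  if (any(sizes_a <= 0) || any(sizes_b <= 0)) {
    tf_stop("tf_argument_error", "cluster sizes must be positive")
  }
  if (length(sizes_b) != nrow(counts) || length(sizes_a) != ncol(counts)) {
    tf_stop("tf_argument_error", "sizes inconsistent with counts")
  }
  scale * counts / outer(sizes_b, sizes_a)
}

#' Define TAD families as cluster intersections
#'
#' One family per non-empty (structural cluster, chromatin-state cluster)
#' pair; its members are the TADs shared by the two clusters. Families are
#' disjoint and together cover every TAD, and are ordered by decreasing
#' size.
#'
#' @param a Structural `cluster_assignment`.
#' @param b Chromatin-state `cluster_assignment` over the same TAD ids.
#' @return A `family_table`: data frame with columns `family_id`,
#'   `struct_cluster`, `state_cluster`, `n_members`, and list-column
#'   `members`.
#' @export
define_families <- function(a, b) {
  check_same_ids(a, b)
  ids <- names(a$labels)
  key <- paste(a$labels[ids], b$labels[ids], sep = "|")
  groups <- split(ids, key)
  sc <- as.integer(sub("\\|.*", "", names(groups)))
  fc <- as.integer(sub(".*\\|", "", names(groups)))
  ord <- order(-lengths(groups), sc, fc)
  out <- data.frame(
    family_id = sprintf("F%03d", seq_along(groups)),
    struct_cluster = sc[ord],
    state_cluster = fc[ord],
    n_members = lengths(groups)[ord],
    stringsAsFactors = FALSE
  )
  out$members <- unname(groups[ord])
  rownames(out) <- NULL
  class(out) <- c("family_table", "data.frame")
  out
}

#' @export
print.family_table <- function(x, ...) {
  cat(sprintf("family_table: %d families over %d TADs\n",
              nrow(x), sum(x$n_members)))
  print(as.data.frame(x[, c("family_id", "struct_cluster", "state_cluster",
                            "n_members", if ("score" %in% names(x)) "score")]))
  invisible(x)
}

#' Family score: fraction of enriched chromatin states
#'
#' The percentage of states whose pooled log2 fold enrichment is positive
#' (`F_s > 1`); `F_s = 0` counts as non-positive. A score below 0.5 flags
#' a family depleted of chromatin states.
#'
#' @param cluster_enrichment A `fold_enrichment` (e.g. from
#'   [cluster_state_enrichment()]) or bare numeric vector of fold values.
#' @return Score in `[0, 1]`.
#' @export
family_score <- function(cluster_enrichment) {
  v <- if (inherits(cluster_enrichment, "fold_enrichment")) {
    cluster_enrichment$values
  } else as.numeric(cluster_enrichment)
  mean(v > 1)
}

# Partition nbins bins into `target` contiguous, maximally even groups.
even_groups <- function(nbins, target) {
  g <- floor((seq_len(nbins) - 1) * target / nbins) + 1L
  g
}

# Resolve one member TAD to a target x target submatrix of its chromosome
# matrix: exact extraction at `target` bins, symmetric flank extension
# below it (odd remainder downstream; clipped at the chromosome bounds
# with asymmetric completion), contiguous block-averaging above it.
member_heatmap <- function(t, cm, target) {
  bs <- cm$bin_size
  nchrom <- n_bins(cm)
  b0 <- round((t$start - cm$origin$start) / bs)   # 0-based first bin
  b1 <- round((t$end - cm$origin$start) / bs)     # 0-based exclusive end
  nb <- b1 - b0
  if (nb < 2) {
    tf_warn("tf_member_warning", "member %s has fewer than 2 bins; skipped", t$id)
    return(NULL)
  }
  if (nb <= target) {
    extra <- target - nb
    left <- extra %/% 2
    right <- extra - left          # odd remainder goes downstream
    lo <- b0 - left
    hi <- b1 + right
    if (lo < 0) {                  # clip and complete on the other side
      hi <- min(nchrom, hi - lo); lo <- 0
      if (extra > 0) tf_warn("tf_clip_warning", "extension clipped at chromosome start")
    }
    if (hi > nchrom) {
      lo <- max(0, lo - (hi - nchrom)); hi <- nchrom
      tf_warn("tf_clip_warning", "extension clipped at chromosome end")
    }
    idx <- (lo + 1):hi
    sub <- cm$values[idx, idx, drop = FALSE]
    if (length(idx) < target) return(NULL)  # chromosome shorter than target
    sub
  } else {
    idx <- (b0 + 1):b1
    sub <- cm$values[idx, idx, drop = FALSE]
    g <- even_groups(nb, target)
    out <- matrix(NA_real_, target, target)
    for (i in seq_len(target)) {
      for (j in seq_len(target)) {
        block <- sub[g == i, g == j, drop = FALSE]
        if (any(!is.na(block))) out[i, j] <- mean(block, na.rm = TRUE)
      }
    }
    out
  }
}

#' Average Hi-C heatmap of a TAD family
#'
#' Each member TAD is brought to a common `target x target` size:
#' members with exactly `target` bins contribute their own chromosome
#' submatrix; smaller members are extended symmetrically into flanking
#' chromosome bins (odd remainder downstream) before extraction; larger
#' members have their bins partitioned into `target` contiguous,
#' maximally even groups and block-averaged. The family heatmap is the
#' elementwise mean over members (missing entries excluded), reported as
#' `log2(mean + 1)`.
#'
#' @param members Interval data frame of family members.
#' @param chrom_matrices Named list of chromosome-wide [contact_matrix()]
#'   objects, keyed by chromosome name.
#' @param target Output size (default 30).
#' @return `target x target` numeric matrix on the log2 scale.
#' @export
average_family_heatmap <- function(members, chrom_matrices, target = 30L) {
  stopifnot(nrow(members) >= 1)
  acc <- matrix(0, target, target)
  cnt <- matrix(0, target, target)
  for (i in seq_len(nrow(members))) {
    t <- members[i, , drop = FALSE]
    cm <- chrom_matrices[[t$chrom]]
    if (is.null(cm)) {
      tf_stop("tf_argument_error", "no chromosome matrix for %s", t$chrom)
    }
    h <- member_heatmap(t, cm, target)
    if (is.null(h)) next
    ok <- !is.na(h)
    acc[ok] <- acc[ok] + h[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  avg <- ifelse(cnt > 0, acc / cnt, NA_real_)
  log2(avg + 1)
}

#' Gene density of a TAD
#'
#' Number of genes overlapping the TAD by at least 1 bp (a gene straddling
#' the boundary counts), divided by the TAD's number of bins
#' (`ceil(length / bin_size)`).
#'
#' @param t One-row interval data frame (the TAD).
#' @param genes Interval data frame of gene annotations.
#' @param bin_size Base pairs per bin.
#' @return Genes per bin.
#' @export
gene_density <- function(t, genes, bin_size) {
  if (bin_size <= 0) tf_stop("tf_argument_error", "bin_size must be > 0")
  nb <- ceiling(interval_width(t) / bin_size)
  if (nrow(genes) == 0) return(0)
  hits <- genes$chrom == t$chrom & genes$start < t$end & genes$end > t$start
  sum(hits) / nb
}

#' Enumerate heatmap configurations for the overlap analysis
#'
#' Every combination of cell type, chromatin-state cluster count, and
#' structural cluster count defines one overlap-enrichment heatmap. With
#' the default grids (functional k in {10, 20, 30}, structural k in
#' {2, 3, 5, 10}) and six cell types this yields 72 configurations.
#'
#' @param cell_types Character vector of cell-type names.
#' @param k_func,k_struct Predefined cluster-count grids.
#' @return Data frame with one row per configuration.
#' @export
heatmap_configurations <- function(cell_types,
                                   k_func = c(10, 20, 30),
                                   k_struct = c(2, 3, 5, 10)) {
  expand.grid(cell_type = cell_types, k_func = k_func, k_struct = k_struct,
              stringsAsFactors = FALSE)
}

#' All unordered pairs of cell types
#'
#' The cross-cell-type comparison is run once per unordered pair; six
#' annotated cell types give 15 pairs.
#'
#' @param cell_types Character vector of distinct cell-type names.
#' @return Data frame with columns `cell_a`, `cell_b`.
#' @export
cell_type_pairs <- function(cell_types) {
  stopifnot(!anyDuplicated(cell_types), length(cell_types) >= 2)
  idx <- utils::combn(length(cell_types), 2)
  data.frame(cell_a = cell_types[idx[1, ]], cell_b = cell_types[idx[2, ]],
             stringsAsFactors = FALSE)
}
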