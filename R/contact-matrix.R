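#' Hi-C contact matrix
#'
#' A symmetric, non-negative per-region contact matrix with an explicit
#' missing-data mask. Zeros are observed zeros; only masked entries are
#' missing. Bin `b` (1-based in R) covers
#' `[origin$start + (b-1) * bin_size, origin$start + b * bin_size)`.
#'
#' @param values Numeric n x n matrix of contacts (NA allowed where masked).
#' @param bin_size Base pairs per bin.
#' @param origin One-row interval data frame the matrix spans; defaults to
#'   an anonymous region of `n * bin_size` bp.
#' @param mask Logical n x n matrix, `TRUE` where the entry is missing;
#'   defaults to `is.na(values)`.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(values, bin_size = 1L, origin = NULL, mask = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) {
    tf_stop("tf_format_error", "contact matrix must be square (got %d x %d)",
            n, ncol(values))
  }
  if (is.null(mask)) mask <- is.na(values)
  mask <- mask | is.na(values)
  if (!isTRUE(all.equal(mask, t(mask)))) {
    tf_stop("tf_format_error", "contact mask must be symmetric")
  }
  obs <- values[!mask]
  if (any(obs < 0)) {
    tf_stop("tf_domain_error", "negative contact value")
  }
  both <- !mask & !t(mask)
  if (any(abs(values[both] - t(values)[both]) > 1e-9)) {
    tf_stop("tf_format_error", "contact matrix not symmetric (tolerance 1e-9)")
  }
  if (is.null(origin)) {
    origin <- genomic_interval("region", 0, n * bin_size)
  }
  n_expect <- (origin$end - origin$start) / bin_size
  if (abs(n_expect - n) > 1e-9) {
    tf_stop("tf_format_error",
            "origin spans %g bins at bin size %d but matrix has %d",
            n_expect, bin_size, n)
  }
  values[mask] <- NA_real_
  structure(
    list(values = values, mask = mask, bin_size = as.integer(bin_size),
         origin = origin),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d x %d bins of %d bp (%s:%g-%g), %d missing entries\n",
              nrow(x$values), ncol(x$values), x$bin_size, x$origin$chrom,
              x$origin$start, x$origin$end, sum(x$mask)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$values)

n_bins <- function(m) nrow(m$values)

# Observed off-diagonal values of a contact matrix.
observed_offdiag <- function(m) {
  keep <- !m$mask & row(m$values) != col(m$values)
  m$values[keep]
}

#' Pairwise TAD similarity matrix
#'
#' @param values Symmetric m x m numeric matrix with unit diagonal.
#' @param kind `"structural"` (TM-score) or `"functional"`
#'   (absolute fold-enrichment correlation).
#' @param tad_ids Character ids, one per row.
#' @return A `similarity_matrix` object (a matrix with attributes).
#' @export
similarity_matrix <- function(values, kind = c("structural", "functional"),
                              tad_ids = rownames(values)) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  m <- nrow(values)
  if (ncol(values) != m) tf_stop("tf_format_error", "similarity matrix must be square")
  if (is.null(tad_ids)) tad_ids <- paste0("tad", seq_len(m))
  if (max(abs(values - t(values))) > 1e-9) {
    tf_stop("tf_domain_error", "similarity matrix must be symmetric")
  }
  if (max(abs(diag(values) - 1)) > 1e-9) {
    tf_stop("tf_domain_error", "similarity matrix diagonal must be 1")
  }
  if (any(values < 0 - 1e-12) || any(values > 1 + 1e-12)) {
    tf_stop("tf_domain_error", "similarities must lie in [0, 1]")
  }
  dimnames(values) <- list(tad_ids, tad_ids)
  structure(values, kind = kind, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("%s similarity matrix over %d TADs\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
  invisible(x)
}
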