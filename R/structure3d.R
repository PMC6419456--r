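#' 3D bead structure of a genomic region
#'
#' Ordered bead coordinates, one bead per genomic bin, in arbitrary spatial
#' units. Bead order follows bin order along the genome.
#'
#' @param coords Numeric n x 3 matrix of (x, y, z) bead positions, n >= 3.
#' @param source Tag for the reconstruction method (e.g. `"mds"`, `"tsne"`,
#'   `"helix"`).
#' @param origin Optional one-row interval data frame the structure spans.
#' @return A `structure3d` object.
#' @export
structure3d <- function(coords, source = "unknown", origin = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) tf_stop("tf_argument_error", "coords must be n x 3")
  if (nrow(coords) < 3) tf_stop("tf_argument_error", "structure needs >= 3 beads")
  if (any(!is.finite(coords))) {
    tf_stop("tf_domain_error", "non-finite bead coordinate")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(coords = coords, source = source, origin = origin),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d beads (source: %s)\n", nrow(x$coords), x$source))
  invisible(x)
}

n_beads <- function(s) nrow(s$coords)

#' Chromatin-state segmentation
#'
#' Non-overlapping labeled intervals (ChromHMM segments dialect), e.g. a
#' 25-state Roadmap model.
#'
#' @param records Data frame with columns `chrom`, `start`, `end`, `state`
#'   (BED4 semantics, 0-based half-open).
#' @param state_labels Ordered character vector of the S legal state labels.
#' @return A `segmentation` object.
#' @export
segmentation <- function(records, state_labels) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    records <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), state = character(),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(records)))
  unknown <- setdiff(unique(records$state), state_labels)
  if (length(unknown)) {
    tf_stop("tf_domain_error", "unknown state label(s): %s",
            paste(unknown, collapse = ", "))
  }
  records <- records[order(records$chrom, records$start), , drop = FALSE]
  rownames(records) <- NULL
  for (chr in unique(records$chrom)) {
    r <- records[records$chrom == chr, ]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)])) {
      tf_stop("tf_format_error", "overlapping segmentation records on %s", chr)
    }
  }
  if (any(records$start >= records$end)) {
    tf_stop("tf_record_error", "segmentation record with start >= end")
  }
  structure(list(records = records, state_labels = as.character(state_labels)),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d records, %d states, chromosomes: %s\n",
              nrow(x$records), length(x$state_labels),
              paste(unique(x$records$chrom), collapse = ", ")))
  invisible(x)
}

#' Default 25 chromatin-state labels
#'
#' Label set matching the Roadmap 25-state imputation-based model naming
#' style (`"1_TssA"` ... `"25_Quies"`); used as the default state universe
#' for synthetic segmentations.
#'
#' @return Character vector of length 25.
#' @export
roadmap25_labels <- function() {
  short <- c("TssA", "PromU", "PromD1", "PromD2", "Tx5", "Tx", "Tx3", "TxWk",
             "TxReg", "TxEnh5", "TxEnh3", "TxEnhW", "EnhA1", "EnhA2", "EnhAF",
             "EnhW1", "EnhW2", "EnhAc", "DNase", "ZNF_Rpts", "Het", "PromP",
             "PromBiv", "ReprPC", "Quies")
  paste0(seq_along(short), "_", short)
}
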