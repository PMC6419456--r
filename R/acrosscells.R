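#' Match TADs with identical coordinates across two cell types
#'
#' A cross-cell-type (acrossCells) pair is two TADs from different cell
#' types on the same chromosome with exactly the same start and end.
#' Matching is strict coordinate equality; a one-bin shift breaks the
#' pair.
#'
#' @param tads_a,tads_b Interval data frames with unique
#'   `(chrom, start, end)` within each list.
#' @return Data frame with columns `chrom`, `start`, `end`, `id_a`,
#'   `id_b`, ordered by chromosome then start.
#' @export
match_across_cells <- function(tads_a, tads_b) {
  for (nm in list(a = tads_a, b = tads_b)) {
    if (anyDuplicated(nm[c("chrom", "start", "end")])) {
      tf_stop("tf_argument_error", "duplicate coordinates within one TAD list")
    }
  }
  m <- merge(tads_a[c("chrom", "start", "end", "id")],
             tads_b[c("chrom", "start", "end", "id")],
             by = c("chrom", "start", "end"), suffixes = c("_a", "_b"))
  m <- m[order(m$chrom, m$start), , drop = FALSE]
  rownames(m) <- NULL
  names(m)[names(m) == "id_a"] <- "id_a"
  m
}

#' Paired similarity measures for one acrossCells TAD pair
#'
#' The chromatin-state measure is the signed Pearson correlation of the
#' two fold-enrichment vectors (unlike within-cell clustering similarity,
#' which takes the absolute value: here the sign distinguishes concordant
#' from discordant state usage). The structural measure is the TM-score
#' of the two reconstructed structures.
#'
#' @param pair One row of [match_across_cells()] output.
#' @param fe_a,fe_b `fold_enrichment` vectors for the TAD in each cell.
#' @param s_a,s_b [structure3d()] reconstructions in each cell.
#' @param cell_a,cell_b Cell-type names.
#' @return One-row data frame: `chrom`, `start`, `end`, `cell_a`,
#'   `cell_b`, `state_correlation` (NA if a vector is constant), `tm`.
#' @export
across_cell_similarity <- function(pair, fe_a, fe_b, s_a, s_b,
                                   cell_a = "cellA", cell_b = "cellB") {
  v1 <- if (inherits(fe_a, "fold_enrichment")) fe_a$values else as.numeric(fe_a)
  v2 <- if (inherits(fe_b, "fold_enrichment")) fe_b$values else as.numeric(fe_b)
  if (length(v1) != length(v2)) tf_stop("tf_argument_error", "length mismatch")
  if (sd(v1) == 0 || sd(v2) == 0) {
    tf_warn("tf_undefined_correlation_warning",
            "constant fold-enrichment vector; correlation undefined")
    r <- NA_real_
  } else {
    r <- cor(v1, v2)
  }
  data.frame(chrom = pair$chrom, start = pair$start, end = pair$end,
             cell_a = cell_a, cell_b = cell_b,
             state_correlation = r, tm = tm_score(s_a, s_b),
             stringsAsFactors = FALSE)
}
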