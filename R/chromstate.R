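# Base pairs of each state overlapping a set of intervals, and genome-wide.
# All overlap arithmetic goes through GenomicRanges.
state_overlap_bases <- function(iv, seg) {
  labels <- seg$state_labels
  out <- setNames(numeric(length(labels)), labels)
  if (nrow(seg$records) == 0 || nrow(iv) == 0) return(out)
  rec_gr <- GenomicRanges::GRanges(
    seg$records$chrom,
    IRanges::IRanges(seg$records$start + 1, seg$records$end)
  )
  # members are not merged: overlap bases are summed per member, so a
  # cluster's pooled enrichment is the member-weighted density ratio
  iv_gr <- GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(iv$start + 1, iv$end)
  )
  # disjoint seqlevels (TAD on a chromosome absent from the segmentation)
  # is an expected no-overlap case, not worth GenomicRanges's warning
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rec_gr, iv_gr))
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(
      rec_gr[S4Vectors::queryHits(hits)], iv_gr[S4Vectors::subjectHits(hits)]
    )
    w <- IRanges::width(ov)
    st <- seg$records$state[S4Vectors::queryHits(hits)]
    agg <- tapply(w, st, sum)
    out[names(agg)] <- agg
  }
  out
}

state_genome_bases <- function(seg) {
  labels <- seg$state_labels
  out <- setNames(numeric(length(labels)), labels)
  if (nrow(seg$records)) {
    agg <- tapply(seg$records$end - seg$records$start, seg$records$state, sum)
    out[names(agg)] <- agg
  }
  out
}

#' Fold enrichment of chromatin states within a TAD
#'
#' For each state `s`,
#' `F_s = (bases of s overlapping the TAD / TAD length) /
#'        (bases of s genome-wide / genome size)`:
#' the in-region density of the state divided by its genome-wide density.
#' `F_s = 1` means neither enriched nor depleted; states absent
#' genome-wide get `F_s = 0`. Bases of the TAD not covered by any record
#' still count toward the TAD length.
#'
#' @param t One-row interval data frame (the TAD).
#' @param seg A [segmentation()].
#' @param genome_size Total genome size in bp (>= covered bases).
#' @return A `fold_enrichment` object: list with `values` (named length-S
#'   vector) and `tad_id`.
#' @export
fold_enrichment <- function(t, seg, genome_size) {
  stopifnot(inherits(seg, "segmentation"), nrow(t) == 1)
  genome <- state_genome_bases(seg)
  if (genome_size < sum(genome)) {
    tf_stop("tf_argument_error", "genome_size smaller than covered bases")
  }
  inside <- state_overlap_bases(t, seg)
  len <- interval_width(t)
  if (sum(inside) == 0) {
    tf_warn("tf_coverage_warning",
            "TAD %s has no overlap with the segmentation", t$id)
    return(structure(list(values = setNames(rep(0, length(genome)),
                                            names(genome)),
                          tad_id = t$id),
                     class = "fold_enrichment"))
  }
  F <- ifelse(genome > 0, (inside / len) / (genome / genome_size), 0)
  structure(list(values = F, tad_id = t$id), class = "fold_enrichment")
}

#' @export
print.fold_enrichment <- function(x, ...) {
  cat(sprintf("fold_enrichment for %s over %d states\n",
              x$tad_id, length(x$values)))
  print(round(x$values, 3))
  invisible(x)
}

#' Functional similarity of two TADs
#'
#' Absolute Pearson correlation of their chromatin-state fold-enrichment
#' vectors, in `[0, 1]`. A constant vector (undefined correlation) yields
#' 0.
#'
#' @param f1,f2 `fold_enrichment` objects or bare numeric vectors of equal
#'   length >= 3.
#' @return `|r|` in `[0, 1]`.
#' @export
functional_similarity <- function(f1, f2) {
  v1 <- if (inherits(f1, "fold_enrichment")) f1$values else as.numeric(f1)
  v2 <- if (inherits(f2, "fold_enrichment")) f2$values else as.numeric(f2)
  if (length(v1) != length(v2)) tf_stop("tf_argument_error", "length mismatch")
  if (length(v1) < 3) tf_stop("tf_argument_error", "need >= 3 states")
  if (sd(v1) == 0 || sd(v2) == 0) return(0)
  abs(cor(v1, v2))
}

#' Functional similarity matrix over a set of TADs
#'
#' @param fes Named list of `fold_enrichment` vectors (names = TAD ids).
#' @return A [similarity_matrix()] of kind `"functional"`.
#' @export
functional_similarity_matrix <- function(fes) {
  m <- length(fes)
  if (m < 2) tf_stop("tf_argument_error", "need >= 2 TADs")
  ids <- names(fes)
  if (is.null(ids)) ids <- vapply(fes, `[[`, "", "tad_id")
  values <- diag(m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      values[i, j] <- values[j, i] <- functional_similarity(fes[[i]], fes[[j]])
    }
  }
  similarity_matrix(values, kind = "functional", tad_ids = ids)
}

#' Pooled fold enrichment of a cluster of TADs
#'
#' The member intervals are treated as one region set: per-state overlap
#' bases and total length are summed over members before the density
#' ratio, so two disjoint pure-state members give the same enrichment as
#' either alone. log2 values are attached (with `-Inf` where `F_s = 0`).
#'
#' @param members Interval data frame of cluster members (non-empty).
#' @param seg A [segmentation()].
#' @param genome_size Genome size in bp.
#' @return A `fold_enrichment` with attribute `log2`.
#' @export
cluster_state_enrichment <- function(members, seg, genome_size) {
  if (is.null(members) || nrow(members) == 0) {
    tf_stop("tf_argument_error", "empty member set")
  }
  genome <- state_genome_bases(seg)
  inside <- state_overlap_bases(members, seg)
  len <- sum(interval_width(members))
  F <- ifelse(genome > 0, (inside / len) / (genome / genome_size), 0)
  out <- structure(
    list(values = F,
         tad_id = sprintf("cluster[%d members]", nrow(members))),
    class = "fold_enrichment"
  )
  attr(out, "log2") <- suppressWarnings(log2(F))
  out
}
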