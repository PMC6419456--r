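#' Feature records (genes / lncRNAs)
#'
#' A feature catalog is an interval data frame with two extra columns:
#' `source` (catalog name) and `feature_class` (`"coding_gene"` or
#' `"lncRNA"`).
#'
#' @param iv Interval data frame (`chrom`, `start`, `end`, `id`, `strand`).
#' @param source Catalog name.
#' @param feature_class `"coding_gene"` or `"lncRNA"`.
#' @return Feature data frame.
#' @export
feature_records <- function(iv, source, feature_class = c("coding_gene", "lncRNA")) {
  feature_class <- match.arg(feature_class)
  validate_intervals(iv)
  iv$source <- source
  iv$feature_class <- feature_class
  iv
}

#' Map features onto TADs by coordinate overlap
#'
#' A feature belongs to a TAD iff their intervals overlap by >= 1 bp on
#' the same chromosome; strand is ignored for membership, and a feature
#' spanning several TADs belongs to all of them. Features overlapping no
#' TAD appear with zero memberships in the attached `unmatched` attribute.
#'
#' @param features Feature data frame (see [feature_records()]).
#' @param tads Interval data frame of TADs.
#' @return Membership data frame (`feature_id`, `source`, `feature_class`,
#'   `tad_id`) with attribute `unmatched` (feature ids with no TAD).
#' @export
map_features_to_tads <- function(features, tads) {
  f_gr <- as_granges(features)
  t_gr <- as_granges(tads)
  hits <- GenomicRanges::findOverlaps(f_gr, t_gr, minoverlap = 1L)
  q <- S4Vectors::queryHits(hits)
  out <- data.frame(
    feature_id = features$id[q],
    source = features$source[q],
    feature_class = features$feature_class[q],
    tad_id = tads$id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  attr(out, "unmatched") <- setdiff(features$id, out$feature_id)
  out
}

#' Unify feature identifiers across catalogs
#'
#' Records from *different* catalogs that overlap by >= 1 bp on the same
#' chromosome and strand describe the same feature; groups are closed
#' transitively (A~B and B~C put A, B, C in one group even when A and C
#' are disjoint). Each group collects the full alias set.
#'
#' @param catalogs List (length >= 2) of feature data frames.
#' @return Data frame (`group_id`, `source`, `id`, `chrom`, `start`,
#'   `end`, `strand`) with one row per original record; rows sharing a
#'   `group_id` are aliases of one feature.
#' @export
unify_feature_ids <- function(catalogs) {
  if (length(catalogs) < 2) tf_stop("tf_argument_error", "need >= 2 catalogs")
  all_rec <- do.call(rbind, lapply(catalogs, function(x) {
    x[c("chrom", "start", "end", "id", "strand", "source")]
  }))
  n <- nrow(all_rec)
  gr <- as_granges(all_rec)
  hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- q < s & all_rec$source[q] != all_rec$source[s] &
    all_rec$strand[q] == all_rec$strand[s]
  g <- igraph::graph_from_data_frame(
    data.frame(from = q[keep], to = s[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  comp <- igraph::components(g)$membership
  # stable group ids: number groups by their first record
  first <- tapply(seq_len(n), comp, min)
  relabel <- setNames(rank(first), names(first))
  out <- all_rec
  out$group_id <- sprintf("G%04d", relabel[as.character(comp[as.character(seq_len(n))])])
  rownames(out) <- NULL
  out[c("group_id", "source", "id", "chrom", "start", "end", "strand")]
}

#' Count features per TAD and class
#'
#' Counts memberships per `(tad_id, feature_class)`. When an alias table
#' from [unify_feature_ids()] is supplied, records in one alias group
#' count once per TAD, not once per catalog entry.
#'
#' @param membership Output of [map_features_to_tads()].
#' @param aliases Optional alias table from [unify_feature_ids()].
#' @return Data frame `tad_id`, `feature_class`, `n`.
#' @export
count_features_per_tad <- function(membership, aliases = NULL) {
  m <- membership
  if (nrow(m) == 0) {
    return(data.frame(tad_id = character(), feature_class = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  if (!is.null(aliases)) {
    key_m <- paste(m$source, m$feature_id)
    key_a <- paste(aliases$source, aliases$id)
    grp <- aliases$group_id[match(key_m, key_a)]
    m$unit <- ifelse(is.na(grp), key_m, grp)
  } else {
    m$unit <- paste(m$source, m$feature_id)
  }
  agg <- aggregate(
    unit ~ tad_id + feature_class, data = m,
    FUN = function(u) length(unique(u))
  )
  names(agg)[3] <- "n"
  agg[order(agg$tad_id, agg$feature_class), , drop = FALSE]
}
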