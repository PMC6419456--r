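#' Genomic intervals
#'
#' Intervals follow the BED convention throughout: 0-based start, exclusive
#' end. A collection of intervals is a plain `data.frame` with columns
#' `chrom`, `start`, `end`, `id`, `strand`; a single interval is a one-row
#' data frame of the same shape.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (base pairs).
#' @param end Exclusive end (base pairs); must satisfy `start < end`.
#' @param id Identifier; defaults to `"chrom:start-end"`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A one-row interval data frame.
#' @examples
#' genomic_interval("chr1", 0, 100000, "TAD1")
#' @export
genomic_interval <- function(chrom, start, end, id = NULL, strand = ".") {
  if (is.null(id) || is.na(id) || !nzchar(id)) {
    id <- sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
  }
  iv <- data.frame(
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), id = as.character(id),
    strand = as.character(strand), stringsAsFactors = FALSE
  )
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv) {
  stopifnot(is.data.frame(iv),
            all(c("chrom", "start", "end", "id", "strand") %in% names(iv)))
  if (any(iv$start < 0)) {
    tf_stop("tf_record_error", "interval start must be >= 0")
  }
  bad <- which(iv$start >= iv$end)
  if (length(bad)) {
    tf_stop("tf_record_error", "interval %d has start >= end (%s:%g-%g)",
            bad[1], iv$chrom[bad[1]], iv$start[bad[1]], iv$end[bad[1]])
  }
  if (any(!nzchar(iv$id))) tf_stop("tf_record_error", "empty interval id")
  if (!all(iv$strand %in% c("+", "-", "."))) {
    tf_stop("tf_record_error", "strand must be one of '+', '-', '.'")
  }
  if (anyDuplicated(iv[c("chrom", "start", "end", "id")])) {
    tf_stop("tf_record_error", "duplicate (chrom,start,end,id) interval")
  }
  invisible(iv)
}

interval_width <- function(iv) iv$end - iv$start

# GRanges view of an interval data frame; all overlap arithmetic in the
# package goes through GenomicRanges. BED half-open [start, end) maps to the
# 1-based closed IRanges convention as [start + 1, end].
as_granges <- function(iv, keep_strand = FALSE) {
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1, end = iv$end),
    strand = if (keep_strand) sub("^\\.$", "*", iv$strand) else "*"
  )
}
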