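#' Read a Hi-C contact matrix from text
#'
#' Two plain-text layouts are supported. `dense`: a whitespace-separated
#' n x n grid, where `NA`/`nan` tokens mark missing entries and zeros are
#' observed zeros. `coo`: triplet lines `i j value` with 0-based bin
#' indices; listing `(i, j)` also fills `(j, i)`, and unlisted pairs are
#' missing.
#'
#' @param path File path.
#' @param format `"dense"` or `"coo"`.
#' @param bin_size Base pairs per bin.
#' @param origin Optional one-row interval data frame the matrix spans.
#'   Required for `coo` (it fixes n); optional for `dense`.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("dense", "coo"),
                                bin_size = 1L, origin = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) tf_stop("tf_io_error", "no such file: %s", path)
  if (format == "dense") {
    rows <- readLines(path)
    rows <- rows[nzchar(trimws(rows))]
    toks <- lapply(strsplit(trimws(rows), "[ \t]+"), function(x) {
      x[x %in% c("NA", "nan", "NaN")] <- NA
      suppressWarnings(as.numeric(x))
    })
    n <- length(toks)
    if (any(lengths(toks) != n)) {
      tf_stop("tf_format_error", "dense matrix in %s is not square", path)
    }
    values <- do.call(rbind, toks)
    contact_matrix(values, bin_size = bin_size, origin = origin)
  } else {
    if (is.null(origin)) {
      tf_stop("tf_argument_error", "coo format requires an origin interval")
    }
    n <- as.integer(round((origin$end - origin$start) / bin_size))
    trip <- read.table(path, header = FALSE,
                       col.names = c("i", "j", "value"),
                       colClasses = c("integer", "integer", "character"))
    trip$value[trip$value %in% c("NA", "nan", "NaN")] <- NA
    trip$value <- suppressWarnings(as.numeric(trip$value))
    if (any(trip$i < 0 | trip$i >= n | trip$j < 0 | trip$j >= n)) {
      tf_stop("tf_bounds_error", "coo index out of range [0, %d) in %s", n, path)
    }
    values <- matrix(NA_real_, n, n)
    values[cbind(trip$i + 1L, trip$j + 1L)] <- trip$value
    values[cbind(trip$j + 1L, trip$i + 1L)] <- trip$value
    contact_matrix(values, bin_size = bin_size, origin = origin)
  }
}

#' Write a contact matrix as COO triplets
#'
#' Writes the observed upper triangle (including the diagonal where
#' observed) as `i j value` lines with 0-based indices.
#'
#' @param m A [contact_matrix()].
#' @param path Output file path.
#' @export
write_contact_matrix_coo <- function(m, path) {
  idx <- which(!m$mask & row(m$values) <= col(m$values), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   value = m$values[idx])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED3+ with optional name in column 4 and strand in column 6; 0-based
#' half-open coordinates. Missing names are auto-assigned
#' `"chrom:start-end"`, missing strand becomes `"."`.
#'
#' @param path BED file path.
#' @return Interval data frame (`chrom`, `start`, `end`, `id`, `strand`)
#'   in file order.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) tf_stop("tf_io_error", "no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      id = character(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t")
  out <- lapply(seq_along(fields), function(ln) {
    f <- fields[[ln]]
    if (length(f) < 3) {
      tf_stop("tf_record_error", "line %d: fewer than 3 BED columns", ln)
    }
    start <- as.numeric(f[2]); end <- as.numeric(f[3])
    if (is.na(start) || is.na(end) || start >= end || start < 0) {
      tf_stop("tf_record_error", "line %d: invalid interval %s:%s-%s",
              ln, f[1], f[2], f[3])
    }
    id <- if (length(f) >= 4 && nzchar(f[4])) f[4] else
      sprintf("%s:%d-%d", f[1], as.integer(start), as.integer(end))
    strand <- if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "."
    data.frame(chrom = f[1], start = start, end = end, id = id,
               strand = strand, stringsAsFactors = FALSE)
  })
  iv <- do.call(rbind, out)
  validate_intervals(iv)
  iv
}

#' Write genomic intervals as BED6
#'
#' @param iv Interval data frame.
#' @param path Output file path.
#' @export
write_intervals <- function(iv, path) {
  validate_intervals(iv)
  df <- data.frame(iv$chrom, as.integer(iv$start), as.integer(iv$end),
                   iv$id, 0L, iv$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromatin-state segmentation from a BED4 file
#'
#' Column 4 holds the state label; labels outside `state_labels` are
#' rejected, as are overlapping records within a chromosome.
#'
#' @param path BED4 file path.
#' @param state_labels Legal state labels (e.g. [roadmap25_labels()]).
#' @return A [segmentation()].
#' @export
read_segmentation <- function(path, state_labels) {
  if (!file.exists(path)) tf_stop("tf_io_error", "no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(segmentation(data.frame(), state_labels))
  }
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) < 4)) {
    tf_stop("tf_format_error", "segmentation requires 4 BED columns")
  }
  rec <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = as.numeric(vapply(fields, `[`, "", 2)),
    end = as.numeric(vapply(fields, `[`, "", 3)),
    state = vapply(fields, `[`, "", 4),
    stringsAsFactors = FALSE
  )
  segmentation(rec, state_labels)
}

#' Write a segmentation as BED4
#'
#' @param seg A [segmentation()].
#' @param path Output file path.
#' @export
write_segmentation <- function(seg, path) {
  r <- seg$records
  df <- data.frame(r$chrom, as.integer(r$start), as.integer(r$end), r$state)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a 3D structure to disk
#'
#' `xyz`: a bead count line, a comment line, then one `C x y z` line per
#' bead. `pdb_like`: one ATOM record per bead with the bead index as the
#' residue number, beads implicitly connected in order. Coordinates are
#' written with 3 decimals, so a read-back reproduces them to 1e-3.
#'
#' @param s A [structure3d()].
#' @param path Output file path.
#' @param format `"xyz"` or `"pdb_like"`.
#' @export
write_structure <- function(s, path, format = c("xyz", "pdb_like")) {
  format <- match.arg(format)
  if (!inherits(s, "structure3d")) tf_stop("tf_argument_error", "not a structure3d")
  if (any(!is.finite(s$coords))) tf_stop("tf_domain_error", "non-finite coordinate")
  n <- n_beads(s)
  if (format == "xyz") {
    lines <- c(
      as.character(n),
      sprintf("beads source=%s", s$source),
      sprintf("C %.3f %.3f %.3f", s$coords[, 1], s$coords[, 2], s$coords[, 3])
    )
  } else {
    lines <- sprintf(
      "ATOM  %5d  CA  BEA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), seq_len(n), s$coords[, 1], s$coords[, 2], s$coords[, 3]
    )
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a 3D structure written by [write_structure()]
#'
#' @param path File path.
#' @param format `"xyz"` or `"pdb_like"`.
#' @param source Source tag for the returned structure.
#' @return A [structure3d()].
#' @export
read_structure <- function(path, format = c("xyz", "pdb_like"),
                           source = "file") {
  format <- match.arg(format)
  if (!file.exists(path)) tf_stop("tf_io_error", "no such file: %s", path)
  lines <- readLines(path)
  if (format == "xyz") {
    n <- as.integer(lines[1])
    rows <- strsplit(trimws(lines[3:(2 + n)]), "[ \t]+")
    coords <- t(vapply(rows, function(f) as.numeric(f[2:4]), numeric(3)))
  } else {
    atoms <- lines[startsWith(lines, "ATOM")]
    coords <- cbind(
      as.numeric(substr(atoms, 31, 38)),
      as.numeric(substr(atoms, 39, 46)),
      as.numeric(substr(atoms, 47, 54))
    )
  }
  structure3d(coords, source = source)
}

#' Write a numeric matrix as TSV with id header row and column
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output file path.
#' @param digits Decimal places to round to; `NA` leaves full precision.
#' @export
write_matrix_tsv <- function(m, path, digits = NA) {
  x <- unclass(as.matrix(m))
  if (!is.na(digits)) x <- round(x, digits)
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
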