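test_that("coo reader fills symmetric entries and masks unlisted pairs", {
  path <- withr::local_tempfile()
  writeLines("0\t1\t5.0", path)
  m <- read_contact_matrix(path, "coo", bin_size = 1,
                           origin = genomic_interval("chr1", 0, 2))
  expect_equal(m$values[1, 2], 5)
  expect_equal(m$values[2, 1], 5)
  expect_true(m$mask[1, 1])
  expect_true(m$mask[2, 2])
})

test_that("dense reader round-trips a grid with an empty mask", {
  path <- withr::local_tempfile()
  grid <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3)
  writeLines(apply(grid, 1, paste, collapse = "\t"), path)
  m <- read_contact_matrix(path, "dense")
  expect_equal(unname(m$values), grid)
  expect_false(any(m$mask))
})

test_that("dense and coo readers agree on equivalent input", {
  v <- matrix(c(NA, 2, 3, 2, NA, 4, 3, 4, NA), 3)
  orig <- genomic_interval("chr1", 0, 3)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeLines(apply(v, 1, function(r) paste(ifelse(is.na(r), "NA", r), collapse = "\t")), p1)
  write_contact_matrix_coo(contact_matrix(v, origin = orig), p2)
  m1 <- read_contact_matrix(p1, "dense", origin = orig)
  m2 <- read_contact_matrix(p2, "coo", origin = orig)
  expect_equal(m1$values, m2$values)
  expect_equal(m1$mask, m2$mask)
})

test_that("malformed contact input is rejected", {
  path <- withr::local_tempfile()
  writeLines(c("1\t2\t3", "4\t5\t6"), path)   # 2 x 3
  expect_error(read_contact_matrix(path, "dense"), class = "tf_format_error")
  writeLines(c("1\t-2", "-2\t1"), path)
  expect_error(read_contact_matrix(path, "dense"), class = "tf_domain_error")
  writeLines("0\t5\t1.0", path)               # index out of range for n = 2
  expect_error(
    read_contact_matrix(path, "coo", origin = genomic_interval("chr1", 0, 2)),
    class = "tf_bounds_error"
  )
})

test_that("BED reader defaults ids and strands and validates records", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100000\tTAD1",
               "chr1\t100000\t200000",
               "chr2\t0\t50000\tTAD3\t0\t-"), path)
  iv <- read_intervals(path)
  expect_equal(iv$id, c("TAD1", "chr1:100000-200000", "TAD3"))
  expect_equal(iv$strand, c(".", ".", "-"))
  writeLines("chr1\t100\t100", path)
  expect_error(read_intervals(path), class = "tf_record_error")
  expect_match(tryCatch(read_intervals(path), error = conditionMessage), "line 1")
})

test_that("interval and segmentation writers round-trip exactly", {
  iv <- rbind(genomic_interval("chr1", 0, 1000, "a", "+"),
              genomic_interval("chr2", 500, 900, "b"))
  p <- withr::local_tempfile()
  write_intervals(iv, p)
  expect_equal(read_intervals(p), iv)

  labels <- c("1_TssA", "25_Quies")
  seg <- segmentation(data.frame(chrom = "chr1", start = c(0, 200),
                                 end = c(200, 400),
                                 state = c("1_TssA", "25_Quies")), labels)
  write_segmentation(seg, p)
  expect_equal(read_segmentation(p, labels), seg)
})

test_that("segmentation reader sorts, and rejects overlaps and unknown labels", {
  labels <- roadmap25_labels()
  p <- withr::local_tempfile()
  writeLines(c("chr1\t200\t400\t25_Quies", "chr1\t0\t200\t1_TssA"), p)
  seg <- read_segmentation(p, labels)
  expect_equal(seg$records$start, c(0, 200))
  writeLines(c("chr1\t0\t300\t1_TssA", "chr1\t200\t400\t25_Quies"), p)
  expect_error(read_segmentation(p, labels), class = "tf_format_error")
  writeLines("chr1\t0\t200\tnot_a_state", p)
  expect_error(read_segmentation(p, labels), class = "tf_domain_error")
  writeLines(character(), p)
  expect_equal(nrow(read_segmentation(p, labels)$records), 0)
})

test_that("structure writers produce the documented layouts and round-trip to 1e-3", {
  s <- gen_structure("helix", 12)
  for (fmt in c("xyz", "pdb_like")) {
    p <- withr::local_tempfile()
    write_structure(s, p, fmt)
    back <- read_structure(p, fmt)
    expect_equal(back$coords, s$coords, tolerance = 1e-3)
  }
  p <- withr::local_tempfile()
  s3 <- structure3d(diag(3))
  write_structure(s3, p, "xyz")
  expect_length(readLines(p), 5)  # count + comment + 3 beads
  bad <- s3
  bad$coords[1, 1] <- NaN
  expect_error(write_structure(bad, p), class = "tf_domain_error")
})

test_that("matrix TSV writer round-trips with ids", {
  m <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- withr::local_tempfile()
  write_matrix_tsv(m, p)
  expect_equal(read_matrix_tsv(p), m)
})
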