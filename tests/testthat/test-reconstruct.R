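make_cm <- function(v) contact_matrix(v, bin_size = 1)

test_that("rescaling maps observed contacts affinely onto [lo, hi]", {
  v <- matrix(c(NA, 2, 4, 2, NA, 3, 4, 3, NA), 3)
  r <- rescale_contacts(make_cm(v))
  expect_equal(sort(unique(r$values[!r$mask])), c(1, 15.5, 30))
  v2 <- matrix(c(NA, 2, 2, NA), 2)
  expect_error(rescale_contacts(make_cm(v2)), class = "tf_degenerate_input_error")
  # strictly increasing affine map on observed entries
  m <- gen_contact_matrix(10, -1, noise_sd = 0.2, seed = 4)
  r2 <- rescale_contacts(m)
  o <- order(m$values[!r2$mask])
  expect_equal(order(r2$values[!r2$mask]), o)
  expect_equal(range(r2$values[!r2$mask]), c(1, 30))
})

test_that("wish distances follow the inverse cube root and keep the mask", {
  v <- matrix(c(NA, 1, 8, 1, NA, 30, 8, 30, NA), 3)
  w <- contacts_to_wish_distances(make_cm(v))
  expect_equal(w$values[1, 2], 1)
  expect_equal(w$values[1, 3], 0.5)
  expect_equal(w$values[2, 3], 0.32183, tolerance = 1e-5)
  expect_equal(diag(w$values), rep(0, 3))
  # strictly decreasing in c
  expect_true(w$values[1, 2] > w$values[1, 3])
  v[1, 2] <- v[2, 1] <- 0
  expect_error(contacts_to_wish_distances(make_cm(v)), class = "tf_domain_error")
})

test_that("MDS recovers exact geometries up to rigid motion and reflection", {
  for (kind in c("segment", "helix")) {
    s <- gen_structure(kind, 20)
    emb <- embed_mds(as.matrix(dist(s$coords)), seed = 1)
    fit <- kabsch_superpose(emb, s, allow_reflection = TRUE)
    expect_lt(fit$rmsd, if (kind == "segment") 1e-3 else 1e-2)
  }
})

test_that("MDS is deterministic given a seed and respects missing-pair weights", {
  m <- gen_contact_matrix(15, -1, noise_sd = 0.2, seed = 9)
  w <- contacts_to_wish_distances(rescale_contacts(m))
  e1 <- embed_mds(w, seed = 5)
  e2 <- embed_mds(w, seed = 5)
  expect_identical(e1$coords, e2$coords)
  # zero-weighted missing pairs: masking a sparse random subset of the
  # distances must not prevent recovery of the geometry
  s <- gen_structure("random_walk", 12, seed = 1)
  d <- as.matrix(dist(s$coords))
  withr::with_seed(8, {
    drop <- which(upper.tri(d), arr.ind = TRUE)
    drop <- drop[sample(nrow(drop), 7), , drop = FALSE]
    d[drop] <- NA
    d[drop[, 2:1]] <- NA
  })
  emb <- embed_mds(d, seed = 2)
  expect_lt(kabsch_superpose(emb, s, allow_reflection = TRUE)$rmsd, 1e-2)
  # fully disconnected observation graph is refused
  d2 <- as.matrix(dist(s$coords))
  d2[1:6, 7:12] <- NA
  d2[7:12, 1:6] <- NA
  expect_error(embed_mds(d2, seed = 1), class = "tf_connectivity_error")
})

test_that("t-SNE selection returns the grid minimum and a full report", {
  s <- gen_structure("helix", 30)
  w <- as.matrix(dist(s$coords))
  res <- embed_tsne_selected(w, s, perplexities = c(5, 15),
                             learning_rates = c(10, 100), seed = 1)
  expect_equal(nrow(res$report), 4)
  best <- kabsch_superpose(res$structure, s, allow_reflection = TRUE)$rmsd
  expect_equal(best, min(res$report$rmsd), tolerance = 1e-9)
  res1 <- embed_tsne_selected(w, s, perplexities = 10, learning_rates = 100,
                              seed = 1)
  expect_equal(nrow(res1$report), 1)  # single configuration always selected
  expect_error(
    embed_tsne_selected(w, s, perplexities = 40, learning_rates = 100),
    class = "tf_argument_error"
  )
})

test_that("radius of gyration matches hand-computed values and is rigid-invariant", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  expect_equal(radius_of_gyration(matrix(1, 4, 3)), 0)
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radius_of_gyration(square), sqrt(0.5), tolerance = 1e-9)
  s <- gen_structure("random_walk", 15, seed = 7)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3)
  moved <- s$coords %*% R + 3
  expect_equal(radius_of_gyration(moved), radius_of_gyration(s), tolerance = 1e-12)
  expect_error(radius_of_gyration(matrix(0, 1, 3)), class = "tf_argument_error")
})

test_that("exponent fits recover exact power laws and flag degenerate input", {
  expect_equal(exponent_parameter(gen_contact_matrix(20, -1, seed = 1)), -1,
               tolerance = 1e-9)
  expect_equal(exponent_parameter(gen_contact_matrix(20, -1.5, seed = 1)), -1.5,
               tolerance = 1e-9)
  const <- matrix(2, 6, 6)
  expect_equal(exponent_parameter(make_cm(const)), 0, tolerance = 1e-12)
  tiny <- gen_contact_matrix(6, -1, seed = 1)
  tiny$mask[abs(row(tiny$values) - col(tiny$values)) > 2] <- TRUE
  tiny$values[tiny$mask] <- NA
  expect_error(exponent_parameter(contact_matrix(tiny$values, mask = tiny$mask)),
               class = "tf_insufficient_data_error")
})

test_that("consistency evaluation reports both correlations with the right signs", {
  expo <- c(-1.5, -1.0, -0.5, -0.2)
  rg <- c(4, 3, 2, 1)                 # strictly decreasing in exponent
  cc <- evaluate_consistency(expo, rg)
  expect_equal(cc$spearman, -1)
  cc2 <- evaluate_consistency(expo, expo)
  expect_equal(cc2$pearson, 1)
  expect_error(evaluate_consistency(c(1, 1, 1), rg[1:3]),
               class = "tf_undefined_correlation_error")
})
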