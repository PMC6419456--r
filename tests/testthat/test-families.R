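block_affinity <- function(sizes) {
  m <- sum(sizes)
  A <- matrix(0, m, m)
  off <- 0
  for (s in sizes) {
    A[off + seq_len(s), off + seq_len(s)] <- 1
    off <- off + s
  }
  dimnames(A) <- list(paste0("t", 1:m), paste0("t", 1:m))
  similarity_matrix(A, kind = "structural")
}

test_that("spectral clustering separates disconnected affinity blocks exactly", {
  sim <- block_affinity(c(4, 3))
  cl <- spectral_cluster(sim, k = 2, seed = 1)
  expect_equal(unname(cl$labels), c(rep(1L, 4), rep(2L, 3)))  # size-ordered
  expect_error(spectral_cluster(sim, k = 1), class = "tf_argument_error")
  expect_error(spectral_cluster(sim, k = 8), class = "tf_argument_error")
  cl2 <- spectral_cluster(sim, k = 2, seed = 1)
  expect_identical(cl$labels, cl2$labels)
})

test_that("overlap counts match a brute-force double loop on random partitions", {
  withr::with_seed(31, {
    ids <- paste0("t", 1:20)
    a <- random_assignment(ids, 4)
    b <- random_assignment(ids, 3)
    counts <- overlap_counts(a, b)
    brute <- matrix(0L, 3, 4)
    for (id in ids) {
      brute[b$labels[id], a$labels[id]] <- brute[b$labels[id], a$labels[id]] + 1L
    }
    expect_equal(unname(counts), brute)
    expect_equal(rowSums(counts), tabulate(b$labels, 3), ignore_attr = TRUE)
    expect_equal(colSums(counts), tabulate(a$labels, 4), ignore_attr = TRUE)
    expect_equal(sum(counts), 20)
  })
})

test_that("identical partitions give a diagonal contingency table", {
  ids <- paste0("t", 1:9)
  labels <- setNames(rep(1:3, each = 3), ids)
  a <- structure(list(labels = labels, k = 3L, kind = "structural"),
                 class = "cluster_assignment")
  b <- structure(list(labels = labels, k = 3L, kind = "functional"),
                 class = "cluster_assignment")
  expect_equal(unname(overlap_counts(a, b)), diag(3) * 3)
  bad <- structure(list(labels = setNames(labels, paste0("x", 1:9)), k = 3L,
                        kind = "functional"), class = "cluster_assignment")
  expect_error(overlap_counts(a, bad), class = "tf_argument_error")
})

test_that("overlap enrichment normalizes by both cluster sizes", {
  expect_equal(round(overlap_enrichment(18, sizes_a = 338, sizes_b = 167), 1), 0.3,
               ignore_attr = TRUE)
  expect_equal(overlap_enrichment(18, 338, 167), 18 * 1000 / (167 * 338),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(overlap_enrichment(0, 10, 10), 0, ignore_attr = TRUE)
  n <- 7
  expect_equal(overlap_enrichment(n, n, n), 1000 / n, ignore_attr = TRUE)
  expect_error(overlap_enrichment(1, 0, 5), class = "tf_argument_error")
})

test_that("families partition the TAD set for arbitrary clustering pairs", {
  withr::with_seed(77, {
    for (rep in 1:50) {
      m <- sample(6:25, 1)
      ids <- paste0("t", seq_len(m))
      a <- random_assignment(ids, sample(2:min(5, m), 1))
      b <- random_assignment(ids, sample(2:min(4, m), 1), kind = "functional")
      fam <- define_families(a, b)
      members <- unlist(fam$members)
      expect_equal(sort(members), sort(ids))      # exhaustive
      expect_equal(anyDuplicated(members), 0L)    # disjoint
      expect_equal(sum(overlap_counts(a, b)), m)
      counts <- overlap_counts(a, b)
      enr <- overlap_enrichment(counts, tabulate(a$labels, a$k),
                                tabulate(b$labels, b$k))
      expect_equal(enr == 0, counts == 0, ignore_attr = TRUE)
      expect_true(all(diff(fam$n_members) <= 0))  # size-ordered
    }
  })
})

test_that("orthogonal balanced partitions yield the full product of families", {
  ids <- paste0("t", 1:8)
  a <- structure(list(labels = setNames(rep(1:2, each = 4), ids), k = 2L,
                      kind = "structural"), class = "cluster_assignment")
  b <- structure(list(labels = setNames(rep(1:2, times = 4), ids), k = 2L,
                      kind = "functional"), class = "cluster_assignment")
  fam <- define_families(a, b)
  expect_equal(nrow(fam), 4)
  expect_equal(fam$n_members, rep(2L, 4), ignore_attr = TRUE)
  fam_same <- define_families(a, a)
  expect_equal(nrow(fam_same), 2)  # families are the clusters themselves
})

test_that("family score is the fraction of enriched states", {
  expect_equal(family_score(rep(2, 25)), 1)
  expect_equal(family_score(rep(0.5, 25)), 0)
  expect_equal(family_score(c(rep(2, 13), rep(0.5, 12))), 0.52)
  expect_equal(family_score(c(rep(2, 13), rep(0, 12))), 0.52)  # F = 0 non-positive
})

test_that("planted cluster recovery attains ARI 1 noise-free and >= 0.9 noisy", {
  recover_ari <- function(noise_sd, seed) {
    co <- gen_cohort(cohort_spec(12, bins_range = c(40L, 40L),
                                 struct_classes = c(-0.5, -1, -1.5),
                                 noise_sd = noise_sd, seed = seed))
    structs <- lapply(names(co$matrices), function(id) {
      reconstruct_tad(co$matrices[[id]], seed = derive_seed(seed, "mds"))
    })
    names(structs) <- names(co$matrices)
    sim <- structural_similarity_matrix(structs)
    cl <- spectral_cluster(sim, 3, seed = seed)
    ari(cl$labels[names(co$true_struct)], co$true_struct)
  }
  expect_equal(recover_ari(0, seed = 1), 1)
  aris <- vapply(1:3, function(s) recover_ari(0.1, seed = s), numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("a depleted chromatin-state class concentrates in one structural cluster", {
  S <- 25
  mk <- function(idx) { p <- rep(0.1 / (S - length(idx)), S); p[idx] <- 0.9 / length(idx); p }
  classes <- list(mk(1:8), mk(9:17), c(rep(0, 24), 1))  # third: quiescent-only
  co <- gen_cohort(cohort_spec(12, bins_range = c(40L, 40L),
                               struct_classes = c(-0.5, -1, -1.5),
                               state_classes = classes, noise_sd = 0.05,
                               seed = 5))
  # round-robin with equal class counts aligns state class 3 with one
  # structural class by construction
  gs <- sum(co$segmentation$records$end - co$segmentation$records$start)
  structs <- lapply(names(co$matrices), function(id) {
    reconstruct_tad(co$matrices[[id]], seed = derive_seed(5, "mds"))
  })
  names(structs) <- names(co$matrices)
  cl_s <- spectral_cluster(structural_similarity_matrix(structs), 3, seed = 2)
  fes <- lapply(seq_len(12), function(i)
    fold_enrichment(co$tads[i, ], co$segmentation, gs))
  names(fes) <- co$tads$id
  cl_f <- spectral_cluster(functional_similarity_matrix(fes), 3, seed = 2)
  # find the functional cluster depleted of states (lowest pooled score)
  scores <- vapply(seq_len(cl_f$k), function(c) {
    mem <- names(cl_f$labels)[cl_f$labels == c]
    family_score(cluster_state_enrichment(co$tads[co$tads$id %in% mem, ],
                                          co$segmentation, gs))
  }, numeric(1))
  depleted <- names(cl_f$labels)[cl_f$labels == which.min(scores)]
  expect_lt(min(scores), 0.5)
  struct_of_depleted <- cl_s$labels[depleted]
  expect_gte(max(table(struct_of_depleted)) / length(depleted), 0.8)
})

test_that("average family heatmaps resize members to the common target", {
  co <- gen_cohort(cohort_spec(5, bins_range = c(30L, 30L), noise_sd = 0,
                               seed = 8))
  cm <- list(chr1 = co$chrom_matrix)
  # 30-bin member: identity of extraction
  t30 <- co$tads[2, ]
  h <- average_family_heatmap(t30, cm, target = 30)
  b0 <- t30$start / co$spec$bin_size
  idx <- (b0 + 1):(b0 + 30)
  expect_equal(h, log2(co$chrom_matrix$values[idx, idx] + 1))
  expect_equal(h[lower.tri(h)], t(h)[lower.tri(h)])  # symmetric

  # 60-bin member: 2 x 2 block averages (oracle computed independently)
  co60 <- gen_cohort(cohort_spec(3, bins_range = c(60L, 60L), noise_sd = 0.1,
                                 seed = 9))
  t60 <- co60$tads[2, ]
  h60 <- average_family_heatmap(t60, list(chr1 = co60$chrom_matrix), target = 30)
  sub <- co60$chrom_matrix$values[(60 + 1):120, (60 + 1):120]
  oracle <- matrix(0, 30, 30)
  for (i in 1:30) for (j in 1:30) {
    oracle[i, j] <- mean(sub[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)],
                         na.rm = TRUE)
  }
  expect_equal(h60, log2(oracle + 1), tolerance = 1e-12)

  # 28-bin member: extended one bin on each side
  co28 <- gen_cohort(cohort_spec(3, bins_range = c(28L, 28L), noise_sd = 0,
                                 seed = 10))
  t28 <- co28$tads[2, ]
  h28 <- average_family_heatmap(t28, list(chr1 = co28$chrom_matrix), target = 30)
  b0 <- t28$start / co28$spec$bin_size
  idx <- (b0 + 1 - 1):(b0 + 28 + 1)
  expect_equal(h28, log2(co28$chrom_matrix$values[idx, idx] + 1))
})

test_that("gene density counts any-overlap genes per bin", {
  t <- genomic_interval("chr1", 0, 1000, "t")
  genes <- rbind(genomic_interval("chr1", 10, 50, "g1"),
                 genomic_interval("chr1", 400, 600, "g2"),
                 genomic_interval("chr1", 950, 1100, "g3"),  # straddles end
                 genomic_interval("chr2", 0, 100, "g4"))
  expect_equal(gene_density(t, genes, bin_size = 100), 0.3)
  expect_equal(gene_density(t, genes[0, ], bin_size = 100), 0)
  expect_error(gene_density(t, genes, bin_size = 0), class = "tf_argument_error")
})
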