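#' Write a synthetic cohort to a directory
#'
#' Materializes a generated cohort in the package's on-disk formats:
#' per-TAD contact matrices as COO triplets, TAD intervals as BED,
#' the segmentation as BED4, planted class labels as TSV, and the cohort
#' parameters as a YAML config.
#'
#' @param cohort Output of [gen_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "matrices"), showWarnings = FALSE)
  for (id in names(cohort$matrices)) {
    write_contact_matrix_coo(cohort$matrices[[id]],
                             file.path(dir, "matrices", paste0(id, ".coo")))
  }
  write_intervals(cohort$tads, file.path(dir, "tads.bed"))
  write_segmentation(cohort$segmentation, file.path(dir, "segmentation.bed"))
  truth <- data.frame(tad_id = names(cohort$true_struct),
                      struct_class = cohort$true_struct,
                      state_class = cohort$true_state)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sp <- cohort$spec
  yaml::write_yaml(
    list(n_tads = sp$n_tads, bins_range = sp$bins_range,
         struct_classes = sp$struct_classes,
         state_classes = lapply(sp$state_classes, as.numeric),
         noise_sd = sp$noise_sd, seed = sp$seed, bin_size = sp$bin_size,
         resolution = sp$resolution, scale = sp$scale),
    file.path(dir, "cohort.yaml")
  )
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param state_labels State universe for the segmentation.
#' @return List with `matrices`, `tads`, `segmentation`, `truth`.
#' @export
read_cohort <- function(dir, state_labels = roadmap25_labels()) {
  tads <- read_intervals(file.path(dir, "tads.bed"))
  cfg <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  matrices <- lapply(seq_len(nrow(tads)), function(i) {
    read_contact_matrix(
      file.path(dir, "matrices", paste0(tads$id[i], ".coo")),
      format = "coo", bin_size = cfg$bin_size, origin = tads[i, ]
    )
  })
  names(matrices) <- tads$id
  seg <- read_segmentation(file.path(dir, "segmentation.bed"), state_labels)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    read.table(truth_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  } else NULL
  list(matrices = matrices, tads = tads, segmentation = seg, truth = truth,
       config = cfg)
}

#' Run the full TAD family pipeline
#'
#' Reconstruct every TAD (rescale, wish distances, MDS), compute per-TAD
#' statistics, build structural (TM-score) and functional (absolute
#' fold-enrichment correlation) similarity matrices, spectrally cluster
#' both, intersect the clusterings into families with pooled-enrichment
#' scores, and (when chromosome-wide matrices are available) average
#' family heatmaps. All randomness derives from the single `seed` via
#' per-stage derived seeds, so re-running with the same config reproduces
#' every output.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `cohort_dir` (a directory written by [write_cohort()]) *or* in-memory
#'   `matrices`, `tads`, `segmentation`; optional `genome_size`
#'   (default: total segmented bases), `lo`/`hi` rescale range (1, 30),
#'   `k_struct` (3), `k_func` (2), `seed` (1), `out_dir` (no files
#'   written when `NULL`), `chrom_matrices` (for family heatmaps),
#'   `heatmap_target` (30).
#' @return A list: `structures`, `stats`, `struct_sim`, `func_sim`,
#'   `clusters` (`structural`, `functional`), `counts`, `enrichment`,
#'   `families` (with `score` column), `heatmaps`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(lo = 1, hi = 30, k_struct = 3L, k_func = 2L, seed = 1L,
                   heatmap_target = 30L, out_dir = NULL, genome_size = NULL,
                   chrom_matrices = NULL)
  config <- modifyList(defaults, config)
  if (!is.null(config$cohort_dir)) {
    co <- read_cohort(config$cohort_dir)
    config$matrices <- co$matrices
    config$tads <- co$tads
    config$segmentation <- co$segmentation
  }
  mats <- config$matrices
  tads <- config$tads
  seg <- config$segmentation
  seed <- config$seed
  n <- length(mats)
  if (config$k_struct > n || config$k_func > n) {
    tf_stop("tf_argument_error",
            "stage clustering: k exceeds the %d TADs", n)
  }
  ids <- tads$id
  log_stage <- function(fmt, ...) message(sprintf(paste0("[tadfam] ", fmt), ...))

  log_stage("reconstructing %d TADs", n)
  # one shared embedding seed across TADs: identical contact matrices
  # must reconstruct to identical structures for TM-scores to compare them
  mds_seed <- derive_seed(seed, "mds")
  structures <- lapply(seq_len(n), function(i) {
    reconstruct_tad(mats[[ids[i]]], seed = mds_seed,
                    lo = config$lo, hi = config$hi)
  })
  names(structures) <- ids
  stats <- data.frame(
    tad_id = ids,
    exponent = vapply(structures, attr, 0, "exponent"),
    rg = vapply(structures, attr, 0, "rg"),
    row.names = NULL
  )

  log_stage("structural similarity (%d pairs)", n * (n - 1) / 2)
  struct_sim <- structural_similarity_matrix(structures)

  log_stage("fold enrichment and functional similarity")
  genome_size <- config$genome_size
  if (is.null(genome_size)) {
    genome_size <- sum(seg$records$end - seg$records$start)
  }
  fes <- lapply(seq_len(n), function(i) {
    fold_enrichment(tads[i, ], seg, genome_size)
  })
  names(fes) <- ids
  func_sim <- functional_similarity_matrix(fes)

  log_stage("spectral clustering (k_struct=%d, k_func=%d)",
            config$k_struct, config$k_func)
  cl_struct <- spectral_cluster(struct_sim, config$k_struct,
                                seed = derive_seed(seed, "cluster_struct"))
  cl_func <- spectral_cluster(func_sim, config$k_func,
                              seed = derive_seed(seed, "cluster_func"))

  counts <- overlap_counts(cl_struct, cl_func)
  enrich <- overlap_enrichment(counts, cluster_sizes(cl_struct),
                               cluster_sizes(cl_func))
  families <- define_families(cl_struct, cl_func)
  families$score <- vapply(families$members, function(mem) {
    family_score(cluster_state_enrichment(tads[tads$id %in% mem, ], seg,
                                          genome_size))
  }, 0)

  heatmaps <- NULL
  if (!is.null(config$chrom_matrices)) {
    log_stage("family heatmaps")
    heatmaps <- lapply(seq_len(nrow(families)), function(i) {
      average_family_heatmap(tads[tads$id %in% families$members[[i]], ],
                             config$chrom_matrices,
                             target = config$heatmap_target)
    })
    names(heatmaps) <- families$family_id
  }

  manifest <- list(
    package = "tadfam",
    version = as.character(utils::packageVersion("tadfam")),
    seed = seed,
    n_tads = n,
    k_struct = config$k_struct, k_func = config$k_func,
    rescale = c(config$lo, config$hi),
    genome_size = genome_size,
    n_families = nrow(families),
    stage_counts = list(structures = length(structures),
                        similarity_dim = dim(struct_sim),
                        families = nrow(families))
  )

  out <- list(structures = structures, stats = stats,
              struct_sim = struct_sim, func_sim = func_sim,
              clusters = list(structural = cl_struct, functional = cl_func),
              counts = counts, enrichment = enrich, families = families,
              heatmaps = heatmaps, manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(res$stats, file.path(out_dir, "stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(res$struct_sim, file.path(out_dir, "struct_sim.tsv"))
  write_matrix_tsv(res$func_sim, file.path(out_dir, "func_sim.tsv"))
  assign_df <- data.frame(
    tad_id = names(res$clusters$structural$labels),
    struct_cluster = unname(res$clusters$structural$labels),
    state_cluster = unname(res$clusters$functional$labels[
      names(res$clusters$structural$labels)])
  )
  write.table(assign_df, file.path(out_dir, "assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(res$counts, file.path(out_dir, "counts.tsv"))
  write_matrix_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"),
                   digits = 1)
  fam <- res$families
  fam_long <- do.call(rbind, lapply(seq_len(nrow(fam)), function(i) {
    data.frame(family_id = fam$family_id[i],
               struct_cluster = fam$struct_cluster[i],
               state_cluster = fam$state_cluster[i],
               tad_id = fam$members[[i]],
               score = fam$score[i])
  }))
  write.table(fam_long, file.path(out_dir, "families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$heatmaps)) {
    dir.create(file.path(out_dir, "heatmaps"), showWarnings = FALSE)
    for (id in names(res$heatmaps)) {
      h <- res$heatmaps[[id]]
      dimnames(h) <- list(paste0("b", seq_len(nrow(h))),
                          paste0("b", seq_len(ncol(h))))
      write_matrix_tsv(h, file.path(out_dir, "heatmaps", paste0(id, ".tsv")))
    }
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
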