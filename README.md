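# tadfam

Classification of topologically associating domains (TADs) into
structural and functional families from Hi-C contact matrices and
chromatin-state segmentations.

TADs are megabase-scale genomic intervals with enriched internal Hi-C
contacts. Two TADs can resemble each other in their three-dimensional
fold and, independently, in the chromatin states their DNA carries.
`tadfam` measures both: it reconstructs a 3D bead model per TAD,
clusters TADs by structural and by chromatin-state similarity, and
defines **families** as the intersections of the two clusterings —
giving each family an enrichment score, an averaged contact heatmap,
and cross-cell-type pairings. It is aimed at 3D-genome researchers who
want to relate TAD architecture to regulatory state, and it ships a
synthetic-data generator with planted ground truth so the whole pipeline
is testable end to end without external downloads.

## Method

For each TAD with contact submatrix *c*:

1. **Wish distances.** Observed contacts are rescaled linearly to
   [1, 30], then converted by *d* = (1/*c*)^(1/3): more contacts, shorter
   target distance. The diagonal is masked (self-distance is 0 by
   definition).
2. **3D reconstruction.** Weighted metric MDS (SMACOF stress
   majorization, zero weight on missing pairs) embeds the wish distances
   in 3D; a t-SNE alternative with minimum-RMSD grid selection is
   provided. Each structure gets two statistics: the contact-decay
   **exponent** (log-log slope of mean contact vs. genomic distance) and
   the **radius of gyration** (compactness); a good reconstruction shows
   a negative correlation between the two across TADs.
3. **Structural similarity.** TM-score between bead chains, normalized
   by the smaller length, maximized over order-preserving
   correspondences and rigid transforms (reflection allowed), with
   d0(L) = max(0.5, 1.24·(L−15)^(1/3) − 1.8) after rescaling chains to a
   3.8-unit mean bond.
4. **Functional similarity.** Per-TAD fold enrichment of each chromatin
   state, F_s = (in-TAD density of s)/(genome-wide density of s);
   similarity is |Pearson r| between two TADs' enrichment vectors.
5. **Clustering and families.** Normalized-Laplacian spectral clustering
   of both similarity matrices (conventional grids: k ∈ {10, 20, 30}
   functional, k ∈ {2, 3, 5, 10} structural); families are the non-empty
   cluster intersections, scored by the fraction of states with
   log2 F_s > 0 (score < 0.5 flags a state-depleted family), and
   summarized by 30 × 30 averaged heatmaps (smaller TADs extended into
   flanking bins, larger ones block-averaged).

Genes and lncRNAs map onto TADs by any-overlap; lncRNA identifiers from
multiple catalogs are unified by same-strand overlap with transitive
closure. TADs occupying identical coordinates in two cell types are
paired and compared by signed enrichment correlation and TM-score.

## Worked example

Generate a 12-TAD synthetic cohort with three planted decay classes and
three planted chromatin-state classes, then run the full pipeline:

```r
library(tadfam)

spec <- cohort_spec(n_tads = 12, bins_range = c(40L, 40L),
                    noise_sd = 0.1, seed = 7)
co <- gen_cohort(spec)

res <- run_pipeline(list(
  matrices = co$matrices, tads = co$tads, segmentation = co$segmentation,
  k_struct = 3, k_func = 3, seed = 1
))

res$counts
#>       stru1 stru2 stru3
#> func1     4     0     0
#> func2     0     4     0
#> func3     0     0     4

round(res$enrichment, 1)
#>       stru1 stru2 stru3
#> func1   250     0     0
#> func2     0   250     0
#> func3     0     0   250

res$families
#> family_table: 3 families over 12 TADs
#>   family_id struct_cluster state_cluster n_members score
#> 1      F001              1             1         4  0.32
#> 2      F002              2             2         4  0.36
#> 3      F003              3             3         4  0.32

head(res$stats, 3)
#>   tad_id   exponent        rg
#> 1 TAD001 -0.4985806 0.4245098
#> 2 TAD002 -0.9998936 0.4989487
#> 3 TAD003 -1.4983983 0.5747696
```

Reading the output: the contingency table (`counts`) shows each
chromatin-state cluster shares all four of its TADs with exactly one
structural cluster — the planted classes were assigned in lockstep, and
both clusterings recovered them. `enrichment` is the size-normalized
overlap (1000·count / (size_func · size_struct); here 1000·4/(4·4) =
250). Each family's score is the fraction of the 25 chromatin states
enriched among its members (all three families occupy a narrow state
block, hence scores near 8/25). The fitted exponents recover the planted
decay classes (−0.5, −1, −1.5), and the radius of gyration increases as
decay steepens — the negative exponent/Rg association expected of a
sound reconstruction.

A command-line interface wrapping the same functions is installed at
`inst/scripts/tadfam`
(`tadfam <simulate|reconstruct|structsim|enrich|families|acrosscells|annotate|run>`).

## Documentation

The methods vignette (`vignettes/tad-families.Rmd`) describes the model
and its assumptions, every tunable parameter with units and defaults,
what the synthetic generator does and does not emulate, numerical
choices, and known limitations.
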