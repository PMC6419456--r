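---
title: "Classifying TADs into structural and functional families"
author: "tadfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying TADs into structural and functional families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadfam)
```

## The problem

Topologically associating domains (TADs) are megabase-scale intervals of
the genome whose interior shows enriched Hi-C contact frequency. Two TADs
can resemble each other in two largely independent ways: their
three-dimensional fold, and the chromatin states their DNA carries. This
package groups the TADs of one cell type along both axes at once: it
reconstructs a 3D bead model per TAD from its Hi-C submatrix, scores
pairwise structural similarity with a TM-score, scores functional
similarity as the absolute correlation of chromatin-state fold-enrichment
profiles, spectrally clusters both similarity matrices, and defines a
*family* as the set of TADs shared by one structural cluster and one
chromatin-state cluster. Families come with an enrichment score, an
averaged 30 x 30 contact heatmap, and cross-cell-type pairings.

## The model, stage by stage

### Contacts to wish distances

Raw contact scales differ between experiments, and the cube-root
conversion below is sensitive to that scale. Each TAD's observed
off-diagonal contacts are therefore first mapped affinely onto
$[1, 30]$ (`rescale_contacts()`; the lower bound of 1 guarantees
positive contacts). Rescaled contacts $c$ become *wish distances*

$$d = (1/c)^{1/3},$$

so the most-contacted pair sits at distance $(1/30)^{1/3} \approx 0.32$
and the least-contacted at $1$. The diagonal is masked throughout:
self-distance is 0 by definition, never derived from a contact value.
Zeros in a dense matrix are observed zeros; only `NA`/`nan` tokens and
unlisted coordinate pairs are treated as missing. A TAD whose observed
contacts are constant is rejected rather than silently filled — such a
matrix carries no distance information.

### Embedding

`embed_mds()` fits the 3-component configuration minimizing the weighted
stress $\sum_{ij} w_{ij}(d_{ij} - \lVert x_i - x_j\rVert)^2$ by SMACOF
majorization, with $w_{ij} = 0$ on missing pairs (they exert no force,
rather than being imputed into the objective). The first start is always
the deterministic classical-MDS (Torgerson) configuration; additional
seeded random restarts (default `n_init = 4`) guard against poor local
minima, and the lowest-stress restart wins. Beads whose observation graph
is disconnected cannot be placed relative to each other and raise an
error.

Wish-distance sets are generally *frustrated* — not realizable in 3D —
so the stress landscape has several near-equal minima that differ
structurally. Two conventions keep embeddings comparable across a
cohort: one shared seed is used for every TAD of a run, and
`reconstruct_tad()` folds a content fingerprint of the matrix into that
seed, so identical matrices always produce identical structures while
distinct matrices draw independent restarts.

A t-SNE embedding (`embed_tsne_selected()`) is provided for comparison.
Because t-SNE output depends strongly on perplexity and learning rate,
one candidate is produced per grid point (defaults: perplexity
$\{5, 10, 30, 50\} \cap [2, n-1]$, learning rate
$\{10, 100, 200, 1000\}$), each candidate is rigidly superposed onto a
reference structure (rotation, translation, reflection allowed — an
embedding has no intrinsic chirality — but *no* scaling), and the
minimum-RMSD candidate is returned together with the full selection
table. MDS structures are the default for all downstream similarity:
across synthetic cohorts the MDS radii of gyration correlate negatively
with the contact-decay exponents, the consistency a good reconstruction
should show, whereas t-SNE structures are much less consistent.

### Structure statistics

Two per-TAD statistics summarize the 2D and 3D views:

* the **exponent parameter** (`exponent_parameter()`): the least-squares
  slope of $\log P(s)$ against $\log s$, where $P(s)$ is the mean
  observed contact at bin separation $s$; separations with $P(s) = 0$
  are excluded and the fit is unweighted. On an exact power law
  $c = |i-j|^{\alpha}$ the estimator returns $\alpha$ to machine
  precision.
* the **radius of gyration** (`radius_of_gyration()`): root-mean-square
  bead distance to the centroid.

Steeper decay (more negative exponent) leaves distant bin pairs near the
maximum wish distance, producing extended, high-Rg structures; shallow
decay produces compact ones. The package's consistency check
(`evaluate_consistency()`) reports Pearson and Spearman correlations
between the two vectors and expects the negative sign.

### Structural similarity: TM-score over bead chains

`tm_score()` computes

$$\mathrm{TM}(a, b) = \max \frac{1}{L_{\min}}
  \sum_{i \in \text{matched}} \frac{1}{1 + (d_i / d_0(L_{\min}))^2},$$

maximized over sequence-order-preserving correspondences and rigid
transforms (reflection allowed), with $L_{\min}$ the smaller bead count
and $d_0(L) = \max\{0.5,\; 1.24 (L - 15)^{1/3} - 1.8\}$. The score is
normalized by the smaller structure, which makes it symmetric in its
arguments. Because $d_0$ is calibrated for protein C-alpha chains, both
chains are first rescaled so their mean consecutive-bead distance is 3.8
units; this keeps the tolerance commensurate while preserving each
structure's compactness relative to its own backbone.

The search is heuristic, in the TM-align mold: superpositions are seeded
from corresponding fragments of length $\max(5, L_{\min}/2)$, each
followed by alternating rigid superposition of the matched set and
dynamic-programming (monotone, free-gap) correspondence refinement until
the matched set stabilizes, plus a polishing pass that re-superposes on
close-pair subsets at several distance cutoffs. The returned value is the
running maximum of the matching score over *every* transform visited —
scoring only the converged full-set RMSD fit demonstrably undershoots the
optimum. The test suite checks the search against exhaustive enumeration
of all order-preserving correspondences (with per-correspondence
least-RMSD superposition) on 10-bead toys; agreement is exact in the
near-identical regime where the full correspondence dominates. Outside
that regime both quantities are lower bounds of the true maximum and the
iterative search can legitimately exceed the enumeration.

One practical regime note: $d_0(L)$ sits at its 0.5 floor for
$L \lesssim 21$ beads, where the score becomes an extremely strict,
nearly length-independent criterion and loses discriminative power for
noisy reconstructions. Structural clustering is reliable for TADs of
roughly 30 bins and above (1.2 Mb at 40 kb resolution); the package's
recovery tests use 40-bin TADs, where planted decay classes are
recovered perfectly.

### Functional similarity: chromatin-state fold enrichment

For a TAD $t$ and state $s$, `fold_enrichment()` computes the density
ratio

$$F_s = \frac{\text{bases of } s \text{ in } t \,/\, |t|}
             {\text{bases of } s \text{ genome-wide} \,/\, G},$$

with $G$ the genome size; $F_s = 1$ means the TAD mirrors the genome.
All overlap arithmetic is base-pair exact (GenomicRanges), not binned.
Bases of $t$ covered by no record count toward $|t|$ but no state;
states absent genome-wide get $F_s = 0$. Functional similarity between
two TADs is $|r|$, the absolute Pearson correlation of their two
fold-enrichment vectors over the full state set (computed on raw fold
values; log2 is used only for display and scoring). A constant vector has
no defined correlation and is assigned similarity 0. Cross-cell-type
comparisons (`across_cell_similarity()`) keep the *signed* correlation
instead — there the sign distinguishes concordant from discordant state
usage, and the observed distributions extend toward negative values.

### Clustering, families, scores, heatmaps

`spectral_cluster()` follows the normalized-Laplacian recipe: the
similarity matrix is the affinity, rows of the top-$k$ eigenvector matrix
of $D^{-1/2} A D^{-1/2}$ are unit-normalized and partitioned by seeded
k-means (20 starts). Cluster indices as such are arbitrary, so labels are
renumbered by decreasing cluster size — the only ordering that is
reproducible across runs and implementations. The conventional grids are
$k \in \{10, 20, 30\}$ for chromatin-state clustering and
$k \in \{2, 3, 5, 10\}$ for structural clustering.

`overlap_counts()` tabulates shared TADs between the two clusterings
(chromatin-state clusters on rows, structural on columns — the
orientation is this package's contract). `overlap_enrichment()` divides
each count by both cluster sizes and scales by 1000, making the value
insensitive to cluster size; display rounds to one decimal (the worked
example: 18 shared TADs between clusters of 167 and 338 give
$1000 \cdot 18 / (167 \cdot 338) = 0.319 \to 0.3$) while computation
keeps full precision.

`define_families()` intersects the two partitions: one family per
non-empty cluster pair, so families are disjoint and exhaustive by
construction. The family score is the fraction of states with
$\log_2 F_s > 0$, computed on the *family's own members* pooled
(overlap bases and lengths summed before the ratio); a score below 0.5
flags a family depleted of chromatin states. The alternative — scoring
the whole chromatin-state cluster — is a one-line change but couples
every family in a cluster to the same score, so the member-pooled
variant is the default.

`average_family_heatmap()` brings every member to a common 30 x 30 size
before averaging: members at exactly 30 bins contribute their chromosome
submatrix; smaller members are extended symmetrically into flanking
chromosome bins (an odd remainder extends downstream; extension beyond a
chromosome end is clipped and completed on the other side, with a
warning); larger members have their bins partitioned into 30 contiguous,
maximally even groups and block-averaged. "Evenly extending" is read as
flank extension in the real chromosome matrix, not interpolation, and
"evenly reducing" as contiguous block-averaging. The family heatmap is
the elementwise mean over members (missing entries excluded), displayed
as $\log_2(\text{mean} + 1)$ — the pseudocount fixes the behaviour at
zero, which a bare "log2 scale" leaves undefined.

### Annotation

Genes and lncRNAs map onto TADs by any-overlap (>= 1 bp, strand
ignored); a feature spanning a boundary belongs to every TAD it touches.
Identifier unification across lncRNA catalogs merges records from
*different* catalogs that overlap by >= 1 bp on the same chromosome *and
strand* (opposite-strand transcripts are distinct genes), closing groups
transitively; per-TAD counts then count one alias group once. Inputs
must already share one genome build.

## The synthetic cohort generator

`gen_cohort()` plants recoverable ground truth so every downstream stage
is testable without external downloads:

* **Contacts.** Off-diagonal entry $(i, j)$ has expectation
  $\mathrm{scale} \cdot |i-j|^{\alpha}$; each structural class is one
  decay exponent $\alpha \le 0$ (defaults $\{-0.5, -1, -1.5\}$, spanning
  shallow to steep decay). Noise is multiplicative log-normal with the
  given log-sd and mean corrected so the expectation is exact; the
  multiplicative form keeps contacts positive, which the wish-distance
  conversion requires. Distance-0 contacts are never generated — the
  diagonal is masked and $|i-j|$ floored at 1.
* **Segmentations.** The chromosome is tiled at 200 bp (the ChromHMM
  convention); each tile draws its state from the profile of the TAD
  containing it. Default state classes are three disjoint blocks of the
  25-state universe (promoter/TSS, transcription/enhancer,
  heterochromatin/quiescent). At least three classes are necessary for
  the functional side to be recoverable at all: with exactly two
  classes, per-TAD enrichment deviations from the genome mixture are
  exact mirror images of each other, so $|r|$ is close to 1 for *every*
  pair and carries no class signal. This is a property of
  absolute-correlation similarity, not of the generator.
* **Assignment.** Classes are assigned round-robin (TAD $i$ gets
  structural class $((i-1) \bmod n_s) + 1$ and state class
  $((i-1) \bmod n_f) + 1$) so tiny cohorts stay balanced; with coprime
  class counts the cohort cycles through every (structural, state) pair,
  which is how the family-recovery tests obtain orthogonal partitions.
* **Determinism.** Every generator is a pure function of its arguments
  including the seed.

What the generator does *not* emulate: KR-normalization artifacts,
translocations or other structural variation, single-cell sparsity,
distance-dependent noise correlation, and inter-TAD contacts (the
chromosome-wide matrix is block-diagonal with the gaps masked). Passing
tests therefore demonstrate that the pipeline recovers planted signal
under idealized power-law decay; they do not establish performance on
real Hi-C with its correlated noise and unmodeled structure.

## Default parameters

| Parameter | Default | Where | Why |
|---|---|---|---|
| rescale range | [1, 30] | `rescale_contacts` | positive contacts; fixed dynamic range for the cube-root conversion |
| wish exponent | 1/3 | `contacts_to_wish_distances` | volume-scaling argument behind $d \sim c^{-1/3}$ |
| MDS restarts | 4 (first = Torgerson) | `embed_mds` | deterministic start plus escape from local minima |
| bond target | 3.8 units | `tm_score` | makes protein-calibrated $d_0$ commensurate with bead chains |
| $d_0$ | $\max(0.5, 1.24(L-15)^{1/3}-1.8)$ | `tm_score` | the standard TM-score length normalization |
| k grids | func {10, 20, 30}, struct {2, 3, 5, 10} | `heatmap_configurations` | the conventional predefined cluster counts |
| heatmap size | 30 x 30 | `average_family_heatmap` | common target size for family averaging |
| bin size | 40 kb | `cohort_spec` | typical TAD-reconstruction resolution |
| segmentation tile | 200 bp | `cohort_spec` | ChromHMM segment granularity |
| enrichment scale | 1000 | `overlap_enrichment` | readable 1-decimal display |

## Numerical choices and degenerate inputs

* Convergence: SMACOF stops when the relative stress decrease falls
  below `tol` (1e-9) or after `max_iter` (300) iterations.
* Ties in cluster-size relabeling break by first occurrence; family
  ordering ties break by (structural, state) index.
* `kmeans` uses 20 restarts under the stage seed; all stage seeds derive
  from the single pipeline seed by name hashing (`derive_seed()`), so
  stages can be re-run in isolation and reproduce the pipeline.
* Degenerate inputs raise classed errors rather than silently
  propagating: constant contact matrices, non-positive contacts at the
  wish-distance step, disconnected observation graphs, empty parameter
  grids, k larger than the cohort, zero-variance vectors in correlation.
* A TAD with no segmentation overlap yields an all-zero enrichment
  vector with a warning; a constant fold-enrichment vector yields
  functional similarity 0 (within-cell) or a missing value with a
  warning (cross-cell).

## Problem sizes in the test suite

The suite validates on scaled-down cohorts chosen to exercise every code
path quickly: 12-TAD cohorts with 40-bin TADs for cluster recovery,
30-TAD mixed-size cohorts (15-25 bins) for the exponent/Rg consistency
check, 10-bead toys for exhaustive TM-score enumeration
($\binom{20}{10}$-scale correspondence spaces are enumerable there), and
50 random partition pairs for the family-partition property.

## Known limitations

* The exponent estimator (unweighted log-log fit on mean contacts per
  separation) is one reasonable choice among several; distance-range
  restriction or weighting would give slightly different values.
* The TM-score search is a heuristic; its optimum-matching guarantee is
  empirical (oracle tests), not proven.
* Applying a protein-calibrated $d_0$ to chromatin beads required a
  scale convention (3.8-unit mean bond); scores for chains shorter than
  ~25 beads are dominated by the $d_0$ floor and should not be
  interpreted comparatively.
* Functional similarity by $|r|$ cannot distinguish anti-correlated
  state profiles; this is inherited from the similarity definition.
* Fold enrichment is base-pair exact; a tool binarizing at 200 bp would
  differ at region edges.
* Cross-cell matching is exact-coordinate only; reciprocal-overlap
  matching across slightly shifted TAD calls is out of scope, as are
  Hi-C normalization, TAD calling, and genome-build conversion.
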