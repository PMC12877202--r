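---
title: "Localization of chip-tagged nuclei and the spatial statistics built on it"
author: "nuclocate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localization of chip-tagged nuclei and the spatial statistics built on it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuclocate)
```

## The measurement model

A spatial-tagging chip is a sequencing flow cell whose clusters carry
cleavable 32-mer oligonucleotide barcodes. Sequencing the chip yields a
whitelist mapping each barcode to the pixel coordinate of its cluster, at a
pitch of roughly 6.2 px (1.64 µm at the 0.265 µm/px pitch this package
fixes as a single constant, `PIXEL_PITCH_UM`). When a tissue section is
laid on the chip, barcodes are cleaved and diffuse into overlying cells,
tagging nuclei; nuclei are extracted, split across eight multiplex tubes,
and processed in droplets. Each captured nucleus — identified by its
(multiplex tube, droplet) pair, the `cell_id` — therefore carries a cloud
of spatial-barcode UMIs whose chip coordinates are noisy evidence of where
it sat.

Localization must contend with four noise processes: sequencing errors in
barcodes, rare chip-synthesis duplications placing one barcode at two
coordinates, barcodes that detach and get re-encapsulated everywhere
("prevalent" barcodes), and droplets containing more than one nucleus or
debris. The pipeline addresses them in order.

## Barcode resolution

Observed barcodes absent from the whitelist are corrected if exactly
reachable by one substitution: among multiple Hamming-distance-1 whitelist
candidates, the one with the highest read support wins. Two deliberate
choices: ties among equally supported candidates are dropped rather than
broken arbitrarily (determinism over yield), and read support is measured
as the summed UMI support each whitelist barcode has in the observed count
table, the only notion of "read counts" available at this stage. Only
substitutions are considered; indels are not part of the error model.
Barcodes observed at more than one chip coordinate are removed wholesale —
with two candidate positions there is no principled way to keep either.

Detached barcodes are removed by a bin-thresholding procedure: the chip is
tiled with 30 px bins, per-bin UMI totals are computed, and any bin whose
total strictly exceeds `k = 20` times the mean per-bin total is flagged;
for each flagged bin the cell with the highest UMI support in that bin is
removed together with all its barcodes, and the procedure iterates until no
bin exceeds the threshold. Two ambiguities are resolved explicitly and kept
configurable: "average UMI count within each bin" is read as the mean of
per-bin totals over non-empty bins (`mean_mode = "bin_total"`, with a
per-barcode alternative), and the filter iterates to convergence by default
(`single_pass = TRUE` gives the one-shot variant, `max_iter` caps the
loop). Bins are half-open intervals anchored at the chip origin. The
threshold scales with the mean, so flagging is invariant to a global
rescaling of UMIs; each iteration removes at least one cell, so termination
is bounded by the number of cells.

## Center classification and position assignment

For each cell with at least 2 spatial-barcode UMIs (cells below that are
reported unclassifiable), UMIs are summed in 100 px (26.5 µm) bins. The
*core center* is the maximal bin and the *core* its 5×5 block; the
*secondary center* is the best bin outside the core, with its own 5×5
block. The ratio of core to secondary-block UMI classifies the footprint:
ratio ≥ 10 unique center, ≥ 2 major center, < 2 multiple centers
(discarded as two nuclei / debris sharing a droplet). Implementation
details that the classification rule does not itself fix: maximal-bin ties
break to the lexicographically smallest (row, col); the secondary block may
overlap the core (each block is defined by its own center; no exclusion
rule is imposed); blocks at the chip border are truncated to existing bins;
and a footprint with no bin outside the core has infinite ratio and is
unique by construction.

Cells with a unique or major center are assigned the position minimizing
the UMI-weighted sum of Euclidean distances to the core barcodes,

$$\hat p = \arg\min_{p \in C}\; \sum_b u_b \, \lVert p - p_b \rVert,$$

the weighted geometric median restricted to a candidate set $C$. The
default candidate set is the observed barcode positions inside the core
("nearest spatial point" semantics); ties break to the lexicographically
smaller coordinate. Diffusion QC reports the UMI-weighted 50/75/95%
quantiles of barcode-to-assigned-position distance; each UMI counts as one
observation and the q-quantile is the distance at which the cumulative UMI
fraction first reaches q. Quantiles use core barcodes by default
(`quantile_scope = "all"` widens to every detected barcode; the narrower
default matches the core-restricted distance definition used for
assignment). An optional tissue polygon mask drops nuclei assigned outside
the section.

`demux_recovery()` quantifies what multiplexing buys: collapsing the 8
tubes into k contiguous groups re-merges cells that share (group, droplet),
re-runs localization, and counts unique/major cells. Merging co-droplet
nuclei produces multi-center footprints, so recovery grows with k; the
acceptance suite checks the ordering on simulations with collision rates
0.05 and 0.2.

## Benchmarking against ground truth

Predicted positions are compared with reference centroids after a
least-squares control-point transform — full 6-dof affine by default, with
a `similarity = TRUE` restriction to rotation+scale+shift since the
appropriate family depends on how the reference image was acquired.
Matching is one-to-one by a globally-shortest-first greedy rule: all
cross distances sorted ascending, pairs accepted while both ends are
unused. This guarantees unique pairings deterministically; it is not the
optimal assignment, but on small cases (tested) it coincides, and its
offset multiset is invariant to input order. A uniform random baseline with
the same matching provides the reference scale: on synthetic tissue at
2 µm diffusion the method's median offset is below 4 µm and the baseline's
is many times larger. Marker-level concordance uses the overlap ratio
|A∩B| / max(|A|, |B|) of expressing cells (raw count > 0) per marker pair,
correlated between platforms with Pearson's r.

## Spatial statistics

**Ro/e** divides observed cluster-by-group counts by chi-square expected
counts (`chisq.test` expectations); entries above 1 mean enrichment, and
cells with zero expectation are reported NaN rather than imputed.

**PCCF** is the ratio of observed (type a, type b) pairs within 30 µm
(inclusive) to the mean pair count over label permutations. Permuting
labels over fixed positions is the conditional-on-pattern null: it
preserves the tissue's spatial structure and tests only the assignment of
types to positions. Same-type pairs are unordered and exclude self-pairs.
The pair search uses a grid-bucket index whose results are contract-tested
to equal the all-pairs computation. A two-sided empirical p-value based on
the (1 + exceedances)/(1 + permutations) estimator accompanies the ratio;
under complete spatial randomness the acceptance suite checks a mean PCCF
within [0.97, 1.03] and a false-positive rate compatible with the nominal
5% over 500 simulated tissues.

**Radial profiles** report per-type mean distances to a niche centroid
(arithmetic mean of member coordinates), e.g. to order cell types around an
immune aggregate core.

## Districting

Each cell is summarized by the cell-type proportions among its neighbors
within 30 µm (self excluded); isolated cells carry no information and are
dropped, reported. These simplex vectors are node features on the Delaunay
triangulation of the featured cells (collinear degenerate inputs fall back
to a kNN graph, flagged). A mean-aggregation graph network in the GraphSAGE
family embeds the nodes:

$$H^{(l)} = \mathrm{relu}\!\left(M H^{(l-1)} W_n^{(l)} + H^{(l-1)} W_s^{(l)} + b^{(l)}\right),$$

with $M$ the row-normalized adjacency and the final layer linear; the
self-term keeps each cell's own composition in play. Training is
unsupervised: per epoch each node draws one graph neighbor as positive and
`n_negatives = 5` random nodes, minimizing a negative-sampling proximity
loss plus `lam = 0.3` times an InfoNCE contrastive term with temperature
`tau = 0.3`. The contrastive similarity is the embedding dot product —
chosen over cosine for its simpler, better-conditioned gradient.
Optimization is Adam at learning rate 0.001 for 150 epochs with dropout
0.25 on hidden activations; hidden/output widths default to 64/32. All
randomness (initialization, sampling, dropout, clustering) flows from one
seed, and `find_districts()` canonicalizes cell order first, so district
partitions are identical under input permutation.

Districts are Leiden communities (modularity objective) of the kNN graph of
embeddings. The resolution default is 0.1 with k = 30: on sparse kNN
graphs, modularity at resolution near 1 resolves micro-communities of
roughly √n scale rather than tissue districts — on planted-niche
benchmarks it fragments both embeddings and raw features into 10–20
clusters — while resolutions in the 0.02–0.2 range recover the planted
partition exactly. The raw-composition baseline (Leiden directly on
features) is kept as a guard: if the embedding ever underperforms it on
planted niches, the embedding, not the benchmark, is at fault.

## Ligand–receptor screening

Candidates are (ligand, receptor, sender type, receiver type) tuples kept
when the ligand is detected in ≥ 10 sender cells, or in ≥ 10% of senders
with the receptor in ≥ 10% of receivers. The spatial correlation index is

$$\mathrm{SCI} = \frac{\sum_{ij} w_{ij}\, \tilde l_i\, \tilde r_j}{\sum_{ij} w_{ij}},$$

with $w_{ij} = 1$ iff sender i is within 100 µm of receiver j and
$\tilde l, \tilde r$ z-scored within senders and receivers — a bivariate
spatial cross-product; the Σw normalization is the default and an
unnormalized variant is exposed. Expression is assumed normalized by the
caller. The null randomizes positions within each cell type, which for a
fixed weight matrix is exactly a within-type permutation of the expression
vectors. The permutation p-value is (1 + exceedances)/(1 + n); with
`adaptive = TRUE` the loop stops once 30 exceedances have accrued, after
which p can no longer fall below the 0.005 significance threshold at the
1000-permutation budget — the early stop changes the estimate but never the
decision, which is what the suite verifies. Multiple testing uses
Benjamini–Hochberg; the "significant" flag applies the 0.005 threshold to
the adjusted value (the package emits both raw and adjusted p so either
reading of a normalized p-value is available). The log2 fold change against
the null median is NA when the ratio is non-positive — a logarithm there
would be an invention.

## Clonotype migration

For each clonotype observed in several districts, mean pseudotime is
computed per district and one movement is recorded per district pair, from
earlier to later mean; exact ties record nothing, since the direction is
indeterminate. Directions depend only on pseudotime order, so any monotone
re-parameterization leaves the graph unchanged. With n districts the
movement counts live on n(n−1) ordered pairs (20 for five districts); the
chi-square test against a uniform expectation over those categories has
df = n(n−1) − 1 = 19, and a user-supplied expected vector is accepted when
uniformity is not the right null. Isotype ratios (e.g. IGHG1:IGHA1) are
reported per district and along a route: for each consecutive transition,
cells of the current district are banded by distance to the nearest cell of
the next district, with the discrete "0" band defined by a 1 µm tolerance
and further bands as half-open intervals (0–50, 50–100, 100–150 µm). Zero
denominators give NA with counts still reported.

## The synthetic generator

`make_chip()` places clusters on a jittered grid (uniform jitter, ±25% of
the 6.2 px pitch) and assigns a duplication-rate fraction of barcodes
(default 0.03%, the chip fabrication figure) to two positions.
`simulate_capture()` draws nucleus positions uniformly within labelled
niche regions (the simplest null compatible with complete spatial
randomness inside a niche), samples cell types from per-niche mixing
proportions, draws negative-binomial UMI yields (mean 30, dispersion 4 by
default; a floor of 2 keeps every nucleus classifiable in principle), and
captures each UMI at the chip cluster nearest a Gaussian displacement of
scale `diffusion_sigma_um` (default 2 µm) — cluster hit probabilities
proportional to the isotropic diffusion kernel up to Voronoi
discretization. Droplet collisions merge disjoint nucleus pairs
(probability `co_droplet_rate` per potential pair); because tubes are
assigned independently, colliding nuclei keep distinct tubes with
probability (n−1)/n, which is exactly the recovery margin multiplexing
exploits. Debris items are small barcode clouds at uniform positions
co-encapsulated into existing droplets — the "multiple centers" failure
mode the classifier must reject. `simulate_expression()` adds
negative-binomial counts with fold-elevated markers per type, and
`simulate_clonotypes()` plants clonotypes along a district route with
pseudotime drifting by a set increment per step.

What the generator does **not** emulate: anisotropic or tissue-dependent
diffusion, optical or indel sequencing errors, segmentation artefacts in
the reference centroids, empty droplets and ambient RNA, or 3D tissue
structure. Tests passing on this generator demonstrate the pipeline's
correctness under its stated model — isotropic diffusion, substitution
errors, independent droplets — not robustness to every artefact of real
chips. One bookkeeping caveat: with droplet collisions enabled, two nuclei
legitimately share a `cell_id`, so the truth table is keyed by nucleus, not
by cell id, in that regime.

## Numerical choices and problem sizes

Distances are inclusive at thresholds ("within r" means ≤ r); bins are
half-open and origin-anchored; all tie-breaks are lexicographic; quantiles
are weighted type-1 (first observation reaching the cumulative fraction).
The diffusion-kernel sanity check (Kolmogorov–Smirnov against the Rayleigh
law at n = 10,000) runs on a fine-pitch chip so that Voronoi snapping
(~0.5 µm at the production pitch) does not confound a test of the kernel
itself. The test and acceptance workloads use 500-nucleus tissues for
localization accuracy and brute-force equivalence, 1,200 nuclei for
multiplex recovery, a 2,000-cell five-niche tissue for district recovery,
500 replicate tissues for PCCF calibration, and 200 interactions for
ligand–receptor calibration — sizes at which every stochastic check has
comfortable statistical margin while the full suite stays desk-scale.

## Known limitations

Localization accuracy is reported against the generator's own model of
diffusion; real chips add unmodelled noise and the absolute offsets will
differ. The greedy matcher is not the Hungarian optimum (deliberately, for
determinism and speed; equivalence is verified only on small cases). The
embedding is a small CPU implementation — faithful to the stated recipe but
not a reimplementation of any specific deep-learning stack, and at 150
epochs on thousands of cells it favours reproducibility over scale.
Pseudotime and cell-type labels are inputs, not products, of this package:
errors in them propagate directly into migration and districting results.
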