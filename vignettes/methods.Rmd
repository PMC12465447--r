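---
title: "Models and methods: compartment and local-interaction analysis of cohesin loss"
author: "cohesinHiC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and scientific question

Cohesin extrudes chromatin loops and thereby concentrates promoter-enhancer
contacts; in post-mitotic neurons its loss changes both local genome folding
and, for a subset of genes, the A/B compartment membership of their distal
intergenic enhancers. `cohesinHiC` implements the computational side of such a
study as a reusable pipeline: binned Hi-C contact matrices from valid-pair
files, Knight-Ruiz (KR) balancing, oriented A/B compartment eigenvector
scores, per-gene 5 Kb gene-body interaction statistics, a ranked-bin
differential-compartment feature analysis, rule-based enhancer classification,
3D DNA-FISH probe-distance quantification, and the nonparametric statistics
used throughout. A synthetic-data generator with a serialised truth manifest
plants known compartment flips, loop depletions and expression changes so that
every stage can be validated end to end without any external download.

Everything upstream of valid pairs (alignment, restriction-fragment
assignment), peak calling, differential-expression testing and gene-ontology
analysis are out of scope; those results enter as input tables.

# Contact matrices and balancing

Valid pairs are read from 4DN pairs-format text, canonically ordered,
filtered (intra-chromosomal pairs below 1 Kb genomic distance removed, the
boundary inclusive; exact coordinate+strand duplicates collapsed) and binned
per chromosome into symmetric sparse count matrices. The three bin sizes that
matter are 5 Kb (gene-body statistics), 25 Kb (compartment analysis) and
500 Kb (broad compartment maps); all are plain parameters. Multiple datasets
per condition are binned separately and pooled by summing raw counts —
balancing weights are always recomputed on the pooled matrix, never summed.

`krBalance()` implements the Knight-Ruiz inner-outer Newton iteration
(conjugate-gradient inner solves with the interior-point safeguards
`delta = 0.1`, `Delta = 3` of the original algorithm), targeting unit row
sums of `diag(w) %*% A %*% diag(w)`. Convergence is declared when the
residual norm falls below `tol` (default 1e-8); non-convergence within
`maxIter` outer iterations returns the current weights with a flag rather
than failing. Because the doubly stochastic scaling of a symmetric
non-negative matrix with support is unique, the tests verify the weights
against an independent symmetric Sinkhorn-Knopp fixed-point iteration run to
1e-12.

**Low-coverage mask.** KR diverges on near-empty rows, so bins are masked
before balancing. The mask takes the bins whose marginal raw count falls
below the 2nd percentile of non-zero marginals, but the threshold is capped
at `maskFloorFrac = 0.25` times the median non-zero marginal. The cap
matters: a pure percentile rule always removes 2% of bins no matter how well
covered they are. On maps whose coverage is tightly distributed — which
includes the synthetic maps here — the uncapped percentile lands close to
typical coverage and deletes exactly the biologically interesting
contact-depleted bins (e.g. bins whose compartment has flipped), while a bin
retaining a quarter of the median coverage poses no numerical risk to the
iteration. On realistically over-dispersed coverage the percentile is far
below the cap and behaves as usual. Both knobs are exposed.

# Compartment scores

The expected contact at each genomic distance is the mean balanced entry over
unmasked bin pairs at that diagonal offset (zeros included). The
observed/expected (O/E) matrix divides each balanced entry by the expected
value at its distance; the compartment signal is read from the Pearson
correlation matrix of O/E rows (pairwise-complete over shared non-missing
columns, with pairs sharing fewer than `minShared = 10` columns set to
missing). Correlating raw matrices instead would be dominated by distance
decay and cannot produce a checkerboard, which is why the O/E step sits in
between.

The per-chromosome score vector is the eigenvector of the largest-magnitude
eigenvalue of that correlation matrix, computed by power iteration on the
unmasked submatrix from a deterministic, slightly graded start vector
(tolerance 1e-12, cap 5000 iterations), re-expanded with `NA` at masked bins
and normalised to unit length. Tests check agreement with a dense `eigen()`
oracle to |cosine| > 1 - 1e-8, and sign-permutation equivariance.

**Orientation.** The eigenvector's global sign is arbitrary, so each
chromosome is oriented against histone-mark evidence: the score vector is
correlated with `rank(H3K27ac density) - rank(H3K9me3 density)` per bin and
flipped if the correlation is negative, making positive scores the active A
compartment. The rank difference is robust to the very different dynamic
ranges of the two marks. A zero-variance evidence track leaves the
chromosome unoriented with a warning — there is no silent fallback to a
second eigenvector, which could diverge quietly from the stated definition.
Orientation is per chromosome because eigenvector signs are independent per
chromosome.

**Differential scores and ranked groups.** Condition profiles are each
unit-normalised per chromosome (eigenvectors are scale-free; no other
cross-condition scaling rule is defensible without spike-ins), then
subtracted (cKO minus control). Bins missing in either condition are
excluded. A-compartment bins of the control (score > 0) are sorted by signed
delta ascending — Fig-4B-style, strongest A-loss first; ranking by |delta|
would interleave gains and losses and is available only by resorting the
returned table — with ties broken by (chromosome, bin index), and cut into
consecutive groups. The group size is 500 in the genome-scale configuration;
on the 20 Mb synthetic genome (~800 bins at 25 Kb, roughly half of them in
A) the analyses use proportionally smaller groups of 50 so that the group
profile resolves at all. Per group the pipeline computes: mean log2
fold-change of the nearest protein-coding gene with control log2 CPM > 0
(edge distance, lower-start tie-break); the fraction of bins overlapping an
expressed gene body by at least 1 bp; and the mean edge distance to the
nearest intergenic peak per mark, where intergenic peaks are those
overlapping neither a gene body nor the strand-aware 500 bp window upstream
of any TSS. Upstream is taken strand-aware because "upstream of a TSS" is a
stranded notion; the window size is a parameter.

Scores of arbitrary intervals (e.g. enhancers) are length-weighted means of
the scores of the bins they overlap, with missing bins dropped from the
weighting.

# Local gene-body interactions

A transcript's interaction score is the mean balanced 5 Kb contact over all
unordered pairs (i < j) of the bins spanning its interval. The diagonal is
excluded for multi-bin transcripts — it is dominated by self-bin signal and
would dilute the loop-sensitive off-diagonal pairs — but a single-bin
transcript falls back to its diagonal entry; an `includeDiagonal` switch
exposes the alternative. Masked pairs drop out of the mean; a fully masked
transcript scores `NA`. Condition fold changes are
`(cko + eps) / (ctrl + eps)` with the pseudocount `eps` defaulting in the
pipeline to 5% of the genome-wide median control score, which stabilises
ratios at lowly covered genes without flattening real depletion. Region-level
fold-change maps rescale the two balanced submatrices to equal region sums
first, so a pure sequencing-depth difference gives a map of ones.

# Enhancer rules

H3K27ac peaks are enhancers when their edge distance to every H3K4me3-bound
TSS exceeds 2 Kb (strict, by the literal reading of "more than"); a TSS is
H3K4me3-bound when its +/-1 Kb window overlaps an H3K4me3 peak (1 Kb is the
conventional promoter half-width; both windows are parameters). An enhancer
is intergenic when it overlaps no gene body. Gene assignment follows the
immediately-flanking rule: an intergenic enhancer belongs to a gene when it
lies between that gene's body and the nearest protein-coding gene body on
that side, so no protein-coding gene intervenes; an enhancer between two
genes is a candidate for both. A gene's most distal enhancer distance is the
maximum edge-to-midpoint distance over its assigned enhancers (midpoints
make the measure robust to peak width). The distance-dependence analysis
pairs each downregulated gene's most distal enhancer distance with that
enhancer's compartment score change and reports the Pearson correlation with
its t-test.

Promoter read density is RPKM-style: summed per-base coverage over merged
H3K27ac peaks that overlap a bound TSS, divided by region length (Kb) and
library size (millions).

# 3D FISH quantification

Volumes are smoothed with a separable 3D Gaussian whose physical sigma
(default 0.15 um) is converted per axis by the voxel spacing, so anisotropic
stacks (0.3 um optical sections vs ~0.1 um pixels) are smoothed isotropically
in physical space; edges use replicate padding, which preserves constants and
conserves interior intensity to within 1%. Spots are 26-connected components
of above-threshold voxels, filtered at `minSpotVoxels = 4`, with
intensity-weighted centroids in micrometres; probe distance is the Euclidean
distance between centroids, and when a channel shows more spots than
expected the brightest is used and the event logged. Neighbour-normalised
fluorescence divides a target cell's mean intensity by the mean of exactly
three nearby unelectroporated cells.

The default threshold rule is Otsu's method on the blurred volume, intended
for use within a nuclear mask where foreground and background occupy
comparable volume; on histogram plateaus the threshold takes the plateau
midpoint. The whole-frame synthetic volumes have no nuclear mask — the
foreground is ~0.1% of voxels, a regime where Otsu's between-class variance
collapses into the background mode — so the recovery experiments use the
quantile rule (`q = 0.999`) instead, which is also what makes segmentation
invariant under global intensity scaling. Sigma, connectivity and the spot
size floor are configuration surface, not claims about the original imaging
macros.

# Statistics

All procedures are implemented from first principles and cross-checked in
the tests against independent oracles (`binom.test`, `p.adjust`, `t.test`,
`kruskal.test`, `cor.test`, and permutation resampling):

* **Sign test** — exact two-sided binomial, zeros dropped:
  `p = min(1, 2 min(P(X <= k), P(X >= k)))` at `p = 0.5`. Equals exhaustive
  enumeration of all `2^n` sign patterns for n <= 12.
* **Mood's median test** — pooled grand median, "above" vs "not above" (ties
  to not-above, the textbook convention), chi-square on the contingency
  table with g-1 df, no continuity correction; expected cells below 5 are
  flagged. A pairwise mode tests every group against a control and feeds
  Benjamini-Hochberg. Because the permutation null of the dichotomy is
  discrete at small n, calibration is asserted as membership of the
  chi-square p in the `[P(T > obs), P(T >= obs)]` permutation bracket rather
  than literal equality.
* **Benjamini-Hochberg** — step-up `q_i = min_{j>=i} p_(j) m / j`, capped at
  1, returned in input order. (Note the step-up map is not idempotent —
  re-adjusting adjusted values inflates them — so no such property is
  asserted.)
* **Student's t** — pooled-variance unpaired and paired forms; zero-variance
  inputs are flagged degenerate.
* **Kruskal-Wallis + Dunn** — tie-corrected H; Dunn's pairwise z with the
  tie-corrected variance and BH-adjusted p-values.
* **Correlation t-test** — `t = r sqrt((n-2)/(1-r^2))` on n-2 df; exact
  linear fits and n = 2 (zero df) are flagged; zero-variance input is
  reported as r = 0, p = 1.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions used throughout the tests and the acceptance script.

**Genome layout.** One 20 Mb chromosome. Alternating A/B segments are laid
out with boundaries snapped to the 25 Kb compartment grid, so every bin has
a definite planted sign. A segments hold 2-5 gene cassettes each; B segments
are H3K9me3-tiled gene deserts of 150-300 Kb carrying a few lowly expressed
genes (some near-silent, to exercise the log2 CPM > 0 eligibility filter).
A cassette is either an ordinary gene (60 of them, 20-80 Kb) or a cohesin
target gene (50, 30-80 Kb) preceded by an intergenic enhancer flank: 1-2
enhancers at distances drawn from [20, 400] Kb with a right-skewed
(Beta(1,3)-scaled) shape, matching the empirical predominance of proximal
enhancers while retaining a distal tail. Drawn lengths are rescaled (flanks,
gaps and B segments only — never gene bodies) when a draw would overflow the
chromosome, keeping layouts valid for any seed. Peak sets follow the layout:
H3K4me3 at expressed TSSs, H3K27ac at promoters and enhancers, RAD21 at
target promoters and enhancers, CTCF at segment boundaries, H3K9me3 over B
segments.

**Contacts.** At the 5 Kb level,
`P(i,j) ~ (1 + |i-j|)^(-alpha) (1 + kappa c_i c_j) L(i,j)` with decay
exponent `alpha = 1`, compartment strength `kappa = 0.6`, signs `c` from the
per-condition manifest, and a loop factor `L = 3` over target gene bodies
and promoter-enhancer pairs, multiplied by the depletion factor 0.5 in the
cKO. Thirty A-to-B flips are planted at intergenic enhancer bins (modes:
random enhancer bins; only enhancers beyond 100 Kb; or a size-matched
uniform draw). Two million pairs are sampled per condition with positions
uniform within bins, plus a small injected rate of sub-1 Kb and duplicate
pairs so the filters are exercised on every run. Fixtures are byte-identical
for a fixed (config, seed).

**Expression.** Negative-binomial counts (dispersion 0.05, 3 replicates; the
zero-dispersion limit is Poisson and is tested by a moment check), means
tied to compartment, true log2 fold-changes applied to cKO means (targets
drawn in [-2.5, -1], 15 upregulated genes at +1). CPM is computed against a
nominal whole-transcriptome depth of 1e6: the simulated genes cover under
1% of a genome, so their own count total is not a meaningful library size —
normalising by it would both let near-silent genes pass the CPM > 1 filter
and bias fold changes by the planted depletion's effect on the total.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: restriction-fragment structure and ligation
artifacts, mappability and repeat-driven coverage holes (the mask-floor cap
discussion above), TAD-scale insulation beyond the gene-body loop factor,
trans contacts, batch effects between replicates, and optical aberrations
beyond Poisson noise in the FISH volumes.

**Problem sizes.** The default fixture (20 Mb, 2e6 pairs) makes the full
two-condition analysis run in about two minutes; the unit suite uses a 6 Mb
/ 2-3e5-pair variant. All sizes scale by configuration.

# Design choices on open points

* Nearest-gene distances use gene-body edges, not TSSs, consistent with the
  gene-body overlap semantics used elsewhere; switching to TSS distance is a
  one-line predicate change.
* Short-range filtering runs before duplicate collapse; for exact-match
  duplicates the composition is order-independent, so the choice is purely
  presentational.
* The ranked-bin curve keeps the final remainder group (dropping it would
  lose bins from the reported table; downstream means are per-group anyway).
* The flanking-enhancer rule assigns an enhancer between two genes to both;
  gene-level analyses use the assignments of the gene under test. One
  consequence, visible in the distance-dependence analysis, is that a gene
  can claim its neighbour's proximal enhancer as its own distal one, which
  dilutes but does not erase the distance-dependent correlation.
* `validateConfig` collects all configuration errors in one pass and
  suggests near-miss key names; the pipeline writes a machine-readable run
  report with filter counts and parameters, and its outputs are
  byte-reproducible for fixed inputs.

# Known limitations

KR weights on matrices without total support are not unique; the masking
step avoids the common cases but pathological block structures can still
converge slowly (they are flagged, not hidden). The correlation matrix is
dense, so compartment calling at 5 Kb resolution on large chromosomes is
deliberately unsupported — compartments are a 25-500 Kb phenomenon. The
FISH segmenter assumes isolated spots; touching probe pairs closer than
about one blurred spot diameter merge into one component and are reported as
a single spot. Mood's test is approximate at very small group sizes, as the
calibration bracket in the tests makes explicit.
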