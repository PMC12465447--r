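# cohesinHiC

Analysis pipeline for studying how loss of the cohesin subunit RAD21
reshapes 3D genome organization in post-mitotic neurons — from Hi-C valid
pairs to A/B compartment changes at intergenic enhancers, local
promoter–enhancer interaction loss at target genes, and 3D DNA-FISH probe
distances. It is written for genomicists who have processed Hi-C and
ChIP-seq data in hand (valid-pair files, peak BEDs, a gene table,
expression tables) and want the downstream compartment / local-interaction
/ enhancer analyses as tested, scriptable R functions.

## What it computes

* **Contact matrices** — 4DN pairs-format parsing, the ≥1 Kb
  intra-chromosomal distance filter with exact-duplicate removal, binning
  at 5/25/500 Kb, pooling of datasets, and **Knight–Ruiz balancing**
  (inner–outer Newton iteration) with a coverage mask: weights `w` such
  that `diag(w) A diag(w)` has unit row sums.
* **A/B compartments** — expected-by-distance, observed/expected, the O/E
  row-correlation matrix and its first eigenvector (power iteration),
  oriented per chromosome so H3K27ac-enriched / H3K9me3-depleted bins score
  positive (A). Differential scores between conditions; control-A bins
  ranked by signed Δscore and cut into sets of 500 with per-group features
  (nearest-gene log2FC, genic fraction, distance to intergenic peaks per
  mark).
* **Local interactions** — per-transcript mean balanced 5 Kb contact over
  all bin pairs spanning the gene body; condition fold changes; region
  fold-change maps with depth rescaling.
* **Enhancers** — H3K27ac peaks > 2 Kb from every H3K4me3-bound TSS;
  intergenic flagging; immediately-flanking gene assignment with no
  intervening protein-coding gene; most-distal-enhancer distances and their
  correlation with compartment score change.
* **3D FISH** — anisotropic 3D Gaussian filtering, 26-connected spot
  segmentation with intensity-weighted centroids, Euclidean probe
  distances, neighbour-normalised fluorescence.
* **Statistics** — exact sign test, Mood's median test, Benjamini–Hochberg,
  pooled-variance t, Kruskal–Wallis with Dunn's post hoc, correlation
  t-test; all first-principles implementations cross-checked against
  independent oracles in the test suite.
* **Synthetic data** — a generator that emits the exact input formats the
  pipeline consumes (pairs text, BED, TSV, chrom.sizes, TIFF volumes) with
  a truth manifest of planted compartment flips, loop depletions and
  expression changes.

See `vignettes/methods.Rmd` for the models, parameter meanings and design
decisions.

## Worked example

Generate a two-condition synthetic study (20 Mb genome, 2×10⁶ contact pairs
per condition, 50 cohesin target genes, 30 planted A→B compartment flips at
intergenic enhancer bins, loop depletion factor 0.5) and run the
compartment analysis:

```r
library(cohesinHiC)

fx <- simulateFixture(tempfile("study"), syntheticConfig(seed = 1))
cs <- readChromSizes(fx$paths$chrom_sizes)
grid <- BinGrid(25000, cs)

balance <- function(path)
  krBalance(binPairs(filterPairs(readPairs(path, cs))$pairs, grid)$matrices$chr1)

act  <- binnedPeakDensity(fx$annotation$peaks$H3K27ac, grid)
rep9 <- binnedPeakDensity(fx$annotation$peaks$H3K9me3, grid)
ctrl <- compartmentProfile(list(chr1 = balance(fx$paths$pairs_control)), act, rep9)
cko  <- compartmentProfile(list(chr1 = balance(fx$paths$pairs_cko)),     act, rep9)

ctrl
#> CompartmentProfile: 800 bins @ 25000 bp on 1 chromosome(s) (0 masked), oriented

s  <- compartmentScores(ctrl)$chr1
ok <- !is.na(s)
mean(sign(s[ok]) == fx$manifest@compartmentSign$control$chr1[ok])
#> [1] 1
```

Every unmasked 25 Kb bin receives its planted compartment sign. Ranking
control-A bins by score change recovers the planted flips and their
enhancer association:

```r
delta  <- deltaScores(ctrl, cko)
groups <- rankAndGroup(delta, ctrl, 50)
groups
#> RankedBinGroups: 514 A-compartment bins in 11 group(s) of 50

fb     <- fx$manifest@flippedBins
decile <- head(groups@bins, ceiling(nrow(groups@bins) / 10))
mean(paste(fb$chrom, fb$bin) %in% paste(decile$chrom, decile$bin))
#> [1] 1
```

All 30 flipped bins fall in the strongest-loss decile. The strongest-loss
group sits on intergenic enhancers (mean distance to intergenic
H3K27ac/RAD21 peaks ≈ 0.26× the all-group mean in this run) while its CTCF
distance profile stays flat (≈ 1.2×), and loop-depleted genes lose
gene-body interactions (median fold change 0.77, sign-test p ≈ 2×10⁻¹⁵,
with unperturbed genes at 1.00).

For file-driven use, `runPipeline()` takes a YAML/list configuration naming
the pairs files per condition, peak BEDs, gene and expression tables, and
writes bedGraphs, TSV tables and a JSON run report; `validateConfig()`
checks a configuration and reports every problem at once.

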