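---
title: "Compressed PSI indexing and splicing-pattern mining: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed PSI indexing and splicing-pattern mining: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceIndex)
```

This vignette is the package's own account of the model it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the simulation-based validation does and does not
establish.

## The data model

The unit of analysis is the *splicing node*: a non-overlapping exonic
region of a gene, numbered 5′→3′ in annotation order and classified by its
splicing behaviour (core exon CE, alternative acceptor AA, alternative
donor AD, retained intron RI). The node label is `<gene>_<node_id>`, e.g.
`Gria2_28`. Per node and cell pool, the percent-spliced-in value
$\psi \in [0,1]$ estimates the fraction of the gene's transcripts that
include the node.

Single cells do not provide enough junction-spanning reads for stable
$\psi$ estimates, so cells of the same annotated type are pooled before
quantification. `poolCells()` shuffles each cell type's cells with a seeded
RNG and chops them into consecutive groups of `poolSize` (default 5). Two
choices here were open:

- *Remainder handling.* A non-empty remainder becomes its own smaller pool.
  Discarding remainders would silently thin rare cell types, which are
  precisely the populations splicing analysis wants to keep.
- *Randomized membership.* Shuffling (rather than taking cells in input
  order) avoids plate- or sort-order artifacts leaking into pools; the
  explicit seed keeps the assignment reproducible.

`assemblePsiMatrix()` applies the confident-quantification filter: an entry
survives iff $\psi$ is non-missing **and** read support is at least
`minReads` (default 10, inclusive — "at least"). The filter threshold is a
property of the upstream quantifier's confidence behaviour and is exposed,
not recomputed. Duplicate (node, pool) rows are an error rather than
last-wins: they indicate a corrupted upstream merge and should not be
papered over. The result is a `PsiMatrix`, a `SummarizedExperiment` with
nodes as rows, pools as columns and explicit `NA` for unquantified entries.

## The compressed index

For each node, with mean $\mu$ and standard deviation computed over
quantified pools only, the deviation $\Delta\psi = \psi - \mu$ is
tripartitioned at threshold $\tau$ (default 0.2):

- $\Delta\psi > \tau$: the **above** side, value $100\,\Delta\psi$;
- $\Delta\psi < -\tau$: the **below** side, value $100\,|\Delta\psi|$;
- otherwise: the near-mean **mask**.

Two boundary conventions needed fixing. First, ties at exactly $\tau$ go to
the mask (strict inequality for encoding): with continuous PSI the case is
measure-zero, but one consistent rule is required, and the mask's recovery
contract ("return the mean") degrades most gracefully for a value that
deviates by exactly $\tau$. Second, the mask generalizes "equal to the
dataset mean" to "quantified but within $\tau$ of the mean" — exact
equality is measure-zero, while distinguishing near-mean from unquantified
is the mask's entire purpose. The scaled values are kept as reals in
$(0, 100]$; no integer rounding is applied, so a stored value of exactly 0
cannot occur.

Each node side is compressed independently:

1. **Positions** (0-based pool indices, strictly increasing) are
   Elias-Fano encoded with low-bit width
   $l = \max(0, \lfloor \log_2(U/m) \rfloor)$ for $m$ positions in a
   universe of $U$ pools: $m\,l$ fixed-width low bits followed by the high
   parts as unary gap codes. This step is exactly lossless and uses about
   $m(2 + \log_2(U/m))$ bits. The codec lives in C++ (`src/ef_codec.cpp`);
   decoding validates stream bounds and reports truncation explicitly.
2. **Values** are quantized to $b$ bits (default 2). A log-normal is fitted
   by the moments of $\ln(\text{values})$; the fitted $k/2^b$ quantiles
   ($k = 1 \dots 2^b - 1$) are cut points; a value's bin is the number of
   cut points at or below it; each bin dequantizes to the **median of the
   original values** in it. Degenerate cases: with a single or constant
   input the fitted sd is 0, every cut point collapses to the same number,
   all values land in one bin, and dequantization is exact. An empty bin's
   representative falls back to the fitted distribution's median of that
   quantile band, $q_{(k+0.5)/2^b}$, which preserves monotonicity of the
   representative sequence.

The log-normal is fitted *per node and side*, not globally: deviation
magnitudes differ wildly between nodes, and a per-node fit keeps the 2-bit
code adaptive at negligible storage cost (two reals per side). The above
and below sides are quantized independently for the same reason.

The mask is itself Elias-Fano coded. Reconstruction
(`recoverPsi`) returns $\mu + \text{rep}/100$ for above pools,
$\mu - \text{rep}/100$ for below pools (both clamped to $[0,1]$), exactly
$\mu$ for mask pools, and `NA` otherwise. The guarantees are: error at most
the within-bin value range for encoded entries, at most $\tau$ for mask
entries, and exact missingness preservation.

`saveIndex()`/`loadIndex()` serialize the index as a single versioned
container; a version string mismatch is an explicit error naming both
versions. Bit-exactness is guaranteed for a load/save round trip within one
package version, not across versions.

## Queries and enrichment

A `patternQuery()` is a set of per-node criteria — included above the mean,
or excluded below it — combined with AND (intersection) or OR (union) over
the decoded position sets. A pool where a queried node is unquantified or
near-mean is simply not in the side and never matches the term; nothing is
imputed.

Cell-type enrichment uses the upper-tail hypergeometric test: for a cell
type with $n$ pools of which $k$ match, with $K$ matches among $N$ pools
total, $p = P(X \ge k)$ under $X \sim \mathrm{Hypergeom}(N, K, n)$,
computed via `phyper`. The tail is upper and **inclusive of the observed
$k$** — the only reading consistent with testing enrichment; exclusion of
the observed count would anti-conservatively halve small p-values. The
significance threshold is raw $p \le 0.05$ by default; a Benjamini-Hochberg
switch exists (`bhAdjust`) but is off by default so that default behaviour
matches the raw-threshold convention of the enrichment framework the
package implements.

## Marker nodes

For a target cell type and a direction (inclusion = above side,
exclusion = below side): TP is a target-type pool in the side, FP a pool of
any other type in the side, FN a target-type pool *not detected* in the
side. FN deliberately counts both unquantified pools and quantified
near-mean pools of the target type — "not detected" is the operative
notion, and this convention is what makes sparse quantification depress
recall rather than silently inflating it. It is exposed as a documented
switch (`countMaskAsFN = FALSE` excludes the near-mean pools). Scores use
the 0/0 → 0 convention throughout: a never-detected node is a useless
marker, and ranking it 0 is the honest choice.

`findMarkers()` evaluates every (node, direction) pair — inclusion and
exclusion compete in one pooled list — and sorts by F1 descending,
precision descending, node label ascending. Precision is the first
tie-break because pool-level false positives are what most corrupts a
marker in practice; the lexicographic final tie-break exists purely for
determinism.

## Mutually exclusive exon pairs

Candidates are all within-gene ordered node pairs whose stored statistics
are compatible with mutual exclusivity: mean-PSI sum within $1 \pm 0.1$ and
sd difference strictly below 0.1. Both filters use the per-node statistics
over *all* quantified pools (not only pools where both nodes are
quantified): that is what the index stores, and requiring joint
quantification would re-introduce a dense pass the index exists to avoid.
Cross-gene pairs are excluded outright — mutual exclusivity is defined
within a transcript — while adjacency is *not* required at candidate stage
(an `adjacentOnly` flag restricts it); the `adjacent` flag (consecutive
ordinal ids) is reported per pair. All node types are admitted by default
and can be restricted via `nodeTypes`.

Each candidate is tested in both orientations (upstream-in/downstream-out
and the reverse) with the AND pattern one-node-above + other-node-below;
pairs with at least one significant cell type are reported. High confidence
requires, in some significant cell type, pattern support in **at least**
50% of the type's pools (inclusive) and a recovered mean PSI difference
between the exons of at least 0.5. The PSI difference is computed from the
index's approximate recovery — the index is the only data available at
query time — and is therefore itself approximate, which is documented in
the output contract.

## Coordinated node blocks

The scan walks each gene 5′→3′ over consecutive ordinal ids. A run seeds
only at a CE node; any node type may extend (restrictable with `ceOnly`),
because coordinated events frequently carry AA/AD/RI nodes mid-run while a
non-CE boundary is a poor anchor. Extension requires the candidate node's
mean and sd each within ±0.1 of the **block aggregate** (the mean of
current members' means/sds). "The previous block" is ambiguous between
last-node and block-aggregate comparison; the aggregate is chosen because
last-node comparison lets a run drift arbitrarily far from where it
started; `aggregate = "last"` provides the other reading. A gap in ordinal
ids closes the run. Only maximal runs of length ≥ 2 are tested — testing
every prefix would multiply the test count without a corresponding gain,
though this is noted as a potential divergence from other implementations.

Each run is tested separately for joint inclusion (all nodes above) and
joint exclusion (all nodes below). Member nodes are collapsed to distinct
exons via a user-supplied node-to-exon map (absent nodes count as their own
exon; the fallback is announced loudly) and blocks need ≥ 3 distinct exons.
High confidence requires support in **strictly more than** 50% of a
significant type's pools. The asymmetry against the MXE rule (inclusive ≥
50%) is intentional: both thresholds are kept exactly as their respective
conventions state them.

## The synthetic generator

`simulateDataset()` emulates the input side end to end: genes with ordered
nodes of CE-rich type composition, cell types with configurable pool
counts, node baselines drawn from a Beta distribution, truncated-Gaussian
noise per entry, independent missingness, and read support drawn so a
configurable fraction fails the 10-read filter. Defaults: 50 genes of 8-12
nodes (~500 nodes), 10 cell types × 8 pools of 5 cells, Beta(2,2)
baselines, noise sd 0.05, 5% unquantified, 5% read-filter failures, mean
read support 30. Noise is truncated-Gaussian rather than Beta-per-entry
because the block and MXE filters are defined in terms of means and sds,
and direct sd control is what the planted structures need; the Beta
baseline still supplies realistic bimodality of node means.

Planted structures are constructed to be recoverable by design, not by
luck: marker nodes sit at baseline $0.5 \mp \delta/2$ so the shifted type
stays in range; MXE pairs are complementary in *every* pool
($\psi_a + \psi_b = 1$, noise mirrored within the pair) with roles reversed
only in the target type, which makes the mean-sum and sd-difference filters
pass by construction; block members share one baseline and flanking nodes
are offset by 0.35 so the scan finds sharp boundaries. Ground truth is
returned alongside the tables.

What the generator does **not** emulate: cell-type-structured missingness
(an optional effect in real data), read-level noise and the quantifier's
confidence-interval behaviour, correlated baselines along a gene, doublets
and ambient contamination, and annotation errors in the node-to-exon map.
Passing the planted-recovery tests therefore shows the machinery is
correct and sensitive at the stated effect sizes under idealized sparsity —
it does not certify recall on real tissues, where missingness is structured
and effect sizes vary.

## Validation scale and numerical notes

The test suite validates the codec on random position sets with universes
up to $10^6$ (10,000 sets in the acceptance pass), query results against a
naive dense ΔPSI scan on 50 random indexes up to 200 pools × 2,000 nodes,
hypergeometric p-values against full draw enumeration for every feasible
configuration with $N \le 12$, and planted-pattern recovery over 20
simulations at the default study geometry (10 types × 8 pools, ~500
nodes, effect size ΔPSI 0.4) with 20 matched null simulations. These sizes
were chosen so the full suite runs comfortably on a single core while
still exercising the index well past the regimes where naive and
compressed paths could accidentally agree.

Numerical conventions collected in one place: encoding inequalities are
strict ($|\Delta\psi| > \tau$); the MXE sd filter is strict ($< 0.1$) and
its pool fraction inclusive ($\ge$ 50%); the block pool fraction is strict
($>$ 50%); `minReads` is inclusive ($\ge$ 10); recovery clamps to $[0,1]$;
marker scores use 0/0 → 0; all RNG-dependent operations take explicit
seeds and restore the caller's RNG state.

## Known limitations

- The mean/sd statistics that drive MXE candidacy and block extension are
  computed once over all quantified pools; a cell type with extreme
  abundance can dominate them.
- `delta_psi` in MXE output inherits quantization error from the 2-bit
  recovery; at the default 0.5 threshold this is immaterial for planted
  effect sizes ≥ 0.5 but can matter near the boundary.
- Pattern mining is restricted to nodes present in the index; nodes
  dropped by the read filter in every pool are invisible downstream.
- The index is append-only in spirit: there is no incremental update; new
  pools require a rebuild.
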