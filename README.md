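# SpliceIndex

Mining cell type-specific alternative splicing patterns from full-length
single-cell RNA-seq, built on a compressed, queryable index of differential
percent-spliced-in (PSI) values.

## The problem

Full-length scRNA-seq protocols (Smart-seq2, VASA-seq and kin) cover whole
transcripts, so local, event-level splicing can be quantified per cell: a
gene is split into non-overlapping exonic *splicing nodes* (core exons CE,
alternative acceptors AA, alternative donors AD, retained introns RI,
numbered 5′→3′), and each node gets a PSI value in [0, 1] — the fraction of
the gene's transcripts that include it — estimated from junction-spanning
reads. Splicing quantification in single cells is extremely sparse, so cells
of the same annotated type are pooled (default 5 cells per pool) and only
entries supported by at least 10 reads are kept.

Even after pooling, a dataset is a large pools × nodes matrix with heavy
missingness, and the questions one wants to ask are combinatorial: which
nodes single out a cell type? which exon pairs are used mutually
exclusively, and where? which runs of consecutive exons switch together?
Answering them exhaustively requires many thousands of set queries against
the matrix, which is what the index makes cheap.

## The method

For each node with dataset-wide mean PSI μ (over quantified pools), the
deviation ΔPSI = ψ − μ is computed per pool. Pools with ΔPSI > τ (default
τ = 0.2) form the node's **above** (differential inclusion) side, pools
with ΔPSI < −τ its **below** (differential exclusion) side, and the scaled
magnitudes 100·|ΔPSI| ∈ (0, 100] are stored. Each side is compressed in two
steps:

1. **Elias-Fano encoding** of the sorted pool positions (lossless): each
   position splits at bit *l* = max(0, ⌊log₂(U/m)⌋) into fixed-width low
   bits and unary-coded high-part gaps, ≈ m·(2 + log₂(U/m)) bits total.
2. **b-bit quantile quantization** of the magnitudes (lossy, default
   b = 2): a log-normal is fitted to the values by the moments of their
   logs, the fitted k/2ᵇ quantiles define bins, and each bin dequantizes to
   the median of the original values it holds.

Quantified pools within τ of the mean go to an Elias-Fano-coded NA mask so
they stay distinguishable from unquantified pools; per-node mean/sd/count
statistics and annotations complete the index. Approximate PSI is
recoverable as μ ± rep/100 (clamped to [0, 1]) or exactly μ for masked
pools. No imputation or model fitting is involved anywhere.

On top of the index:

- **Queries**: AND/OR combinations of per-node include/exclude criteria
  return matching pools by set intersection/union of decoded positions.
- **Enrichment**: for a cell type with n pools, k of them matching, K
  matches among N pools overall, the upper-tail hypergeometric p-value
  P(X ≥ k) tests concentration of the pattern (significant at p ≤ 0.05).
- **Marker nodes** (`findMarkers`): every (node, direction) pair is scored
  by precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R), where a
  TP is a target-type pool carrying the inclusion/exclusion signal, an FP
  the same in another type, and an FN a target-type pool without the signal
  (near-mean or unquantified); ranked by F1.
- **Mutually exclusive exons** (`detectMxe`): within-gene node pairs with
  mean-PSI sum 1 ± 0.1 and sd difference < 0.1 are tested for cell types
  enriched in the include-one/exclude-other joint pattern; pairs carried by
  ≥ 50% of a significant type's pools with |ΔPSI| between the exons ≥ 0.5
  are flagged high-confidence.
- **Coordinated node blocks** (`detectBlocks`): a 5′→3′ scan seeds runs at
  CE nodes and extends while the next node's mean and sd stay within ± 0.1
  of the running block aggregate; runs are tested for joint inclusion
  ("above") and joint exclusion ("below") separately, collapsed to distinct
  exons (≥ 3 required), with > 50% pool support marking high confidence.

A deterministic synthetic-data generator (`simConfig`/`simulateDataset`)
emulates the whole input side — Whippet-style PSI tables, cell annotations,
node-to-exon maps — with planted markers, MXE pairs and blocks recorded as
ground truth, so the full pipeline is testable without any download.

## Worked example

```r
library(SpliceIndex)

cfg <- simConfig(
  n_genes = 20, nodes_per_gene = c(8, 10), n_cell_types = 6,
  planted_markers = list(list(cell_type = "T01", delta = 0.4,
                              direction = "inclusion")),
  planted_mxe    = list(list(cell_type = "T02", psi_high = 0.9,
                             psi_low = 0.1)),
  planted_blocks = list(list(cell_type = "T03", block_len = 4,
                             delta = 0.4, direction = "above")),
  seed = 42)
sim <- simulateDataset(cfg)
mat <- assemblePsiMatrix(sim$records, sim$pools)   # >=10 reads filter
idx <- buildIndex(mat)                             # tau = 0.2, bits = 2
idx
#> CompressedIndex: 176 nodes x 48 pools (6 cell types)
#>   encoded nodes: 7 | tau = 0.2 | bits = 2 | min reads = 10

head(findMarkers(idx, "T01"), 1)
#>     node gene cell_type direction tp fp fn precision recall        f1
#> 1 G003_2 G003       T01 inclusion  5  0  3         1  0.625 0.7692308

detectMxe(idx)
#>   gene node_a node_b orientation cell_type k n K  N      p_value fraction
#> 1 G001 G001_3 G001_4  a_in_b_out       T02 6 8 6 48 2.281707e-06     0.75
#>   delta_psi adjacent high_confidence
#> 1 0.7575816     TRUE            TRUE

detectBlocks(idx, exonMap = sim$exon_map)
#>   gene                       nodes node_start node_end n_nodes n_exons
#> 1 G002 G002_2,G002_3,G002_4,G002_5          2        5       4       4
#>   direction cell_type k n K  N      p_value fraction high_confidence
#> 1     above       T03 6 8 6 48 2.281707e-06     0.75            TRUE
```

All three planted patterns come back: the marker node `G003_2` tops the T01
ranking (perfect precision; recall 0.625 because some T01 pools fall to the
missingness and read filters — exactly the recall pathology sparse splicing
data shows), the complementary pair `G001_3`/`G001_4` is a high-confidence
adjacent MXE in T02 (the two exons' recovered PSI differ by 0.76), and the
four-node run in `G002` is a high-confidence coordinated inclusion block in
T03. The `k n K N` columns are the hypergeometric counts behind each
p-value; `fraction = k/n` is the pool support within the cell type.

The same pipeline is scriptable from a shell via
`Rscript inst/scripts/spliceindex.R <pool|assemble|build|info|query|markers|mxe|blocks|simulate> ...`.

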