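# Shared in-code fixtures and independent oracles.

# Build a PsiMatrix directly from a dense pools x nodes value matrix.
# Nodes are split into genes of `nodesPerGene` consecutive ids; all CE unless
# nodeTypes given. cellTypes: one label per pool.
densePsiMatrix <- function(values, cellTypes, nodesPerGene = 10L,
                           nodeTypes = NULL) {
  nP <- nrow(values); nN <- ncol(values)
  stopifnot(length(cellTypes) == nP)
  geneIdx <- (seq_len(nN) - 1L) %/% nodesPerGene + 1L
  nodeId <- (seq_len(nN) - 1L) %% nodesPerGene + 1L
  gene <- sprintf("G%03d", geneIdx)
  if (is.null(nodeTypes)) nodeTypes <- rep("CE", nN)
  pools <- data.frame(pool_id = sprintf("%s.p%03d", cellTypes, seq_len(nP)),
                      cell_type = cellTypes, cells = "x", n_cells = 1L,
                      stringsAsFactors = FALSE)
  records <- data.frame(
    gene = rep(gene, each = nP), node_id = rep(nodeId, each = nP),
    chrom = "chr1", start = rep(100L * seq_len(nN), each = nP),
    end = rep(100L * seq_len(nN) + 50L, each = nP), strand = "+",
    node_type = rep(nodeTypes, each = nP),
    pool_id = rep(pools$pool_id, times = nN),
    psi = as.vector(values), total_reads = 50L, stringsAsFactors = FALSE)
  suppressWarnings(assemblePsiMatrix(records, pools, minReads = 10L))
}

# random dense PSI matrix with missingness
randomPsiMatrix <- function(nP, nN, naRate = 0.1, nTypes = 4L, seed = 1L,
                            nodesPerGene = 10L) {
  set.seed(seed)
  vals <- matrix(runif(nP * nN), nrow = nP)
  vals[matrix(runif(nP * nN) < naRate, nrow = nP)] <- NA_real_
  # keep every pool and node quantified at least once so dims are stable
  vals[1, ] <- ifelse(is.na(vals[1, ]), 0.5, vals[1, ])
  cellTypes <- sprintf("T%02d", rep_len(seq_len(nTypes), nP))
  densePsiMatrix(vals, cellTypes, nodesPerGene = nodesPerGene)
}

denseValues <- function(mat) t(SummarizedExperiment::assay(mat, "psi"))

# independent oracle: above/below/mask tripartition by a dense scan
naiveTripartition <- function(values, tau) {
  lapply(seq_len(ncol(values)), function(j) {
    col <- unname(values[, j])
    q <- which(!is.na(col))
    m <- mean(col[q])
    d <- col[q] - m
    list(mean = m,
         above = q[d > tau] - 1L,
         below = q[d < -tau] - 1L,
         mask = q[abs(d) <= tau & (d <= tau & d >= -tau)] - 1L)
  })
}

# independent oracle for pattern queries on the dense matrix
naiveQuery <- function(values, poolIds, terms, combine, tau) {
  sets <- lapply(seq_len(nrow(terms)), function(i) {
    col <- values[, terms$col[i]]
    m <- mean(col, na.rm = TRUE)
    d <- col - m
    if (terms$direction[i] == "included-above") which(!is.na(d) & d > tau)
    else which(!is.na(d) & d < -tau)
  })
  hits <- if (combine == "AND") Reduce(intersect, sets) else Reduce(union, sets)
  poolIds[sort(hits)]
}

# brute-force upper-tail hypergeometric by enumerating all draws
enumHyper <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# toy three-pool node used across examples: PSI 0.1 / 0.5 / 0.9
toyThreePoolMatrix <- function() {
  vals <- cbind(c(0.1, 0.5, 0.9))
  densePsiMatrix(vals, cellTypes = c("A", "A", "B"), nodesPerGene = 1L)
}
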