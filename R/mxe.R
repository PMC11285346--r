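# shared enrichment core: given matching pool positions (0-based), tally per
# cell type and compute upper-tail hypergeometric p-values
enrichMatches <- function(index, hits, alpha = 0.05) {
  ct <- index@pools$cell_type
  N <- nPools(index)
  K <- length(hits)
  isHit <- logical(N)
  isHit[hits + 1L] <- TRUE
  types <- sort(unique(ct))
  res <- data.frame(
    cell_type = types,
    k = vapply(types, function(t) sum(isHit & ct == t), 1L),
    n = vapply(types, function(t) sum(ct == t), 1L),
    K = K, N = N, stringsAsFactors = FALSE
  )
  res$p_value <- mapply(hypergeomPvalue, res$k, res$n,
                        MoreArgs = list(K = K, N = N))
  res$significant <- res$p_value <= alpha
  res[order(res$p_value, res$cell_type), ]
}

#' Enumerate candidate mutually exclusive exon pairs
#'
#' All ordered within-gene node pairs (upstream node first, by ordinal node
#' id) whose stored statistics are compatible with mutual exclusivity:
#' mean PSI values summing to 1 +/- 0.1 and PSI standard deviations
#' differing by less than 0.1. Both filters are evaluated on the per-node
#' statistics computed over all quantified pools at build time.
#'
#' @param index a [CompressedIndex-class]
#' @param nodeTypes node types admitted (default all; e.g. `c("CE")`)
#' @param adjacentOnly restrict to pairs with consecutive node ids
#'   (default `FALSE`)
#' @param meanSumTol tolerance around a mean-PSI sum of 1 (default 0.1)
#' @param sdDiffMax strict upper bound on the sd difference (default 0.1)
#' @param ... unused
#' @return data.frame with `gene`, `node_a`, `node_b`, `id_a`, `id_b`,
#'   `adjacent`, ordered by (gene, id_a, id_b)
#' @rdname candidateMxePairs
#' @export
setMethod("candidateMxePairs", "CompressedIndex",
          function(index, nodeTypes = NULL, adjacentOnly = FALSE,
                   meanSumTol = 0.1, sdDiffMax = 0.1, ...) {
  nodes <- index@nodes
  if (!is.null(nodeTypes))
    nodes <- nodes[nodes$node_type %in% nodeTypes, , drop = FALSE]
  out <- list()
  for (g in unique(nodes$gene)) {
    sub <- nodes[nodes$gene == g, , drop = FALSE]
    sub <- sub[order(sub$node_id), , drop = FALSE]
    if (nrow(sub) < 2L) next
    idx <- utils::combn(nrow(sub), 2L)
    a <- idx[1, ]; b <- idx[2, ]
    keep <- abs(sub$mean_psi[a] + sub$mean_psi[b] - 1) <= meanSumTol &
      abs(sub$sd_psi[a] - sub$sd_psi[b]) < sdDiffMax
    if (adjacentOnly) keep <- keep & (sub$node_id[b] - sub$node_id[a] == 1L)
    if (!any(keep)) next
    out[[g]] <- data.frame(
      gene = g,
      node_a = rownames(sub)[a[keep]], node_b = rownames(sub)[b[keep]],
      id_a = sub$node_id[a[keep]], id_b = sub$node_id[b[keep]],
      adjacent = sub$node_id[b[keep]] - sub$node_id[a[keep]] == 1L,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(gene = character(), node_a = character(),
                      node_b = character(), id_a = integer(),
                      id_b = integer(), adjacent = logical()))
  res <- do.call(rbind, out)
  res <- res[order(res$gene, res$id_a, res$id_b), ]
  rownames(res) <- NULL
  res
})

#' Detect cell type-specific mutually exclusive exon pairs
#'
#' For every candidate pair from [candidateMxePairs()] and both
#' orientations (upstream in / downstream out, and the reverse), the joint
#' pattern "one node above the mean AND the other below" is tested for
#' cell-type enrichment with the upper-tail hypergeometric test. Pairs with
#' at least one significant cell type are reported, one row per significant
#' (pair, orientation, cell type). A pair is flagged high-confidence when
#' some significant cell type carries the pattern in at least
#' `minPoolFraction` of its pools and the two nodes' mean recovered PSI in
#' that cell type differ by at least `minDeltaPsi`.
#'
#' @param index a [CompressedIndex-class]
#' @param alpha significance threshold (default 0.05)
#' @param minPoolFraction inclusive minimum fraction of the cell type's
#'   pools carrying the pattern (default 0.5)
#' @param minDeltaPsi inclusive minimum |PSI(b) - PSI(a)| (default 0.5)
#' @param nodeTypes,adjacentOnly forwarded to [candidateMxePairs()]
#' @param ... unused
#' @return data.frame with one row per (pair, orientation, significant cell
#'   type): `gene`, `node_a`, `node_b`, `orientation` (`"a_in_b_out"` or
#'   `"a_out_b_in"`), `cell_type`, `k`, `n`, `K`, `N`, `p_value`,
#'   `fraction`, `delta_psi`, `adjacent`, `high_confidence`
#' @rdname detectMxe
#' @export
setMethod("detectMxe", "CompressedIndex",
          function(index, alpha = 0.05, minPoolFraction = 0.5,
                   minDeltaPsi = 0.5, nodeTypes = NULL,
                   adjacentOnly = FALSE, ...) {
  cand <- candidateMxePairs(index, nodeTypes = nodeTypes,
                            adjacentOnly = adjacentOnly)
  empty <- data.frame(
    gene = character(), node_a = character(), node_b = character(),
    orientation = character(), cell_type = character(),
    k = integer(), n = integer(), K = integer(), N = integer(),
    p_value = numeric(), fraction = numeric(), delta_psi = numeric(),
    adjacent = logical(), high_confidence = logical())
  if (nrow(cand) == 0L) return(empty)

  labs <- unique(c(cand$node_a, cand$node_b))
  posAbove <- lapply(labs, function(l) sidePositions(index, l, "above"))
  posBelow <- lapply(labs, function(l) sidePositions(index, l, "below"))
  names(posAbove) <- names(posBelow) <- labs
  psiCache <- new.env(parent = emptyenv())
  getPsi <- function(l) {
    if (is.null(psiCache[[l]])) psiCache[[l]] <- recoverPsi(index, l)
    psiCache[[l]]
  }
  ct <- index@pools$cell_type

  rows <- list(); r <- 0L
  for (i in seq_len(nrow(cand))) {
    a <- cand$node_a[i]; b <- cand$node_b[i]
    for (orient in c("a_in_b_out", "a_out_b_in")) {
      hits <- if (orient == "a_in_b_out")
        intersect(posAbove[[a]], posBelow[[b]])
      else intersect(posBelow[[a]], posAbove[[b]])
      if (length(hits) == 0L) next
      enr <- enrichMatches(index, hits, alpha)
      sig <- enr[enr$significant, , drop = FALSE]
      if (nrow(sig) == 0L) next
      sig$fraction <- sig$k / sig$n
      sig$delta_psi <- vapply(sig$cell_type, function(t) {
        pa <- getPsi(a)[ct == t]; pb <- getPsi(b)[ct == t]
        abs(mean(pb, na.rm = TRUE) - mean(pa, na.rm = TRUE))
      }, 1)
      r <- r + 1L
      rows[[r]] <- cbind(
        data.frame(gene = cand$gene[i], node_a = a, node_b = b,
                   orientation = orient, stringsAsFactors = FALSE),
        sig[, c("cell_type", "k", "n", "K", "N", "p_value",
                "fraction", "delta_psi")],
        data.frame(adjacent = cand$adjacent[i]))
    }
  }
  if (!r) return(empty)
  res <- do.call(rbind, rows)
  hc <- res$fraction >= minPoolFraction & res$delta_psi >= minDeltaPsi
  pairKey <- paste(res$node_a, res$node_b)
  res$high_confidence <- ave(hc, pairKey, FUN = any) > 0
  res <- res[order(res$gene, res$node_a, res$node_b, res$orientation,
                   res$p_value, res$cell_type), ]
  rownames(res) <- NULL
  res
})
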