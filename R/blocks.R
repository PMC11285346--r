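#' Read a node-to-exon mapping table
#'
#' TSV with columns `gene`, `node_id`, `exon_id` associating each splicing
#' node with the actual exon it belongs to (several consecutive nodes can
#' map to one exon). Used by [detectBlocks()] to count distinct exons in a
#' node block; nodes absent from the map count as their own exon.
#'
#' @param path TSV path
#' @return data.frame with `gene`, `node_id`, `exon_id`
#' @export
readExonMap <- function(path) {
  em <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#",
                          colClasses = c(gene = "character",
                                         node_id = "integer",
                                         exon_id = "character"))
  if (!all(c("gene", "node_id", "exon_id") %in% colnames(em)))
    stop("exon map needs columns gene, node_id, exon_id")
  em
}

#' Scan a gene for candidate coordinately spliced node runs
#'
#' Left-to-right (5' to 3' in annotation order) scan over a gene's nodes by
#' ordinal id. A run is seeded at a core-exon (CE) node; the next node
#' (consecutive id) joins the current run iff its mean PSI and PSI standard
#' deviation each differ by at most `simTol` from the running block
#' aggregate (the mean of member node means/sds; `aggregate = "last"`
#' compares to the last member instead). When the criterion fails, or ids
#' stop being consecutive, the run closes and a new run may start at the
#' next CE node. Non-CE nodes can extend a run but never start one
#' (`ceOnly = TRUE` restricts extension to CE nodes too). Runs of at least
#' two nodes are returned.
#'
#' @param index a [CompressedIndex-class]
#' @param gene gene identifier
#' @param simTol similarity tolerance for mean and sd (default 0.1)
#' @param aggregate `"block"` (compare to block aggregate, default) or
#'   `"last"` (compare to last member node)
#' @param ceOnly logical; only CE nodes may extend a run (default `FALSE`)
#' @param ... unused
#' @return list of character vectors of node labels (candidate runs)
#' @rdname seedAndExtendBlocks
#' @export
setMethod("seedAndExtendBlocks", "CompressedIndex",
          function(index, gene, simTol = 0.1, aggregate = c("block", "last"),
                   ceOnly = FALSE, ...) {
  aggregate <- match.arg(aggregate)
  nodes <- index@nodes[index@nodes$gene == gene, , drop = FALSE]
  if (nrow(nodes) == 0L) stop("unknown gene: ", gene)
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  runs <- list()
  cur <- integer(0)  # row indices of current run members
  close <- function() {
    if (length(cur) >= 2L) runs[[length(runs) + 1L]] <<- rownames(nodes)[cur]
    cur <<- integer(0)
  }
  for (i in seq_len(nrow(nodes))) {
    isCE <- nodes$node_type[i] == "CE"
    if (length(cur)) {
      consecutive <- nodes$node_id[i] == nodes$node_id[cur[length(cur)]] + 1L
      ref <- if (aggregate == "block") cur else cur[length(cur)]
      fits <- consecutive &&
        abs(nodes$mean_psi[i] - mean(nodes$mean_psi[ref])) <= simTol &&
        abs(nodes$sd_psi[i] - mean(nodes$sd_psi[ref])) <= simTol &&
        (!ceOnly || isCE)
      if (fits) {
        cur <- c(cur, i)
        next
      }
      close()
    }
    if (isCE) cur <- i
  }
  close()
  runs
})

#' Detect cell type-specific coordinately spliced node blocks
#'
#' For every candidate run from [seedAndExtendBlocks()] the joint patterns
#' "all member nodes above the mean" (direction `above`, coordinated
#' inclusion) and "all member nodes below" (direction `below`, coordinated
#' exclusion) are tested separately for cell-type enrichment. Runs
#' significant in at least one cell type are kept; member nodes are then
#' collapsed to distinct exons through the node-to-exon map (a node absent
#' from the map is its own exon) and blocks covering at least `minExons`
#' distinct exons are reported. A block is high-confidence when some
#' significant cell type carries it in strictly more than `minPoolFraction`
#' of its pools.
#'
#' @param index a [CompressedIndex-class]
#' @param exonMap data.frame from [readExonMap()], or `NULL` for the
#'   identity fallback (each node its own exon; reported via a message)
#' @param alpha significance threshold (default 0.05)
#' @param minExons minimum number of distinct exons (default 3)
#' @param minPoolFraction strict lower bound on the pool fraction for the
#'   high-confidence flag (default 0.5)
#' @param simTol,aggregate,ceOnly forwarded to [seedAndExtendBlocks()]
#' @param ... unused
#' @return data.frame with one row per (block, direction, significant cell
#'   type): `gene`, `nodes` (comma-joined labels), `node_start`,
#'   `node_end`, `n_nodes`, `n_exons`, `direction`, `cell_type`, `k`, `n`,
#'   `K`, `N`, `p_value`, `fraction`, `high_confidence`
#' @rdname detectBlocks
#' @export
setMethod("detectBlocks", "CompressedIndex",
          function(index, exonMap = NULL, alpha = 0.05, minExons = 3L,
                   minPoolFraction = 0.5, simTol = 0.1,
                   aggregate = "block", ceOnly = FALSE, ...) {
  if (is.null(exonMap)) {
    message("no exon map supplied: every node counts as its own exon")
    exonMap <- data.frame(gene = character(), node_id = integer(),
                          exon_id = character())
  } else {
    known <- paste0(exonMap$gene, "_", exonMap$node_id) %in%
      rownames(index@nodes)
    if (any(!known)) {
      warning(sum(!known), " exon-map entr(ies) reference unknown nodes; ignored")
      exonMap <- exonMap[known, , drop = FALSE]
    }
  }
  exonOf <- function(labels) {
    key <- match(labels, paste0(exonMap$gene, "_", exonMap$node_id))
    ifelse(is.na(key), labels, exonMap$exon_id[key])
  }
  empty <- data.frame(
    gene = character(), nodes = character(), node_start = integer(),
    node_end = integer(), n_nodes = integer(), n_exons = integer(),
    direction = character(), cell_type = character(), k = integer(),
    n = integer(), K = integer(), N = integer(), p_value = numeric(),
    fraction = numeric(), high_confidence = logical())

  rows <- list(); r <- 0L
  for (g in unique(index@nodes$gene)) {
    runs <- seedAndExtendBlocks(index, g, simTol = simTol,
                                aggregate = aggregate, ceOnly = ceOnly)
    for (run in runs) {
      nExons <- length(unique(exonOf(run)))
      if (nExons < minExons) next
      for (direction in c("above", "below")) {
        sets <- lapply(run, function(l) sidePositions(index, l, direction))
        hits <- Reduce(intersect, sets)
        if (length(hits) == 0L) next
        enr <- enrichMatches(index, hits, alpha)
        sig <- enr[enr$significant, , drop = FALSE]
        if (nrow(sig) == 0L) next
        sig$fraction <- sig$k / sig$n
        ids <- index@nodes[run, "node_id"]
        r <- r + 1L
        rows[[r]] <- cbind(
          data.frame(gene = g, nodes = paste(run, collapse = ","),
                     node_start = min(ids), node_end = max(ids),
                     n_nodes = length(run), n_exons = nExons,
                     direction = direction, stringsAsFactors = FALSE),
          sig[, c("cell_type", "k", "n", "K", "N", "p_value", "fraction")])
      }
    }
  }
  if (!r) return(empty)
  res <- do.call(rbind, rows)
  blockKey <- paste(res$gene, res$node_start, res$node_end, res$direction)
  res$high_confidence <-
    ave(res$fraction > minPoolFraction, blockKey, FUN = any) > 0
  res <- res[order(res$gene, res$node_start, res$direction, res$p_value,
                   res$cell_type), ]
  rownames(res) <- NULL
  res
})
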