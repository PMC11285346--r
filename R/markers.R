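#' Score a node as a marker of a cell type
#'
#' Counts, over cell pools, how well differential inclusion (above side) or
#' exclusion (below side) of a node singles out a cell type. A true positive
#' is a pool of the target type present in the node's side; a false positive
#' is a pool of any other type in that side; a false negative is a pool of
#' the target type not detected as included/excluded — by default this
#' counts both unquantified pools and quantified near-mean (mask) pools,
#' which is what makes sparse quantification depress recall.
#' Scores: precision = tp/(tp+fp), recall = tp/(tp+fn), F1 their harmonic
#' mean; 0/0 cases score 0 (a never-detected node is a useless marker).
#'
#' @param index a [CompressedIndex-class]
#' @param node node label
#' @param cellType target cell type
#' @param direction `"inclusion"` (above) or `"exclusion"` (below)
#' @param countMaskAsFN logical; count quantified near-mean pools of the
#'   target type as false negatives (default `TRUE`)
#' @param ... unused
#' @return one-row data.frame: `node`, `gene`, `cell_type`, `direction`,
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#' @rdname evaluateMarker
#' @export
setMethod("evaluateMarker", "CompressedIndex",
          function(index, node, cellType, direction = c("inclusion", "exclusion"),
                   countMaskAsFN = TRUE, ...) {
  node <- .checkNode(index, node)
  direction <- match.arg(direction)
  if (!cellType %in% index@pools$cell_type)
    stop("unknown cell type: ", cellType)
  side <- if (direction == "inclusion") "above" else "below"
  pos <- sidePositions(index, node, side)
  inType <- index@pools$cell_type == cellType
  tp <- sum(inType[pos + 1L])
  fp <- length(pos) - tp
  fn <- sum(inType) - tp
  if (!countMaskAsFN) {
    maskType <- sum(inType[efDecode(index@mask[[node]]) + 1L])
    fn <- fn - maskType
  }
  markerScoreRow(index, node, cellType, direction, tp, fp, fn)
})

markerScoreRow <- function(index, node, cellType, direction, tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  data.frame(node = node, gene = index@nodes[node, "gene"],
             cell_type = cellType, direction = direction,
             tp = tp, fp = fp, fn = fn,
             precision = precision, recall = recall, f1 = f1,
             stringsAsFactors = FALSE)
}

#' Exhaustive marker-node search for a cell type
#'
#' Evaluates every (node, direction) pair in the index with
#' [evaluateMarker()] and ranks by F1 descending, breaking ties by
#' precision descending and then node label, so the ranking is
#' deterministic. Inclusion and exclusion markers compete in one pooled
#' list.
#'
#' @param index a [CompressedIndex-class]
#' @param cellType target cell type
#' @param topN number of markers to return (default 20)
#' @param minF1 minimum F1 score to be reported (default 0)
#' @param countMaskAsFN see [evaluateMarker()]
#' @param ... unused
#' @return data.frame of ranked marker scores (columns as in
#'   [evaluateMarker()])
#' @rdname findMarkers
#' @export
setMethod("findMarkers", "CompressedIndex",
          function(index, cellType, topN = 20L, minF1 = 0,
                   countMaskAsFN = TRUE, ...) {
  if (!cellType %in% index@pools$cell_type)
    stop("unknown cell type: ", cellType)
  inType <- index@pools$cell_type == cellType
  nType <- sum(inType)
  labs <- rownames(index@nodes)
  rows <- vector("list", 2L * length(labs))
  r <- 0L
  for (lab in labs) {
    maskType <- if (!countMaskAsFN)
      sum(inType[efDecode(index@mask[[lab]]) + 1L]) else 0L
    for (direction in c("inclusion", "exclusion")) {
      side <- if (direction == "inclusion") "above" else "below"
      pos <- sidePositions(index, lab, side)
      tp <- sum(inType[pos + 1L])
      fp <- length(pos) - tp
      fn <- nType - tp - maskType
      r <- r + 1L
      rows[[r]] <- markerScoreRow(index, lab, cellType, direction, tp, fp, fn)
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(-res$f1, -res$precision, res$node), ]
  res <- res[res$f1 >= minF1, , drop = FALSE]
  res <- utils::head(res, topN)
  rownames(res) <- NULL
  res
})
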