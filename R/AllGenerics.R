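#' @rdname buildIndex
#' @export
setGeneric("buildIndex", function(x, tau = 0.2, bits = 2L, ...)
  standardGeneric("buildIndex"))

#' @rdname poolsMatching
#' @export
setGeneric("poolsMatching", function(index, query, ...)
  standardGeneric("poolsMatching"))

#' @rdname recoverPsi
#' @export
setGeneric("recoverPsi", function(index, node, ...)
  standardGeneric("recoverPsi"))

#' @rdname hyperQueryCellTypes
#' @export
setGeneric("hyperQueryCellTypes", function(index, query, alpha = 0.05, ...)
  standardGeneric("hyperQueryCellTypes"))

#' @rdname evaluateMarker
#' @export
setGeneric("evaluateMarker", function(index, node, cellType, direction, ...)
  standardGeneric("evaluateMarker"))

#' @rdname findMarkers
#' @export
setGeneric("findMarkers", function(index, cellType, topN = 20L, minF1 = 0, ...)
  standardGeneric("findMarkers"))

#' @rdname candidateMxePairs
#' @export
setGeneric("candidateMxePairs", function(index, ...)
  standardGeneric("candidateMxePairs"))

#' @rdname detectMxe
#' @export
setGeneric("detectMxe", function(index, alpha = 0.05, minPoolFraction = 0.5,
                                 minDeltaPsi = 0.5, ...)
  standardGeneric("detectMxe"))

#' @rdname seedAndExtendBlocks
#' @export
setGeneric("seedAndExtendBlocks", function(index, gene, simTol = 0.1, ...)
  standardGeneric("seedAndExtendBlocks"))

#' @rdname detectBlocks
#' @export
setGeneric("detectBlocks", function(index, exonMap = NULL, alpha = 0.05,
                                    minExons = 3L, minPoolFraction = 0.5, ...)
  standardGeneric("detectBlocks"))

#' Number of cell pools in an index
#' @param index a [CompressedIndex-class]
#' @return integer
#' @export
setGeneric("nPools", function(index) standardGeneric("nPools"))

#' Number of splicing nodes in an index
#' @param index a [CompressedIndex-class]
#' @return integer
#' @export
setGeneric("nNodes", function(index) standardGeneric("nNodes"))

#' Per-node statistics stored in an index
#'
#' Node annotation together with `mean_psi`, `sd_psi` and `n_quantified`
#' (all computed over quantified pools only at build time).
#'
#' @param index a [CompressedIndex-class]
#' @return data.frame with one row per node; rownames are node labels
#' @export
setGeneric("nodeStats", function(index) standardGeneric("nodeStats"))

#' Pool annotation of an index
#' @param index a [CompressedIndex-class]
#' @return data.frame with `pool_id` and `cell_type`
#' @export
setGeneric("poolInfo", function(index) standardGeneric("poolInfo"))

#' Build parameters of an index
#' @param index a [CompressedIndex-class]
#' @return list with `tau`, `bits`, `min_reads`, `version`
#' @export
setGeneric("indexParams", function(index) standardGeneric("indexParams"))

#' Cell types present in an index
#' @param index a [CompressedIndex-class]
#' @return character vector of distinct cell-type labels
#' @export
setGeneric("cellTypes", function(index) standardGeneric("cellTypes"))
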