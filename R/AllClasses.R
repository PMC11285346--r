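#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats phyper qlnorm sd median p.adjust rbeta rnorm rpois runif
#' @useDynLib SpliceIndex, .registration = TRUE
NULL

#' PsiMatrix: pools-by-nodes percent-spliced-in matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding one assay,
#' `"psi"`, with splicing nodes as rows and cell pools as columns. Missing
#' entries (`NA`) mark node/pool combinations that were unquantified or
#' failed the confident-quantification read filter. `rowData()` carries the
#' node annotation (gene, ordinal node id, coordinates, strand, node type);
#' `colData()` carries the pool annotation (pool id, cell type, member
#' cells).
#'
#' @slot minReads the read-support threshold applied when the matrix was
#'   assembled (entries with fewer supporting reads are `NA`).
#'
#' @seealso [assemblePsiMatrix()], [buildIndex()]
#' @export
setClass("PsiMatrix",
  contains = "SummarizedExperiment",
  slots = c(minReads = "integer"),
  prototype = prototype(minReads = 10L)
)

setValidity("PsiMatrix", function(object) {
  msg <- character()
  if (!"psi" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'psi' is required")
  else {
    v <- SummarizedExperiment::assay(object, "psi")
    if (any(v < 0 | v > 1, na.rm = TRUE))
      msg <- c(msg, "PSI values must lie in [0, 1]")
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("gene", "node_id", "chrom", "start", "end", "strand", "node_type")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste0("rowData must contain: ", paste(need, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("pool_id", "cell_type") %in% colnames(cd)))
    msg <- c(msg, "colData must contain pool_id and cell_type")
  if (length(msg)) msg else TRUE
})

#' CompressedIndex: the queryable two-sided differential-PSI index
#'
#' The compressed representation of a [PsiMatrix-class]: per node, the pools
#' whose PSI deviates from the node's dataset-wide mean by more than `tau`
#' are split into an "above" (differential inclusion) and a "below"
#' (differential exclusion) side. Each side stores the pool positions as an
#' Elias-Fano bitstream and the scaled deviation magnitudes (100 * |dPSI|)
#' as b-bit quantile bins of a fitted log-normal, together with the bin
#' representatives used for dequantization. Quantified pools within `tau` of
#' the mean are kept in an Elias-Fano-coded NA mask so that near-mean pools
#' remain distinguishable from unquantified ones. Per-node mean/sd/count
#' statistics and the node annotation complete the index.
#'
#' @slot pools data.frame with columns `pool_id`, `cell_type` (one row per
#'   pool, in matrix column order).
#' @slot nodes data.frame of node annotation plus `mean_psi`, `sd_psi`,
#'   `n_quantified`; rownames are node labels (`<gene>_<node_id>`).
#' @slot above,below named lists (by node label); each element is `NULL` (no
#'   encoded entries on that side) or a list with `ef` (Elias-Fano stream),
#'   `bins`, `log_mu`, `log_sigma`, `bin_reps`.
#' @slot mask named list of Elias-Fano streams of quantified-but-near-mean
#'   pool positions.
#' @slot params list with `tau`, `bits`, `min_reads` and the container
#'   `version`.
#'
#' @seealso [buildIndex()], [poolsMatching()], [recoverPsi()]
#' @export
setClass("CompressedIndex",
  slots = c(
    pools = "data.frame",
    nodes = "data.frame",
    above = "list",
    below = "list",
    mask = "list",
    params = "list"
  )
)

setValidity("CompressedIndex", function(object) {
  msg <- character()
  labs <- rownames(object@nodes)
  if (!all(c("pool_id", "cell_type") %in% colnames(object@pools)))
    msg <- c(msg, "pools must have pool_id and cell_type columns")
  if (anyDuplicated(object@pools$pool_id))
    msg <- c(msg, "pool ids must be unique")
  for (slot in c("above", "below", "mask")) {
    nm <- names(methods::slot(object, slot))
    if (!setequal(nm, labs))
      msg <- c(msg, sprintf("names of @%s must match node labels", slot))
  }
  p <- object@params
  if (!all(c("tau", "bits", "version") %in% names(p)))
    msg <- c(msg, "params must contain tau, bits, version")
  else if (p$tau <= 0 || p$tau >= 1)
    msg <- c(msg, "tau must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})
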