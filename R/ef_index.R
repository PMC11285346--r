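#' Elias-Fano encode a sorted position set
#'
#' Encodes a strictly increasing sequence of 0-based integers drawn from
#' `[0, universe)` into the canonical Elias-Fano layout: each value is split
#' at bit `l = max(0, floor(log2(universe / m)))` into a fixed-width low part
#' and a unary-gap-coded high part. The encoding is exactly lossless and
#' uses close to `m * (2 + log2(universe/m))` bits.
#'
#' @param positions strictly increasing integer vector, `0 <= p < universe`
#' @param universe the position universe size (number of pools)
#' @return a list of class `"efStream"`: `bytes` (raw), `m`, `universe`,
#'   `l`, `nbits`
#' @examples
#' s <- efEncode(c(2L, 3L, 5L, 7L, 11L, 13L), 16L)
#' efDecode(s)
#' @export
efEncode <- function(positions, universe) {
  s <- .efEncodeCpp(as.integer(positions), as.integer(universe))
  class(s) <- "efStream"
  s
}

#' Decode an Elias-Fano stream
#'
#' Exact inverse of [efEncode()].
#'
#' @param stream an `"efStream"` list as returned by [efEncode()]
#' @return the original integer positions
#' @export
efDecode <- function(stream) {
  stopifnot(is.list(stream),
            all(c("bytes", "m", "universe", "l") %in% names(stream)))
  .efDecodeCpp(stream$bytes, stream$m, stream$universe, stream$l)
}

#' Quantize positive deviation values into log-normal quantile bins
#'
#' Fits a log-normal to the values by the moments of `log(values)` and cuts
#' the fitted distribution at the `k/2^bits` quantiles (`k = 1 ..
#' 2^bits - 1`). A value's bin index is the number of cut points at or below
#' it (0-based). Each bin's representative, used for dequantization, is the
#' median of the original values falling in it; an empty bin falls back to
#' the fitted distribution's median of that quantile band. With a single or
#' constant input the fitted sd is 0 and all values share one bin whose
#' representative reproduces them exactly.
#'
#' @param values positive reals (scaled deviations in (0, 100])
#' @param bits bits per stored value, between 1 and 8 (default 2)
#' @return list with `bins` (0-based integer bin per value), `log_mu`,
#'   `log_sigma`, `bin_reps` (length `2^bits`, non-decreasing)
#' @export
quantizeValues <- function(values, bits = 2L) {
  bits <- as.integer(bits)
  if (is.na(bits) || bits < 1L || bits > 8L)
    stop("bits must lie in [1, 8]")
  if (length(values) == 0L)
    stop("quantizeValues needs at least one value")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be positive and finite")
  lv <- log(values)
  mu <- mean(lv)
  sigma <- if (length(lv) > 1L) stats::sd(lv) else 0
  if (!is.finite(sigma)) sigma <- 0
  nb <- 2L^bits
  cuts <- stats::qlnorm(seq_len(nb - 1L) / nb, meanlog = mu, sdlog = sigma)
  bins <- findInterval(values, cuts)  # count of cut points <= value
  reps <- numeric(nb)
  for (k in seq_len(nb) - 1L) {
    inBin <- values[bins == k]
    reps[k + 1L] <- if (length(inBin)) stats::median(inBin)
      else stats::qlnorm((k + 0.5) / nb, meanlog = mu, sdlog = sigma)
  }
  list(bins = as.integer(bins), log_mu = mu, log_sigma = sigma,
       bin_reps = reps)
}

#' Center PSI values and split into above/below/mask
#'
#' For each node the dataset-wide mean over quantified pools is subtracted;
#' pools with deviation `> tau` go to the "above" side, `< -tau` to the
#' "below" side (magnitudes scaled by 100 so stored values lie in (0, 100]),
#' and remaining quantified pools (including ties at exactly `tau`) to the
#' near-mean mask. Unquantified pools belong to none of the three sets.
#' Nodes whose column is entirely missing are dropped with a warning.
#'
#' @param matrix a [PsiMatrix-class]
#' @param tau deviation threshold in (0, 1), default 0.2
#' @return named list (per node label) of lists with `stats`
#'   (`mean_psi`, `sd_psi`, `n_quantified`), `above` / `below` (0-based
#'   pool positions and scaled values), and `mask` (0-based positions)
#' @export
centerAndSplit <- function(matrix, tau = 0.2) {
  stopifnot(methods::is(matrix, "PsiMatrix"))
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  v <- SummarizedExperiment::assay(matrix, "psi")
  out <- vector("list", nrow(v))
  names(out) <- rownames(v)
  drop <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    col <- unname(v[i, ])
    q <- which(!is.na(col))
    if (length(q) == 0L) { drop[i] <- TRUE; next }
    m <- mean(col[q])
    s <- if (length(q) > 1L) stats::sd(col[q]) else 0
    d <- col[q] - m
    ab <- d > tau
    be <- d < -tau
    out[[i]] <- list(
      stats = list(mean_psi = m, sd_psi = s, n_quantified = length(q)),
      above = list(positions = q[ab] - 1L, values = 100 * d[ab]),
      below = list(positions = q[be] - 1L, values = 100 * (-d[be])),
      mask = q[!ab & !be] - 1L
    )
  }
  if (any(drop))
    warning(sum(drop), " all-missing node(s) dropped: ",
            paste(utils::head(names(out)[drop], 5), collapse = ", "))
  out[!drop]
}

.CONTAINER_VERSION <- "spliceindex-1"

encodeSide <- function(positions, values, universe, bits) {
  if (length(positions) == 0L) return(NULL)
  q <- quantizeValues(values, bits)
  list(ef = efEncode(positions, universe), bins = q$bins,
       log_mu = q$log_mu, log_sigma = q$log_sigma, bin_reps = q$bin_reps)
}

#' Build the compressed two-sided differential-PSI index
#'
#' Applies [centerAndSplit()] and compresses each node side with
#' [efEncode()] (positions) and [quantizeValues()] (deviation magnitudes).
#' Near-mean quantified pools are kept in an Elias-Fano-coded mask so they
#' can be recovered as the node mean. Nodes with no encoded entry on either
#' side are retained in the statistics and mask only.
#'
#' @param x a [PsiMatrix-class]
#' @param tau deviation threshold (default 0.2)
#' @param bits quantizer bits (default 2)
#' @param ... unused
#' @return a [CompressedIndex-class]
#' @rdname buildIndex
#' @export
setMethod("buildIndex", "PsiMatrix", function(x, tau = 0.2, bits = 2L, ...) {
  bits <- as.integer(bits)
  split <- centerAndSplit(x, tau)
  nP <- ncol(SummarizedExperiment::assay(x, "psi"))
  labs <- names(split)
  rd <- as.data.frame(SummarizedExperiment::rowData(x))[labs, , drop = FALSE]
  stats <- do.call(rbind, lapply(split, function(e) as.data.frame(e$stats)))
  nodes <- cbind(rd, stats)
  rownames(nodes) <- labs
  above <- lapply(split, function(e)
    encodeSide(e$above$positions, e$above$values, nP, bits))
  below <- lapply(split, function(e)
    encodeSide(e$below$positions, e$below$values, nP, bits))
  mask <- lapply(split, function(e) efEncode(e$mask, nP))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  pools <- data.frame(pool_id = cd$pool_id, cell_type = cd$cell_type,
                      stringsAsFactors = FALSE)
  methods::new("CompressedIndex",
               pools = pools, nodes = nodes,
               above = above, below = below, mask = mask,
               params = list(tau = tau, bits = bits,
                             min_reads = x@minReads,
                             version = .CONTAINER_VERSION))
})

#' @rdname nPools
#' @export
setMethod("nPools", "CompressedIndex", function(index) nrow(index@pools))

#' @rdname nNodes
#' @export
setMethod("nNodes", "CompressedIndex", function(index) nrow(index@nodes))

#' @rdname nodeStats
#' @export
setMethod("nodeStats", "CompressedIndex", function(index) index@nodes)

#' @rdname poolInfo
#' @export
setMethod("poolInfo", "CompressedIndex", function(index) index@pools)

#' @rdname indexParams
#' @export
setMethod("indexParams", "CompressedIndex", function(index) index@params)

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "CompressedIndex",
          function(index) sort(unique(index@pools$cell_type)))

#' @describeIn CompressedIndex-class compact summary mirroring the index
#'   parameter block (node/pool counts, encoded nodes, tau, bits)
#' @param object a `CompressedIndex`
#' @export
setMethod("show", "CompressedIndex", function(object) {
  enc <- sum(!vapply(object@above, is.null, TRUE) |
               !vapply(object@below, is.null, TRUE))
  cat(sprintf("CompressedIndex: %d nodes x %d pools (%d cell types)\n",
              nNodes(object), nPools(object),
              length(cellTypes(object))))
  cat(sprintf("  encoded nodes: %d | tau = %g | bits = %d | min reads = %d\n",
              enc, object@params$tau, object@params$bits,
              object@params$min_reads))
  invisible(NULL)
})

# positions (0-based) of a node side; integer(0) when side is NULL
sidePositions <- function(index, label, side) {
  s <- methods::slot(index, side)[[label]]
  if (is.null(s)) integer(0) else efDecode(s$ef)
}

.checkNode <- function(index, node) {
  if (!node %in% rownames(index@nodes))
    stop("unknown node: ", node)
  node
}

#' Save an index to a single-file container
#'
#' Serializes the index (a versioned structured payload: bitstreams as raw
#' vectors plus metadata tables) to one file. [loadIndex()] restores every
#' field bit-exactly.
#'
#' @param index a [CompressedIndex-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
saveIndex <- function(index, path) {
  stopifnot(methods::is(index, "CompressedIndex"))
  payload <- list(container = "SpliceIndex",
                  version = index@params$version,
                  pools = index@pools, nodes = index@nodes,
                  above = index@above, below = index@below,
                  mask = index@mask, params = index@params)
  saveRDS(payload, path)
  invisible(path)
}

#' Load an index saved by [saveIndex()]
#'
#' @param path container file path
#' @return a [CompressedIndex-class]
#' @export
loadIndex <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable index container: ", path, " (", conditionMessage(e),
         ")", call. = FALSE))
  if (!is.list(payload) || !identical(payload$container, "SpliceIndex"))
    stop("file is not a SpliceIndex container: ", path)
  if (!identical(payload$version, .CONTAINER_VERSION))
    stop("container version mismatch: file has '", payload$version,
         "', this build reads '", .CONTAINER_VERSION, "'")
  methods::new("CompressedIndex",
               pools = payload$pools, nodes = payload$nodes,
               above = payload$above, below = payload$below,
               mask = payload$mask, params = payload$params)
}
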