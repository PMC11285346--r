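#' Construct a splicing pattern query
#'
#' A pattern is a set of per-node criteria: nodes that must be differentially
#' included (in the "above" side, i.e. PSI well above the node's dataset
#' mean) and nodes that must be differentially excluded (in the "below"
#' side). Terms are combined with AND (all criteria hold in the same pool)
#' or OR (any criterion holds).
#'
#' @param include node labels required to be included above the mean
#' @param exclude node labels required to be excluded below the mean
#' @param combine `"AND"` or `"OR"`
#' @return an object of class `"PatternQuery"`
#' @examples
#' patternQuery(include = "Gria2_29", exclude = "Gria2_28", combine = "AND")
#' @export
patternQuery <- function(include = character(), exclude = character(),
                         combine = c("AND", "OR")) {
  combine <- match.arg(toupper(combine[1]), c("AND", "OR"))
  terms <- rbind(
    if (length(include)) data.frame(node = include, direction = "included-above"),
    if (length(exclude)) data.frame(node = exclude, direction = "excluded-below")
  )
  if (is.null(terms) || nrow(terms) == 0L)
    stop("a pattern query needs at least one term")
  if (anyDuplicated(terms))
    stop("duplicate (node, direction) term(s) in query")
  structure(list(terms = terms, combine = combine), class = "PatternQuery")
}

#' @export
print.PatternQuery <- function(x, ...) {
  cat(sprintf("PatternQuery (%s over %d terms)\n", x$combine, nrow(x$terms)))
  for (i in seq_len(nrow(x$terms)))
    cat(sprintf("  %s [%s]\n", x$terms$node[i], x$terms$direction[i]))
  invisible(x)
}

#' Find cell pools matching a splicing pattern
#'
#' Decodes the queried node sides from the index and combines them by set
#' intersection (AND) or union (OR). Pools where a queried node is
#' unquantified, or quantified but near the mean, are not in either side and
#' therefore never match that term; no imputation is performed.
#'
#' @param index a [CompressedIndex-class]
#' @param query a `"PatternQuery"` from [patternQuery()]
#' @param ... unused
#' @return character vector of matching pool ids, in pool order
#' @rdname poolsMatching
#' @export
setMethod("poolsMatching", "CompressedIndex", function(index, query, ...) {
  stopifnot(inherits(query, "PatternQuery"))
  sets <- lapply(seq_len(nrow(query$terms)), function(i) {
    node <- .checkNode(index, query$terms$node[i])
    side <- if (query$terms$direction[i] == "included-above") "above" else "below"
    sidePositions(index, node, side)
  })
  hits <- if (query$combine == "AND") Reduce(intersect, sets)
          else Reduce(union, sets)
  index@pools$pool_id[sort(hits) + 1L]
})

#' Recover approximate PSI values for a node
#'
#' Reconstructs the per-pool PSI of a node from the lossy index: pools on
#' the above side get `mean + rep/100`, pools on the below side
#' `mean - rep/100` (where `rep` is the dequantized deviation magnitude,
#' clamped to `[0, 1]`), near-mean mask pools get exactly the node mean, and
#' unquantified pools stay `NA`.
#'
#' @param index a [CompressedIndex-class]
#' @param node node label
#' @param ... unused
#' @return named numeric vector over pools (names are pool ids)
#' @rdname recoverPsi
#' @export
setMethod("recoverPsi", "CompressedIndex", function(index, node, ...) {
  node <- .checkNode(index, node)
  m <- index@nodes[node, "mean_psi"]
  out <- rep(NA_real_, nPools(index))
  names(out) <- index@pools$pool_id
  for (side in c("above", "below")) {
    s <- methods::slot(index, side)[[node]]
    if (is.null(s)) next
    pos <- efDecode(s$ef)
    rep_ <- s$bin_reps[s$bins + 1L] / 100
    out[pos + 1L] <- if (side == "above") pmin(1, pmax(0, m + rep_))
                     else pmin(1, pmax(0, m - rep_))
  }
  out[efDecode(index@mask[[node]]) + 1L] <- m
  out
})

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of at
#' least `k` pattern-carrying pools among the `n` pools of a cell type,
#' when `K` of the `N` pools overall carry the pattern. The tail includes
#' the observed `k`, the reading consistent with testing enrichment.
#'
#' @param k observed successes in the cell type
#' @param n pools of the cell type
#' @param K pattern-carrying pools overall
#' @param N total pools
#' @return the p-value
#' @examples
#' hypergeomPvalue(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeomPvalue <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K))
    stop("infeasible hypergeometric counts (k=", k, ", n=", n,
         ", K=", K, ", N=", N, ")")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Cell-type enrichment of a splicing pattern
#'
#' Runs [poolsMatching()] and tests each cell type for over-representation
#' among the matching pools with the upper-tail hypergeometric test. For a
#' cell type with `n` pools, `k` of which match, against `K` matches among
#' `N` pools overall, the p-value is `P(X >= k)`. Raw p-values are compared
#' against `alpha` by default; optional Benjamini-Hochberg adjustment is
#' available but off by default.
#'
#' @param index a [CompressedIndex-class]
#' @param query a `"PatternQuery"`
#' @param alpha significance threshold (default 0.05)
#' @param bhAdjust logical; adjust p-values by Benjamini-Hochberg before the
#'   threshold is applied (default `FALSE`)
#' @param ... unused
#' @return data.frame with one row per cell type: `cell_type`, `k`, `n`,
#'   `K`, `N`, `p_value` (and `p_adj` if `bhAdjust`), `significant`;
#'   sorted by p ascending, ties broken by cell type name
#' @rdname hyperQueryCellTypes
#' @export
setMethod("hyperQueryCellTypes", "CompressedIndex",
          function(index, query, alpha = 0.05, bhAdjust = FALSE, ...) {
  hits <- poolsMatching(index, query)
  ct <- index@pools$cell_type
  N <- nPools(index)
  K <- length(hits)
  isHit <- index@pools$pool_id %in% hits
  types <- sort(unique(ct))
  res <- data.frame(
    cell_type = types,
    k = vapply(types, function(t) sum(isHit & ct == t), 1L),
    n = vapply(types, function(t) sum(ct == t), 1L),
    K = K, N = N, stringsAsFactors = FALSE
  )
  res$p_value <- mapply(hypergeomPvalue, res$k, res$n,
                        MoreArgs = list(K = K, N = N))
  if (bhAdjust) {
    res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_adj <= alpha
  } else {
    res$significant <- res$p_value <= alpha
  }
  res <- res[order(res$p_value, res$cell_type), ]
  rownames(res) <- NULL
  res
})
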