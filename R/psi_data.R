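#' Read a Whippet-style node-level PSI table
#'
#' Parses a tab-separated table with (at least) the columns `Gene`, `Node`,
#' `Coord`, `Strand`, `Type`, `Psi`, `Total_Reads` into one record per row.
#' `Coord` is expected in the `chr:start-end` display convention (1-based,
#' inclusive). A pool identifier column (`Pool`, or `Sample`) associates each
#' row with a cell pool. Gzip-compressed files are handled transparently.
#'
#' @param path path to the TSV (optionally `.gz`)
#' @param poolColumn name of the column holding the pool id (default
#'   `"Pool"`, falling back to `"Sample"` when absent)
#' @return a data.frame of PSI records with columns `gene`, `node_id`,
#'   `chrom`, `start`, `end`, `strand`, `node_type`, `pool_id`, `psi`,
#'   `total_reads`. Missing (`NA` or empty) PSI values are `NA`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("Gene\tNode\tCoord\tStrand\tType\tPsi\tTotal_Reads\tPool",
#'              "Gria2\t28\tchr3:80692286-80692400\t+\tCE\t0.85\t25\tp1"), tsv)
#' readPsiTable(tsv)
#' @export
readPsiTable <- function(path, poolColumn = "Pool") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#",
                           quote = "", check.names = FALSE)
  need <- c("Gene", "Node", "Coord", "Strand", "Type", "Psi", "Total_Reads")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("PSI table is missing required column(s): ", paste(miss, collapse = ", "))
  if (!poolColumn %in% colnames(tab)) {
    if ("Sample" %in% colnames(tab)) poolColumn <- "Sample"
    else stop("PSI table has no pool column ('", poolColumn, "' or 'Sample')")
  }
  coords <- parseCoordString(tab$Coord)
  node_id <- suppressWarnings(as.integer(tab$Node))
  if (anyNA(node_id) || any(node_id < 1))
    stop("Node column must hold positive integers")
  psi <- suppressWarnings(as.numeric(ifelse(tab$Psi %in% c("", "NA", "na"),
                                            NA_character_, tab$Psi)))
  bad <- which(!is.na(psi) & (psi < 0 | psi > 1))
  if (length(bad))
    stop("Psi outside [0, 1] on line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  reads <- suppressWarnings(as.integer(tab$Total_Reads))
  if (anyNA(reads) || any(reads < 0))
    stop("Total_Reads must hold non-negative integers")
  data.frame(
    gene = tab$Gene, node_id = node_id,
    chrom = coords$chrom, start = coords$start, end = coords$end,
    strand = tab$Strand, node_type = tab$Type,
    pool_id = tab[[poolColumn]], psi = psi, total_reads = reads,
    stringsAsFactors = FALSE
  )
}

# "chr:start-end" -> chrom/start/end; 1-based inclusive, start <= end required
parseCoordString <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- which(vapply(m, length, 1L) != 4L)
  if (length(bad))
    stop("malformed coordinate string on line ", bad[1] + 1L, ": '",
         x[bad[1]], "' (expected chr:start-end)")
  start <- as.integer(vapply(m, `[`, "", 3L))
  end <- as.integer(vapply(m, `[`, "", 4L))
  rev <- which(start > end)
  if (length(rev))
    stop("coordinate start > end on line ", rev[1] + 1L, ": '", x[rev[1]], "'")
  list(chrom = vapply(m, `[`, "", 2L), start = start, end = end)
}

#' Read a cell-to-cell-type annotation table
#'
#' @param path TSV with columns `cell_id` and `cell_type` (header required)
#' @return data.frame with unique `cell_id` and its `cell_type`
#' @export
readCellAnnotations <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (!all(c("cell_id", "cell_type") %in% colnames(ann)))
    stop("annotation table needs columns cell_id and cell_type")
  if (anyDuplicated(ann$cell_id))
    stop("duplicate cell_id in annotation table")
  ann[, c("cell_id", "cell_type")]
}

#' Assign cells to same-cell-type pools
#'
#' Cells of each cell type are shuffled with a seeded RNG and chopped into
#' consecutive groups of `poolSize`; a non-empty remainder forms its own
#' smaller pool rather than being discarded, so rare cell types are never
#' silently thinned. The assignment is deterministic for a fixed seed.
#'
#' @param annotations data.frame with `cell_id`, `cell_type` (see
#'   [readCellAnnotations()])
#' @param poolSize target number of cells per pool (default 5)
#' @param seed integer seed for the shuffle
#' @return data.frame with one row per pool: `pool_id`, `cell_type`,
#'   `cells` (comma-joined member cell ids) and `n_cells`
#' @examples
#' ann <- data.frame(cell_id = paste0("c", 1:12), cell_type = "T1")
#' poolCells(ann, poolSize = 5, seed = 1)  # pools of sizes 5, 5, 2
#' @export
poolCells <- function(annotations, poolSize = 5L, seed = 1L) {
  stopifnot(poolSize >= 1L)
  if (!all(c("cell_id", "cell_type") %in% colnames(annotations)))
    stop("annotations need columns cell_id and cell_type")
  if (anyDuplicated(annotations$cell_id))
    stop("duplicate cell_id in annotations")
  types <- sort(unique(annotations$cell_type))
  out <- vector("list", length(types))
  withSeed(seed, {
    for (i in seq_along(types)) {
      ct <- types[i]
      cells <- annotations$cell_id[annotations$cell_type == ct]
      if (length(cells) == 0L) {
        warning("cell type '", ct, "' has no cells; skipped")
        next
      }
      cells <- sample(cells)
      grp <- ceiling(seq_along(cells) / poolSize)
      members <- split(cells, grp)
      out[[i]] <- data.frame(
        pool_id = sprintf("%s.%d", ct, seq_along(members)),
        cell_type = ct,
        cells = vapply(members, paste, "", collapse = ","),
        n_cells = lengths(members),
        stringsAsFactors = FALSE
      )
    }
  })
  pools <- do.call(rbind, out)
  rownames(pools) <- NULL
  pools
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Average per-cell PSI records into per-pool records
#'
#' Fallback for datasets quantified per cell rather than per pool: records
#' whose pool column holds cell ids are aggregated into one record per
#' (node, pool) using the pool membership table. PSI is averaged across the
#' pool's quantified cells weighted by read support, and read counts are
#' summed, so the pooled record reflects the evidence the pool actually
#' carries. Pseudobulk quantification upstream of this package remains the
#' first choice; this path trades its read-level pooling for a
#' quantification-level approximation.
#'
#' @param records PSI records from [readPsiTable()] whose `pool_id` column
#'   holds cell ids
#' @param pools pool table from [poolCells()]
#' @return PSI records keyed by pool, suitable for [assemblePsiMatrix()]
#' @export
poolAveragePsi <- function(records, pools) {
  cellToPool <- do.call(rbind, lapply(seq_len(nrow(pools)), function(i)
    data.frame(cell_id = strsplit(pools$cells[i], ",", fixed = TRUE)[[1]],
               pool_id = pools$pool_id[i], stringsAsFactors = FALSE)))
  unknown <- setdiff(unique(records$pool_id), cellToPool$cell_id)
  if (length(unknown))
    stop("records reference cell id(s) absent from the pool table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  pool <- cellToPool$pool_id[match(records$pool_id, cellToPool$cell_id)]
  label <- paste0(records$gene, "_", records$node_id)
  key <- paste(label, pool, sep = "\r")
  agg <- lapply(split(seq_len(nrow(records)), key), function(ii) {
    sub <- records[ii, ]
    q <- !is.na(sub$psi) & sub$total_reads > 0
    psi <- if (any(q)) sum(sub$psi[q] * sub$total_reads[q]) /
      sum(sub$total_reads[q]) else NA_real_
    out <- sub[1, ]
    out$psi <- psi
    out$total_reads <- sum(sub$total_reads[q])
    out
  })
  res <- do.call(rbind, agg)
  res$pool_id <- pool[match(names(agg), key)]
  rownames(res) <- NULL
  res[order(res$gene, res$node_id, res$pool_id), ]
}

#' Assemble a pools-by-nodes PSI matrix
#'
#' Joins per-(node, pool) PSI records against a pool table and applies the
#' confident-quantification filter: an entry is present iff its PSI is
#' non-missing and supported by at least `minReads` reads (inclusive bound,
#' default 10). Nodes with no surviving entry are dropped and reported via a
#' warning.
#'
#' @param records data.frame of PSI records from [readPsiTable()] (or the
#'   synthetic generator)
#' @param pools pool table from [poolCells()]
#' @param minReads minimum read support for a confident PSI value
#' @return a [PsiMatrix-class] (nodes as rows, pools as columns)
#' @export
assemblePsiMatrix <- function(records, pools, minReads = 10L) {
  stopifnot(minReads >= 0L)
  unknown <- setdiff(unique(records$pool_id), pools$pool_id)
  if (length(unknown))
    stop("records reference unknown pool id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  label <- paste0(records$gene, "_", records$node_id)
  key <- paste(label, records$pool_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (node, pool) record(s): ",
         paste(gsub("\r", " @ ", utils::head(dup, 5)), collapse = "; "))
  }
  nodeTab <- unique(records[, c("gene", "node_id", "chrom", "start", "end",
                                "strand", "node_type")])
  nodeTab$label <- paste0(nodeTab$gene, "_", nodeTab$node_id)
  if (anyDuplicated(nodeTab$label))
    stop("node label(s) with conflicting annotation: ",
         paste(unique(nodeTab$label[duplicated(nodeTab$label)]), collapse = ", "))
  nodeTab <- nodeTab[order(nodeTab$gene, nodeTab$node_id), ]
  rownames(nodeTab) <- nodeTab$label

  psi <- matrix(NA_real_, nrow = nrow(nodeTab), ncol = nrow(pools),
                dimnames = list(nodeTab$label, pools$pool_id))
  keep <- !is.na(records$psi) & records$total_reads >= minReads
  psi[cbind(match(label[keep], nodeTab$label),
            match(records$pool_id[keep], pools$pool_id))] <- records$psi[keep]

  empty <- rowSums(!is.na(psi)) == 0L
  if (any(empty)) {
    warning(sum(empty), " node(s) with no confidently quantified entry dropped: ",
            paste(utils::head(rownames(psi)[empty], 5), collapse = ", "),
            if (sum(empty) > 5) ", ..." else "")
    psi <- psi[!empty, , drop = FALSE]
    nodeTab <- nodeTab[!empty, , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(psi = psi),
    rowData = S4Vectors::DataFrame(nodeTab[, c("gene", "node_id", "chrom",
                                               "start", "end", "strand",
                                               "node_type")]),
    colData = S4Vectors::DataFrame(pools, row.names = pools$pool_id)
  )
  methods::new("PsiMatrix", se, minReads = as.integer(minReads))
}

#' @describeIn PsiMatrix-class compact summary
#' @param object a `PsiMatrix`
#' @export
setMethod("show", "PsiMatrix", function(object) {
  v <- SummarizedExperiment::assay(object, "psi")
  cat(sprintf(
    "PsiMatrix: %d splicing nodes x %d cell pools (%d cell types)\n",
    nrow(v), ncol(v),
    length(unique(SummarizedExperiment::colData(object)$cell_type))))
  cat(sprintf("  quantified entries: %d (%.1f%%), min reads %d\n",
              sum(!is.na(v)), 100 * mean(!is.na(v)), object@minReads))
  invisible(NULL)
})

#' Write a pool table as TSV
#'
#' @param pools pool table from [poolCells()]
#' @param path output path
#' @param header logical; prepend a `#`-prefixed parameter line
#' @return `path`, invisibly
#' @export
writePoolsTsv <- function(pools, path, header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("# SpliceIndex pools", con)
  utils::write.table(pools, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pool table written by [writePoolsTsv()]
#' @param path TSV path
#' @return pool data.frame
#' @export
readPoolsTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", colClasses = c(
                      pool_id = "character", cell_type = "character",
                      cells = "character", n_cells = "integer"))
}
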