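#' Configuration for the synthetic splicing dataset generator
#'
#' Collects and validates the parameters of [simulateDataset()]. The
#' defaults describe a mid-sized full-length scRNA-seq experiment after
#' pooling: 50 genes of 8-12 nodes (about 500 nodes), 10 cell types with 8
#' pools of 5 cells each, node baseline inclusion drawn from a Beta
#' distribution, truncated-Gaussian measurement noise on PSI, and a small
#' unquantified fraction on top of a read-depth filter.
#'
#' @param n_genes number of genes
#' @param nodes_per_gene integer range (min, max) of nodes per gene
#' @param n_cell_types number of cell types
#' @param pools_per_type integer range (min, max) of pools per cell type
#' @param pool_size cells per pool (default 5)
#' @param baseline_shape Beta shape pair for node baseline PSI
#' @param noise_sd per-entry Gaussian noise sd on PSI (default 0.05)
#' @param na_rate probability an entry is unquantified (default 0.05)
#' @param read_fail_rate fraction of entries whose read support falls below
#'   the default 10-read filter (default 0.05)
#' @param mean_reads mean read support of confidently covered entries
#' @param planted_markers list of `list(cell_type=, delta=, direction=)`
#'   (`direction` is `"inclusion"` or `"exclusion"`)
#' @param planted_mxe list of `list(cell_type=, psi_high=, psi_low=)` with
#'   `psi_high + psi_low = 1`
#' @param planted_blocks list of
#'   `list(cell_type=, block_len=, delta=, direction=)` (`direction` is
#'   `"above"` or `"below"`)
#' @param seed RNG seed; the full output is deterministic per seed
#' @return a validated list of class `"SimConfig"`
#' @export
simConfig <- function(n_genes = 50L, nodes_per_gene = c(8L, 12L),
                      n_cell_types = 10L, pools_per_type = c(8L, 8L),
                      pool_size = 5L, baseline_shape = c(2, 2),
                      noise_sd = 0.05, na_rate = 0.05,
                      read_fail_rate = 0.05, mean_reads = 30,
                      planted_markers = list(), planted_mxe = list(),
                      planted_blocks = list(), seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              nodes_per_gene = as.integer(nodes_per_gene),
              n_cell_types = as.integer(n_cell_types),
              pools_per_type = as.integer(pools_per_type),
              pool_size = as.integer(pool_size),
              baseline_shape = baseline_shape, noise_sd = noise_sd,
              na_rate = na_rate, read_fail_rate = read_fail_rate,
              mean_reads = mean_reads,
              planted_markers = planted_markers,
              planted_mxe = planted_mxe, planted_blocks = planted_blocks,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L, length(cfg$nodes_per_gene) == 2L,
            cfg$nodes_per_gene[1] >= 2L,
            cfg$nodes_per_gene[1] <= cfg$nodes_per_gene[2],
            cfg$n_cell_types >= 2L, length(cfg$pools_per_type) == 2L,
            cfg$pools_per_type[1] >= 1L, cfg$pool_size >= 1L,
            all(cfg$baseline_shape > 0), cfg$noise_sd >= 0,
            cfg$na_rate >= 0, cfg$na_rate <= 1,
            cfg$read_fail_rate >= 0, cfg$read_fail_rate <= 1,
            cfg$mean_reads >= 10)
  types <- simCellTypes(cfg$n_cell_types)
  checkPlant <- function(entries, what, fields) {
    for (e in entries) {
      if (!all(fields %in% names(e)))
        stop("planted ", what, " needs fields: ", paste(fields, collapse = ", "))
      if (!e$cell_type %in% types)
        stop("planted ", what, " references unknown cell type ", e$cell_type)
    }
  }
  checkPlant(cfg$planted_markers, "marker", c("cell_type", "delta", "direction"))
  checkPlant(cfg$planted_mxe, "MXE pair", c("cell_type", "psi_high", "psi_low"))
  checkPlant(cfg$planted_blocks, "block",
             c("cell_type", "block_len", "delta", "direction"))
  for (e in cfg$planted_markers)
    if (e$delta <= 0 || e$delta > 1 || 0.5 + e$delta / 2 > 1)
      stop("planted marker delta out of range: ", e$delta)
  for (e in cfg$planted_mxe)
    if (abs(e$psi_high + e$psi_low - 1) > 1e-8 || e$psi_high <= e$psi_low)
      stop("planted MXE must have psi_high + psi_low = 1 and psi_high > psi_low")
  for (e in cfg$planted_blocks) {
    if (e$block_len + 2L > cfg$nodes_per_gene[1])
      stop("planted block of ", e$block_len,
           " exons does not fit a gene of ", cfg$nodes_per_gene[1],
           " nodes (flanks needed)")
    if (!e$direction %in% c("above", "below"))
      stop("planted block direction must be 'above' or 'below'")
  }
  nPlantGenes <- length(cfg$planted_markers) + length(cfg$planted_mxe) +
    length(cfg$planted_blocks)
  if (nPlantGenes > cfg$n_genes)
    stop("more planted patterns (", nPlantGenes, ") than genes (",
         cfg$n_genes, ")")
  if (length(cfg$planted_mxe) && cfg$nodes_per_gene[1] < 4L)
    stop("planted MXE pairs need genes of at least 4 nodes")
  structure(cfg, class = "SimConfig")
}

simCellTypes <- function(n) sprintf("T%02d", seq_len(n))

#' Simulate a synthetic splicing dataset with planted ground truth
#'
#' Generates a Whippet-style PSI record table, a cell annotation table and a
#' node-to-exon map, together with the planted truth, all deterministic per
#' seed. Non-planted entries are `clamp(base + N(0, noise_sd), 0, 1)` with
#' the node baseline drawn from the configured Beta distribution. Planted
#' markers shift the target cell type by `delta`; planted MXE pairs are
#' generated complementary (`psi_a + psi_b = 1` in every pool, roles
#' reversed only in the target type, which makes them pass the
#' mean-sum/sd-difference candidate filters by construction); planted
#' blocks share a common baseline (within the scan tolerance) and are
#' jointly shifted in the target type, with flanking nodes offset so the
#' block has sharp boundaries. Unquantified entries are drawn independently
#' at `na_rate`, and read support is drawn so that about `read_fail_rate`
#' of entries fall below the 10-read filter.
#'
#' @param config a [simConfig()] object
#' @return list of class `"SpliceSim"` with `records` (PSI record
#'   data.frame as from [readPsiTable()]), `annotations` (cell table),
#'   `pools` (pool table from [poolCells()]), `exon_map`, `truth` (lists
#'   `markers`, `mxe`, `blocks`) and `config`
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  withSeed(cfg$seed, {
    types <- simCellTypes(cfg$n_cell_types)
    nPoolsType <- if (cfg$pools_per_type[1] == cfg$pools_per_type[2])
      rep(cfg$pools_per_type[1], cfg$n_cell_types)
    else sample(cfg$pools_per_type[1]:cfg$pools_per_type[2],
                cfg$n_cell_types, replace = TRUE)
    annotations <- do.call(rbind, lapply(seq_along(types), function(i)
      data.frame(cell_id = sprintf("%s_c%03d", types[i],
                                   seq_len(nPoolsType[i] * cfg$pool_size)),
                 cell_type = types[i], stringsAsFactors = FALSE)))
    pools <- poolCells(annotations, poolSize = cfg$pool_size, seed = cfg$seed)
    nP <- nrow(pools)
    poolType <- pools$cell_type

    genes <- sprintf("G%03d", seq_len(cfg$n_genes))
    nNodesGene <- if (cfg$nodes_per_gene[1] == cfg$nodes_per_gene[2])
      rep(cfg$nodes_per_gene[1], cfg$n_genes)
    else sample(cfg$nodes_per_gene[1]:cfg$nodes_per_gene[2],
                cfg$n_genes, replace = TRUE)

    # node table: CE-rich types, first/last node always CE, plain coordinates
    nodeTab <- do.call(rbind, lapply(seq_len(cfg$n_genes), function(g) {
      k <- nNodesGene[g]
      ty <- sample(c("CE", "AA", "AD", "RI"), k, replace = TRUE,
                   prob = c(0.7, 0.1, 0.1, 0.1))
      ty[c(1, k)] <- "CE"
      width <- sample(60:240, k, replace = TRUE)
      start <- 10000L * g + cumsum(c(0L, width[-k] + 400L))
      data.frame(gene = genes[g], node_id = seq_len(k),
                 chrom = sprintf("chr%d", (g - 1L) %% 5L + 1L),
                 start = start, end = start + width,
                 strand = if (g %% 2L) "+" else "-", node_type = ty,
                 stringsAsFactors = FALSE)
    }))
    nN <- nrow(nodeTab)
    base <- stats::rbeta(nN, cfg$baseline_shape[1], cfg$baseline_shape[2])
    psi <- matrix(rep(base, each = nP), nrow = nP)  # pools x nodes

    nodeRow <- function(g, id) which(nodeTab$gene == g & nodeTab$node_id == id)
    plantGene <- 0L
    nextGene <- function() { plantGene <<- plantGene + 1L; genes[plantGene] }

    truthMx <- truthBl <- truthMk <- NULL
    for (e in cfg$planted_mxe) {
      g <- nextGene()
      idA <- 3L; idB <- 4L
      rA <- nodeRow(g, idA); rB <- nodeRow(g, idB)
      nodeTab$node_type[c(rA, rB)] <- "CE"
      tgt <- poolType == e$cell_type
      a <- ifelse(tgt, e$psi_high, 0.5)
      psi[, rA] <- a
      psi[, rB] <- 1 - a  # complementary everywhere; noise added later mirrors
      truthMx <- rbind(truthMx, data.frame(
        node_a = paste0(g, "_", idA), node_b = paste0(g, "_", idB),
        cell_type = e$cell_type, orientation = "a_in_b_out",
        stringsAsFactors = FALSE))
    }
    for (e in cfg$planted_blocks) {
      g <- nextGene()
      k <- nNodesGene[match(g, genes)]
      first <- 2L
      ids <- seq(first, first + e$block_len - 1L)
      rows <- vapply(ids, function(id) nodeRow(g, id), 1L)
      nodeTab$node_type[rows] <- "CE"
      blockBase <- if (e$direction == "above") 0.3 else 0.7
      shift <- if (e$direction == "above") e$delta else -e$delta
      tgt <- poolType == e$cell_type
      for (rr in rows) psi[, rr] <- blockBase + ifelse(tgt, shift, 0)
      # sharp boundaries: flanking nodes sit well outside the scan tolerance
      flanks <- c(nodeRow(g, first - 1L),
                  if (first + e$block_len <= k) nodeRow(g, first + e$block_len))
      for (rr in flanks) psi[, rr] <- min(blockBase + 0.35, 0.95)
      truthBl <- rbind(truthBl, data.frame(
        gene = g, node_start = min(ids), node_end = max(ids),
        cell_type = e$cell_type, direction = e$direction,
        stringsAsFactors = FALSE))
    }
    for (e in cfg$planted_markers) {
      g <- nextGene()
      id <- 2L
      rr <- nodeRow(g, id)
      markerBase <- if (e$direction == "inclusion") 0.5 - e$delta / 2
                    else 0.5 + e$delta / 2
      shift <- if (e$direction == "inclusion") e$delta else -e$delta
      tgt <- poolType == e$cell_type
      psi[, rr] <- markerBase + ifelse(tgt, shift, 0)
      truthMk <- rbind(truthMk, data.frame(
        node = paste0(g, "_", id), cell_type = e$cell_type,
        direction = e$direction, stringsAsFactors = FALSE))
    }

    # measurement noise, mirrored within planted-MXE pairs to keep psi_a +
    # psi_b = 1 exactly (equal sds, mean sum 1)
    noise <- matrix(stats::rnorm(nP * nN, 0, cfg$noise_sd), nrow = nP)
    for (i in seq_len(nrow(truthMx %||% data.frame()))) {
      rA <- which(paste0(nodeTab$gene, "_", nodeTab$node_id) == truthMx$node_a[i])
      rB <- which(paste0(nodeTab$gene, "_", nodeTab$node_id) == truthMx$node_b[i])
      noise[, rB] <- -noise[, rA]
    }
    psi <- pmin(1, pmax(0, psi + noise))

    na <- matrix(stats::runif(nP * nN) < cfg$na_rate, nrow = nP)
    psi[na] <- NA_real_
    lowReads <- stats::runif(nP * nN) < cfg$read_fail_rate
    reads <- matrix(10L + stats::rpois(nP * nN, cfg$mean_reads - 10), nrow = nP)
    reads[lowReads] <- sample(0:9, sum(lowReads), replace = TRUE)

    records <- data.frame(
      gene = rep(nodeTab$gene, each = nP),
      node_id = rep(nodeTab$node_id, each = nP),
      chrom = rep(nodeTab$chrom, each = nP),
      start = rep(nodeTab$start, each = nP),
      end = rep(nodeTab$end, each = nP),
      strand = rep(nodeTab$strand, each = nP),
      node_type = rep(nodeTab$node_type, each = nP),
      pool_id = rep(pools$pool_id, times = nN),
      psi = as.vector(psi),
      total_reads = as.vector(reads),
      stringsAsFactors = FALSE
    )
    exonMap <- data.frame(gene = nodeTab$gene, node_id = nodeTab$node_id,
                          exon_id = sprintf("%s:e%d", nodeTab$gene,
                                            nodeTab$node_id),
                          stringsAsFactors = FALSE)
    structure(list(records = records, annotations = annotations,
                   pools = pools, exon_map = exonMap,
                   truth = list(markers = truthMk %||% emptyMarkers(),
                                mxe = truthMx %||% emptyMxe(),
                                blocks = truthBl %||% emptyBlocks()),
                   config = cfg),
              class = "SpliceSim")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
emptyMarkers <- function() data.frame(node = character(),
                                      cell_type = character(),
                                      direction = character())
emptyMxe <- function() data.frame(node_a = character(), node_b = character(),
                                  cell_type = character(),
                                  orientation = character())
emptyBlocks <- function() data.frame(gene = character(),
                                     node_start = integer(),
                                     node_end = integer(),
                                     cell_type = character(),
                                     direction = character())

#' @export
print.SpliceSim <- function(x, ...) {
  cat(sprintf(
    "SpliceSim: %d genes, %d nodes, %d cell types, %d pools (seed %d)\n",
    x$config$n_genes, nrow(x$exon_map), x$config$n_cell_types,
    nrow(x$pools), x$config$seed))
  cat(sprintf("  planted: %d markers, %d MXE pairs, %d blocks\n",
              nrow(x$truth$markers), nrow(x$truth$mxe),
              nrow(x$truth$blocks)))
  invisible(x)
}

#' Write a simulated dataset as a plain-text fixture
#'
#' Writes `psi.tsv` (Whippet-style PSI records with a `Pool` column),
#' `cells.tsv` (cell annotations), `exon_map.tsv` and `truth.json` into
#' `outdir`. Reading the files back reproduces the in-memory objects.
#'
#' @param sim a `"SpliceSim"` from [simulateDataset()]
#' @param outdir output directory (created if missing)
#' @return named character vector of the written paths, invisibly
#' @export
writeFixture <- function(sim, outdir) {
  stopifnot(inherits(sim, "SpliceSim"))
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stop("cannot create output directory: ", outdir)
  rec <- sim$records
  psiTab <- data.frame(
    Gene = rec$gene, Node = rec$node_id,
    Coord = sprintf("%s:%d-%d", rec$chrom, rec$start, rec$end),
    Strand = rec$strand, Type = rec$node_type,
    Psi = ifelse(is.na(rec$psi), "NA", formatC(rec$psi, digits = 6,
                                               format = "f")),
    Total_Reads = rec$total_reads, Pool = rec$pool_id,
    stringsAsFactors = FALSE)
  paths <- c(psi = file.path(outdir, "psi.tsv"),
             cells = file.path(outdir, "cells.tsv"),
             exon_map = file.path(outdir, "exon_map.tsv"),
             truth = file.path(outdir, "truth.json"))
  utils::write.table(psiTab, paths["psi"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$annotations, paths["cells"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$exon_map, paths["exon_map"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(sim$truth, dataframe = "rows", pretty = TRUE),
             paths["truth"])
  invisible(paths)
}
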