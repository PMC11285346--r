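statNode <- function(m, x) c(m, m - x, m + x)

test_that("the scan extends on similar stats and breaks on a jump", {
  vals <- cbind(statNode(0.50, 0.10), statNode(0.55, 0.12),
                statNode(0.52, 0.08), statNode(0.90, 0.10))
  idx <- buildIndex(densePsiMatrix(vals, c("A", "B", "C"), nodesPerGene = 4L))
  runs <- seedAndExtendBlocks(idx, "G001")
  expect_equal(runs, list(c("G001_1", "G001_2", "G001_3")))
})

test_that("identical stats give one run spanning the gene", {
  vals <- do.call(cbind, rep(list(statNode(0.5, 0.1)), 6))
  idx <- buildIndex(densePsiMatrix(vals, c("A", "B", "C"), nodesPerGene = 6L))
  runs <- seedAndExtendBlocks(idx, "G001")
  expect_equal(runs, list(paste0("G001_", 1:6)))
})

test_that("non-CE nodes may extend but never seed a run", {
  vals <- do.call(cbind, rep(list(statNode(0.5, 0.1)), 5))
  types <- c("AA", "CE", "AD", "CE", "CE")
  idx <- buildIndex(densePsiMatrix(vals, c("A", "B", "C"), nodesPerGene = 5L,
                                   nodeTypes = types))
  runs <- seedAndExtendBlocks(idx, "G001")
  # run starts at node 2 (first CE), absorbs the AD node and the rest
  expect_equal(runs, list(paste0("G001_", 2:5)))
  runsCE <- seedAndExtendBlocks(idx, "G001", ceOnly = TRUE)
  expect_equal(runsCE, list(paste0("G001_", 4:5)))
})

test_that("the scan agrees with an independent re-implementation", {
  set.seed(17)
  for (rep in 1:6) {
    nNodes <- sample(6:14, 1)
    means <- runif(nNodes, 0.3, 0.7)
    sds <- runif(nNodes, 0.02, 0.2)
    vals <- do.call(cbind, lapply(seq_len(nNodes), function(i)
      statNode(means[i], sds[i])))
    types <- sample(c("CE", "AA"), nNodes, replace = TRUE, prob = c(0.7, 0.3))
    idx <- buildIndex(densePsiMatrix(vals, c("A", "B", "C"),
                                     nodesPerGene = nNodes,
                                     nodeTypes = types))
    # oracle: direct left-to-right application of the rule on known stats
    st <- nodeStats(idx)
    st <- st[order(st$node_id), ]
    oracle <- list(); cur <- integer(0)
    closeRun <- function(runs, cur, labels) {
      if (length(cur) >= 2L) runs[[length(runs) + 1L]] <- labels[cur]
      runs
    }
    for (i in seq_len(nrow(st))) {
      if (length(cur) &&
          abs(st$mean_psi[i] - mean(st$mean_psi[cur])) <= 0.1 &&
          abs(st$sd_psi[i] - mean(st$sd_psi[cur])) <= 0.1) {
        cur <- c(cur, i)
      } else {
        oracle <- closeRun(oracle, cur, rownames(st))
        cur <- if (st$node_type[i] == "CE") i else integer(0)
      }
    }
    oracle <- closeRun(oracle, cur, rownames(st))
    expect_equal(seedAndExtendBlocks(idx, "G001"), oracle)
  }
})

test_that("a planted block is recovered with direction and confidence", {
  cfg <- simConfig(n_genes = 15, nodes_per_gene = c(8, 10), n_cell_types = 5,
                   planted_blocks = list(list(cell_type = "T04",
                                              block_len = 4, delta = 0.4,
                                              direction = "above")),
                   seed = 401)
  sim <- simulateDataset(cfg)
  idx <- buildIndex(assemblePsiMatrix(sim$records, sim$pools))
  res <- suppressMessages(detectBlocks(idx, exonMap = sim$exon_map))
  truth <- sim$truth$blocks
  hit <- res[res$gene == truth$gene & res$direction == truth$direction &
               res$cell_type == truth$cell_type &
               res$node_start <= truth$node_start &
               res$node_end >= truth$node_end, ]
  expect_gte(nrow(hit), 1L)
  expect_true(all(hit$p_value <= 0.05))
  expect_true(any(hit$high_confidence))
})

test_that("blocks collapsing to fewer than three exons are rejected", {
  cfg <- simConfig(n_genes = 10, nodes_per_gene = c(8, 8), n_cell_types = 5,
                   planted_blocks = list(list(cell_type = "T02",
                                              block_len = 3, delta = 0.4,
                                              direction = "above")),
                   seed = 402)
  sim <- simulateDataset(cfg)
  idx <- buildIndex(assemblePsiMatrix(sim$records, sim$pools))
  truth <- sim$truth$blocks
  # with one exon per node the 3-node block passes
  withMap <- suppressMessages(detectBlocks(idx, exonMap = sim$exon_map))
  expect_gte(nrow(withMap[withMap$gene == truth$gene, ]), 1L)
  # collapse the block's first two nodes into one exon: only 2 exons remain
  em <- sim$exon_map
  sel <- em$gene == truth$gene & em$node_id %in%
    c(truth$node_start, truth$node_start + 1L)
  em$exon_id[sel] <- "mergedExon"
  collapsed <- suppressMessages(detectBlocks(idx, exonMap = em))
  expect_equal(nrow(collapsed[collapsed$gene == truth$gene &
                                collapsed$node_start == truth$node_start &
                                collapsed$node_end == truth$node_end, ]), 0L)
})

test_that("unknown exon-map entries warn and are ignored", {
  vals <- do.call(cbind, rep(list(statNode(0.5, 0.1)), 4))
  idx <- buildIndex(densePsiMatrix(vals, c("A", "B", "C"), nodesPerGene = 4L))
  em <- data.frame(gene = c("G001", "Nope"), node_id = c(1L, 9L),
                   exon_id = c("e1", "e9"))
  expect_warning(detectBlocks(idx, exonMap = em), "unknown nodes")
})

test_that("reported blocks are maximal and directions stay separate", {
  cfg <- simConfig(n_genes = 12, nodes_per_gene = c(8, 10), n_cell_types = 5,
                   planted_blocks = list(list(cell_type = "T01",
                                              block_len = 4, delta = 0.4,
                                              direction = "below")),
                   seed = 403)
  sim <- simulateDataset(cfg)
  idx <- buildIndex(assemblePsiMatrix(sim$records, sim$pools))
  res <- suppressMessages(detectBlocks(idx, exonMap = sim$exon_map))
  # no reported block is a strict prefix of another candidate run of its gene
  for (i in seq_len(nrow(res))) {
    runs <- seedAndExtendBlocks(idx, res$gene[i])
    nodes <- strsplit(res$nodes[i], ",")[[1]]
    for (run in runs) {
      if (length(run) > length(nodes))
        expect_false(identical(run[seq_along(nodes)], nodes))
    }
  }
  # a pool cannot match both directions of one block
  for (i in seq_len(nrow(res))) {
    nodes <- strsplit(res$nodes[i], ",")[[1]]
    above <- Reduce(intersect, lapply(nodes, function(l)
      SpliceIndex:::sidePositions(idx, l, "above")))
    below <- Reduce(intersect, lapply(nodes, function(l)
      SpliceIndex:::sidePositions(idx, l, "below")))
    expect_length(intersect(above, below), 0L)
  }
})

test_that("null simulations produce no high-confidence blocks", {
  for (seed in 410:412) {
    sim <- simulateDataset(simConfig(n_genes = 12, nodes_per_gene = c(6, 8),
                                     n_cell_types = 4, seed = seed))
    idx <- buildIndex(assemblePsiMatrix(sim$records, sim$pools))
    res <- suppressMessages(detectBlocks(idx, exonMap = sim$exon_map))
    expect_equal(sum(res$high_confidence), 0L)
  }
})
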