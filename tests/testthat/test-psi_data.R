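test_that("readPsiTable parses rows, missing PSI, and rejects bad input", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Gene\tNode\tCoord\tStrand\tType\tPsi\tTotal_Reads\tPool",
    "Gria2\t28\tchr3:80692286-80692400\t+\tCE\t0.85\t25\tp1",
    "Gria2\t29\tchr3:80691000-80691100\t+\tCE\tNA\t3\tp1"), tsv)
  rec <- readPsiTable(tsv)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$gene[1], "Gria2")
  expect_equal(rec$node_id[1], 28L)
  expect_equal(rec$chrom[1], "chr3")
  expect_equal(rec$start[1], 80692286L)
  expect_equal(rec$end[1], 80692400L)
  expect_equal(rec$psi[1], 0.85)
  expect_equal(rec$total_reads[1], 25L)
  expect_true(is.na(rec$psi[2]))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tNode\tCoord\tStrand\tType\tPsi\tTotal_Reads\tPool",
               "G1\t3\tchr1:100-90\t+\tCE\t0.5\t12\tp1"), bad)
  expect_error(readPsiTable(bad), "start > end")

  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tNode\tCoord\tStrand\tType\tPsi\tTotal_Reads\tPool",
               "G1\t3\tchr1_100_200\t+\tCE\t0.5\t12\tp1"), bad2)
  expect_error(readPsiTable(bad2), "malformed coordinate")

  bad3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tNode\tCoord\tStrand\tType\tPsi\tTotal_Reads\tPool",
               "G1\t3\tchr1:100-200\t+\tCE\t1.5\t12\tp1"), bad3)
  expect_error(readPsiTable(bad3), "outside \\[0, 1\\]")
})

test_that("readPsiTable reads gzip-compressed tables", {
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "w")
  writeLines(c("Gene\tNode\tCoord\tStrand\tType\tPsi\tTotal_Reads\tPool",
               "G1\t1\tchr1:1-10\t+\tCE\t0.4\t20\tp1"), con)
  close(con)
  expect_equal(readPsiTable(gz)$psi, 0.4)
})

test_that("poolCells chops shuffled cells into pools with a remainder pool", {
  ann <- data.frame(cell_id = paste0("c", 1:12), cell_type = "T1")
  pools <- poolCells(ann, poolSize = 5, seed = 7)
  expect_equal(sort(pools$n_cells), c(2L, 5L, 5L))
  expect_equal(poolCells(ann, poolSize = 5, seed = 7), pools)  # deterministic

  one <- poolCells(data.frame(cell_id = paste0("c", 1:5), cell_type = "T1"),
                   poolSize = 5, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_cells, 5L)
})

test_that("pooling partitions cells within cell type", {
  set.seed(11)
  for (rep in 1:5) {
    nc <- sample(20:60, 1)
    ann <- data.frame(cell_id = paste0("c", seq_len(nc)),
                      cell_type = sample(c("A", "B", "C"), nc, replace = TRUE))
    pools <- poolCells(ann, poolSize = sample(2:6, 1), seed = rep)
    members <- strsplit(pools$cells, ",")
    expect_setequal(unlist(members), ann$cell_id)        # every cell once
    expect_false(anyDuplicated(unlist(members)) > 0)
    for (i in seq_len(nrow(pools)))                      # types homogeneous
      expect_true(all(ann$cell_type[match(members[[i]], ann$cell_id)] ==
                        pools$cell_type[i]))
  }
})

test_that("assemblePsiMatrix applies the inclusive >=10 read filter", {
  pools <- data.frame(pool_id = c("p1", "p2"), cell_type = "A",
                      cells = "x", n_cells = 1L)
  rec <- data.frame(gene = "G1", node_id = c(1L, 1L, 2L, 2L), chrom = "chr1",
                    start = 1L, end = 10L, strand = "+", node_type = "CE",
                    pool_id = c("p1", "p2", "p1", "p2"),
                    psi = c(0.7, 0.7, 0.3, 0.4),
                    total_reads = c(9L, 10L, 50L, 50L))
  mat <- assemblePsiMatrix(rec, pools, minReads = 10)
  v <- SummarizedExperiment::assay(mat, "psi")
  expect_true(is.na(v["G1_1", "p1"]))   # 9 reads: filtered
  expect_equal(v["G1_1", "p2"], 0.7)    # exactly 10 reads: kept
})

test_that("assemblePsiMatrix drops empty nodes and rejects duplicates", {
  pools <- data.frame(pool_id = paste0("p", 1:4), cell_type = "A",
                      cells = "x", n_cells = 1L)
  rec <- expand.grid(node_id = 1:3, pool_id = paste0("p", 1:4),
                     stringsAsFactors = FALSE)
  rec$gene <- "G1"; rec$chrom <- "chr1"; rec$start <- 1L; rec$end <- 10L
  rec$strand <- "+"; rec$node_type <- "CE"; rec$psi <- 0.5
  rec$total_reads <- ifelse(rec$node_id == 2, 5L, 30L)  # node 2 all below 10
  expect_warning(mat <- assemblePsiMatrix(rec, pools), "G1_2")
  expect_equal(rownames(mat), c("G1_1", "G1_3"))
  expect_equal(dim(SummarizedExperiment::assay(mat, "psi")), c(2L, 4L))

  dup <- rbind(rec, rec[1, ])
  expect_error(suppressWarnings(assemblePsiMatrix(dup, pools)), "duplicate")
})

test_that("raising minReads never adds present entries", {
  set.seed(3)
  pools <- data.frame(pool_id = paste0("p", 1:6), cell_type = "A",
                      cells = "x", n_cells = 1L)
  rec <- expand.grid(node_id = 1:8, pool_id = pools$pool_id,
                     stringsAsFactors = FALSE)
  rec$gene <- "G1"; rec$chrom <- "chr1"; rec$start <- 1L; rec$end <- 10L
  rec$strand <- "+"; rec$node_type <- "CE"
  rec$psi <- runif(nrow(rec)); rec$total_reads <- rpois(nrow(rec), 12)
  present <- vapply(c(0L, 5L, 10L, 15L, 20L), function(mr) {
    m <- tryCatch(suppressWarnings(assemblePsiMatrix(rec, pools, minReads = mr)),
                  error = function(e) NULL)
    if (is.null(m)) 0L else sum(!is.na(SummarizedExperiment::assay(m, "psi")))
  }, 1L)
  expect_true(all(diff(present) <= 0))
})

test_that("pool table write/read round trip is lossless", {
  ann <- data.frame(cell_id = paste0("c", 1:17),
                    cell_type = rep(c("A", "B"), c(9, 8)))
  pools <- poolCells(ann, poolSize = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePoolsTsv(pools, path)
  expect_equal(readPoolsTsv(path), pools)
})

test_that("per-cell PSI records can be averaged into pools", {
  ann <- data.frame(cell_id = paste0("c", 1:4), cell_type = "A")
  pools <- poolCells(ann, poolSize = 4, seed = 1)
  rec <- data.frame(gene = "G1", node_id = 1L, chrom = "chr1", start = 1L,
                    end = 10L, strand = "+", node_type = "CE",
                    pool_id = paste0("c", 1:4),
                    psi = c(0.2, 0.4, NA, 0.8),
                    total_reads = c(10L, 30L, 0L, 20L))
  pooled <- poolAveragePsi(rec, pools)
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$pool_id, pools$pool_id[1])
  # read-weighted mean over quantified cells
  expect_equal(pooled$psi, (0.2 * 10 + 0.4 * 30 + 0.8 * 20) / 60)
  expect_equal(pooled$total_reads, 60L)
  # unknown cells are an error, and the output feeds assemblePsiMatrix
  expect_error(poolAveragePsi(transform(rec, pool_id = "c9"), pools),
               "absent from the pool table")
  mat <- assemblePsiMatrix(pooled, pools)
  expect_equal(dim(SummarizedExperiment::assay(mat, "psi")), c(1L, 1L))
})
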