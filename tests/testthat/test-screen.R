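# Expression-screen arithmetic

hand_matrix <- function() {
  # 3 genes (g2 mitochondrial) x 6 cells, hand-checkable
  m <- matrix(c(5, 0, 3,
                5, 5, 0,
                0, 0, 0,
                1, 1, 1,
                0, 2, 0,
                10, 0, 10), nrow = 3,
              dimnames = list(c("g1", "MT-g2", "g3"), paste0("c", 1:6)))
  count_matrix(m, "A", mito_genes = "MT-g2")
}

test_that("per-cell QC metrics match hand arithmetic", {
  qc <- compute_cell_qc(hand_matrix())
  expect_equal(qc$nFeature, c(2L, 2L, 0L, 3L, 1L, 2L))
  expect_equal(qc$nCount, c(8L, 10L, 0L, 3L, 2L, 20L))
  expect_equal(qc$pct_mito, c(0, 50, 0, 100 / 3, 100, 0))
  expect_error(count_matrix(matrix(1, 2, 2, dimnames = list(c("a", "b"),
                                                            c("x", "y"))),
                            mito_genes = "zz"),
               class = "oq_error_parameter")
})

test_that("QC filter inequalities are strict at every boundary", {
  qc <- tibble::tibble(
    cell = paste0("c", 1:7),
    nFeature = c(200, 199, 8000, 8001, 500, 500, 500),
    nCount = c(1000, 1000, 1000, 1000, 50000, 50001, 1000),
    pct_mito = c(5, 5, 5, 5, 5, 5, 20.0001))
  surv <- qc_filter(qc)
  expect_identical(surv, c("c1", "c3", "c5"))
})

test_that("downsampling is seeded, order-preserving and proportion-faithful", {
  ex <- make_count_experiment(n_genes = 60, n_cells_per_sample = 10000,
                              n_clusters = 3, seed = 2)
  m <- ex$sample_a
  d1 <- downsample_cells(m, 6400, seed = 5)
  d2 <- downsample_cells(m, 6400, seed = 5)
  expect_identical(colnames(d1$counts), colnames(d2$counts))
  expect_equal(ncol(d1$counts), 6400)
  # n = total keeps every cell in order
  all_kept <- downsample_cells(m, 10000, seed = 5)
  expect_identical(colnames(all_kept$counts), colnames(m$counts))
  # 10,000 -> 6,400: cluster proportions stay within 3 percentage points of
  # the source across 50 seeds (hypergeometric sampling)
  src_prop <- prop.table(table(m$clusters))
  for (s in 1:50) {
    d <- downsample_cells(m, 6400, seed = s)
    expect_lt(max(abs(prop.table(table(d$clusters)) - src_prop)), 0.03)
  }
  expect_error(downsample_cells(m, 0), class = "oq_error_parameter")
  expect_error(downsample_cells(m, 20000), class = "oq_error_parameter")
  expect_warning(dd <- downsample_cells(m, 20000, allow_smaller = TRUE))
  expect_identical(dd, m)
})

test_that("log2 sample ratios follow the pseudocount formula", {
  # two genes, one cluster, counts chosen so normalized means are 8 vs 2
  a <- count_matrix(matrix(c(8, 2, 9990, 8, 2, 9990), 3,
                           dimnames = list(c("g1", "g2", "bulk"),
                                           c("a1", "a2"))),
                    "A", clusters = c("1", "1"))
  b <- count_matrix(matrix(c(2, 8, 9990, 2, 8, 9990), 3,
                           dimnames = list(c("g1", "g2", "bulk"),
                                           c("b1", "b2"))),
                    "B", clusters = c("1", "1"))
  rt <- cluster_aggregate_log2ratio(a, b, pseudocount = 0)
  expect_equal(rt$log2_ratio[rt$gene == "g1"], 2)
  expect_equal(rt$log2_ratio[rt$gene == "g2"], -2)

  # antisymmetry under sample swap, shared pseudocount
  ex <- make_count_experiment(n_genes = 80, n_cells_per_sample = 60,
                              n_clusters = 2, seed = 3)
  r_ab <- cluster_aggregate_log2ratio(ex$sample_a, ex$sample_b)
  r_ba <- cluster_aggregate_log2ratio(ex$sample_b, ex$sample_a)
  expect_equal(r_ab$log2_ratio, -r_ba$log2_ratio)

  # mean_a == mean_b gives 0 for any pseudocount
  same <- cluster_aggregate_log2ratio(ex$sample_a, ex$sample_a,
                                      pseudocount = 0.37)
  expect_true(all(same$log2_ratio == 0))

  # pseudobulk mode collapses clusters
  pb <- cluster_aggregate_log2ratio(ex$sample_a, ex$sample_b,
                                    mode = "pseudobulk")
  expect_identical(unique(pb$cluster), "all")

  # a cluster present in one sample only is flagged, not dropped
  b_only <- count_matrix(ex$sample_b$counts, "B",
                         clusters = rep("9", ncol(ex$sample_b$counts)))
  r_flag <- cluster_aggregate_log2ratio(ex$sample_a, b_only)
  expect_true(all(!r_flag$shared))
  expect_true(all(is.na(r_flag$log2_ratio)))
})

test_that("DE selection is strict, ordered and permutation-invariant", {
  rt <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"), cluster = "1",
    mean_a = 1, mean_b = 1,
    log2_ratio = c(1.0, 1.01, -1.01, 0), shared = TRUE)
  sel <- select_de_genes(rt)
  expect_identical(sel$gene, c("g2", "g3"))
  expect_identical(sel$direction, c("up", "down"))
  # row permutation does not change the output
  expect_identical(select_de_genes(rt[c(3, 1, 4, 2), ]), sel)
  expect_error(select_de_genes(rt, threshold = 0),
               class = "oq_error_parameter")
})

test_that("enrichment cutoff assignment keeps >= 7.5 and flags ties", {
  e <- tibble::tibble(
    cluster = c("1", "1", "2", "3", "3"),
    set = c("neuron", "glia", "glia", "zeta", "astro"),
    nes = c(7.5, 7.2, 3, 9, 9))
  out <- filter_enrichment(e)
  expect_identical(out$assignment[out$cluster == "1"], "neuron")  # 7.5 kept
  expect_identical(out$assignment[out$cluster == "2"], "unassigned")
  expect_identical(out$assignment[out$cluster == "3"], "astro")   # lexicographic
  expect_true(out$tie[out$cluster == "3"])
})

test_that("binomial overrepresentation matches exact tail sums", {
  bg <- paste0("g", 1:10)
  # set = background: p0 = 1, k = n, raw p = 1
  r <- overrepresentation_test(c("g1", "g2"), bg, list(all = bg))
  expect_identical(r$p0, 1)
  expect_identical(r$p_raw, 1)

  # worked case: n = 5, p0 = 0.5, k = 5 -> 0.03125; m = 2 sets -> 0.0625
  bg2 <- paste0("g", 1:100)
  sets <- list(hit = paste0("g", 1:50), other = paste0("g", 51:100))
  r2 <- overrepresentation_test(paste0("g", 1:5), bg2, sets)
  expect_identical(r2$p_raw[r2$set == "hit"], 0.03125)
  expect_identical(r2$p_adj[r2$set == "hit"], 0.0625)
  # k = 0 -> raw p = 1
  expect_identical(r2$p_raw[r2$set == "other"], 1)

  # brute-force pmf tail sums across random gene-set configurations
  withr::with_seed(99, {
    for (i in 1:50) {
      bg_n <- sample(40:200, 1)
      bgi <- paste0("g", seq_len(bg_n))
      set_i <- sample(bgi, sample(5:bg_n, 1))
      qry <- sample(bgi, sample(1:30, 1))
      r_i <- overrepresentation_test(qry, bgi, list(s = set_i))
      k <- length(intersect(qry, set_i))
      p_brute <- if (k == 0) 1 else
        sum(dbinom(k:length(qry), length(qry), length(set_i) / bg_n))
      expect_lt(abs(r_i$p_raw - p_brute), 1e-10)
    }
  })

  expect_error(overrepresentation_test("g1", character(), list(a = "g1")),
               class = "oq_error_parameter")
  expect_error(overrepresentation_test("zz", bg, list(a = "g1")),
               class = "oq_error_parameter")
})

test_that("GMT files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tsource\tg2\tg9"), path)
  sets <- read_gmt(path)
  expect_identical(sets, list(setA = c("g1", "g2", "g3"), setB = c("g2", "g9")))
  writeLines("broken\tonlydesc", path)
  expect_error(read_gmt(path), class = "oq_error_parameter")
})
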