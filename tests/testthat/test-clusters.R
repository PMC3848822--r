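test_that("a single hit extends six genes to either side", {
  genes <- make_genes(100)
  cl <- call_clusters(make_hits(genes, 10), genes)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$first_index, 4L)
  expect_equal(cl$last_index, 16L)
  expect_equal(cl$n_genes, 13L)
  expect_equal(cl$cluster_id, "G1_1")
})

test_that("windows clip at replicon ends", {
  genes <- make_genes(20)
  cl <- call_clusters(make_hits(genes, 3), genes)
  expect_equal(cl$first_index, 0L)
  expect_equal(cl$last_index, 9L)
})

test_that("hits chain within the window and merge on overlap", {
  genes <- make_genes(100)
  # gap 5 <= 6: one chain
  cl <- call_clusters(make_hits(genes, c(10, 15)), genes)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$first_index, cl$last_index), c(4L, 21L))
  # gap 10 > 6 but extensions overlap: merged into one locus
  cl2 <- call_clusters(make_hits(genes, c(10, 20)), genes)
  expect_equal(nrow(cl2), 1)
  expect_equal(c(cl2$first_index, cl2$last_index), c(4L, 26L))
  expect_equal(cl2$n_hits, 2L)
  # without overlap merging the two chains stay separate
  cl3 <- call_clusters(make_hits(genes, c(10, 20)), genes,
                       merge_overlapping_extensions = FALSE)
  expect_equal(nrow(cl3), 2)
  # under the looser reading they are one chain again
  cl4 <- call_clusters(make_hits(genes, c(10, 20)), genes,
                       join_rule = "extensions_overlap",
                       merge_overlapping_extensions = FALSE)
  expect_equal(nrow(cl4), 1)
})

test_that("non-significant hits and unknown replicons are rejected", {
  genes <- make_genes(50)
  expect_error(
    call_clusters(make_hits(genes, 10, significant = FALSE), genes),
    "significant")
  stray <- make_hits(genes, 10)
  stray$replicon_id <- "chrX"
  expect_error(call_clusters(stray, genes), "chrX")
})

test_that("clusters are numbered per genome in replicon-then-index order", {
  genes <- dplyr::bind_rows(
    make_genes(60, replicon = "chr1", prefix = "A"),
    make_genes(60, replicon = "chr2", prefix = "B")
  )
  hits <- dplyr::bind_rows(
    make_hits(genes[genes$replicon_id == "chr2", ], 30),
    make_hits(genes[genes$replicon_id == "chr1", ], c(10, 40))
  )
  cl <- call_clusters(hits, genes)
  expect_equal(cl$cluster_id, c("G1_1", "G1_2", "G1_3"))
  expect_equal(cl$replicon_id, c("chr1", "chr1", "chr2"))
})

test_that("window clustering matches the brute-force oracle", {
  set.seed(101)
  for (case in 1:150) {
    n <- sample(20:200, 1)
    k <- sample(1:20, 1)
    w <- sample(0:8, 1)
    idx <- sort(sample(0:(n - 1), min(k, n)))
    genes <- make_genes(n)
    hits <- make_hits(genes, idx)
    for (rule in c("hit_in_window", "extensions_overlap")) {
      got <- call_clusters(hits, genes, window = w, join_rule = rule)
      want <- oracle_window_clusters(idx, n, w, join_rule = rule,
                                     merge = TRUE)
      expect_equal(got$first_index, want$first_index)
      expect_equal(got$last_index, want$last_index)
      expect_equal(lapply(got$hits, function(h) sort(h$gene_index)),
                   want$hits)
    }
  }
})

test_that("every hit lands in exactly one cluster and ranges are disjoint", {
  set.seed(77)
  for (case in 1:30) {
    n <- sample(50:200, 1)
    idx <- sort(sample(0:(n - 1), sample(2:15, 1)))
    genes <- make_genes(n)
    cl <- call_clusters(make_hits(genes, idx), genes)
    covered <- unlist(lapply(cl$hits, function(h) h$gene_index))
    expect_equal(sort(covered), idx)
    if (nrow(cl) > 1) {
      expect_true(all(cl$first_index[-1] > cl$last_index[-nrow(cl)]))
    }
    expect_true(all(cl$first_index <= cl$last_index))
    expect_true(all(cl$first_index >= 0 & cl$last_index <= n - 1))
  }
})

test_that("widening the window never shrinks spans nor adds clusters", {
  set.seed(303)
  for (case in 1:20) {
    n <- 200
    idx <- sort(sample(0:(n - 1), 12))
    genes <- make_genes(n)
    hits <- make_hits(genes, idx)
    prev <- call_clusters(hits, genes, window = 2)
    for (w in c(4, 6, 10)) {
      cur <- call_clusters(hits, genes, window = w)
      expect_lte(nrow(cur), nrow(prev))
      expect_lte(min(cur$first_index), min(prev$first_index))
      expect_gte(max(cur$last_index), max(prev$last_index))
      prev <- cur
    }
  }
})

test_that("hybrid clusters count once per class in the census", {
  genes <- make_genes(100)
  hits <- dplyr::bind_rows(
    make_hits(genes, 10, sm_class = "NRPS", model = "NRPS_C"),
    make_hits(genes, 12, sm_class = "PKS1", model = "PKS1_KS")
  )
  cl <- call_clusters(hits, genes)
  expect_equal(nrow(cl), 1)
  expect_setequal(cl$classes[[1]], c("NRPS", "PKS1"))
  cs <- class_census(cl)
  expect_equal(cs$n[cs$sm_class == "NRPS"], 1L)
  expect_equal(cs$n[cs$sm_class == "PKS1"], 1L)
  totals <- attr(cs, "n_clusters")
  expect_equal(totals$n_clusters, 1L)
  # class counts can exceed the cluster count
  expect_gte(sum(cs$n), totals$n_clusters[1])
})

test_that("census of zero clusters is all zero", {
  genes <- make_genes(10)
  cl <- call_clusters(make_hits(genes, integer(0))[0, ], genes)
  cs <- class_census(cl)
  expect_equal(nrow(cs), 0)
})

test_that("census equals a direct recount on random cluster sets", {
  set.seed(55)
  for (case in 1:10) {
    n_cl <- 10
    classes <- lapply(seq_len(n_cl), function(i) {
      sort(sample(sm_classes(), sample(1:3, 1)))
    })
    clusters <- tibble::tibble(
      cluster_id = paste0("G1_", seq_len(n_cl)),
      genome_id = "G1",
      classes = classes
    )
    cs <- class_census(clusters)
    for (cls in sm_classes()) {
      want <- sum(vapply(classes, function(x) cls %in% x, logical(1)))
      expect_equal(cs$n[cs$sm_class == cls], want)
    }
  }
})

test_that("NRPS:PKS ratio pools the three PKS types", {
  cs1 <- tibble::tibble(genome_id = "X",
                        sm_class = c("NRPS", "PKS1", "PKS2"),
                        n = c(14L, 3L, 2L))
  expect_equal(nrps_pks_ratio(cs1), 2.8)
  cs2 <- tibble::tibble(genome_id = "X",
                        sm_class = c("NRPS", "PKS1", "PKS3"),
                        n = c(9L, 12L, 8L))
  expect_equal(nrps_pks_ratio(cs2), 0.45)
  cs3 <- tibble::tibble(genome_id = "X", sm_class = c("NRPS", "PKS1"),
                        n = c(0L, 7L))
  expect_equal(nrps_pks_ratio(cs3), 0)
  cs4 <- tibble::tibble(genome_id = "X", sm_class = "NRPS", n = 5L)
  expect_message(r <- nrps_pks_ratio(cs4), "undefined")
  expect_true(is.na(r))
})
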