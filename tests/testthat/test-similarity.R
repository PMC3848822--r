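test_that("multi-copy groups contribute the smaller copy number", {
  # one genome with 2 copies, the other with 4: the pair shares 2
  groups <- tibble::tibble(
    group_id = "g1",
    genome_id = c("tw", "tw", "sb", "sb", "sb", "sb"),
    locus_tag = paste0("t", 1:6)
  )
  expect_equal(shared_gene_count(groups, "tw", "sb"), 2L)
  expect_equal(shared_gene_count(groups, "sb", "tw"), 2L)
})

test_that("genomes sharing no groups count zero; unknown ids error", {
  groups <- tibble::tibble(
    group_id = c("g1", "g2"), genome_id = c("A", "B"),
    locus_tag = c("a1", "b1")
  )
  expect_equal(shared_gene_count(groups, "A", "B"), 0L)
  expect_error(shared_gene_count(groups, "A", "Z"), "Z")
  expect_error(shared_gene_count(groups, "A", "A"), "distinct")
})

test_that("identical genomes score 1 both ways; nesting is asymmetric", {
  # two identical genomes: every gene in a shared single-copy group
  groups <- tidyr::expand_grid(g = sprintf("og%02d", 1:50),
                               genome_id = c("A", "B")) |>
    dplyr::transmute(group_id = g, genome_id,
                     locus_tag = paste0(genome_id, "_", group_id))
  sim <- genome_similarity(groups, c(A = 50, B = 50))
  expect_true(all(sim$fraction == 1))

  # genome a (100 genes, all shared) nested in b (400 genes)
  groups2 <- tidyr::expand_grid(g = sprintf("og%03d", 1:100),
                                genome_id = c("a", "b")) |>
    dplyr::transmute(group_id = g, genome_id,
                     locus_tag = paste0(genome_id, "_", group_id))
  sim2 <- genome_similarity(groups2, c(a = 100, b = 400))
  expect_equal(sim2$fraction["b", "a"], 1.0)   # a's column: all shared
  expect_equal(sim2$fraction["a", "b"], 0.25)  # b's column: a quarter
})

test_that("zero-gene genomes are rejected", {
  groups <- tibble::tibble(group_id = "g1", genome_id = "A",
                           locus_tag = "x")
  expect_error(genome_similarity(groups, c(A = 1, B = 0)), "B")
})

test_that("similarity matrices satisfy the reciprocity identity", {
  set.seed(99)
  for (case in 1:25) {
    genomes <- paste0("G", 1:sample(3:6, 1))
    groups <- random_groups(sample(20:60, 1), genomes)
    # G must cover grouped genes; add singletons on top
    counts <- dplyr::count(groups, genome_id)
    G <- setNames(counts$n + sample(50:200, nrow(counts)),
                  counts$genome_id)
    G <- G[genomes]
    G[is.na(G)] <- 100
    names(G) <- genomes
    sim <- genome_similarity(groups, G)
    Fm <- sim$fraction
    expect_true(all(diag(Fm) == 1))
    expect_true(all(Fm >= 0 & Fm <= 1))
    expect_equal(sim$shared, t(sim$shared))
    # F[i,j] * G_j == F[j,i] * G_i
    lhs <- sweep(Fm, 2, sim$G, "*")
    expect_true(max(abs(lhs - t(lhs))) < 1e-12)
    # spot-check shared counts against the per-group oracle
    a <- genomes[1]; b <- genomes[2]
    expect_equal(sim$shared[a, b], oracle_shared_count(groups, a, b))
  }
})

test_that("a private gene lowers its own column only", {
  groups <- tidyr::expand_grid(g = sprintf("og%02d", 1:30),
                               genome_id = c("A", "B", "C")) |>
    dplyr::transmute(group_id = g, genome_id,
                     locus_tag = paste0(genome_id, "_", group_id))
  before <- genome_similarity(groups, c(A = 30, B = 30, C = 30))
  # give A an extra private (ungrouped) gene: G_A rises, S unchanged
  after <- genome_similarity(groups, c(A = 31, B = 30, C = 30))
  expect_true(all(after$fraction[c("B", "C"), "A"] <
                    before$fraction[c("B", "C"), "A"]))
  expect_equal(after$fraction["A", "A"], 1)
  expect_equal(after$fraction[c("B", "C"), c("B", "C")],
               before$fraction[c("B", "C"), c("B", "C")])
})

test_that("the smallest genome's column is high, the largest's low", {
  # a reduced genome nested in two big ones, mirroring the contrast
  # between a degenerate pathogen and a large free-living genome
  core <- sprintf("core%03d", 1:80)
  groups <- dplyr::bind_rows(
    tidyr::expand_grid(group_id = core,
                       genome_id = c("tiny", "big1", "big2")) |>
      dplyr::mutate(locus_tag = paste0(genome_id, "_", group_id)),
    tidyr::expand_grid(group_id = sprintf("acc%03d", 1:300),
                       genome_id = c("big1", "big2")) |>
      dplyr::mutate(locus_tag = paste0(genome_id, "_", group_id))
  )
  sim <- genome_similarity(groups, c(tiny = 100, big1 = 800, big2 = 800))
  off <- function(m, j) m[setdiff(rownames(m), j), j]
  expect_true(all(off(sim$fraction, "tiny") >= 0.8))
  expect_true(all(off(sim$fraction, "big1") <= 0.5))
})

test_that("heatmap tables honour tree order and round-trip", {
  groups <- tidyr::expand_grid(g = sprintf("og%02d", 1:20),
                               genome_id = c("A", "B", "C")) |>
    dplyr::transmute(group_id = g, genome_id,
                     locus_tag = paste0(genome_id, "_", group_id))
  sim <- genome_similarity(groups, c(A = 25, B = 30, C = 40))

  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((C:1,A:1):1,B:1);", nwk)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_heatmap_table(sim, tf, order = nwk)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(back$genome_id, c("C", "A", "B"))
  expect_equal(names(back)[-1], c("C", "A", "B"))
  reordered <- set_genome_order(sim, c("C", "A", "B"))
  expect_equal(as.matrix(back[, -1]), reordered$fraction,
               ignore_attr = TRUE, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", bad)
  expect_error(write_heatmap_table(sim, tf, order = bad), "C")
})

test_that("tidy and glance summarise the similarity object", {
  groups <- tibble::tibble(group_id = "g1", genome_id = c("A", "B"),
                           locus_tag = c("a", "b"))
  sim <- genome_similarity(groups, c(A = 2, B = 4))
  td <- tidy(sim)
  expect_equal(nrow(td), 4)
  expect_equal(td$fraction[td$genome_i == "A" & td$genome_j == "B"],
               0.25)
  gl <- glance(sim)
  expect_equal(gl$n_genomes, 2)
})
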