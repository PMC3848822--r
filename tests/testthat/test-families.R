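# Build a gene table, groups and clusters where cluster k covers genes
# with the homolog groups given in `content` (list of chr vectors, one
# per cluster; NA entries mean ungrouped genes).
planted_cluster_set <- function(content, classes,
                                genomes = rep("G1", length(content))) {
  stopifnot(length(content) == length(classes))
  genes_list <- list()
  groups_list <- list()
  clusters <- list()
  per_genome_count <- table(factor(genomes, levels = unique(genomes)))
  next_idx <- setNames(rep(0L, length(unique(genomes))), unique(genomes))
  cluster_seq <- setNames(rep(0L, length(unique(genomes))),
                          unique(genomes))
  for (k in seq_along(content)) {
    gm <- genomes[k]
    n <- length(content[[k]])
    idx0 <- next_idx[[gm]]
    next_idx[[gm]] <- idx0 + n + 20L  # spacer between clusters
    cluster_seq[[gm]] <- cluster_seq[[gm]] + 1L
    tags <- sprintf("%s_c%d_%02d", gm, k, seq_len(n))
    genes_list[[k]] <- tibble::tibble(
      genome_id = gm, replicon_id = "chr1",
      replicon_type = "chromosome", locus_tag = tags,
      gene_index = idx0 + seq_len(n) - 1L,
      start = (idx0 + seq_len(n)) * 1000,
      end = (idx0 + seq_len(n)) * 1000 + 800,
      strand = "+", product = NA_character_
    )
    grouped <- !is.na(content[[k]])
    groups_list[[k]] <- tibble::tibble(
      group_id = content[[k]][grouped], genome_id = gm,
      locus_tag = tags[grouped]
    )
    hit <- tibble::tibble(
      genome_id = gm, replicon_id = "chr1", locus_tag = tags[1],
      gene_index = idx0, sm_class = classes[[k]][1],
      model_name = "M", score = 100, evalue = 1e-30,
      significant = TRUE
    )
    clusters[[k]] <- tibble::tibble(
      cluster_id = sprintf("%s_%d", gm, cluster_seq[[gm]]),
      genome_id = gm, replicon_id = "chr1",
      first_index = idx0, last_index = idx0 + n - 1L,
      first_locus = tags[1], last_locus = tags[n],
      n_genes = n, n_hits = 1L,
      classes = list(sort(classes[[k]])), hits = list(hit)
    )
  }
  # fill the spacer positions with ungrouped genes so gene_index is
  # contiguous per genome
  genes <- dplyr::bind_rows(genes_list)
  fillers <- lapply(unique(genomes), function(gm) {
    have <- sort(genes$gene_index[genes$genome_id == gm])
    missing <- setdiff(0:max(have), have)
    if (length(missing) == 0) return(NULL)
    tibble::tibble(
      genome_id = gm, replicon_id = "chr1",
      replicon_type = "chromosome",
      locus_tag = sprintf("%s_fill_%04d", gm, missing),
      gene_index = missing,
      start = (missing + 1) * 1000, end = (missing + 1) * 1000 + 800,
      strand = "+", product = NA_character_
    )
  })
  genes <- dplyr::bind_rows(genes, dplyr::bind_rows(fillers)) |>
    dplyr::arrange(genome_id, gene_index)
  list(genes = genes, groups = dplyr::bind_rows(groups_list),
       clusters = dplyr::bind_rows(clusters))
}

test_that("content similarity is shared groups over the smaller cluster", {
  fx <- planted_cluster_set(
    content = list(
      sprintf("og%02d", 1:10),
      c(sprintf("og%02d", 1:7), sprintf("pr%02d", 1:7))
    ),
    classes = list("NRPS", "NRPS"),
    genomes = c("G1", "G2")
  )
  # 10 vs 14 genes, 7 groups shared single-copy
  expect_equal(
    cluster_content_similarity(fx$clusters[1, ], fx$clusters[2, ],
                               fx$genes, fx$groups),
    0.7)
  # identical clusters
  fx2 <- planted_cluster_set(
    content = list(sprintf("og%02d", 1:8), sprintf("og%02d", 1:8)),
    classes = list("PKS1", "PKS1"), genomes = c("G1", "G2"))
  expect_equal(
    cluster_content_similarity(fx2$clusters[1, ], fx2$clusters[2, ],
                               fx2$genes, fx2$groups), 1.0)
  # no shared groups
  fx3 <- planted_cluster_set(
    content = list(sprintf("a%02d", 1:5), sprintf("b%02d", 1:5)),
    classes = list("NRPS", "NRPS"), genomes = c("G1", "G2"))
  expect_equal(
    cluster_content_similarity(fx3$clusters[1, ], fx3$clusters[2, ],
                               fx3$genes, fx3$groups), 0.0)
})

test_that("families form from planted copies; unrelated stay apart", {
  fx <- planted_cluster_set(
    content = list(
      sprintf("fam%02d", 1:10), sprintf("fam%02d", 1:10),
      sprintf("fam%02d", 1:10),
      sprintf("uniq_a%02d", 1:8), sprintf("uniq_b%02d", 1:9)
    ),
    classes = list("NRPS", "NRPS", "NRPS", "NRPS", "NRPS"),
    genomes = c("G1", "G2", "G3", "G1", "G2")
  )
  fam <- group_families(fx$clusters, fx$genes, fx$groups)
  sizes <- sort(table(fam$family_id), decreasing = TRUE)
  expect_equal(unname(as.integer(sizes)), c(3L, 1L, 1L))
  # the three planted copies share one family
  planted <- fam$family_id[1:3]
  expect_equal(length(unique(planted)), 1)

  # a threshold above 1 keeps everything separate
  singletons <- group_families(fx$clusters, fx$genes, fx$groups,
                               threshold = 1.01)
  expect_equal(dplyr::n_distinct(singletons$family_id),
               nrow(fx$clusters))
})

test_that("class sets must intersect for clusters to join a family", {
  fx <- planted_cluster_set(
    content = list(sprintf("og%02d", 1:10), sprintf("og%02d", 1:10)),
    classes = list("NRPS", "terpene"),
    genomes = c("G1", "G2")
  )
  fam <- group_families(fx$clusters, fx$genes, fx$groups)
  expect_equal(dplyr::n_distinct(fam$family_id), 2)
})

test_that("random cluster sets partition identically to union-find", {
  set.seed(404)
  pool <- sprintf("og%02d", 1:40)
  for (case in 1:6) {
    n_cl <- 30
    content <- lapply(seq_len(n_cl), function(i) {
      sample(pool, sample(5:12, 1))
    })
    classes <- lapply(seq_len(n_cl), function(i) {
      sample(c("NRPS", "PKS1", "terpene"), 1)
    })
    genomes <- sample(paste0("G", 1:5), n_cl, replace = TRUE)
    fx <- planted_cluster_set(content, classes, genomes)
    fam <- group_families(fx$clusters, fx$genes, fx$groups,
                          threshold = 0.5)
    # oracle partition from the pairwise similarity matrix
    simmat <- matrix(0, n_cl, n_cl)
    for (i in 1:(n_cl - 1)) {
      for (j in (i + 1):n_cl) {
        shared <- length(intersect(content[[i]], content[[j]]))
        simmat[i, j] <- simmat[j, i] <-
          shared / min(length(content[[i]]), length(content[[j]]))
      }
    }
    want <- oracle_family_partition(simmat, classes, 0.5)
    got <- as.integer(factor(fam$family_id))
    expect_equal(rand_index(got, want), 1.0)
    # partition property: sizes sum to the cluster count
    expect_equal(sum(table(fam$family_id)), n_cl)
  }
})

test_that("raising the threshold only refines the partition", {
  set.seed(21)
  pool <- sprintf("og%02d", 1:30)
  content <- lapply(1:15, function(i) sample(pool, sample(6:10, 1)))
  classes <- rep(list("NRPS"), 15)
  fx <- planted_cluster_set(content, classes,
                            sample(paste0("G", 1:3), 15, replace = TRUE))
  prev <- group_families(fx$clusters, fx$genes, fx$groups,
                         threshold = 0.2)$family_id
  for (th in c(0.4, 0.6, 0.8)) {
    cur <- group_families(fx$clusters, fx$genes, fx$groups,
                          threshold = th)$family_id
    # same family at the higher threshold implies same at the lower
    for (i in 1:14) {
      for (j in (i + 1):15) {
        if (cur[i] == cur[j]) expect_equal(prev[i], prev[j])
      }
    }
    prev <- cur
  }
})

test_that("conservation histograms bin families by size", {
  # three unique PKS families and one family of four
  fx <- planted_cluster_set(
    content = c(
      lapply(1:3, function(i) sprintf("uniq%d_%02d", i, 1:8)),
      rep(list(sprintf("famP%02d", 1:10)), 4)
    ),
    classes = rep(list("PKS1"), 7),
    genomes = c("G1", "G2", "G3", "G1", "G2", "G3", "G4")
  )
  fam <- group_families(fx$clusters, fx$genes, fx$groups)
  h <- conservation_histogram(fam, "PKS1")
  expect_equal(h$family_size, c(1L, 4L))
  expect_equal(h$n_families, c(3L, 1L))
  # a class with no families gives an empty histogram
  h2 <- conservation_histogram(fam, "lanthipeptide")
  expect_equal(nrow(h2), 0)
})

test_that("multi-copy families within one genome are allowed", {
  fx <- planted_cluster_set(
    content = rep(list(sprintf("lan%02d", 1:10)), 4),
    classes = rep(list("lanthipeptide"), 4),
    genomes = c("G1", "G1", "G2", "G2")
  )
  fam <- group_families(fx$clusters, fx$genes, fx$groups)
  fs <- family_summary(fam)
  expect_equal(fs$size, 4L)
  expect_equal(fs$n_genomes, 2L)
  expect_gte(fs$size, fs$n_genomes)
})
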