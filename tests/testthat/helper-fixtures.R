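# In-code fixtures shared across test files.

# Minimal gene table: n genes on one replicon, evenly spaced coordinates.
make_genes <- function(n, genome = "G1", replicon = "chr1",
                       prefix = genome) {
  tibble::tibble(
    genome_id = genome,
    replicon_id = replicon,
    replicon_type = "chromosome",
    locus_tag = sprintf("%s_%04d", prefix, seq_len(n)),
    gene_index = seq_len(n) - 1L,
    start = seq_len(n) * 1000,
    end = seq_len(n) * 1000 + 800,
    strand = "+",
    product = NA_character_
  )
}

# Significant hits at the given gene indices of a gene table.
make_hits <- function(genes, idx, sm_class = "NRPS",
                      model = "NRPS_C", significant = TRUE) {
  g <- genes[match(idx, genes$gene_index), ]
  tibble::tibble(
    genome_id = g$genome_id,
    replicon_id = g$replicon_id,
    locus_tag = g$locus_tag,
    gene_index = g$gene_index,
    sm_class = rep_len(sm_class, length(idx)),
    model_name = rep_len(model, length(idx)),
    score = 120,
    evalue = 1e-30,
    significant = significant
  )
}

# Random homolog-group membership table over the given genomes.
random_groups <- function(n_groups, genomes, max_copies = 4,
                          p_present = 0.7) {
  rows <- list()
  tag <- 0L
  for (g in seq_len(n_groups)) {
    for (gn in genomes) {
      if (runif(1) < p_present) {
        copies <- sample.int(max_copies, 1)
        for (k in seq_len(copies)) {
          tag <- tag + 1L
          rows[[length(rows) + 1]] <- tibble::tibble(
            group_id = sprintf("g%03d", g),
            genome_id = gn,
            locus_tag = sprintf("%s_t%05d", gn, tag)
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

# A small genus spec that keeps simulation fast in unit tests.
small_spec <- function(seed = 11, ...) {
  genus_spec(
    n_genomes = 3,
    genes_per_genome = c(260, 300),
    core_fraction = 0.5,
    planted_families = tibble::tibble(
      family = c("famA", "famB", "lanthiX"),
      classes = list("NRPS", c("NRPS", "PKS1"), "lanthipeptide"),
      members = list(c("G1", "G2", "G3"), "G2", "G3"),
      core_genes = c(10L, 12L, 10L),
      hit_offsets = list(4L, c(3L, 8L), 5L),
      hit_models = list("NRPS_C", c("NRPS_C", "PKS1_KS"), "LanC"),
      n_precursors = c(0L, 0L, 2L)
    ),
    seed = seed,
    ...
  )
}
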