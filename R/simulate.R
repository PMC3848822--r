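#' Specify a synthetic genus
#'
#' Describes a simulated bacterial genus for end-to-end testing of the
#' pipeline: several genomes sharing a single-copy core gene set, private
#' accessory genes, and planted biosynthetic gene clusters with
#' controlled cross-genome family structure (shared, unique, multi-copy
#' and hybrid clusters). The default emulates a small actinomycete-like
#' genus: 5 genomes of roughly 2,000 genes each with a 70% core, and 12
#' planted clusters (two of them NRPS/PKS hybrids) in 7 families.
#'
#' Planted clusters are spaced so that the gap between the signature
#' hits of different clusters always exceeds twice the calling window;
#' called clusters therefore correspond one-to-one to planted ones.
#'
#' @param n_genomes Number of genomes (ids `G1`, `G2`, ...).
#' @param genes_per_genome Two-element range for the backbone gene count
#'   per genome (planted cluster genes and their flanks are added on
#'   top).
#' @param core_fraction Fraction of the smallest backbone that is core,
#'   i.e. present single-copy in every genome, in `[0, 1]`.
#' @param planted_families Tibble describing the planted cluster
#'   families; see [default_planted_families()] for the columns.
#' @param window Calling window the spacing guarantees are computed for
#'   (default 6).
#' @param neighborhood_randomization When `TRUE` (default) the genes
#'   flanking each planted cluster are private to their genome, so
#'   cluster neighbourhoods differ between family members; when `FALSE`
#'   flanking genes are shared within a family (conserved
#'   neighbourhoods).
#' @param protein_len Two-element range of random protein lengths.
#' @param seed Integer seed; the simulation is a deterministic function
#'   of the spec including this seed.
#' @return A list of class `genus_spec`.
#' @seealso [simulate_genus()]
#' @export
genus_spec <- function(n_genomes = 5,
                       genes_per_genome = c(1900, 2100),
                       core_fraction = 0.7,
                       planted_families = default_planted_families(),
                       window = 6,
                       neighborhood_randomization = TRUE,
                       protein_len = c(50, 200),
                       seed = 1) {
  stopifnot(n_genomes >= 1, length(genes_per_genome) == 2,
            genes_per_genome[1] <= genes_per_genome[2],
            core_fraction >= 0, core_fraction <= 1, window >= 0)
  genome_ids <- paste0("G", seq_len(n_genomes))
  bad <- setdiff(unique(unlist(planted_families$members)), genome_ids)
  if (length(bad) > 0) {
    abort(paste0("planted_families mention unknown genome(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(
    list(n_genomes = n_genomes, genome_ids = genome_ids,
         genes_per_genome = genes_per_genome,
         core_fraction = core_fraction,
         planted_families = planted_families, window = window,
         neighborhood_randomization = neighborhood_randomization,
         protein_len = protein_len, seed = seed),
    class = "genus_spec"
  )
}

#' Default planted cluster families
#'
#' The family layout used by the default [genus_spec()]: a 3-member NRPS
#' family, a 4-member PKS family, two unique NRPS/PKS hybrid clusters,
#' one lanthipeptide cluster carrying two planted precursor peptides,
#' and two further unique clusters (terpene,
#' aerobactin-like siderophore) — 12 clusters in 7 families over 5
#' genomes.
#'
#' @return A tibble with columns `family` (name), `classes` (list of
#'   class sets), `members` (list of genome ids, repeated for
#'   multi-copy), `core_genes` (planted core length in genes),
#'   `hit_offsets` (list of 0-based signature positions within the
#'   core), `hit_models` (list of model names, parallel to
#'   `hit_offsets`), `n_precursors` (planted precursor peptides, for
#'   lanthipeptide families).
#' @export
default_planted_families <- function() {
  tibble(
    family = c("nrps_shared", "pks_shared", "hybrid_a", "hybrid_b",
               "lanthi", "terpene_u", "sidero_u"),
    classes = list("NRPS", "PKS1", c("NRPS", "PKS1"), c("NRPS", "PKS2"),
                   "lanthipeptide", "terpene", "aerobactin_siderophore"),
    members = list(c("G1", "G2", "G3"), c("G1", "G2", "G3", "G4"),
                   "G4", "G5", "G5", "G2", "G3"),
    core_genes = c(10L, 12L, 14L, 14L, 10L, 8L, 9L),
    hit_offsets = list(4L, 5L, c(4L, 9L), c(4L, 9L), 5L, 3L, 4L),
    hit_models = list("NRPS_C", "PKS1_KS", c("NRPS_C", "PKS1_KS"),
                      c("NRPS_C", "PKS2_KS"), "LanC", "Terpene_synth",
                      "IucA_IucC"),
    n_precursors = c(0L, 0L, 0L, 0L, 2L, 0L, 0L)
  )
}

#' Simulate a synthetic genus
#'
#' Generates the genomes described by a [genus_spec()]: an ordered gene
#' table with random protein sequences, a homolog-group table (core
#' groups single-copy in every genome; planted-cluster genes grouped
#' within their family; accessory genes ungrouped), a signature-hit
#' table containing exactly the planted signature genes with scores
#' above the bundled cutoffs, and a truth manifest recording what was
#' planted and what the pipeline is expected to recover.
#'
#' The output is a deterministic function of the spec (including its
#' seed): rerunning with the same spec reproduces it exactly, and two
#' seeds differ in locus tags and neighbourhoods but share the same
#' truth topology (family sizes, classes, copy numbers).
#'
#' @param spec A `genus_spec`.
#' @return A list of class `bgc_genus_sim` with elements `genes`
#'   (gene table including `protein_seq`), `groups`, `hits`, `truth`
#'   (list: `clusters` tibble with planted cores, expected called
#'   bounds, classes, family assignment; `census`; `G`; `precursors`),
#'   and `spec`.
#' @export
simulate_genus <- function(spec) {
  stopifnot(inherits(spec, "genus_spec"))
  set.seed(spec$seed)
  w <- spec$window
  fams <- spec$planted_families
  cutoffs <- default_model_cutoffs()

  base_n <- round(runif(spec$n_genomes, spec$genes_per_genome[1],
                        spec$genes_per_genome[2]))
  names(base_n) <- spec$genome_ids
  core_size <- round(spec$core_fraction * min(base_n))
  core_groups <- sprintf("OG%05d", seq_len(core_size))

  # precursor templates per lanthipeptide family: length 40, fixed
  # L-D motif and two invariant cysteines plus a threonine
  prec_template <- list()
  for (k in seq_len(nrow(fams))) {
    if (fams$n_precursors[k] > 0) {
      tpl <- sample(aa_alphabet(gap = FALSE), 40, replace = TRUE)
      tpl[c(10, 11, 20, 25, 30)] <- c("L", "D", "C", "T", "C")
      prec_template[[fams$family[k]]] <- tpl
    }
  }

  # planted blocks, one row per cluster occurrence
  blocks <- purrr::map(seq_len(nrow(fams)), function(k) {
    members <- fams$members[[k]]
    tibble(family = fams$family[k], genome_id = members,
           copy = seq_along(members), fam_row = k)
  }) |> bind_rows()

  genome_parts <- purrr::map(spec$genome_ids, function(g) {
    simulate_one_genome(g, base_n[[g]], core_groups,
                        blocks[blocks$genome_id == g, ], fams, spec,
                        prec_template, cutoffs)
  })

  genes <- bind_rows(purrr::map(genome_parts, "genes"))
  groups <- bind_rows(purrr::map(genome_parts, "groups")) |>
    arrange(.data$group_id, .data$genome_id, .data$locus_tag)
  hits <- bind_rows(purrr::map(genome_parts, "hits"))
  truth_clusters <- bind_rows(purrr::map(genome_parts, "truth")) |>
    group_by(.data$genome_id) |>
    arrange(.data$first_index, .by_group = TRUE) |>
    mutate(cluster_id = paste0(.data$genome_id, "_", row_number())) |>
    ungroup()
  precursors <- bind_rows(purrr::map(genome_parts, "precursors"))

  census <- truth_clusters |>
    select(all_of(c("genome_id", "cluster_id", "classes"))) |>
    tidyr::unnest_longer("classes", values_to = "sm_class") |>
    dplyr::count(.data$genome_id, .data$sm_class) |>
    tidyr::complete(genome_id = spec$genome_ids,
                    sm_class = sm_classes(), fill = list(n = 0L)) |>
    arrange(.data$genome_id, match(.data$sm_class, sm_classes()))

  structure(
    list(genes = genes, groups = groups, hits = hits,
         truth = list(clusters = truth_clusters, census = census,
                      G = purrr::map_int(purrr::map(genome_parts,
                                                    "genes"), nrow) |>
                        setNames(spec$genome_ids),
                      precursors = precursors),
         spec = spec),
    class = "bgc_genus_sim"
  )
}

# Build one genome: backbone (shuffled core + private accessory genes)
# with planted cluster blocks and their flanks inserted between evenly
# sized backbone chunks.
simulate_one_genome <- function(g, base, core_groups, blocks, fams,
                                spec, prec_template, cutoffs) {
  w <- as.integer(spec$window)
  k_blocks <- nrow(blocks)
  min_chunk <- 5L
  if (base < min_chunk * (k_blocks + 1)) {
    abort(paste0("Genome ", g, ": backbone of ", base, " genes cannot ",
                 "host ", k_blocks, " planted clusters with chunks of ",
                 min_chunk))
  }

  # backbone: every core group once + private accessory, random order
  n_acc <- base - length(core_groups)
  if (n_acc < 0) {
    abort(paste0("Genome ", g, ": core (", length(core_groups),
                 ") exceeds backbone size (", base, ")"))
  }
  backbone <- tibble(
    group_id = c(core_groups, rep(NA_character_, n_acc)),
    kind = c(rep("core", length(core_groups)), rep("acc", n_acc))
  )
  backbone <- backbone[sample(nrow(backbone)), ]
  chunk_sizes <- diff(round(seq(0, base, length.out = k_blocks + 2)))
  if (any(chunk_sizes < min_chunk)) {
    abort(paste0("Genome ", g, ": planted clusters do not fit with the ",
                 "required spacing"))
  }

  pieces <- list()
  cut_at <- cumsum(chunk_sizes)
  start_at <- c(1, head(cut_at, -1) + 1)
  for (b in seq_len(k_blocks + 1)) {
    chunk <- backbone[start_at[b]:cut_at[b], ]
    chunk$family <- NA_character_
    chunk$offset <- NA_integer_
    pieces[[length(pieces) + 1]] <- chunk
    if (b <= k_blocks) {
      fam_row <- fams[blocks$fam_row[b], ]
      fam <- fam_row$family
      nb_left <- if (spec$neighborhood_randomization) {
        tibble(group_id = rep(NA_character_, w), kind = "flank",
               family = NA_character_, offset = NA_integer_)
      } else {
        tibble(group_id = sprintf("NB_%s_L_%02d", fam, seq_len(w)),
               kind = "flank", family = NA_character_,
               offset = NA_integer_)
      }
      nb_right <- if (spec$neighborhood_randomization) {
        tibble(group_id = rep(NA_character_, w), kind = "flank",
               family = NA_character_, offset = NA_integer_)
      } else {
        tibble(group_id = sprintf("NB_%s_R_%02d", fam, seq_len(w)),
               kind = "flank", family = NA_character_,
               offset = NA_integer_)
      }
      core <- tibble(
        group_id = sprintf("FG_%s_%02d", fam,
                           seq_len(fam_row$core_genes)),
        kind = "planted", family = fam,
        offset = seq_len(fam_row$core_genes) - 1L
      )
      pieces[[length(pieces) + 1]] <- nb_left
      pieces[[length(pieces) + 1]] <- core
      pieces[[length(pieces) + 1]] <- nb_right
    }
  }
  layout <- bind_rows(pieces)
  n_total <- nrow(layout)
  layout$gene_index <- seq_len(n_total) - 1L
  layout$locus_tag <- sprintf("%s_%05d", g, seq_len(n_total))

  # protein lengths: signature genes long, precursors short
  plen <- round(runif(n_total, spec$protein_len[1], spec$protein_len[2]))
  hit_rows <- integer(0)
  hit_models <- character(0)
  prec_rows <- integer(0)
  prec_fams <- character(0)
  truth <- list()
  for (b in seq_len(k_blocks)) {
    fam_row <- fams[blocks$fam_row[b], ]
    fam <- fam_row$family
    block_rows <- which(layout$kind == "planted" & layout$family == fam)
    # multi-copy genomes: pick the b-th planted stretch of this family
    copies_before <- sum(blocks$family[seq_len(b - 1)] == fam)
    block_rows <- block_rows[
      seq(copies_before * fam_row$core_genes + 1,
          (copies_before + 1) * fam_row$core_genes)]
    offs <- fam_row$hit_offsets[[1]]
    rows <- block_rows[offs + 1L]
    plen[rows] <- round(runif(length(rows), 350, 600))
    hit_rows <- c(hit_rows, rows)
    hit_models <- c(hit_models, fam_row$hit_models[[1]])
    if (fam_row$n_precursors > 0) {
      # precursor-bearing clusters: all other genes in and around the
      # block are long, so the short-ORF filter recovers exactly the
      # planted peptides
      around <- c(block_rows,
                  seq(block_rows[1] - w, block_rows[1] - 1),
                  seq(block_rows[length(block_rows)] + 1,
                      block_rows[length(block_rows)] + w))
      around <- setdiff(around[around >= 1 & around <= n_total], rows)
      plen[around] <- round(runif(length(around), 150, 300))
    }
    if (fam_row$n_precursors > 0) {
      # precursor genes sit at fixed core offsets clear of the hits
      p_off <- setdiff(seq_len(fam_row$core_genes) - 1L, offs)
      p_off <- p_off[c(3, 8)][seq_len(fam_row$n_precursors)]
      p <- block_rows[p_off + 1L]
      plen[p] <- 40L
      prec_rows <- c(prec_rows, p)
      prec_fams <- c(prec_fams, rep(fam, length(p)))
    }
    hit_indices <- layout$gene_index[rows]
    truth[[length(truth) + 1]] <- tibble(
      genome_id = g, replicon_id = "chr1", family = fam,
      core_first_index = layout$gene_index[block_rows[1]],
      core_last_index =
        layout$gene_index[block_rows[fam_row$core_genes]],
      first_index = max(0L, min(hit_indices) - w),
      last_index = min(n_total - 1L, max(hit_indices) + w),
      classes = fam_row$classes,
      hit_indices = list(sort(hit_indices)),
      hit_locus_tags = list(layout$locus_tag[rows][order(hit_indices)])
    )
  }

  # random protein sequences, then planted features
  aa <- aa_alphabet(gap = FALSE)
  seqs <- vapply(plen, function(L) {
    paste(sample(aa, L, replace = TRUE), collapse = "")
  }, character(1))
  for (i in seq_along(prec_rows)) {
    tpl <- prec_template[[prec_fams[i]]]
    mut <- sample(setdiff(seq_along(tpl), c(10, 11, 20, 25, 30)), 3)
    tpl[mut] <- sample(aa, 3, replace = TRUE)
    seqs[prec_rows[i]] <- paste(tpl, collapse = "")
  }
  # PepM signature genes carry the EDK-X(5)-NS motif
  pepm <- hit_rows[hit_models == "PepM"]
  for (r in pepm) {
    s <- strsplit(seqs[r], "")[[1]]
    at <- 10
    s[at:(at + 9)] <- c("E", "D", "K", sample(aa, 5, replace = TRUE),
                        "N", "S")
    seqs[r] <- paste(s, collapse = "")
  }

  # nucleotide coordinates consistent with the gene order
  nuc_len <- 3 * plen + 3
  gaps <- round(runif(n_total, 50, 200))
  starts <- cumsum(c(1, head(nuc_len + gaps, -1)))
  ends <- starts + nuc_len - 1

  genes <- tibble(
    genome_id = g, replicon_id = "chr1", replicon_type = "chromosome",
    locus_tag = layout$locus_tag, gene_index = layout$gene_index,
    start = starts, end = ends,
    strand = sample(c("+", "-"), n_total, replace = TRUE),
    product = dplyr::case_when(
      layout$kind == "core" ~ "conserved hypothetical protein",
      layout$kind == "planted" ~ "biosynthetic protein",
      TRUE ~ "hypothetical protein"
    ),
    protein_seq = seqs
  )

  groups <- layout |>
    dplyr::filter(!is.na(.data$group_id)) |>
    mutate(genome_id = g) |>
    select(all_of(c("group_id", "genome_id", "locus_tag")))

  hit_cut <- cutoffs$min_score[match(hit_models, cutoffs$model_name)]
  hits <- tibble(
    locus_tag = layout$locus_tag[hit_rows],
    model_name = hit_models,
    score = hit_cut + round(runif(length(hit_rows), 30, 150), 1),
    evalue = 10^-round(runif(length(hit_rows), 20, 60), 1)
  )

  precursors <- tibble(
    genome_id = rep(g, length(prec_rows)),
    family = prec_fams,
    locus_tag = layout$locus_tag[prec_rows],
    gene_index = layout$gene_index[prec_rows]
  )

  list(genes = genes, groups = groups, hits = hits,
       truth = bind_rows(truth), precursors = precursors)
}

#' Write a simulated genus to files
#'
#' Emits the standard input files for the pipeline — gene table TSV,
#' GFF3, protein FASTA, OrthoMCL-format groups file, hits TSV — plus a
#' JSON truth manifest. Output is byte-identical for identical specs
#' (no timestamps).
#'
#' @param sim A `bgc_genus_sim` from [simulate_genus()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_genus <- function(sim, dir) {
  stopifnot(inherits(sim, "bgc_genus_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genes = file.path(dir, "genes.tsv"),
    gff = file.path(dir, "genes.gff3"),
    proteins = file.path(dir, "proteins.fasta"),
    groups = file.path(dir, "groups.txt"),
    hits = file.path(dir, "hits.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_gene_table(sim$genes, paths[["genes"]])
  write_gene_gff3(sim$genes, paths[["gff"]])
  write_protein_fasta(sim$genes, paths[["proteins"]])
  write_orthomcl_groups(sim$groups, paths[["groups"]])
  readr::write_tsv(sim$hits, paths[["hits"]])
  manifest <- list(
    genome_ids = sim$spec$genome_ids,
    window = sim$spec$window,
    seed = sim$spec$seed,
    G = as.list(sim$truth$G),
    clusters = sim$truth$clusters |>
      mutate(classes = purrr::map_chr(.data$classes, paste,
                                      collapse = ";"),
             hit_indices = purrr::map_chr(.data$hit_indices, paste,
                                          collapse = ";")) |>
      select(-"hit_locus_tags"),
    census = sim$truth$census,
    precursors = sim$truth$precursors
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @export
print.bgc_genus_sim <- function(x, ...) {
  cat("<bgc_genus_sim> ", x$spec$n_genomes, " genomes, ",
      nrow(x$genes), " genes, ", nrow(x$truth$clusters),
      " planted clusters\n", sep = "")
  invisible(x)
}
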