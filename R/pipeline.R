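#' Run the full comparative BGC pipeline
#'
#' Executes the complete analysis from files on disk: read genes, groups
#' and hits; optionally screen proteins for the PepM phosphonate motif
#' and drop PKS hits on fatty-acid synthases; call clusters with the
#' window rule; tally classes; compute the genome-similarity matrix;
#' group clusters into families; build conservation histograms; and
#' delineate family boundaries. All result tables are written as TSV to
#' `out_dir` together with a JSON run manifest echoing every parameter,
#' making a run a pure function of its inputs and configuration:
#' rerunning with the same inputs produces identical outputs.
#'
#' @param genes_path Gene table (TSV) or GFF3 file; see
#'   [read_gene_table()].
#' @param hits_path Signature-hit table (TSV or HMMER3 domtblout).
#' @param groups_path OrthoMCL-format groups file.
#' @param out_dir Output directory (created if needed).
#' @param proteins_path Optional protein FASTA; required for the PepM
#'   motif screen.
#' @param fas_path Optional TSV of fatty-acid-synthase scores
#'   (`locus_tag`, `fas_score`) for [resolve_fas_conflicts()].
#' @param genes_format,hits_format Input formats (see the readers).
#' @param model_cutoffs Model/cutoff table (default
#'   [default_model_cutoffs()]).
#' @param window Calling window (default 6 genes).
#' @param join_rule Window-join reading, see [call_clusters()].
#' @param merge_overlapping_extensions See [call_clusters()].
#' @param threshold Family-grouping similarity threshold (default 0.5).
#' @param similarity_method `"containment"` or `"jaccard"`.
#' @param min_fraction Boundary-delineation conservation cutoff
#'   (default 0.8).
#' @param include_plasmids Keep plasmid replicons? Default `FALSE`.
#' @param scan_pepm Run the PepM motif screen over `proteins_path` and
#'   add the resulting phosphonate hits? Default `FALSE`.
#' @param genome_order Optional genome order (character vector or
#'   newick path) for the similarity table.
#' @return Invisibly, a list with `genes`, `hits`, `clusters`, `census`,
#'   `similarity`, `families` (cluster tibble with `family_id`),
#'   `family_summary`, `histograms`, `boundaries`, and `paths` of the
#'   written files.
#' @export
run_bgc_pipeline <- function(genes_path, hits_path, groups_path, out_dir,
                             proteins_path = NULL, fas_path = NULL,
                             genes_format = c("tsv", "gff3"),
                             hits_format = c("tsv", "domtblout"),
                             model_cutoffs = default_model_cutoffs(),
                             window = 6,
                             join_rule = c("hit_in_window",
                                           "extensions_overlap"),
                             merge_overlapping_extensions = TRUE,
                             threshold = 0.5,
                             similarity_method = c("containment",
                                                   "jaccard"),
                             min_fraction = 0.8,
                             include_plasmids = FALSE,
                             scan_pepm = FALSE,
                             genome_order = NULL) {
  genes_format <- match.arg(genes_format)
  hits_format <- match.arg(hits_format)
  join_rule <- match.arg(join_rule)
  similarity_method <- match.arg(similarity_method)
  for (arg in c("genes_path", "hits_path", "groups_path")) {
    p <- get(arg)
    if (!is.character(p) || length(p) != 1 || !file.exists(p)) {
      abort(paste0("Input file for `", arg, "` not found: '",
                   if (is.character(p)) p else "<not a path>", "'"))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  genes <- read_gene_table(genes_path, format = genes_format,
                           include_plasmids = include_plasmids)
  groups <- read_orthomcl_groups(groups_path)
  hits <- read_hits(hits_path, genes, format = hits_format,
                    model_cutoffs = model_cutoffs)
  if (scan_pepm) {
    if (is.null(proteins_path)) {
      abort("scan_pepm = TRUE needs `proteins_path`")
    }
    genes <- add_protein_seqs(genes, proteins_path)
    pepm <- scan_pepm_motif(setNames(genes$protein_seq,
                                     genes$locus_tag)[
                              !is.na(genes$protein_seq)],
                            genes)
    hits <- bind_rows(hits, select(pepm, -"motif_start"))
  } else if (!is.null(proteins_path)) {
    genes <- add_protein_seqs(genes, proteins_path)
  }
  if (!is.null(fas_path)) {
    fas <- readr::read_tsv(fas_path, show_col_types = FALSE)
    hits <- resolve_fas_conflicts(hits, fas)
  }

  sig <- dplyr::filter(hits, .data$significant)
  clusters <- call_clusters(sig, genes, window = window,
                            join_rule = join_rule,
                            merge_overlapping_extensions =
                              merge_overlapping_extensions)
  census <- class_census(clusters)
  sim <- genome_similarity(groups, genes)
  if (!is.null(genome_order)) sim <- set_genome_order(sim, genome_order)
  fam_clusters <- group_families(clusters, genes, groups,
                                 threshold = threshold,
                                 method = similarity_method)
  fams <- family_summary(fam_clusters)
  histograms <- purrr::map(sm_classes(), function(cl) {
    h <- conservation_histogram(fam_clusters, cl)
    if (nrow(h) > 0) mutate(h, sm_class = cl) else NULL
  }) |>
    purrr::compact() |>
    bind_rows()
  if (nrow(histograms) > 0) {
    histograms <- select(histograms,
                         all_of(c("sm_class", "family_size",
                                  "n_families")))
  } else {
    histograms <- tibble(sm_class = character(),
                         family_size = integer(),
                         n_families = integer())
  }
  multi <- family_summary(fam_clusters)
  boundaries <- if (any(multi$size >= 2)) {
    delineate_boundaries(fam_clusters, genes, groups,
                         min_fraction = min_fraction)
  } else {
    tibble(family_id = character(), cluster_id = character(),
           trimmed_first_index = integer(),
           trimmed_last_index = integer(),
           trimmed_first_locus = character(),
           trimmed_last_locus = character())
  }

  paths <- c(
    clusters = file.path(out_dir, "clusters.tsv"),
    census = file.path(out_dir, "census.tsv"),
    similarity = file.path(out_dir, "similarity.tsv"),
    families = file.path(out_dir, "families.tsv"),
    histograms = file.path(out_dir, "histograms.tsv"),
    boundaries = file.path(out_dir, "boundaries.tsv"),
    manifest = file.path(out_dir, "run_manifest.json")
  )
  readr::write_tsv(flatten_clusters(fam_clusters), paths[["clusters"]])
  readr::write_tsv(census, paths[["census"]])
  write_heatmap_table(sim, paths[["similarity"]])
  readr::write_tsv(
    fams |> mutate(classes = purrr::map_chr(.data$classes, paste,
                                            collapse = ";"),
                   members = purrr::map_chr(.data$members, paste,
                                            collapse = ";")),
    paths[["families"]])
  readr::write_tsv(histograms, paths[["histograms"]])
  readr::write_tsv(
    select(boundaries, -dplyr::any_of("conservation")),
    paths[["boundaries"]])
  config <- list(
    genes_path = genes_path, hits_path = hits_path,
    groups_path = groups_path, proteins_path = proteins_path,
    fas_path = fas_path, genes_format = genes_format,
    hits_format = hits_format, window = window, join_rule = join_rule,
    merge_overlapping_extensions = merge_overlapping_extensions,
    threshold = threshold, similarity_method = similarity_method,
    min_fraction = min_fraction, include_plasmids = include_plasmids,
    scan_pepm = scan_pepm
  )
  jsonlite::write_json(config, paths[["manifest"]], auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)

  invisible(list(genes = genes, hits = hits, clusters = clusters,
                 census = census, similarity = sim,
                 families = fam_clusters, family_summary = fams,
                 histograms = histograms, boundaries = boundaries,
                 paths = paths))
}

# TSV-safe view of a cluster tibble (list columns flattened).
flatten_clusters <- function(clusters) {
  out <- clusters |>
    mutate(classes = purrr::map_chr(.data$classes, paste,
                                    collapse = ";")) |>
    select(-dplyr::any_of("hits"))
  out
}

#' Bar chart of cluster classes per genome
#'
#' Stacked per-genome counts of clusters by secondary-metabolite class;
#' hybrids count once per class.
#'
#' @param census Census tibble from [class_census()].
#' @return A ggplot object.
#' @export
plot_class_census <- function(census) {
  df <- dplyr::filter(census, .data$n > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$genome_id, .data$n,
                                   fill = .data$sm_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "gene clusters", fill = "class",
                  title = "Secondary-metabolite cluster census") +
    ggplot2::theme_minimal()
}

#' Conservation histogram plot for one class
#'
#' Family-size histogram (how many families of the class occur once,
#' twice, ... within the genus).
#'
#' @param clusters Cluster tibble with `family_id`
#'   (see [group_families()]).
#' @param sm_class Class to plot.
#' @return A ggplot object.
#' @export
plot_conservation <- function(clusters, sm_class) {
  h <- conservation_histogram(clusters, sm_class)
  ggplot2::ggplot(h, ggplot2::aes(.data$family_size,
                                  .data$n_families)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = function(l)
      seq(1, max(l[2], 1))) +
    ggplot2::labs(x = "family size (clusters per family)",
                  y = "families",
                  title = paste0(sm_class, " cluster conservation")) +
    ggplot2::theme_minimal()
}
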