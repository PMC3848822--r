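#' Call biosynthetic gene clusters by the six-gene window rule
#'
#' Converts significant signature hits into gene clusters. Within each
#' replicon, hits are sorted by gene ordinal and chained: the window is
#' re-initiated at every hit, and a following hit joins the same cluster
#' when it falls within the join distance. Each chain's bounds are then
#' extended `window` genes to either side of its outermost hits and
#' clipped at the replicon ends.
#'
#' Two readings of the join distance are exposed. `"hit_in_window"`
#' (default) joins a hit lying within `window` genes of the previous hit.
#' `"extensions_overlap"` joins hits whose `window`-gene extensions
#' overlap (gap of at most `2 * window`). Under the default reading, two
#' chains can end up with overlapping extended ranges; because a cluster
#' is a single genomic locus, such chains are merged into one cluster
#' when `merge_overlapping_extensions` is `TRUE` (default), which makes
#' cluster ranges on a replicon pairwise disjoint.
#'
#' @param hits Hit tibble (see [read_hits()]); all rows must be
#'   significant, and every (genome, replicon) must exist in `genes`.
#' @param genes Gene table (see [read_gene_table()]).
#' @param window Number of genes extended to either side of a hit;
#'   default 6.
#' @param join_rule `"hit_in_window"` or `"extensions_overlap"`.
#' @param merge_overlapping_extensions Merge chains whose extended ranges
#'   overlap? Default `TRUE`.
#' @return A tibble with one row per cluster: `cluster_id`
#'   (`"<genome>_<n>"`, numbered per genome from 1 in replicon-then-index
#'   order), `genome_id`, `replicon_id`, `first_index`, `last_index`
#'   (0-based inclusive gene-index bounds), `first_locus`, `last_locus`,
#'   `n_genes`, `n_hits`, `classes` (list column of class sets) and
#'   `hits` (list column of the member hit rows).
#' @export
call_clusters <- function(hits, genes, window = 6,
                          join_rule = c("hit_in_window",
                                        "extensions_overlap"),
                          merge_overlapping_extensions = TRUE) {
  join_rule <- match.arg(join_rule)
  stopifnot(is.numeric(window), length(window) == 1, window >= 0)
  window <- as.integer(window)
  if (nrow(hits) > 0 && !all(hits$significant)) {
    abort("call_clusters() requires significant hits only; filter first")
  }
  repl_sizes <- genes |>
    group_by(.data$genome_id, .data$replicon_id) |>
    summarise(n_genes = n(), .groups = "drop")
  if (nrow(hits) > 0) {
    unknown <- hits |>
      distinct(.data$genome_id, .data$replicon_id) |>
      anti_join(repl_sizes, by = c("genome_id", "replicon_id"))
    if (nrow(unknown) > 0) {
      abort(paste0("Hit(s) on replicon(s) absent from the gene table: ",
                   paste(paste0(unknown$genome_id, "/",
                                unknown$replicon_id), collapse = ", ")))
    }
  }
  join_gap <- if (join_rule == "hit_in_window") window else 2L * window

  empty <- tibble(
    cluster_id = character(), genome_id = character(),
    replicon_id = character(), first_index = integer(),
    last_index = integer(), first_locus = character(),
    last_locus = character(), n_genes = integer(), n_hits = integer(),
    classes = list(), hits = list()
  )
  if (nrow(hits) == 0) return(empty)

  # replicon display order: order of appearance in the sorted gene table
  repl_order <- genes |> distinct(.data$genome_id, .data$replicon_id) |>
    mutate(.repl_rank = row_number())

  per_repl <- hits |>
    group_by(.data$genome_id, .data$replicon_id) |>
    dplyr::group_split()

  blocks <- purrr::map(per_repl, function(h) {
    gsz <- repl_sizes$n_genes[repl_sizes$genome_id == h$genome_id[1] &
                                repl_sizes$replicon_id == h$replicon_id[1]]
    h <- arrange(h, .data$gene_index)
    idx <- h$gene_index
    # chain: new cluster when the gap to the previous hit exceeds join_gap
    chain <- cumsum(c(1L, as.integer(diff(idx) > join_gap)))
    spans <- tibble(chain = chain, gene_index = idx) |>
      group_by(.data$chain) |>
      summarise(first_index = max(0L, min(.data$gene_index) - window),
                last_index = min(gsz - 1L, max(.data$gene_index) + window),
                .groups = "drop")
    if (merge_overlapping_extensions && nrow(spans) > 1) {
      # iterative interval merge on the extended ranges (sorted, so one
      # left-to-right pass suffices)
      merged_id <- integer(nrow(spans))
      merged_id[1] <- 1L
      for (k in 2:nrow(spans)) {
        prev <- which(merged_id == merged_id[k - 1])
        merged_id[k] <- if (spans$first_index[k] <=
                              max(spans$last_index[prev])) {
          merged_id[k - 1]
        } else {
          merged_id[k - 1] + 1L
        }
      }
      spans <- spans |>
        mutate(chain = merged_id) |>
        group_by(.data$chain) |>
        summarise(first_index = min(.data$first_index),
                  last_index = max(.data$last_index), .groups = "drop")
      chain <- merged_id[chain]
    }
    spans$hits <- purrr::map(spans$chain, function(cl) {
      select(h[chain == cl, ], -dplyr::any_of(".repl_rank"))
    })
    spans$genome_id <- h$genome_id[1]
    spans$replicon_id <- h$replicon_id[1]
    spans
  })

  out <- bind_rows(blocks) |>
    left_join(repl_order, by = c("genome_id", "replicon_id")) |>
    arrange(.data$genome_id, .data$.repl_rank, .data$first_index) |>
    group_by(.data$genome_id) |>
    mutate(cluster_id = paste0(.data$genome_id, "_", row_number())) |>
    ungroup() |>
    mutate(
      n_genes = .data$last_index - .data$first_index + 1L,
      n_hits = purrr::map_int(.data$hits, nrow),
      classes = purrr::map(.data$hits,
                           ~ sort(unique(.x$sm_class)))
    )

  # locus tags at the cluster bounds, for reporting
  bounds <- genes |>
    select(all_of(c("genome_id", "replicon_id", "gene_index",
                    "locus_tag")))
  out <- out |>
    left_join(rename(bounds, first_locus = "locus_tag"),
              by = c("genome_id", "replicon_id",
                     first_index = "gene_index")) |>
    left_join(rename(bounds, last_locus = "locus_tag"),
              by = c("genome_id", "replicon_id",
                     last_index = "gene_index"))
  select(out, all_of(names(empty)))
}

#' Tally clusters by secondary-metabolite class
#'
#' Counts, per genome, the clusters containing each class. A hybrid
#' cluster counts once toward every class it contains — an NRPS/PKS
#' hybrid is counted once as an NRPS and once as a PKS — so class counts
#' can sum to more than the number of clusters, which is reported
#' separately in the `n_clusters` attribute.
#'
#' @param clusters Cluster tibble from [call_clusters()].
#' @param classes Classes to tabulate (default all 13, zero-filled).
#' @return A tibble with `genome_id`, `sm_class`, `n` (clusters of that
#'   genome containing that class), carrying an `n_clusters` attribute
#'   (tibble of total clusters per genome).
#' @export
class_census <- function(clusters, classes = sm_classes()) {
  genome_ids <- unique(clusters$genome_id)
  totals <- clusters |> dplyr::count(.data$genome_id, name = "n_clusters")
  if (nrow(clusters) == 0) {
    out <- tibble(genome_id = character(), sm_class = character(),
                  n = integer())
  } else {
    long <- clusters |>
      select(all_of(c("genome_id", "cluster_id", "classes"))) |>
      tidyr::unnest_longer("classes", values_to = "sm_class")
    out <- long |>
      dplyr::count(.data$genome_id, .data$sm_class) |>
      tidyr::complete(
        genome_id = genome_ids,
        sm_class = classes,
        fill = list(n = 0L)
      ) |>
      dplyr::filter(.data$sm_class %in% classes) |>
      arrange(.data$genome_id,
              match(.data$sm_class, classes))
  }
  attr(out, "n_clusters") <- totals
  out
}

#' Ratio of NRPS to PKS cluster counts
#'
#' Pools cluster-class counts over a genome set and returns the ratio of
#' NRPS-containing cluster counts to PKS-containing cluster counts (all
#' three PKS types pooled). With no PKS clusters the ratio is undefined
#' and `NA` is returned with a message.
#'
#' @param census A census tibble from [class_census()], or several
#'   row-bound together.
#' @return A single number, or `NA_real_` when the PKS denominator is 0.
#' @export
#' @examples
#' # a genus with 14 NRPS-containing and 5 PKS-containing clusters
#' cs <- tibble::tibble(
#'   genome_id = "G", sm_class = c("NRPS", "PKS1"), n = c(14L, 5L)
#' )
#' nrps_pks_ratio(cs) # 2.8
nrps_pks_ratio <- function(census) {
  n_nrps <- sum(census$n[census$sm_class == "NRPS"])
  n_pks <- sum(census$n[census$sm_class %in% pks_classes()])
  if (n_pks == 0) {
    inform("No PKS clusters: NRPS:PKS ratio is undefined")
    return(NA_real_)
  }
  n_nrps / n_pks
}
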