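# Homolog-group multiset for every gene-index range of each cluster:
# list (keyed by cluster_id) of tibbles group_id / n copies. Genes absent
# from any group are counted in cluster size but carry no group.
cluster_group_content <- function(clusters, genes, groups) {
  membership <- groups |>
    distinct(.data$genome_id, .data$locus_tag, .data$group_id)
  purrr::map(seq_len(nrow(clusters)), function(k) {
    cl <- clusters[k, ]
    g <- genes |>
      dplyr::filter(.data$genome_id == cl$genome_id,
                    .data$replicon_id == cl$replicon_id,
                    .data$gene_index >= cl$first_index,
                    .data$gene_index <= cl$last_index)
    g |>
      inner_join(membership, by = c("genome_id", "locus_tag")) |>
      dplyr::count(.data$group_id)
  }) |>
    setNames(clusters$cluster_id)
}

#' Gene-content similarity between two clusters
#'
#' Scores how much of the smaller cluster's gene content is shared with
#' the larger: the number of homolog groups shared between the two
#' clusters (min-copy counted, as in [shared_gene_count()]) divided by
#' the gene count of the smaller cluster (`"containment"`, default).
#' With containment, a small cluster fully nested in a larger one scores
#' 1, so families whose members have undergone large-scale expansion
#' still group together; `"jaccard"` divides by the union size instead.
#'
#' @param c1,c2 Single-row cluster tibbles (from [call_clusters()]).
#' @param genes Gene table covering both clusters.
#' @param groups Homolog-group tibble.
#' @param method `"containment"` (default) or `"jaccard"`.
#' @return A number in `[0, 1]`.
#' @export
cluster_content_similarity <- function(c1, c2, genes, groups,
                                       method = c("containment",
                                                  "jaccard")) {
  method <- match.arg(method)
  both <- bind_rows(c1, c2)
  if (nrow(both) != 2) abort("c1 and c2 must be single-row clusters")
  if (any(both$n_genes < 1)) abort("Empty cluster: similarity undefined")
  content <- cluster_group_content(both, genes, groups)
  pair_content_similarity(content[[1]], content[[2]],
                          both$n_genes[1], both$n_genes[2], method)
}

pair_content_similarity <- function(g1, g2, n1, n2, method) {
  shared <- g1 |>
    inner_join(g2, by = "group_id", suffix = c("_1", "_2")) |>
    summarise(s = sum(pmin(.data$n_1, .data$n_2))) |>
    pull("s")
  shared <- if (length(shared)) shared else 0
  denom <- switch(method,
    containment = min(n1, n2),
    jaccard = n1 + n2 - shared
  )
  if (denom == 0) 0 else shared / denom
}

#' Group clusters into gene cluster families
#'
#' Partitions a genus's clusters into gene cluster families (GCFs):
#' clusters are nodes of a graph with an edge wherever the gene-content
#' similarity reaches `threshold` *and* the class sets intersect (so
#' unrelated classes cannot chain through shared transport or regulatory
#' genes); families are the connected components. Singleton clusters
#' become size-1 families. A genome may contribute several members to
#' one family (multi-copy families).
#'
#' Family ids are deterministic: families are sorted by their smallest
#' member `cluster_id` and labelled `F1`, `F2`, ...
#'
#' @param clusters Cluster tibble from [call_clusters()], one genus.
#' @param genes Gene table covering the clusters.
#' @param groups Homolog-group tibble.
#' @param threshold Similarity needed for an edge, in `(0, 1]`
#'   (default 0.5). Values above 1 yield all-singleton families.
#' @param method Similarity flavour, see [cluster_content_similarity()].
#' @return `clusters` with a `family_id` column added.
#' @seealso [family_summary()], [conservation_histogram()],
#'   [delineate_boundaries()]
#' @export
group_families <- function(clusters, genes, groups, threshold = 0.5,
                           method = c("containment", "jaccard")) {
  method <- match.arg(method)
  if (!(threshold > 0)) abort("threshold must be positive")
  n <- nrow(clusters)
  if (n == 0) {
    clusters$family_id <- character()
    return(clusters)
  }
  content <- cluster_group_content(clusters, genes, groups)
  edges <- NULL
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    keep <- purrr::map_lgl(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (length(intersect(clusters$classes[[i]],
                           clusters$classes[[j]])) == 0) {
        return(FALSE)
      }
      sim <- pair_content_similarity(content[[i]], content[[j]],
                                     clusters$n_genes[i],
                                     clusters$n_genes[j], method)
      sim >= threshold
    })
    edges <- pairs[, keep, drop = FALSE]
  }
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && ncol(edges) > 0) {
    gr <- igraph::add_edges(gr, as.vector(edges))
  }
  comp <- igraph::components(gr)$membership
  # deterministic ids: rank components by their smallest member cluster_id
  comp_rank <- rank(tapply(clusters$cluster_id, comp, min),
                    ties.method = "first")
  clusters$family_id <- paste0("F", comp_rank[as.character(comp)])
  clusters
}

#' Summarise gene cluster families
#'
#' One row per family: size (member count), number of distinct genomes,
#' pooled class set and member cluster ids.
#'
#' @param clusters Cluster tibble with a `family_id` column
#'   (see [group_families()]).
#' @return A tibble with `family_id`, `size`, `n_genomes`, `classes`
#'   (list column), `members` (list column of cluster ids).
#' @export
family_summary <- function(clusters) {
  if (!"family_id" %in% names(clusters)) {
    abort("clusters lack family_id; run group_families() first")
  }
  clusters |>
    group_by(.data$family_id) |>
    summarise(
      size = n(),
      n_genomes = dplyr::n_distinct(.data$genome_id),
      classes = list(sort(unique(unlist(.data$classes)))),
      members = list(sort(.data$cluster_id)),
      .groups = "drop"
    ) |>
    arrange(as.integer(sub("^F", "", .data$family_id)))
}

#' Conservation histogram of a cluster class
#'
#' How conserved are the clusters of one class within a genus: counts
#' families whose class set contains `sm_class`, binned by family size.
#' A genus where three PKS families are unique to single genomes and one
#' PKS family recurs four times yields the histogram `{1: 3, 4: 1}`.
#'
#' @param clusters Cluster tibble with `family_id`
#'   (see [group_families()]), one genus.
#' @param sm_class Class to tabulate (see [sm_classes()]).
#' @return A tibble with `family_size` and `n_families` (empty when the
#'   genus has no family of that class).
#' @export
conservation_histogram <- function(clusters, sm_class) {
  fams <- family_summary(clusters)
  fams <- fams[purrr::map_lgl(fams$classes, ~ sm_class %in% .x), ]
  if (nrow(fams) == 0) {
    return(tibble(family_size = integer(), n_families = integer()))
  }
  fams |>
    dplyr::count(family_size = .data$size, name = "n_families") |>
    arrange(.data$family_size)
}

#' Delineate cluster boundaries from conserved gene content
#'
#' Within a gene cluster family, the biosynthetic core travels together
#' while the flanking genes differ between genomic backgrounds. For each
#' member cluster, every gene in its (window-extended) range is scored
#' by the fraction of the *other* members whose gene content contains
#' its homolog group; the trimmed cluster is the maximal contiguous run
#' of genes with conservation at or above `min_fraction` that contains
#' the member's signature hit(s). Signature-hit positions are always
#' treated as conserved. With `min_fraction = 0` the trimmed range is
#' the full cluster range.
#'
#' Boundaries are undefined for size-1 families (no second context to
#' compare against): requesting one is an error, and by default only
#' families of size >= 2 are processed.
#'
#' @param clusters Cluster tibble with `family_id`
#'   (see [group_families()]).
#' @param genes Gene table covering the clusters.
#' @param groups Homolog-group tibble.
#' @param min_fraction Conservation fraction a gene needs to stay inside
#'   the trimmed cluster, in `[0, 1]` (default 0.8).
#' @param family_ids Families to process. Default: all of size >= 2.
#' @return A tibble with one row per member cluster: `family_id`,
#'   `cluster_id`, `trimmed_first_index`, `trimmed_last_index`,
#'   `trimmed_first_locus`, `trimmed_last_locus`, and a `conservation`
#'   list column (per-gene tibble of `gene_index`, `locus_tag`,
#'   `fraction`).
#' @export
delineate_boundaries <- function(clusters, genes, groups,
                                 min_fraction = 0.8, family_ids = NULL) {
  if (!"family_id" %in% names(clusters)) {
    abort("clusters lack family_id; run group_families() first")
  }
  sizes <- clusters |> dplyr::count(.data$family_id)
  if (is.null(family_ids)) {
    family_ids <- sizes$family_id[sizes$n >= 2]
    if (length(family_ids) == 0) {
      abort("No family of size >= 2: boundaries undefined")
    }
  } else {
    unknown <- setdiff(family_ids, sizes$family_id)
    if (length(unknown) > 0) {
      abort(paste0("Unknown family id(s): ",
                   paste(unknown, collapse = ", ")))
    }
    single <- intersect(family_ids, sizes$family_id[sizes$n < 2])
    if (length(single) > 0) {
      abort(paste0("Family of size 1 has no boundaries: ",
                   paste(single, collapse = ", ")))
    }
  }
  members <- dplyr::filter(clusters, .data$family_id %in% family_ids)
  content <- cluster_group_content(members, genes, groups)
  membership <- groups |>
    distinct(.data$genome_id, .data$locus_tag, .data$group_id)

  out <- purrr::map(seq_len(nrow(members)), function(k) {
    cl <- members[k, ]
    others <- which(members$family_id == cl$family_id)
    others <- setdiff(others, k)
    other_groups <- purrr::map(others, ~ content[[.x]]$group_id)
    g <- genes |>
      dplyr::filter(.data$genome_id == cl$genome_id,
                    .data$replicon_id == cl$replicon_id,
                    .data$gene_index >= cl$first_index,
                    .data$gene_index <= cl$last_index) |>
      arrange(.data$gene_index) |>
      left_join(membership, by = c("genome_id", "locus_tag"))
    frac <- purrr::map_dbl(g$group_id, function(gid) {
      if (is.na(gid)) return(0)
      mean(purrr::map_lgl(other_groups, ~ gid %in% .x))
    })
    hit_idx <- sort(cl$hits[[1]]$gene_index)
    conserved <- frac >= min_fraction
    conserved[g$gene_index %in% hit_idx] <- TRUE
    # contiguous runs of equal conservation status; hits sit in
    # conserved runs by construction
    run <- cumsum(c(TRUE, diff(conserved) != 0))
    first_run <- run[g$gene_index == min(hit_idx)]
    last_run <- run[g$gene_index == max(hit_idx)]
    trimmed_first <- min(g$gene_index[run == first_run])
    trimmed_last <- max(g$gene_index[run == last_run])
    tibble(
      family_id = cl$family_id,
      cluster_id = cl$cluster_id,
      trimmed_first_index = trimmed_first,
      trimmed_last_index = trimmed_last,
      trimmed_first_locus =
        g$locus_tag[g$gene_index == trimmed_first],
      trimmed_last_locus =
        g$locus_tag[g$gene_index == trimmed_last],
      conservation = list(tibble(gene_index = g$gene_index,
                                 locus_tag = g$locus_tag,
                                 fraction = frac))
    )
  })
  bind_rows(out)
}
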