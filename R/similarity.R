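#' Shared-gene count between two genomes under the min-copy rule
#'
#' For each homolog group containing genes from both genomes, the group
#' contributes the smaller of the two copy numbers — when one genome has
#' two copies of a gene and the other has four, the pair shares two. The
#' shared-gene count is the sum of these per-group minima.
#'
#' @param groups Homolog-group tibble (see [read_orthomcl_groups()]).
#' @param a,b Genome ids, `a != b`; both must be known (a genome with
#'   zero grouped genes is known only if listed in `known_genomes`).
#' @param known_genomes Optional character vector of valid genome ids;
#'   defaults to the genomes present in `groups`.
#' @return Integer shared-gene count.
#' @export
shared_gene_count <- function(groups, a, b,
                              known_genomes = unique(groups$genome_id)) {
  if (a == b) abort("shared_gene_count() needs two distinct genomes")
  unknown <- setdiff(c(a, b), known_genomes)
  if (length(unknown) > 0) {
    abort(paste0("Unknown genome id(s): ", paste(unknown, collapse = ", ")))
  }
  counts <- groups |>
    dplyr::filter(.data$genome_id %in% c(a, b)) |>
    dplyr::count(.data$group_id, .data$genome_id) |>
    tidyr::pivot_wider(names_from = "genome_id", values_from = "n",
                       values_fill = 0L)
  if (!a %in% names(counts)) counts[[a]] <- 0L
  if (!b %in% names(counts)) counts[[b]] <- 0L
  as.integer(sum(pmin(counts[[a]], counts[[b]])))
}

#' Pairwise genome similarity from homolog groups
#'
#' Builds the genome-by-genome similarity matrix: the shared-gene count
#' `S[i, j]` between genomes `i` and `j` under the min-copy rule, and the
#' fraction `F[i, j] = S[i, j] / G[j]` where `G[j]` is the total number
#' of protein-coding genes of the *column* genome. Dividing by one
#' genome's size makes `F` asymmetric — each pair has two similarity
#' values — so a reduced genome's column is uniformly high (almost all
#' its genes are shared) while a very large genome's column is uniformly
#' low. Genes absent from every group (singletons) count toward `G` but
#' never toward `S`; the diagonal of `F` is fixed at 1 and
#' `S[i, i] = G[i]`.
#'
#' @param groups Homolog-group tibble (see [read_orthomcl_groups()]).
#' @param genomes Either a gene table covering all genomes (gene counts
#'   are taken per genome) or a named numeric vector of gene counts
#'   `G`. Every genome must have `G >= 1`.
#' @return An object of class `bgc_similarity`: a list with integer
#'   matrix `shared`, numeric matrix `fraction` (rows `i`, columns `j`,
#'   `F[i, j] = S[i, j] / G[j]`), vector `G`, and `genome_order`.
#'   Supports [tidy()], [glance()], [autoplot()] and
#'   [write_heatmap_table()].
#' @export
genome_similarity <- function(groups, genomes) {
  G <- genome_sizes(genomes)
  if (any(G < 1)) {
    abort(paste0("Genome(s) with zero genes (similarity undefined): ",
                 paste(names(G)[G < 1], collapse = ", ")))
  }
  stray <- setdiff(unique(groups$genome_id), names(G))
  if (length(stray) > 0) {
    abort(paste0("Groups mention genome(s) without gene counts: ",
                 paste(stray, collapse = ", ")))
  }
  ids <- names(G)
  n <- length(ids)
  S <- matrix(0L, n, n, dimnames = list(ids, ids))
  # per-group copy-number matrix, then per-pair min-sums
  cn <- groups |>
    dplyr::count(.data$group_id, .data$genome_id)
  if (nrow(cn) > 0) {
    cmat <- matrix(0L, length(unique(cn$group_id)), n,
                   dimnames = list(unique(cn$group_id), ids))
    cmat[cbind(cn$group_id, cn$genome_id)] <- cn$n
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          s <- sum(pmin(cmat[, i], cmat[, j]))
          S[i, j] <- s
          S[j, i] <- s
        }
      }
    }
  }
  diag(S) <- as.integer(G)
  Fm <- sweep(S, 2, G, "/")
  diag(Fm) <- 1
  structure(
    list(shared = S, fraction = Fm, G = G, genome_order = ids),
    class = "bgc_similarity"
  )
}

# Accept a gene table or a named vector of gene counts.
genome_sizes <- function(genomes) {
  if (is.data.frame(genomes)) {
    tb <- genomes |> dplyr::count(.data$genome_id)
    setNames(as.double(tb$n), tb$genome_id)
  } else if (is.numeric(genomes) && !is.null(names(genomes))) {
    genomes
  } else {
    abort("genomes must be a gene table or a named vector of gene counts")
  }
}

#' Reorder the genomes of a similarity matrix
#'
#' Sets the display order of a similarity matrix, typically to the leaf
#' order of a phylogenetic tree so that related genomes are adjacent in
#' the heatmap. The order must be a permutation of the genomes.
#'
#' @param x A `bgc_similarity` object.
#' @param order Character vector of genome ids, or a path to a newick
#'   tree file whose leaf order is used.
#' @return The reordered `bgc_similarity` object.
#' @export
set_genome_order <- function(x, order) {
  stopifnot(inherits(x, "bgc_similarity"))
  if (is.character(order) && length(order) == 1 && file.exists(order)) {
    order <- newick_leaf_order(order)
  }
  missing <- setdiff(x$genome_order, order)
  extra <- setdiff(order, x$genome_order)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "Order is not a permutation of the genomes.",
      if (length(missing) > 0)
        paste0(" Missing: ", paste(missing, collapse = ", "), "."),
      if (length(extra) > 0)
        paste0(" Unknown: ", paste(extra, collapse = ", "), ".")
    ))
  }
  x$shared <- x$shared[order, order, drop = FALSE]
  x$fraction <- x$fraction[order, order, drop = FALSE]
  x$G <- x$G[order]
  x$genome_order <- order
  x
}

#' Leaf order of a newick tree
#'
#' Reads a newick file and returns its tip labels in plotting order,
#' used to arrange similarity-matrix axes like a phylogeny.
#'
#' @param path Path to a newick file (first tree used).
#' @return Character vector of tip labels.
#' @export
newick_leaf_order <- function(path) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  tree$tip.label
}

#' Write a similarity matrix as a heatmap table
#'
#' Writes the fraction matrix as TSV with genomes on both axes in the
#' display order (rows `i` by columns `j`, `F[i, j] = S[i, j] / G[j]`).
#'
#' @param x A `bgc_similarity` object.
#' @param path Output TSV path.
#' @param order Optional genome order (character vector or newick path),
#'   applied via [set_genome_order()] before writing.
#' @param what `"fraction"` (default) or `"shared"`.
#' @return `path`, invisibly.
#' @export
write_heatmap_table <- function(x, path, order = NULL,
                                what = c("fraction", "shared")) {
  what <- match.arg(what)
  if (!is.null(order)) x <- set_genome_order(x, order)
  m <- x[[what]]
  df <- bind_cols(tibble(genome_id = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @describeIn genome_similarity Long-format view: one row per ordered
#'   genome pair with shared count and fraction.
#' @param x A `bgc_similarity` object.
#' @param ... Unused.
#' @method tidy bgc_similarity
#' @export
tidy.bgc_similarity <- function(x, ...) {
  ids <- x$genome_order
  tidyr::expand_grid(genome_i = ids, genome_j = ids) |>
    mutate(
      shared = as.integer(x$shared[cbind(.data$genome_i, .data$genome_j)]),
      fraction = as.numeric(
        x$fraction[cbind(.data$genome_i, .data$genome_j)])
    )
}

#' @describeIn genome_similarity One-row summary: genome count, gene
#'   count range, and off-diagonal fraction range.
#' @method glance bgc_similarity
#' @export
glance.bgc_similarity <- function(x, ...) {
  off <- x$fraction[row(x$fraction) != col(x$fraction)]
  tibble(
    n_genomes = length(x$genome_order),
    min_genes = min(x$G), max_genes = max(x$G),
    min_fraction = if (length(off)) min(off) else NA_real_,
    max_fraction = if (length(off)) max(off) else NA_real_
  )
}

#' @export
print.bgc_similarity <- function(x, ...) {
  cat("<bgc_similarity> ", length(x$genome_order), " genomes, ",
      min(x$G), "-", max(x$G), " genes\n", sep = "")
  invisible(x)
}

#' @describeIn genome_similarity Heatmap of the fraction matrix in the
#'   display order (columns are the denominator genomes).
#' @param object A `bgc_similarity` object.
#' @method autoplot bgc_similarity
#' @export
autoplot.bgc_similarity <- function(object, ...) {
  df <- tidy(object) |>
    mutate(
      genome_i = factor(.data$genome_i, levels = object$genome_order),
      genome_j = factor(.data$genome_j, levels = object$genome_order)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$genome_j, .data$genome_i,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "S/G(col)") +
    ggplot2::scale_y_discrete(limits = rev(object$genome_order)) +
    ggplot2::labs(x = "denominator genome (column)", y = NULL,
                  title = "Whole-genome similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 90, hjust = 1))
  }
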