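#' Select single-copy ribosomal-protein homolog groups
#'
#' Picks the homolog groups suitable for a concatenated phylogeny: a
#' group qualifies when (a) it contains a reference-genome gene whose
#' product annotation matches a ribosomal-protein pattern and (b) it has
#' exactly one member in every genome. The bundled pattern set covers
#' the 41 ribosomal proteins conventionally used
#' (see [ribosomal_protein_names()]); matching is case-insensitive, so
#' annotations like \dQuote{50S ribosomal protein L1} qualify.
#'
#' @param groups Homolog-group tibble (see [read_orthomcl_groups()]).
#' @param annotations Tibble with `locus_tag` and `product` for the
#'   reference genome's genes (or a named character vector of products
#'   keyed by locus tag).
#' @param genomes Genomes that must each contribute exactly one member;
#'   default all genomes present in `groups`.
#' @param patterns Regular expressions a product must match; default
#'   [ribosomal_protein_patterns()].
#' @return Sorted character vector of qualifying `group_id`s; an error
#'   (suggesting relaxed patterns) when none qualify.
#' @export
select_single_copy_groups <- function(groups, annotations,
                                      genomes = unique(groups$genome_id),
                                      patterns =
                                        ribosomal_protein_patterns()) {
  if (!is.data.frame(annotations)) {
    annotations <- tibble(locus_tag = names(annotations),
                          product = unname(annotations))
  }
  big_pattern <- paste0("(", paste(patterns, collapse = ")|("), ")")
  ribo_tags <- annotations$locus_tag[
    grepl(big_pattern, annotations$product, ignore.case = TRUE)
  ]
  candidate <- unique(groups$group_id[groups$locus_tag %in% ribo_tags])
  copy_counts <- groups |>
    dplyr::filter(.data$group_id %in% candidate,
                  .data$genome_id %in% genomes) |>
    dplyr::count(.data$group_id, .data$genome_id)
  ok <- copy_counts |>
    group_by(.data$group_id) |>
    summarise(universal_single =
                n() == length(genomes) && all(.data$n == 1L),
              .groups = "drop") |>
    dplyr::filter(.data$universal_single)
  if (nrow(ok) == 0) {
    abort(paste0("No ribosomal-protein group is single-copy in every ",
                 "genome; consider relaxing the product patterns"))
  }
  sort(ok$group_id)
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Joins per-gene multiple alignments (one per selected homolog group,
#' each covering every genome) into one concatenated sequence per
#' genome, in a canonical gene order (sorted group id) so shuffled input
#' produces identical output. Within a gene all sequences must have
#' equal length, and every genome must be present in every alignment.
#'
#' @param alignments Named list (by group id) of alignments; each
#'   alignment is a named character vector or `Biostrings::AAStringSet`
#'   keyed by genome id.
#' @return An object of class `bgc_concat`: list with `sequences`
#'   (named character vector, one concatenation per genome),
#'   `gene_order` (sorted group ids), `gene_lengths` (named integer
#'   vector), and `total_length`.
#' @export
concatenate_alignments <- function(alignments) {
  if (length(alignments) == 0) abort("No alignments supplied")
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    abort("Alignments must be named by group id")
  }
  alignments <- purrr::map(alignments, function(a) {
    if (methods::is(a, "AAStringSet")) setNames(as.character(a), names(a))
    else a
  })
  gene_order <- sort(names(alignments))
  genomes <- sort(names(alignments[[1]]))
  for (gid in gene_order) {
    a <- alignments[[gid]]
    missing <- setdiff(genomes, names(a))
    extra <- setdiff(names(a), genomes)
    if (length(missing) > 0 || length(extra) > 0) {
      abort(paste0("Alignment '", gid, "' does not cover the same ",
                   "genomes as the others (missing: ",
                   paste(missing, collapse = ", "), ")"))
    }
    if (length(unique(nchar(a))) != 1) {
      abort(paste0("Ragged alignment '", gid,
                   "': sequences differ in length"))
    }
  }
  gene_lengths <- purrr::map_int(alignments[gene_order],
                                 ~ nchar(.x[[1]]))
  sequences <- setNames(purrr::map_chr(genomes, function(g) {
    paste(purrr::map_chr(gene_order, ~ alignments[[.x]][[g]]),
          collapse = "")
  }), genomes)
  structure(
    list(sequences = sequences, gene_order = gene_order,
         gene_lengths = gene_lengths,
         total_length = sum(gene_lengths)),
    class = "bgc_concat"
  )
}

#' @export
print.bgc_concat <- function(x, ...) {
  cat("<bgc_concat> ", length(x$sequences), " genomes x ",
      x$total_length, " aligned residues (", length(x$gene_order),
      " genes)\n", sep = "")
  invisible(x)
}

#' @describeIn concatenate_alignments Per-gene view of the supermatrix:
#'   group id, aligned length, and cumulative offset.
#' @param x A `bgc_concat` object.
#' @param ... Unused.
#' @method tidy bgc_concat
#' @export
tidy.bgc_concat <- function(x, ...) {
  tibble(
    group_id = x$gene_order,
    length = as.integer(x$gene_lengths),
    offset = cumsum(c(0L, head(as.integer(x$gene_lengths), -1)))
  )
}

#' @describeIn concatenate_alignments One-row summary of the
#'   supermatrix.
#' @method glance bgc_concat
#' @export
glance.bgc_concat <- function(x, ...) {
  tibble(n_genomes = length(x$sequences),
         n_genes = length(x$gene_order),
         total_length = x$total_length)
}

#' Write a concatenated supermatrix to FASTA
#'
#' @param x A `bgc_concat` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_concat_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x$sequences), path)
  invisible(path)
}
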