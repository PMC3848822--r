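#' Read an ordered gene table
#'
#' Reads protein-coding genes from a TSV gene table or a GFF3 file and
#' returns them as one tidy tibble with a per-replicon gene ordinal. The
#' gene ordinal — not the nucleotide coordinate — is the unit of the
#' six-gene window rule used by [call_clusters()], so genes are sorted by
#' start coordinate within each replicon and numbered `0..N-1`. Ties on
#' start are broken by end coordinate, then locus tag.
#'
#' Plasmid replicons are dropped by default (set `include_plasmids = TRUE`
#' to keep them); the classification comes from a `replicon_type`
#' column/attribute and defaults to `"chromosome"` when absent.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` (columns `genome_id`, `replicon_id`, `locus_tag`,
#'   `start`, `end`, and optionally `strand`, `product`, `replicon_type`,
#'   `protein_seq`) or `"gff3"` (CDS features with a `locus_tag`
#'   attribute).
#' @param genome_id Genome identifier used for GFF3 input, which carries
#'   none; defaults to the file name without extension. Ignored for TSV.
#' @param include_plasmids Keep replicons annotated as plasmids? Default
#'   `FALSE`, so plasmids are excluded from gene counts and all downstream
#'   comparisons.
#' @return A tibble with columns `genome_id`, `replicon_id`,
#'   `replicon_type`, `locus_tag`, `gene_index` (0-based, per replicon),
#'   `start`, `end`, `strand`, `product`, and `protein_seq` when present.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' readr::write_tsv(tibble::tibble(
#'   genome_id = "G1", replicon_id = "chr", locus_tag = c("a", "b", "c"),
#'   start = c(100, 900, 500), end = c(400, 1200, 800)
#' ), tf)
#' read_gene_table(tf)
read_gene_table <- function(path, format = c("tsv", "gff3"),
                            genome_id = NULL, include_plasmids = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("Gene table file not found: '", path, "'"))
  }
  genes <- switch(format,
    tsv  = read_gene_table_tsv(path),
    gff3 = read_gene_table_gff3(path, genome_id = genome_id)
  )
  as_gene_table(genes, include_plasmids = include_plasmids)
}

read_gene_table_tsv <- function(path) {
  if (!any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    return(tibble(genome_id = character(), replicon_id = character(),
                  locus_tag = character(), start = double(),
                  end = double()))
  }
  genes <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             start = readr::col_double(),
                             end = readr::col_double(),
                             .default = readr::col_character()
                           ))
  required <- c("genome_id", "replicon_id", "locus_tag", "start", "end")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    abort(paste0("Gene table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  genes
}

read_gene_table_gff3 <- function(path, genome_id = NULL) {
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  gff <- as_tibble(rtracklayer::readGFF(path))
  if (nrow(gff) == 0) {
    return(tibble(genome_id = character(), replicon_id = character(),
                  locus_tag = character(), start = double(), end = double()))
  }
  cds <- dplyr::filter(gff, .data$type == "CDS")
  tibble(
    genome_id = genome_id,
    replicon_id = as.character(cds$seqid),
    replicon_type = if ("replicon_type" %in% names(cds)) {
      as.character(cds$replicon_type)
    } else NA_character_,
    locus_tag = as.character(cds$locus_tag),
    start = as.double(cds$start),
    end = as.double(cds$end),
    strand = as.character(cds$strand),
    product = if ("product" %in% names(cds)) as.character(cds$product)
              else NA_character_
  )
}

#' Normalise a gene data frame into an ordered gene table
#'
#' Applies the same ordering, indexing and validation as
#' [read_gene_table()] to an in-memory data frame: optional plasmid
#' filtering, sorting by `(replicon_id, start, end, locus_tag)`, and
#' assignment of the 0-based per-replicon `gene_index`.
#'
#' @param genes Data frame with at least `genome_id`, `replicon_id`,
#'   `locus_tag`; `start`/`end` are used for ordering when present.
#' @inheritParams read_gene_table
#' @return A tibble in gene-table form (see [read_gene_table()]).
#' @export
as_gene_table <- function(genes, include_plasmids = FALSE) {
  genes <- as_tibble(genes)
  if (!"replicon_type" %in% names(genes)) genes$replicon_type <- NA_character_
  genes$replicon_type <- dplyr::coalesce(genes$replicon_type, "chromosome")
  if (!"strand" %in% names(genes)) genes$strand <- NA_character_
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  if (!"start" %in% names(genes)) genes$start <- NA_real_
  if (!"end" %in% names(genes)) genes$end <- NA_real_

  if (!include_plasmids) {
    genes <- dplyr::filter(genes, .data$replicon_type != "plasmid")
  }
  if (nrow(genes) > 0) {
    bad <- dplyr::filter(genes, !is.na(.data$start) & !is.na(.data$end) &
                           .data$start > .data$end)
    if (nrow(bad) > 0) {
      abort(paste0("start > end for locus_tag(s): ",
                   paste(head(bad$locus_tag, 5), collapse = ", ")))
    }
    dup <- genes |>
      dplyr::count(.data$genome_id, .data$locus_tag) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort(paste0("Duplicate locus_tag(s) within a genome: ",
                   paste(head(dup$locus_tag, 5), collapse = ", ")))
    }
  }
  genes <- genes |>
    arrange(.data$genome_id, .data$replicon_id, .data$start, .data$end,
            .data$locus_tag) |>
    group_by(.data$genome_id, .data$replicon_id) |>
    mutate(gene_index = row_number() - 1L) |>
    ungroup()

  front <- c("genome_id", "replicon_id", "replicon_type", "locus_tag",
             "gene_index", "start", "end", "strand", "product")
  select(genes, all_of(front), dplyr::everything())
}

#' Write a gene table to TSV
#'
#' Writes the columns of a gene table (as produced by [read_gene_table()])
#' so that re-reading reproduces locus tags, coordinates and index
#' assignment. Protein sequences, if attached, are not written; use
#' [write_protein_fasta()] for those.
#'
#' @param genes A gene-table tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  cols <- intersect(c("genome_id", "replicon_id", "replicon_type",
                      "locus_tag", "gene_index", "start", "end", "strand",
                      "product"), names(genes))
  readr::write_tsv(select(genes, all_of(cols)), path)
  invisible(path)
}

#' Write a gene table as GFF3
#'
#' Emits one CDS feature per gene with `locus_tag`, `product` and
#' `replicon_type` attributes, suitable for round-tripping through
#' [read_gene_table()] with `format = "gff3"`.
#'
#' @inheritParams write_gene_table
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    attrs <- paste0(
      "ID=", genes$locus_tag, ";locus_tag=", genes$locus_tag,
      ";replicon_type=", genes$replicon_type,
      ifelse(is.na(genes$product), "", paste0(";product=", genes$product))
    )
    writeLines(paste(genes$replicon_id, "bgcfam", "CDS",
                     format(genes$start, scientific = FALSE, trim = TRUE),
                     format(genes$end, scientific = FALSE, trim = TRUE),
                     ".", dplyr::coalesce(genes$strand, "+"), "0",
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Attach protein sequences to a gene table
#'
#' Joins amino-acid sequences from a FASTA file (headers are locus tags)
#' onto a gene table as a `protein_seq` column.
#'
#' @param genes A gene-table tibble.
#' @param fasta Path to a protein FASTA file, or a named character vector /
#'   `Biostrings::AAStringSet` keyed by locus tag.
#' @return `genes` with a `protein_seq` column (NA where no sequence).
#' @export
add_protein_seqs <- function(genes, fasta) {
  seqs <- as_aa_vector(fasta)
  genes$protein_seq <- unname(seqs[genes$locus_tag])
  genes
}

#' Write protein sequences from a gene table to FASTA
#'
#' @param genes A gene-table tibble with a `protein_seq` column.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(genes, path) {
  if (!"protein_seq" %in% names(genes)) {
    abort("Gene table has no protein_seq column")
  }
  keep <- dplyr::filter(genes, !is.na(.data$protein_seq))
  aas <- Biostrings::AAStringSet(setNames(keep$protein_seq, keep$locus_tag))
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

# Accept a FASTA path, named character vector or AAStringSet.
as_aa_vector <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    x <- Biostrings::readAAStringSet(x)
  }
  if (methods::is(x, "AAStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (!is.character(x) || is.null(names(x))) {
    abort("Protein sequences must be a FASTA path or named character vector")
  }
  # FASTA headers may carry descriptions after the locus tag
  names(x) <- sub("\\s.*$", "", names(x))
  x
}
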