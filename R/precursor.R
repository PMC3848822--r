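#' Extract candidate lanthipeptide precursor peptides from a cluster
#'
#' Lanthipeptide precursors are short ribosomal peptides whose cysteine,
#' serine and threonine residues form the lanthionine rings, so within a
#' lanthipeptide cluster they can be recognised as short ORFs enriched
#' in those residues. A protein in the cluster qualifies when it is at
#' most `max_len` residues long, contains at least `min_cys` cysteines
#' and at least `min_ser_thr` serine-or-threonine residues, and is not
#' itself a signature-hit gene (the cyclase). This detection heuristic
#' is deliberately simple; its parameters are exposed and its behaviour
#' is characterised on simulated data only.
#'
#' @param clusters Cluster tibble (rows with a lanthipeptide class; see
#'   [call_clusters()]).
#' @param genes Gene table with a `protein_seq` column.
#' @param max_len Maximum precursor length in residues (default 120).
#' @param min_cys Minimum cysteine count (default 2).
#' @param min_ser_thr Minimum serine + threonine count (default 1).
#' @return A tibble with `cluster_id`, `genome_id`, `locus_tag`,
#'   `gene_index`, `length`, `protein_seq`; zero rows (not an error)
#'   when a cluster holds no qualifying ORF.
#' @export
extract_candidate_precursors <- function(clusters, genes, max_len = 120,
                                         min_cys = 2, min_ser_thr = 1) {
  if (!"protein_seq" %in% names(genes) ||
      all(is.na(genes$protein_seq))) {
    abort("Gene table has no protein sequences; attach them first")
  }
  lanthi <- clusters[purrr::map_lgl(clusters$classes,
                                    ~ "lanthipeptide" %in% .x), ]
  out <- purrr::map(seq_len(nrow(lanthi)), function(k) {
    cl <- lanthi[k, ]
    hit_tags <- cl$hits[[1]]$locus_tag
    g <- genes |>
      dplyr::filter(.data$genome_id == cl$genome_id,
                    .data$replicon_id == cl$replicon_id,
                    .data$gene_index >= cl$first_index,
                    .data$gene_index <= cl$last_index,
                    !.data$locus_tag %in% hit_tags,
                    !is.na(.data$protein_seq))
    seq_up <- toupper(g$protein_seq)
    len <- nchar(seq_up)
    n_c <- stringr::str_count(seq_up, "C")
    n_st <- stringr::str_count(seq_up, "[ST]")
    keep <- len <= max_len & n_c >= min_cys & n_st >= min_ser_thr
    tibble(
      cluster_id = cl$cluster_id,
      genome_id = cl$genome_id,
      locus_tag = g$locus_tag[keep],
      gene_index = g$gene_index[keep],
      length = len[keep],
      protein_seq = g$protein_seq[keep]
    )
  })
  bind_rows(out)
}

#' Build a position-frequency matrix from peptide sequences
#'
#' Counts, per alignment column, the occurrences of each amino acid (20
#' letters plus the gap symbol `-`), as the numeric core of a sequence
#' logo. Sequences must all have the same length; pre-align them
#' externally otherwise. The consensus takes each column's most frequent
#' symbol, breaking ties alphabetically (gap last).
#'
#' @param sequences Character vector (or named vector /
#'   `Biostrings::AAStringSet`) of equal-length peptide sequences.
#' @return An object of class `bgc_pfm`: list with `counts`
#'   (positions x symbols integer matrix), `n_sequences`, `length`,
#'   `consensus`, and `alphabet`. Supports [tidy()], [glance()],
#'   [autoplot()] and [write_pfm()].
#' @export
#' @examples
#' pfm <- build_pfm(c("AC", "AD"))
#' pfm$consensus
#' tidy(pfm)
build_pfm <- function(sequences) {
  if (methods::is(sequences, "AAStringSet")) {
    sequences <- as.character(sequences)
  }
  sequences <- toupper(unname(sequences))
  if (length(sequences) == 0) abort("No sequences supplied")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    abort("Sequences differ in length; align them before build_pfm()")
  }
  len <- lens[1]
  alphabet <- aa_alphabet(gap = TRUE)
  mat <- matrix(0L, nrow = len, ncol = length(alphabet),
                dimnames = list(NULL, alphabet))
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                  nrow = len)
  bad <- setdiff(unique(as.vector(chars)), alphabet)
  if (length(bad) > 0) {
    abort(paste0("Symbol(s) outside the amino-acid alphabet + gap: ",
                 paste(bad, collapse = ", ")))
  }
  for (p in seq_len(len)) {
    tb <- table(factor(chars[p, ], levels = alphabet))
    mat[p, ] <- as.integer(tb)
  }
  consensus <- paste(alphabet[apply(mat, 1, which.max)], collapse = "")
  structure(
    list(counts = mat, n_sequences = length(sequences), length = len,
         consensus = consensus, alphabet = alphabet),
    class = "bgc_pfm"
  )
}

#' @export
print.bgc_pfm <- function(x, ...) {
  cat("<bgc_pfm> ", x$n_sequences, " sequences x ", x$length,
      " positions; consensus ", x$consensus, "\n", sep = "")
  invisible(x)
}

#' @describeIn build_pfm Long-format view: `position`, `symbol`,
#'   `count`, `freq`, and per-position information content in bits
#'   (log2(20) minus the column's Shannon entropy over non-gap symbols).
#' @param x A `bgc_pfm` object.
#' @param ... Unused.
#' @method tidy bgc_pfm
#' @export
tidy.bgc_pfm <- function(x, ...) {
  df <- as_tibble(x$counts) |>
    mutate(position = row_number()) |>
    tidyr::pivot_longer(-"position", names_to = "symbol",
                        values_to = "count") |>
    mutate(freq = .data$count / x$n_sequences)
  bits <- df |>
    dplyr::filter(.data$symbol != "-") |>
    group_by(.data$position) |>
    summarise(bits = {
      p <- .data$count / sum(.data$count)
      p <- p[p > 0]
      if (length(p) == 0) 0 else log2(20) + sum(p * log2(p))
    }, .groups = "drop")
  left_join(df, bits, by = "position") |>
    arrange(.data$position, match(.data$symbol, x$alphabet))
}

#' @describeIn build_pfm One-row summary with consensus string.
#' @method glance bgc_pfm
#' @export
glance.bgc_pfm <- function(x, ...) {
  tibble(n_sequences = x$n_sequences, length = x$length,
         consensus = x$consensus)
}

#' @describeIn build_pfm Stacked per-position residue frequencies
#'   (text-based logo substitute).
#' @param object A `bgc_pfm` object.
#' @method autoplot bgc_pfm
#' @export
autoplot.bgc_pfm <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$freq,
                                   fill = .data$symbol,
                                   label = .data$symbol)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_text(position = ggplot2::position_stack(vjust = 0.5),
                       size = 3) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$length)) +
    ggplot2::labs(x = "position", y = "frequency",
                  title = "Precursor position frequencies") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Write a position-frequency matrix as TSV
#'
#' Rows are positions, columns the 20 amino acids plus gap.
#'
#' @param x A `bgc_pfm` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(x, path) {
  df <- bind_cols(tibble(position = seq_len(x$length)),
                  as_tibble(x$counts))
  readr::write_tsv(df, path)
  invisible(path)
}
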