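#' Read signature-enzyme hits
#'
#' Reads signature-enzyme detections from either a simplified TSV
#' (columns `locus_tag`, `model_name`, `score`, `evalue`; extra columns
#' ignored) or an HMMER3 `domtblout` file, joins them to the gene table
#' by locus tag to acquire genome, replicon and gene ordinal, maps each
#' model to its secondary-metabolite class, and flags significance
#' against the per-model cutoffs.
#'
#' @param path Path to the hits file.
#' @param genes Gene table (see [read_gene_table()]) used to resolve
#'   locus tags; hits on unknown locus tags are an error.
#' @param format `"tsv"` or `"domtblout"`.
#' @param model_cutoffs Table with `model_name`, `sm_class` and at least
#'   one of `min_score` / `max_evalue` per model (default
#'   [default_model_cutoffs()]). A model absent from this table is an
#'   error.
#' @return A tibble of hits: `genome_id`, `replicon_id`, `locus_tag`,
#'   `gene_index`, `sm_class`, `model_name`, `score`, `evalue`,
#'   `significant`. A gene may carry hits of several classes.
#' @export
read_hits <- function(path, genes, format = c("tsv", "domtblout"),
                      model_cutoffs = default_model_cutoffs()) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("Hits file not found: '", path, "'"))
  }
  if (!any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    return(annotate_hits(tibble(locus_tag = character(),
                                model_name = character(),
                                score = double(), evalue = double()),
                         genes, model_cutoffs))
  }
  raw <- switch(format,
    tsv = readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            score = readr::col_double(),
                            evalue = readr::col_double(),
                            .default = readr::col_character()
                          )),
    domtblout = read_domtblout(path)
  )
  required <- c("locus_tag", "model_name", "score")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Hits input is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"evalue" %in% names(raw)) raw$evalue <- NA_real_
  annotate_hits(select(raw, all_of(c("locus_tag", "model_name", "score",
                                     "evalue"))),
                genes, model_cutoffs)
}

# HMMER3 --domtblout: whitespace-delimited, 22 fixed columns then a
# free-text description; '#' comment lines skipped. Full-sequence E-value
# (col 7) and score (col 8) are used.
read_domtblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    return(tibble(locus_tag = character(), model_name = character(),
                  score = double(), evalue = double()))
  }
  fields <- strsplit(lines, "\\s+")
  short <- which(lengths(fields) < 13)
  if (length(short) > 0) {
    abort(paste0("domtblout row with too few columns at data line ",
                 short[1]))
  }
  tibble(
    locus_tag = purrr::map_chr(fields, 1),
    model_name = purrr::map_chr(fields, 4),
    evalue = as.numeric(purrr::map_chr(fields, 7)),
    score = as.numeric(purrr::map_chr(fields, 8))
  )
}

#' Annotate raw hits with genome coordinates, class and significance
#'
#' Joins a raw hit table (`locus_tag`, `model_name`, `score`, `evalue`)
#' to the gene table and the model/cutoff table, producing the full hit
#' tibble that [read_hits()] returns. Useful when hits are already in
#' memory (e.g. from [simulate_genus()]).
#'
#' @param raw Tibble with `locus_tag`, `model_name`, `score` and
#'   optionally `evalue`.
#' @inheritParams read_hits
#' @return A hit tibble; see [read_hits()].
#' @export
annotate_hits <- function(raw, genes,
                          model_cutoffs = default_model_cutoffs()) {
  if (!"evalue" %in% names(raw)) raw$evalue <- NA_real_
  model_cutoffs <- as_tibble(model_cutoffs)
  unknown_models <- setdiff(unique(raw$model_name),
                            model_cutoffs$model_name)
  if (length(unknown_models) > 0) {
    abort(paste0("Model(s) absent from the model/cutoff table: ",
                 paste(unknown_models, collapse = ", ")))
  }
  unknown_loci <- setdiff(unique(raw$locus_tag), genes$locus_tag)
  if (length(unknown_loci) > 0) {
    abort(paste0("Hit(s) on locus_tag(s) absent from the gene table: ",
                 paste(head(unknown_loci, 10), collapse = ", ")))
  }
  if (!"min_score" %in% names(model_cutoffs)) {
    model_cutoffs$min_score <- NA_real_
  }
  if (!"max_evalue" %in% names(model_cutoffs)) {
    model_cutoffs$max_evalue <- NA_real_
  }
  raw |>
    left_join(select(genes, all_of(c("genome_id", "replicon_id",
                                     "locus_tag", "gene_index"))),
              by = "locus_tag") |>
    left_join(select(model_cutoffs, all_of(c("model_name", "sm_class",
                                             "min_score", "max_evalue"))),
              by = "model_name") |>
    mutate(
      significant =
        (is.na(.data$min_score) | .data$score >= .data$min_score) &
        (is.na(.data$max_evalue) |
           (!is.na(.data$evalue) & .data$evalue <= .data$max_evalue))
    ) |>
    select(all_of(c("genome_id", "replicon_id", "locus_tag", "gene_index",
                    "sm_class", "model_name", "score", "evalue",
                    "significant")))
}

#' Remove PKS hits on fatty-acid synthases
#'
#' Fatty-acid synthases share domains with polyketide synthases and are
#' picked up by the PKS models. Given a table of FAS-model scores per
#' gene, any PKS-class hit whose gene scores higher against the FAS model
#' than against the PKS model is dropped before cluster calling. With no
#' FAS table the hits pass through unchanged.
#'
#' @param hits Hit tibble from [read_hits()].
#' @param fas_scores Optional tibble with `locus_tag` and `fas_score`.
#' @return The filtered hit tibble.
#' @export
resolve_fas_conflicts <- function(hits, fas_scores = NULL) {
  if (is.null(fas_scores) || nrow(fas_scores) == 0) {
    return(hits)
  }
  fas <- fas_scores |>
    group_by(.data$locus_tag) |>
    summarise(fas_score = max(.data$fas_score), .groups = "drop")
  hits |>
    left_join(fas, by = "locus_tag") |>
    dplyr::filter(!(.data$sm_class %in% pks_classes() &
                      !is.na(.data$fas_score) &
                      .data$fas_score > .data$score)) |>
    select(-"fas_score")
}

#' Screen proteins for the PepM phosphonate motif
#'
#' Phosphoenolpyruvate mutase (PepM), the entry enzyme of phosphonate
#' biosynthesis, carries a conserved EDK-X(5)-NS motif: residues `E`,
#' `D`, `K`, then exactly five arbitrary residues, then `N`, `S`. Every
#' sequence containing the motif yields one phosphonate-class hit at the
#' first match position. The scan walks each sequence position by
#' position rather than delegating to a pattern engine.
#'
#' Sequences are uppercased before scanning; characters outside the
#' 20-letter amino-acid alphabet plus `X` trigger a warning and are
#' scanned literally.
#'
#' @param proteins A FASTA path, named character vector or
#'   `Biostrings::AAStringSet` of protein sequences keyed by locus tag.
#' @param genes Optional gene table; when supplied, hits are joined to it
#'   (unknown locus tags are then an error) so that the result can enter
#'   [call_clusters()] directly.
#' @return A tibble of phosphonate hits with `locus_tag`, `model_name`
#'   (`"PepM_motif"`), `motif_start` (1-based position of the `E`),
#'   `score`/`evalue` set to `NA`, `significant = TRUE`, plus genome
#'   coordinates when `genes` is given.
#' @export
#' @examples
#' scan_pepm_motif(c(p1 = "MEDKAAAAANSW", p2 = "MEDKAAAANSW"))
scan_pepm_motif <- function(proteins, genes = NULL) {
  seqs <- toupper(as_aa_vector(proteins))
  ok_chars <- paste0("^[", paste(aa_alphabet(gap = FALSE), collapse = ""),
                     "X]*$")
  odd <- !grepl(ok_chars, seqs)
  if (any(odd)) {
    warn(paste0("Sequence(s) with non-standard residues scanned ",
                "literally: ",
                paste(head(names(seqs)[odd], 5), collapse = ", ")))
  }
  pos <- unname(vapply(seqs, pepm_first_match, integer(1)))
  found <- tibble(
    locus_tag = names(seqs)[pos > 0L],
    model_name = "PepM_motif",
    motif_start = pos[pos > 0L],
    score = NA_real_,
    evalue = NA_real_,
    sm_class = "phosphonate",
    significant = TRUE
  )
  if (!is.null(genes)) {
    unknown <- setdiff(found$locus_tag, genes$locus_tag)
    if (length(unknown) > 0) {
      abort(paste0("Motif hit(s) on locus_tag(s) absent from the gene ",
                   "table: ", paste(head(unknown, 10), collapse = ", ")))
    }
    found <- found |>
      left_join(select(genes, all_of(c("genome_id", "replicon_id",
                                       "locus_tag", "gene_index"))),
                by = "locus_tag") |>
      select(all_of(c("genome_id", "replicon_id", "locus_tag",
                      "gene_index", "sm_class", "model_name", "score",
                      "evalue", "significant", "motif_start")))
  }
  found
}

# First 1-based position of E-D-K-x(5)-N-S, or 0L; explicit positional
# walk (tests compare it against a regular-expression oracle).
pepm_first_match <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 10L) return(0L)
  for (i in seq_len(n - 9L)) {
    if (chars[i] == "E" && chars[i + 1L] == "D" && chars[i + 2L] == "K" &&
        chars[i + 8L] == "N" && chars[i + 9L] == "S") {
      return(i)
    }
  }
  0L
}
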