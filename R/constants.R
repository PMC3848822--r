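#' Secondary-metabolite classes recognised by the pipeline
#'
#' The thirteen biosynthetic classes whose signature enzymes are used for
#' cluster calling: three polyketide synthase types, nonribosomal peptide
#' synthetases, indolocarbazoles, aerobactin-like (NRPS-independent)
#' siderophores, butyrolactones, aminoglycosides, beta-lactams, terpene
#' synthases, lanthipeptide cyclases, thiazole/oxazole-modified microcins
#' (YcaO domain) and phosphonates (PepM).
#'
#' @return Character vector of the 13 class labels.
#' @export
#' @examples
#' sm_classes()
sm_classes <- function() {
  c("PKS1", "PKS2", "PKS3", "NRPS", "indolocarbazole",
    "aerobactin_siderophore", "butyrolactone", "aminoglycoside",
    "beta_lactam", "terpene", "lanthipeptide", "TOMM", "phosphonate")
}

# The PKS sub-types, pooled when forming the NRPS:PKS ratio.
pks_classes <- function() c("PKS1", "PKS2", "PKS3")

#' Default signature-model table
#'
#' A bundled table mapping profile-HMM model names to secondary-metabolite
#' classes with per-model bit-score cutoffs. Real analyses should supply the
#' cutoff table that accompanies their model set; this default covers the 13
#' classes with one model each and is the table used by the synthetic-genus
#' simulator, plus a fatty-acid-synthase model used only for screening out
#' FAS genes hit by the PKS models.
#'
#' @return A tibble with columns `model_name`, `sm_class`, `min_score`.
#' @export
#' @examples
#' default_model_cutoffs()
default_model_cutoffs <- function() {
  tibble::tribble(
    ~model_name,     ~sm_class,                ~min_score,
    "PKS1_KS",       "PKS1",                   50,
    "PKS2_KS",       "PKS2",                   50,
    "PKS3",          "PKS3",                   50,
    "NRPS_C",        "NRPS",                   50,
    "IndC",          "indolocarbazole",        50,
    "IucA_IucC",     "aerobactin_siderophore", 50,
    "AfsA",          "butyrolactone",          50,
    "AGly",          "aminoglycoside",         50,
    "BLS",           "beta_lactam",            50,
    "Terpene_synth", "terpene",                50,
    "LanC",          "lanthipeptide",          50,
    "YcaO",          "TOMM",                   50,
    "PepM",          "phosphonate",            50
  )
}

#' Ribosomal proteins used for concatenated phylogenies
#'
#' The 41 ribosomal proteins conventionally taken for a concatenated
#' supermatrix of single-copy genes shared by all strains of a genus.
#'
#' @return Character vector of ribosomal-protein names (e.g. `"L1"`,
#'   `"L7/L12"`, `"S12"`).
#' @export
ribosomal_protein_names <- function() {
  c("L1", "L2", "L3", "L4", "L5", "L6", "L7/L12", "L9", "L10", "L11",
    "L13", "L14", "L15", "L16", "L17", "L18", "L19", "L20", "L21", "L22",
    "L23", "L24", "L25p", "L27", "L29", "L35",
    "S1", "S3", "S5", "S6", "S7", "S8", "S9", "S10", "S11", "S12", "S13",
    "S15", "S17", "S19", "S20")
}

#' Regular expressions matching ribosomal-protein product annotations
#'
#' One case-insensitive pattern per protein in [ribosomal_protein_names()],
#' matching annotations such as \dQuote{50S ribosomal protein L1}. Word
#' boundaries prevent `L1` from matching `L11`.
#'
#' @param names Protein names to build patterns for.
#' @return Character vector of regular expressions.
#' @export
ribosomal_protein_patterns <- function(names = ribosomal_protein_names()) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", names)
  paste0("ribosomal protein ", esc, "\\b")
}

# 20-letter amino-acid alphabet; gap symbol sorts last for consensus ties.
aa_alphabet <- function(gap = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (gap) c(aa, "-") else aa
}
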