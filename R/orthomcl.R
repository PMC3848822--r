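#' Read an OrthoMCL-style groups file
#'
#' Parses the classic one-group-per-line format
#' `GROUPID: taxon|gene taxon|gene ...` into a long tibble of group
#' memberships. Taxon labels can be remapped to genome identifiers with a
#' named `taxon_map`. A gene may belong to at most one group; duplicate
#' membership across lines is an error, as is a line without a colon.
#'
#' @param path Path to the groups file.
#' @param taxon_map Optional named character vector mapping file taxon
#'   labels to genome ids (`c(tw = "T_whipplei")`). Unmapped taxa keep
#'   their label.
#' @return A tibble with columns `group_id`, `genome_id`, `locus_tag`;
#'   one row per group member (multi-copy members appear once per copy).
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines("g1: A|x A|y B|z", tf)
#' read_orthomcl_groups(tf)
read_orthomcl_groups <- function(path, taxon_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Groups file not found: '", path, "'"))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(tibble(group_id = character(), genome_id = character(),
                  locus_tag = character()))
  }
  no_colon <- keep[!grepl(":", lines[keep], fixed = TRUE)]
  if (length(no_colon) > 0) {
    abort(paste0("Malformed groups line (no ':') at line ", no_colon[1],
                 ": '", substr(lines[no_colon[1]], 1, 60), "'"))
  }
  parsed <- purrr::map(keep, function(i) {
    parts <- strsplit(lines[i], ":", fixed = TRUE)[[1]]
    gid <- trimws(parts[1])
    members <- strsplit(trimws(paste(parts[-1], collapse = ":")),
                        "\\s+")[[1]]
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      abort(paste0("Group '", gid, "' at line ", i, " has no members"))
    }
    taxon <- sub("\\|.*$", "", members)
    gene <- sub("^[^|]*\\|", "", members)
    bad <- !grepl("|", members, fixed = TRUE)
    if (any(bad)) {
      abort(paste0("Member '", members[bad][1], "' at line ", i,
                   " is not of the form taxon|gene"))
    }
    tibble(group_id = gid, genome_id = taxon, locus_tag = gene)
  })
  groups <- bind_rows(parsed)
  if (!is.null(taxon_map)) {
    hit <- groups$genome_id %in% names(taxon_map)
    groups$genome_id[hit] <- unname(taxon_map[groups$genome_id[hit]])
  }
  validate_homolog_groups(groups)
  groups
}

#' Validate homolog-group memberships
#'
#' Checks the group-table invariants: each `(genome_id, locus_tag)` pair
#' belongs to at most one group, and every group has at least one member.
#'
#' @param groups Tibble with `group_id`, `genome_id`, `locus_tag`.
#' @return `groups`, invisibly; errors on violation.
#' @export
validate_homolog_groups <- function(groups) {
  dup <- groups |>
    distinct(.data$group_id, .data$genome_id, .data$locus_tag) |>
    dplyr::count(.data$genome_id, .data$locus_tag) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Gene(s) assigned to more than one homolog group: ",
                 paste(head(paste0(dup$genome_id, "|", dup$locus_tag), 5),
                       collapse = ", ")))
  }
  invisible(groups)
}

#' Write homolog groups in OrthoMCL format
#'
#' @param groups Tibble with `group_id`, `genome_id`, `locus_tag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_orthomcl_groups <- function(groups, path) {
  lines <- groups |>
    mutate(member = paste0(.data$genome_id, "|", .data$locus_tag)) |>
    group_by(.data$group_id) |>
    summarise(line = paste0(.data$group_id[1], ": ",
                            paste(.data$member, collapse = " ")),
              .groups = "drop") |>
    arrange(.data$group_id)
  writeLines(lines$line, path)
  invisible(path)
}
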