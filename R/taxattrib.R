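#' Read an ORF taxonomy table
#'
#' TSV with columns `orf_id`, `lineage`, `rank` (`family` or `phylum`); one
#' row per ORF.
#'
#' @param path TSV path.
#' @return Tibble with those columns.
#' @export
read_taxonomy_table <- function(path) {
  tx <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  dup <- unique(tx$orf_id[duplicated(tx$orf_id)])
  if (length(dup) > 0L) {
    rlang::abort(paste0("duplicate orf_id in taxonomy table: ",
                        paste(dup, collapse = ", ")))
  }
  tx
}

#' Attach lineages to gene assignments
#'
#' Left-joins the taxonomy table onto the assignments; ORFs without a
#' taxonomy row are retained with lineage `"unassigned"`.
#'
#' @param assignments Assignment tibble.
#' @param tax_table Tibble `orf_id`, `lineage`, `rank` (one row per ORF).
#' @return `assignments` with `lineage` and `rank` columns added.
#' @export
attach_taxonomy <- function(assignments, tax_table) {
  dup <- unique(tax_table$orf_id[duplicated(tax_table$orf_id)])
  if (length(dup) > 0L) {
    rlang::abort(paste0("duplicate orf_id in taxonomy table: ",
                        paste(dup, collapse = ", ")))
  }
  idx <- match(assignments$orf_id, tax_table$orf_id)
  assignments$lineage <- ifelse(is.na(idx), "unassigned", tax_table$lineage[idx])
  assignments$rank <- ifelse(is.na(idx), NA_character_, tax_table$rank[idx])
  assignments
}

#' Lineage-by-enzyme contribution matrix
#'
#' Presence of each enzyme code within each bacterial lineage, per sample: a
#' cell is present iff at least one unambiguous gene of that code was
#' attributed to that lineage, independent of abundance. Genes with lineage
#' `"unassigned"` are excluded from the matrix and counted in the
#' `unassigned` footer.
#'
#' @param assignments Assignment tibble with lineages attached (one or more
#'   samples).
#' @return A `contribution_matrix`: list with `cells` (tibble `sample_id`,
#'   `lineage`, `enzyme_code`, `n_genes`, `present`) and `unassigned`
#'   (tibble `sample_id`, `n_genes`).
#' @export
contribution_matrix <- function(assignments) {
  stopifnot("lineage" %in% names(assignments))
  un <- assignments[!assignments$ambiguous, , drop = FALSE]
  unassigned <- dplyr::count(
    un[un$lineage == "unassigned", , drop = FALSE],
    .data$sample_id, name = "n_genes"
  )
  used <- un[un$lineage != "unassigned", , drop = FALSE]
  cells <- dplyr::count(used, .data$sample_id, .data$lineage, .data$enzyme_code,
                        name = "n_genes")
  cells$present <- cells$n_genes >= 1L
  cells <- cells[order(cells$sample_id, cells$lineage, cells$enzyme_code,
                       method = "radix"), , drop = FALSE]
  structure(list(cells = tibble::as_tibble(cells),
                 unassigned = tibble::as_tibble(unassigned)),
            class = "contribution_matrix")
}

#' @export
print.contribution_matrix <- function(x, ...) {
  cat("<contribution_matrix> ", nrow(x$cells), " present cells across ",
      length(unique(x$cells$sample_id)), " sample(s), ",
      length(unique(x$cells$lineage)), " lineages, ",
      length(unique(x$cells$enzyme_code)), " enzyme codes\n", sep = "")
  invisible(x)
}

#' Lineages contributing to one enzyme code
#'
#' @param matrix A [contribution_matrix()].
#' @param enzyme_code Catalog code.
#' @param sample_id Optional: restrict to one sample; default is the union
#'   over samples.
#' @return Sorted character vector of lineages with presence.
#' @export
lineages_for_code <- function(matrix, enzyme_code, sample_id = NULL) {
  cells <- matrix$cells
  cells <- cells[cells$enzyme_code == enzyme_code & cells$present, , drop = FALSE]
  if (!is.null(sample_id)) {
    cells <- cells[cells$sample_id %in% sample_id, , drop = FALSE]
  }
  sort(unique(cells$lineage))
}

#' Read a 16S relative-abundance profile
#'
#' TSV with a `lineage` column and one percentage column per sample. Decimal
#' commas (the European dialect used in printed community tables) are
#' detected and converted.
#'
#' @param path TSV path.
#' @return Tibble: `lineage` plus one numeric column per sample, percentages.
#' @export
read_16s_profile <- function(path) {
  pr <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  for (col in setdiff(names(pr), "lineage")) {
    x <- pr[[col]]
    if (any(grepl(",", x, fixed = TRUE))) x <- sub(",", ".", x, fixed = TRUE)
    pr[[col]] <- as.numeric(x)
  }
  bad <- vapply(pr[setdiff(names(pr), "lineage")],
                function(x) any(is.na(x) | x < 0), logical(1))
  if (any(bad)) rlang::abort("16S profile contains missing or negative abundances")
  pr
}

#' Compare catabolic-gene and 16S lineage shares
#'
#' For one sample, sets the share of each lineage in the catabolic gene pool
#' (percent of unambiguous genes, `"unassigned"` included in the
#' denominator) against its 16S rRNA relative abundance. Lineages appearing
#' in either source are reported.
#'
#' @param assignments Assignment tibble with lineages attached.
#' @param profile_16s Tibble from [read_16s_profile()].
#' @param sample_id Sample to compare; must match a profile column and the
#'   assignments' sample.
#' @return Tibble: `lineage`, `catabolic_share`, `share_16s` (both percent;
#'   0 where the lineage is absent from a source).
#' @export
lineage_share_comparison <- function(assignments, profile_16s, sample_id) {
  if (!sample_id %in% names(profile_16s)) {
    rlang::abort(paste0("sample '", sample_id, "' not found in 16S profile columns: ",
                        paste(setdiff(names(profile_16s), "lineage"), collapse = ", ")))
  }
  asg <- assignments[assignments$sample_id == sample_id & !assignments$ambiguous, ,
                     drop = FALSE]
  if (nrow(asg) == 0L) {
    rlang::abort(paste0("no unambiguous assignments for sample '", sample_id, "'"))
  }
  counts <- dplyr::count(asg, .data$lineage, name = "n")
  counts$catabolic_share <- 100 * counts$n / sum(counts$n)
  lineages <- sort(union(counts$lineage, profile_16s$lineage))
  tibble::tibble(
    lineage = lineages,
    catabolic_share = {
      x <- counts$catabolic_share[match(lineages, counts$lineage)]
      ifelse(is.na(x), 0, x)
    },
    share_16s = {
      x <- profile_16s[[sample_id]][match(lineages, profile_16s$lineage)]
      ifelse(is.na(x), 0, x)
    }
  )
}
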