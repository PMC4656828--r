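#' Parse a 12-column BLAST-tabular hit table
#'
#' Reads the standard tab-separated outfmt-6 layout (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore) with no
#' header. Query ids are ORF identifiers, subject ids are reference-family
#' identifiers. Row order is preserved.
#'
#' @param path Path to a tab-separated hit table (may be empty).
#' @return Tibble of hit records: `orf_id`, `family_id`, `percent_identity`,
#'   `alignment_length` (amino acids), `evalue`, `bitscore`, plus the raw
#'   coordinate columns.
#' @export
parse_hit_table <- function(path) {
  cols <- c("orf_id", "family_id", "percent_identity", "alignment_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  empty <- tibble::as_tibble(stats::setNames(
    c(list(character(0), character(0)), rep(list(numeric(0)), 10)), cols
  ))
  empty$alignment_length <- integer(0)
  if (!file.exists(path)) rlang::abort(paste0("hit table not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1]
    rlang::abort(paste0("malformed hit table row at line ", bad, ": expected >= 12 tab-separated fields, found ", nf[bad]))
  }
  mat <- t(vapply(fields, function(f) f[1:12], character(12)))
  num <- function(j, what) {
    x <- suppressWarnings(as.numeric(mat[, j]))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1]
      rlang::abort(paste0("non-numeric ", what, " at line ", bad, ": '", mat[bad, j], "'"))
    }
    x
  }
  out <- tibble::tibble(
    orf_id = mat[, 1], family_id = mat[, 2],
    percent_identity = num(3, "percent identity"),
    alignment_length = as.integer(num(4, "alignment length")),
    mismatch = num(5, "mismatch count"), gapopen = num(6, "gap-open count"),
    qstart = num(7, "qstart"), qend = num(8, "qend"),
    sstart = num(9, "sstart"), send = num(10, "send"),
    evalue = num(11, "e-value"), bitscore = num(12, "bitscore")
  )
  if (any(out$percent_identity < 0 | out$percent_identity > 100)) {
    rlang::abort("percent identity outside [0, 100]")
  }
  if (any(out$alignment_length < 1L)) rlang::abort("alignment length below 1")
  out
}

#' Filter homology hits on identity and alignment length
#'
#' Keeps a hit iff `percent_identity` exceeds `min_identity` and
#' `alignment_length` exceeds `min_aln_len`. Both comparisons are strict by
#' default (a 50.0%-identity or 50-residue hit is dropped); set
#' `strict = FALSE` for an inclusive (`>=`) sensitivity variant. Row order is
#' preserved.
#'
#' @param hits Tibble from [parse_hit_table()].
#' @param min_identity Identity threshold, percent (default 50).
#' @param min_aln_len Alignment-length threshold, amino acids (default 50).
#' @param strict Use strict `>` comparisons (default `TRUE`).
#' @return The surviving subset of `hits`.
#' @export
filter_hits <- function(hits, min_identity = 50, min_aln_len = 50, strict = TRUE) {
  stopifnot(min_identity >= 0, min_identity <= 100, min_aln_len >= 0)
  keep <- if (strict) {
    hits$percent_identity > min_identity & hits$alignment_length > min_aln_len
  } else {
    hits$percent_identity >= min_identity & hits$alignment_length >= min_aln_len
  }
  hits[keep, , drop = FALSE]
}

#' Select the best hit per ORF
#'
#' One reference family per gene: for each `orf_id` the hit with the highest
#' bitscore is retained; ties are broken by lower e-value, then by
#' lexicographically smallest `family_id`, so the result is deterministic.
#'
#' @param hits Filtered hit tibble.
#' @return One row per `orf_id`, ordered by `orf_id`.
#' @export
select_best_hit <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$orf_id, -hits$bitscore, hits$evalue, hits$family_id,
               method = "radix")
  sorted <- hits[ord, , drop = FALSE]
  sorted[!duplicated(sorted$orf_id), , drop = FALSE]
}

#' Assign genes to degradation reactions or ambiguity classes
#'
#' Maps each best hit through the catalog family map. Families mapped to a
#' specific enzyme class yield unambiguous assignments; families mapped to a
#' nonspecific cluster (or to a class declared `specific = FALSE`) yield
#' ambiguous assignments carrying an ambiguity class (`"rieske"` for
#' Rieske-oxygenase clusters, `"exdo"` for extradiol-dioxygenase clusters).
#' Manual overrides — the curation step that stands in for expert tree
#' placement — are applied last.
#'
#' @param best_hits One row per ORF, from [select_best_hit()].
#' @param catalog A [reaction_catalog].
#' @param sample_id Sample label attached to every assignment.
#' @param overrides Optional tibble (`orf_id`, `enzyme_code`) where
#'   `enzyme_code` is a catalog code or `"ambiguous"`.
#' @return Assignment tibble: `orf_id`, `sample_id`, `enzyme_code` (`NA` when
#'   ambiguous), `ambiguous`, `ambiguity_class` (`"rieske"`, `"exdo"`,
#'   `"none"`), `source_family`, `overridden`.
#' @export
assign_reactions <- function(best_hits, catalog, sample_id = "sample",
                             overrides = NULL) {
  fam <- catalog$family_map
  unknown <- setdiff(unique(best_hits$family_id), fam$family_id)
  if (length(unknown) > 0L) {
    rlang::abort(paste0("hit families absent from catalog family map: ",
                        paste(unknown, collapse = ", ")))
  }
  if (nrow(best_hits) == 0L) {
    return(tibble::tibble(
      orf_id = character(), sample_id = character(), enzyme_code = character(),
      ambiguous = logical(), ambiguity_class = character(),
      source_family = character(), overridden = logical()
    ))
  }
  target <- fam$enzyme_code[match(best_hits$family_id, fam$family_id)]
  nonspecific_class <- catalog$enzyme_classes$code[!catalog$enzyme_classes$specific]
  is_amb <- startsWith(target, "nonspecific:") | target %in% nonspecific_class
  sf <- family_superfamily(catalog, target)
  amb_class <- ifelse(!is_amb, "none",
                      ifelse(sf == "rieske_oxygenase", "rieske", "exdo"))
  out <- tibble::tibble(
    orf_id = best_hits$orf_id,
    sample_id = sample_id,
    enzyme_code = ifelse(is_amb, NA_character_, target),
    ambiguous = is_amb,
    ambiguity_class = amb_class,
    source_family = best_hits$family_id,
    overridden = FALSE
  )
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    bad <- setdiff(setdiff(unique(overrides$enzyme_code), "ambiguous"),
                   catalog$enzyme_classes$code)
    if (length(bad) > 0L) {
      rlang::abort(paste0("override to unknown enzyme code: ",
                          paste(bad, collapse = ", ")))
    }
    idx <- match(out$orf_id, overrides$orf_id)
    hit <- !is.na(idx)
    code <- overrides$enzyme_code[idx[hit]]
    out$enzyme_code[hit] <- ifelse(code == "ambiguous", NA_character_, code)
    out$ambiguous[hit] <- code == "ambiguous"
    src_sf <- family_superfamily(catalog, fam$enzyme_code[match(out$source_family[hit], fam$family_id)])
    out$ambiguity_class[hit] <- ifelse(
      code != "ambiguous", "none",
      ifelse(src_sf == "rieske_oxygenase", "rieske", "exdo")
    )
    out$overridden[hit] <- TRUE
  }
  out[order(out$orf_id, method = "radix"), , drop = FALSE]
}

#' Bundle assignments into a sample profile
#'
#' @param sample_id Sample label.
#' @param total_orf_count Total number of predicted protein-coding genes in
#'   the sample (the denominator for [relative_abundance()]).
#' @param assignments Assignment tibble for this sample.
#' @return A `sample_profile` object.
#' @export
sample_profile <- function(sample_id, total_orf_count, assignments) {
  total_orf_count <- as.integer(total_orf_count)
  if (total_orf_count < nrow(assignments)) {
    rlang::abort("total ORF count below the number of catabolic assignments")
  }
  structure(
    list(sample_id = sample_id, total_orf_count = total_orf_count,
         assignments = assignments),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("<sample_profile> ", x$sample_id, ": ", nrow(x$assignments),
      " catabolic genes of ", x$total_orf_count, " ORFs (",
      format(relative_abundance(x), nsmall = 2), "%)\n", sep = "")
  invisible(x)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Relative abundance of catabolic genes
#'
#' Percentage of the sample's protein-coding genes that received a catabolic
#' assignment, rounded half-up to two decimals.
#'
#' @param profile A [sample_profile()].
#' @return Percentage (numeric scalar).
#' @export
relative_abundance <- function(profile) {
  if (profile$total_orf_count <= 0L) {
    rlang::abort("total ORF count must be positive")
  }
  round_half_up(100 * nrow(profile$assignments) / profile$total_orf_count, 2)
}

#' Gene counts per enzyme superfamily
#'
#' Tallies assignments by structural superfamily. Ambiguous genes are
#' included: a nonspecific Rieske or extradiol cluster fixes the superfamily
#' even when no single reaction can be assigned. Counts therefore sum to the
#' total number of assignments.
#'
#' @param assignments Assignment tibble.
#' @param catalog A [reaction_catalog].
#' @return Tibble `superfamily`, `n`, sorted by superfamily.
#' @export
superfamily_counts <- function(assignments, catalog) {
  if (nrow(assignments) == 0L) {
    return(tibble::tibble(superfamily = character(), n = integer()))
  }
  fam <- catalog$family_map
  target <- ifelse(assignments$ambiguous,
                   fam$enzyme_code[match(assignments$source_family, fam$family_id)],
                   assignments$enzyme_code)
  sf <- family_superfamily(catalog, target)
  dplyr::arrange(dplyr::count(tibble::tibble(superfamily = sf), .data$superfamily),
                 .data$superfamily)
}

#' Run the full screening stage on one hit table
#'
#' parse -> filter -> best hit -> assignment, the per-sample screening
#' pipeline.
#'
#' @inheritParams filter_hits
#' @inheritParams assign_reactions
#' @param path Hit-table path.
#' @param total_orf_count Total predicted genes in the sample.
#' @return A [sample_profile()].
#' @export
screen_sample <- function(path, catalog, sample_id, total_orf_count,
                          min_identity = 50, min_aln_len = 50, strict = TRUE,
                          overrides = NULL) {
  hits <- parse_hit_table(path)
  kept <- filter_hits(hits, min_identity, min_aln_len, strict = strict)
  best <- select_best_hit(kept)
  asg <- assign_reactions(best, catalog, sample_id, overrides)
  sample_profile(sample_id, total_orf_count, asg)
}
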