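#' @importFrom rlang .data abort
#' @importFrom tibble tibble as_tibble
NULL

#' Recognised enzyme superfamilies
#'
#' Structural superfamilies of the aromatic ring-attacking and ring-cleaving
#' enzymes covered by the reaction catalog: Rieske non-heme iron oxygenases,
#' extradiol dioxygenases of the cupin fold, other extradiol dioxygenases,
#' intradiol dioxygenases, flavin monooxygenases, hydroxylases, and a catch-all
#' class.
#'
#' @format Character vector of superfamily identifiers.
#' @export
SUPERFAMILIES <- c(
  "rieske_oxygenase", "exdo_cupin", "exdo_other",
  "intradiol_dioxygenase", "monooxygenase", "hydroxylase", "other"
)

#' Construct a reaction catalog
#'
#' A reaction catalog is the data contract between homology screening and
#' network reconstruction: it maps reference protein families to enzyme-class
#' codes, and enzyme codes to degradation reactions (substrate, product,
#' single- vs multi-step, and the root pollutant whose pathway the reaction
#' belongs to).
#'
#' @param compounds Tibble with columns `canonical_name` (lowercase, unique),
#'   `synonyms` (list-column of character vectors), `note`.
#' @param enzyme_classes Tibble with columns `code`, `full_name`,
#'   `superfamily` (one of [SUPERFAMILIES]), `specific` (logical; `FALSE`
#'   marks generic clusters whose hits are ambiguous).
#' @param reactions Tibble with columns `reaction_id`, `enzyme_code`,
#'   `substrate`, `product`, `step_kind` (`"single"` or `"multi"`),
#'   `root_pollutant`.
#' @param family_map Tibble with columns `family_id`, `enzyme_code`; the
#'   latter is either an enzyme-class code or `"nonspecific:<superfamily>"`
#'   for families that cannot be resolved to a single reaction specificity.
#' @param validate If `TRUE` (default), abort on any invariant violation.
#'
#' @return An object of class `reaction_catalog`.
#' @export
reaction_catalog <- function(compounds, enzyme_classes, reactions, family_map,
                             validate = TRUE) {
  compounds <- as_tibble(compounds)
  if (!is.list(compounds$synonyms)) {
    compounds$synonyms <- split_synonyms(compounds$synonyms)
  }
  cat <- structure(
    list(
      compounds = compounds,
      enzyme_classes = as_tibble(enzyme_classes),
      reactions = as_tibble(reactions),
      family_map = as_tibble(family_map)
    ),
    class = "reaction_catalog"
  )
  cat$id <- rlang::hash(list(cat$compounds, cat$enzyme_classes,
                             cat$reactions, cat$family_map))
  if (validate) {
    report <- validate_catalog(cat)
    if (nrow(report) > 0L) {
      abort(paste0(
        "invalid reaction catalog:\n",
        paste0("  [", report$rule, "] ", report$entity, ": ",
               report$message, collapse = "\n")
      ), class = "aromnet_validation_error")
    }
  }
  cat
}

split_synonyms <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
  })
}

#' Load a reaction catalog from disk
#'
#' Two on-disk dialects are supported: `tsv` (a directory holding
#' `compounds.tsv`, `classes.tsv`, `reactions.tsv`, `family_map.tsv`, for
#' human editing; synonyms pipe-separated) and `json` (a single file, for
#' lossless round-trips).
#'
#' @param path Directory (`tsv`) or file (`json`).
#' @param format `"tsv"` or `"json"`.
#' @return A validated [reaction_catalog].
#' @export
load_catalog <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("catalog path does not exist: ", path))
  }
  if (format == "tsv") {
    read_part <- function(name, cols) {
      f <- file.path(path, name)
      if (!file.exists(f)) abort(paste0("missing catalog table: ", f))
      readr::read_tsv(f, col_types = cols, progress = FALSE)
    }
    compounds <- read_part("compounds.tsv", readr::cols(
      canonical_name = "c", synonyms = "c", note = "c"
    ))
    classes <- read_part("classes.tsv", readr::cols(
      code = "c", full_name = "c", superfamily = "c", specific = "l"
    ))
    reactions <- read_part("reactions.tsv", readr::cols(.default = "c"))
    family_map <- read_part("family_map.tsv", readr::cols(.default = "c"))
    compounds$synonyms <- split_synonyms(compounds$synonyms)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (part in c("compounds", "enzyme_classes", "reactions", "family_map")) {
      if (is.null(raw[[part]]) || length(raw[[part]]) == 0L) {
        raw[[part]] <- NULL
      }
    }
    compounds <- as_tibble(raw$compounds)
    if (nrow(compounds) > 0L && !is.list(compounds$synonyms)) {
      compounds$synonyms <- as.list(compounds$synonyms)
    }
    classes <- as_tibble(raw$enzyme_classes)
    reactions <- as_tibble(raw$reactions)
    family_map <- as_tibble(raw$family_map)
  }
  if (nrow(classes) == 0L) {
    abort("invalid reaction catalog: no enzyme classes",
          class = "aromnet_validation_error")
  }
  reaction_catalog(compounds, classes, reactions, family_map)
}

#' Write a reaction catalog to disk
#'
#' Inverse of [load_catalog()]; a write followed by a load reproduces the
#' catalog field by field.
#'
#' @inheritParams load_catalog
#' @param catalog A [reaction_catalog].
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(catalog, "reaction_catalog"))
  if (format == "tsv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    compounds <- catalog$compounds
    compounds$synonyms <- vapply(compounds$synonyms, paste, "", collapse = "|")
    readr::write_tsv(compounds, file.path(path, "compounds.tsv"), progress = FALSE)
    readr::write_tsv(catalog$enzyme_classes, file.path(path, "classes.tsv"), progress = FALSE)
    readr::write_tsv(catalog$reactions, file.path(path, "reactions.tsv"), progress = FALSE)
    readr::write_tsv(catalog$family_map, file.path(path, "family_map.tsv"), progress = FALSE)
  } else {
    jsonlite::write_json(
      list(
        compounds = catalog$compounds,
        enzyme_classes = catalog$enzyme_classes,
        reactions = catalog$reactions,
        family_map = catalog$family_map
      ),
      path, dataframe = "columns", auto_unbox = FALSE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

#' Validate a reaction catalog
#'
#' Checks every structural invariant (unique codes and compound names,
#' synonym disjointness, referential integrity of reactions and the family
#' map, at least one reaction per specific enzyme class) and reports
#' violations instead of aborting.
#'
#' @param catalog A `reaction_catalog` (validated or not).
#' @return Tibble with columns `entity`, `rule`, `message`; zero rows iff the
#'   catalog satisfies all invariants.
#' @export
validate_catalog <- function(catalog) {
  v <- list()
  add <- function(entity, rule, message) {
    v[[length(v) + 1L]] <<- tibble(entity = entity, rule = rule, message = message)
  }
  cls <- catalog$enzyme_classes
  cmp <- catalog$compounds
  rxn <- catalog$reactions
  fam <- catalog$family_map

  if (nrow(cls) == 0L) add("catalog", "no_enzyme_classes", "no enzyme classes")
  dup <- unique(cls$code[duplicated(cls$code)])
  for (d in dup) add(d, "duplicate_enzyme_code", paste0("enzyme code '", d, "' declared more than once"))
  bad_sf <- setdiff(unique(cls$superfamily), SUPERFAMILIES)
  for (s in bad_sf) add(s, "unknown_superfamily", paste0("superfamily '", s, "' is not recognised"))

  if (any(!nzchar(cmp$canonical_name) | is.na(cmp$canonical_name))) {
    add("compounds", "empty_canonical_name", "compound with empty canonical name")
  }
  dupc <- unique(cmp$canonical_name[duplicated(cmp$canonical_name)])
  for (d in dupc) add(d, "duplicate_compound", paste0("compound '", d, "' declared more than once"))
  syn <- unlist(cmp$synonyms)
  dups <- unique(syn[duplicated(syn)])
  for (d in dups) add(d, "synonym_not_disjoint", paste0("synonym '", d, "' appears under more than one compound"))
  clash <- intersect(syn, cmp$canonical_name)
  for (d in clash) add(d, "synonym_shadows_canonical", paste0("synonym '", d, "' is also a canonical compound name"))

  known <- cmp$canonical_name
  duprx <- unique(rxn$reaction_id[duplicated(rxn$reaction_id)])
  for (d in duprx) add(d, "duplicate_reaction_id", paste0("reaction id '", d, "' declared more than once"))
  for (i in seq_len(nrow(rxn))) {
    r <- rxn[i, ]
    if (!r$enzyme_code %in% cls$code) {
      add(r$reaction_id, "unknown_enzyme_code", paste0("enzyme code '", r$enzyme_code, "' not declared"))
    }
    for (field in c("substrate", "product", "root_pollutant")) {
      if (!r[[field]] %in% known) {
        add(r$reaction_id, "unknown_compound", paste0(field, " '", r[[field]], "' not in compound list"))
      }
    }
    if (!r$step_kind %in% c("single", "multi")) {
      add(r$reaction_id, "bad_step_kind", paste0("step_kind '", r$step_kind, "' must be 'single' or 'multi'"))
    }
  }
  specific_codes <- cls$code[cls$specific]
  no_rxn <- setdiff(specific_codes, rxn$enzyme_code)
  for (d in no_rxn) add(d, "specific_class_without_reaction", paste0("specific enzyme class '", d, "' has no reaction"))

  dupf <- unique(fam$family_id[duplicated(fam$family_id)])
  for (d in dupf) add(d, "duplicate_family_id", paste0("family '", d, "' mapped more than once"))
  for (i in seq_len(nrow(fam))) {
    val <- fam$enzyme_code[i]
    ok <- val %in% cls$code ||
      (startsWith(val, "nonspecific:") && sub("^nonspecific:", "", val) %in% SUPERFAMILIES)
    if (!ok) add(fam$family_id[i], "unresolved_family_target", paste0("family target '", val, "' resolves to no enzyme class or superfamily"))
  }

  if (length(v) == 0L) {
    tibble(entity = character(), rule = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' The packaged default reaction catalog
#'
#' Nineteen enzyme-class codes covering ring-attacking and ring-cleaving
#' steps in the degradation of biphenyl, gentisate, indole-3-acetate,
#' quinoline, phenanthrene, 2-chlorobenzoate and further pollutants, with a
#' family map that includes nonspecific Rieske-oxygenase and extradiol-
#' dioxygenase clusters.
#'
#' @return A validated [reaction_catalog].
#' @export
default_catalog <- function() {
  if (is.null(.aromnet_env$default_catalog)) {
    path <- system.file("extdata", "catalog", package = "aromnet", mustWork = TRUE)
    .aromnet_env$default_catalog <- load_catalog(path, format = "tsv")
  }
  .aromnet_env$default_catalog
}

.aromnet_env <- new.env(parent = emptyenv())

#' Resolve a compound name against the catalog
#'
#' Maps a canonical name or any registered synonym (case-insensitively) to
#' the canonical compound name.
#'
#' @param catalog A [reaction_catalog].
#' @param name Compound name or synonym.
#' @return Canonical name, or `NA_character_` when unknown.
#' @export
resolve_compound <- function(catalog, name) {
  vapply(name, function(nm) {
    nm_l <- tolower(nm)
    hit <- catalog$compounds$canonical_name == nm_l
    if (any(hit)) return(catalog$compounds$canonical_name[which(hit)[1]])
    syn_hit <- vapply(catalog$compounds$synonyms,
                      function(s) nm_l %in% tolower(s), logical(1))
    if (any(syn_hit)) return(catalog$compounds$canonical_name[which(syn_hit)[1]])
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.reaction_catalog <- function(x, ...) {
  cat("<reaction_catalog> ",
      nrow(x$enzyme_classes), " enzyme classes, ",
      nrow(x$reactions), " reactions, ",
      nrow(x$compounds), " compounds, ",
      nrow(x$family_map), " reference families\n", sep = "")
  invisible(x)
}

# superfamily of a family-map target ("Cat" -> class superfamily,
# "nonspecific:exdo_cupin" -> "exdo_cupin")
family_superfamily <- function(catalog, target) {
  vapply(target, function(t) {
    if (startsWith(t, "nonspecific:")) {
      sub("^nonspecific:", "", t)
    } else {
      sf <- catalog$enzyme_classes$superfamily[catalog$enzyme_classes$code == t]
      if (length(sf) == 0L) NA_character_ else sf[1]
    }
  }, character(1), USE.NAMES = FALSE)
}
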