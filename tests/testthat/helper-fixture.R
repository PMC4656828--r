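# Build the packaged two-microcosm fixture once per test run.
.fixture_cache <- new.env(parent = emptyenv())

ancona_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$fx <- build_ancona_fixture(
      dir = file.path(tempdir(), "aromnet_ancona_fixture")
    )
  }
  .fixture_cache$fx
}

ancona_result <- function() {
  if (is.null(.fixture_cache$res)) {
    .fixture_cache$res <- run_pipeline_on_bundle(ancona_fixture()$dir)
  }
  .fixture_cache$res
}

# Hand-rolled assignment tables for unit tests.
mk_asg <- function(codes, ambiguous_classes = character(0), sample_id = "S") {
  n <- length(codes) + length(ambiguous_classes)
  tibble::tibble(
    orf_id = sprintf("%s_o%03d", sample_id, seq_len(n)),
    sample_id = sample_id,
    enzyme_code = c(codes, rep(NA_character_, length(ambiguous_classes))),
    ambiguous = c(rep(FALSE, length(codes)), rep(TRUE, length(ambiguous_classes))),
    ambiguity_class = c(rep("none", length(codes)), ambiguous_classes),
    source_family = "ad_cat_1",
    overridden = FALSE
  )
}

# Minimal hand-built catalog for unit tests: two specific classes, one
# nonspecific cluster family.
tiny_catalog <- function() {
  reaction_catalog(
    compounds = tibble::tibble(
      canonical_name = c("phenol", "catechol", "muconate", "toluene"),
      synonyms = list("hydroxybenzene", "1,2-dihydroxybenzene", character(0),
                      "methylbenzene"),
      note = ""
    ),
    enzyme_classes = tibble::tibble(
      code = c("PhH", "CatA"),
      full_name = c("phenol hydroxylase", "catechol 1,2-dioxygenase"),
      superfamily = c("monooxygenase", "intradiol_dioxygenase"),
      specific = TRUE
    ),
    reactions = tibble::tibble(
      reaction_id = c("r_phh", "r_cata"),
      enzyme_code = c("PhH", "CatA"),
      substrate = c("phenol", "catechol"),
      product = c("catechol", "muconate"),
      step_kind = c("single", "multi"),
      root_pollutant = c("toluene", "toluene")
    ),
    family_map = tibble::tibble(
      family_id = c("f_phh", "f_cata", "f_rieske_nc"),
      enzyme_code = c("PhH", "CatA", "nonspecific:rieske_oxygenase")
    )
  )
}
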