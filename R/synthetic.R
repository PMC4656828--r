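#' @importFrom stats runif setNames
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

guess_rank <- function(lineage) {
  ifelse(grepl("aceae$", lineage), "family", "phylum")
}

new_synthetic_truth <- function(seed, samples, genes, catalog_id) {
  structure(
    list(seed = as.integer(seed), samples = samples,
         genes = tibble::as_tibble(genes), catalog_id = catalog_id),
    class = "synthetic_truth"
  )
}

#' Generate a synthetic ground truth
#'
#' Plants, per sample, a known number of catabolic genes per enzyme code and
#' per ambiguity class, a lineage for every gene (drawn from a stated
#' composition), a decoy count and a total ORF count. The truth is the
#' reference record against which pipeline recovery is tested; the matching
#' input files come from [emit_dataset()].
#'
#' @param config List with `seed` (integer) and `samples`, a named list where
#'   each element has: `specific` (named integer vector, enzyme code ->
#'   gene count), `ambiguous` (named integer vector over
#'   `rieske_oxygenase` / `exdo_cupin` / `exdo_other`), `lineages` (named
#'   numeric composition to sample gene lineages from, or `NULL` for all
#'   `"unassigned"`), `decoys` (count of hits built to fail the screen) and
#'   `total_orfs`.
#' @param catalog Catalog the dataset will be screened against (defaults to
#'   the packaged one); planted codes must exist in it.
#' @return A `synthetic_truth`: the config echo plus a gene-level table
#'   (`orf_id`, `sample_id`, `kind`, `enzyme_code`, `superfamily`,
#'   `lineage`, `rank`), deterministic given the seed.
#' @export
generate_truth <- function(config, catalog = default_catalog()) {
  stopifnot(is.numeric(config$seed), length(config$samples) >= 1)
  genes <- list()
  for (sid in names(config$samples)) {
    sc <- config$samples[[sid]]
    specific <- sc$specific %||% integer(0)
    ambiguous <- sc$ambiguous %||% integer(0)
    if (any(c(specific, ambiguous, sc$decoys %||% 0L) < 0)) {
      rlang::abort(paste0("negative planted count in sample '", sid, "'"))
    }
    bad <- setdiff(names(specific), catalog$enzyme_classes$code)
    if (length(bad) > 0L) {
      rlang::abort(paste0("planted enzyme code(s) not in catalog: ",
                          paste(bad, collapse = ", ")))
    }
    bad_cls <- setdiff(names(ambiguous),
                       c("rieske_oxygenase", "exdo_cupin", "exdo_other"))
    if (length(bad_cls) > 0L) {
      rlang::abort(paste0("unknown ambiguity class(es): ",
                          paste(bad_cls, collapse = ", ")))
    }
    n_genes <- sum(specific) + sum(ambiguous)
    if (is.null(sc$total_orfs) || sc$total_orfs < n_genes) {
      rlang::abort(paste0("sample '", sid, "': total_orfs must be >= planted catabolic genes (",
                          n_genes, ")"))
    }
    code_vec <- c(rep(names(specific), times = specific),
                  rep(names(ambiguous), times = ambiguous))
    kind <- c(rep("specific", sum(specific)), rep("ambiguous", sum(ambiguous)))
    sf <- character(length(code_vec))
    if (sum(specific) > 0L) {
      sf[kind == "specific"] <- catalog$enzyme_classes$superfamily[
        match(code_vec[kind == "specific"], catalog$enzyme_classes$code)]
    }
    sf[kind == "ambiguous"] <- code_vec[kind == "ambiguous"]
    lineage <- if (is.null(sc$lineages) || n_genes == 0L) {
      rep("unassigned", n_genes)
    } else {
      comp <- sc$lineages / sum(sc$lineages)
      with_local_seed(config$seed + match(sid, names(config$samples)),
                      sample(names(comp), n_genes, replace = TRUE, prob = comp))
    }
    if (n_genes > 0L) {
      genes[[sid]] <- tibble::tibble(
        sample_id = sid, kind = kind,
        enzyme_code = ifelse(kind == "specific", code_vec, NA_character_),
        superfamily = sf, lineage = lineage,
        rank = ifelse(lineage == "unassigned", NA_character_, guess_rank(lineage))
      )
    }
  }
  genes <- if (length(genes) > 0L) dplyr::bind_rows(genes) else
    tibble::tibble(sample_id = character(), kind = character(),
                   enzyme_code = character(), superfamily = character(),
                   lineage = character(), rank = character())
  # stable ORF identifiers: a seeded permutation per sample so planted genes
  # and decoys interleave in the emitted tables
  genes$orf_id <- NA_character_
  for (sid in names(config$samples)) {
    rows <- which(genes$sample_id == sid)
    n_dec <- config$samples[[sid]]$decoys %||% 0L
    ids <- with_local_seed(config$seed + 1000L + match(sid, names(config$samples)),
                           sample(length(rows) + n_dec))
    genes$orf_id[rows] <- sprintf("%s_orf_%05d", sid, ids[seq_along(rows)])
    config$samples[[sid]]$decoy_ids <-
      sprintf("%s_orf_%05d", sid, ids[seq_len(n_dec) + length(rows)])
  }
  new_synthetic_truth(config$seed, config$samples,
                      genes[, c("orf_id", "sample_id", "kind", "enzyme_code",
                                "superfamily", "lineage", "rank")],
                      catalog$id)
}

#' Planted counts of a synthetic truth
#'
#' @param truth A `synthetic_truth`.
#' @return Tibble `sample_id`, `kind`, `label` (enzyme code for specific
#'   genes, ambiguity superfamily for ambiguous ones), `n`.
#' @export
planted_counts <- function(truth) {
  g <- truth$genes
  g$label <- ifelse(g$kind == "specific", g$enzyme_code, g$superfamily)
  out <- dplyr::count(g, .data$sample_id, .data$kind, .data$label, name = "n")
  out[order(out$sample_id, out$kind, out$label, method = "radix"), , drop = FALSE]
}

nonspecific_family <- function(catalog, superfamily) {
  fam <- catalog$family_map
  hit <- fam$family_id[fam$enzyme_code == paste0("nonspecific:", superfamily)]
  if (length(hit) == 0L) {
    rlang::abort(paste0("catalog has no nonspecific family for superfamily '",
                        superfamily, "'"))
  }
  sort(hit)[1]
}

format_hit_row <- function(orf, fam, ident, len, evalue, bits) {
  mism <- max(0L, as.integer(round(len * (100 - ident) / 100)))
  sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.1f",
          orf, fam, ident, len, mism, sample(0:3, 1L),
          1L, len, 1L, len, evalue, bits)
}

#' Write the input files for a synthetic truth
#'
#' Emits, per sample, a 12-column BLAST-tabular hit table and a taxonomy
#' table, plus a shared totals table. Every planted gene gets one hit that
#' passes the default screen (identity drawn above 50%, alignment length
#' above 50 aa, seeded uniform); roughly half additionally get sub-optimal
#' secondary hits so best-hit selection is exercised; every decoy gets one
#' hit built to fail the screen (identity at or below 50% or length at or
#' below 50 aa). Output is byte-deterministic given the truth.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param dir Output directory (created if needed).
#' @param catalog Catalog used to pick reference-family identifiers.
#' @return Named list of written paths, invisibly.
#' @export
emit_dataset <- function(truth, dir, catalog = default_catalog()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  fam <- catalog$family_map
  with_local_seed(truth$seed + 5000L, {
    for (sid in names(truth$samples)) {
      g <- truth$genes[truth$genes$sample_id == sid, , drop = FALSE]
      rows <- character(0)
      for (i in seq_len(nrow(g))) {
        gene <- g[i, ]
        family <- if (gene$kind == "specific") {
          cands <- sort(fam$family_id[fam$enzyme_code == gene$enzyme_code])
          cands[sample.int(length(cands), 1L)]
        } else {
          nonspecific_family(catalog, gene$superfamily)
        }
        ident <- round(runif(1, 50.1, 99.9), 1)
        len <- sample(51:400, 1L)
        bits <- round(runif(1, 150, 300), 1)
        evalue <- 10^(-runif(1, 20, 80))
        rows <- c(rows, format_hit_row(gene$orf_id, family, ident, len, evalue, bits))
        n_extra <- sample(0:2, 1L)
        for (k in seq_len(n_extra)) {
          fam2 <- fam$family_id[sample.int(nrow(fam), 1L)]
          pass <- runif(1) < 0.5
          ident2 <- if (pass) round(runif(1, 50.1, 99.9), 1) else round(runif(1, 20, 49.9), 1)
          len2 <- if (pass) sample(51:400, 1L) else sample(10:50, 1L)
          bits2 <- round(bits - runif(1, 5, 50), 1)
          rows <- c(rows, format_hit_row(gene$orf_id, fam2, ident2, len2,
                                         10^(-runif(1, 5, 19)), bits2))
        }
      }
      dec_ids <- truth$samples[[sid]]$decoy_ids %||% character(0)
      for (orf in dec_ids) {
        family <- fam$family_id[sample.int(nrow(fam), 1L)]
        if (runif(1) < 0.5) {
          ident <- round(runif(1, 20, 50), 1); len <- sample(51:400, 1L)
        } else {
          ident <- round(runif(1, 55, 95), 1); len <- sample(10:50, 1L)
        }
        rows <- c(rows, format_hit_row(orf, family, ident, len,
                                       10^(-runif(1, 3, 30)), round(runif(1, 40, 140), 1)))
      }
      ord <- order(vapply(strsplit(rows, "\t", fixed = TRUE), `[[`, "", 1),
                   method = "radix")
      hp <- file.path(dir, paste0("hits_", sid, ".tsv"))
      readr::write_lines(rows[ord], hp)
      paths[[paste0("hits_", sid)]] <- hp

      tx <- g[g$lineage != "unassigned", c("orf_id", "lineage", "rank")]
      tx <- tx[order(tx$orf_id, method = "radix"), , drop = FALSE]
      tp <- file.path(dir, paste0("taxonomy_", sid, ".tsv"))
      readr::write_tsv(tx, tp, progress = FALSE)
      paths[[paste0("taxonomy_", sid)]] <- tp
    }
  })
  totals <- tibble::tibble(
    sample_id = names(truth$samples),
    total_orf_count = vapply(truth$samples, function(s) as.integer(s$total_orfs),
                             integer(1))
  )
  tp <- file.path(dir, "totals.tsv")
  readr::write_tsv(totals, tp, progress = FALSE)
  paths$totals <- tp
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Packaged two-microcosm fixture ("Ancona fixture")
# ---------------------------------------------------------------------------

# Per-gene lineage plan for the fixture. The published record gives only
# aggregates (per-code totals, ambiguity-class totals, lineage presence
# patterns); the per-gene rows here are an explicit aggregate-preserving
# disaggregation, declared as such in the manifest.
ancona_gene_plan <- function() {
  plan <- function(sample_id, code, lineage, n) {
    tibble::tibble(sample_id = sample_id, kind = "specific",
                   enzyme_code = code, lineage = rep(lineage, times = n))
  }
  amb <- function(sample_id, superfamily, lineage, n) {
    tibble::tibble(sample_id = sample_id, kind = "ambiguous",
                   enzyme_code = NA_character_, superfamily = superfamily,
                   lineage = rep(lineage, times = n))
  }
  ua <- dplyr::bind_rows(
    plan("UA", "Cat", c("Alcanivoracaceae", "Alteromonadaceae", "Rhodobacteraceae",
                        "Actinobacteria", "Oceanospirillaceae", "Halomonadaceae"),
         c(4L, 4L, 3L, 3L, 2L, 1L)),
    plan("UA", "Gen", "Alteromonadaceae", 1L),
    plan("UA", "Bzt", "Rhodobacteraceae", 1L),
    plan("UA", "2CB", "Halomonadaceae", 1L),
    plan("UA", "Bph", "Pseudomonadaceae", 2L),
    plan("UA", "Bzn", "Pseudomonadaceae", 1L),
    plan("UA", "Ind", "Rhodobacteraceae", 1L),
    plan("UA", "Hna", "Alcanivoracaceae", 1L),
    plan("UA", "Dhb", c("Halomonadaceae", "Alteromonadaceae"), c(2L, 1L)),
    plan("UA", "Odm", c("Alcanivoracaceae", "Piscirickettsiaceae"), c(1L, 1L)),
    plan("UA", "Orc", "Firmicutes", 2L),
    plan("UA", "Dpp", "Alteromonadaceae", 1L),
    plan("UA", "Hpc", "Pseudomonadaceae", 1L),
    plan("UA", "Ibu", "Aeromonadaceae", 1L),
    amb("UA", "rieske_oxygenase",
        c("Alteromonadaceae", "Rhodobacteraceae", "Alcanivoracaceae"), c(2L, 1L, 1L)),
    amb("UA", "exdo_cupin", "Alteromonadaceae", 1L),
    amb("UA", "exdo_other",
        c("Alcanivoracaceae", "Firmicutes", "Rhodobacteraceae", "Halomonadaceae"),
        c(2L, 1L, 1L, 1L))
  )
  amm <- dplyr::bind_rows(
    plan("AMM", "Cat", c("Alcanivoracaceae", "Alteromonadaceae", "Rhodobacteraceae",
                         "Vibrionaceae", "Aeromonadaceae"),
         c(4L, 3L, 3L, 2L, 2L)),
    plan("AMM", "Gen", c("Aeromonadaceae", "Alcanivoracaceae", "Alteromonadaceae",
                         "Oceanospirillaceae", "Rhodobacteraceae", "Firmicutes"),
         c(2L, 2L, 2L, 2L, 1L, 1L)),
    plan("AMM", "Bzt", c("Rhodobacteraceae", "Alteromonadaceae"), c(1L, 1L)),
    plan("AMM", "2CB", c("Alcanivoracaceae", "Rhodobacteraceae"), c(1L, 1L)),
    plan("AMM", "Bph", "Rhodobacteraceae", 1L),
    plan("AMM", "Ind", "Alteromonadaceae", 1L),
    plan("AMM", "Abs", "Alcanivoracaceae", 1L),
    plan("AMM", "Cum", "Rhodobacteraceae", 1L),
    plan("AMM", "Pht", "Rhodobacteraceae", 1L),
    plan("AMM", "Hna", "Alcanivoracaceae", 1L),
    plan("AMM", "Dhb", c("Alteromonadaceae", "Oceanospirillaceae",
                         "Piscirickettsiaceae", "Firmicutes"), c(2L, 1L, 1L, 1L)),
    plan("AMM", "Odm", c("Halomonadaceae", "Vibrionaceae", "Alteromonadaceae",
                         "Xanthomonadaceae"), c(1L, 1L, 1L, 1L)),
    plan("AMM", "Thb", c("Alcanivoracaceae", "Rhodobacteraceae"), c(1L, 1L)),
    plan("AMM", "Pca", c("Rhodobacteraceae", "Actinobacteria"), c(2L, 1L)),
    amb("AMM", "rieske_oxygenase",
        c("Rhodobacteraceae", "Alteromonadaceae", "Alcanivoracaceae",
          "Vibrionaceae", "Firmicutes"), c(4L, 3L, 2L, 1L, 1L)),
    amb("AMM", "exdo_cupin", "Rhodobacteraceae", 1L),
    amb("AMM", "exdo_other",
        c("Alteromonadaceae", "Alcanivoracaceae", "Rhodobacteraceae",
          "Aeromonadaceae"), c(2L, 1L, 1L, 1L))
  )
  dplyr::bind_rows(ua, amm)
}

SIX_COMMON_ROOTS <- c("2-chlorobenzoate", "indole-3-acetate", "biphenyl",
                      "gentisate", "quinoline", "phenanthrene")
UA_ONLY_ROOTS <- c("orcinol", "ibuprofen", "phenylpropionate",
                   "homoprotocatechuate", "benzene")
AMM_ONLY_ROOTS <- c("4-aminobenzenesulfonate", "p-cumate", "dibenzofuran",
                    "phthalate")

#' Build the packaged two-microcosm fixture
#'
#' Constructs the uric-acid (UA) and ammonium (AMM) microcosm dataset bundle:
#' per-sample hit tables, taxonomy tables, a totals table, the catalog as
#' JSON, the 16S community profile and a manifest. The bundle is an
#' aggregate-preserving disaggregation: its per-gene rows are invented, but
#' every published aggregate it is built to satisfy (45/65 screened genes,
#' 35/48 unambiguous, 4/11 ambiguous Rieske, 6/6 ambiguous EXDO, Cat edge
#' weights 17/14, Gen 1/10, superfamily fold changes 2x and 4x, the
#' nine-substrate common set, the six common root pollutants, the UA- and
#' AMM-specific root sets, the lineage presence patterns, ORF totals
#' 27,893/32,180) is recomputed after the build and recorded in the manifest
#' with its status. One constraint set in the published record is internally
#' inconsistent (a single benzoate/2-chlorobenzoate gene in UA cannot yield
#' both common substrates); the fixture plants one gene per code instead and
#' the manifest marks that constraint as deviating.
#'
#' @param dir Output directory for the bundle.
#' @param seed Seed for the nuisance quantities (identities, lengths, scores,
#'   row interleaving). The planted aggregates do not depend on it.
#' @return List: `dir`, `paths`, `truth`, `catalog`, `manifest` (constraint
#'   checklist as a tibble).
#' @export
build_ancona_fixture <- function(dir = tempfile("ancona_fixture_"),
                                 seed = 20151124L) {
  catalog <- default_catalog()
  plan <- ancona_gene_plan()
  cls <- catalog$enzyme_classes
  plan$superfamily <- ifelse(
    plan$kind == "specific",
    cls$superfamily[match(plan$enzyme_code, cls$code)],
    plan$superfamily
  )
  plan$rank <- guess_rank(plan$lineage)
  totals <- c(UA = 27893L, AMM = 32180L)
  decoys <- c(UA = 25L, AMM = 30L)
  samples <- lapply(names(totals), function(sid) {
    list(total_orfs = totals[[sid]], decoys = decoys[[sid]])
  })
  names(samples) <- names(totals)
  genes <- plan
  genes$orf_id <- NA_character_
  for (sid in names(samples)) {
    rows <- which(genes$sample_id == sid)
    n_dec <- samples[[sid]]$decoys
    ids <- with_local_seed(seed + 1000L + match(sid, names(samples)),
                           sample(length(rows) + n_dec))
    genes$orf_id[rows] <- sprintf("%s_orf_%05d", sid, ids[seq_along(rows)])
    samples[[sid]]$decoy_ids <-
      sprintf("%s_orf_%05d", sid, ids[seq_len(n_dec) + length(rows)])
  }
  truth <- new_synthetic_truth(
    seed, samples,
    genes[, c("orf_id", "sample_id", "kind", "enzyme_code", "superfamily",
              "lineage", "rank")],
    catalog$id
  )
  paths <- emit_dataset(truth, dir, catalog)
  paths$catalog <- file.path(dir, "catalog.json")
  write_catalog(catalog, paths$catalog, format = "json")
  paths$profile16s <- file.path(dir, "profile16s.tsv")
  file.copy(system.file("extdata", "profile16s_ancona.tsv", package = "aromnet",
                        mustWork = TRUE),
            paths$profile16s, overwrite = TRUE)
  manifest <- ancona_manifest(dir, truth, catalog)
  jsonlite::write_json(
    list(seed = seed,
         note = paste("per-gene rows are an aggregate-preserving disaggregation;",
                      "only the listed aggregate constraints are source-derived"),
         constraints = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths$manifest <- file.path(dir, "manifest.json")
  failed <- manifest$name[manifest$status == "violated"]
  if (length(failed) > 0L) {
    rlang::abort(paste0("fixture build violates constraint(s): ",
                        paste(failed, collapse = ", ")))
  }
  list(dir = dir, paths = paths, truth = truth, catalog = catalog,
       manifest = manifest)
}

# Recompute every fixture constraint by running the pipeline on the emitted
# files; status is "satisfied", "deviates" (the documented benzoate/2CB
# inconsistency) or "violated".
ancona_manifest <- function(dir, truth, catalog) {
  profiles <- lapply(names(truth$samples), function(sid) {
    screen_sample(file.path(dir, paste0("hits_", sid, ".tsv")), catalog,
                  sample_id = sid,
                  total_orf_count = truth$samples[[sid]]$total_orfs)
  })
  names(profiles) <- names(truth$samples)
  nets <- lapply(profiles, function(p) build_network(p$assignments, catalog, p$sample_id))
  asg <- lapply(names(profiles), function(sid) {
    attach_taxonomy(profiles[[sid]]$assignments,
                    read_taxonomy_table(file.path(dir, paste0("taxonomy_", sid, ".tsv"))))
  })
  names(asg) <- names(profiles)
  cm <- contribution_matrix(dplyr::bind_rows(asg))
  sfc <- lapply(profiles, function(p) superfamily_counts(p$assignments, catalog))
  sf_n <- function(sid, sf) {
    t <- sfc[[sid]]
    n <- t$n[t$superfamily == sf]
    if (length(n) == 0L) 0L else n
  }
  amb_n <- function(sid, cls) {
    a <- profiles[[sid]]$assignments
    sum(a$ambiguous & a$ambiguity_class == cls)
  }
  venn_s <- substrate_venn(nets$UA, nets$AMM, level = "substrate")
  venn_r <- substrate_venn(nets$UA, nets$AMM, level = "root_pollutant")

  rec <- list()
  chk <- function(name, expected, actual, status = NULL) {
    same <- isTRUE(all.equal(expected, actual))
    rec[[length(rec) + 1L]] <<- tibble::tibble(
      name = name,
      expected = paste(expected, collapse = "; "),
      actual = paste(actual, collapse = "; "),
      status = status %||% if (same) "satisfied" else "violated"
    )
  }
  chk("ua_screened_total", 45L, nrow(profiles$UA$assignments))
  chk("amm_screened_total", 65L, nrow(profiles$AMM$assignments))
  chk("ua_relative_abundance_pct", 0.16, relative_abundance(profiles$UA))
  chk("amm_relative_abundance_pct", 0.20, relative_abundance(profiles$AMM))
  chk("ua_unambiguous", 35L, sum(!profiles$UA$assignments$ambiguous))
  chk("amm_unambiguous", 48L, sum(!profiles$AMM$assignments$ambiguous))
  chk("ua_ambiguous_rieske", 4L, amb_n("UA", "rieske"))
  chk("amm_ambiguous_rieske", 11L, amb_n("AMM", "rieske"))
  chk("ua_ambiguous_exdo", 6L, amb_n("UA", "exdo"))
  chk("amm_ambiguous_exdo", 6L, amb_n("AMM", "exdo"))
  chk("ua_cat_edge_weight", 17L, edge_weight(nets$UA, "Cat"))
  chk("amm_cat_edge_weight", 14L, edge_weight(nets$AMM, "Cat"))
  chk("ua_gen_edge_weight", 1L, edge_weight(nets$UA, "Gen"))
  chk("amm_gen_edge_weight", 10L, edge_weight(nets$AMM, "Gen"))
  ua_b2 <- edge_weight(nets$UA, "Bzt") + edge_weight(nets$UA, "2CB")
  chk("ua_bzt_2cb_total", 1L, ua_b2,
      status = if (ua_b2 == 2L) "deviates" else "violated")
  chk("amm_bzt_2cb_total", 4L,
      edge_weight(nets$AMM, "Bzt") + edge_weight(nets$AMM, "2CB"))
  chk("rieske_fold_amm_vs_ua", 2,
      sf_n("AMM", "rieske_oxygenase") / sf_n("UA", "rieske_oxygenase"))
  chk("exdo_cupin_fold_amm_vs_ua", 4,
      sf_n("AMM", "exdo_cupin") / sf_n("UA", "exdo_cupin"))
  chk("substrate_venn_common_size", 9L, length(venn_s$common))
  chk("root_pollutant_common_set", sort(SIX_COMMON_ROOTS), venn_r$common)
  chk("ua_only_roots", sort(UA_ONLY_ROOTS), venn_r$a_only)
  chk("amm_only_roots", sort(AMM_ONLY_ROOTS), venn_r$b_only)
  chk("gen_amm_lineages",
      sort(c("Aeromonadaceae", "Alcanivoracaceae", "Alteromonadaceae",
             "Oceanospirillaceae", "Rhodobacteraceae", "Firmicutes")),
      lineages_for_code(cm, "Gen", "AMM"))
  chk("gen_ua_lineages", "Alteromonadaceae", lineages_for_code(cm, "Gen", "UA"))
  chk("cat_lineage_union_size", 8L, length(lineages_for_code(cm, "Cat")))
  chk("pseudomonadaceae_absent_in_amm", 0L,
      sum(cm$cells$sample_id == "AMM" & cm$cells$lineage == "Pseudomonadaceae"))
  chk("ua_total_orfs", 27893L, profiles$UA$total_orf_count)
  chk("amm_total_orfs", 32180L, profiles$AMM$total_orf_count)
  dplyr::bind_rows(rec)
}
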