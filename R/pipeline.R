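#' Assemble a pipeline configuration
#'
#' Collects and validates the inputs for one end-to-end run: the catalog,
#' per-sample hit tables and taxonomy tables, the 16S profile and the
#' screening thresholds. All referenced files must exist; validation happens
#' here, before any output is written.
#'
#' @param catalog Path to a catalog (`json` file or `tsv` directory).
#' @param hits Named character vector, sample id -> hit-table path.
#' @param taxonomy Named character vector, sample id -> taxonomy-table path
#'   (same names as `hits`).
#' @param totals Named numeric vector, sample id -> total ORF count, or a
#'   path to a `totals.tsv` (columns `sample_id`, `total_orf_count`).
#' @param profile16s Path to the 16S profile TSV, or `NULL` to skip the
#'   lineage-share stage.
#' @param min_identity,min_aln_len,strict Screening thresholds, see
#'   [filter_hits()].
#' @param out_dir Output directory, or `NULL` to return results only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(catalog, hits, taxonomy = NULL, totals,
                            profile16s = NULL, min_identity = 50,
                            min_aln_len = 50, strict = TRUE, out_dir = NULL) {
  paths <- c(catalog = catalog, hits, taxonomy,
             if (is.character(totals)) c(totals = totals),
             if (!is.null(profile16s)) c(profile16s = profile16s))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    rlang::abort(paste0("missing input file(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (is.null(names(hits)) || any(!nzchar(names(hits)))) {
    rlang::abort("hit tables must be a named vector: sample id -> path")
  }
  if (!is.null(taxonomy) && !setequal(names(taxonomy), names(hits))) {
    rlang::abort("taxonomy tables must cover the same sample ids as the hit tables")
  }
  if (is.character(totals)) {
    tt <- readr::read_tsv(totals, col_types = readr::cols(
      sample_id = "c", total_orf_count = "i"), progress = FALSE)
    totals <- setNames(tt$total_orf_count, tt$sample_id)
  }
  if (any(!names(hits) %in% names(totals))) {
    rlang::abort("every sample needs a total ORF count")
  }
  structure(
    list(catalog = catalog, hits = hits, taxonomy = taxonomy,
         totals = totals, profile16s = profile16s,
         min_identity = min_identity, min_aln_len = min_aln_len,
         strict = strict, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full reconstruction pipeline
#'
#' Screening, per-sample network reconstruction, two-sample comparison
#' (substrate and root-pollutant Venn partitions, per-enzyme counts,
#' superfamily counts) and taxonomic attribution, in one deterministic pass.
#' When the config names an output directory, every stage's table is written
#' there along with a JSON summary of all headline counts.
#'
#' @param config A [pipeline_config()].
#' @return List: `profiles`, `assignments` (with lineages when taxonomy was
#'   given), `networks`, `venn` (both levels, for two-sample runs),
#'   `enzyme_comparison`, `superfamily_counts`, `contribution` (a
#'   [contribution_matrix()]), `lineage_shares`, `summary` (plain list, the
#'   JSON payload).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  catalog <- if (dir.exists(config$catalog)) {
    load_catalog(config$catalog, "tsv")
  } else {
    load_catalog(config$catalog, "json")
  }
  samples <- names(config$hits)
  profiles <- lapply(samples, function(sid) {
    screen_sample(config$hits[[sid]], catalog, sample_id = sid,
                  total_orf_count = config$totals[[sid]],
                  min_identity = config$min_identity,
                  min_aln_len = config$min_aln_len, strict = config$strict)
  })
  names(profiles) <- samples

  assignments <- dplyr::bind_rows(lapply(profiles, function(p) p$assignments))
  if (!is.null(config$taxonomy)) {
    assignments <- dplyr::bind_rows(lapply(samples, function(sid) {
      attach_taxonomy(profiles[[sid]]$assignments,
                      read_taxonomy_table(config$taxonomy[[sid]]))
    }))
  }
  networks <- lapply(profiles, function(p) {
    build_network(p$assignments, catalog, p$sample_id)
  })
  sfc <- lapply(profiles, function(p) superfamily_counts(p$assignments, catalog))

  venn <- NULL
  comparison <- NULL
  if (length(samples) == 2L) {
    venn <- list(
      substrate = substrate_venn(networks[[1]], networks[[2]], "substrate"),
      root_pollutant = substrate_venn(networks[[1]], networks[[2]], "root_pollutant")
    )
    comparison <- compare_enzyme_counts(profiles[[1]], profiles[[2]])
  }

  contribution <- NULL
  shares <- NULL
  if (!is.null(config$taxonomy)) {
    contribution <- contribution_matrix(assignments)
    if (!is.null(config$profile16s)) {
      profile <- read_16s_profile(config$profile16s)
      shares <- lapply(samples, function(sid) {
        lineage_share_comparison(assignments, profile, sid)
      })
      names(shares) <- samples
    }
  }

  summary <- list(
    thresholds = list(min_identity = config$min_identity,
                      min_aln_len = config$min_aln_len,
                      strict = config$strict),
    samples = lapply(profiles, function(p) {
      a <- p$assignments
      net <- networks[[p$sample_id]]
      list(
        total_orf_count = p$total_orf_count,
        screened_genes = nrow(a),
        relative_abundance_pct = relative_abundance(p),
        unambiguous = sum(!a$ambiguous),
        ambiguous_rieske = sum(a$ambiguous & a$ambiguity_class == "rieske"),
        ambiguous_exdo = sum(a$ambiguous & a$ambiguity_class == "exdo"),
        network_nodes = length(net$nodes),
        network_edges = nrow(net$edges),
        network_total_weight = sum(net$edges$weight),
        edge_weights = setNames(as.list(net$edges$weight), net$edges$enzyme_code)
      )
    }),
    venn = if (!is.null(venn)) lapply(venn, function(v) {
      list(common = v$common, a_only = v$a_only, b_only = v$b_only)
    })
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)
    readr::write_tsv(assignments, out("assignments.tsv"), progress = FALSE)
    for (sid in samples) {
      for (fmt in c("graphml", "dot", "sif")) {
        export_network(networks[[sid]],
                       out(paste0("network_", sid, ".", fmt)), fmt)
      }
    }
    if (!is.null(comparison)) {
      readr::write_tsv(comparison, out("enzyme_comparison.tsv"), progress = FALSE)
    }
    if (!is.null(contribution)) {
      readr::write_tsv(contribution$cells, out("contribution_matrix.tsv"),
                       progress = FALSE)
    }
    if (!is.null(shares)) {
      for (sid in samples) {
        readr::write_tsv(shares[[sid]],
                         out(paste0("lineage_shares_", sid, ".tsv")),
                         progress = FALSE)
      }
    }
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  list(profiles = profiles, assignments = assignments, networks = networks,
       venn = venn, enzyme_comparison = comparison, superfamily_counts = sfc,
       contribution = contribution, lineage_shares = shares, summary = summary)
}

#' Run the pipeline on a fixture bundle directory
#'
#' Convenience wrapper wiring a [build_ancona_fixture()] (or
#' [emit_dataset()]) bundle into [pipeline_config()] + [run_pipeline()].
#'
#' @param dir Bundle directory.
#' @param samples Sample ids (default both microcosms, UA first).
#' @param out_dir Optional output directory.
#' @inheritParams pipeline_config
#' @return See [run_pipeline()].
#' @export
run_pipeline_on_bundle <- function(dir, samples = c("UA", "AMM"),
                                   out_dir = NULL, min_identity = 50,
                                   min_aln_len = 50, strict = TRUE) {
  cfg <- pipeline_config(
    catalog = file.path(dir, "catalog.json"),
    hits = setNames(file.path(dir, paste0("hits_", samples, ".tsv")), samples),
    taxonomy = setNames(file.path(dir, paste0("taxonomy_", samples, ".tsv")),
                        samples),
    totals = file.path(dir, "totals.tsv"),
    profile16s = {
      p <- file.path(dir, "profile16s.tsv")
      if (file.exists(p)) p else NULL
    },
    min_identity = min_identity, min_aln_len = min_aln_len, strict = strict,
    out_dir = out_dir
  )
  run_pipeline(cfg)
}
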