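#' Build a degradation network from reaction assignments
#'
#' Nodes are compounds; each directed edge is one catalog reaction
#' (substrate -> product, labelled with its enzyme code) weighted by the
#' number of genes assigned to that reaction in the sample. Ambiguous
#' assignments are excluded here, not by the caller, so the sum of edge
#' weights always equals the sample's unambiguous gene count.
#'
#' @param assignments Assignment tibble (may contain ambiguous rows).
#' @param catalog A [reaction_catalog].
#' @param sample_id Optional label; defaults to the assignments' sample.
#' @return A `degradation_network`: list with `sample_id`, `nodes`
#'   (character), `edges` (tibble `substrate`, `product`, `enzyme_code`,
#'   `weight`, `step_kind`, `root_pollutant`), `catalog_id`.
#' @export
build_network <- function(assignments, catalog, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- if (nrow(assignments) > 0L) assignments$sample_id[1] else "sample"
  }
  used <- assignments[!assignments$ambiguous, , drop = FALSE]
  empty_edges <- tibble::tibble(
    substrate = character(), product = character(), enzyme_code = character(),
    weight = integer(), step_kind = character(), root_pollutant = character()
  )
  if (nrow(used) == 0L) {
    return(structure(
      list(sample_id = sample_id, nodes = character(), edges = empty_edges,
           catalog_id = catalog$id),
      class = "degradation_network"
    ))
  }
  rxn <- catalog$reactions
  missing <- setdiff(unique(used$enzyme_code), rxn$enzyme_code)
  if (length(missing) > 0L) {
    rlang::abort(paste0("no catalog reaction for enzyme code(s): ",
                        paste(missing, collapse = ", ")))
  }
  multi <- names(which(table(rxn$enzyme_code) > 1L))
  multi <- intersect(multi, unique(used$enzyme_code))
  if (length(multi) > 0L) {
    rlang::abort(paste0("enzyme code(s) map to more than one catalog reaction, ",
                        "cannot place genes on a unique edge: ",
                        paste(multi, collapse = ", ")))
  }
  counts <- dplyr::count(used, .data$enzyme_code, name = "weight")
  edges <- dplyr::inner_join(rxn, counts, by = "enzyme_code")
  edges <- tibble::tibble(
    substrate = edges$substrate, product = edges$product,
    enzyme_code = edges$enzyme_code, weight = as.integer(edges$weight),
    step_kind = edges$step_kind, root_pollutant = edges$root_pollutant
  )
  edges <- edges[order(edges$substrate, edges$product, edges$enzyme_code,
                       method = "radix"), , drop = FALSE]
  nodes <- sort(unique(c(edges$substrate, edges$product)))
  structure(
    list(sample_id = sample_id, nodes = nodes, edges = edges,
         catalog_id = catalog$id),
    class = "degradation_network"
  )
}

#' @export
print.degradation_network <- function(x, ...) {
  cat("<degradation_network> ", x$sample_id, ": ", length(x$nodes),
      " compounds, ", nrow(x$edges), " reactions, total weight ",
      sum(x$edges$weight), "\n", sep = "")
  invisible(x)
}

#' Summary statistics of a degradation network
#'
#' @param net A `degradation_network`.
#' @return List: `sample_id`, `node_count`, `edge_count`, `substrate_set`,
#'   `root_pollutant_set`, `total_weight`.
#' @export
network_summary <- function(net) {
  list(
    sample_id = net$sample_id,
    node_count = length(net$nodes),
    edge_count = nrow(net$edges),
    substrate_set = sort(unique(net$edges$substrate)),
    root_pollutant_set = sort(unique(net$edges$root_pollutant)),
    total_weight = sum(net$edges$weight)
  )
}

#' Edge weight of one enzyme code
#'
#' @param net A `degradation_network`.
#' @param enzyme_code Catalog code (e.g. `"Cat"`).
#' @return Integer gene count; 0 when the reaction is absent.
#' @export
edge_weight <- function(net, enzyme_code) {
  w <- net$edges$weight[net$edges$enzyme_code == enzyme_code]
  if (length(w) == 0L) 0L else sum(w)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$substrate, to = net$edges$product,
                   weight = net$edges$weight, enzyme_code = net$edges$enzyme_code,
                   step_kind = net$edges$step_kind,
                   root_pollutant = net$edges$root_pollutant,
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
  g
}

#' Export a degradation network
#'
#' Writers for three interchange formats. GraphML (via igraph) and SIF carry
#' `weight` and `step_kind` as attributes; the Graphviz DOT writer encodes
#' gene counts as line thickness (`penwidth = 1 + weight - min(weight)`,
#' linear) and draws multi-step reactions dashed, single-step reactions
#' solid. Nodes and edges are written in sorted order, so repeated exports
#' are byte-identical.
#'
#' @param net A `degradation_network`.
#' @param path Output file.
#' @param format `"graphml"`, `"dot"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "dot", "sif")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) rlang::abort(
                       paste0("unknown network export format: ",
                              paste(format, collapse = "/"))))
  e <- net$edges
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "dot") {
    minw <- if (nrow(e) > 0L) min(e$weight) else 1L
    lines <- c(
      paste0("digraph \"", net$sample_id, "\" {"),
      paste0("  \"", net$nodes, "\";"),
      sprintf("  \"%s\" -> \"%s\" [label=\"%s\", weight=%d, penwidth=%d, style=%s];",
              e$substrate, e$product, e$enzyme_code, e$weight,
              1L + e$weight - minw,
              ifelse(e$step_kind == "multi", "dashed", "solid")),
      "}"
    )
    readr::write_lines(lines, path)
  } else {
    lines <- sprintf("%s\t%s\t%s\t%d\t%s",
                     e$substrate, e$enzyme_code, e$product, e$weight, e$step_kind)
    readr::write_lines(lines, path)
  }
  invisible(path)
}

#' Import a GraphML export back into a degradation network
#'
#' Round-trip companion of [export_network()]; edge weights, enzyme codes,
#' step kinds and root pollutants are restored.
#'
#' @param path GraphML file written by [export_network()].
#' @param sample_id Label for the restored network.
#' @return A `degradation_network`.
#' @export
import_network_graphml <- function(path, sample_id = "imported") {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble::tibble(
    substrate = el$from, product = el$to, enzyme_code = el$enzyme_code,
    weight = as.integer(el$weight), step_kind = el$step_kind,
    root_pollutant = el$root_pollutant
  )
  edges <- edges[order(edges$substrate, edges$product, edges$enzyme_code,
                       method = "radix"), , drop = FALSE]
  structure(
    list(sample_id = sample_id,
         nodes = sort(igraph::V(g)$name), edges = edges, catalog_id = NA_character_),
    class = "degradation_network"
  )
}
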