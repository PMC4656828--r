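#!/usr/bin/env Rscript
# Network stage: turn each sample's unambiguous assignments into a
# count-weighted substrate->product graph and export it in GraphML, DOT and
# SIF under results/networks/.

library(aromnet)
library(readr)

catalog <- default_catalog()
dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)

for (sid in c("UA", "AMM")) {
  a <- read_tsv(file.path("results/screening", paste0("assignments_", sid, ".tsv")),
                show_col_types = FALSE)
  net <- build_network(a, catalog, sid)
  s <- network_summary(net)
  message(sid, ": ", s$edge_count, " reactions over ", s$node_count,
          " compounds, total gene weight ", s$total_weight,
          "; heaviest edge ",
          net$edges$enzyme_code[which.max(net$edges$weight)],
          " (", max(net$edges$weight), " genes)")
  for (fmt in c("graphml", "dot", "sif")) {
    export_network(net, file.path("results/networks",
                                  paste0("network_", sid, ".", fmt)), fmt)
  }
}
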