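#!/usr/bin/env Rscript
# Taxonomy stage: attribute catabolic genes to bacterial lineages, build the
# lineage x enzyme presence matrix and compare catabolic-gene shares against
# 16S rRNA community shares. Writes results/taxonomy/.

library(aromnet)
library(readr)
library(dplyr)

dir.create("results/taxonomy", showWarnings = FALSE, recursive = TRUE)

asg <- bind_rows(lapply(c("UA", "AMM"), function(sid) {
  attach_taxonomy(
    read_tsv(file.path("results/screening", paste0("assignments_", sid, ".tsv")),
             show_col_types = FALSE),
    read_taxonomy_table(file.path("results/fixture",
                                  paste0("taxonomy_", sid, ".tsv")))
  )
}))

cm <- contribution_matrix(asg)
write_tsv(cm$cells, "results/taxonomy/contribution_matrix.tsv")
message("catechol dioxygenase (Cat) lineage union: ",
        paste(lineages_for_code(cm, "Cat"), collapse = ", "))
message("gentisate dioxygenase (Gen) in AMM: ",
        paste(lineages_for_code(cm, "Gen", "AMM"), collapse = ", "))
message("gentisate dioxygenase (Gen) in UA: ",
        paste(lineages_for_code(cm, "Gen", "UA"), collapse = ", "))

profile <- read_16s_profile("results/fixture/profile16s.tsv")
for (sid in c("UA", "AMM")) {
  shares <- lineage_share_comparison(asg, profile, sid)
  write_tsv(shares, file.path("results/taxonomy",
                              paste0("lineage_shares_", sid, ".tsv")))
  top <- shares[order(-shares$catabolic_share), ][1:3, ]
  message(sid, " top catabolic lineages: ",
          paste0(top$lineage, " (", sprintf("%.1f", top$catabolic_share),
                 "% genes vs ", sprintf("%.1f", top$share_16s), "% 16S)",
                 collapse = ", "))
}
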