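#!/usr/bin/env Rscript
# Screening stage: parse the per-sample homology hit tables, apply the
# >50% identity / >50 aa filters, pick best hits and assign enzyme codes.
# Writes assignments and superfamily tallies under results/screening/.

library(aromnet)
library(readr)

catalog <- default_catalog()
dir.create("results/screening", showWarnings = FALSE, recursive = TRUE)

totals <- read_tsv("results/fixture/totals.tsv", show_col_types = FALSE)

for (i in seq_len(nrow(totals))) {
  sid <- totals$sample_id[i]
  prof <- screen_sample(file.path("results/fixture", paste0("hits_", sid, ".tsv")),
                        catalog, sid, totals$total_orf_count[i])
  a <- prof$assignments
  message(sid, ": ", nrow(a), " catabolic genes of ", prof$total_orf_count,
          " ORFs (", format(relative_abundance(prof), nsmall = 2), "%); ",
          sum(!a$ambiguous), " unambiguous, ",
          sum(a$ambiguity_class == "rieske"), " ambiguous Rieske, ",
          sum(a$ambiguity_class == "exdo"), " ambiguous EXDO")
  write_tsv(a, file.path("results/screening", paste0("assignments_", sid, ".tsv")))
  write_tsv(superfamily_counts(a, catalog),
            file.path("results/screening", paste0("superfamilies_", sid, ".tsv")))
}
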