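# Brute-force oracle for the filter + best-hit rules: plain row-by-row loops,
# independent of the vectorised implementation under test.
oracle_filter_best <- function(hits, min_identity = 50, min_aln_len = 50) {
  kept <- list()
  for (i in seq_len(nrow(hits))) {
    r <- hits[i, ]
    if (r$percent_identity > min_identity && r$alignment_length > min_aln_len) {
      kept[[length(kept) + 1L]] <- r
    }
  }
  if (length(kept) == 0L) return(hits[0, ])
  kept <- do.call(rbind, kept)
  best <- list()
  for (orf in sort(unique(kept$orf_id))) {
    rows <- kept[kept$orf_id == orf, ]
    b <- rows[1, ]
    for (j in seq_len(nrow(rows))[-1]) {
      r <- rows[j, ]
      better <- r$bitscore > b$bitscore ||
        (r$bitscore == b$bitscore && r$evalue < b$evalue) ||
        (r$bitscore == b$bitscore && r$evalue == b$evalue &&
           r$family_id < b$family_id)
      if (better) b <- r
    }
    best[[orf]] <- b
  }
  do.call(rbind, best)
}

# Random hit tables with deliberate score ties and threshold-straddling values.
random_hit_table <- function(n, n_orfs = max(2L, n %/% 2L),
                             families = default_catalog()$family_map$family_id) {
  tibble::tibble(
    orf_id = sprintf("orf_%03d", sample.int(n_orfs, n, replace = TRUE)),
    family_id = sample(families, n, replace = TRUE),
    percent_identity = round(runif(n, 30, 100), 1),
    alignment_length = sample(20:200, n, replace = TRUE),
    mismatch = 0, gapopen = 0, qstart = 1, qend = 1, sstart = 1, send = 1,
    evalue = signif(10^(-sample(0:30, n, replace = TRUE)), 3),
    bitscore = round(runif(n, 5, 30)) * 10  # coarse grid to force ties
  )
}

write_hit_tsv <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.1f",
                   hits$orf_id, hits$family_id, hits$percent_identity,
                   hits$alignment_length, as.integer(hits$mismatch),
                   as.integer(hits$gapopen), as.integer(hits$qstart),
                   as.integer(hits$qend), as.integer(hits$sstart),
                   as.integer(hits$send), hits$evalue, hits$bitscore)
  readr::write_lines(lines, path)
  path
}
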