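make_hits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    orf_id = vapply(rows, `[[`, "", 1),
    family_id = vapply(rows, `[[`, "", 2),
    percent_identity = as.numeric(vapply(rows, `[[`, "", 3)),
    alignment_length = as.integer(vapply(rows, `[[`, "", 4)),
    mismatch = 0, gapopen = 0, qstart = 1, qend = 1, sstart = 1, send = 1,
    evalue = as.numeric(vapply(rows, `[[`, "", 5)),
    bitscore = as.numeric(vapply(rows, `[[`, "", 6))
  )
}

test_that("hit tables parse field-by-field and reject malformed rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("orf1\tfam_cat_1\t78.2\t120\t20\t1\t1\t120\t5\t124\t1e-40\t180",
               "orf2\tfam_gen_1\t55.0\t60\t27\t0\t1\t60\t1\t60\t1e-10\t90"),
             path)
  hits <- parse_hit_table(path)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$orf_id[1], "orf1")
  expect_equal(hits$percent_identity[1], 78.2)
  expect_equal(hits$alignment_length[1], 120L)
  expect_equal(hits$bitscore[2], 90)

  writeLines("orf1\tfam\t78.2\t120\t20\t1\t1\t120\t5\t124\t1e-40", path)
  expect_error(parse_hit_table(path), "line 1")

  writeLines("orf1\tfam\tabc\t120\t20\t1\t1\t120\t5\t124\t1e-40\t180", path)
  expect_error(parse_hit_table(path), "non-numeric")

  writeLines(character(0), path)
  expect_equal(nrow(parse_hit_table(path)), 0L)
})

test_that("both screening thresholds are strict at the boundary", {
  hits <- make_hits(
    list("a", "f", "50.0", "120", "1e-30", "100"),  # identity at threshold
    list("b", "f", "75.0", "50", "1e-30", "100"),   # length at threshold
    list("c", "f", "75.0", "51", "1e-30", "100"),   # both just above
    list("d", "f", "50.1", "120", "1e-30", "100")
  )
  kept <- filter_hits(hits)
  expect_setequal(kept$orf_id, c("c", "d"))
  # inclusive variant admits the boundary hits
  expect_setequal(filter_hits(hits, strict = FALSE)$orf_id, c("a", "b", "c", "d"))
})

test_that("raising either threshold never increases the surviving hit count", {
  set.seed(401)
  for (rep in 1:5) {
    hits <- random_hit_table(80)
    for (id_thr in c(30, 40, 50, 60, 70)) {
      n_prev <- Inf
      for (len_thr in c(20, 50, 80, 120)) {
        n <- nrow(filter_hits(hits, id_thr, len_thr))
        expect_lte(n, n_prev)
        n_prev <- n
      }
    }
    counts <- vapply(c(30, 50, 70, 90),
                     function(t) nrow(filter_hits(hits, min_identity = t)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("best-hit selection maximises bitscore with e-value then family tie-breaks", {
  hits <- make_hits(
    list("orf1", "fA", "80", "100", "1e-30", "180"),
    list("orf1", "fB", "80", "100", "1e-50", "90"),
    list("orf2", "fC", "80", "100", "1e-40", "150"),
    list("orf2", "fD", "80", "100", "1e-20", "150"),
    list("orf3", "fZ", "80", "100", "1e-40", "150"),
    list("orf3", "fA", "80", "100", "1e-40", "150"),
    list("orf4", "fE", "80", "100", "1e-10", "60")
  )
  best <- select_best_hit(hits)
  expect_equal(nrow(best), 4L)
  expect_equal(best$family_id[best$orf_id == "orf1"], "fA")  # higher bitscore
  expect_equal(best$family_id[best$orf_id == "orf2"], "fC")  # lower e-value
  expect_equal(best$family_id[best$orf_id == "orf3"], "fA")  # lexicographic
  expect_equal(best$family_id[best$orf_id == "orf4"], "fE")  # single hit
})

test_that("filter + best-hit agrees with the brute-force oracle on random tables", {
  set.seed(402)
  for (rep in 1:25) {
    hits <- random_hit_table(sample(1:100, 1))
    mine <- select_best_hit(filter_hits(hits))
    oracle <- oracle_filter_best(hits)
    mine <- mine[order(mine$orf_id), ]
    expect_equal(mine$orf_id, oracle$orf_id)
    expect_equal(mine$family_id, oracle$family_id)
    expect_equal(mine$bitscore, oracle$bitscore)
  }
})

test_that("assignments follow the family map, ambiguity classes and overrides", {
  cat <- default_catalog()
  best <- make_hits(
    list("orf1", "ad_cat_1", "80", "100", "1e-30", "200"),
    list("orf2", "ad_rieske_unclassified", "70", "90", "1e-20", "150"),
    list("orf3", "ad_exdo_cupin_unclassified", "70", "90", "1e-20", "150"),
    list("orf4", "ad_gen_2", "85", "120", "1e-35", "220"),
    list("orf5", "ad_bph_1", "66", "140", "1e-25", "180")
  )
  asg <- assign_reactions(best, cat, "S1")
  expect_equal(asg$enzyme_code[asg$orf_id == "orf1"], "Cat")
  expect_false(asg$ambiguous[asg$orf_id == "orf1"])
  expect_equal(asg$ambiguity_class[asg$orf_id == "orf1"], "none")
  expect_true(asg$ambiguous[asg$orf_id == "orf2"])
  expect_equal(asg$ambiguity_class[asg$orf_id == "orf2"], "rieske")
  expect_true(is.na(asg$enzyme_code[asg$orf_id == "orf2"]))
  expect_equal(asg$ambiguity_class[asg$orf_id == "orf3"], "exdo")
  expect_equal(asg$enzyme_code[asg$orf_id == "orf4"], "Gen")
  # ambiguous <=> enzyme_code NA, ambiguity_class none <=> !ambiguous
  expect_equal(asg$ambiguous, is.na(asg$enzyme_code))
  expect_equal(asg$ambiguity_class == "none", !asg$ambiguous)

  over <- tibble::tibble(orf_id = c("orf2", "orf5"),
                         enzyme_code = c("Gen", "ambiguous"))
  asg2 <- assign_reactions(best, cat, "S1", overrides = over)
  expect_equal(asg2$enzyme_code[asg2$orf_id == "orf2"], "Gen")
  expect_false(asg2$ambiguous[asg2$orf_id == "orf2"])
  expect_true(asg2$ambiguous[asg2$orf_id == "orf5"])
  expect_equal(asg2$ambiguity_class[asg2$orf_id == "orf5"], "rieske")
  expect_true(all(asg2$overridden[asg2$orf_id %in% over$orf_id]))

  unknown <- make_hits(list("orfX", "no_such_family", "80", "100", "1e-30", "200"))
  expect_error(assign_reactions(unknown, cat, "S1"), "no_such_family")
})

test_that("relative abundance is a half-up two-decimal percentage", {
  mk <- function(n, total) {
    sample_profile("S", total,
                   tibble::tibble(orf_id = sprintf("o%d", seq_len(n)),
                                  sample_id = "S", enzyme_code = "Cat",
                                  ambiguous = FALSE, ambiguity_class = "none",
                                  source_family = "ad_cat_1", overridden = FALSE))
  }
  expect_equal(relative_abundance(mk(45, 27893)), 0.16)
  expect_equal(relative_abundance(mk(65, 32180)), 0.20)
  expect_equal(relative_abundance(mk(12, 6000)), 0.20)
  expect_equal(relative_abundance(mk(0, 5000)), 0.00)
  expect_error(sample_profile("S", 0, mk(5, 100)$assignments), "ORF count")
})

test_that("superfamily counts include ambiguous genes and sum to the total", {
  cat <- default_catalog()
  best <- make_hits(
    list("orf1", "ad_cat_1", "80", "100", "1e-30", "200"),
    list("orf2", "ad_bph_1", "80", "100", "1e-30", "200"),
    list("orf3", "ad_rieske_unclassified", "70", "90", "1e-20", "150"),
    list("orf4", "ad_gen_1", "85", "120", "1e-35", "220")
  )
  asg <- assign_reactions(best, cat, "S1")
  counts <- superfamily_counts(asg, cat)
  expect_equal(sum(counts$n), nrow(asg))
  expect_equal(counts$n[counts$superfamily == "rieske_oxygenase"], 2L)
  expect_equal(counts$n[counts$superfamily == "exdo_cupin"], 1L)
  expect_equal(nrow(superfamily_counts(asg[0, ], cat)), 0L)
})
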