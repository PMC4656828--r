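small_config <- function(seed = 11L) {
  list(seed = seed, samples = list(
    S1 = list(specific = c(Cat = 4L, Gen = 3L, Bph = 2L, Orc = 1L),
              ambiguous = c(rieske_oxygenase = 2L, exdo_other = 1L),
              lineages = c(Alteromonadaceae = 0.5, Rhodobacteraceae = 0.3,
                           Firmicutes = 0.2),
              decoys = 5L, total_orfs = 500L)
  ))
}

test_that("truth generation is deterministic and echoes planted counts", {
  t1 <- generate_truth(small_config())
  t2 <- generate_truth(small_config())
  expect_identical(t1$genes, t2$genes)
  pc <- planted_counts(t1)
  expect_equal(pc$n[pc$label == "Cat"], 4L)
  expect_equal(pc$n[pc$label == "rieske_oxygenase"], 2L)
  expect_equal(sum(pc$n), 13L)
  # lineage sampling respects the stated support
  expect_true(all(t1$genes$lineage %in%
                    c("Alteromonadaceae", "Rhodobacteraceae", "Firmicutes")))
  # changing the seed changes the nuisance draws but not the counts
  t3 <- generate_truth(small_config(seed = 99L))
  expect_equal(planted_counts(t3)$n, pc$n)
})

test_that("inconsistent or degenerate configs are handled", {
  bad <- small_config()
  bad$samples$S1$total_orfs <- 5L
  expect_error(generate_truth(bad), "total_orfs")

  neg <- small_config()
  neg$samples$S1$specific[["Cat"]] <- -1L
  expect_error(generate_truth(neg), "negative")

  unknown <- small_config()
  names(unknown$samples$S1$specific)[1] <- "Zzz"
  expect_error(generate_truth(unknown), "Zzz")

  zero <- list(seed = 1L, samples = list(
    S1 = list(specific = integer(0), ambiguous = integer(0),
              lineages = NULL, decoys = 0L, total_orfs = 100L)))
  t0 <- generate_truth(zero)
  expect_equal(nrow(t0$genes), 0L)
})

test_that("screening an emitted dataset recovers the planted truth exactly", {
  truth <- generate_truth(small_config())
  dir <- withr::local_tempdir()
  emit_dataset(truth, dir)
  prof <- screen_sample(file.path(dir, "hits_S1.tsv"), default_catalog(),
                        "S1", 500L)
  expect_equal(nrow(prof$assignments), 13L)  # decoys all rejected
  a <- prof$assignments
  expect_equal(sum(!a$ambiguous), 10L)
  expect_equal(sum(a$ambiguous & a$ambiguity_class == "rieske"), 2L)
  expect_equal(sum(a$ambiguous & a$ambiguity_class == "exdo"), 1L)
  got <- table(a$enzyme_code[!a$ambiguous])
  expect_equal(got[["Cat"]], 4L)
  expect_equal(got[["Gen"]], 3L)
  expect_equal(got[["Bph"]], 2L)
  expect_equal(got[["Orc"]], 1L)
})

test_that("a decoy-only truth yields zero assignments after screening", {
  cfg <- list(seed = 7L, samples = list(
    S1 = list(specific = integer(0), ambiguous = integer(0),
              lineages = NULL, decoys = 8L, total_orfs = 100L)))
  dir <- withr::local_tempdir()
  emit_dataset(generate_truth(cfg), dir)
  hits <- parse_hit_table(file.path(dir, "hits_S1.tsv"))
  expect_equal(nrow(hits), 8L)
  expect_equal(nrow(filter_hits(hits)), 0L)
})

test_that("dataset emission is byte-deterministic", {
  truth <- generate_truth(small_config())
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_dataset(truth, d1)
  emit_dataset(truth, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("two fixture builds produce identical bundles and a clean manifest", {
  fx <- ancona_fixture()
  d2 <- withr::local_tempdir()
  fx2 <- build_ancona_fixture(d2)
  for (f in setdiff(list.files(fx$dir), "manifest.json")) {
    expect_identical(readLines(file.path(fx$dir, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), label = f)
  }
  expect_identical(fx$manifest, fx2$manifest)
  # every constraint recomputes as satisfied except the documented
  # benzoate/2-chlorobenzoate deviation
  expect_equal(sum(fx$manifest$status == "violated"), 0L)
  expect_equal(fx$manifest$name[fx$manifest$status == "deviates"],
               "ua_bzt_2cb_total")
})
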