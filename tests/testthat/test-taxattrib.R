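test_that("taxonomy attaches by ORF id and missing ORFs stay as unassigned", {
  asg <- mk_asg(c("Cat", "Gen", "Orc"), sample_id = "S")
  tax <- tibble::tibble(orf_id = asg$orf_id[1:2],
                        lineage = c("Alteromonadaceae", "Firmicutes"),
                        rank = c("family", "phylum"))
  out <- attach_taxonomy(asg, tax)
  expect_equal(out$lineage, c("Alteromonadaceae", "Firmicutes", "unassigned"))
  expect_equal(out$rank, c("family", "phylum", NA))
  expect_equal(nrow(out), nrow(asg))

  empty <- attach_taxonomy(asg, tax[0, ])
  expect_true(all(empty$lineage == "unassigned"))

  dup <- rbind(tax, tax[1, ])
  expect_error(attach_taxonomy(asg, dup), "duplicate")
})

test_that("contribution matrix records presence of unambiguous genes only", {
  asg <- mk_asg(c("Cat", "Cat", "Gen"), ambiguous_classes = "rieske",
                sample_id = "S")
  tax <- tibble::tibble(
    orf_id = asg$orf_id,
    lineage = c("Alteromonadaceae", "Alteromonadaceae", "unlisted-lineage",
                "Rhodobacteraceae"),
    rank = "family"
  )
  tax$lineage[3] <- "Rhodobacteraceae"
  out <- attach_taxonomy(asg, tax)
  cm <- contribution_matrix(out)
  # ambiguous Rhodobacteraceae gene contributes no cell
  expect_equal(sort(unique(cm$cells$lineage)),
               c("Alteromonadaceae", "Rhodobacteraceae"))
  alt <- cm$cells[cm$cells$lineage == "Alteromonadaceae", ]
  expect_equal(alt$enzyme_code, "Cat")
  expect_equal(alt$n_genes, 2L)
  expect_true(all(cm$cells$present == (cm$cells$n_genes >= 1L)))

  # unassigned genes are excluded from the matrix but counted in the footer
  out$lineage[1] <- "unassigned"
  cm2 <- contribution_matrix(out)
  expect_equal(cm2$unassigned$n_genes, 1L)
  expect_equal(cm2$cells$n_genes[cm2$cells$lineage == "Alteromonadaceae"], 1L)

  expect_equal(nrow(contribution_matrix(out[0, ])$cells), 0L)
})

test_that("adding a gene can only switch presence cells from absent to present", {
  base <- mk_asg(c("Cat", "Gen"), sample_id = "S")
  tax <- tibble::tibble(orf_id = base$orf_id, lineage = "Alteromonadaceae",
                        rank = "family")
  cm_small <- contribution_matrix(attach_taxonomy(base, tax))
  extra <- mk_asg("Orc", sample_id = "S")
  extra$orf_id <- "S_new"
  grown <- rbind(attach_taxonomy(base, tax),
                 attach_taxonomy(extra, tibble::tibble(
                   orf_id = "S_new", lineage = "Firmicutes", rank = "phylum")))
  cm_big <- contribution_matrix(grown)
  key <- function(cm) paste(cm$cells$sample_id, cm$cells$lineage, cm$cells$enzyme_code)
  expect_true(all(key(cm_small) %in% key(cm_big)))
})

test_that("16S profiles with decimal commas are parsed to percentages", {
  profile <- read_16s_profile(
    system.file("extdata", "profile16s_ancona.tsv", package = "aromnet")
  )
  expect_equal(profile$AMM[profile$lineage == "Rhodobacteraceae"], 18.20)
  expect_equal(profile$UA[profile$lineage == "Rhodobacteraceae"], 0.81)
  expect_equal(profile$UA[profile$lineage == "Alteromonadaceae"], 19.18)
  expect_true(all(profile$AMM >= 0))
  # named lineages plus the Others bucket account for the whole community
  expect_lte(sum(profile$AMM[profile$lineage != "Others"]), 100)
  expect_equal(sum(profile$AMM), 100, tolerance = 0.01)
})

test_that("lineage shares compare catabolic genes against 16S abundances", {
  asg <- mk_asg(c("Cat", "Cat", "Gen", "Orc"), sample_id = "AMM")
  tax <- tibble::tibble(
    orf_id = asg$orf_id[1:3],
    lineage = c("Rhodobacteraceae", "Rhodobacteraceae", "Alteromonadaceae"),
    rank = "family"
  )
  out <- attach_taxonomy(asg, tax)
  profile <- read_16s_profile(
    system.file("extdata", "profile16s_ancona.tsv", package = "aromnet")
  )
  shares <- lineage_share_comparison(out, profile, "AMM")
  expect_equal(shares$catabolic_share[shares$lineage == "Rhodobacteraceae"], 50)
  expect_equal(shares$share_16s[shares$lineage == "Rhodobacteraceae"], 18.20)
  expect_equal(shares$catabolic_share[shares$lineage == "unassigned"], 25)
  expect_equal(sum(shares$catabolic_share), 100)
  expect_error(lineage_share_comparison(out, profile, "XX"), "XX")
})
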