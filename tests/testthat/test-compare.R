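mk_profile <- function(codes, sample_id, total = 1000L,
                       ambiguous_classes = character(0)) {
  asg <- mk_asg(codes, ambiguous_classes, sample_id)
  sample_profile(sample_id, total, asg)
}

test_that("the Venn partition is disjoint, exhaustive and catalog-guarded", {
  cat <- default_catalog()
  net_a <- build_network(mk_asg(c("Cat", "Gen", "Orc"), sample_id = "A"), cat)
  net_b <- build_network(mk_asg(c("Cat", "Pht"), sample_id = "B"), cat)
  v <- substrate_venn(net_a, net_b, "substrate")
  expect_equal(v$common, "catechol")
  expect_setequal(v$a_only, c("gentisate", "orcinol"))
  expect_equal(v$b_only, "phthalate")
  expect_length(intersect(v$common, c(v$a_only, v$b_only)), 0)
  expect_setequal(c(v$common, v$a_only, v$b_only),
                  union(network_summary(net_a)$substrate_set,
                        network_summary(net_b)$substrate_set))

  # identical networks -> nothing sample-specific
  v_same <- substrate_venn(net_a, net_a, "substrate")
  expect_length(v_same$a_only, 0)
  expect_length(v_same$b_only, 0)

  # root-pollutant level rolls substrates up to their pathway's pollutant
  v_root <- substrate_venn(net_a, net_b, "root_pollutant")
  expect_equal(v_root$common, "biphenyl")
  expect_setequal(v_root$a_only, c("gentisate", "orcinol"))
  expect_equal(v_root$b_only, "phthalate")

  other <- tiny_catalog()
  net_c <- build_network(mk_asg("PhH", sample_id = "C"), other)
  expect_error(substrate_venn(net_a, net_c), "different catalogs")
})

test_that("enzyme count comparison zero-fills absences and flags undefined folds", {
  pa <- mk_profile(c("Cat", "Cat", "Gen", "Orc"), "A")
  pb <- mk_profile(c("Cat", "Gen", "Gen", "Gen", "Pht"), "B")
  tab <- compare_enzyme_counts(pa, pb)
  expect_setequal(tab$enzyme_code, c("Cat", "Gen", "Orc", "Pht"))
  g <- tab[tab$enzyme_code == "Gen", ]
  expect_equal(g$count_A, 1L)
  expect_equal(g$count_B, 3L)
  expect_equal(g$fold_B_vs_A, 3)
  p <- tab[tab$enzyme_code == "Pht", ]
  expect_equal(p$count_A, 0L)
  expect_false(p$fold_defined)
  expect_true(is.na(p$fold_B_vs_A))
  o <- tab[tab$enzyme_code == "Orc", ]
  expect_equal(o$count_B, 0L)
  expect_equal(o$fold_B_vs_A, 0)
  # per-sample totals equal the network total weight
  cat <- default_catalog()
  expect_equal(sum(tab$count_A),
               sum(build_network(pa$assignments, cat)$edges$weight))
  expect_equal(sum(tab$count_B),
               sum(build_network(pb$assignments, cat)$edges$weight))
})

test_that("residual percentages follow the control-corrected arithmetic", {
  pt <- tibble::tibble(
    compound = c("phthalate", "naphthalene", "benzene"),
    initial = c(100, 100, 250),
    final = c(21, 100, 125),
    control_final = c(100, 100, 250)
  )
  res <- degradation_summary(pt)
  expect_equal(res$residual_percent, c(21, 100, 50))

  # scale invariance per compound
  pt2 <- pt
  pt2[1, c("initial", "final", "control_final")] <-
    pt2[1, c("initial", "final", "control_final")] * 7.3
  expect_equal(degradation_summary(pt2)$residual_percent, res$residual_percent)

  # abiotic loss in the control is credited back, never below zero
  pt3 <- tibble::tibble(compound = "x", initial = 100, final = 10,
                        control_final = 80)
  expect_equal(degradation_summary(pt3)$residual_percent, 30)
  pt4 <- tibble::tibble(compound = "x", initial = 100, final = 5,
                        control_final = 115)
  expect_equal(degradation_summary(pt4)$residual_percent, 0)

  bad <- tibble::tibble(compound = "y", initial = 0, final = 1, control_final = 1)
  expect_error(degradation_summary(bad), "y")
})

test_that("intermediate fold changes are plain area ratios", {
  expect_equal(intermediate_fold_change(22.2, 1.0), 22.2)
  expect_equal(intermediate_fold_change(1.0, 4.0), 0.25)
  expect_true(is.na(intermediate_fold_change(1.0, 0)))
})
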