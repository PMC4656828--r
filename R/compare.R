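#' Venn partition of substrates between two networks
#'
#' Splits the compounds degraded by two samples into common, A-only and
#' B-only sets, either at the level of direct reaction substrates
#' (intermediates included) or at the level of root pollutants (the initial
#' pollutant of each reaction's pathway).
#'
#' @param net_a,net_b `degradation_network`s built against the same catalog.
#' @param level `"substrate"` or `"root_pollutant"`.
#' @return A `venn_partition`: list with `label_a`, `label_b`, `common`,
#'   `a_only`, `b_only` (sorted character vectors) and `level`.
#' @export
substrate_venn <- function(net_a, net_b, level = c("substrate", "root_pollutant")) {
  level <- match.arg(level)
  if (!identical(net_a$catalog_id, net_b$catalog_id)) {
    rlang::abort("networks were built against different catalogs")
  }
  pick <- function(net) {
    s <- network_summary(net)
    if (level == "substrate") s$substrate_set else s$root_pollutant_set
  }
  a <- pick(net_a)
  b <- pick(net_b)
  structure(
    list(label_a = net_a$sample_id, label_b = net_b$sample_id, level = level,
         common = sort(intersect(a, b)),
         a_only = sort(setdiff(a, b)),
         b_only = sort(setdiff(b, a))),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> level=", x$level, ": ",
      length(x$common), " common, ",
      length(x$a_only), " ", x$label_a, "-only, ",
      length(x$b_only), " ", x$label_b, "-only\n", sep = "")
  invisible(x)
}

#' Per-enzyme gene-count comparison between two samples
#'
#' One row per enzyme code observed in either sample; a code absent from a
#' sample counts 0. The fold change is count_b / count_a (direction B over A,
#' with the sample labels in the column names) and is `NA` where count_a is
#' zero.
#'
#' @param profile_a,profile_b [sample_profile()]s.
#' @return Tibble: `enzyme_code`, `count_<A>`, `count_<B>`, `fold_<B>_vs_<A>`,
#'   `fold_defined`.
#' @export
compare_enzyme_counts <- function(profile_a, profile_b) {
  count_codes <- function(p) {
    a <- p$assignments
    a <- a[!a$ambiguous, , drop = FALSE]
    dplyr::count(a, .data$enzyme_code, name = "n")
  }
  ca <- count_codes(profile_a)
  cb <- count_codes(profile_b)
  all_codes <- sort(union(ca$enzyme_code, cb$enzyme_code))
  na <- ca$n[match(all_codes, ca$enzyme_code)]
  nb <- cb$n[match(all_codes, cb$enzyme_code)]
  na[is.na(na)] <- 0L
  nb[is.na(nb)] <- 0L
  out <- tibble::tibble(
    enzyme_code = all_codes,
    count_a = as.integer(na),
    count_b = as.integer(nb),
    fold = ifelse(na > 0L, nb / na, NA_real_),
    fold_defined = na > 0L
  )
  names(out) <- c("enzyme_code",
                  paste0("count_", profile_a$sample_id),
                  paste0("count_", profile_b$sample_id),
                  paste0("fold_", profile_b$sample_id, "_vs_", profile_a$sample_id),
                  "fold_defined")
  out
}

#' Residual-percentage summary of a degradation assay
#'
#' For each compound in a peak table (columns `compound`, `initial`, `final`,
#' `control_final`, all peak areas in the same arbitrary units), computes the
#' residual percentage after control correction:
#' `100 * max(final - drift, 0) / initial`, where the drift term is the
#' abiotic change seen in the control (`control_final - initial`). 100 means
#' no degradation, 0 total degradation.
#'
#' @param peak_table Tibble/data frame with the four columns above.
#' @return Tibble `compound`, `residual_percent`.
#' @export
degradation_summary <- function(peak_table) {
  pt <- tibble::as_tibble(peak_table)
  if (any(pt$initial <= 0)) {
    bad <- pt$compound[pt$initial <= 0]
    rlang::abort(paste0("non-positive initial peak area for: ",
                        paste(bad, collapse = ", ")))
  }
  drift <- pt$control_final - pt$initial
  tibble::tibble(
    compound = pt$compound,
    residual_percent = 100 * pmax(pt$final - drift, 0) / pt$initial
  )
}

#' Fold change of an intermediate's abundance between two samples
#'
#' Ratio of peak areas (sample A over sample B) for degradation
#' intermediates detected in both assays.
#'
#' @param area_a,area_b Peak areas (same arbitrary units).
#' @return `area_a / area_b`; `NA` where `area_b` is zero.
#' @export
intermediate_fold_change <- function(area_a, area_b) {
  ifelse(area_b > 0, area_a / area_b, NA_real_)
}
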