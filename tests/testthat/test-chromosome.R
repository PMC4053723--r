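mk_genic <- function(statuses, par1 = rep(FALSE, length(statuses))) {
  n <- length(statuses)
  list(
    genic = tibble::tibble(
      gene = sprintf("g%02d", seq_len(n)),
      status = factor(statuses, levels = genic_status_levels())),
    annotation = tibble::tibble(
      gene = sprintf("g%02d", seq_len(n)), chrom = "chrX",
      start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
      strand = "+", score = 0L, par1 = par1))
}

test_that("adjacency counts match hand enumeration", {
  f <- mk_genic(rep("subject", 3))
  out <- adjacency_counts(f$genic, f$annotation)
  expect_equal(out$observed[out$pair == "subject|subject"], 2L)
  expect_equal(sum(out$observed), 2L)

  f <- mk_genic(c("escape", "subject", "escape"))
  out <- adjacency_counts(f$genic, f$annotation)
  expect_equal(out$observed[out$pair == "escape|subject"], 2L)

  # 12-gene fixture, counts enumerated by hand
  sts <- c("subject", "subject", "escape", "escape", "variable_escape",
           "subject", "subject", "variable_escape", "variable_escape",
           "escape", "subject", "subject")
  f <- mk_genic(sts)
  out <- adjacency_counts(f$genic, f$annotation)
  got <- stats::setNames(out$observed, out$pair)
  # pairs: ss, se, ee, ev, vs, ss, sv, vv, ve, es, ss
  expect_equal(got[["subject|subject"]], 3L)
  expect_equal(got[["escape|escape"]], 1L)
  expect_equal(got[["variable_escape|variable_escape"]], 1L)
  expect_equal(got[["escape|subject"]], 2L)
  expect_equal(got[["escape|variable_escape"]], 2L)
  expect_equal(got[["subject|variable_escape"]], 2L)
  expect_equal(sum(out$observed), 11L)

  # PAR1 exclusion removes leading escape genes
  f <- mk_genic(c("escape", "escape", "subject", "subject"),
                par1 = c(TRUE, TRUE, FALSE, FALSE))
  out <- adjacency_counts(f$genic, f$annotation)
  expect_equal(sum(out$observed), 1L)
  expect_error(adjacency_counts(f$genic[3, ], f$annotation), "two")
})

test_that("chi-square components and residuals follow the printed formulas", {
  res <- adjacency_chi_square(c(pair_a = 39, pair_b = 258),
                              c(pair_a = 6, pair_b = 173))
  expect_equal(round(res$component, 1), c(181.5, 41.8))
  expect_equal(round(res$std_residual, 1), c(13.5, 6.5))
  expect_equal(attr(res, "statistic"), sum(res$component))
  # observed == expected -> zero statistic, p = 1
  null <- adjacency_chi_square(c(a = 10, b = 20), c(a = 10, b = 20))
  expect_equal(attr(null, "statistic"), 0)
  expect_equal(attr(null, "p_value"), 1)
  # zero expected counts excluded with a warning
  expect_warning(
    part <- adjacency_chi_square(c(a = 5, b = 2), c(a = 5, b = 0)),
    "excluded")
  expect_equal(nrow(part), 1L)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$statistic, attr(res, "statistic"))
})

test_that("permutation expectations match the exchangeable closed form", {
  # 5 + 5 statuses: under permutation, P(adjacent same-status pair of one
  # class) = (5/10)(4/9); 9 adjacent slots
  f <- mk_genic(rep(c("escape", "subject"), each = 5))
  perm <- permutation_expected(f$genic, f$annotation,
                               n_permutations = 4000, seed = 3)
  exp_same <- 9 * (5 / 10) * (4 / 9)
  got <- stats::setNames(perm$expected$expected, perm$expected$pair)
  expect_equal(got[["escape|escape"]], exp_same, tolerance = 0.05)
  expect_equal(got[["subject|subject"]], exp_same, tolerance = 0.05)
  expect_equal(got[["escape|subject"]], 9 - 2 * exp_same,
               tolerance = 0.05)
  # determinism under a fixed seed
  perm2 <- permutation_expected(f$genic, f$annotation,
                                n_permutations = 4000, seed = 3)
  expect_identical(perm$expected, perm2$expected)
  expect_identical(perm$p_empirical, perm2$p_empirical)
  # single-status degenerate case: expected = observed, p = 1
  g <- mk_genic(rep("subject", 6))
  p1 <- permutation_expected(g$genic, g$annotation,
                             n_permutations = 100, seed = 1)
  expect_equal(p1$expected$expected[p1$expected$pair == "subject|subject"],
               5)
  expect_equal(p1$p_empirical, 1)
})

test_that("clustered statuses are detected as non-random", {
  res <- study_pipeline()
  expect_lt(res$adjacency$p_empirical, 0.05)
  # same-status pairs are enriched
  tab <- tidy(res$adjacency$test)
  same <- tab$pair %in% c("escape|escape", "subject|subject",
                          "variable_escape|variable_escape")
  expect_true(all(tab$std_residual[same] > 0))
})

# -- cross-sample-set classification -----------------------------------------

mk_per_set <- function(a, b, c_, n = c(10L, 10L, 10L)) {
  tibble::tibble(gene = "g1",
                 sample_set = c("LCL1", "LCL2", "FIB"),
                 status = c(a, b, c_),
                 n_females = n)
}

test_that("cross-set decision tree covers the category taxonomy", {
  cl <- function(tab) {
    cross_set_classify(tab, c("LCL1", "LCL2"), "FIB")$category
  }
  expect_equal(cl(mk_per_set("escape", "escape", "escape")),
               "consistent_escape")
  # two LCL populations disagree, third uninformative
  expect_equal(cl(mk_per_set("escape", "subject", "escape",
                             n = c(10L, 10L, 2L))),
               "population_specific")
  # LCL populations agree, fibroblasts differ
  expect_equal(cl(mk_per_set("subject", "subject", "escape")),
               "cell_line_specific")
  # all three disagree: both axes implicated
  expect_equal(cl(mk_per_set("escape", "subject", "variable_escape")),
               "population_and_cell_line")
  # one LCL + FIB disagreeing: axis unidentifiable
  expect_equal(cl(mk_per_set("escape", "subject", "escape",
                             n = c(2L, 10L, 10L))),
               "inconsistent")
  # one LCL + FIB agreeing: consistent
  expect_equal(cl(mk_per_set("escape", "subject", "subject",
                             n = c(2L, 10L, 10L))),
               "consistent_subject")
  # fewer than two informative sets: not classifiable
  expect_true(is.na(cl(mk_per_set("escape", "subject", "subject",
                                  n = c(10L, 2L, 2L)))))
})

test_that("cross-set classification is symmetric in the two LCL sets", {
  tab <- mk_per_set("escape", "subject", "escape")
  a <- cross_set_classify(tab, c("LCL1", "LCL2"), "FIB")$category
  b <- cross_set_classify(tab, c("LCL2", "LCL1"), "FIB")$category
  expect_identical(a, b)
})

# -- group-R mono-allelic screen ---------------------------------------------

test_that("group-R screen applies the q995 cut and the fraction rule", {
  profiles <- tibble::tibble(
    sample_id = sprintf("f%d", 1:7), sample_set = "S1",
    avg_subject_ai = c(0.05, 0.06, 0.05, 0.055, 0.05, 0.06, 0.05),
    n_training_genes = 20L, group = "R", skew = NA_real_,
    slope = NA_real_, intercept = NA_real_, p_value = 0.5,
    n_regression_genes = 30L)
  th <- tibble::tibble(sample_set = "S1", q90 = 0.05, q95 = 0.1,
                       q995 = 0.3)
  gai <- dplyr::bind_rows(
    # balanced gene: bi-allelic everywhere
    tibble::tibble(gene = "bal", sample_id = sprintf("f%d", 1:6),
                   sample_set = "S1", ai = 0.02, n_probes = 2L),
    # imprinted gene: mono-allelic in all females
    tibble::tibble(gene = "imp", sample_id = sprintf("f%d", 1:6),
                   sample_set = "S1", ai = 0.48, n_probes = 3L),
    # mono in exactly 1 of 7 females: 6/7 bi-allelic >= 7/9 -> bi
    tibble::tibble(gene = "rare", sample_id = sprintf("f%d", 1:7),
                   sample_set = "S1", ai = c(0.4, rep(0.02, 6)),
                   n_probes = 2L))
  out <- group_r_allelic(gai, profiles, th)
  cat_by <- stats::setNames(out$genic$category, out$genic$gene)
  expect_equal(cat_by[["bal"]], "bi")
  expect_equal(cat_by[["imp"]], "mono")
  expect_equal(cat_by[["rare"]], "bi")
})

test_that("a Grubbs outlier female is excluded from the screen", {
  profiles <- tibble::tibble(
    sample_id = sprintf("f%d", 1:5), sample_set = "S1",
    avg_subject_ai = c(0.05, 0.06, 0.05, 0.055, 0.30),
    n_training_genes = 20L, group = "R", skew = NA_real_,
    slope = NA_real_, intercept = NA_real_, p_value = 0.5,
    n_regression_genes = 30L)
  th <- tibble::tibble(sample_set = "S1", q90 = 0.05, q95 = 0.1,
                       q995 = 0.3)
  gai <- tibble::tibble(gene = "g", sample_id = sprintf("f%d", 1:5),
                        sample_set = "S1", ai = 0.02, n_probes = 2L)
  out <- group_r_allelic(gai, profiles, th)
  expect_equal(out$outliers$sample_id, "f5")
  expect_false("f5" %in% out$per_female$sample_id)
})

test_that("the planted imprinted gene is flagged mono-allelic", {
  co <- study_cohort()
  res <- study_pipeline()
  imp <- co$truth$genes$gene[co$truth$genes$archetype == "imprinted"]
  row <- dplyr::filter(res$group_r$genic, .data$gene == imp)
  expect_equal(row$category, "mono")
})

# -- histone ChIP class comparison -------------------------------------------

test_that("ChIP comparison assigns regions by strand-resolved coordinates
           and recovers the planted ordering", {
  co <- small_cohort()
  chip <- simulate_chip(co)
  truth <- attr(chip, "chip_truth")
  classes <- dplyr::rename(truth, expression_class = "class")
  res <- chip_class_compare(chip, co$annotation, classes)
  for (mk in unique(res$class_means$mark)) {
    body <- res$class_means |>
      dplyr::filter(.data$mark == mk, .data$region == "gene_body") |>
      dplyr::arrange(factor(.data$expression_class,
                            levels = expression_class_levels()))
    # AI rises monotonically as Xi expression falls across classes
    expect_true(all(diff(body$mean_ai) > 0))
  }
  # gene body has roughly chip_body_factor more probes than promoter
  n_by_region <- res$class_means |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = sum(.data$n))
  ratio <- n_by_region$n[n_by_region$region == "gene_body"] /
    n_by_region$n[n_by_region$region == "promoter"]
  expect_gt(ratio, 20)
  # planted differences are detected after correction
  body_tests <- dplyr::filter(res$tests, .data$region == "gene_body")
  expect_true(all(body_tests$p_adjusted < 0.05))
})

test_that("ChIP null: equal class means yield few corrected flags", {
  co <- small_cohort()
  flags <- purrr::map_int(1:20, function(i) {
    cfg <- cohort_config(n_females_per_set = 6, n_autosomal_probes = 800,
                         seed = 1000 + i,
                         chip_class_means = c(
                           escape_in_PAR1_range = 0.25,
                           escape_outside_PAR1_range = 0.25,
                           subject_ge5 = 0.25, subject_lt5 = 0.25),
                         n_chip_samples = 1, chip_body_factor = 5,
                         chip_marks = "H3K4me3")
    chip <- simulate_chip(co, cfg)
    classes <- dplyr::rename(attr(chip, "chip_truth"),
                             expression_class = "class")
    res <- chip_class_compare(chip, co$annotation, classes)
    sum(res$tests$p_adjusted < 0.05)
  })
  # corrected pairwise tests under the null: flag rate well under the
  # nominal level across 20 replicates x (6 pairs x 2 regions)
  expect_lte(sum(flags) / (20 * 12), 0.07)
})

test_that("a single-class ChIP table yields summaries but no tests", {
  co <- small_cohort()
  chip <- simulate_chip(co)
  truth <- attr(chip, "chip_truth")
  one_class <- truth$gene[truth$class == "subject_lt5"]
  classes <- tibble::tibble(gene = one_class,
                            expression_class = "subject_lt5")
  res <- chip_class_compare(chip, co$annotation, classes)
  expect_gt(nrow(res$class_means), 0)
  expect_true(is.null(res$tests) || nrow(res$tests) == 0)
})
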