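# -- intensity decay fit ----------------------------------------------------

decay_fixture <- function(n = 5000, tau = 2000, y0 = 0.3, plateau = 0.02,
                          noise = 0.01, seed = 77) {
  xciscan:::with_seed(seed, {
    intensity <- stats::rlnorm(n, log(2500), 1)
    mu <- plateau + (y0 - plateau) * exp(-intensity / tau)
    probe_rows(sprintf("p%05d", seq_len(n)), NA_character_,
               sprintf("u%02d", sample(30, n, replace = TRUE)),
               frac_cdna = pmin(pmax(mu + stats::rnorm(n, 0, noise), 0), 1),
               informative = FALSE, intensity = intensity)
  })
}

test_that("decay fit recovers the generated Tau within 10%", {
  fit <- fit_intensity_decay(decay_fixture(), "SETA")
  expect_lt(abs(fit$tau - 2000) / 2000, 0.10)
  expect_lt(abs(fit$y0 - 0.3), 0.03)
  expect_lt(abs(fit$plateau - 0.02), 0.01)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$tau, fit$tau)
})

test_that("decay fit is scale-equivariant in intensity", {
  dat <- decay_fixture(n = 3000)
  fit1 <- fit_intensity_decay(dat)
  dat2 <- dat
  dat2$intensity <- dat2$intensity * 2
  fit2 <- fit_intensity_decay(dat2)
  expect_equal(fit2$tau / fit1$tau, 2, tolerance = 0.02)
})

test_that("degenerate and undersized decay inputs raise errors", {
  flat <- probe_rows(sprintf("p%03d", 1:100), NA_character_, "u1",
                     frac_cdna = rep(0.1, 100), informative = FALSE,
                     intensity = seq(100, 5000, length.out = 100))
  expect_error(fit_intensity_decay(flat, "FLAT"), "degenerate")
  expect_error(fit_intensity_decay(flat[1:5, ], "TINY"), ">= 20")
})

# -- intensity filter -------------------------------------------------------

test_that("intensity filter matches a counting oracle and reports per set", {
  tab <- probe_rows(sprintf("p%02d", 1:10), "g1",
                    sample_id = rep(c("f1", "f2"), 5),
                    frac_cdna = 0.5,
                    sample_set = rep(c("S1", "S2"), each = 5),
                    intensity = c(100, 200, 300, 400, 500,
                                  600, 700, 800, 900, 1000))
  tau <- tibble::tibble(sample_set = c("S1", "S2"), tau = c(250, 800))
  flt <- apply_intensity_filter(tab, tau)
  # oracle by hand: S1 keeps 300,400,500; S2 keeps 900,1000
  expect_equal(sort(flt$probes$intensity), c(300, 400, 500, 900, 1000))
  rep1 <- dplyr::arrange(flt$report, .data$sample_set)
  expect_equal(rep1$excluded, c(2L, 3L))
  expect_equal(rep1$retained, c(3L, 2L))
  # strict inequality: intensity exactly tau is excluded
  expect_false(250 %in% flt$probes$intensity)
  # missing tau errors
  expect_error(apply_intensity_filter(tab, tau[1, ]), "S2")
})

test_that("intensity filter is idempotent and monotone in tau", {
  co <- small_cohort()
  expr <- dplyr::filter(co$probes, .data$channel == "expression")
  f1 <- apply_intensity_filter(expr, 2000)
  f2 <- apply_intensity_filter(f1$probes, 2000)
  expect_identical(f1$probes, f2$probes)
  f_hi <- apply_intensity_filter(expr, 5000)
  key <- function(p) paste(p$probe_id, p$sample_id)
  expect_true(all(key(f_hi$probes) %in% key(f1$probes)))
})

# -- genomic-DNA ratio filter ----------------------------------------------

test_that("gDNA bias rule follows the 50%-prevalence, one-set trigger", {
  mk <- function(id, gdna, set) {
    probe_rows(id, "g1", sprintf("f%d_%s", seq_along(gdna), set),
               frac_cdna = 0.5, sample_set = set, frac_gdna = gdna)
  }
  tab <- dplyr::bind_rows(
    mk("balanced", rep(0.5, 4), "S1"),
    # 3 of 4 females biased in S1 -> excluded everywhere
    mk("biased", c(0.9, 0.9, 0.9, 0.5), "S1"),
    mk("biased", rep(0.5, 4), "S2"),
    # 1 of 4 in each set -> below prevalence, retained
    mk("sporadic", c(0.75, 0.5, 0.5, 0.5), "S1"),
    mk("sporadic", c(0.75, 0.5, 0.5, 0.5), "S2"),
    # symmetric: low ratios count via the minor-allele mirror
    mk("low_side", c(0.1, 0.1, 0.5, 0.5), "S1"))
  out <- flag_gdna_biased_probes(tab)
  expect_setequal(out, c("biased", "low_side"))
})

test_that("QC filters are idempotent end to end", {
  co <- small_cohort()
  qc1 <- run_probe_qc(co$probes)
  qc2 <- run_probe_qc(qc1$probes, tau = qc1$tau)
  expect_identical(qc1$probes, qc2$probes)
})

# -- two-probe concordance --------------------------------------------------

concordance_boundaries <- function(females, e3_s = 0.32) {
  tibble::tibble(sample_id = females, sample_set = "S1", group = "1",
                 skew = 0.9, e1_e2 = 0.05, e2_e3 = 0.11, e3_s = e3_s)
}

test_that("identical probes are fully concordant; an S/E1 split is flagged", {
  females <- sprintf("f%d", 1:4)
  # 30 background genes at a 17% discordance rate to set the cohort rate,
  # plus one gene whose probes always disagree
  xciscan:::with_seed(99, {
    bg <- purrr::map(1:30, function(g) {
      disc <- stats::runif(4) < 0.17
      dplyr::bind_rows(
        probe_rows(sprintf("gb%d_a", g), sprintf("gb%d", g), females,
                   frac_cdna = 0.5 + 0.4),
        probe_rows(sprintf("gb%d_b", g), sprintf("gb%d", g), females,
                   frac_cdna = 0.5 + ifelse(disc, 0.05, 0.4)))
    }) |> purrr::list_rbind()
  })
  split_gene <- dplyr::bind_rows(
    probe_rows("gs_a", "gs", females, frac_cdna = 0.9),   # always S
    probe_rows("gs_b", "gs", females, frac_cdna = 0.51))  # always E1
  same_gene <- dplyr::bind_rows(
    probe_rows("gc_a", "gc", females, frac_cdna = 0.9),
    probe_rows("gc_b", "gc", females, frac_cdna = 0.9))
  res <- probe_concordance(dplyr::bind_rows(bg, split_gene, same_gene),
                           concordance_boundaries(females))
  per <- res$per_gene
  expect_equal(per$concordance[per$gene == "gc"], 1)
  expect_false(per$flagged[per$gene == "gc"])
  expect_equal(per$n_discordant[per$gene == "gs"], 4L)
  expect_true(per$flagged[per$gene == "gs"])
  # chi-square oracle at k = 4 discordant of 4, cohort rate p0
  p0 <- 1 - res$overall_concordance
  oracle <- suppressWarnings(
    stats::chisq.test(c(4, 0), p = c(p0, 1 - p0)))$p.value
  expect_equal(per$p_value[per$gene == "gs"], oracle)
  expect_lt(per$p_value[per$gene == "gs"], 0.05)
})

test_that("uniform-rate discordance flags about the nominal 5% of genes", {
  # null calibration: 2000 two-probe genes, 6 females, discordance
  # generated at a uniform 15% rate
  females <- sprintf("f%d", 1:6)
  n_genes <- 2000
  tab <- xciscan:::with_seed(123, {
    disc <- matrix(stats::runif(n_genes * 6) < 0.15, n_genes)
    purrr::map(seq_len(n_genes), function(g) {
      dplyr::bind_rows(
        probe_rows(sprintf("g%d_a", g), sprintf("g%04d", g), females,
                   frac_cdna = 0.9),
        probe_rows(sprintf("g%d_b", g), sprintf("g%04d", g), females,
                   frac_cdna = ifelse(disc[g, ], 0.55, 0.9)))
    }) |> purrr::list_rbind()
  })
  res <- probe_concordance(tab, concordance_boundaries(females))
  expect_lte(mean(res$per_gene$flagged), 0.07)
})

test_that("the |dAI| concordance definition is available and labelled", {
  females <- "f1"
  tab <- dplyr::bind_rows(
    probe_rows("a", "g", females, frac_cdna = 0.95),
    probe_rows("b", "g", females, frac_cdna = 0.80))
  res <- probe_concordance(tab, concordance_boundaries(females),
                           definition = "delta", delta = 0.1)
  expect_equal(res$definition, "delta")
  expect_equal(res$per_gene$n_discordant, 1L)  # |0.45 - 0.30| >= 0.1
})
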