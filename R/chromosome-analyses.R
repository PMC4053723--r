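#' Observed adjacency counts of genic statuses along the chromosome
#'
#' Orders classified genes by position (ties broken by gene id), excludes
#' PAR1 genes (a known escape cluster that would dominate the signal), and
#' counts unordered status pairs over consecutive genes.
#'
#' @param genic [aggregate_genic()] output (or any tibble with `gene`,
#'   `status`).
#' @param annotation Gene annotation tibble with `gene`, `start`, `par1`.
#' @param exclude_par1 Drop PAR1 genes first (default TRUE).
#' @return Tibble: `pair` (e.g. `"escape|subject"`, labels sorted within
#'   the pair), `observed`.
#' @export
adjacency_counts <- function(genic, annotation, exclude_par1 = TRUE) {
  dat <- genic |>
    dplyr::inner_join(annotation[, c("gene", "start", "par1")],
                      by = "gene")
  if (exclude_par1) dat <- dplyr::filter(dat, !.data$par1)
  if (nrow(dat) < 2) {
    stop("need at least two classified genes for adjacency counts",
         call. = FALSE)
  }
  dat <- dplyr::arrange(dat, .data$start, .data$gene)
  s <- as.character(dat$status)
  a <- s[-length(s)]
  b <- s[-1]
  pairs_seen <- paste(pmin(a, b), pmax(a, b), sep = "|")
  lv <- sort(unique(as.character(genic$status)))
  all_pairs <- outer(lv, lv, function(x, y) paste(pmin(x, y),
                                                  pmax(x, y), sep = "|"))
  all_pairs <- sort(unique(as.vector(all_pairs)))
  counts <- table(factor(pairs_seen, levels = all_pairs))
  tibble::tibble(pair = all_pairs, observed = as.integer(counts))
}

#' Expected adjacency counts under positional permutation
#'
#' The null hypothesis is that XCI statuses are exchangeable across gene
#' positions. Statuses are permuted over the ordered positions
#' `n_permutations` times; expected pair counts are the permutation means,
#' and an empirical p-value for the total chi-square statistic (observed vs
#' those expectations) is returned.
#'
#' @param genic,annotation,exclude_par1 As in [adjacency_counts()].
#' @param n_permutations At least 100 (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return List: `expected` (tibble `pair`, `expected`), `observed`,
#'   `p_empirical`, `n_permutations`.
#' @export
permutation_expected <- function(genic, annotation, n_permutations = 1000,
                                 seed = 1L, exclude_par1 = TRUE) {
  stopifnot(n_permutations >= 100)
  obs <- adjacency_counts(genic, annotation, exclude_par1)
  count_pairs <- function(s) {
    a <- s[-length(s)]; b <- s[-1]
    table(factor(paste(pmin(a, b), pmax(a, b), sep = "|"),
                 levels = obs$pair))
  }
  dat <- genic |>
    dplyr::inner_join(annotation[, c("gene", "start", "par1")],
                      by = "gene")
  if (exclude_par1) dat <- dplyr::filter(dat, !.data$par1)
  s0 <- as.character(dplyr::arrange(dat, .data$start, .data$gene)$status)
  perm_counts <- with_seed(seed, {
    matrix(vapply(seq_len(n_permutations),
                  function(i) as.integer(count_pairs(sample(s0))),
                  integer(length(obs$pair))),
           nrow = length(obs$pair))
  })
  expected <- rowMeans(perm_counts)
  stat <- function(o, e) sum((o - e)^2 / e, na.rm = TRUE)
  keep <- expected > 0
  obs_stat <- stat(obs$observed[keep], expected[keep])
  perm_stats <- apply(perm_counts, 2,
                      function(o) stat(o[keep], expected[keep]))
  list(expected = tibble::tibble(pair = obs$pair, expected = expected),
       observed = obs,
       p_empirical = (1 + sum(perm_stats >= obs_stat)) /
         (n_permutations + 1),
       n_permutations = n_permutations)
}

#' Chi-square test of adjacency counts against expected counts
#'
#' Per status pair: component `(observed - expected)^2 / expected` and
#' standardized residual `(observed - expected) / sqrt(expected)`. The
#' total statistic is the sum of components, tested against a chi-square
#' distribution with `df` degrees of freedom (default: number of included
#' pairs minus one). Pairs with zero expected count are excluded with a
#' warning.
#'
#' @param observed Tibble `pair`, `observed`, or a named numeric vector.
#' @param expected Tibble `pair`, `expected`, or a named/numeric vector
#'   aligned with `observed`.
#' @param df Degrees of freedom for the p-value.
#' @return Tibble of class `adjacency_test`: per-pair `observed`,
#'   `expected`, `component`, `std_residual`; attributes `statistic`, `df`,
#'   `p_value`.
#' @examples
#' adjacency_chi_square(c(`escape|escape` = 39), c(`escape|escape` = 6))
#' @export
adjacency_chi_square <- function(observed, expected, df = NULL) {
  if (!is.data.frame(observed)) {
    observed <- tibble::tibble(pair = names(observed) %||%
                                 as.character(seq_along(observed)),
                               observed = as.numeric(observed))
  }
  if (!is.data.frame(expected)) {
    expected <- tibble::tibble(
      pair = names(expected) %||% observed$pair,
      expected = as.numeric(expected))
  }
  tab <- dplyr::inner_join(observed, expected, by = "pair")
  if (any(tab$expected <= 0)) {
    warning(sum(tab$expected <= 0),
            " pair(s) with non-positive expected count excluded",
            call. = FALSE)
    tab <- tab[tab$expected > 0, ]
  }
  tab <- tab |>
    dplyr::mutate(
      component = (.data$observed - .data$expected)^2 / .data$expected,
      std_residual = (.data$observed - .data$expected) /
        sqrt(.data$expected))
  if (is.null(df)) df <- max(nrow(tab) - 1, 1)
  statistic <- sum(tab$component)
  structure(tab, class = c("adjacency_test", class(tab)),
            statistic = statistic, df = df,
            p_value = stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' @export
print.adjacency_test <- function(x, ...) {
  cat(sprintf("<adjacency_test> X2 = %.1f on %d df, p = %.4g\n",
              attr(x, "statistic"), attr(x, "df"), attr(x, "p_value")))
  NextMethod()
}

#' Cross-sample-set XCI comparison
#'
#' Compares genic statuses between sample sets, using only sets with at
#' least `min_females` informative females for the gene. With two
#' lymphoblastoid populations (`lcl_sets`) and one other-cell-type set, a
#' gene is `consistent_<status>` when all informative sets agree;
#' `population_specific` when the two LCL populations disagree (unless the
#' third set disagrees with both, implying `population_and_cell_line`);
#' `cell_line_specific` when the LCL sets agree but the other cell type
#' differs; `inconsistent` when the axis of disagreement cannot be
#' identified (e.g. one LCL set plus the fibroblast set disagreeing).
#'
#' @param per_set_genic Tibble with `gene`, `sample_set`, `status`,
#'   `n_females` — e.g. [aggregate_genic()] run per sample set.
#' @param lcl_sets Character vector (length 2): the same-cell-type sets.
#' @param other_set The remaining set.
#' @param min_females Informativity cutoff per set (default 5).
#' @return Tibble: `gene`, one status column per set (NA when
#'   uninformative), `n_informative_sets`, `category`.
#' @export
cross_set_classify <- function(per_set_genic, lcl_sets, other_set,
                               min_females = 5) {
  stopifnot(length(lcl_sets) == 2, length(other_set) == 1)
  wide <- per_set_genic |>
    dplyr::filter(.data$n_females >= min_females) |>
    dplyr::mutate(status = as.character(.data$status)) |>
    dplyr::select("gene", "sample_set", "status") |>
    tidyr::pivot_wider(names_from = "sample_set", values_from = "status")
  for (s in c(lcl_sets, other_set)) {
    if (!s %in% names(wide)) wide[[s]] <- NA_character_
  }
  a <- wide[[lcl_sets[1]]]
  b <- wide[[lcl_sets[2]]]
  c_ <- wide[[other_set]]
  n_inf <- (!is.na(a)) + (!is.na(b)) + (!is.na(c_))
  same_or_na <- function(x, y) is.na(x) | is.na(y) | x == y
  all_agree <- same_or_na(a, b) & same_or_na(a, c_) & same_or_na(b, c_)
  consensus <- dplyr::coalesce(a, b, c_)

  category <- dplyr::case_when(
    n_inf < 2 ~ NA_character_,
    all_agree ~ paste0("consistent_", consensus),
    # both LCL populations informative and disagreeing
    !is.na(a) & !is.na(b) & a != b &
      !is.na(c_) & c_ != a & c_ != b ~ "population_and_cell_line",
    !is.na(a) & !is.na(b) & a != b ~ "population_specific",
    # LCL populations agree (both informative) but other cell type differs
    !is.na(a) & !is.na(b) & a == b & !is.na(c_) & c_ != a ~
      "cell_line_specific",
    TRUE ~ "inconsistent")
  wide$n_informative_sets <- n_inf
  wide$category <- category
  wide
}

#' Mono-allelic expression screen in group-R females
#'
#' In females with random XCI every X-linked gene should look bi-allelic;
#' mono-allelic expression there indicates imprinting (or another
#' parent-of-origin effect) rather than XCI. After excluding Grubbs
#' outliers, each gene with at least two informative probes in a group-R
#' female is called mono-allelic when its mean AI exceeds the sample set's
#' autosomal 99.5% threshold. Genic categories apply the same fraction
#' rule as the XCI aggregation to the bi-allelic fraction: `bi` when at
#' least 7/9 of females are bi-allelic, `mono` when at most 2/9 are, else
#' `variable_allelic`.
#'
#' @param gene_ai [gene_female_ai()] output (post-QC).
#' @param profiles [classify_females()] output.
#' @param thresholds [autosomal_thresholds()] output.
#' @param alpha Grubbs significance level (default 0.05).
#' @param bi_lo,bi_hi Fraction bounds (defaults 2/9 and 7/9).
#' @return List of class `group_r_screen`: `per_female` (gene, sample_id,
#'   sample_set, ai, mono), `genic` (gene, n_females, frac_biallelic,
#'   category), `outliers` (tibble of excluded females with Z and p).
#' @export
group_r_allelic <- function(gene_ai, profiles, thresholds, alpha = 0.05,
                            bi_lo = 2 / 9, bi_hi = 7 / 9) {
  gr <- dplyr::filter(profiles, .data$group == "R")
  outliers <- gr |>
    dplyr::group_by(.data$sample_set) |>
    dplyr::group_map(function(d, key) {
      g <- grubbs_outlier(d$avg_subject_ai, alpha = alpha)
      if (!g$applicable || is.na(g$outlier_index)) return(NULL)
      tibble::tibble(sample_id = d$sample_id[g$outlier_index],
                     sample_set = key$sample_set,
                     avg_subject_ai = d$avg_subject_ai[g$outlier_index],
                     z = g$z, p_value = g$p_value)
    }) |>
    purrr::list_rbind()
  keep <- setdiff(gr$sample_id, outliers$sample_id)
  per_female <- gene_ai |>
    dplyr::filter(.data$sample_id %in% keep) |>
    dplyr::left_join(thresholds[, c("sample_set", "q995")],
                     by = "sample_set") |>
    dplyr::mutate(mono = .data$ai > .data$q995) |>
    dplyr::select("gene", "sample_id", "sample_set", "ai", "n_probes",
                  "mono")
  genic <- per_female |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_females = dplyr::n(),
                     frac_biallelic = mean(!.data$mono),
                     .groups = "drop") |>
    dplyr::mutate(category = dplyr::case_when(
      .data$frac_biallelic >= bi_hi ~ "bi",
      .data$frac_biallelic <= bi_lo ~ "mono",
      TRUE ~ "variable_allelic"))
  structure(list(per_female = per_female, genic = genic,
                 outliers = outliers),
            class = "group_r_screen")
}

#' @export
print.group_r_screen <- function(x, ...) {
  cat("<group_r_screen>", nrow(x$genic), "genes,",
      sum(x$genic$category == "mono"), "mono-allelic,",
      nrow(x$outliers %||% data.frame()), "outlier female(s) excluded\n")
  invisible(x)
}

#' Histone ChIP allelic imbalance across expression classes
#'
#' Assigns ChIP probes to the promoter (within 1 kb of the strand-resolved
#' TSS) and gene body (TSS to TES) of annotated genes, then per mark and
#' region compares mean |AI| across gene expression classes with all
#' pairwise two-tailed t-tests, corrected within each mark-by-region family.
#'
#' @param chip_probes ChIP probe table (`channel` of the form
#'   `"chip:<mark>"`).
#' @param annotation Gene annotation with `gene`, `start`, `end`, `strand`.
#' @param classes Tibble `gene`, `expression_class` (e.g. from
#'   [par1_range_classes()]).
#' @param promoter_halfwidth Promoter window half-width in bp (default
#'   1000).
#' @param correction Multiple-testing method (default `"holm"`; any
#'   [stats::p.adjust()] method).
#' @return List of class `chip_class_summary`: `class_means` (mark, region,
#'   expression_class, mean_ai, se, n) and `tests` (mark, region, class_a,
#'   class_b, t, df, p_value, p_adjusted).
#' @export
chip_class_compare <- function(chip_probes, annotation, classes,
                               promoter_halfwidth = 1000,
                               correction = "holm") {
  ann <- annotation |>
    dplyr::mutate(tss = ifelse(.data$strand == "-", .data$end,
                               .data$start),
                  tes = ifelse(.data$strand == "-", .data$start,
                               .data$end))
  dat <- chip_probes |>
    dplyr::filter(startsWith(.data$channel, "chip:"), .data$informative) |>
    dplyr::mutate(mark = sub("^chip:", "", .data$channel),
                  ai = abs(.data$frac_cdna - 0.5)) |>
    dplyr::inner_join(ann[, c("gene", "tss", "tes")], by = "gene") |>
    dplyr::inner_join(classes[, c("gene", "expression_class")],
                      by = "gene") |>
    dplyr::filter(!is.na(.data$expression_class))
  dat <- dplyr::bind_rows(
    dat |>
      dplyr::filter(abs(.data$pos - .data$tss) <= promoter_halfwidth) |>
      dplyr::mutate(region = "promoter"),
    dat |>
      dplyr::filter(.data$pos >= pmin(.data$tss, .data$tes),
                    .data$pos <= pmax(.data$tss, .data$tes)) |>
      dplyr::mutate(region = "gene_body"))

  class_means <- dat |>
    dplyr::group_by(.data$mark, .data$region, .data$expression_class) |>
    dplyr::summarise(mean_ai = mean(.data$ai),
                     se = stats::sd(.data$ai) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")

  tests <- dat |>
    dplyr::group_by(.data$mark, .data$region) |>
    dplyr::group_map(function(d, key) {
      cls <- d |>
        dplyr::count(.data$expression_class) |>
        dplyr::filter(.data$n >= 2) |>
        dplyr::pull(.data$expression_class)
      if (length(cls) < 2) return(NULL)
      pairs <- utils::combn(sort(cls), 2)
      res <- apply(pairs, 2, function(p) {
        tt <- stats::t.test(d$ai[d$expression_class == p[1]],
                            d$ai[d$expression_class == p[2]])
        tibble::tibble(class_a = p[1], class_b = p[2],
                       t = unname(tt$statistic),
                       df = unname(tt$parameter),
                       p_value = tt$p.value)
      })
      res <- purrr::list_rbind(res)
      res$p_adjusted <- stats::p.adjust(res$p_value, method = correction)
      dplyr::bind_cols(key, res)
    }) |>
    purrr::list_rbind()

  structure(list(class_means = class_means, tests = tests,
                 correction = correction),
            class = "chip_class_summary")
}

#' @export
print.chip_class_summary <- function(x, ...) {
  cat("<chip_class_summary>\n")
  print(x$class_means)
  invisible(x)
}
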