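#' Skew-adjusted status boundaries per female
#'
#' Computes, for every group-1 and group-2 female, the AI cut-points that
#' separate the three escape levels and the subject class. For group 1 the
#' E1:E2 and E2:E3 boundaries are the sample set's autosomal 90% and 95%
#' quantiles, and the E3:S boundary is the AI corresponding to 10% Xi
#' expression at the female's skew ([expected_ai()]`(skew, 0.10)`). For
#' group 2 all three boundaries are mapped through the female's regression
#' line (`slope * boundary + intercept`); the group-1-level E3:S reference
#' is taken at the mean group-1 skew of the sample set. Boundaries are
#' clipped into `[0, 0.5]` and re-ordered (with a warning) if the mapping
#' inverts them.
#'
#' @param profiles [classify_females()] output.
#' @param thresholds [autosomal_thresholds()] output.
#' @param xi_cutoff Xi expression level defining the escape/subject split
#'   (default 0.10).
#' @return Tibble: `sample_id`, `sample_set`, `group`, `skew`, `e1_e2`,
#'   `e2_e3`, `e3_s`. Group-R females are absent (no boundaries are defined
#'   for them).
#' @export
female_boundaries <- function(profiles, thresholds, xi_cutoff = 0.10) {
  if (all(profiles$group == "R")) {
    stop("no boundaries are defined for group-R females (random XCI)",
         call. = FALSE)
  }
  ref_skew <- profiles |>
    dplyr::filter(.data$group == "1") |>
    dplyr::group_by(.data$sample_set) |>
    dplyr::summarise(g1_skew = mean(.data$skew), .groups = "drop")
  out <- profiles |>
    dplyr::filter(.data$group %in% c("1", "2")) |>
    dplyr::left_join(thresholds, by = "sample_set") |>
    dplyr::left_join(ref_skew, by = "sample_set") |>
    dplyr::mutate(
      e1_e2 = ifelse(.data$group == "1", .data$q90,
                     .data$slope * .data$q90 + .data$intercept),
      e2_e3 = ifelse(.data$group == "1", .data$q95,
                     .data$slope * .data$q95 + .data$intercept),
      e3_s = ifelse(.data$group == "1",
                    expected_ai(.data$skew, xi_cutoff),
                    .data$slope * expected_ai(.data$g1_skew, xi_cutoff) +
                      .data$intercept),
      dplyr::across(c("e1_e2", "e2_e3", "e3_s"),
                    \(x) pmin(pmax(x, 0), 0.5)))
  inverted <- with(out, e1_e2 > e2_e3 | e2_e3 > e3_s)
  if (any(inverted, na.rm = TRUE)) {
    warning(sum(inverted, na.rm = TRUE),
            " female(s) had inverted boundaries after rescaling; re-ordered",
            call. = FALSE)
    fix <- t(apply(as.matrix(out[, c("e1_e2", "e2_e3", "e3_s")]), 1, sort))
    out$e1_e2 <- fix[, 1]; out$e2_e3 <- fix[, 2]; out$e3_s <- fix[, 3]
  }
  dplyr::select(out, "sample_id", "sample_set", "group", "skew",
                "e1_e2", "e2_e3", "e3_s")
}

#' Per-gene, per-female XCI status and %Xi
#'
#' Assigns each gene (with at least `min_probes` informative probes) in each
#' group-1/2 female a status from its mean AI and the female's boundaries:
#' lower AI means more expression from the inactive X, so `E1` if
#' `ai < e1_e2`, `E2` if below `e2_e3`, `E3` if below `e3_s`, and `S`
#' (subject; less than the cutoff level of Xi expression) at or above
#' `e3_s`. The AI is also inverted into the Xi:Xa expression ratio at the
#' female's skew ([xi_from_ai()]; negative solutions clamp to 0).
#'
#' @param gene_ai [gene_female_ai()] output.
#' @param boundaries [female_boundaries()] output.
#' @return Tibble: `gene`, `sample_id`, `sample_set`, `group`, `ai`,
#'   `n_probes`, `status` (factor E1/E2/E3/S), `xi`.
#' @export
call_genes <- function(gene_ai, boundaries) {
  gene_ai |>
    dplyr::inner_join(
      boundaries[, c("sample_id", "group", "skew", "e1_e2", "e2_e3",
                     "e3_s")],
      by = "sample_id") |>
    dplyr::mutate(
      status = factor(
        dplyr::case_when(
          .data$ai < .data$e1_e2 ~ "E1",
          .data$ai < .data$e2_e3 ~ "E2",
          .data$ai < .data$e3_s ~ "E3",
          TRUE ~ "S"),
        levels = xci_status_levels()),
      xi = xi_from_ai(pmin(.data$ai, 0.5), .data$skew)) |>
    dplyr::select("gene", "sample_id", "sample_set", "group", "ai",
                  "n_probes", "status", "xi")
}

#' Aggregate per-female calls into genic XCI statuses
#'
#' A gene escapes in a female when its call is E1, E2 or E3. Genes where the
#' escaping fraction of informative females is at least 7/9 are classified
#' `escape`, at most 2/9 `subject`, and in between `variable_escape` (the
#' fractions are kept as exact rationals so that 7 of 9 females reproduces
#' the canonical hybrid-panel rule). Variable-escape genes are subtyped:
#' `bimodal` when at least `bimodal_fraction` of calls are E1 or S and both
#' occur; otherwise `borderline` when every call is S or E3; otherwise
#' `heterogeneous`.
#'
#' @param calls [call_genes()] output.
#' @param min_females Minimum informative females per gene (default 1).
#' @param escape_lo,escape_hi Genic fraction bounds (defaults 2/9 and 7/9).
#' @param bimodal_fraction Minimum E1-or-S fraction for the bimodal subtype
#'   (default 0.75).
#' @return Tibble of class `genic_xci`: `gene`, `n_females`,
#'   `frac_escaping`, `status` (subject/variable_escape/escape),
#'   `subtype` (NA unless variable), `mean_xi`, `sd_xi`.
#' @export
aggregate_genic <- function(calls, min_females = 1, escape_lo = 2 / 9,
                            escape_hi = 7 / 9, bimodal_fraction = 0.75) {
  out <- calls |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_females = dplyr::n(),
      frac_escaping = mean(.data$status != "S"),
      mean_xi = mean(.data$xi),
      sd_xi = stats::sd(.data$xi),
      subtype = variable_subtype(.data$status, bimodal_fraction),
      .groups = "drop") |>
    dplyr::filter(.data$n_females >= min_females) |>
    dplyr::mutate(
      status = factor(
        dplyr::case_when(
          .data$frac_escaping >= escape_hi ~ "escape",
          .data$frac_escaping <= escape_lo ~ "subject",
          TRUE ~ "variable_escape"),
        levels = genic_status_levels()),
      subtype = ifelse(.data$status == "variable_escape", .data$subtype,
                       NA_character_)) |>
    dplyr::select("gene", "n_females", "frac_escaping", "status",
                  "subtype", "mean_xi", "sd_xi")
  class(out) <- c("genic_xci", class(out))
  out
}

#' Subtype of a variable-escape call pattern
#'
#' @param statuses Factor/character vector of per-female calls (E1/E2/E3/S).
#' @param bimodal_fraction Minimum fraction of calls in `{E1, S}`.
#' @return One of `"bimodal"`, `"borderline"`, `"heterogeneous"`.
#' @export
variable_subtype <- function(statuses, bimodal_fraction = 0.75) {
  s <- as.character(statuses)
  extreme <- mean(s %in% c("E1", "S"))
  if (extreme >= bimodal_fraction && any(s == "E1") && any(s == "S")) {
    "bimodal"
  } else if (all(s %in% c("S", "E3"))) {
    "borderline"
  } else {
    "heterogeneous"
  }
}

#' Expression classes anchored on the PAR1 %Xi range
#'
#' PAR1 genes escape XCI with the highest Xi expression observed; the span
#' of their mean %Xi defines a reference range. Escape genes whose mean %Xi
#' reaches the bottom of that range are `escape_in_PAR1_range`, other escape
#' genes `escape_outside_PAR1_range`; subject genes split at 5% Xi
#' expression into `subject_ge5` and `subject_lt5`. Variable-escape genes
#' get no class (`NA`).
#'
#' @param genic [aggregate_genic()] output.
#' @param par1_genes Character vector of PAR1 gene ids.
#' @param subject_split Xi level splitting subject genes (default 0.05,
#'   inclusive on the high side).
#' @return `genic` with an added `expression_class` column and attribute
#'   `"par1_range"` (length-2 numeric, NA when no PAR1 gene is informative).
#' @export
par1_range_classes <- function(genic, par1_genes, subject_split = 0.05) {
  par1_xi <- genic$mean_xi[genic$gene %in% par1_genes]
  if (length(par1_xi) == 0) {
    warning("no informative PAR1 genes; escape genes not split by range",
            call. = FALSE)
    rng <- c(NA_real_, NA_real_)
  } else {
    rng <- range(par1_xi)
  }
  genic$expression_class <- dplyr::case_when(
    genic$status == "escape" & !is.na(rng[1]) & genic$mean_xi >= rng[1] ~
      "escape_in_PAR1_range",
    genic$status == "escape" ~ "escape_outside_PAR1_range",
    genic$status == "subject" & genic$mean_xi >= subject_split ~
      "subject_ge5",
    genic$status == "subject" ~ "subject_lt5",
    TRUE ~ NA_character_)
  attr(genic, "par1_range") <- rng
  genic
}
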