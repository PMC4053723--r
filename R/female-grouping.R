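#' Per-gene, per-female mean allelic imbalance
#'
#' Collapses informative probe measurements into one AI value per gene per
#' female: the unweighted mean of per-probe `|frac_cdna - 0.5|`. Genes with
#' fewer than `min_probes` informative probes in a female are dropped, since
#' a single probe cannot be checked for internal consistency.
#'
#' @param probes Probe table (post-QC, expression channel).
#' @param min_probes Minimum informative probes per gene per female
#'   (default 2).
#' @return Tibble: `gene`, `sample_id`, `sample_set`, `ai`, `n_probes`.
#' @export
gene_female_ai <- function(probes, min_probes = 2) {
  probes |>
    dplyr::filter(.data$informative, !is.na(.data$gene)) |>
    dplyr::group_by(.data$gene, .data$sample_id, .data$sample_set) |>
    dplyr::summarise(ai = mean(abs(.data$frac_cdna - 0.5)),
                     n_probes = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_probes >= min_probes)
}

#' Autosomal AI quantile thresholds per sample set
#'
#' The AI distribution of informative autosomal probes calibrates what
#' counts as "balanced" in each sample set: the 90th and 95th percentiles
#' become the E1:E2 and E2:E3 escape boundaries and the 99.5th percentile is
#' the group-1 / mono-allelic threshold (the AI exceeded by only 0.5% of
#' autosomal probes).
#'
#' @param probes Probe table (post-QC); autosomal rows are those with
#'   `is.na(gene)`.
#' @param quantiles Three probabilities, default `c(0.90, 0.95, 0.995)`.
#' @return Tibble: `sample_set`, `q90`, `q95`, `q995`.
#' @export
autosomal_thresholds <- function(probes, quantiles = c(0.90, 0.95, 0.995)) {
  stopifnot(length(quantiles) == 3, !is.unsorted(quantiles))
  auto <- probes |>
    dplyr::filter(.data$informative, is.na(.data$gene))
  if (nrow(auto) == 0) {
    stop("no informative autosomal probes to calibrate thresholds",
         call. = FALSE)
  }
  auto |>
    dplyr::group_by(.data$sample_set) |>
    dplyr::summarise(
      q90 = stats::quantile(abs(.data$frac_cdna - 0.5), quantiles[1],
                            names = FALSE),
      q95 = stats::quantile(abs(.data$frac_cdna - 0.5), quantiles[2],
                            names = FALSE),
      q995 = stats::quantile(abs(.data$frac_cdna - 0.5), quantiles[3],
                             names = FALSE),
      .groups = "drop")
}

#' Average genic AI over a training-set gene list
#'
#' The mean, over training genes with at least `min_probes` informative
#' probes in the female, of the per-gene mean AI. This is the quantity that
#' estimates skewing when computed over the subject training set.
#'
#' @param gene_ai Output of [gene_female_ai()].
#' @param training_genes Character vector of training gene ids.
#' @param min_probes Minimum informative probes per gene (already enforced
#'   by [gene_female_ai()]; repeated here for stand-alone use).
#' @return Tibble: `sample_id`, `sample_set`, `avg_training_ai` (NA when no
#'   gene qualifies), `n_training_genes`.
#' @export
average_training_ai <- function(gene_ai, training_genes, min_probes = 2) {
  gene_ai |>
    dplyr::filter(.data$n_probes >= min_probes) |>
    dplyr::group_by(.data$sample_id, .data$sample_set) |>
    dplyr::summarise(
      avg_training_ai = mean(.data$ai[.data$gene %in% training_genes]),
      n_training_genes = sum(.data$gene %in% training_genes),
      .groups = "drop") |>
    dplyr::mutate(avg_training_ai = ifelse(.data$n_training_genes == 0,
                                           NA_real_,
                                           .data$avg_training_ai))
}

#' Classify females into skewing groups 1, 2 and R
#'
#' Group 1: average subject-training AI strictly greater than the sample
#' set's autosomal 99.5% threshold (highly skewed XCI). Remaining females
#' are regressed, gene by gene, against the mean per-gene AI of the group-1
#' females of their sample set, restricted to genes whose group-1 genic call
#' is consistently subject or escape; a significant slope (p <= `alpha`)
#' indicates detectable partial skewing (group 2), otherwise XCI is
#' effectively random (group R). Skew estimates (`0.5 + avg_subject_ai`) are
#' reported for groups 1 and 2 only; AI carries no Xi information in group R.
#'
#' @param gene_ai Output of [gene_female_ai()] on post-QC probes.
#' @param subject_training Character vector of subject training gene ids.
#' @param thresholds Output of [autosomal_thresholds()].
#' @param alpha Slope-test significance level for group 2 (default 0.05).
#' @param min_regression_genes Minimum consistent genes shared with the
#'   group-1 reference for the regression to be attempted (default 10).
#' @return Tibble of class `female_profiles` (one row per female):
#'   `sample_id`, `sample_set`, `avg_subject_ai`, `n_training_genes`,
#'   `group` (`"1"`, `"2"`, `"R"`), `skew`, `slope`, `intercept`,
#'   `p_value`, `n_regression_genes`.
#' @export
classify_females <- function(gene_ai, subject_training, thresholds,
                             alpha = 0.05, min_regression_genes = 10) {
  prof <- average_training_ai(gene_ai, subject_training) |>
    dplyr::left_join(thresholds, by = "sample_set") |>
    dplyr::rename(avg_subject_ai = "avg_training_ai") |>
    dplyr::mutate(group = ifelse(!is.na(.data$avg_subject_ai) &
                                   .data$avg_subject_ai > .data$q995,
                                 "1", NA_character_))

  # group-1 reference per sample set: mean per-gene AI over group-1 females,
  # restricted to genes with a consistent (subject or escape) group-1 call
  out <- prof |>
    dplyr::group_by(.data$sample_set) |>
    dplyr::group_map(function(d, key) {
      set <- key$sample_set
      g1 <- d$sample_id[!is.na(d$group) & d$group == "1"]
      if (length(g1) == 0) {
        warning("no group-1 females in sample set '", set,
                "'; remaining females assigned group R", call. = FALSE)
        d$group[is.na(d$group)] <- "R"
        d$slope <- NA_real_; d$intercept <- NA_real_
        d$p_value <- NA_real_; d$n_regression_genes <- 0L
        return(d)
      }
      set_ai <- dplyr::filter(gene_ai, .data$sample_set == set)
      consistent <- consistent_group1_genes(set_ai, d, g1)
      ref <- set_ai |>
        dplyr::filter(.data$sample_id %in% g1,
                      .data$gene %in% consistent) |>
        dplyr::group_by(.data$gene) |>
        dplyr::summarise(ref_ai = mean(.data$ai), .groups = "drop")
      fits <- lapply(d$sample_id, function(sid) {
        if (sid %in% g1) {
          return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                                p_value = NA_real_,
                                n_regression_genes = NA_integer_))
        }
        y <- set_ai |>
          dplyr::filter(.data$sample_id == sid) |>
          dplyr::inner_join(ref, by = "gene")
        if (nrow(y) < min_regression_genes) {
          return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                                p_value = NA_real_,
                                n_regression_genes = nrow(y)))
        }
        fit <- stats::lm(ai ~ ref_ai, data = y)
        cf <- summary(fit)$coefficients
        tibble::tibble(slope = cf["ref_ai", "Estimate"],
                       intercept = cf["(Intercept)", "Estimate"],
                       p_value = cf["ref_ai", "Pr(>|t|)"],
                       n_regression_genes = nrow(y))
      })
      d <- dplyr::bind_cols(d, purrr::list_rbind(fits))
      d$group[is.na(d$group)] <- ifelse(
        !is.na(d$p_value[is.na(d$group)]) &
          d$p_value[is.na(d$group)] <= alpha, "2", "R")
      d$sample_set <- set
      d
    }, .keep = TRUE) |>
    purrr::list_rbind()

  out <- out |>
    dplyr::mutate(skew = ifelse(.data$group %in% c("1", "2"),
                                skew_from_subject_ai(
                                  pmin(.data$avg_subject_ai, 0.5)),
                                NA_real_)) |>
    dplyr::select("sample_id", "sample_set", "avg_subject_ai",
                  "n_training_genes", "group", "skew", "slope",
                  "intercept", "p_value", "n_regression_genes")
  class(out) <- c("female_profiles", class(out))
  out
}

# Genes whose genic call across the group-1 females of a set is consistently
# subject or escape (not variable): used as the regression reference.
consistent_group1_genes <- function(set_ai, profiles, group1_ids) {
  g1prof <- profiles[profiles$sample_id %in% group1_ids, ]
  skew <- skew_from_subject_ai(pmin(g1prof$avg_subject_ai, 0.5))
  e3s <- stats::setNames(expected_ai(skew, 0.10), g1prof$sample_id)
  calls <- set_ai |>
    dplyr::filter(.data$sample_id %in% group1_ids) |>
    dplyr::mutate(escape = .data$ai < e3s[.data$sample_id])
  calls |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(frac = mean(.data$escape), .groups = "drop") |>
    dplyr::filter(.data$frac <= 2 / 9 | .data$frac >= 7 / 9) |>
    dplyr::pull(.data$gene)
}

#' Grubbs outlier test for group-R females
#'
#' Maximum-normed-residual test on the average genic AIs of the group-R
#' females of one sample set, one-sided toward high AI by default (a
#' "random-XCI" female with an unusually high AI is likely misclassified and
#' would contaminate the mono-allelic imprinting screen). The p-value uses
#' the standard t transformation of the Grubbs statistic.
#'
#' @param x Numeric vector of average genic AIs (one per group-R female).
#' @param alpha Significance level (default 0.05).
#' @param two_sided Test the largest absolute deviation instead of the
#'   largest positive one.
#' @return List of class `grubbs_test`: `z` (statistic; 0 when the sample
#'   standard deviation is 0), `p_value`, `outlier_index` (index of the
#'   flagged value, or `NA`), `applicable` (`FALSE` when `n < 3`).
#' @export
grubbs_outlier <- function(x, alpha = 0.05, two_sided = FALSE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) {
    return(structure(list(z = NA_real_, p_value = NA_real_,
                          outlier_index = NA_integer_, applicable = FALSE),
                     class = "grubbs_test"))
  }
  s <- stats::sd(x)
  if (s < 1e-12) {
    return(structure(list(z = 0, p_value = 1,
                          outlier_index = NA_integer_, applicable = TRUE),
                     class = "grubbs_test"))
  }
  dev <- if (two_sided) abs(x - mean(x)) else x - mean(x)
  idx <- which.max(dev)
  z <- dev[idx] / s
  # p-value via the t transformation of the maximum normed residual
  tsq <- (n * (n - 2) * z^2) / ((n - 1)^2 - n * z^2)
  p <- if (tsq < 0) 0 else {
    n * stats::pt(sqrt(tsq), df = n - 2, lower.tail = FALSE) *
      (if (two_sided) 2 else 1)
  }
  p <- min(max(p, 0), 1)
  structure(list(z = unname(z), p_value = p,
                 outlier_index = if (p < alpha) idx else NA_integer_,
                 applicable = TRUE),
            class = "grubbs_test")
}

#' @export
print.grubbs_test <- function(x, ...) {
  if (!x$applicable) {
    cat("<grubbs_test> not applicable (n < 3)\n")
  } else {
    cat(sprintf("<grubbs_test> Z = %.4f, p = %.4g, outlier: %s\n",
                x$z, x$p_value,
                ifelse(is.na(x$outlier_index), "none",
                       paste("index", x$outlier_index))))
  }
  invisible(x)
}
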