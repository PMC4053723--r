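#' Fit the one-phase intensity decay of AI in homozygous females
#'
#' Homozygous (uninformative) probes should show no allelic imbalance, yet at
#' low total cDNA intensity measurement noise inflates their apparent AI.
#' This fits `AI = plateau + (y0 - plateau) * exp(-intensity / tau)` by
#' nonlinear least squares to the uninformative probes of one sample set; the
#' fitted `tau` is the sample-set-specific minimum-intensity threshold below
#' which probes are considered unreliable.
#'
#' For a homozygous probe the apparent AI is the deviation of the observed
#' allele-1 fraction from the nearer mono-allelic pole, `min(f, 1 - f)`.
#'
#' @param uninformative_probes Probe-table rows restricted to homozygous
#'   (`informative == FALSE`) females of one sample set; needs columns
#'   `intensity` and `frac_cdna`.
#' @param sample_set Label used in error messages.
#' @return An object of class `decay_fit`: list with `y0`, `plateau`, `tau`,
#'   `sigma` (residual standard error), `n`, `sample_set`, and the `nls` fit.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_females_per_set = 4, seed = 2))
#' homo <- dplyr::filter(cohort$probes, !informative, sample_set == "LCL1")
#' fit <- fit_intensity_decay(homo, "LCL1")
#' fit$tau
#' @export
fit_intensity_decay <- function(uninformative_probes, sample_set = "all") {
  dat <- tibble::tibble(
    intensity = uninformative_probes$intensity,
    ai = homozygous_ai(uninformative_probes$frac_cdna))
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 20) {
    stop("intensity-decay fit for sample set '", sample_set,
         "' needs >= 20 uninformative probes, got ", nrow(dat),
         call. = FALSE)
  }
  if (diff(range(dat$ai)) < 1e-12 || diff(range(dat$intensity)) < 1e-12) {
    stop("degenerate intensity-decay fit for sample set '", sample_set,
         "': AI or intensity shows no variation", call. = FALSE)
  }
  # data-driven starting values: extremes of the intensity range anchor y0
  # and the plateau; tau starts at the intensity of the half-way AI
  dec <- stats::quantile(dat$intensity, c(0.1, 0.9))
  y0_0 <- mean(dat$ai[dat$intensity <= dec[1]])
  pl_0 <- mean(dat$ai[dat$intensity >= dec[2]])
  half <- (y0_0 + pl_0) / 2
  ord <- order(dat$intensity)
  run_mean <- stats::filter(dat$ai[ord], rep(1 / 51, 51), sides = 2)
  tau_0 <- dat$intensity[ord][which(run_mean <= half)[1]]
  if (is.na(tau_0) || tau_0 <= 0) tau_0 <- stats::median(dat$intensity)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      ai ~ plateau + (y0 - plateau) * exp(-intensity / tau),
      data = dat,
      start = list(y0 = y0_0, plateau = pl_0, tau = tau_0),
      lower = c(y0 = 0, plateau = 0, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("intensity-decay fit failed to converge for sample set '",
           sample_set, "': ", conditionMessage(e), call. = FALSE)
    })
  est <- stats::coef(fit)
  structure(
    list(y0 = unname(est["y0"]), plateau = unname(est["plateau"]),
         tau = unname(est["tau"]), sigma = stats::sigma(fit),
         n = nrow(dat), sample_set = sample_set, fit = fit),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> set %s: tau = %.0f, y0 = %.4f, plateau = %.4f (n = %d)\n",
    x$sample_set, x$tau, x$y0, x$plateau, x$n))
  invisible(x)
}

# apparent AI of a homozygous probe: distance from the nearer mono-allelic
# pole of the allele-1 fraction
homozygous_ai <- function(frac) pmin(frac, 1 - frac)

#' Fit per-sample-set intensity thresholds (Tau)
#'
#' Convenience wrapper running [fit_intensity_decay()] on the homozygous
#' probes of every sample set in a probe table.
#'
#' @param probes Probe table (expression channel).
#' @return Tibble: `sample_set`, `tau`, `y0`, `plateau`, `n`.
#' @export
fit_tau_thresholds <- function(probes) {
  probes |>
    dplyr::filter(.data$channel == "expression", !.data$informative) |>
    dplyr::group_by(.data$sample_set) |>
    dplyr::group_map(function(d, key) {
      f <- fit_intensity_decay(d, key$sample_set)
      tibble::tibble(sample_set = key$sample_set, tau = f$tau, y0 = f$y0,
                     plateau = f$plateau, n = f$n)
    }) |>
    purrr::list_rbind()
}

#' Remove probes below the sample-set intensity threshold
#'
#' Retains probe measurements whose total cDNA intensity is strictly greater
#' than their sample set's Tau, per the strict "greater than" rule.
#'
#' @param probes Probe table.
#' @param tau Tibble with columns `sample_set`, `tau` (e.g. from
#'   [fit_tau_thresholds()]), or a single number applied to all sets.
#' @return List of class `probe_filter`: `probes` (surviving rows) and
#'   `report` (tibble of per-set excluded/retained counts, rule
#'   `"low_intensity"`).
#' @export
apply_intensity_filter <- function(probes, tau) {
  if (is.numeric(tau) && is.null(dim(tau))) {
    tau <- tibble::tibble(sample_set = unique(probes$sample_set),
                          tau = tau[1])
  }
  missing <- setdiff(unique(probes$sample_set), tau$sample_set)
  if (length(missing) > 0) {
    stop("no tau threshold for sample set(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::left_join(probes, tau[, c("sample_set", "tau")],
                             by = "sample_set")
  keep <- joined$intensity > joined$tau
  report <- joined |>
    dplyr::mutate(kept = ifelse(keep, "retained", "excluded")) |>
    dplyr::count(.data$sample_set, .data$kept) |>
    tidyr::pivot_wider(names_from = "kept", values_from = "n",
                       values_fill = 0L)
  for (col in c("retained", "excluded")) {
    if (!col %in% names(report)) report[[col]] <- 0L
  }
  report$rule <- "low_intensity"
  structure(list(probes = probes[keep, , drop = FALSE],
                 report = report[, c("sample_set", "rule", "excluded",
                                     "retained")]),
            class = "probe_filter")
}

#' Flag probes with a biased genomic-DNA allele ratio
#'
#' A probe is excluded globally (from all sample sets) if, in any single
#' sample set, at least half of its informative females show a genomic-DNA
#' allele ratio whose major-allele fraction exceeds `cutoff`. Such probes
#' have a hybridisation bias that mimics mono-allelic expression.
#'
#' @param probes Probe table (expression channel; genomic-DNA fractions in
#'   the `frac_gdna` column).
#' @param cutoff Major-allele genomic-DNA fraction above which a female's
#'   ratio counts as biased (default 0.7).
#' @param prevalence Minimum fraction of informative females that must be
#'   biased within one sample set (default 0.5).
#' @return Character vector of excluded probe ids.
#' @export
flag_gdna_biased_probes <- function(probes, cutoff = 0.7,
                                    prevalence = 0.5) {
  check_range(probes$frac_gdna, 0, 1, "frac_gdna")
  probes |>
    dplyr::filter(.data$informative) |>
    dplyr::group_by(.data$probe_id, .data$sample_set) |>
    dplyr::summarise(
      biased = mean(pmax(.data$frac_gdna, 1 - .data$frac_gdna) > cutoff),
      .groups = "drop") |>
    dplyr::filter(.data$biased >= prevalence) |>
    dplyr::pull(.data$probe_id) |>
    unique()
}

#' Run the full probe-exclusion stage
#'
#' Fits per-sample-set Tau thresholds on homozygous probes (unless supplied),
#' removes low-intensity measurements, then drops genomic-DNA-biased probes
#' in every sample set.
#'
#' @param probes Probe table.
#' @param tau Optional precomputed tau tibble; fitted when `NULL`.
#' @param gdna_cutoff,gdna_prevalence Passed to [flag_gdna_biased_probes()].
#' @return List of class `probe_qc`: `probes` (surviving measurements),
#'   `tau` (threshold tibble), `report` (exclusion counts per rule and set),
#'   `gdna_excluded` (probe ids).
#' @export
run_probe_qc <- function(probes, tau = NULL, gdna_cutoff = 0.7,
                         gdna_prevalence = 0.5) {
  expr <- dplyr::filter(probes, .data$channel == "expression")
  if (is.null(tau)) tau <- fit_tau_thresholds(expr)
  flt <- apply_intensity_filter(expr, tau)
  gdna_bad <- flag_gdna_biased_probes(flt$probes, gdna_cutoff,
                                      gdna_prevalence)
  gdna_report <- flt$probes |>
    dplyr::mutate(kept = !.data$probe_id %in% gdna_bad) |>
    dplyr::group_by(.data$sample_set) |>
    dplyr::summarise(excluded = sum(!.data$kept),
                     retained = sum(.data$kept), .groups = "drop") |>
    dplyr::mutate(rule = "gdna_ratio")
  surviving <- dplyr::filter(flt$probes, !.data$probe_id %in% gdna_bad)
  structure(
    list(probes = surviving, tau = tau,
         report = dplyr::bind_rows(
           flt$report,
           gdna_report[, c("sample_set", "rule", "excluded", "retained")]),
         gdna_excluded = gdna_bad),
    class = "probe_qc")
}

#' @export
print.probe_qc <- function(x, ...) {
  cat("<probe_qc>", nrow(x$probes), "surviving measurements\n")
  print(x$report)
  invisible(x)
}

#' Concordance of probe pairs within two-probe genes
#'
#' For genes with exactly two surviving probes, checks per informative
#' female whether the two probes yield the same subject-vs-escape call at
#' that female's E3:S boundary (`definition = "call"`), or agree within an
#' absolute AI tolerance (`definition = "delta"`). Each gene's discordant
#' count is then tested against the cohort-wide discordance rate with a
#' one-sample chi-square test, flagging genes enriched for discordant
#' probes.
#'
#' @param probes Surviving probe table (post-QC, expression channel).
#' @param boundaries Tibble from [female_boundaries()]: one row per group-1/2
#'   female with the `e3_s` boundary. Only females present here are used.
#' @param definition `"call"` (default) or `"delta"`.
#' @param delta AI tolerance when `definition = "delta"`.
#' @param alpha Significance level for the enrichment flag.
#' @return List of class `probe_concordance`: `per_gene` tibble (gene,
#'   n_females, n_discordant, concordance, statistic, p_value, flagged),
#'   `overall_concordance`, `definition`.
#' @export
probe_concordance <- function(probes, boundaries, definition = c("call",
                                                                 "delta"),
                              delta = 0.1, alpha = 0.05) {
  definition <- match.arg(definition)
  two_probe <- probes |>
    dplyr::filter(.data$informative, !is.na(.data$gene)) |>
    dplyr::distinct(.data$gene, .data$probe_id) |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n == 2)
  dat <- probes |>
    dplyr::filter(.data$informative, .data$gene %in% two_probe$gene) |>
    dplyr::mutate(ai = abs(.data$frac_cdna - 0.5)) |>
    dplyr::inner_join(boundaries[, c("sample_id", "e3_s")],
                      by = "sample_id") |>
    dplyr::group_by(.data$gene, .data$sample_id) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(
      discordant = if (definition == "call") {
        sum(.data$ai >= .data$e3_s) == 1
      } else {
        abs(diff(.data$ai)) >= delta
      },
      .groups = "drop")
  if (nrow(dat) == 0) {
    return(structure(list(per_gene = tibble::tibble(),
                          overall_concordance = NA_real_,
                          definition = definition),
                     class = "probe_concordance"))
  }
  p0 <- mean(dat$discordant)
  per_gene <- dat |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_females = dplyr::n(),
                     n_discordant = sum(.data$discordant),
                     .groups = "drop") |>
    dplyr::mutate(
      concordance = 1 - .data$n_discordant / .data$n_females,
      test = purrr::map2(.data$n_discordant, .data$n_females, function(d, n) {
        if (p0 <= 0 || p0 >= 1) {
          return(tibble::tibble(statistic = 0, p_value = 1))
        }
        tt <- suppressWarnings(
          stats::chisq.test(c(d, n - d), p = c(p0, 1 - p0)))
        tibble::tibble(statistic = unname(tt$statistic),
                       p_value = unname(tt$p.value))
      })) |>
    tidyr::unnest("test") |>
    dplyr::mutate(flagged = .data$p_value < alpha &
                    .data$n_discordant / .data$n_females > p0)
  structure(list(per_gene = per_gene, overall_concordance = 1 - p0,
                 definition = definition),
            class = "probe_concordance")
}

#' @export
print.probe_concordance <- function(x, ...) {
  cat(sprintf(
    "<probe_concordance> %.1f%% concordant (definition: %s), %d genes, %d flagged\n",
    100 * x$overall_concordance, x$definition, nrow(x$per_gene),
    sum(x$per_gene$flagged %||% FALSE)))
  invisible(x)
}
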