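#' Forward model: allelic imbalance expected at a given skew and Xi expression
#'
#' Computes the allelic imbalance (AI) expected at an X-linked locus in a
#' female whose XCI is skewed so that a fraction `skew` of cells carry the
#' majority X as the active X, when the gene is expressed from the inactive X
#' at `xi` times the active-X level (Xa expression is normalised to 1).
#'
#' With `s = skew` and `e = xi`, the expected allele-1 expression fraction is
#' `f = (s + e * (1 - s)) / (1 + e)` and `AI = |f - 0.5|`, which simplifies to
#' `AI = |s - 0.5| * |1 - e| / (1 + e)`. AI is 0 for a balanced locus and 0.5
#' for mono-allelic expression. Allele labelling is arbitrary, so only the
#' absolute deviation is meaningful.
#'
#' @param skew Numeric vector of skew fractions in `[0.5, 1]`: the proportion
#'   of cells with the majority X active.
#' @param xi Numeric vector of Xi expression levels `>= 0`, as a fraction of
#'   the Xa level (1 = Xi expresses at the Xa level).
#' @return Numeric vector of AI values in `[0, 0.5]`.
#' @examples
#' expected_ai(0.8891, 0.10)  # ~0.3184
#' expected_ai(0.5, 0.3)      # random XCI is always balanced
#' @seealso [xi_from_ai()] for the inverse, [skew_from_subject_ai()].
#' @export
expected_ai <- function(skew, xi) {
  check_range(skew, 0.5, 1, "skew")
  if (any(xi < 0, na.rm = TRUE)) {
    stop("`xi` must be >= 0 (Xi expression as a fraction of Xa)", call. = FALSE)
  }
  f <- (skew + xi * (1 - skew)) / (1 + xi)
  abs(f - 0.5)
}

#' Invert the AI model: Xi expression implied by an observed AI
#'
#' Solves the forward model for the Xi:Xa expression ratio given an observed
#' AI and the female's skew. AIs larger than the skew can explain (i.e. above
#' `skew - 0.5`, typically from an underestimated skew) would yield a negative
#' solution; these are clamped to 0 so downstream consumers never see a
#' negative %Xi.
#'
#' @param ai Numeric vector of AI values in `[0, 0.5]`.
#' @param skew Numeric vector of skew fractions, strictly greater than 0.5
#'   (the inversion is undefined under random XCI; group-R females must not
#'   be passed here).
#' @return Numeric vector of Xi expression levels (fraction of Xa, `>= 0`).
#' @examples
#' xi_from_ai(0.3184, 0.8891)  # ~0.10
#' xi_from_ai(0.45, 0.8891)    # 0, clamped
#' @export
xi_from_ai <- function(ai, skew) {
  check_range(ai, 0, 0.5, "ai")
  if (any(skew <= 0.5, na.rm = TRUE)) {
    stop("inversion undefined at skew <= 0.5: AI carries no Xi information ",
         "under random XCI (group-R females)", call. = FALSE)
  }
  check_range(skew, 0.5, 1, "skew")
  f <- 0.5 + ai
  e <- (skew - f) / (f + skew - 1)
  pmax(e, 0)
}

#' Skew implied by the average AI of genes subject to XCI
#'
#' Genes fully silenced on the inactive X (`xi = 0`) have `AI = skew - 0.5`,
#' so the average genic AI over a subject-gene training set estimates the
#' female's skew as `0.5 + AI`.
#'
#' @param avg_subject_ai Numeric vector of average genic AI values in
#'   `[0, 0.5]`.
#' @return Skew fraction in `[0.5, 1]`.
#' @examples
#' skew_from_subject_ai(0.3891)  # 0.8891, i.e. 88.91% skewed
#' @export
skew_from_subject_ai <- function(avg_subject_ai) {
  check_range(avg_subject_ai, 0, 0.5, "avg_subject_ai")
  0.5 + avg_subject_ai
}

# per-female call levels, ordered from highest Xi expression to silenced
xci_status_levels <- function() c("E1", "E2", "E3", "S")

# genic statuses and variable-escape subtypes
genic_status_levels <- function() c("subject", "variable_escape", "escape")
variable_subtype_levels <- function() c("bimodal", "borderline", "heterogeneous")
expression_class_levels <- function() {
  c("escape_in_PAR1_range", "escape_outside_PAR1_range",
    "subject_ge5", "subject_lt5")
}

check_range <- function(x, lo, hi, name) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop(sprintf("`%s` must lie in [%s, %s]; offending value: %.6g",
                 name, format(lo), format(hi), x[which(bad)[1]]),
         call. = FALSE)
  }
  invisible(x)
}
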