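#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an intensity-decay fit
#'
#' @param x A `decay_fit` from [fit_intensity_decay()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std_error`.
#' @export
tidy.decay_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                 std_error = cf[, "Std. Error"])
}

#' @rdname tidy.decay_fit
#' @return `glance()`: one row with `tau`, `y0`, `plateau`, `sigma`, `n`,
#'   `sample_set`.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, y0 = x$y0, plateau = x$plateau,
                 sigma = x$sigma, n = x$n, sample_set = x$sample_set)
}

#' Tidy an adjacency chi-square test
#'
#' @param x An `adjacency_test` from [adjacency_chi_square()].
#' @param ... Unused.
#' @return Per-pair tibble with `pair`, `observed`, `expected`,
#'   `component`, `std_residual`.
#' @export
tidy.adjacency_test <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("pair", "observed", "expected",
                                 "component", "std_residual")])
}

#' @rdname tidy.adjacency_test
#' @return `glance()`: one row with `statistic`, `df`, `p_value`.
#' @export
glance.adjacency_test <- function(x, ...) {
  tibble::tibble(statistic = attr(x, "statistic"), df = attr(x, "df"),
                 p_value = attr(x, "p_value"))
}

#' Tidy a Grubbs outlier test
#'
#' @param x A `grubbs_test` from [grubbs_outlier()].
#' @param ... Unused.
#' @return One-row tibble: `z`, `p_value`, `outlier_index`, `applicable`.
#' @export
tidy.grubbs_test <- function(x, ...) {
  tibble::tibble(z = x$z, p_value = x$p_value,
                 outlier_index = x$outlier_index,
                 applicable = x$applicable)
}
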