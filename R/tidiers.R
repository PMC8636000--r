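#' Tidy a meta-regression fit
#'
#' One row per coefficient with its estimate, uncertainty, and interval
#' (t-based confidence interval for OLS, equal-tailed 95% credible interval
#' for the Bayesian fit).
#'
#' @param x A `florsel_meta_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.florsel_meta_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    conf.low = unname(x$conf.low),
    conf.high = unname(x$conf.high)
  )
}

#' One-row summary of a meta-regression fit
#'
#' @param x A `florsel_meta_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `method`, `ic_type`, `ic`, `p.value`,
#'   `vertex`, `n` (and `rhat_max` for Bayesian fits).
#' @export
glance.florsel_meta_fit <- function(x, ...) {
  out <- tibble::tibble(
    model = x$model,
    method = x$method,
    ic_type = x$ic_type,
    ic = x$ic,
    p.value = x$p,
    vertex = x$vertex,
    n = x$n
  )
  if (x$method == "bayes") out$rhat_max <- max(x$rhat, na.rm = TRUE)
  out
}

#' @export
tidy.florsel_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("term", "df", "sumsq", "meansq",
                                 "statistic", "p.value")])
}
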