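meta_design <- function(x, degree) {
  stopifnot(degree %in% 1:2)
  X <- cbind(1, x)
  if (degree == 2) X <- cbind(X, x^2)
  colnames(X) <- c("c0", "c1", "c2")[seq_len(degree + 1)]
  X
}

new_meta_fit <- function(x) structure(x, class = "florsel_meta_fit")

#' Ordinary least squares meta-regression with AIC
#'
#' Regresses an across-population response (the opportunity for selection,
#' or the absolute mediated selection gradient) on herbivory intensity `x`
#' (original scale), either linearly (`degree = 1`) or with a quadratic term
#' (`degree = 2`). Returns the coefficients, their SEs and 95% confidence
#' intervals, the Gaussian AIC, the overall F-test p-value, and — for
#' quadratic fits with a nonzero curvature — the vertex `-c1 / (2 c2)` of
#' the fitted parabola. Candidate fits of different degree on the same
#' points are compared by AIC: the lowest AIC fits best.
#'
#' @param points A tibble with columns `x` and `y` (an `se` column, if
#'   present, is ignored: OLS treats the response as error-free).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return A `florsel_meta_fit` object.
#' @seealso [bayes_meta()] for the measurement-error counterpart,
#'   [curve_vertex()].
#' @export
#' @examples
#' pts <- tibble::tibble(x = seq(0.1, 0.6, length.out = 11))
#' pts$y <- 0.135 + 5.4429 * pts$x - 6.3298 * pts$x^2
#' glance(ols_meta(pts, degree = 2))
ols_meta <- function(points, degree = 2) {
  stopifnot(degree %in% 1:2, all(c("x", "y") %in% names(points)))
  n <- nrow(points)
  if (n < degree + 2) {
    abort(paste0("need at least ", degree + 2, " points for degree ", degree),
          class = "florsel_design_error")
  }
  d <- tibble::tibble(x = points$x, y = points$y)
  fit <- if (degree == 1) lm(y ~ x, data = d) else lm(y ~ x + I(x^2), data = d)
  if (fit$rank < degree + 1) {
    abort("rank-deficient design (duplicate x values?)",
          class = "florsel_design_error")
  }
  cf <- setNames(coef(fit), c("c0", "c1", "c2")[seq_len(degree + 1)])
  sm <- suppressWarnings(summary(fit))  # "essentially perfect fit" is fine
  se <- setNames(sm$coefficients[, "Std. Error"], names(cf))
  tcrit <- stats::qt(0.975, df.residual(fit))
  fstat <- sm$fstatistic
  p_overall <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  vertex <- if (degree == 2 && is.finite(cf["c2"]) && cf["c2"] != 0) {
    unname(-cf["c1"] / (2 * cf["c2"]))
  } else {
    NA_real_
  }
  new_meta_fit(list(
    model = if (degree == 1) "linear" else "quadratic",
    method = "ols",
    degree = degree,
    coefficients = cf,
    se = se,
    conf.low = cf - tcrit * se,
    conf.high = cf + tcrit * se,
    ic = stats::AIC(fit),
    ic_type = "AIC",
    p = p_overall,
    vertex = vertex,
    n = n,
    r.squared = sm$r.squared,
    points = points,
    fit = fit
  ))
}

#' Bayesian measurement-error meta-regression with DIC
#'
#' Hierarchical model for summary-level effect sizes with known sampling
#' error: `y_j ~ Normal(theta_j, se_j^2)` with `se_j` fixed, and `theta_j ~
#' Normal(c0 + c1 x_j (+ c2 x_j^2), sigma2)`. Priors are a diffuse normal on
#' the regression coefficients (variance `beta_prior_var`) and
#' inverse-gamma(`ig_shape`, `ig_scale`) on the residual variance. All full
#' conditionals are conjugate, so the model is fitted by a Gibbs sampler
#' (compiled). Model support is summarised by the deviance information
#' criterion with the Spiegelhalter effective-parameter count, `DIC = Dbar +
#' pD`, `pD = Dbar - D(posterior means)`, where the deviance is evaluated on
#' the marginal likelihood `y_j ~ Normal(x_j'c, sigma2 + se_j^2)`; the lowest
#' DIC among candidate degrees fits best.
#'
#' Convergence is monitored by the potential scale reduction factor across
#' chains; `rhat > 1.1` on any coefficient attaches a warning. The fit is
#' exactly reproducible for a fixed `seed` and chain configuration.
#'
#' @param points A tibble with columns `x`, `y`, and positive `se`.
#' @param degree 1 (linear) or 2 (quadratic).
#' @param chains,iter,burnin,thin MCMC configuration (defaults: 2 chains of
#'   13000 iterations, 3000 burn-in, thinning 10).
#' @param seed Integer seed; chain sub-seeds are derived from it.
#' @param beta_prior_var Prior variance of the coefficients (default `1e8`,
#'   effectively flat).
#' @param ig_shape,ig_scale Inverse-gamma prior on the residual variance
#'   (default 0.001, 0.001, weakly informative).
#' @return A `florsel_meta_fit` object with posterior means, 95% credible
#'   intervals, `ic` (DIC), `pd`, `rhat`, `n_draws`, `vertex`, and the
#'   retained draws.
#' @export
bayes_meta <- function(points, degree = 2, chains = 2, iter = 13000,
                       burnin = 3000, thin = 10, seed = 1L,
                       beta_prior_var = 1e8,
                       ig_shape = 0.001, ig_scale = 0.001) {
  stopifnot(degree %in% 1:2, all(c("x", "y", "se") %in% names(points)),
            chains >= 1, iter > burnin, thin >= 1)
  if (anyNA(points$se) || any(points$se <= 0)) {
    abort("bayes_meta needs a positive sampling SE for every point",
          class = "florsel_domain_error")
  }
  n <- nrow(points)
  if (n < degree + 2) {
    abort(paste0("need at least ", degree + 2, " points for degree ", degree),
          class = "florsel_design_error")
  }
  X <- meta_design(points$x, degree)
  y <- points$y
  se2 <- points$se^2

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  runs <- lapply(seq_len(chains), function(ch) {
    set.seed(chain_seeds[ch])
    gibbs_me_chain(y, X, se2, as.integer(iter), as.integer(burnin),
                   as.integer(thin), beta_prior_var, ig_shape, ig_scale)
  })

  beta_draws <- do.call(rbind, lapply(runs, `[[`, "beta"))
  colnames(beta_draws) <- colnames(X)
  sigma2_draws <- unlist(lapply(runs, `[[`, "sigma2"))
  dev_draws <- unlist(lapply(runs, `[[`, "deviance"))

  cf <- colMeans(beta_draws)
  sigma2_hat <- mean(sigma2_draws)
  v_hat <- sigma2_hat + se2
  dev_hat <- sum(log(2 * pi * v_hat) + (y - drop(X %*% cf))^2 / v_hat)
  dbar <- mean(dev_draws)
  pd <- dbar - dev_hat
  dic <- dbar + pd

  ci <- apply(beta_draws, 2, quantile, probs = c(0.025, 0.975))
  param_chains <- lapply(runs, function(r) cbind(r$beta, r$sigma2))
  rhat <- gelman_rhat(param_chains)
  names(rhat) <- c(colnames(X), "sigma2")
  if (chains >= 2 && any(rhat > 1.1, na.rm = TRUE)) {
    warn(paste0("possible non-convergence: max rhat = ",
                signif(max(rhat, na.rm = TRUE), 4)))
  }
  vertex <- if (degree == 2 && cf["c2"] != 0) unname(-cf["c1"] / (2 * cf["c2"]))
            else NA_real_

  new_meta_fit(list(
    model = if (degree == 1) "linear" else "quadratic",
    method = "bayes",
    degree = degree,
    coefficients = cf,
    se = apply(beta_draws, 2, sd),
    conf.low = ci[1, ],
    conf.high = ci[2, ],
    ic = dic,
    ic_type = "DIC",
    pd = pd,
    p = NA_real_,
    vertex = vertex,
    n = n,
    sigma2 = sigma2_hat,
    rhat = rhat,
    n_draws = nrow(beta_draws),
    draws = beta_draws,
    sigma2_draws = sigma2_draws,
    points = points,
    seed = seed,
    mcmc = list(chains = chains, iter = iter, burnin = burnin, thin = thin)
  ))
}

gelman_rhat <- function(chains) {
  m <- length(chains)
  if (m < 2) return(rep(NA_real_, ncol(chains[[1]])))
  n <- nrow(chains[[1]])
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    draws <- vapply(chains, function(ch) ch[, j], numeric(n))
    means <- colMeans(draws)
    W <- mean(apply(draws, 2, var))
    B <- n * var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Vertex of a fitted quadratic curve
#'
#' The stationary point `x* = -c1 / (2 c2)` of a quadratic fit, i.e. the
#' interaction intensity at which the fitted response peaks (`c2 < 0`,
#' `"maximum"`) or bottoms out (`c2 > 0`, `"minimum"`).
#'
#' @param fit A quadratic `florsel_meta_fit`, or a numeric coefficient
#'   vector `c(c0, c1, c2)`.
#' @return A one-row tibble with `x_star` and `kind`.
#' @export
#' @examples
#' curve_vertex(c(-0.206, 2.1713, -2.9216))$x_star  # ~0.3716
curve_vertex <- function(fit) {
  cf <- if (inherits(fit, "florsel_meta_fit")) fit$coefficients
        else as.numeric(fit)
  if (length(cf) < 3 || is.na(cf[3]) || cf[3] == 0) {
    abort("no vertex: fit has no (nonzero) quadratic term",
          class = "florsel_no_vertex_error")
  }
  tibble::tibble(
    x_star = unname(-cf[2] / (2 * cf[3])),
    kind = if (cf[3] < 0) "maximum" else "minimum"
  )
}

#' @export
print.florsel_meta_fit <- function(x, ...) {
  cat(sprintf("%s %s meta-regression (n = %d)\n",
              switch(x$method, ols = "OLS", bayes = "Bayesian"),
              x$model, x$n))
  est <- cbind(estimate = x$coefficients, se = x$se,
               `2.5%` = x$conf.low, `97.5%` = x$conf.high)
  print(round(est, 5))
  cat(sprintf("%s = %.3f", x$ic_type, x$ic))
  if (!is.na(x$p)) cat(sprintf(", overall p = %.4g", x$p))
  if (!is.na(x$vertex)) cat(sprintf(", vertex at x = %.4f", x$vertex))
  cat("\n")
  invisible(x)
}
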