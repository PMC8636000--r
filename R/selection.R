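#' Relative fitness within a group
#'
#' Divides each individual's absolute fitness by the group mean, so the
#' returned vector has mean exactly 1. Selection gradients estimated on this
#' scale are comparable across populations and treatments.
#'
#' @param w Numeric vector of absolute fitness (e.g. total seeds per plant).
#' @return Numeric vector `w / mean(w)`.
#' @export
#' @examples
#' relativize_fitness(c(2, 4, 6))  # 0.5 1.0 1.5
relativize_fitness <- function(w) {
  if (length(w) < 1 || anyNA(w)) {
    abort("fitness vector must be non-empty and free of NA",
          class = "florsel_domain_error")
  }
  m <- mean(w)
  if (m <= 0) {
    abort("degenerate slice: mean fitness is not positive",
          class = "florsel_degenerate_slice_error")
  }
  w / m
}

#' Variance-standardize trait columns
#'
#' Column-wise `(x - mean) / sd` with the sample SD (n - 1 denominator), so
#' every column has mean 0 and variance 1. Regression coefficients of
#' relative fitness on these columns are selection gradients in units of
#' trait standard deviations.
#'
#' @param x Numeric matrix or data frame of trait values, one column per
#'   trait; at least 2 rows.
#' @return A numeric matrix of the same shape.
#' @export
#' @examples
#' standardize_traits(cbind(z = c(1, 2, 3)))  # -1 0 1
standardize_traits <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    abort("need at least 2 rows to standardize",
          class = "florsel_domain_error")
  }
  sds <- apply(x, 2, sd)
  degenerate <- which(!is.finite(sds) | sds <= 0)
  if (length(degenerate) > 0) {
    nm <- colnames(x)[degenerate]
    if (is.null(nm)) nm <- paste0("column ", degenerate)
    abort(paste0("zero-variance trait(s): ", paste(nm, collapse = ", ")),
          class = "florsel_degenerate_trait_error")
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Build standardized population-by-treatment slices
#'
#' Adds relative fitness `w` (mean 1) and standardized trait columns
#' `z_<trait>` (mean 0, variance 1) to a plant table. By default moments are
#' taken within each population x treatment slice; `pooling = "population"`
#' uses population-wide moments (both treatments pooled) instead, so that HP
#' and HE gradients are expressed on a common scale.
#'
#' Plants with missing traits or fitness, or with zero flowers, are dropped
#' with a message giving the count.
#'
#' @param data A plant table.
#' @param traits Trait columns; default [trait_cols].
#' @param fitness Fitness column; default `"seeds_total"`.
#' @param pooling `"slice"` (default) or `"population"`.
#' @return The filtered tibble with added `w` and `z_*` columns.
#' @export
standardize_slices <- function(data, traits = trait_cols,
                               fitness = "seeds_total",
                               pooling = c("slice", "population")) {
  pooling <- match.arg(pooling)
  need <- c("population_id", "treatment", traits, fitness)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "florsel_schema_error")
  }
  ok <- stats::complete.cases(data[c(traits, fitness)])
  if ("n_flowers" %in% names(data)) {
    ok <- ok & !is.na(data$n_flowers) & data$n_flowers > 0
  }
  if (any(!ok)) {
    message(sum(!ok), " plant(s) dropped from gradient estimation ",
            "(missing values or zero flowers)")
    data <- data[ok, ]
  }
  grp <- if (pooling == "slice") c("population_id", "treatment")
         else "population_id"
  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(d, key) {
      z <- standardize_traits(as.matrix(d[traits]))
      colnames(z) <- paste0("z_", traits)
      d$w <- relativize_fitness(d[[fitness]])
      dplyr::bind_cols(d, tibble::as_tibble(z))
    }) |>
    dplyr::ungroup()
  out
}

#' Opportunity for selection
#'
#' The variance in relative fitness, `I = Var(w)` (sample variance, n - 1),
#' an upper bound on the strength of selection in a group. Given a plant
#' table, `I` is computed per population x treatment slice; given a numeric
#' vector of relative fitness, a single value is returned.
#'
#' @param data A plant table, or a numeric vector of relative fitness.
#' @param fitness Fitness column used when `data` is a table.
#' @return A tibble with columns `population_id`, `treatment`, `I`, `n`
#'   (single-row with just `I` and `n` for vector input).
#' @export
#' @examples
#' opportunity_for_selection(c(0.5, 1, 1.5))$I  # 0.25
opportunity_for_selection <- function(data, fitness = "seeds_total") {
  if (is.numeric(data)) {
    if (length(data) < 2) {
      abort("need at least 2 individuals", class = "florsel_domain_error")
    }
    return(tibble::tibble(I = var(data), n = length(data)))
  }
  data |>
    dplyr::group_by(.data$population_id, .data$treatment) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) {
        abort(paste0("need at least 2 individuals in slice ",
                     paste(unlist(key), collapse = "/")),
              class = "florsel_domain_error")
      }
      w <- relativize_fitness(d[[fitness]])
      tibble::tibble(I = var(w), n = length(w))
    }) |>
    dplyr::ungroup()
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` is from regressing predictor `k`
#' on all the other predictors (with intercept). A perfectly collinear
#' column is flagged with `Inf`.
#'
#' @param x Numeric matrix or data frame of predictor columns (no
#'   intercept column).
#' @return Named numeric vector of VIFs, one per column, each `>= 1`.
#' @export
#' @examples
#' z1 <- rnorm(50); z2 <- rnorm(50)
#' vif(cbind(z1, z2, z3 = z1 + z2))
vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p == 1) {
    return(setNames(1, colnames(x)))
  }
  out <- vapply(seq_len(p), function(k) {
    fit <- stats::lm.fit(cbind(1, x[, -k, drop = FALSE]), x[, k])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, k] - mean(x[, k]))^2)
    if (tss <= 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  nm <- colnames(x)
  if (!is.null(nm)) names(out) <- nm
  out
}

#' Lande-Arnold selection gradients per population and treatment
#'
#' For each population x treatment slice, fits the multiple regression of
#' relative fitness on the variance-standardized traits by ordinary least
#' squares. The linear coefficients are the directional selection gradients
#' `beta`; with `quadratic = TRUE`, squared-trait terms are added and the
#' quadratic gradients `gamma` are twice the fitted squared-term
#' coefficients (the doubling convention). Standard errors and two-sided
#' t-test p-values come from the fit; variance inflation factors ([vif()])
#' diagnose collinearity among the model terms. A VIF above `vif_warn`
#' (default 5, the conventional multicollinearity alarm) triggers a warning;
#' values at or above 1.8 are noted in the `vif_note` attribute.
#'
#' @param data A plant table.
#' @param traits Trait columns; default [trait_cols].
#' @param fitness Fitness column; default `"seeds_total"`.
#' @param quadratic Add squared-trait terms and report `gamma`? Default
#'   `FALSE` (directional gradients only).
#' @param pooling Moment pooling for standardization, see
#'   [standardize_slices()].
#' @param vif_warn Warning threshold for VIFs.
#' @return A tibble of class `florsel_gradients`: one row per population x
#'   treatment x trait with `beta`, `se`, `p`, `vif`, `n` (and `gamma`,
#'   `gamma_se`, `gamma_p`, `gamma_vif` when `quadratic`).
#' @export
#' @examples
#' plants <- simulate_study(sim_config(n_populations = 2,
#'   pairs_per_population = 40, seed = 7))
#' selection_gradients(plants)
selection_gradients <- function(data, traits = trait_cols,
                                fitness = "seeds_total",
                                quadratic = FALSE,
                                pooling = c("slice", "population"),
                                vif_warn = 5) {
  pooling <- match.arg(pooling)
  sl <- standardize_slices(data, traits, fitness, pooling)
  zc <- paste0("z_", traits)

  out <- sl |>
    dplyr::group_by(.data$population_id, .data$treatment) |>
    dplyr::group_modify(function(d, key) {
      X <- as.matrix(d[zc])
      colnames(X) <- traits
      if (quadratic) {
        Xq <- X^2
        colnames(Xq) <- paste0(traits, "^2")
        X <- cbind(X, Xq)
      }
      n <- nrow(d)
      n_terms <- ncol(X) + 1
      if (n <= n_terms + 1) {
        abort(paste0("slice ", paste(unlist(key), collapse = "/"),
                     ": n = ", n, " too small for ", n_terms, " model terms"),
              class = "florsel_domain_error")
      }
      M <- cbind(`(Intercept)` = 1, X)
      qr_M <- qr(M)
      if (qr_M$rank < ncol(M)) {
        dep <- colnames(M)[qr_M$pivot[-seq_len(qr_M$rank)]]
        abort(paste0("rank-deficient design; dependent column(s): ",
                     paste(dep, collapse = ", ")),
              class = "florsel_collinearity_error")
      }
      fit <- stats::lm.fit(M, d$w)
      dfres <- n - ncol(M)
      rss <- sum(fit$residuals^2)
      sigma2 <- rss / dfres
      XtXinv <- chol2inv(chol(crossprod(M)))
      se_all <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
      b_all <- fit$coefficients
      exact <- sigma2 < 1e-25
      p_all <- if (exact) rep(NA_real_, length(b_all))
               else 2 * pt(abs(b_all / se_all), dfres, lower.tail = FALSE)
      v <- vif(X)
      res <- tibble::tibble(
        trait = traits,
        beta = unname(b_all[traits]),
        se = unname(se_all[match(traits, colnames(M))]),
        p = unname(p_all[match(traits, colnames(M))]),
        vif = unname(v[traits]),
        n = n
      )
      if (quadratic) {
        qn <- paste0(traits, "^2")
        idx <- match(qn, colnames(M))
        res$gamma <- 2 * unname(b_all[idx])
        res$gamma_se <- 2 * unname(se_all[idx])
        res$gamma_p <- unname(p_all[idx])
        res$gamma_vif <- unname(v[qn])
      }
      res
    }) |>
    dplyr::ungroup()

  big <- out$vif[is.finite(out$vif)]
  if (quadratic) big <- c(big, out$gamma_vif[is.finite(out$gamma_vif)])
  if (any(out$vif >= vif_warn, na.rm = TRUE) ||
      (quadratic && any(out$gamma_vif >= vif_warn, na.rm = TRUE))) {
    warn(paste0("VIF >= ", vif_warn,
                " for some term(s): multicollinearity likely"))
  }
  attr(out, "vif_note") <- if (length(big) && max(big) >= 1.8) {
    paste0("max VIF ", signif(max(big), 3), " (>= 1.8)")
  } else {
    paste0("all VIFs < 1.8")
  }
  attr(out, "pooling") <- pooling
  attr(out, "quadratic") <- quadratic
  class(out) <- c("florsel_gradients", class(out))
  out
}
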