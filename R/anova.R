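apply_transform <- function(x, transform, response) {
  switch(transform,
    none = x,
    log10 = {
      if (any(x < 0, na.rm = TRUE)) {
        abort(paste0("log10 transform needs nonnegative ", response),
              class = "florsel_domain_error")
      }
      if (any(x == 0, na.rm = TRUE)) {
        message("zeros in ", response, ": using log10(x + 1)")
        log10(x + 1)
      } else {
        log10(x)
      }
    },
    sqrt = {
      if (any(x < 0, na.rm = TRUE)) {
        abort(paste0("sqrt transform needs nonnegative ", response),
              class = "florsel_domain_error")
      }
      sqrt(x)
    }
  )
}

anova_tidy <- function(tab, transform, response) {
  out <- tibble::tibble(
    term = rownames(tab),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p.value = tab$`Pr(>F)`
  )
  attr(out, "transform") <- transform
  attr(out, "response") <- response
  class(out) <- c("florsel_anova", class(out))
  out
}

#' Two-way ANOVA of a response on population and treatment
#'
#' Fits `response ~ population + treatment + population:treatment` on a
#' transformed scale and returns the ANOVA table. The conventional
#' transforms for this design are `log10` for floral traits and fitness
#' components and `sqrt` for herbivory intensity; `log10` falls back to
#' `log10(x + 1)` when the response contains zeros (fruit or seed counts).
#'
#' @param data A plant table.
#' @param response Response column name; `"herbivory"` is computed on the
#'   fly via [herbivory_intensity()] if absent.
#' @param transform `"none"`, `"log10"`, or `"sqrt"`.
#' @param ss `"sequential"` (Type I, default) or `"marginal"` (Type II);
#'   they coincide for balanced designs.
#' @return A `florsel_anova` tibble with columns `term`, `df`, `sumsq`,
#'   `meansq`, `statistic` (F), `p.value`.
#' @export
two_way_anova <- function(data, response,
                          transform = c("none", "log10", "sqrt"),
                          ss = c("sequential", "marginal")) {
  transform <- match.arg(transform)
  ss <- match.arg(ss)
  if (identical(response, "herbivory") && !"herbivory" %in% names(data)) {
    data <- herbivory_intensity(data)
  }
  if (!response %in% names(data)) {
    abort(paste0("response column not found: ", response),
          class = "florsel_schema_error")
  }
  d <- data[!is.na(data[[response]]), ]
  for (f in c("population_id", "treatment")) {
    if (length(unique(d[[f]])) < 2) {
      abort(paste0("factor ", f, " has fewer than 2 levels"),
            class = "florsel_design_error")
    }
  }
  d$.y <- apply_transform(d[[response]], transform, response)
  d$population_id <- factor(d$population_id)
  d$treatment <- factor(d$treatment)

  full <- lm(.y ~ population_id * treatment, data = d)
  if (ss == "sequential") {
    tab <- as.data.frame(anova(full))
  } else {
    m_ab <- lm(.y ~ population_id + treatment, data = d)
    m_a <- lm(.y ~ population_id, data = d)
    m_b <- lm(.y ~ treatment, data = d)
    rss <- function(m) sum(resid(m)^2)
    dfr <- df.residual(full)
    mse <- rss(full) / dfr
    rows <- list(
      population_id = c(df.residual(m_b) - df.residual(m_ab),
                        rss(m_b) - rss(m_ab)),
      treatment = c(df.residual(m_a) - df.residual(m_ab),
                    rss(m_a) - rss(m_ab)),
      `population_id:treatment` = c(df.residual(m_ab) - dfr,
                                    rss(m_ab) - rss(full))
    )
    tab <- do.call(rbind, lapply(rows, function(r) {
      data.frame(Df = r[1], `Sum Sq` = r[2], `Mean Sq` = r[2] / r[1],
                 `F value` = (r[2] / r[1]) / mse,
                 `Pr(>F)` = pf((r[2] / r[1]) / mse, r[1], dfr,
                               lower.tail = FALSE),
                 check.names = FALSE)
    }))
    tab <- rbind(tab, Residuals = data.frame(
      Df = dfr, `Sum Sq` = rss(full), `Mean Sq` = mse,
      `F value` = NA_real_, `Pr(>F)` = NA_real_, check.names = FALSE))
  }
  anova_tidy(tab, transform, response)
}

#' ANCOVA tests for spatial and treatment variation in selection
#'
#' Builds slice-standardized relative fitness and traits first (the
#' gradients' own scale), then fits one pooled linear model and reports its
#' sequential ANOVA table.
#'
#' * `scope = "mediated_full"`: relative fitness on the standardized traits,
#'   population, treatment, trait x population, trait x treatment, and
#'   trait x population x treatment. A significant three-way interaction for
#'   a trait indicates that herbivore-mediated selection on that trait
#'   varies among populations.
#' * `scope = "net_HP_only"`: herbivore-present records only, with trait x
#'   population interactions; a significant interaction indicates that net
#'   directional selection varies among populations.
#'
#' @param data A plant table.
#' @param scope `"mediated_full"` (default) or `"net_HP_only"`.
#' @param traits,fitness As in [selection_gradients()].
#' @return A `florsel_anova` tibble (sequential, Type I sums of squares).
#' @export
ancova_variation <- function(data, scope = c("mediated_full", "net_HP_only"),
                             traits = trait_cols, fitness = "seeds_total") {
  scope <- match.arg(scope)
  if (scope == "net_HP_only") {
    data <- dplyr::filter(data, .data$treatment == "HP")
    if (nrow(data) == 0) {
      abort("no HP records", class = "florsel_design_error")
    }
  }
  sl <- standardize_slices(data, traits, fitness, pooling = "slice")
  sl$population_id <- factor(sl$population_id)
  sl$treatment <- factor(sl$treatment)
  zc <- paste0("z_", traits)
  zq <- paste0("`", zc, "`")

  if (scope == "mediated_full") {
    if (length(unique(sl$treatment)) < 2) {
      abort("mediated_full needs both treatments",
            class = "florsel_design_error")
    }
    cells <- table(sl$population_id, sl$treatment)
    if (any(cells == 0)) {
      bad <- which(cells == 0, arr.ind = TRUE)[1, ]
      abort(paste0("unestimable interaction: empty cell ",
                   rownames(cells)[bad[1]], " x ", colnames(cells)[bad[2]]),
            class = "florsel_design_error")
    }
    rhs <- c(zq, "population_id", "treatment",
             paste0(zq, ":population_id"),
             paste0(zq, ":treatment"),
             paste0(zq, ":population_id:treatment"))
  } else {
    rhs <- c(zq, "population_id", paste0(zq, ":population_id"))
  }
  fml <- as.formula(paste("w ~", paste(rhs, collapse = " + ")))
  fit <- lm(fml, data = sl)
  anova_tidy(as.data.frame(anova(fit)), "none", "relative fitness")
}

#' Treatment contrast of selection gradients
#'
#' The herbivore-mediated selection gradient is the difference between the
#' gradient with herbivores present and with herbivores excluded,
#' `delta_beta = beta_HP - beta_HE`, with standard error propagated as the
#' root sum of squares `sqrt(SE_HP^2 + SE_HE^2)`. A normal-approximation
#' two-sided p-value of `delta_beta / se` is included as `p_z`.
#'
#' @param grad_hp,grad_he [selection_gradients()] rows for the HP and HE
#'   treatment of the same population(s); trait sets must match.
#' @return A tibble with `population_id`, `trait`, `delta_beta`, `se`,
#'   `p_z`, `n_hp`, `n_he`.
#' @export
#' @examples
#' hp <- tibble::tibble(population_id = "p1", trait = "n_flowers",
#'                      beta = 0.5, se = 0.3, n = 80)
#' he <- tibble::tibble(population_id = "p1", trait = "n_flowers",
#'                      beta = 0.2, se = 0.4, n = 80)
#' mediated_contrast(hp, he)  # delta_beta 0.3, se 0.5
mediated_contrast <- function(grad_hp, grad_he) {
  key <- c("population_id", "trait")
  if (!setequal(paste(grad_hp$population_id, grad_hp$trait),
                paste(grad_he$population_id, grad_he$trait))) {
    abort("HP and HE gradients cover different population/trait sets",
          class = "florsel_alignment_error")
  }
  joined <- dplyr::inner_join(
    dplyr::select(grad_hp, dplyr::all_of(key), beta_hp = "beta",
                  se_hp = "se", n_hp = "n"),
    dplyr::select(grad_he, dplyr::all_of(key), beta_he = "beta",
                  se_he = "se", n_he = "n"),
    by = key
  )
  joined |>
    dplyr::mutate(
      delta_beta = .data$beta_hp - .data$beta_he,
      se = sqrt(.data$se_hp^2 + .data$se_he^2),
      p_z = 2 * pnorm(abs(.data$delta_beta) / .data$se, lower.tail = FALSE)
    ) |>
    dplyr::select(dplyr::all_of(key), "delta_beta", "se", "p_z",
                  "n_hp", "n_he")
}

#' Herbivore-mediated selection per population and trait
#'
#' Estimates selection gradients separately for the two treatments within
#' each population, forms the treatment contrast `delta_beta = beta_HP -
#' beta_HE` with its propagated SE ([mediated_contrast()]), and attaches a
#' per-population significance test: the trait x treatment interaction
#' p-value from an ANCOVA of relative fitness on the standardized traits,
#' treatment, and their interactions, fitted within the population
#' (sequential sums of squares). Both this interaction p (`p_interaction`,
#' the authoritative test) and the normal-approximation contrast p (`p_z`)
#' are reported, because summary tables in this literature are ambiguous
#' about which is printed.
#'
#' @inheritParams selection_gradients
#' @return A tibble of class `florsel_mediated`: one row per population x
#'   trait with `delta_beta`, `se`, `p_interaction`, `p_z`, `n_hp`, `n_he`.
#' @export
mediated_selection <- function(data, traits = trait_cols,
                               fitness = "seeds_total",
                               pooling = c("slice", "population")) {
  pooling <- match.arg(pooling)
  grads <- selection_gradients(data, traits, fitness, quadratic = FALSE,
                               pooling = pooling)
  contrast <- mediated_contrast(
    dplyr::filter(grads, .data$treatment == "HP"),
    dplyr::filter(grads, .data$treatment == "HE")
  )

  sl <- standardize_slices(data, traits, fitness, pooling = "slice")
  sl$treatment <- factor(sl$treatment)
  zc <- paste0("z_", traits)
  zq <- paste0("`", zc, "`")
  fml <- as.formula(paste(
    "w ~", paste(c(zq, "treatment", paste0(zq, ":treatment")),
                 collapse = " + ")
  ))
  p_int <- sl |>
    dplyr::group_by(.data$population_id) |>
    dplyr::group_modify(function(d, key) {
      tab <- anova(lm(fml, data = d))
      idx <- match(paste0(zc, ":treatment"), rownames(tab))
      tibble::tibble(trait = traits, p_interaction = tab$`Pr(>F)`[idx])
    }) |>
    dplyr::ungroup()

  out <- contrast |>
    dplyr::left_join(p_int, by = c("population_id", "trait")) |>
    dplyr::select("population_id", "trait", "delta_beta", "se",
                  "p_interaction", "p_z", "n_hp", "n_he")
  class(out) <- c("florsel_mediated", class(out))
  out
}
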