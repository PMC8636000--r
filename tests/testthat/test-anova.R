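balanced_cells <- function(values = c(1, 2, 3)) {
  # every population x treatment cell holds the same values: all effects zero
  tidyr::expand_grid(
    population_id = c("p1", "p2"), treatment = c("HP", "HE"),
    v = values
  ) |>
    dplyr::group_by(population_id, treatment) |>
    dplyr::mutate(pair_id = as.character(dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::rename(seeds_total = v)
}

test_that("identical cell means give zero F and p of one", {
  out <- two_way_anova(balanced_cells(), "seeds_total")
  eff <- dplyr::filter(out, term != "Residuals")
  expect_equal(eff$statistic, rep(0, 3), tolerance = 1e-12)
  expect_equal(eff$p.value, rep(1, 3), tolerance = 1e-12)
})

test_that("ANOVA F equals the nested-RSS brute-force computation", {
  d <- small_sim(41, n_pop = 3, pairs = 4)  # 24 rows
  out <- two_way_anova(d, "seeds_total", transform = "log10")
  y <- log10(d$seeds_total + if (any(d$seeds_total == 0)) 1 else 0)
  A <- factor(d$population_id); B <- factor(d$treatment)
  rss <- function(f) sum(resid(lm(f))^2)
  r0 <- rss(y ~ 1); rA <- rss(y ~ A); rAB <- rss(y ~ A + B)
  rfull <- rss(y ~ A * B)
  dfr <- nrow(d) - length(levels(A)) * length(levels(B))
  mse <- rfull / dfr
  f_seq <- c((r0 - rA) / (length(levels(A)) - 1),
             (rA - rAB) / 1,
             (rAB - rfull) / (length(levels(A)) - 1)) / mse
  expect_equal(out$statistic[1:3], f_seq, tolerance = 1e-8)
})

test_that("transforms are applied and guarded", {
  d <- small_sim(43, n_pop = 2, pairs = 10)
  d$n_fruits[1] <- 0
  expect_message(two_way_anova(d, "n_fruits", "log10"), "log10\\(x \\+ 1\\)")
  d$seeds_total[1] <- -1
  expect_error(two_way_anova(d, "seeds_total", "sqrt"),
               class = "florsel_domain_error")
  expect_error(two_way_anova(d, "nope"), class = "florsel_schema_error")
  d1 <- dplyr::filter(small_sim(44), treatment == "HP")
  expect_error(two_way_anova(d1, "seeds_total"),
               class = "florsel_design_error")
})

test_that("sequential and marginal sums of squares coincide on balanced data", {
  set.seed(9)
  d <- balanced_cells(rnorm(6, 10, 2))
  s1 <- two_way_anova(d, "seeds_total", ss = "sequential")
  s2 <- two_way_anova(d, "seeds_total", ss = "marginal")
  expect_equal(s1$sumsq, s2$sumsq[match(s1$term, s2$term)], tolerance = 1e-10)
})

test_that("a pure treatment shift is detected while the interaction stays null", {
  ps <- t(vapply(1:60, function(s) {
    d <- small_sim(s, n_pop = 2, pairs = 30)
    d$seeds_total <- exp(rnorm(nrow(d), 5, 0.4)) *
      ifelse(d$treatment == "HE", 1.6, 1)
    out <- two_way_anova(d, "seeds_total", "log10")
    c(trt = out$p.value[out$term == "treatment"],
      int = out$p.value[out$term == "population_id:treatment"])
  }, numeric(2)))
  expect_true(all(ps[, "trt"] < 0.01))
  expect_gt(ks.test(ps[, "int"], "punif")$p.value, 0.01)
})

test_that("ANCOVA tables carry the expected interaction terms", {
  d <- small_sim(47, n_pop = 3, pairs = 25)
  v <- suppressMessages(ancova_variation(d))
  expect_true(all(paste0("z_", trait_cols, ":population_id:treatment")
                  %in% v$term))
  expect_false("population_id:treatment" %in% v$term)
  hp <- suppressMessages(ancova_variation(d, "net_HP_only"))
  expect_true(all(paste0("z_", trait_cols, ":population_id") %in% hp$term))
  expect_false(any(grepl("treatment", hp$term)))
})

test_that("ANCOVA nested-model F identity holds", {
  d <- small_sim(53, n_pop = 3, pairs = 20)
  v <- suppressMessages(ancova_variation(d, "net_HP_only"))
  sl <- suppressMessages(standardize_slices(
    dplyr::filter(d, treatment == "HP")))
  sl$population_id <- factor(sl$population_id)
  full <- lm(w ~ (z_flowering_start + z_n_flowers + z_corolla_size) *
               population_id, data = sl)
  red <- lm(w ~ z_flowering_start + z_n_flowers + z_corolla_size +
              population_id + z_flowering_start:population_id +
              z_n_flowers:population_id, data = sl)
  dd <- df.residual(red) - df.residual(full)
  f_oracle <- ((sum(resid(red)^2) - sum(resid(full)^2)) / dd) /
    (sum(resid(full)^2) / df.residual(full))
  expect_equal(v$statistic[v$term == "z_corolla_size:population_id"],
               f_oracle, tolerance = 1e-8)
})

test_that("SE propagation is the root sum of squares", {
  hp <- tibble::tibble(population_id = "p1", trait = c("a", "b"),
                       beta = c(0.5, 0.1), se = c(0.3, 0.12), n = 50)
  he <- tibble::tibble(population_id = "p1", trait = c("a", "b"),
                       beta = c(0.2, 0.1), se = c(0.4, 0.05), n = 50)
  out <- mediated_contrast(hp, he)
  expect_equal(out$se[out$trait == "a"], 0.5)  # 3-4-5
  expect_equal(out$delta_beta, c(0.3, 0))
  expect_true(all(out$se >= pmax(hp$se, he$se)))
  expect_error(mediated_contrast(hp, he[1, ]),
               class = "florsel_alignment_error")
})

test_that("the treatment contrast is antisymmetric and its SE symmetric", {
  set.seed(61)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    hp <- tibble::tibble(population_id = "p", trait = letters[1:k],
                         beta = rnorm(k), se = runif(k, 0.05, 0.5), n = 40)
    he <- tibble::tibble(population_id = "p", trait = letters[1:k],
                         beta = rnorm(k), se = runif(k, 0.05, 0.5), n = 40)
    ab <- mediated_contrast(hp, he)
    ba <- mediated_contrast(he, hp)
    expect_equal(ab$delta_beta, -ba$delta_beta)
    expect_equal(ab$se, ba$se)
  }
})

test_that("mediated selection recovers a printed-scale contrast from components", {
  hp <- tibble::tibble(population_id = "pop4", trait = "flowering_start",
                       beta = 0.479, se = 0.08, n = 90)
  he <- tibble::tibble(population_id = "pop4", trait = "flowering_start",
                       beta = 0.349, se = 0.0633, n = 90)
  out <- mediated_contrast(hp, he)
  expect_equal(out$delta_beta, 0.13, tolerance = 1e-12)
  expect_equal(out$se, sqrt(0.08^2 + 0.0633^2), tolerance = 1e-12)
})

test_that("mediated_selection ties contrasts to per-population interaction tests", {
  d <- small_sim(67, n_pop = 2, pairs = 40)
  m <- suppressMessages(mediated_selection(d))
  expect_equal(nrow(m), 2 * 3)
  expect_true(all(c("delta_beta", "se", "p_interaction", "p_z") %in% names(m)))
  expect_true(all(m$p_interaction >= 0 & m$p_interaction <= 1))
  # contrast equals the difference of the slice gradients
  g <- suppressMessages(selection_gradients(d))
  ghp <- dplyr::filter(g, treatment == "HP")
  ghe <- dplyr::filter(g, treatment == "HE")
  key <- paste(m$population_id, m$trait)
  expect_equal(
    m$delta_beta,
    ghp$beta[match(key, paste(ghp$population_id, ghp$trait))] -
      ghe$beta[match(key, paste(ghe$population_id, ghe$trait))]
  )
})

test_that("count fitness makes the flower-number interaction test anti-conservative", {
  # seeds scale with flower number, so residual variance is coupled to that
  # trait; the equal-slopes F test then rejects too often even when the
  # no-preference null holds. This is a property of the analysis on count
  # fitness, not of the generator.
  ps <- vapply(1:60, function(s) {
    d <- simulate_study(sim_config(
      n_populations = 4, pairs_per_population = 40,
      attack_preference = c(n_flowers = 0, flowering_start = 0,
                            corolla_size = 0),
      seed = 7000 + s
    ))
    v <- suppressWarnings(suppressMessages(ancova_variation(d)))
    v$p.value[v$term == "z_n_flowers:population_id:treatment"]
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})
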