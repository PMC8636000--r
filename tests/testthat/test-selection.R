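test_that("relative fitness has mean one and preserves proportions", {
  expect_equal(relativize_fitness(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(relativize_fitness(rep(3.7, 5)), rep(1, 5))
  expect_equal(relativize_fitness(c(0, 0, 9)), c(0, 0, 3))
  expect_error(relativize_fitness(c(0, 0, 0)),
               class = "florsel_degenerate_slice_error")
  for (seed in 1:5) {
    set.seed(seed)
    w <- relativize_fitness(rgamma(50, 2, 0.1))
    expect_equal(mean(w), 1, tolerance = 1e-12)
  }
})

test_that("trait standardization gives mean 0, variance 1, and is idempotent", {
  expect_equal(unname(standardize_traits(cbind(c(1, 2, 3)))[, 1]),
               c(-1, 0, 1))
  set.seed(4)
  x <- cbind(a = rnorm(30, 100, 7), b = runif(30))
  z <- standardize_traits(x)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, var)), c(1, 1), tolerance = 1e-10)
  expect_equal(standardize_traits(z), z, tolerance = 1e-12)
  expect_error(standardize_traits(cbind(a = rep(2, 10), b = rnorm(10))),
               regexp = "a", class = "florsel_degenerate_trait_error")
})

test_that("standardized slices satisfy their defining moments", {
  d <- small_sim(13, n_pop = 3, pairs = 25)
  sl <- standardize_slices(d)
  by_slice <- sl |>
    dplyr::group_by(population_id, treatment) |>
    dplyr::summarise(mw = mean(w), mz = mean(z_n_flowers),
                     vz = var(z_n_flowers), .groups = "drop")
  expect_equal(by_slice$mw, rep(1, 6), tolerance = 1e-10)
  expect_equal(by_slice$mz, rep(0, 6), tolerance = 1e-10)
  expect_equal(by_slice$vz, rep(1, 6), tolerance = 1e-8)
  # population pooling: moments hold per population, not per slice
  slp <- standardize_slices(d, pooling = "population")
  by_pop <- slp |>
    dplyr::group_by(population_id) |>
    dplyr::summarise(mz = mean(z_corolla_size), vz = var(z_corolla_size),
                     .groups = "drop")
  expect_equal(by_pop$mz, rep(0, 3), tolerance = 1e-10)
  expect_equal(by_pop$vz, rep(1, 3), tolerance = 1e-8)
})

test_that("opportunity for selection is the variance of relative fitness", {
  expect_equal(opportunity_for_selection(c(0.5, 1, 1.5))$I, 0.25)
  expect_equal(opportunity_for_selection(rep(2, 8) / 2)$I, 0)
  expect_error(opportunity_for_selection(1), class = "florsel_domain_error")
})

test_that("opportunity matches the closed-form relativized-lognormal variance", {
  # X lognormal(mu, s2): Var(X / E X) = exp(s2) - 1
  set.seed(42)
  s <- 0.5
  w <- relativize_fitness(exp(rnorm(40000, 3, s)))
  expect_equal(opportunity_for_selection(w)$I, exp(s^2) - 1,
               tolerance = 0.05)
})

test_that("gradients solve the normal equations on random small designs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(12:30, 1)
    d <- tibble::tibble(
      population_id = "p", pair_id = as.character(seq_len(n)),
      treatment = rep(c("HP", "HE"), length.out = n),
      flowering_start = round(rnorm(n, 180, 8)),
      n_flowers = sample(5:30, n, replace = TRUE),
      corolla_size = rnorm(n, 30, 3),
      seeds_total = rgamma(n, 4, 1 / 100)
    )
    g <- suppressWarnings(suppressMessages(
      selection_gradients(d, pooling = "population")
    ))
    for (trt in c("HP", "HE")) {
      idx <- d$treatment == trt
      z <- standardize_traits(as.matrix(
        d[c("flowering_start", "n_flowers", "corolla_size")]))
      w <- relativize_fitness(d$seeds_total)
      bf <- normal_eq_beta(z[idx, ], w[idx])[-1]
      expect_equal(g$beta[g$treatment == trt], unname(bf), tolerance = 1e-8)
    }
  }
})

test_that("a single standardized trait's gradient equals the selection differential", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 24
    d <- tibble::tibble(
      population_id = "p", pair_id = as.character(1:n),
      treatment = rep(c("HP", "HE"), length.out = n),
      flowering_start = round(rnorm(n, 180, 8)),
      seeds_total = rgamma(n, 4, 1 / 100)
    )
    g <- suppressMessages(selection_gradients(d, traits = "flowering_start"))
    for (trt in c("HP", "HE")) {
      i <- d$treatment == trt
      z <- drop(standardize_traits(cbind(d$flowering_start[i])))
      w <- relativize_fitness(d$seeds_total[i])
      expect_equal(g$beta[g$treatment == trt], cov(w, z),
                   tolerance = 1e-10)
    }
  }
})

test_that("an exact linear fitness-trait relation gives beta with degenerate error", {
  n <- 12
  z_raw <- seq(-2, 2, length.out = n) * 5 + 180
  d <- tibble::tibble(
    population_id = "p", pair_id = as.character(1:n), treatment = "HP",
    flowering_start = z_raw,
    seeds_total = 100 * (1 + 0.3 * standardize_traits(cbind(z_raw))[, 1])
  )
  d <- dplyr::bind_rows(d, dplyr::mutate(d, treatment = "HE"))
  d$pair_id <- as.character(seq_len(nrow(d)))
  g <- suppressMessages(selection_gradients(d, traits = "flowering_start"))
  expect_equal(g$beta, rep(0.3, 2), tolerance = 1e-10)
  expect_equal(g$se, rep(0, 2), tolerance = 1e-6)
  expect_true(all(is.na(g$p)))
})

test_that("gradients are invariant to affine trait rescaling and fitness scaling", {
  d <- small_sim(19, n_pop = 2, pairs = 30)
  g1 <- suppressMessages(selection_gradients(d))
  d2 <- dplyr::mutate(d,
    flowering_start = 3 * flowering_start - 40,
    corolla_size = corolla_size / 10,
    seeds_total = seeds_total * 7.3
  )
  g2 <- suppressMessages(selection_gradients(d2))
  expect_equal(g1$beta, g2$beta, tolerance = 1e-10)
  expect_equal(g1$se, g2$se, tolerance = 1e-10)
})

test_that("null traits give uniform gradient p-values", {
  # permuted fitness labels: each trait's t-test p is uniform
  set.seed(31)
  base <- small_sim(23, n_pop = 1, pairs = 40)
  ps <- vapply(1:400, function(i) {
    d <- base
    d$seeds_total <- sample(d$seeds_total)
    g <- suppressMessages(selection_gradients(d))
    g$p[g$treatment == "HP" & g$trait == "corolla_size"]
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  frac <- mean(ps < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("vif matches its closed form and flags aliasing", {
  set.seed(2)
  # columns orthogonal to each other and to the intercept
  x <- qr.Q(qr(cbind(1, matrix(rnorm(80), 20, 4))))[, 2:4]
  expect_equal(unname(vif(x)), rep(1, 3), tolerance = 1e-10)
  # two columns with known correlation r: VIF = 1 / (1 - r^2)
  n <- 1e5
  a <- rnorm(n)
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  v <- vif(cbind(a, b))
  expect_equal(unname(v), rep(1 / (1 - 0.36), 2), tolerance = 0.02)
  # duplicated column is flagged infinite
  expect_true(all(is.infinite(vif(cbind(a, a)))))
})

test_that("vif agrees with the standard regression-diagnostics implementation", {
  skip_if_not_installed("car")
  d <- small_sim(29, n_pop = 1, pairs = 50)
  sl <- standardize_slices(d)
  hp <- dplyr::filter(sl, treatment == "HP")
  fit <- lm(w ~ z_flowering_start + z_n_flowers + z_corolla_size, data = hp)
  expect_equal(
    unname(vif(as.matrix(hp[paste0("z_", trait_cols)]))),
    unname(car::vif(fit)),
    tolerance = 1e-10
  )
})

test_that("rank-deficient designs raise a collinearity error naming columns", {
  d <- small_sim(5, n_pop = 1, pairs = 30)
  d$corolla_size <- d$n_flowers * 2 + 1  # perfectly collinear after scaling
  expect_error(suppressMessages(selection_gradients(d)),
               class = "florsel_collinearity_error")
})

test_that("quadratic gradients use the doubling convention", {
  set.seed(77)
  n <- 200
  z_raw <- rnorm(n, 20, 5)
  z <- drop(standardize_traits(cbind(z_raw)))
  w_abs <- 100 * (1 + 0.2 * z - 0.15 * z^2 + rnorm(n, 0, 0.02))
  d <- tibble::tibble(
    population_id = "p", pair_id = as.character(1:n),
    treatment = rep(c("HP", "HE"), each = n / 2),
    flowering_start = z_raw, seeds_total = w_abs - min(w_abs) + 1
  )
  g <- suppressMessages(selection_gradients(
    d, traits = "flowering_start", quadratic = TRUE))
  # gamma = 2 x fitted squared-term coefficient: refit directly
  hp <- d$treatment == "HP"
  zs <- drop(standardize_traits(cbind(d$flowering_start[hp])))
  ws <- relativize_fitness(d$seeds_total[hp])
  cf <- coef(lm(ws ~ zs + I(zs^2)))
  expect_equal(g$gamma[g$treatment == "HP"], unname(2 * cf[3]),
               tolerance = 1e-10)
  expect_true(all(c("gamma", "gamma_se", "gamma_vif") %in% names(g)))
})
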