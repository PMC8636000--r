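# small programmatic fixtures shared across test files

# a minimal valid 4-row table: 1 population, 2 pairs, both treatments
tiny_plants <- function() {
  tibble::tibble(
    population_id = "pop01",
    pair_id = rep(c("pair001", "pair002"), each = 2),
    treatment = rep(c("HP", "HE"), 2),
    flowering_start = c(180, 182, 175, 178),
    n_flowers = c(20, 12, 12, 15),
    corolla_size = c(30.5, 29.1, 31.2, 28.8),
    n_fruits = c(10, 8, 6, 9),
    seeds_per_fruit = c(40, 45, 38, 50),
    seeds_total = c(400, 360, 228, 450),
    n_damaged_flowers = c(5, 0, 12, 0)
  )
}

# random valid plant table via the generator, small and fast
small_sim <- function(seed, n_pop = 2, pairs = 20, ...) {
  simulate_study(sim_config(n_populations = n_pop,
                            pairs_per_population = pairs, seed = seed, ...))
}

# brute-force OLS by normal equations: coefficients of w ~ 1 + X
normal_eq_beta <- function(X, w) {
  M <- cbind(1, X)
  drop(solve(t(M) %*% M, t(M) %*% w))
}

# numerical quadrature oracle for folded-normal mean and variance
folded_quadrature <- function(mu, sigma) {
  dens <- function(t) dnorm(t, mu, sigma) + dnorm(-t, mu, sigma)
  m <- integrate(function(t) t * dens(t), 0, Inf, rel.tol = 1e-12)$value
  m2 <- integrate(function(t) t^2 * dens(t), 0, Inf, rel.tol = 1e-12)$value
  c(mean = m, variance = m2 - m^2)
}
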