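#' Configuration for the paired-plant study simulator
#'
#' Describes a multi-population paired herbivore-present / herbivore-exclusion
#' experiment on a flowering herb. Defaults emulate the field design the
#' analysis chain assumes: 11 populations, 60-125 plant pairs per population,
#' population mean herbivory intensities spanning roughly 0.15-0.56, herbivore
#' preference for many-flowered and later-flowering plants, and seed loss
#' proportional to per-plant damage.
#'
#' @param n_populations Number of populations.
#' @param pairs_per_population Plant pairs per population: a single count, or
#'   a length-2 range sampled uniformly per population.
#' @param trait_means,trait_sds Named means/SDs for `flowering_start` (day of
#'   year), `n_flowers` (count; negative-binomial mean), `corolla_size` (mm).
#' @param nb_size_flowers Negative-binomial size (overdispersion) for flower
#'   number; smaller is more overdispersed.
#' @param attack_baseline Per-population logit-scale attack baselines
#'   (length `n_populations`). Default `NULL` places them so population mean
#'   per-flower attack probabilities are evenly spaced on `intensity_range`.
#' @param attack_preference Named coefficients (on within-population
#'   standardized traits) of herbivore preference in the per-flower attack
#'   logit: `n_flowers`, `flowering_start`, `corolla_size`.
#' @param damage_fitness_cost Fraction of seed production lost per unit
#'   herbivory intensity, in \[0, 1\] (seed predation on top of the loss of
#'   damaged flowers themselves).
#' @param fruit_prob Probability an undamaged flower sets a fruit.
#' @param seeds_per_fruit_mean,seeds_per_fruit_dispersion Gamma-Poisson
#'   (negative binomial) mean and size for seeds per fruit.
#' @param exclusion_fidelity Probability a herbivore is removed in the HE
#'   treatment; 1 (default) reproduces near-perfect manual exclusion.
#' @param attack_aggregation Intra-plant correlation of flower damage in
#'   \[0, 1): each plant's realized per-flower attack probability is
#'   beta-distributed around the logistic mean with this intraclass
#'   correlation, mimicking larvae that cluster on a plant and move among its
#'   flowers. 0 gives independent per-flower attacks; default 0.35.
#' @param scenario `"nonlinear"` (default): the realized damage cost per
#'   population attenuates as interaction intensity grows (plant defense /
#'   saturation), producing hump-shaped opportunity-intensity relations;
#'   `"linear"`: constant cost over a low-intensity span, producing
#'   near-linear relations.
#' @param intensity_range Target span of population mean herbivory
#'   intensities. Default `c(0.154, 0.557)` for `"nonlinear"` (the field
#'   range the design emulates) and `c(0.05, 0.25)` for `"linear"`.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return A `florsel_sim_config` list.
#' @seealso [simulate_study()]
#' @export
sim_config <- function(n_populations = 11,
                       pairs_per_population = c(60, 125),
                       trait_means = c(flowering_start = 180, n_flowers = 18,
                                       corolla_size = 30),
                       trait_sds = c(flowering_start = 10, n_flowers = 6,
                                     corolla_size = 3),
                       nb_size_flowers = 10,
                       attack_baseline = NULL,
                       attack_preference = c(n_flowers = 0.3,
                                             flowering_start = 0.2,
                                             corolla_size = 0),
                       damage_fitness_cost = 0.5,
                       fruit_prob = 0.6,
                       seeds_per_fruit_mean = 50,
                       seeds_per_fruit_dispersion = 5,
                       exclusion_fidelity = 1,
                       attack_aggregation = 0.35,
                       scenario = c("nonlinear", "linear"),
                       intensity_range = NULL,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(intensity_range)) {
    intensity_range <- if (scenario == "nonlinear") c(0.154, 0.557)
                       else c(0.05, 0.25)
  }
  stopifnot(
    n_populations >= 1,
    length(pairs_per_population) %in% c(1, 2),
    all(pairs_per_population >= 1),
    all(trait_cols %in% names(trait_means)),
    all(trait_cols %in% names(trait_sds))
  )
  if (any(trait_sds <= 0)) {
    abort("trait_sds must all be > 0", class = "florsel_config_error")
  }
  if (exclusion_fidelity < 0 || exclusion_fidelity > 1) {
    abort("exclusion_fidelity must be in [0, 1]",
          class = "florsel_config_error")
  }
  if (damage_fitness_cost < 0 || damage_fitness_cost > 1) {
    abort("damage_fitness_cost must be in [0, 1]",
          class = "florsel_config_error")
  }
  if (attack_aggregation < 0 || attack_aggregation >= 1) {
    abort("attack_aggregation must be in [0, 1)",
          class = "florsel_config_error")
  }
  if (is.null(attack_baseline)) {
    attack_baseline <- qlogis(seq(intensity_range[1], intensity_range[2],
                                  length.out = n_populations))
  }
  if (length(attack_baseline) != n_populations) {
    abort("attack_baseline must have one value per population",
          class = "florsel_config_error")
  }
  structure(
    list(
      n_populations = as.integer(n_populations),
      pairs_per_population = pairs_per_population,
      trait_means = trait_means, trait_sds = trait_sds,
      nb_size_flowers = nb_size_flowers,
      attack_baseline = attack_baseline,
      attack_preference = attack_preference[trait_cols],
      damage_fitness_cost = damage_fitness_cost,
      fruit_prob = fruit_prob,
      seeds_per_fruit_mean = seeds_per_fruit_mean,
      seeds_per_fruit_dispersion = seeds_per_fruit_dispersion,
      exclusion_fidelity = exclusion_fidelity,
      attack_aggregation = attack_aggregation,
      scenario = scenario,
      intensity_range = intensity_range,
      seed = as.integer(seed)
    ),
    class = "florsel_sim_config"
  )
}

#' Simulate a paired herbivore-present / herbivore-exclusion study
#'
#' Generates an individual-plant table with the statistical structure the
#' downstream selection analyses assume. Within each population, pairs of
#' plants are drawn with independent floral traits; one plant per pair is
#' assigned to each treatment. Each flower is attacked with the plant's
#' per-flower probability, whose mean is `plogis(baseline_pop + preference .
#' standardized traits)` (times `1 - exclusion_fidelity` under HE) and which
#' is beta-distributed across plants with intraclass correlation
#' `attack_aggregation` (clustered larvae). Fruits are set with probability
#' `fruit_prob` by the flowers that escaped effective damage; total seed
#' production is gamma-Poisson around `n_fruits * seeds_per_fruit_mean`,
#' then reduced multiplicatively by `cost_pop * herbivory intensity` (seed
#' predation). Under the `"nonlinear"` scenario both the per-flower severity
#' of damage (`1 - p_pop`) and the seed-predation cost
#' (`cost * sqrt(1 - p_pop)`) attenuate with the population attack rate,
#' mimicking induced defense and tolerance at high interaction intensity;
#' this makes the opportunity for selection rise and then fall across the
#' intensity gradient. Under `"linear"` damage is uniformly costly.
#'
#' The run is deterministic given `config$seed`; populations use seed
#' sub-streams so their records do not change if populations are reordered
#' or subset.
#'
#' @param config A [sim_config()].
#' @return A validated plant table (tibble) with the columns of
#'   [plant_cols].
#' @export
#' @examples
#' plants <- simulate_study(sim_config(n_populations = 3,
#'   pairs_per_population = 20, seed = 42))
#' population_intensity(plants, "HP")
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "florsel_sim_config"))
  set.seed(config$seed)
  pop_seeds <- sample.int(.Machine$integer.max - 1L, config$n_populations)

  pops <- purrr::map(seq_len(config$n_populations), function(i) {
    set.seed(pop_seeds[i])
    rng <- config$pairs_per_population
    n_pairs <- if (length(rng) == 2) sample(seq(rng[1], rng[2]), 1) else rng
    n <- 2L * n_pairs

    fs <- round(rnorm(n, config$trait_means["flowering_start"],
                      config$trait_sds["flowering_start"]))
    nf <- pmax(1, rnbinom(n, mu = config$trait_means["n_flowers"],
                          size = config$nb_size_flowers))
    cs <- pmax(1, rnorm(n, config$trait_means["corolla_size"],
                        config$trait_sds["corolla_size"]))

    z <- cbind(
      flowering_start = (fs - config$trait_means["flowering_start"]) /
        config$trait_sds["flowering_start"],
      n_flowers = (nf - config$trait_means["n_flowers"]) /
        config$trait_sds["n_flowers"],
      corolla_size = (cs - config$trait_means["corolla_size"]) /
        config$trait_sds["corolla_size"]
    )
    eta <- config$attack_baseline[i] +
      drop(z %*% config$attack_preference[colnames(z)])
    p_attack <- plogis(eta)

    treatment <- rep(c("HP", "HE"), n_pairs)
    p_eff <- ifelse(treatment == "HE",
                    p_attack * (1 - config$exclusion_fidelity), p_attack)
    # aggregated attacks: the plant's realized per-flower probability is
    # beta-distributed around p_eff with intraclass correlation rho
    rho <- config$attack_aggregation
    p_plant <- p_eff
    if (rho > 0) {
      conc <- (1 - rho) / rho
      interior <- p_eff > 0 & p_eff < 1
      p_plant[interior] <- rbeta(sum(interior), p_eff[interior] * conc,
                                 (1 - p_eff[interior]) * conc)
    }
    n_damaged <- rbinom(n, nf, p_plant)
    intensity <- n_damaged / nf

    p_pop <- plogis(config$attack_baseline[i])
    if (config$scenario == "nonlinear") {
      # induced defense / tolerance: in heavily attacked populations a
      # damaged flower is less likely to be a total loss, and seed predation
      # per unit damage attenuates
      severity_pop <- 1 - p_pop
      cost_pop <- config$damage_fitness_cost * sqrt(1 - p_pop)
    } else {
      severity_pop <- 1
      cost_pop <- config$damage_fitness_cost
    }

    fruiting_pool <- nf - round(severity_pop * n_damaged)
    n_fruits <- rbinom(n, fruiting_pool, config$fruit_prob)
    raw_seeds <- numeric(n)
    pos <- n_fruits > 0
    raw_seeds[pos] <- rnbinom(
      sum(pos),
      mu = n_fruits[pos] * config$seeds_per_fruit_mean,
      size = n_fruits[pos] * config$seeds_per_fruit_dispersion
    )
    seeds_total <- raw_seeds * (1 - cost_pop * intensity)
    spf <- ifelse(n_fruits > 0, seeds_total / n_fruits, 0)

    tibble::tibble(
      population_id = sprintf("pop%02d", i),
      pair_id = sprintf("pair%03d", rep(seq_len(n_pairs), each = 2)),
      treatment = treatment,
      flowering_start = fs,
      n_flowers = as.numeric(nf),
      corolla_size = cs,
      n_fruits = as.numeric(n_fruits),
      seeds_per_fruit = spf,
      seeds_total = seeds_total,
      n_damaged_flowers = as.numeric(n_damaged)
    )
  })
  validate_plant_table(dplyr::bind_rows(pops))
}

#' Configuration for the meta-regression recovery simulator
#'
#' Summary-level points for the across-population models: known herbivory
#' intensities `x`, responses generated from a linear or quadratic curve, and
#' known sampling standard errors.
#'
#' @param n_populations Number of points (populations); at least 4 so a
#'   quadratic fit retains a residual degree of freedom.
#' @param curve Numeric `c(c0, c1, c2)` of `y = c0 + c1 x + c2 x^2`.
#' @param x_range Interval in \[0, 1\] for uniform `x`.
#' @param se_mean,se_sd Mean/SD of the known sampling SEs (truncated at 0).
#' @param seed Integer seed.
#' @return A `florsel_meta_config` list.
#' @export
meta_config <- function(n_populations = 11,
                        curve = c(0, 1, 0),
                        x_range = c(0.154, 0.557),
                        se_mean = 0.1, se_sd = 0.02,
                        seed = 1L) {
  if (n_populations < 4) {
    abort("n_populations must be >= 4 for a quadratic fit",
          class = "florsel_config_error")
  }
  stopifnot(length(curve) == 3, length(x_range) == 2,
            x_range[1] >= 0, x_range[2] <= 1, se_mean >= 0, se_sd >= 0)
  structure(
    list(n_populations = as.integer(n_populations), curve = curve,
         x_range = x_range, se_mean = se_mean, se_sd = se_sd,
         seed = as.integer(seed)),
    class = "florsel_meta_config"
  )
}

#' Simulate summary-level meta-regression points
#'
#' `x_j ~ Uniform(x_range)`; true response from the configured curve;
#' observed `y_j = true_j + Normal(0, se_j^2)` with `se_j` drawn from the SE
#' distribution and reported as known.
#'
#' @param config A [meta_config()].
#' @return A tibble with columns `population`, `x`, `y`, `se`.
#' @export
simulate_meta_points <- function(config = meta_config()) {
  stopifnot(inherits(config, "florsel_meta_config"))
  set.seed(config$seed)
  n <- config$n_populations
  x <- runif(n, config$x_range[1], config$x_range[2])
  se <- pmax(rnorm(n, config$se_mean, config$se_sd), 0)
  truth <- config$curve[1] + config$curve[2] * x + config$curve[3] * x^2
  tibble::tibble(
    population = sprintf("pop%02d", seq_len(n)),
    x = x,
    y = truth + rnorm(n, 0, se),
    se = se
  )
}
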