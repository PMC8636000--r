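#' Column schema of the individual-plant table
#'
#' One row per plant: its population, its pair within the population, the
#' herbivory treatment it received (`"HP"` herbivore-present, `"HE"`
#' herbivore-exclusion), three floral traits (flowering start as day of year,
#' total flower number, corolla size in mm averaged over the first three
#' flowers), female fitness components (fruit count, seeds per fruit, total
#' seeds), and the count of herbivore-damaged flowers.
#'
#' @format A character vector of the ten required column names, in canonical
#'   order.
#' @export
plant_cols <- c(
  "population_id", "pair_id", "treatment",
  "flowering_start", "n_flowers", "corolla_size",
  "n_fruits", "seeds_per_fruit", "seeds_total",
  "n_damaged_flowers"
)

#' The three floral traits under selection
#' @format Character vector of trait column names.
#' @export
trait_cols <- c("flowering_start", "n_flowers", "corolla_size")

plant_col_types <- readr::cols(
  population_id = readr::col_character(),
  pair_id = readr::col_character(),
  treatment = readr::col_character(),
  flowering_start = readr::col_double(),
  n_flowers = readr::col_double(),
  corolla_size = readr::col_double(),
  n_fruits = readr::col_double(),
  seeds_per_fruit = readr::col_double(),
  seeds_total = readr::col_double(),
  n_damaged_flowers = readr::col_double()
)

#' Read an individual-plant table from delimited text
#'
#' Reads a CSV (default) or TSV plant table with the exact header documented
#' in [plant_cols], validates it with [validate_plant_table()], and returns a
#' tibble in file order.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A validated tibble with the columns of [plant_cols].
#' @seealso [write_plant_table()], [validate_plant_table()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_plant_table(simulate_study(sim_config(n_populations = 2,
#'   pairs_per_population = 5, seed = 1)), f)
#' head(read_plant_table(f))
read_plant_table <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("plant table not found: ", path), class = "florsel_io_error")
  }
  # readr's own parse warning is superseded by the typed error below
  data <- suppressWarnings(
    readr::read_delim(path, delim = delim, col_types = plant_col_types,
                      na = c("", "NA"))
  )
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(
      paste0("unparseable cell(s) in ", path, ": first at line ",
             probs$row[1], ", column ", probs$col[1]),
      class = "florsel_parse_error"
    )
  }
  validate_plant_table(data)
}

#' Write an individual-plant table to delimited text
#'
#' @param data A plant table (validated on the way out).
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_plant_table <- function(data, path, delim = ",") {
  data <- validate_plant_table(data)
  readr::write_delim(data[plant_cols], path, delim = delim, na = "NA")
  invisible(path)
}

#' Validate an individual-plant table
#'
#' Checks the schema (all columns of [plant_cols] present), the treatment
#' coding (`"HP"`/`"HE"`), non-negativity of counts, and the row-level
#' invariants `n_damaged_flowers <= n_flowers` and `n_fruits <= n_flowers`.
#' Violations are reported with the offending data line number (header = line
#' 1, so data row i is line i + 1).
#'
#' @param data A data frame to validate.
#' @return The data as a tibble, invisibly usable, with columns in canonical
#'   order first.
#' @export
validate_plant_table <- function(data) {
  missing_cols <- setdiff(plant_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("plant table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "florsel_schema_error"
    )
  }
  data <- tibble::as_tibble(data)

  bad_trt <- which(!data$treatment %in% c("HP", "HE"))
  if (length(bad_trt) > 0) {
    abort(
      paste0("treatment must be 'HP' or 'HE'; invalid value at line ",
             bad_trt[1] + 1L),
      class = "florsel_validation_error"
    )
  }
  check_rows <- function(bad, what) {
    bad <- which(bad)
    if (length(bad) > 0) {
      abort(
        paste0(what, " at line ", bad[1] + 1L,
               if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)")),
        class = "florsel_validation_error"
      )
    }
  }
  num_cols <- setdiff(plant_cols, c("population_id", "pair_id", "treatment"))
  for (cl in num_cols) {
    check_rows(!is.na(data[[cl]]) & data[[cl]] < 0,
               paste0("negative ", cl))
  }
  check_rows(
    !is.na(data$n_damaged_flowers) & !is.na(data$n_flowers) &
      data$n_damaged_flowers > data$n_flowers,
    "n_damaged_flowers > n_flowers"
  )
  check_rows(
    !is.na(data$n_fruits) & !is.na(data$n_flowers) &
      data$n_fruits > data$n_flowers,
    "n_fruits > n_flowers"
  )

  dup <- duplicated(data[c("population_id", "pair_id", "treatment")])
  if (any(dup)) {
    abort(
      paste0("duplicate (population, pair, treatment) record at line ",
             which(dup)[1] + 1L),
      class = "florsel_validation_error"
    )
  }
  one_sided <- data |>
    dplyr::distinct(.data$population_id, .data$treatment) |>
    dplyr::count(.data$population_id) |>
    dplyr::filter(.data$n < 2)
  if (nrow(one_sided) > 0) {
    abort(
      paste0("population(s) missing one treatment arm: ",
             paste(one_sided$population_id, collapse = ", ")),
      class = "florsel_validation_error"
    )
  }
  data[c(plant_cols, setdiff(names(data), plant_cols))]
}

#' Per-plant herbivory intensity
#'
#' The proportion of a plant's flowers showing herbivore damage:
#' `n_damaged_flowers / n_flowers`. Plants without flowers have no defined
#' intensity; they are returned as `NA` with a warning (and are excluded from
#' all downstream intensity and selection analyses) or raise an error,
#' depending on `zero_flowers`.
#'
#' @param data A plant table.
#' @param zero_flowers `"warn"` (default): `NA` intensity plus a warning
#'   counting the affected plants; `"error"`: fail on the first such plant.
#' @return `data` with an added `herbivory` column in \[0, 1\].
#' @export
#' @examples
#' d <- tibble::tibble(n_damaged_flowers = c(5, 0, 12),
#'                     n_flowers = c(20, 12, 12))
#' herbivory_intensity(d)$herbivory  # 0.25, 0, 1
herbivory_intensity <- function(data, zero_flowers = c("warn", "error")) {
  zero_flowers <- match.arg(zero_flowers)
  if (!all(c("n_damaged_flowers", "n_flowers") %in% names(data))) {
    abort("data needs columns n_damaged_flowers and n_flowers",
          class = "florsel_schema_error")
  }
  zero <- !is.na(data$n_flowers) & data$n_flowers == 0
  if (any(zero)) {
    if (zero_flowers == "error") {
      abort(paste0("herbivory intensity undefined for plant(s) with zero ",
                   "flowers (first at row ", which(zero)[1], ")"),
            class = "florsel_domain_error")
    }
    warn(paste0(sum(zero), " plant(s) with zero flowers: herbivory intensity ",
                "set to NA and excluded from analyses"))
  }
  data |>
    dplyr::mutate(
      herbivory = ifelse(zero, NA_real_,
                         .data$n_damaged_flowers / .data$n_flowers)
    )
}

#' Population-level herbivory intensity
#'
#' Mean and sample SD (n - 1 denominator) of per-plant herbivory intensity
#' within each population, by treatment. The herbivore-present (HP) slice is
#' the interaction-intensity axis of the across-population meta-regressions.
#'
#' @param data A plant table.
#' @param treatment Treatments to summarise; default both.
#' @return A tibble with columns `population_id`, `treatment`, `mean`, `sd`,
#'   `n` (plants with defined intensity).
#' @export
population_intensity <- function(data, treatment = c("HP", "HE")) {
  treatment <- match.arg(treatment, several.ok = TRUE)
  if (!"herbivory" %in% names(data)) {
    data <- herbivory_intensity(data)
  }
  out <- data |>
    dplyr::filter(.data$treatment %in% !!treatment, !is.na(.data$herbivory)) |>
    dplyr::group_by(.data$population_id, .data$treatment) |>
    dplyr::summarise(
      mean = mean(.data$herbivory),
      sd = sd(.data$herbivory),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (nrow(out) == 0) {
    abort("no plants with defined herbivory intensity in the requested slice",
          class = "florsel_empty_slice_error")
  }
  out
}
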