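#' Default head-group trajectories of the choline-rescue scenario
#'
#' Start (choline-starved, t = 0) and post-rescue steady-state targets in
#' mol\% of total lipid, encoding the reported rescue phenotype: PC nearly
#' depleted then rising, PE elevated then falling, PS slightly low then
#' rising, TAG elevated then falling, PI/PA/DAG flat. Both columns sum to
#' 100.
#'
#' @return Tibble with `lipid_class`, `start_pct`, `end_pct`, `half_time_h`.
#' @export
default_class_trajectories <- function() {
  tibble::tribble(
    ~lipid_class, ~start_pct, ~end_pct, ~half_time_h,
    "PC",   2, 30, 4,
    "PE",  35, 17, 4,
    "PS",   4,  7, 4,
    "PI",  12, 13, 4,
    "PA",   3,  3, 4,
    "DAG",  3,  3, 4,
    "TAG", 41, 27, 4
  )
}

#' Default within-class acyl-species trajectories
#'
#' Within-class mol\% targets: PE 32:1 and PS 32:1 start near 30 mol\% of
#' their class and fall after rescue, with a compensatory rise of the 34:2
#' species; minor classes are held flat. Each class's start and end columns
#' sum to 100.
#'
#' @return Tibble with `lipid_class`, `species`, `start_pct`, `end_pct`.
#' @export
default_acyl_trajectories <- function() {
  tibble::tribble(
    ~lipid_class, ~species,   ~start_pct, ~end_pct,
    "PC",  "PC 32:1",  25, 20,
    "PC",  "PC 32:2",  25, 25,
    "PC",  "PC 34:1",  25, 25,
    "PC",  "PC 34:2",  25, 30,
    "PE",  "PE 32:1",  30, 12,
    "PE",  "PE 32:2",  15, 15,
    "PE",  "PE 34:1",  20, 20,
    "PE",  "PE 34:2",  25, 43,
    "PE",  "PE 36:2",  10, 10,
    "PS",  "PS 32:1",  30, 12,
    "PS",  "PS 32:2",  25, 25,
    "PS",  "PS 34:1",  25, 25,
    "PS",  "PS 34:2",  20, 38,
    "PI",  "PI 34:1",  60, 60,
    "PI",  "PI 34:2",  40, 40,
    "PA",  "PA 34:1",  50, 50,
    "PA",  "PA 34:2",  50, 50,
    "DAG", "DAG 34:1", 60, 60,
    "DAG", "DAG 36:2", 40, 40,
    "TAG", "TAG 48:2", 50, 50,
    "TAG", "TAG 50:3", 50, 50
  )
}

#' Define a synthetic choline-rescue scenario
#'
#' Describes a time course in which choline-starved cells (PC-depleted,
#' PE-rich) are rescued with 1 mM choline and their lipidome relaxes toward a
#' replete steady state by saturating (single-exponential) kinetics.
#' Measurement noise is multiplicative lognormal: amounts are positive and
#' their spread grows with the mean, matching replicate scatter in lipidomic
#' data. The defaults encode the rescue phenotype the pipeline is designed to
#' analyse and serve as ground truth for every downstream stage.
#'
#' @param time_points Sampling times in hours after choline addition.
#' @param n_replicates Independent replicates per time point.
#' @param class_trajectories See [default_class_trajectories()].
#' @param acyl_trajectories See [default_acyl_trajectories()].
#' @param noise_cv Coefficient of variation of the multiplicative measurement
#'   noise (default 0.15).
#' @param total_lipid_nmol Total lipid scale per sample, nmol per 50 mg
#'   biomass.
#' @param condition Condition label stamped on every sample.
#' @return An object of class `rescue_scenario`.
#' @export
#' @examples
#' rescue_scenario()
rescue_scenario <- function(time_points = c(0, 2, 4, 8, 24),
                            n_replicates = 3,
                            class_trajectories = default_class_trajectories(),
                            acyl_trajectories = default_acyl_trajectories(),
                            noise_cv = 0.15,
                            total_lipid_nmol = 400,
                            condition = "3d_rescue") {
  if (any(time_points < 0)) abort("time_points must be >= 0 hours")
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (total_lipid_nmol <= 0) abort("total_lipid_nmol must be > 0")
  for (col in c("start_pct", "end_pct")) {
    if (abs(sum(class_trajectories[[col]]) - 100) > 1e-6) {
      abort(sprintf("Class trajectory %s values must sum to 100", col))
    }
    bad <- acyl_trajectories |>
      group_by(.data$lipid_class) |>
      summarise(s = sum(.data[[col]]), .groups = "drop") |>
      filter(abs(.data$s - 100) > 1e-6)
    if (nrow(bad) > 0L) {
      abort(sprintf(
        "Acyl trajectory %s values for class %s must sum to 100", col, bad$lipid_class[1]
      ))
    }
  }
  if (!all(acyl_trajectories$lipid_class %in% class_trajectories$lipid_class)) {
    abort("Every acyl trajectory class needs a class trajectory")
  }
  structure(
    list(
      time_points = sort(unique(time_points)), n_replicates = as.integer(n_replicates),
      class_trajectories = class_trajectories, acyl_trajectories = acyl_trajectories,
      noise_cv = noise_cv, total_lipid_nmol = total_lipid_nmol, condition = condition
    ),
    class = "rescue_scenario"
  )
}

#' @export
print.rescue_scenario <- function(x, ...) {
  cat(sprintf(
    "<rescue_scenario '%s'> %d time points x %d replicates, %d species, noise CV %.2g\n",
    x$condition, length(x$time_points), x$n_replicates,
    nrow(x$acyl_trajectories), x$noise_cv
  ))
  invisible(x)
}

# saturating single-exponential interpolation between start and end targets
.saturating <- function(start, end, t, half_time) {
  frac <- 1 - 2^(-t / half_time)
  start + (end - start) * frac
}

.expected_composition <- function(scenario, time_h) {
  cls <- scenario$class_trajectories |>
    mutate(class_pct = .saturating(.data$start_pct, .data$end_pct, time_h, .data$half_time_h)) |>
    mutate(class_pct = 100 * .data$class_pct / sum(.data$class_pct)) |>
    select("lipid_class", "class_pct")
  scenario$acyl_trajectories |>
    group_by(.data$lipid_class) |>
    mutate(acyl_pct = {
      ht <- scenario$class_trajectories$half_time_h[
        match(.data$lipid_class[1], scenario$class_trajectories$lipid_class)
      ]
      p <- .saturating(.data$start_pct, .data$end_pct, time_h, ht)
      100 * p / sum(p)
    }) |>
    ungroup() |>
    left_join(cls, by = "lipid_class") |>
    mutate(
      time_h = time_h,
      expected_nmol = scenario$total_lipid_nmol * (.data$class_pct / 100) * (.data$acyl_pct / 100)
    ) |>
    select("time_h", "lipid_class", "species", "class_pct", "acyl_pct", "expected_nmol")
}

#' Generate a synthetic choline-rescue time course
#'
#' Draws, for every (time point, replicate), a lipidome whose expectation is
#' the scenario's interpolated composition scaled to the total lipid amount,
#' multiplied by mean-one lognormal noise with the configured CV. The
#' noise-free expectations are returned alongside as ground truth.
#'
#' @param scenario A [rescue_scenario()].
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A list with `samples` (tibble: `sample_id`, `condition`, `time_h`,
#'   `replicate`, `species`, `amount_nmol`), `truth` (noise-free expectations
#'   per time point) and `scenario`.
#' @export
#' @examples
#' tc <- generate_timecourse(rescue_scenario(), seed = 1)
#' head(tc$samples)
generate_timecourse <- function(scenario = rescue_scenario(), seed = NULL) {
  stopifnot(inherits(scenario, "rescue_scenario"))
  if (!is.null(seed)) set.seed(seed)
  truth <- purrr::map(scenario$time_points, ~ .expected_composition(scenario, .x)) |>
    bind_rows() |>
    mutate(condition = scenario$condition, .before = 1)
  sdlog <- sqrt(log(1 + scenario$noise_cv^2))
  samples <- tidyr::expand_grid(
    replicate = seq_len(scenario$n_replicates),
    truth
  ) |>
    mutate(
      sample_id = sprintf("%s_t%g_r%d", .data$condition, .data$time_h, .data$replicate),
      amount_nmol = .data$expected_nmol *
        rlnorm(dplyr::n(), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    ) |>
    select("sample_id", "condition", "time_h", "replicate", "species", "amount_nmol")
  list(samples = samples, truth = truth, scenario = scenario)
}

#' Simulate an integrated peak table from known amounts
#'
#' Inverts the internal-standard quantification model: each analyte's area is
#' its amount times a class response factor times mean-one lognormal response
#' noise, and each sample gains one row per internal standard (area = spiked
#' amount times the same response factor, with its own noise draw). Running
#' [areas_to_amounts()] on the zero-noise output recovers the input amounts
#' exactly.
#'
#' @param samples Quantified tibble (metadata columns, `species`,
#'   `amount_nmol`).
#' @param standards A [standard_config()] tibble.
#' @param surrogate_map Class -> standard-class mapping for classes without a
#'   spiked standard; classes covered neither way raise an error.
#' @param response_noise_cv CV of the multiplicative response noise.
#' @param response_factors Named numeric vector of per-standard-class response
#'   factors; defaults to a fixed spread around 1.
#' @param seed Integer seed.
#' @return A peak tibble (metadata columns, `species`, `area`) including the
#'   standard rows.
#' @export
generate_peak_table <- function(samples, standards = standard_config(),
                                surrogate_map = default_surrogate_map(),
                                response_noise_cv = 0, response_factors = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- .species_info(samples)
  cls <- unique(df$lipid_class)
  std_for <- setNames(cls, cls)
  missing_std <- setdiff(cls, standards$lipid_class)
  std_for[missing_std] <- surrogate_map[missing_std]
  uncovered <- missing_std[is.na(std_for[missing_std])]
  if (length(uncovered) > 0L) {
    abort(sprintf(
      "Class %s has neither an internal standard nor a surrogate mapping", uncovered[1]
    ))
  }
  if (is.null(response_factors)) {
    response_factors <- setNames(
      1 + 0.15 * seq_along(standards$lipid_class), standards$lipid_class
    )
  }
  sdlog <- sqrt(log(1 + response_noise_cv^2))
  noise <- function(n) {
    if (response_noise_cv == 0) rep(1, n) else rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  keys <- .sample_keys(df)
  analyte_rows <- df |>
    mutate(
      std_class = unname(std_for[.data$lipid_class]),
      area = .data$amount_nmol * unname(response_factors[.data$std_class]) * noise(n())
    ) |>
    select(all_of(keys), "species", "area")
  needed <- standards |> filter(.data$lipid_class %in% unique(unname(std_for)))
  std_rows <- df |>
    distinct(across(all_of(keys))) |>
    tidyr::expand_grid(needed) |>
    mutate(
      species = .data$standard_species,
      area = .data$spike_nmol * unname(response_factors[.data$lipid_class]) * noise(n())
    ) |>
    select(all_of(keys), "species", "area")
  bind_rows(analyte_rows, std_rows) |> arrange(across(all_of(c(keys, "species"))))
}
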