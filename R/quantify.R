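#' Internal standard configuration
#'
#' One deuterated standard per lipid class, spiked at a known amount; analyte
#' amounts are expressed relative to the class-matched standard (single-point
#' response-factor model, no calibration curves). The default species set is
#' the classic yeast shotgun panel (CE, LPC, PC, PE, SM, TAG standards).
#' `spike_nmol` is a required experimental parameter: instrument protocols
#' state standard concentrations in mass units and the mass-to-mole conversion
#' depends on the exact standard, so no built-in constant is trustworthy. The
#' default of 10 nmol per standard is a documentation convention only.
#'
#' @param spike_nmol Spiked amount per standard in nmol; a scalar (recycled) or
#'   a vector named by lipid class.
#' @param species Character vector of standard species names, named by lipid
#'   class. All must carry an isotope label.
#' @return Tibble with columns `lipid_class`, `standard_species`, `spike_nmol`.
#' @export
#' @examples
#' standard_config(spike_nmol = 10)
standard_config <- function(
    spike_nmol = 10,
    species = c(
      CE = "CE(18:0-d6)",
      LPC = "LPC(14:0-d42)",
      PC = "PC(C16:0-d31/C18:1)",
      PE = "PE(C16:0-d31/C18:1)",
      SM = "SM(16:0-d31)",
      TAG = "TAG 48:0-d93"
    )) {
  parsed <- parse_species(unname(species))
  if (!all(parsed$is_internal_standard)) {
    abort("All standard species must carry an isotope label (e.g. '-d31')")
  }
  if (!all(names(species) == parsed$lipid_class)) {
    abort("Standard species classes must match their names")
  }
  if (is.null(names(spike_nmol))) {
    spike <- rep_len(spike_nmol, length(species))
  } else {
    spike <- spike_nmol[names(species)]
  }
  if (any(!is.finite(spike) | spike <= 0)) abort("spike_nmol must be finite and > 0")
  tibble(
    lipid_class = names(species),
    standard_species = parsed$species,
    spike_nmol = as.numeric(spike)
  )
}

#' Default surrogate-standard mapping
#'
#' Classes without a spiked standard are quantified against the nearest
#' glycerophospholipid standard: PC for the anionic phospholipids and TAG for
#' DAG. The mapping is a convention (protocols rarely state one) and is
#' recorded in the quantified output via the `standard_class` column.
#'
#' @return Named character vector: analyte class -> standard class.
#' @export
default_surrogate_map <- function() {
  c(PS = "PC", PI = "PC", PA = "PC", PG = "PC", DAG = "TAG")
}

.sample_key_cols <- c("sample_id", "condition", "time_h", "replicate")

.sample_keys <- function(df) intersect(.sample_key_cols, names(df))

#' Convert integrated peak areas to absolute amounts
#'
#' Implements the single-point internal-standard model:
#' `amount = area(analyte) / area(class standard) * spike_nmol(class)`.
#' Amounts are in nmol per 50 mg biomass under the default configuration (the
#' unit follows the spiked amount; ratios and mol\% are unit-invariant).
#' Standard rows are consumed as references and excluded from the output.
#'
#' @param peaks Tibble with columns `sample_id`, `species`, `area` (plus any
#'   metadata columns such as `condition`, `time_h`, `replicate`).
#' @param standards A [standard_config()] tibble.
#' @param surrogate_map Named character vector mapping classes without a
#'   spiked standard to the class whose standard quantifies them.
#' @return Tibble of quantified samples: metadata columns, `species`,
#'   `amount_nmol` and `standard_class` (the class of the standard used).
#' @export
areas_to_amounts <- function(peaks, standards = standard_config(),
                             surrogate_map = default_surrogate_map()) {
  stopifnot(all(c("sample_id", "species", "area") %in% names(peaks)))
  if (any(!is.finite(peaks$area) | peaks$area < 0)) {
    abort("Peak areas must be finite and >= 0")
  }
  p <- .species_info(peaks)
  std_rows <- p |>
    filter(.data$is_internal_standard, .data$species %in% standards$standard_species) |>
    inner_join(standards, by = c("species" = "standard_species", "lipid_class")) |>
    select(all_of(.sample_keys(p)), standard_class = "lipid_class",
           std_area = "area", "spike_nmol")

  analytes <- p |> filter(!.data$is_internal_standard)
  cls <- unique(analytes$lipid_class)
  std_for <- setNames(cls, cls)
  missing_std <- setdiff(cls, standards$lipid_class)
  std_for[missing_std] <- surrogate_map[missing_std]
  if (anyNA(std_for)) {
    abort(sprintf(
      "No internal standard or surrogate mapping for class %s",
      setdiff(missing_std, names(surrogate_map))[1]
    ))
  }
  analytes$standard_class <- unname(std_for[analytes$lipid_class])

  keys <- .sample_keys(p)
  out <- dplyr::left_join(analytes, std_rows, by = c(keys, "standard_class"))
  no_std <- is.na(out$std_area) | out$std_area <= 0
  if (any(no_std)) {
    i <- which(no_std)[1]
    abort(sprintf(
      "Missing or non-positive internal standard area for class %s in sample '%s'",
      out$standard_class[i], out$sample_id[i]
    ))
  }
  out$amount_nmol <- out$area / out$std_area * out$spike_nmol
  out |> select(all_of(keys), "species", "amount_nmol", "standard_class")
}

.drop_standards <- function(df) {
  if (!"is_internal_standard" %in% names(df)) df <- .species_info(df)
  filter(df, !.data$is_internal_standard)
}

#' Head-group composition as mol% of total lipid
#'
#' @param samples Quantified tibble with metadata columns, `species` and
#'   `amount_nmol`. Internal standards are excluded automatically.
#' @param included_classes Classes forming the denominator; defaults to every
#'   class present.
#' @return Tibble with the sample metadata, `lipid_class` and `mol_pct`;
#'   within each sample the values sum to 100.
#' @export
class_mol_percent <- function(samples, included_classes = NULL) {
  df <- .drop_standards(samples)
  if (!is.null(included_classes)) {
    df <- filter(df, .data$lipid_class %in% included_classes)
  }
  if (nrow(df) == 0L || all(df$amount_nmol == 0)) {
    abort("Undefined composition: no included species with a positive amount")
  }
  keys <- .sample_keys(df)
  df |>
    group_by(across(all_of(c(keys, "lipid_class")))) |>
    summarise(amount = sum(.data$amount_nmol), .groups = "drop_last") |>
    mutate(mol_pct = 100 * .data$amount / sum(.data$amount)) |>
    ungroup() |>
    select(-"amount")
}

#' Acyl-species composition within one lipid class
#'
#' Expresses each sum-composition species of a class as mol\% of the class
#' total (e.g. PE 32:1 as a share of total PE).
#'
#' @inheritParams class_mol_percent
#' @param lipid_class A single class code.
#' @return Tibble with the sample metadata, `species` and `mol_pct`; values
#'   sum to 100 within each sample.
#' @export
fa_mol_percent <- function(samples, lipid_class) {
  stopifnot(length(lipid_class) == 1L)
  df <- .drop_standards(samples) |> filter(.data$lipid_class == !!lipid_class)
  keys <- .sample_keys(df)
  if (nrow(df) == 0L) {
    abort(sprintf("Undefined composition: class %s absent from samples", lipid_class))
  }
  tot <- df |>
    group_by(across(all_of(keys))) |>
    summarise(total = sum(.data$amount_nmol), .groups = "drop")
  if (any(tot$total <= 0)) {
    abort(sprintf("Undefined composition: class %s has zero total amount", lipid_class))
  }
  df |>
    group_by(across(all_of(c(keys, "species")))) |>
    summarise(amount = sum(.data$amount_nmol), .groups = "drop_last") |>
    mutate(mol_pct = 100 * .data$amount / sum(.data$amount)) |>
    ungroup() |>
    select(-"amount") |>
    arrange(across(all_of(keys)))
}

#' PC/PE ratio per sample
#'
#' The ratio of total phosphatidylcholine to total phosphatidylethanolamine
#' amount, the classic readout of choline-rescue experiments.
#'
#' @inheritParams class_mol_percent
#' @return Tibble with the sample metadata and `pc_pe_ratio`.
#' @export
pc_pe_ratio <- function(samples) {
  df <- .drop_standards(samples)
  keys <- .sample_keys(df)
  out <- df |>
    group_by(across(all_of(keys))) |>
    summarise(
      pc = sum(.data$amount_nmol[.data$lipid_class == "PC"]),
      pe = sum(.data$amount_nmol[.data$lipid_class == "PE"]),
      .groups = "drop"
    )
  if (any(out$pe <= 0)) {
    abort(sprintf(
      "PC/PE ratio undefined: zero total PE in sample '%s'",
      out$sample_id[which(out$pe <= 0)[1]]
    ))
  }
  out |> mutate(pc_pe_ratio = .data$pc / .data$pe) |> select(-"pc", -"pe")
}
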