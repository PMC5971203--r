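#' Parameters of the coarse-grained P_SCE model
#'
#' P_SCE weights each lipid by a coarse-grained factor
#' `w = head_term(class) + unsat_increment * double bonds (summed over
#' chains)`, then partitions species against the pivot lipid PE 34:1: lipids
#' with `w > w(pivot)` are type II (increase stored curvature elastic stress),
#' lipids with `w <= w(pivot)` are type 0 (decrease it). The shipped
#' coefficients are an implementer parameterization constrained by the
#' qualitative physics only (unsaturation increases w; the small PE headgroup
#' outweighs PC; the pivot sits at PE 34:1); they are not canonical values and
#' live here precisely so they can be edited or recalibrated with
#' [calibrate_w()].
#'
#' @param head_terms Named numeric vector of per-class head-group terms; all
#'   positive.
#' @param unsat_increment Increment of w per chain double bond; positive.
#' @param pivot_species Pivot lipid name (default `"PE 34:1"`).
#' @param included_classes Classes entering the ratio. TAG is excluded by
#'   default (lipid-droplet associated, not in bilayer membranes) and so is
#'   PG (no parameters); both can be added for sensitivity runs.
#' @param denominator_mode `"inverse_weight"` (default; type 0 amounts are
#'   weighted by 1/w) or `"direct_weight"` (weighted by w). The published
#'   rendering of the ratio is typographically ambiguous between the two, so
#'   the reading is a switch rather than a hard-coded choice.
#' @return An object of class `psce_params`.
#' @export
#' @examples
#' psce_params()
psce_params <- function(
    head_terms = c(
      PC = 0.27, PE = 0.33, PS = 0.27, PA = 0.37, PI = 0.23,
      DAG = 0.43, PG = 0.23, TAG = 0.50, CE = 0.20, LPC = 0.15, SM = 0.20
    ),
    unsat_increment = 0.1,
    pivot_species = "PE 34:1",
    included_classes = c("PC", "PE", "PS", "PA", "PI", "DAG"),
    denominator_mode = c("inverse_weight", "direct_weight")) {
  denominator_mode <- match.arg(denominator_mode)
  if (any(!is.finite(head_terms) | head_terms <= 0)) {
    abort("All head-group terms must be finite and > 0")
  }
  if (!is.finite(unsat_increment) || unsat_increment < 0) {
    abort("unsat_increment must be finite and >= 0")
  }
  pivot <- parse_species(pivot_species)
  if (!pivot$lipid_class %in% names(head_terms)) {
    abort("The pivot species' class must have a head-group term")
  }
  structure(
    list(
      head_terms = head_terms, unsat_increment = unsat_increment,
      pivot_species = pivot$species, included_classes = included_classes,
      denominator_mode = denominator_mode
    ),
    class = "psce_params"
  )
}

#' @export
print.psce_params <- function(x, ...) {
  cat(sprintf(
    "<psce_params> pivot %s (w = %.3g), unsat increment %.3g, %s denominator\n",
    x$pivot_species, compute_w(x$pivot_species, x), x$unsat_increment,
    x$denominator_mode
  ))
  cat("  classes:", paste(x$included_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Coarse-grained lipid weighting factor w
#'
#' `w = head_term(class) + unsat_increment * total double bonds`. Under this
#' linear model the per-chain sum of unsaturation increments equals the
#' increment times the species' total double-bond count, so sum compositions
#' are accepted directly.
#'
#' @param species Character vector of species names or a parsed species
#'   tibble.
#' @param params A [psce_params()] object.
#' @return Numeric vector of w values, named by canonical species.
#' @export
#' @examples
#' compute_w(c("PE 34:1", "PE 34:2", "PC 32:0"))
compute_w <- function(species, params = psce_params()) {
  if (is.character(species)) species <- parse_species(species)
  missing <- setdiff(unique(species$lipid_class), names(params$head_terms))
  if (length(missing) > 0L) {
    abort(sprintf("No head-group term for class %s in the w model", missing[1]))
  }
  w <- unname(params$head_terms[species$lipid_class]) +
    params$unsat_increment * species$total_double_bonds
  setNames(w, species$species)
}

#' Classify lipids as type II or type 0 against the pivot
#'
#' Lipids with `w > w(pivot)` are type II; lipids with `w <= w(pivot)` —
#' including the pivot itself and any species exactly on the boundary — are
#' type 0.
#'
#' @inheritParams compute_w
#' @return Tibble with `species`, `w` and `type` (`"type_II"` / `"type_0"`).
#' @export
#' @examples
#' classify_lipids(c("PE 34:1", "PE 34:2", "PC 32:1"))
classify_lipids <- function(species, params = psce_params()) {
  w <- compute_w(species, params)
  w_lp <- unname(compute_w(params$pivot_species, params))
  tibble(
    species = names(w), w = unname(w),
    type = ifelse(unname(w) > w_lp, "type_II", "type_0")
  )
}

#' P_SCE: weighted ratio proxy of total membrane SCE stress
#'
#' For each sample, restricted to the parameter set's lipid classes,
#' `P_SCE = sum_n w_n * [L_II,n] / sum_m g(w_m) * [L_0,m]` where the sums run
#' over all type II and all type 0 species respectively and `g(w) = 1/w`
#' under the default denominator mode. The ratio is invariant to uniform
#' rescaling of the amounts, so nmol and mol\% inputs are equivalent.
#'
#' @param samples Quantified tibble (metadata columns, `species`,
#'   `amount_nmol`).
#' @param params A [psce_params()] object.
#' @return An object of class `sce_psce` with [tidy()] (per-sample `p_sce`,
#'   `numerator`, `denominator`), [glance()] and [autoplot()] methods.
#' @export
psce <- function(samples, params = psce_params()) {
  stopifnot(inherits(params, "psce_params"))
  df <- .drop_standards(samples) |>
    filter(.data$lipid_class %in% params$included_classes)
  if (nrow(df) == 0L) abort("No species from the included classes present")
  keys <- .sample_keys(df)
  comp <- df |>
    group_by(across(all_of(c(keys, "species")))) |>
    summarise(amount_nmol = sum(.data$amount_nmol), .groups = "drop")
  cls <- classify_lipids(unique(comp$species), params)
  comp <- left_join(comp, cls, by = "species")
  g <- switch(params$denominator_mode,
    inverse_weight = function(w) 1 / w,
    direct_weight = function(w) w
  )
  res <- comp |>
    group_by(across(all_of(keys))) |>
    summarise(
      numerator = sum(.data$w[.data$type == "type_II"] *
                        .data$amount_nmol[.data$type == "type_II"]),
      denominator = sum(g(.data$w[.data$type == "type_0"]) *
                          .data$amount_nmol[.data$type == "type_0"]),
      .groups = "drop"
    )
  if (any(res$denominator <= 0)) {
    abort(sprintf(
      "P_SCE undefined: no type 0 species with positive amount in sample '%s'",
      res$sample_id[which(res$denominator <= 0)[1]]
    ))
  }
  res$p_sce <- res$numerator / res$denominator
  structure(
    list(samples = res, classification = cls, params = params),
    class = "sce_psce"
  )
}

#' @export
print.sce_psce <- function(x, ...) {
  cat(sprintf(
    "<sce_psce> %d sample(s), pivot %s, %d type II / %d type 0 species\n",
    nrow(x$samples), x$params$pivot_species,
    sum(x$classification$type == "type_II"), sum(x$classification$type == "type_0")
  ))
  print(x$samples, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sce_psce <- function(x, ...) x$samples

#' @exportS3Method generics::glance
glance.sce_psce <- function(x, ...) {
  tibble(
    pivot_species = x$params$pivot_species,
    denominator_mode = x$params$denominator_mode,
    n_samples = nrow(x$samples),
    n_type_II = sum(x$classification$type == "type_II"),
    n_type_0 = sum(x$classification$type == "type_0"),
    mean_p_sce = mean(x$samples$p_sce),
    cv_p_sce = sd(x$samples$p_sce) / mean(x$samples$p_sce)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.sce_psce <- function(object, ...) {
  d <- object$samples
  if (!"time_h" %in% names(d)) d$time_h <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$p_sce)) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Time after choline (h)", y = expression(P[SCE]),
      title = "Total SCE stress proxy"
    ) +
    ggplot2::theme_minimal()
}

#' Calibrate w coefficients by P_SCE variance minimization
#'
#' Selects, from a finite grid of candidate coefficient sets, the one giving
#' the lowest variance of P_SCE across a collection of samples — the
#' selection principle used for the published weighting factors, where the
#' chosen w values minimized P_SCE variance across asynchronous cell
#' populations. Deterministic: ties go to the first grid row.
#'
#' @param samples Quantified tibble containing at least three samples.
#' @param params Baseline [psce_params()]; grid columns override its fields.
#' @param grid A tibble; each row is a candidate. Recognised columns:
#'   `unsat_increment` and `head_<CLASS>` (e.g. `head_PE`).
#' @return The winning `psce_params` object, with the evaluated grid (plus a
#'   `p_sce_variance` column) attached as attribute `"calibration"`.
#' @export
calibrate_w <- function(samples, params = psce_params(), grid) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    abort("calibrate_w needs a non-empty grid of candidate coefficients")
  }
  probe <- psce(samples, params)
  if (nrow(probe$samples) < 3L) {
    abort("calibrate_w needs at least three samples to measure P_SCE variance")
  }
  candidates <- purrr::map(seq_len(nrow(grid)), function(i) {
    p <- params
    row <- grid[i, , drop = FALSE]
    if ("unsat_increment" %in% names(row)) p$unsat_increment <- row$unsat_increment
    head_cols <- grep("^head_", names(row), value = TRUE)
    for (hc in head_cols) {
      p$head_terms[[sub("^head_", "", hc)]] <- row[[hc]]
    }
    p
  })
  variances <- purrr::map_dbl(candidates, function(p) {
    var(psce(samples, p)$samples$p_sce)
  })
  best <- which.min(variances) # which.min returns the first minimum
  out <- candidates[[best]]
  attr(out, "calibration") <- mutate(as_tibble(grid), p_sce_variance = variances)
  out
}
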