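.mean_sd <- function(df, value, by) {
  df |>
    group_by(across(all_of(by))) |>
    summarise(
      mean = mean(.data[[value]]),
      sd = if (dplyr::n() > 1) sd(.data[[value]]) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' End-to-end SCE stress report for a sample collection
#'
#' Runs the whole pipeline on quantified samples and aggregates, per time
#' point, mean and SD of: head-group mol\%, within-class acyl mol\% for the
#' major phospholipid classes, the PC/PE ratio, the lipid SCE stress estimate
#' tau and the P_SCE proxy. When every time point carries at least two
#' replicates, the PC/PE ratio, tau and P_SCE series are additionally tested
#' across time points by one-way ANOVA with Bonferroni pairwise comparisons;
#' with single samples the statistics section is empty. All parameter
#' snapshots are embedded so a report is traceable to the exact variant and
#' coefficient sets used.
#'
#' @param samples Quantified tibble (metadata columns incl. `time_h`,
#'   `species`, `amount_nmol`).
#' @param c0_table,chain_table,variant,k_m Passed to [estimate_tau()].
#' @param params [psce_params()] for the P_SCE stage.
#' @param fa_classes Classes whose within-class composition is reported.
#' @return An object of class `sce_report` with [tidy()], [glance()],
#'   [autoplot()] and [write_report()] support.
#' @export
run_report <- function(samples, c0_table = default_c0_table(),
                       chain_table = default_chain_table(),
                       variant = sce_variant(), k_m = 5.0e-20,
                       params = psce_params(),
                       fa_classes = c("PC", "PE", "PS")) {
  if (!"time_h" %in% names(samples)) abort("run_report needs a time_h column")
  comp <- class_mol_percent(samples)
  fa <- purrr::map(fa_classes, ~ fa_mol_percent(samples, .x) |>
                     mutate(lipid_class = .x)) |> bind_rows()
  ratio <- pc_pe_ratio(samples)
  tau_fit <- estimate_tau(samples, c0_table, chain_table, variant, k_m)
  psce_fit <- psce(samples, params)

  summaries <- list(
    class_composition = .mean_sd(comp, "mol_pct", c("time_h", "lipid_class")),
    fa_composition = .mean_sd(fa, "mol_pct", c("time_h", "lipid_class", "species")),
    pc_pe = .mean_sd(ratio, "pc_pe_ratio", "time_h"),
    tau = .mean_sd(tau_fit$samples, "tau_N", "time_h"),
    p_sce = .mean_sd(psce_fit$samples, "p_sce", "time_h")
  )

  per_sample <- list(pc_pe = ratio, tau = tau_fit$samples, p_sce = psce_fit$samples)
  metric_col <- c(pc_pe = "pc_pe_ratio", tau = "tau_N", p_sce = "p_sce")
  can_test <- all(summaries$pc_pe$n >= 2) && nrow(summaries$pc_pe) >= 2
  stats <- if (can_test) {
    purrr::imap(per_sample, function(d, nm) {
      a <- anova_bonferroni(d, !!rlang::sym(metric_col[[nm]]), !!rlang::sym("time_h"))
      mutate(tidy(a), metric = nm, omnibus_p = a$omnibus$p_value, .before = 1)
    }) |> bind_rows()
  } else {
    tibble()
  }

  structure(
    list(
      summaries = summaries, stats = stats,
      tau_fit = tau_fit, psce_fit = psce_fit,
      provenance = list(
        package = "lipidsce",
        version = as.character(utils::packageVersion("lipidsce")),
        variant = variant, k_m = k_m, psce_params = params,
        n_samples = nrow(ratio)
      )
    ),
    class = "sce_report"
  )
}

#' @export
print.sce_report <- function(x, ...) {
  cat(sprintf(
    "<sce_report> %d sample(s) | tau variant '%s' | pivot %s\n",
    x$provenance$n_samples, x$provenance$variant$name,
    x$provenance$psce_params$pivot_species
  ))
  cat("\nPC/PE ratio (mean +/- SD by time point):\n")
  print(x$summaries$pc_pe)
  cat("\nLipid SCE stress tau (N):\n")
  print(x$summaries$tau)
  cat("\nP_SCE:\n")
  print(x$summaries$p_sce)
  if (nrow(x$stats) > 0) {
    cat("\nPairwise statistics (Bonferroni):\n")
    print(x$stats)
  } else {
    cat("\n(no replicate statistics: fewer than two replicates per time point)\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sce_report <- function(x, ...) {
  bind_rows(
    x$summaries$pc_pe |> mutate(metric = "pc_pe_ratio", .before = 1),
    x$summaries$tau |> mutate(metric = "tau_N", .before = 1),
    x$summaries$p_sce |> mutate(metric = "p_sce", .before = 1)
  )
}

#' @exportS3Method generics::glance
glance.sce_report <- function(x, ...) {
  tau <- x$summaries$tau$mean
  ps <- x$summaries$p_sce$mean
  tibble(
    n_samples = x$provenance$n_samples,
    n_time_points = nrow(x$summaries$tau),
    tau_max_N = max(tau), tau_min_N = min(tau),
    tau_max_min_ratio = max(tau) / min(tau),
    p_sce_max_min_ratio = max(ps) / min(ps),
    cv_tau = sd(tau) / mean(tau),
    cv_p_sce = sd(ps) / mean(ps)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.sce_report <- function(object, ...) {
  d <- tidy(object)
  labels <- c(pc_pe_ratio = "PC/PE ratio", tau_N = "tau (N)", p_sce = "P_SCE")
  d$metric <- factor(labels[d$metric], levels = unname(labels))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean - dplyr::coalesce(.data$sd, 0),
        ymax = .data$mean + dplyr::coalesce(.data$sd, 0)
      ),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Time after choline (h)", y = "mean +/- SD") +
    ggplot2::theme_minimal()
}

#' Plot head-group composition over time
#'
#' @param report An [run_report()] result.
#' @return A ggplot.
#' @export
plot_composition <- function(report) {
  stopifnot(inherits(report, "sce_report"))
  d <- report$summaries$class_composition
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$time_h), y = .data$mean, fill = factor(.data$time_h)
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - dplyr::coalesce(.data$sd, 0),
        ymax = .data$mean + dplyr::coalesce(.data$sd, 0)
      ),
      width = 0.3
    ) +
    ggplot2::facet_wrap(~lipid_class, scales = "free_y") +
    ggplot2::labs(
      x = "Time after choline (h)", y = "mol% total lipid",
      fill = "time (h)"
    ) +
    ggplot2::theme_minimal()
}

#' Write a report to delimited text plus a provenance record
#'
#' Writes each summary table and the statistics as CSV and the full parameter
#' snapshot (variant, K_M, w coefficients, package version) as YAML, so every
#' run is machine-readably traceable.
#'
#' @param report An `sce_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sce_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$summaries)) {
    readr::write_csv(report$summaries[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  readr::write_csv(
    if (nrow(report$stats) > 0) report$stats else tibble(metric = character()),
    file.path(dir, "statistics.csv")
  )
  prov <- report$provenance
  yaml::write_yaml(
    list(
      package = prov$package, version = prov$version,
      n_samples = prov$n_samples,
      k_m_joules = prov$k_m,
      variant = list(
        name = prov$variant$name,
        included_classes = prov$variant$included_classes,
        allow_speculative = prov$variant$allow_speculative
      ),
      psce_params = list(
        head_terms = as.list(prov$psce_params$head_terms),
        unsat_increment = prov$psce_params$unsat_increment,
        pivot_species = prov$psce_params$pivot_species,
        included_classes = prov$psce_params$included_classes,
        denominator_mode = prov$psce_params$denominator_mode
      )
    ),
    file.path(dir, "provenance.yaml")
  )
  invisible(dir)
}
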