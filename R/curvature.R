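#' Default lipid spontaneous-curvature table
#'
#' Spontaneous curvatures C0 = 1/R0 (inverse meters, measured at the pivotal
#' plane; negative for inverse-curvature lipids such as PE, PA and DAG) for
#' the dioleoyl / palmitoyl-oleoyl series that anchors the lookup fallback.
#' Values are rounded literature-scale numbers; rows whose provenance says
#' "estimate" were interpolated by headgroup/chain analogy and the PI row is a
#' speculative class-level default (no measured PI curvatures exist). The
#' table is an editable parameter, not ground truth: replace any row via
#' [read_c0_table()] or plain tibble manipulation.
#'
#' @return Tibble with columns `lipid_class`, `chains` (per-chain composition
#'   text, `NA` for a class-level default), `c0_per_m`, `speculative`,
#'   `provenance`.
#' @export
#' @examples
#' default_c0_table()
default_c0_table <- function() {
  t <- tibble::tribble(
    ~lipid_class, ~chains,     ~c0_per_nm, ~speculative, ~provenance,
    "PE",  "18:1/18:1", -0.350, FALSE, "DOPE; inverse-hexagonal phase X-ray at the pivotal plane",
    "PE",  "16:0/18:1", -0.316, FALSE, "POPE; inverse-hexagonal phase X-ray",
    "PC",  "18:1/18:1", -0.091, FALSE, "DOPC; inverted-phase dual-solvent estimate",
    "PC",  "16:0/18:1", -0.022, FALSE, "POPC; inverted-phase dual-solvent estimate",
    "PC",  "16:0/16:0",  0.000, FALSE, "di-saturated PC; near-cylindrical packing, rounded to zero",
    "PS",  "18:1/18:1",  0.074, FALSE, "DOPS; osmotic-stress estimate, charged headgroup",
    "PS",  "16:0/18:1",  0.020, FALSE, "POPS analog; headgroup-series interpolation (estimate)",
    "PA",  "18:1/18:1", -0.460, FALSE, "DOPA; ionization-dependent, mid-range value",
    "PA",  "16:0/18:1", -0.320, FALSE, "POPA analog; chain-series interpolation (estimate)",
    "PG",  "18:1/18:1", -0.050, FALSE, "DOPG; weakly negative, charged headgroup (estimate)",
    "PG",  "16:0/18:1", -0.040, FALSE, "POPG analog; interpolation (estimate)",
    "DAG", "18:1/18:1", -0.990, FALSE, "dioleoylglycerol; inverse-hexagonal phase X-ray",
    "DAG", "16:0/18:1", -0.890, FALSE, "palmitoyl-oleoyl glycerol; interpolation (estimate)",
    "LPC", "14:0",       0.260, FALSE, "lyso-PC; positive monolayer curvature",
    "PI",  NA,          -0.050, TRUE,  "speculative class-level default; no measured PI curvatures"
  )
  t |>
    mutate(c0_per_m = .data$c0_per_nm * 1e9) |>
    select("lipid_class", "chains", "c0_per_m", "speculative", "provenance")
}

#' Read / write a spontaneous-curvature parameter table
#'
#' Plain CSV with columns `lipid_class`, `chains`, `c0`, `unit` (`per_m` or
#' `per_nm`), `speculative`, `provenance`. Internally everything is held in
#' inverse meters.
#'
#' @param path File path.
#' @return For `read_c0_table()`, a tibble in the shape of
#'   [default_c0_table()].
#' @export
read_c0_table <- function(path) {
  t <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("lipid_class", "chains", "c0", "unit", "speculative", "provenance")
  if (!all(need %in% names(t))) {
    abort(sprintf("C0 table must have columns: %s", paste(need, collapse = ", ")))
  }
  if (!all(t$unit %in% c("per_m", "per_nm"))) abort("C0 unit must be 'per_m' or 'per_nm'")
  if (any(!is.finite(t$c0))) abort("All C0 values must be finite")
  if (any(!nzchar(t$provenance) | is.na(t$provenance))) abort("Every C0 row needs a provenance note")
  t |>
    mutate(c0_per_m = ifelse(.data$unit == "per_nm", .data$c0 * 1e9, .data$c0)) |>
    select("lipid_class", "chains", "c0_per_m", "speculative", "provenance")
}

#' @rdname read_c0_table
#' @param c0_table A C0 table as returned by [default_c0_table()].
#' @export
write_c0_table <- function(c0_table, path) {
  c0_table |>
    mutate(c0 = .data$c0_per_m, unit = "per_m") |>
    select("lipid_class", "chains", "c0", "unit", "speculative", "provenance") |>
    readr::write_csv(path)
  invisible(path)
}

#' Define a class-inclusion variant for the lipid SCE stress estimate
#'
#' The default variant includes exactly the bilayer-forming phospholipid
#' classes PC, PE, PS, PA and PG. PI is excluded by default (no measured
#' curvatures; include it together with `allow_speculative = TRUE` for a
#' sensitivity run) and DAG/TAG are excluded as lipid-droplet associated.
#'
#' @param name Variant label, recorded in every result.
#' @param included_classes Non-empty set of class codes.
#' @param allow_speculative Permit speculative class-level C0 defaults?
#' @return An object of class `sce_variant`.
#' @export
#' @examples
#' sce_variant()
#' sce_variant("with_PI", c("PC", "PE", "PS", "PA", "PG", "PI"),
#'             allow_speculative = TRUE)
sce_variant <- function(name = "default",
                        included_classes = c("PC", "PE", "PS", "PA", "PG"),
                        allow_speculative = FALSE) {
  if (length(included_classes) == 0L) abort("A variant needs a non-empty class set")
  unknown <- setdiff(included_classes, lipid_classes())
  if (length(unknown) > 0L) abort(sprintf("Unknown class in variant: %s", unknown[1]))
  structure(
    list(
      name = name, included_classes = included_classes,
      allow_speculative = isTRUE(allow_speculative)
    ),
    class = "sce_variant"
  )
}

#' @export
print.sce_variant <- function(x, ...) {
  cat(sprintf(
    "<sce_variant '%s'> classes: %s%s\n", x$name,
    paste(x$included_classes, collapse = ", "),
    if (x$allow_speculative) " (speculative C0 allowed)" else ""
  ))
  invisible(x)
}

.chain_key <- function(chains) {
  # order-free chain composition key, isotope labels ignored
  purrr::map_chr(chains, function(ch) {
    if (is.null(ch)) return(NA_character_)
    paste(sort(sprintf("%d:%d", ch$carbons, ch$double_bonds)), collapse = "/")
  })
}

.db_key <- function(chains) {
  purrr::map_chr(chains, function(ch) {
    if (is.null(ch)) return(NA_character_)
    paste(sort(ch$double_bonds), collapse = ",")
  })
}

.prepare_c0 <- function(c0_table) {
  has_chains <- !is.na(c0_table$chains)
  parsed <- purrr::map(c0_table$chains, function(s) {
    if (is.na(s)) return(NULL)
    cm <- stringr::str_match(stringr::str_trim(stringr::str_split(s, "/")[[1]]), .chain_rx)
    tibble(carbons = as.integer(cm[, 3]), double_bonds = as.integer(cm[, 4]))
  })
  c0_table$chain_key <- .chain_key(parsed)
  c0_table$db_key <- .db_key(parsed)
  c0_table$entry_carbons <- purrr::map_int(parsed, function(ch) {
    if (is.null(ch)) NA_integer_ else sum(ch$carbons)
  })
  c0_table
}

#' Look up spontaneous curvatures with the chain-matching fallback
#'
#' For each species: (1) prefer an exact (class, per-chain composition) match;
#' (2) otherwise, among same-class entries with the identical per-chain
#' double-bond multiset, take the entry with minimal absolute total-carbon
#' difference, breaking ties toward the shorter chain (`match_kind =
#' "fallback"`); (3) otherwise, if permitted, use the speculative class-level
#' default. Species that cannot be matched raise an error naming them.
#'
#' @param species Parsed species tibble with chains assigned (see
#'   [parse_species()] and [assign_chains()]), or a character vector of names
#'   (chains are then assigned with the default table).
#' @param c0_table A C0 table, see [default_c0_table()].
#' @param allow_speculative Permit speculative class-level defaults?
#' @return Tibble with `species`, `lipid_class`, `c0_per_m`, `match_kind`
#'   (one of `exact`, `fallback`, `speculative`) and `matched_entry`.
#' @export
#' @examples
#' lookup_c0(c("PE 34:1", "PE 32:2"))
lookup_c0 <- function(species, c0_table = default_c0_table(), allow_speculative = FALSE) {
  if (is.character(species)) species <- assign_chains(parse_species(species))
  if (any(purrr::map_lgl(species$chains, is.null))) {
    abort("lookup_c0 needs species with chains assigned; see assign_chains()")
  }
  tab <- .prepare_c0(c0_table)
  sp_chain_key <- .chain_key(species$chains)
  sp_db_key <- .db_key(species$chains)

  rows <- purrr::map(seq_len(nrow(species)), function(i) {
    cls <- species$lipid_class[i]
    cand <- tab[tab$lipid_class == cls & !is.na(tab$chain_key), , drop = FALSE]
    hit <- cand[cand$chain_key == sp_chain_key[i], , drop = FALSE]
    if (nrow(hit) > 0L) {
      return(tibble(
        c0_per_m = hit$c0_per_m[1], match_kind = "exact", matched_entry = hit$chains[1]
      ))
    }
    cand <- cand[cand$db_key == sp_db_key[i], , drop = FALSE]
    if (nrow(cand) > 0L) {
      dist <- abs(cand$entry_carbons - species$total_carbons[i])
      best <- which(dist == min(dist))
      if (length(best) > 1L) best <- best[which.min(cand$entry_carbons[best])]
      return(tibble(
        c0_per_m = cand$c0_per_m[best], match_kind = "fallback",
        matched_entry = cand$chains[best]
      ))
    }
    spec_row <- tab[tab$lipid_class == cls & is.na(tab$chain_key), , drop = FALSE]
    if (allow_speculative && nrow(spec_row) > 0L) {
      return(tibble(
        c0_per_m = spec_row$c0_per_m[1], match_kind = "speculative",
        matched_entry = NA_character_
      ))
    }
    abort(sprintf(
      "No spontaneous curvature available for species '%s'%s",
      species$species[i],
      if (nrow(spec_row) > 0L) " (speculative defaults disallowed)" else ""
    ))
  })
  bind_cols(species[, c("species", "lipid_class")], bind_rows(rows))
}

#' Ideal-additive-mixing spontaneous curvature
#'
#' The spontaneous curvature of a lipid mixture under ideal additive mixing:
#' the mole-fraction weighted mean of the component curvatures,
#' `C0mix = sum(x_i * C0_i)`. With two components this is
#' `(1 - xB) * C0A + xB * C0B`.
#'
#' @param amounts Non-negative amounts (any common unit; only proportions
#'   matter), at least one positive.
#' @param c0 Spontaneous curvatures, same length, inverse meters.
#' @return `C0mix` in inverse meters.
#' @export
#' @examples
#' mix_c0(c(1, 1), c(-1.0e8, -3.0e8)) # -2.0e8
mix_c0 <- function(amounts, c0) {
  stopifnot(length(amounts) == length(c0))
  if (any(!is.finite(amounts) | amounts < 0)) abort("Amounts must be finite and >= 0")
  total <- sum(amounts)
  if (total <= 0) abort("Undefined composition: all amounts are zero")
  sum((amounts / total) * c0)
}

#' Estimate the lipid contribution to membrane SCE stress
#'
#' For each sample: restrict to the variant's lipid classes, form mole
#' fractions, mix spontaneous curvatures ideally and convert to a stored
#' curvature elastic stress via `tau = -2 * K_M * C0mix`, with a single
#' average monolayer bending modulus `K_M` (default 5.0e-20 J). Internal
#' standards are excluded.
#'
#' @param samples Quantified tibble (metadata columns, `species`,
#'   `amount_nmol`).
#' @param c0_table C0 parameter table, see [default_c0_table()].
#' @param chain_table Chain-assignment table, see [default_chain_table()].
#' @param variant Class-inclusion variant, see [sce_variant()].
#' @param k_m Monolayer bending modulus in joules.
#' @return An object of class `sce_tau`, with [tidy()] (per-sample `c0_mix`
#'   and `tau_N`), [glance()] and [autoplot()] methods.
#' @export
estimate_tau <- function(samples, c0_table = default_c0_table(),
                         chain_table = default_chain_table(),
                         variant = sce_variant(), k_m = 5.0e-20) {
  stopifnot(inherits(variant, "sce_variant"))
  if (!is.finite(k_m) || k_m <= 0) abort("k_m must be a positive bending modulus in joules")
  df <- .drop_standards(samples) |>
    filter(.data$lipid_class %in% variant$included_classes)
  if (nrow(df) == 0L) {
    abort(sprintf(
      "No species from the variant's classes (%s) present",
      paste(variant$included_classes, collapse = ", ")
    ))
  }
  keys <- .sample_keys(df)
  comp <- df |>
    group_by(across(all_of(c(keys, "species")))) |>
    summarise(amount_nmol = sum(.data$amount_nmol), .groups = "drop")

  sp <- assign_chains(parse_species(unique(comp$species)), chain_table)
  lk <- lookup_c0(sp, c0_table, allow_speculative = variant$allow_speculative)
  comp <- left_join(comp, lk[, c("species", "c0_per_m", "match_kind")], by = "species")

  res <- comp |>
    group_by(across(all_of(keys))) |>
    summarise(
      c0_mix_per_m = mix_c0(.data$amount_nmol, .data$c0_per_m),
      .groups = "drop"
    ) |>
    mutate(tau_N = -2 * k_m * .data$c0_mix_per_m)

  structure(
    list(samples = res, lookups = lk, variant = variant, k_m = k_m),
    class = "sce_tau"
  )
}

#' @export
print.sce_tau <- function(x, ...) {
  cat(sprintf(
    "<sce_tau> %d sample(s), variant '%s', K_M = %.3g J\n",
    nrow(x$samples), x$variant$name, x$k_m
  ))
  print(x$samples, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sce_tau <- function(x, ...) x$samples

#' @exportS3Method generics::glance
glance.sce_tau <- function(x, ...) {
  tibble(
    variant = x$variant$name,
    k_m = x$k_m,
    n_samples = nrow(x$samples),
    n_species = nrow(x$lookups),
    n_exact = sum(x$lookups$match_kind == "exact"),
    n_fallback = sum(x$lookups$match_kind == "fallback"),
    n_speculative = sum(x$lookups$match_kind == "speculative"),
    mean_tau_N = mean(x$samples$tau_N),
    cv_tau = sd(x$samples$tau_N) / mean(x$samples$tau_N)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.sce_tau <- function(object, ...) {
  d <- object$samples
  if (!"time_h" %in% names(d)) {
    d$time_h <- seq_len(nrow(d))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$tau_N)) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Time after choline (h)", y = expression(tau ~ "(N)"),
      title = sprintf("Lipid contribution to SCE stress ('%s' variant)", object$variant$name)
    ) +
    ggplot2::theme_minimal()
}

.tau_series <- function(fit) {
  d <- fit$samples
  if ("time_h" %in% names(d)) {
    d |>
      group_by(.data$time_h) |>
      summarise(tau = mean(.data$tau_N), .groups = "drop") |>
      arrange(.data$time_h) |>
      pull("tau")
  } else {
    d$tau_N
  }
}

#' Sensitivity of the SCE stress trend to class-inclusion choices
#'
#' Recomputes the per-time-point mean tau series under each alternate variant
#' (e.g. adding PI with speculative curvatures, or adding DAG) and flags
#' whether the sign pattern of successive differences matches the base
#' variant, i.e. whether the reported trend is preserved.
#'
#' @inheritParams estimate_tau
#' @param base The reference variant.
#' @param alternates List of alternate [sce_variant()] objects.
#' @return An object of class `sce_sensitivity`; [tidy()] returns one row per
#'   variant with `trend_preserved` and the tau series summary.
#' @export
sensitivity_analysis <- function(samples, c0_table = default_c0_table(),
                                 chain_table = default_chain_table(),
                                 base = sce_variant(), alternates = list(),
                                 k_m = 5.0e-20) {
  fits <- c(list(base = estimate_tau(samples, c0_table, chain_table, base, k_m)),
            setNames(
              purrr::map(alternates, ~ estimate_tau(samples, c0_table, chain_table, .x, k_m)),
              purrr::map_chr(alternates, "name")
            ))
  base_series <- .tau_series(fits[[1]])
  if (length(base_series) < 2L) {
    abort("Sensitivity analysis needs a series of at least two samples/time points")
  }
  summary <- purrr::imap(fits, function(fit, nm) {
    s <- .tau_series(fit)
    tibble(
      variant = fit$variant$name,
      n_points = length(s),
      min_tau_N = min(s), max_tau_N = max(s),
      trend_preserved = identical(sign(diff(s)), sign(diff(base_series)))
    )
  }) |> bind_rows()
  structure(list(fits = fits, summary = summary), class = "sce_sensitivity")
}

#' @exportS3Method generics::tidy
tidy.sce_sensitivity <- function(x, ...) x$summary

#' @export
print.sce_sensitivity <- function(x, ...) {
  cat("<sce_sensitivity>\n")
  print(x$summary, ...)
  invisible(x)
}
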