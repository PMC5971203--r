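.stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

.check_groups <- function(values, groups, min_groups = 2L, min_per_group = 2L) {
  if (anyNA(values) || any(!is.finite(values))) abort("Group values must be finite")
  counts <- table(groups)
  if (length(counts) < min_groups) {
    abort(sprintf("Need at least %d groups, got %d", min_groups, length(counts)))
  }
  if (any(counts < min_per_group)) {
    abort(sprintf(
      "Every group needs >= %d values for variance-based tests (group '%s' has %d)",
      min_per_group, names(counts)[which(counts < min_per_group)[1]],
      min(counts)
    ))
  }
  invisible(counts)
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' The omnibus test is a standard one-way analysis of variance. All pairwise
#' group comparisons are then made with pooled-variance (Student) two-sample
#' t tests and Bonferroni-adjusted: `p_adj = min(1, p_raw * m)` where `m` is
#' the number of pairs; with exactly two groups there is a single comparison
#' and no correction is applied (and the omnibus p equals the pooled t test
#' p). Significance tiers follow the usual star convention with significance
#' declared at p < 0.05.
#'
#' @param data A data frame.
#' @param value Column of measurements (tidy-eval).
#' @param group Column of group labels (tidy-eval).
#' @return An object of class `sce_anova`: [glance()] gives the omnibus row,
#'   [tidy()] the pairwise table (`group1`, `group2`, `mean_diff`, `p_raw`,
#'   `p_adj`, `signif`).
#' @export
#' @examples
#' d <- data.frame(g = rep(c("a", "b", "c"), each = 4), y = rnorm(12))
#' tidy(anova_bonferroni(d, y, g))
anova_bonferroni <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  .check_groups(v, g)
  fit <- aov(v ~ factor(g))
  atab <- anova(fit)
  omnibus_p <- atab[["Pr(>F)"]][1]

  labs <- unique(g)
  pairs <- utils::combn(labs, 2L, simplify = FALSE)
  m <- length(pairs)
  pw <- purrr::map(pairs, function(p) {
    x <- v[g == p[1]]
    y <- v[g == p[2]]
    tt <- t.test(x, y, var.equal = TRUE)
    tibble(
      group1 = p[1], group2 = p[2],
      mean_diff = mean(x) - mean(y),
      p_raw = tt$p.value,
      p_adj = min(1, tt$p.value * m)
    )
  }) |>
    bind_rows() |>
    mutate(signif = .stars(.data$p_adj))
  structure(
    list(
      omnibus = tibble(
        statistic = atab[["F value"]][1], df_between = atab[["Df"]][1],
        df_within = atab[["Df"]][2], p_value = omnibus_p,
        n_comparisons = m
      ),
      pairwise = pw
    ),
    class = "sce_anova"
  )
}

#' @exportS3Method generics::tidy
tidy.sce_anova <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.sce_anova <- function(x, ...) x$omnibus

#' @export
print.sce_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.3g, p = %.3g; %d Bonferroni pair(s)\n",
    x$omnibus$df_between, x$omnibus$df_within, x$omnibus$statistic,
    x$omnibus$p_value, x$omnibus$n_comparisons
  ))
  print(x$pairwise, ...)
  invisible(x)
}

#' Two-tailed pooled-variance two-sample t test
#'
#' Student's t test (equal-variance form), two-sided, for exactly two groups.
#'
#' @inheritParams anova_bonferroni
#' @return Tibble with `group1`, `group2`, `mean_diff`, `statistic`, `df`,
#'   `p_value` and `signif`.
#' @export
two_group_t <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  counts <- table(g)
  if (length(counts) != 2L) abort("two_group_t needs exactly two groups")
  .check_groups(v, g)
  labs <- unique(g)
  x <- v[g == labs[1]]
  y <- v[g == labs[2]]
  tt <- t.test(x, y, var.equal = TRUE)
  tibble(
    group1 = labs[1], group2 = labs[2],
    mean_diff = mean(x) - mean(y),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, signif = .stars(tt$p.value)
  )
}
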