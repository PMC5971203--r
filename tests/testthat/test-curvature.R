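test_that("exact table entries are preferred and returned as exact matches", {
  lk <- lookup_c0(parse_species("PE(16:0/18:1)"))
  expect_equal(lk$match_kind, "exact")
  expect_equal(lk$c0_per_m, -0.316e9)
  # chain order must not matter
  lk2 <- lookup_c0(parse_species("PE(18:1/16:0)"))
  expect_equal(lk2$c0_per_m, lk$c0_per_m)
})

test_that("the fallback picks the same-unsaturation entry closest in chain length", {
  tab <- tibble::tibble(
    lipid_class = c("PE", "PE"),
    chains = c("16:1/18:1", "16:1/16:1"), # 34:2 and 32:2, both {1,1}
    c0_per_m = c(-3e8, -2e8),
    speculative = FALSE,
    provenance = "test"
  )
  sp <- parse_species("PE(18:1/18:1)") # 36:2, absent from the table
  lk <- lookup_c0(sp, tab)
  expect_equal(lk$match_kind, "fallback")
  expect_equal(lk$c0_per_m, -3e8) # |36-34| beats |36-32|
})

test_that("carbon-distance ties break toward the shorter chain, deterministically", {
  tab <- tibble::tibble(
    lipid_class = "PE",
    chains = c("16:1/16:1", "18:1/18:1"), # 32:2 and 36:2, both 2 carbons away
    c0_per_m = c(-2e8, -4e8),
    speculative = FALSE, provenance = "test"
  )
  sp <- parse_species("PE(16:1/18:1)") # 34:2
  lk <- lookup_c0(sp, tab)
  expect_equal(lk$c0_per_m, -2e8)
  expect_equal(lk$matched_entry, "16:1/16:1")
})

test_that("fallback choice matches exhaustive enumeration on randomized tables", {
  set.seed(4021)
  carbons_pool <- c(14L, 16L, 18L, 20L)
  for (i in 1:200) {
    n_entries <- sample(2:6, 1)
    entries <- purrr::map_chr(seq_len(n_entries), function(.) {
      c1 <- sample(carbons_pool, 1); c2 <- sample(carbons_pool, 1)
      d1 <- sample(0:2, 1); d2 <- sample(0:2, 1)
      sprintf("%d:%d/%d:%d", c1, d1, c2, d2)
    })
    tab <- tibble::tibble(
      lipid_class = "PE", chains = entries,
      c0_per_m = -runif(n_entries, 1e8, 5e8),
      speculative = FALSE, provenance = "rand"
    )
    c1 <- sample(carbons_pool, 1); c2 <- sample(carbons_pool, 1)
    d1 <- sample(0:2, 1); d2 <- sample(0:2, 1)
    sp <- parse_species(sprintf("PE(%d:%d/%d:%d)", c1, d1, c2, d2))
    want <- oracle_lookup(
      sp$chains[[1]], "PE", sp$total_carbons,
      lipidsce:::.prepare_c0(tab)
    )
    if (is.null(want)) {
      expect_error(lookup_c0(sp, tab), "No spontaneous curvature")
    } else {
      got <- lookup_c0(sp, tab)
      expect_equal(got$c0_per_m, want$c0)
      expect_equal(got$match_kind, want$kind)
    }
  }
})

test_that("PI has no measured curvature: errors unless speculative values are allowed", {
  sp <- assign_chains(parse_species("PI 34:1"))
  expect_error(lookup_c0(sp, allow_speculative = FALSE), "PI 34:1")
  lk <- lookup_c0(sp, allow_speculative = TRUE)
  expect_equal(lk$match_kind, "speculative")
  expect_equal(lk$c0_per_m, -0.05e9)
})

test_that("ideal mixing reproduces the hand-derived two-component case", {
  # equimolar mixture of C0 = -1e8 and -3e8 m^-1
  c0m <- mix_c0(c(1, 1), c(-1.0e8, -3.0e8))
  expect_equal(c0m, -2.0e8)
  # tau = -2 K_M C0mix with K_M = 5e-20 J
  expect_equal(-2 * 5.0e-20 * c0m, 2.0e-11)
  # single-component edge: C0mix is that component's C0
  expect_equal(mix_c0(5, -2.5e8), -2.5e8)
})

test_that("mixing equals a brute-force per-molecule average on integer compositions", {
  set.seed(77)
  for (i in 1:100) {
    k <- sample(1:6, 1)
    counts <- sample(1:40, k, replace = TRUE)
    c0 <- runif(k, -5e8, 2e8)
    expect_equal(mix_c0(counts, c0), bf_mix_c0(counts, c0), tolerance = 1e-12)
  }
})

test_that("C0mix is permutation/scale invariant, bounded, and monotone", {
  set.seed(88)
  a <- runif(5, 0.1, 10)
  c0 <- runif(5, -5e8, 1e8)
  base <- mix_c0(a, c0)
  perm <- sample(5)
  expect_equal(mix_c0(a[perm], c0[perm]), base)
  expect_equal(mix_c0(a * 123.4, c0), base)
  expect_gte(base, min(c0))
  expect_lte(base, max(c0))
  # raising the share of the most negative component drives C0mix down
  # (hence tau = -2 K_M C0mix up)
  worst <- which.min(c0)
  prev <- base
  for (f in c(2, 4, 8)) {
    a2 <- a; a2[worst] <- a[worst] * f
    cur <- mix_c0(a2, c0)
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("tau and C0mix have opposite signs and tau is exactly -2*K_M*C0mix", {
  tc <- generate_timecourse(rescue_scenario(), seed = 9)
  fit <- estimate_tau(tc$samples)
  expect_identical(fit$samples$tau_N, -2 * fit$k_m * fit$samples$c0_mix_per_m)
  expect_true(all(sign(fit$samples$tau_N) == -sign(fit$samples$c0_mix_per_m)))
})

test_that("the PC-depleted state carries the highest lipid SCE stress", {
  tc <- generate_timecourse(rescue_scenario(noise_cv = 0, n_replicates = 1), seed = 10)
  fit <- estimate_tau(tc$samples)
  d <- dplyr::arrange(fit$samples, time_h)
  expect_equal(which.max(d$tau_N), 1L)
  expect_gt(d$tau_N[1], d$tau_N[nrow(d)])
})

test_that("variants validate their class sets and lookups fail without parameters", {
  expect_error(sce_variant(included_classes = character()), "non-empty")
  expect_error(sce_variant(included_classes = "XYZ"), "Unknown class")
  tc <- generate_timecourse(rescue_scenario(), seed = 13)
  expect_error(
    estimate_tau(tc$samples, variant = sce_variant("pi", c("PC", "PE", "PI"))),
    "PI"
  )
})

test_that("trend sensitivity: identical alternates give zero delta; PI and DAG preserve trends", {
  tc <- generate_timecourse(rescue_scenario(), seed = 14)
  s0 <- sensitivity_analysis(tc$samples, alternates = list(sce_variant()))
  expect_true(all(tidy(s0)$trend_preserved))
  expect_equal(tidy(s0)$min_tau_N[1], tidy(s0)$min_tau_N[2])

  alts <- list(
    sce_variant("with_PI", c("PC", "PE", "PS", "PA", "PG", "PI"), allow_speculative = TRUE),
    sce_variant("with_DAG", c("PC", "PE", "PS", "PA", "PG", "DAG"))
  )
  s <- sensitivity_analysis(tc$samples, alternates = alts)
  expect_true(all(tidy(s)$trend_preserved))
})
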