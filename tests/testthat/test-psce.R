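test_that("the pivot's weight anchors the classification boundary", {
  p <- psce_params()
  w_lp <- unname(compute_w(p$pivot_species, p))
  cls <- classify_lipids(c("PE 34:1", "PE 34:2", "PE 32:1", "PC 32:0"), p)
  # the pivot itself and anything at exactly w_Lp is type 0
  expect_equal(cls$type[cls$species == "PE 34:1"], "type_0")
  expect_equal(cls$type[cls$species == "PE 32:1"], "type_0") # same w as pivot
  # one more double bond crosses the boundary
  expect_equal(cls$type[cls$species == "PE 34:2"], "type_II")
  expect_gt(cls$w[cls$species == "PE 34:2"], w_lp)
  # saturated PC is type 0 under the shipped coefficients
  expect_equal(cls$type[cls$species == "PC 32:0"], "type_0")
})

test_that("w is the head term plus the unsaturation increment per double bond", {
  p <- psce_params()
  expect_equal(unname(compute_w("PE 34:0", p)), unname(p$head_terms["PE"]))
  expect_equal(
    unname(compute_w("PE 34:3", p) - compute_w("PE 34:2", p)),
    p$unsat_increment
  )
  # strictly increasing in unsaturation
  w <- compute_w(sprintf("PC 34:%d", 0:4), p)
  expect_true(all(diff(w) > 0))
  expect_error(compute_w("PC 34:1", psce_params(head_terms = c(PE = 0.33))), "PC")
})

test_that("raising the pivot's weight never converts type 0 into type II", {
  sp <- c("PC 32:0", "PC 34:2", "PE 32:1", "PE 34:2", "PA 34:1", "DAG 36:2")
  lo <- classify_lipids(sp, psce_params(pivot_species = "PE 34:1"))
  hi <- classify_lipids(sp, psce_params(pivot_species = "PE 34:3"))
  was_0 <- lo$species[lo$type == "type_0"]
  expect_true(all(hi$type[hi$species %in% was_0] == "type_0"))
})

test_that("the ratio control function matches its hand-evaluated example", {
  # one type II lipid (w = 2, amount 10) over one type 0 lipid (w = 1,
  # amount 10) with the inverse-weight denominator: 2*10 / (10/1) = 2
  p <- psce_params(
    head_terms = c(PE = 1, PC = 1, DAG = 2),
    unsat_increment = 0, pivot_species = "PE 34:1"
  )
  s <- make_sample(c("DAG 34:1" = 10, "PC 34:1" = 10))
  fit <- psce(s, p)
  expect_equal(fit$samples$numerator, 20)
  expect_equal(fit$samples$denominator, 10)
  expect_equal(fit$samples$p_sce, 2)
  # direct-weight reading of the denominator is available as a switch
  p2 <- psce_params(
    head_terms = c(PE = 1, PC = 1, DAG = 2), unsat_increment = 0,
    pivot_species = "PE 34:1", denominator_mode = "direct_weight"
  )
  expect_equal(psce(s, p2)$samples$p_sce, 2) # w = 1 so both readings agree
})

test_that("all-type-0 compositions give zero; no positive type 0 amount is an error", {
  p <- tenth_grid_params()
  expect_equal(psce(make_sample(c("PC 34:1" = 5, "PE 34:1" = 3)), p)$samples$p_sce, 0)
  expect_error(
    psce(make_sample(c("PE 34:2" = 5, "PC 34:1" = 0)), p),
    "no type 0 species with positive amount"
  )
})

test_that("P_SCE is scale-invariant and monotone in each type's amounts", {
  s <- make_sample(c(
    "PC 34:1" = 30, "PC 34:2" = 10, "PE 34:1" = 12, "PE 34:2" = 8,
    "PS 32:1" = 4, "DAG 34:1" = 2
  ))
  p <- psce_params()
  base <- psce(s, p)$samples$p_sce
  expect_equal(psce(dplyr::mutate(s, amount_nmol = amount_nmol * 7), p)$samples$p_sce,
               base, tolerance = 1e-12)
  bump <- function(spec, f) {
    psce(dplyr::mutate(s, amount_nmol = ifelse(species == spec, amount_nmol * f, amount_nmol)),
         p)$samples$p_sce
  }
  expect_gt(bump("PE 34:2", 2), base)  # more type II raises stress
  expect_lt(bump("PC 34:1", 2), base)  # more type 0 lowers it
})

test_that("P_SCE agrees exactly with a rational-arithmetic oracle on integer inputs", {
  p <- tenth_grid_params()
  set.seed(55)
  pool_II <- c("PE 34:2", "PE 36:3", "PA 34:1", "DAG 34:1", "DAG 36:2")
  pool_0 <- c("PC 34:1", "PC 32:0", "PE 34:1", "PI 34:1", "PS 32:1")
  for (i in 1:50) {
    sp_II <- sample(pool_II, sample(1:3, 1))
    sp_0 <- sample(pool_0, sample(2:4, 1))
    a_II <- sample(1:30, length(sp_II), replace = TRUE)
    a_0 <- sample(1:30, length(sp_0), replace = TRUE)
    s <- make_sample(setNames(c(a_II, a_0), c(sp_II, sp_0)))
    got <- psce(s, p)$samples$p_sce
    w10_II <- round(10 * unname(compute_w(sp_II, p)))
    w10_0 <- round(10 * unname(compute_w(sp_0, p)))
    want <- rational_psce(a_II, w10_II, a_0, w10_0)
    expect_equal(got, want, tolerance = 1e-13)
    # sanity: the sampled pools really are type II / type 0 under these params
    cls <- classify_lipids(c(sp_II, sp_0), p)
    expect_equal(cls$type, rep(c("type_II", "type_0"), c(length(sp_II), length(sp_0))))
  }
})

test_that("w calibration returns the grid point minimizing P_SCE variance", {
  p <- psce_params()
  # populations constructed so that, under the true increment, the weighted
  # type II pool is constant: w1*a1 + w2*a2 = 12 with two 2-double-bond species
  w1 <- unname(compute_w("PE 34:2", p))
  w2 <- unname(compute_w("DAG 36:2", p))
  samples <- purrr::map(1:6, function(i) {
    a1 <- 2 + i
    a2 <- (12 - w1 * a1) / w2
    make_sample(
      c("PE 34:2" = a1, "DAG 36:2" = a2, "PC 34:1" = 50),
      sample_id = sprintf("pop%d", i)
    )
  }) |> dplyr::bind_rows()
  grid <- tibble::tibble(unsat_increment = seq(0.025, 0.2, by = 0.025))
  won <- calibrate_w(samples, p, grid)
  expect_equal(won$unsat_increment, 0.1)
  cal <- attr(won, "calibration")
  expect_equal(nrow(cal), nrow(grid))
  expect_equal(cal$p_sce_variance[cal$unsat_increment == 0.1], 0, tolerance = 1e-20)
  # identity: a grid holding only the current coefficients returns them
  same <- calibrate_w(samples, p, tibble::tibble(unsat_increment = p$unsat_increment))
  expect_equal(same$unsat_increment, p$unsat_increment)
})

test_that("calibration refuses degenerate inputs", {
  p <- psce_params()
  one <- make_sample(c("PE 34:2" = 5, "PC 34:1" = 50))
  expect_error(calibrate_w(one, p, tibble::tibble(unsat_increment = 0.1)),
               "at least three samples")
  three <- dplyr::bind_rows(purrr::map(1:3, ~ make_sample(
    c("PE 34:2" = 5, "PC 34:1" = 50), sample_id = paste0("s", .x)
  )))
  expect_error(calibrate_w(three, p, tibble::tibble()), "non-empty grid")
})
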