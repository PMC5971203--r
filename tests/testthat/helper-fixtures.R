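# fixtures and independent oracles shared across the suite

# one-sample quantified tibble from named amounts
make_sample <- function(amounts, sample_id = "s1", condition = "test",
                        time_h = 0, replicate = 1L) {
  tibble::tibble(
    sample_id = sample_id, condition = condition, time_h = time_h,
    replicate = replicate,
    species = names(amounts), amount_nmol = unname(amounts)
  )
}

# brute-force mixing oracle: expand an integer composition to one row per
# molecule and average the per-molecule spontaneous curvatures
bf_mix_c0 <- function(counts, c0) {
  stopifnot(all(counts == round(counts)))
  mean(rep(c0, times = counts))
}

# exhaustive-enumeration oracle for the C0 fallback rule; works on a prepared
# table representation independent of the package's lookup path
oracle_lookup <- function(sp_chains, sp_class, sp_carbons, table) {
  # table: data.frame with lipid_class, chain_key, db_key, entry_carbons, c0_per_m
  sp_chain_key <- paste(sort(sprintf("%d:%d", sp_chains$carbons, sp_chains$double_bonds)),
                        collapse = "/")
  sp_db_key <- paste(sort(sp_chains$double_bonds), collapse = ",")
  cand <- table[table$lipid_class == sp_class, , drop = FALSE]
  exact <- cand[cand$chain_key == sp_chain_key, , drop = FALSE]
  if (nrow(exact) > 0) return(list(c0 = exact$c0_per_m[1], kind = "exact"))
  cand <- cand[cand$db_key == sp_db_key, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(abs(cand$entry_carbons - sp_carbons), cand$entry_carbons), , drop = FALSE]
  list(c0 = cand$c0_per_m[1], kind = "fallback")
}

# exact rational-arithmetic P_SCE oracle: integer amounts, w values that are
# integer multiples of 1/10, inverse-weight denominator. All intermediate
# products stay far below 2^53 so double arithmetic is exact.
rational_psce <- function(amounts_II, w10_II, amounts_0, w10_0) {
  num10 <- sum(w10_II * amounts_II)          # numerator * 10
  prod0 <- prod(w10_0)
  den_num <- sum(vapply(seq_along(w10_0), function(m) {
    10 * amounts_0[m] * prod(w10_0[-m])
  }, numeric(1)))                            # denominator * prod0
  (num10 * prod0) / (10 * den_num)
}

# w-model params on a 1/10 grid for exact-arithmetic comparisons
tenth_grid_params <- function() {
  psce_params(
    head_terms = c(PC = 0.4, PE = 0.7, PS = 0.5, PA = 0.8, PI = 0.4, DAG = 0.9,
                   PG = 0.4, TAG = 1.0, CE = 0.3, LPC = 0.2, SM = 0.3),
    unsat_increment = 0.1,
    pivot_species = "PE 34:1"
  )
}
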