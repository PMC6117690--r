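# Shared fixture builders: everything is generated in code at test time.

small_config <- function(n = 100, seed = 11, lethality = 0, ...) {
  generator_config(n_strains = n, lethality = lethality, seed = seed, ...)
}

# a deterministic three-reaction chain whose polytope is a single point
point_chain_model <- function() {
  metabolic_model(
    data.frame(rxn_id = c("UPT", "R1", "EXP"), subsystem = "chain",
               lb = c(1, 0, 0), ub = c(1, 10, 10),
               stringsAsFactors = FALSE),
    list(UPT = c(A = 1), R1 = c(A = -1, B = 1), EXP = c(B = -1)),
    target_reaction = "R1")
}

# brute-force re-evaluation of the two fluorescence threshold rules,
# strain by strain and rule by rule, independent of fluorescence_filter()
brute_force_fluorescence <- function(plate) {
  ids <- sort(unique(plate$strain_id))
  pass <- logical(length(ids))
  for (i in seq_along(ids)) {
    rows <- plate[plate$strain_id == ids[i], ]
    m_od <- mean(rows$od625)
    m_chl <- mean(rows$rfu_chla)
    m_nr <- mean(rows$rfu_nilered)
    pass[i] <- (m_chl >= 2309 * m_od - 24.3) &&
      (m_nr >= 167.1 * m_od - 0.21)
  }
  ids[pass]
}
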