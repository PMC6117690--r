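test_that("toy network loads identically from TSV and SBML", {
  toy <- build_toy_network()
  tsv <- load_model(system.file("extdata", "toy_network.tsv",
                                package = "fucoscreen"))
  sbml <- load_model(system.file("extdata", "toy_network_sbml.xml",
                                 package = "fucoscreen"))
  for (m in list(tsv, sbml)) {
    expect_identical(m$S[rownames(toy$S), colnames(toy$S)], toy$S)
    expect_equal(m$reactions$lb, toy$reactions$lb)
    expect_equal(m$reactions$ub, toy$reactions$ub)
    expect_identical(m$reactions$subsystem, toy$reactions$subsystem)
  }
})

test_that("toy network has the expected pathway structure", {
  toy <- build_toy_network()
  # fucoxanthin and chlorophyll branches both consume GGPP
  expect_lt(toy$S["ggpp_p", "PSY"], 0)
  expect_lt(toy$S["ggpp_p", "GGDR"], 0)
  expect_true(all(c("carotenoid biosynthesis",
                    "porphyrin and chlorophyll metabolism",
                    "lipid metabolism", "fatty acid elongation") %in%
                    toy$reactions$subsystem))
  expect_equal(toy$target_reaction, "FUCO_SYN")
  # feasible with positive target flux
  fs <- sample_fluxes(toy, n_samples = 50, seed = 1)
  expect_gt(max(fs$samples[, "FUCO_SYN"]), 0)
})

test_that("model parsing reports malformed input precisely", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rxn_id\tsubsystem\tlb\tub\tequation",
               "R1\ts\t0\t1\t1 a_c -> 1 b_c",
               "R2\ts\t0\t1\tnonsense equation here"), tmp)
  expect_error(load_model(tmp), "row 2")
  writeLines(c("rxn_id\tsubsystem\tlb\tub\tequation",
               "R1\ts\t2\t1\t1 a_c -> 1 b_c"), tmp)
  expect_error(load_model(tmp, target_reaction = "R1"), "lb > ub")
  writeLines(c("rxn_id\tsubsystem\tlb\tub\tequation",
               "R1\ts\t0\t1\t1 a_c -> 1 b_c"), tmp)
  expect_error(load_model(tmp, target_reaction = "NOPE"), "target")
})

test_that("model writers round-trip through their readers", {
  toy <- build_toy_network()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  xml <- withr::local_tempfile(fileext = ".xml")
  write_model_tsv(toy, tsv)
  write_model_sbml(toy, xml)
  for (m in list(load_model(tsv), load_model(xml))) {
    expect_identical(m$S[rownames(toy$S), colnames(toy$S)], toy$S)
    expect_equal(m$reactions[, c("lb", "ub")], toy$reactions[, c("lb", "ub")])
  }
})

test_that("samples satisfy steady state and bounds, reproducibly", {
  toy <- build_toy_network()
  fs <- sample_fluxes(toy, n_samples = 400, seed = 5)
  expect_lte(max(fs$residuals), 1e-8)
  lb <- toy$reactions$lb; ub <- toy$reactions$ub
  expect_true(all(t(fs$samples) >= lb - 1e-9))
  expect_true(all(t(fs$samples) <= ub + 1e-9))
  fs2 <- sample_fluxes(toy, n_samples = 400, seed = 5)
  expect_identical(fs$samples, fs2$samples)
  expect_error(sample_fluxes(toy, n_samples = 1), ">= 2")
  expect_error(sample_fluxes(toy, method = "gibbs"), "unknown sampling")
})

test_that("a fully determined chain collapses to its unique flux point", {
  chain <- point_chain_model()
  fs <- sample_fluxes(chain, n_samples = 20, seed = 2)
  expect_true(fs$point_polytope)
  expect_equal(unname(fs$samples),
               matrix(1, 20, 3), tolerance = 1e-9)
  # zero-variance target: correlation analysis must refuse
  expect_error(correlate_with_target(fs), "zero variance")
})

test_that("infeasible bounds are rejected at the feasibility solve", {
  bad <- metabolic_model(
    data.frame(rxn_id = c("IN", "OUT"), subsystem = "x",
               lb = c(2, 0), ub = c(3, 1), stringsAsFactors = FALSE),
    list(IN = c(A = 1), OUT = c(A = -1)), "OUT")
  expect_error(sample_fluxes(bad, n_samples = 10, seed = 1), "infeasible")
})

test_that("stoichiometric coupling gives unit correlation to machine precision", {
  toy <- build_toy_network()
  fs <- sample_fluxes(toy, n_samples = 600, seed = 7)
  rep <- correlate_with_target(fs)
  # PSY -> FUCO_SYN -> DM_FUCO is a 1:1 linear chain
  chain_ids <- c("PSY", "FUCO_SYN", "DM_FUCO")
  expect_equal(rep$r[match(chain_ids, rep$rxn_id)], rep(1, 3),
               tolerance = 1e-12)
  expect_equal(max(abs(fs$samples[, "PSY"] - fs$samples[, "FUCO_SYN"])), 0,
               tolerance = 1e-12)
})

test_that("a disconnected subnetwork is uncorrelated with the target", {
  toy <- build_toy_network()
  fs <- sample_fluxes(toy, n_samples = 5000, seed = 9)
  rep <- correlate_with_target(fs)
  expect_lt(abs(rep$r[rep$rxn_id == "EX_URA"]), 0.1)
  expect_lt(abs(rep$r[rep$rxn_id == "DM_URA"]), 0.1)
})

test_that("a rival branch on a fixed precursor supply is anticorrelated", {
  cm <- build_competition_network()
  fs <- sample_fluxes(cm, n_samples = 1000, seed = 11)
  rep <- correlate_with_target(fs)
  r_rival <- rep$r[rep$rxn_id == "BRANCH_B"]
  expect_lt(r_rival, 0)
  # brute-force oracle: dense grid over the 1-simplex of splits
  f <- seq(0, 1, by = 0.001)
  oracle_sign <- sign(cor(f, 1 - f))
  expect_equal(sign(r_rival), oracle_sign)
  # the split constraint makes the anticorrelation exact
  expect_equal(r_rival, -1, tolerance = 1e-12)
  # the fixed supply itself has no variance and is flagged, not dropped
  expect_true(rep$zero_variance[rep$rxn_id == "SRC"])
  expect_true(is.na(rep$r[rep$rxn_id == "SRC"]))
})

test_that("correlation estimates are stable under sample doubling", {
  toy <- build_toy_network()
  r1 <- correlate_with_target(sample_fluxes(toy, 2500, seed = 13))$r
  r2 <- correlate_with_target(sample_fluxes(toy, 5000, seed = 14))$r
  expect_lt(max(abs(r1 - r2), na.rm = TRUE), 0.05)
})

test_that("classification partitions reactions and is threshold-monotone", {
  toy <- build_toy_network()
  fs <- sample_fluxes(toy, n_samples = 800, seed = 15)
  rep <- correlate_with_target(fs)
  cls <- classify_correlations(rep, threshold = 0.7)
  counts <- table(cls$report$class)
  expect_equal(sum(counts), nrow(rep))
  # target correlates with itself
  expect_equal(rep$r[rep$rxn_id == "FUCO_SYN"], 1)
  # threshold 1: only exactly-coupled reactions classified
  strict <- classify_correlations(rep, threshold = 1)
  classified_strict <- strict$report$rxn_id[strict$report$class !=
                                              "uncorrelated"]
  expect_true(all(classified_strict %in% c("PSY", "FUCO_SYN", "DM_FUCO")))
  expect_true("FUCO_SYN" %in% classified_strict)
  # lowering the threshold never shrinks the classified set
  prev <- character(0)
  for (thr in c(0.9, 0.7, 0.5, 0.3)) {
    cl <- classify_correlations(rep, thr)
    now <- cl$report$rxn_id[cl$report$class != "uncorrelated"]
    expect_true(all(prev %in% now))
    prev <- now
  }
  expect_error(classify_correlations(rep, 0), "threshold")
  # subsystem summary covers every subsystem once
  expect_setequal(cls$subsystem_summary$subsystem,
                  unique(toy$reactions$subsystem))
})

test_that("blocked reactions are those with zero bounds", {
  toy <- build_toy_network()
  toy$reactions$ub[toy$reactions$rxn_id == "EX_URA"] <- 0
  blocked_model <- metabolic_model(
    toy$reactions,
    stats::setNames(lapply(colnames(toy$S), function(r) {
      s <- toy$S[, r]; s[s != 0]
    }), colnames(toy$S)),
    "FUCO_SYN")
  fs <- sample_fluxes(blocked_model, n_samples = 300, seed = 17)
  blk <- blocked_reactions(fs)
  expect_true(all(c("EX_URA", "DM_URA") %in% blk))
  expect_false("FUCO_SYN" %in% blk)
})
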